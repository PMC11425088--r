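#' Dual-illumination movie container
#'
#' A `T x H x W` intensity stack acquired under alternating blue
#' (calcium-sensitive) and green (reflectance) illumination, with optional
#' per-frame channel labels.
#'
#' @param frames numeric array `c(T, H, W)`.
#' @param fps_total interleaved acquisition rate (frames/s); per-channel
#'   rate is half of it. Default 30 (15 per channel).
#' @param labels optional per-frame labels in
#'   `{"blue","green","outlier","unlabeled"}`.
#' @return A list of class `dual_channel_movie`.
#' @export
dual_channel_movie <- function(frames, fps_total = 30, labels = NULL) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[1] >= 2)
  if (!is.null(labels)) stopifnot(length(labels) == dim(frames)[1])
  structure(list(frames = frames, fps_total = fps_total,
                 labels = labels %||% rep("unlabeled", dim(frames)[1])),
            class = "dual_channel_movie")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify frames into blue/green channels and flag outliers
#'
#' Two-means clustering on per-frame mean intensity separates the blue
#' and green illumination populations (initialized at the intensity
#' extremes, so the result is deterministic). By convention the brighter
#' cluster is blue (configurable). Frames farther than `outlier_sd` robust
#' SDs (MAD) from their cluster's robust center are relabeled `outlier` —
#' these are LED dropouts or gross motion artifacts.
#'
#' @param movie a [dual_channel_movie].
#' @param outlier_sd robust-SD multiple for outlier flagging, default 5.
#' @param blue_brighter is the blue channel the brighter one? Default TRUE.
#' @return Character vector of per-frame labels.
#' @export
segregate_channels <- function(movie, outlier_sd = 5, blue_brighter = TRUE) {
  x <- apply(movie$frames, 1, mean)
  if (diff(range(x)) == 0)
    stop("separability error: constant frame intensities, cannot cluster")
  km <- stats::kmeans(x, centers = matrix(range(x), 2, 1))
  cl <- km$cluster
  ctr <- vapply(1:2, function(k) stats::median(x[cl == k]), 0)
  rsd <- vapply(1:2, function(k) stats::mad(x[cl == k]), 0)
  lab01 <- c("a", "b")[cl]
  out <- abs(x - ctr[cl]) > outlier_sd * rsd[cl]
  pooled <- sqrt(mean(rsd[is.finite(rsd)]^2))
  if (abs(ctr[1] - ctr[2]) < 2 * pooled)
    stop("separability error: channel intensity clusters overlap")
  bright <- which.max(ctr)
  blue_k <- if (blue_brighter) bright else (3 - bright)
  labels <- ifelse(cl == blue_k, "blue", "green")
  labels[out] <- "outlier"
  labels
}

#' Rigid motion correction by FFT cross-correlation
#'
#' Estimates a per-frame integer translation against a template (mean of
#' the first `k` frames by default, or a given frame) from the peak of the
#' circular cross-correlation, and removes it. All-zero frames get shift 0
#' with a warning.
#'
#' @param stack single-channel `T x H x W` array.
#' @param template `"mean_first_k"` or an integer frame index.
#' @param k number of leading frames averaged for the template, default 10.
#' @return `list(corrected = stack, shifts = T x 2 integer matrix (dy, dx))`.
#' @export
rigid_motion_correct <- function(stack, template = "mean_first_k", k = 10) {
  d <- dim(stack)
  stopifnot(length(d) == 3, d[1] >= 2)
  Tn <- d[1]; H <- d[2]; W <- d[3]
  tmpl <- if (identical(template, "mean_first_k")) {
    kk <- min(k, Tn)
    apply(stack[seq_len(kk), , , drop = FALSE], c(2, 3), mean)
  } else {
    stack[as.integer(template), , ]
  }
  Ft <- stats::fft(tmpl)
  shifts <- matrix(0L, Tn, 2)
  corrected <- stack
  wrap <- function(i, n) { s <- i - 1L; as.integer(if (s > n / 2) s - n else s) }
  zero_warned <- FALSE
  for (t in seq_len(Tn)) {
    fr <- stack[t, , ]
    if (all(fr == 0)) {
      if (!zero_warned) { warning("all-zero frame(s): shift set to 0"); zero_warned <- TRUE }
      next
    }
    cc <- Re(stats::fft(stats::fft(fr) * Conj(Ft), inverse = TRUE))
    pk <- arrayInd(which.max(cc), c(H, W))
    dy <- wrap(pk[1], H); dx <- wrap(pk[2], W)
    shifts[t, ] <- c(dy, dx)
    if (dy != 0 || dx != 0) corrected[t, , ] <- roll_matrix(fr, -dy, -dx)
  }
  list(corrected = corrected, shifts = shifts)
}

#' Area-weighted bilinear binning
#'
#' Resamples each frame to `round(f * H) x round(f * W)` by exact
#' area-overlap averaging (each output pixel is the area-weighted mean of
#' the input pixels it covers), so the frame mean is preserved. The
#' preprocessing chain compresses frames to 80% of their original size.
#'
#' @param x a `T x H x W` stack, a single `H x W` frame, or a logical mask.
#' @param target_fraction linear scale factor in (0, 1], default 0.8.
#' @return Resampled stack/frame of the same kind (masks are re-thresholded
#'   at 0.5 coverage).
#' @export
spatial_bin <- function(x, target_fraction = 0.8) {
  stopifnot(target_fraction > 0, target_fraction <= 1)
  if (target_fraction == 1) return(x)
  is_mask <- is.logical(x)
  bin_frame <- function(fr, Wr, Wc) Wr %*% fr %*% t(Wc)
  if (length(dim(x)) == 3) {
    d <- dim(x)
    Wr <- area_weights(d[2], max(1L, round(target_fraction * d[2])))
    Wc <- area_weights(d[3], max(1L, round(target_fraction * d[3])))
    out <- array(0, c(d[1], nrow(Wr), nrow(Wc)))
    for (t in seq_len(d[1])) out[t, , ] <- bin_frame(x[t, , ], Wr, Wc)
    out
  } else {
    fr <- if (is_mask) (x * 1) else x
    Wr <- area_weights(nrow(fr), max(1L, round(target_fraction * nrow(fr))))
    Wc <- area_weights(ncol(fr), max(1L, round(target_fraction * ncol(fr))))
    out <- bin_frame(fr, Wr, Wc)
    if (is_mask) out >= 0.5 else out
  }
}

# m x n row-stochastic matrix of fractional overlaps between n input cells
# and m equal output cells spanning the same interval
area_weights <- function(n, m) {
  scale <- n / m
  Wt <- matrix(0, m, n)
  for (i in seq_len(m)) {
    lo <- (i - 1) * scale; hi <- i * scale
    j0 <- floor(lo) + 1; j1 <- ceiling(hi)
    for (j in j0:min(j1, n)) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) Wt[i, j] <- ov / scale
    }
  }
  Wt
}

#' Average per-trial brain masks into a consensus mask
#'
#' A pixel enters the averaged mask when it is present in at least a
#' `vote` fraction of the per-trial masks (majority vote at the default
#' 0.5; `vote = 1` gives the intersection).
#'
#' @param masks list of logical `H x W` matrices of identical shape.
#' @param vote inclusion threshold in (0, 1], default 0.5.
#' @return Logical consensus mask.
#' @export
average_masks <- function(masks, vote = 0.5) {
  stopifnot(length(masks) >= 1, vote > 0, vote <= 1)
  d <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) identical(dim(m), d), TRUE)))
    stop("mask shape mismatch")
  Reduce(`+`, lapply(masks, function(m) m * 1)) / length(masks) >= vote
}

#' DF/F with ratiometric hemodynamic correction
#'
#' Per in-mask pixel, `DF/F = (F - F0) / F0` is computed for the blue
#' (calcium) and green (reflectance) stacks against a baseline `F0` (the
#' per-pixel trial mean by default, or a rolling percentile). The
#' hemodynamically corrected signal divides out the shared reflectance
#' fluctuation ratiometrically:
#' `(1 + DF/F_blue) / (1 + DF/F_green) - 1`. A regression alternative
#' (subtracting the least-squares projection of the green DF/F from the
#' blue, per pixel) is available. Out-of-mask pixels are zero and excluded
#' from all statistics.
#'
#' @param blue,green paired single-channel `T x H x W` stacks with equal
#'   frame counts.
#' @param mask logical `H x W` brain mask.
#' @param baseline `"trial_mean"` or `"rolling_percentile"`.
#' @param method `"ratiometric"` (default) or `"regression"`.
#' @param window_s,percentile rolling-baseline parameters (window seconds
#'   at `fps`, default 30 s, 10th percentile).
#' @param fps per-channel frame rate (needed for the rolling baseline).
#' @return `list(corrected = , uncorrected = )`, both `T x H x W` DF/F
#'   stacks (dimensionless).
#' @export
compute_dff <- function(blue, green, mask, baseline = c("trial_mean", "rolling_percentile"),
                        method = c("ratiometric", "regression"),
                        window_s = 30, percentile = 0.1, fps = 15) {
  baseline <- match.arg(baseline)
  method <- match.arg(method)
  stopifnot(identical(dim(blue), dim(green)),
            identical(dim(blue)[2:3], dim(mask)))
  d <- dim(blue); Tn <- d[1]; P <- d[2] * d[3]
  mb <- matrix(blue, Tn, P); mg <- matrix(green, Tn, P)
  inm <- as.vector(mask)
  dff_of <- function(m) {
    f0 <- if (baseline == "trial_mean") {
      matrix(colMeans(m), Tn, P, byrow = TRUE)
    } else {
      w <- max(3L, round(window_s * fps))
      apply(m, 2, function(x) rolling_quantile(x, w, percentile))
    }
    if (any(f0[, inm] <= 0))
      stop("baseline error: F0 <= 0 at an in-mask pixel")
    (m - f0) / f0
  }
  db <- dff_of(mb); dg <- dff_of(mg)
  corr <- if (method == "ratiometric") {
    (1 + db) / (1 + dg) - 1
  } else {
    out <- db
    for (j in which(inm)) {
      g <- dg[, j]
      vg <- sum(g^2)
      out[, j] <- if (vg > 0) db[, j] - (sum(db[, j] * g) / vg) * g else db[, j]
    }
    out
  }
  db[, !inm] <- 0; corr[, !inm] <- 0
  list(corrected = array(corr, d), uncorrected = array(db, d))
}

rolling_quantile <- function(x, w, p) {
  n <- length(x); h <- w %/% 2
  vapply(seq_len(n), function(i)
    stats::quantile(x[max(1, i - h):min(n, i + h)], p, names = FALSE), 0)
}

#' Zero-phase Chebyshev band-pass filter
#'
#' Chebyshev type-I band-pass (cutoffs 0.1 and 5 Hz by default) applied
#' forward and backward (`signal::filtfilt`) for zero phase distortion; DC
#' is removed. The per-channel sampling rate must exceed twice the upper
#' cutoff.
#'
#' @param x numeric vector, `T x P` matrix, or `T x H x W` array; time runs
#'   along the first dimension.
#' @param fps per-channel sampling rate in frames/s.
#' @param low_hz,high_hz band edges in Hz, defaults 0.1 and 5.
#' @param order filter order, default 2.
#' @param ripple_db pass-band ripple in dB, default 0.2 (keeps the
#'   two-pass pass-band gain above 0.9).
#' @return Filtered object of the same shape.
#' @export
temporal_bandpass <- function(x, fps, low_hz = 0.1, high_hz = 5,
                              order = 2, ripple_db = 0.2) {
  if (fps <= 2 * high_hz)
    stop("parameter error: sampling rate ", fps,
         " fps cannot support a ", high_hz, " Hz cutoff")
  bf <- signal::cheby1(order, ripple_db, c(low_hz, high_hz) / (fps / 2),
                       type = "pass")
  f1 <- function(v) signal::filtfilt(bf, v - mean(v))
  if (is.null(dim(x))) return(f1(x))
  d <- dim(x)
  m <- matrix(x, d[1], prod(d[-1]))
  keep <- which(apply(m, 2, function(v) any(v != v[1])))
  out <- matrix(0, d[1], ncol(m))
  for (j in keep) out[, j] <- f1(m[, j])
  array(out, d)
}

#' Mask-aware spatial box smoothing
#'
#' Each in-mask pixel is replaced by the mean of the in-mask pixels inside
#' a `size_px x size_px` window centered on it (the 7-pixel
#' nearest-neighbor average of the preprocessing chain); out-of-mask
#' neighbors are excluded, out-of-mask pixels stay zero. A disk kernel of
#' radius `(size_px - 1) / 2` is available as an alternative reading of
#' the neighborhood.
#'
#' @param x `T x H x W` stack or `H x W` frame.
#' @param mask logical `H x W` mask.
#' @param size_px odd window size, default 7.
#' @param kernel `"box"` (default) or `"disk"`.
#' @return Smoothed object of the same shape.
#' @export
spatial_smooth <- function(x, mask, size_px = 7, kernel = c("box", "disk")) {
  kernel <- match.arg(kernel)
  stopifnot(size_px %% 2 == 1)
  kmat <- if (kernel == "box") matrix(1, size_px, size_px) else {
    r <- (size_px - 1) / 2
    yy <- matrix(-r:r, size_px, size_px); xx <- t(yy)
    (yy^2 + xx^2 <= r^2) * 1
  }
  den <- conv2_same(mask * 1, kmat)
  smooth_frame <- function(fr) {
    num <- conv2_same(fr * mask, kmat)
    out <- matrix(0, nrow(fr), ncol(fr))
    out[mask] <- num[mask] / den[mask]
    out
  }
  if (length(dim(x)) == 3) {
    out <- x
    for (t in seq_len(dim(x)[1])) out[t, , ] <- smooth_frame(x[t, , ])
    out
  } else smooth_frame(x)
}

# 2D "same" convolution with zero padding (kernel of odd size)
conv2_same <- function(m, k) {
  H <- nrow(m); W <- ncol(m); kh <- nrow(k); kw <- ncol(k)
  ph <- kh %/% 2; pw <- kw %/% 2
  pad <- matrix(0, H + 2 * ph, W + 2 * pw)
  pad[ph + seq_len(H), pw + seq_len(W)] <- m
  out <- matrix(0, H, W)
  for (a in seq_len(kh)) for (b in seq_len(kw)) {
    if (k[a, b] == 0) next
    out <- out + k[a, b] * pad[(a - 1) + seq_len(H), (b - 1) + seq_len(W)]
  }
  out
}

#' Per-pixel temporal z-scoring
#'
#' Standardizes each in-mask pixel's time series to mean 0 and SD 1, using
#' the population (N-denominator) SD. Zero-variance in-mask pixels are set
#' to 0 and counted in the `n_flat` attribute.
#'
#' @param x `T x H x W` stack.
#' @param mask logical `H x W` mask.
#' @return Z-scored stack; out-of-mask pixels are 0.
#' @export
zscore_pixels <- function(x, mask) {
  d <- dim(x); Tn <- d[1]
  m <- matrix(x, Tn, prod(d[-1]))
  inm <- as.vector(mask)
  mu <- colMeans(m)
  sdp <- sqrt(colMeans(m^2) - mu^2)
  out <- matrix(0, Tn, ncol(m))
  flat <- 0L
  for (j in which(inm)) {
    if (sdp[j] > 0) out[, j] <- (m[, j] - mu[j]) / sdp[j] else flat <- flat + 1L
  }
  res <- array(out, d)
  attr(res, "n_flat") <- flat
  res
}

#' Run the full preprocessing chain in its canonical order
#'
#' Segregate channels -> motion-correct -> bin -> mask -> DF/F (with
#' hemodynamic correction) -> temporal band-pass -> spatial smooth ->
#' per-pixel z-score. The stage order is fixed; a `stages` subset must
#' respect it (out-of-order requests are rejected), which guards against
#' accidentally, say, z-scoring before filtering.
#'
#' Blue frames are paired with their nearest-in-time green frame after
#' outlier removal, giving equal-length channel stacks on the per-channel
#' clock (half the interleaved rate).
#'
#' @param movie a [dual_channel_movie].
#' @param mask logical `H x W` brain mask at the raw movie resolution
#'   (default: all pixels).
#' @param stages character vector of stages to run, a subsequence of
#'   `c("segregate","motion_correct","bin","dff","bandpass","smooth","zscore")`.
#' @param bin_fraction linear binning factor, default 0.8.
#' @param dff_method,baseline passed to [compute_dff].
#' @param low_hz,high_hz,order,ripple_db passed to [temporal_bandpass].
#' @param smooth_px passed to [spatial_smooth], default 7.
#' @param outlier_sd passed to [segregate_channels], default 5.
#' @return A list of class `dff_movie`: `dff` (`T x H' x W'`, z-scored
#'   corrected DF/F), `fps_channel`, `mask` (binned), `labels`,
#'   `shifts_blue`, `shifts_green`, `qc` (outlier count, flat-pixel count,
#'   stage list).
#' @export
run_calcium_pipeline <- function(movie, mask = NULL,
                                 stages = c("segregate", "motion_correct", "bin",
                                            "dff", "bandpass", "smooth", "zscore"),
                                 bin_fraction = 0.8,
                                 dff_method = "ratiometric",
                                 baseline = "trial_mean",
                                 low_hz = 0.1, high_hz = 5, order = 2,
                                 ripple_db = 0.2, smooth_px = 7,
                                 outlier_sd = 5) {
  canon <- c("segregate", "motion_correct", "bin", "dff", "bandpass",
             "smooth", "zscore")
  if (!all(stages %in% canon))
    stop("unknown stage(s): ", paste(setdiff(stages, canon), collapse = ", "))
  if (is.unsorted(match(stages, canon)))
    stop("out-of-order stage request: required order is ",
         paste(canon, collapse = " -> "))
  d <- dim(movie$frames)
  if (is.null(mask)) mask <- matrix(TRUE, d[2], d[3])
  labels <- if ("segregate" %in% stages)
    segregate_channels(movie, outlier_sd = outlier_sd) else movie$labels
  bi <- which(labels == "blue"); gi <- which(labels == "green")
  if (!length(bi) || !length(gi)) stop("segregation found an empty channel")
  # nearest green for each blue, by frame index
  gi_for_b <- vapply(bi, function(b) gi[which.min(abs(gi - b))], 0L)
  blue <- movie$frames[bi, , , drop = FALSE]
  green <- movie$frames[gi_for_b, , , drop = FALSE]
  shifts_b <- shifts_g <- NULL
  if ("motion_correct" %in% stages) {
    mcb <- rigid_motion_correct(blue); blue <- mcb$corrected; shifts_b <- mcb$shifts
    mcg <- rigid_motion_correct(green); green <- mcg$corrected; shifts_g <- mcg$shifts
  }
  if ("bin" %in% stages && bin_fraction < 1) {
    blue <- spatial_bin(blue, bin_fraction)
    green <- spatial_bin(green, bin_fraction)
    mask <- spatial_bin(mask, bin_fraction)
  }
  fps_ch <- movie$fps_total / 2
  out <- blue
  if ("dff" %in% stages) {
    dd <- compute_dff(blue, green, mask, baseline = baseline,
                      method = dff_method, fps = fps_ch)
    out <- dd$corrected
  }
  if ("bandpass" %in% stages)
    out <- temporal_bandpass(out, fps = fps_ch, low_hz = low_hz,
                             high_hz = high_hz, order = order,
                             ripple_db = ripple_db)
  if ("smooth" %in% stages) out <- spatial_smooth(out, mask, size_px = smooth_px)
  n_flat <- 0L
  if ("zscore" %in% stages) {
    out <- zscore_pixels(out, mask)
    n_flat <- attr(out, "n_flat") %||% 0L
  }
  structure(list(dff = out, fps_channel = fps_ch, mask = mask,
                 labels = labels, shifts_blue = shifts_b,
                 shifts_green = shifts_g,
                 qc = list(n_outliers = sum(labels == "outlier"),
                           n_flat_pixels = n_flat, stages = stages)),
            class = "dff_movie")
}

#' Read or write a movie as a multi-page TIFF stack
#'
#' @param path TIFF file path.
#' @param movie a [dual_channel_movie] (for writing).
#' @param fps_total interleaved rate attached on reading.
#' @param scale intensity divisor mapping to TIFF's [0,1] range (uint16
#'   full scale by default).
#' @name movie_tiff
#' @return `read_movie_tiff` returns a [dual_channel_movie];
#'   `write_movie_tiff` returns `path` invisibly.
NULL

#' @rdname movie_tiff
#' @export
read_movie_tiff <- function(path, fps_total = 30, scale = 65535) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF I/O")
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (t in seq_along(pages)) arr[t, , ] <- pages[[t]] * scale
  dual_channel_movie(arr, fps_total = fps_total)
}

#' @rdname movie_tiff
#' @export
write_movie_tiff <- function(movie, path, scale = 65535) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF I/O")
  pages <- lapply(seq_len(dim(movie$frames)[1]), function(t)
    pmin(pmax(movie$frames[t, , ] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}
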