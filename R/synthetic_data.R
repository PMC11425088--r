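# All generators take an explicit integer seed and restore the caller's RNG
# state on exit; no global random state leaks.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Generate an arena-constrained trajectory with known heading truth
#'
#' Produces a two-keypoint pose stream (head, tailbase) together with its
#' ground truth: position in meters, continuous unwrapped heading angle
#' (degrees, clockwise-positive in the y-down image view) and cumulative
#' signed rotation. The animal is modeled as a rigid two-point body of
#' fixed length; heading follows a Gaussian turn-rate random walk and the
#' body advances along the heading at `mean_speed`, stopping at walls.
#'
#' When `n_full_turns` is given the trajectory is a scripted pirouette: the
#' body stays at the arena center and rotates at a constant rate so that
#' the net cumulative rotation is exactly `360 * n_full_turns` degrees
#' (signed; positive = clockwise).
#'
#' @param arena an [arena_spec].
#' @param duration_s trajectory duration in seconds.
#' @param mean_speed forward speed in m/s (default 0.1, a mouse at a walk).
#' @param turn_rate_sd standard deviation of the heading turn rate in
#'   deg/s (default 60).
#' @param n_full_turns optional signed number of full turns (pirouette mode).
#' @param body_length_px head-tailbase distance in pixels, default 60.
#' @param seed integer seed; identical seeds give identical streams.
#' @return `list(stream = pose_stream, truth = data.frame)` where truth has
#'   per-frame `x_m`, `y_m`, `heading_deg` (unwrapped) and `cumrot_deg`
#'   (heading relative to the first frame).
#' @export
generate_trajectory <- function(arena, duration_s, mean_speed = 0.1,
                                turn_rate_sd = 60, n_full_turns = NULL,
                                body_length_px = 60, seed = 1L) {
  stopifnot(duration_s > 0)
  n <- max(2L, as.integer(round(duration_s * arena$fps)))
  if (mean_speed / arena$fps > arena$size_m)
    stop("infeasible speed: the animal would leave the arena within one frame")
  with_seed(seed, {
    if (!is.null(n_full_turns)) {
      heading <- seq(0, 360 * n_full_turns, length.out = n)
      cx <- arena$size_m / 2
      pos <- cbind(rep(cx, n), rep(arena$size_m / 2, n))
      if (arena$kind == "linear") pos[, 2] <- 0.05
    } else {
      heading <- cumsum(c(stats::runif(1, 0, 360),
                          stats::rnorm(n - 1, 0, turn_rate_sd / arena$fps)))
      pos <- matrix(0, n, 2)
      half_body_m <- (body_length_px / 2 + 2) / arena$px_per_m
      pos[1, ] <- c(arena$size_m / 2, arena$size_m / 2)
      if (arena$kind == "linear") pos[1, 2] <- 0.05
      step_m <- mean_speed / arena$fps
      inside <- function(p) {
        if (arena$kind == "circular") {
          sqrt(sum((p - arena$size_m / 2)^2)) < arena$size_m / 2 - half_body_m
        } else if (arena$kind == "linear") {
          p[1] > half_body_m && p[1] < arena$size_m - half_body_m
        } else {
          all(p > half_body_m) && all(p < arena$size_m - half_body_m)
        }
      }
      for (i in 2:n) {
        th <- heading[i] * pi / 180
        cand <- pos[i - 1, ] + step_m * c(cos(th), sin(th))
        if (arena$kind == "linear") cand[2] <- pos[i - 1, 2]
        pos[i, ] <- if (inside(cand)) cand else pos[i - 1, ]
      }
    }
    th <- heading * pi / 180
    half <- body_length_px / 2
    center_px <- pos * arena$px_per_m
    head_px <- center_px + half * cbind(cos(th), sin(th))
    tail_px <- center_px - half * cbind(cos(th), sin(th))
    stream <- pose_stream(frame = seq_len(n) - 1L,
                          head_x = head_px[, 1], head_y = head_px[, 2],
                          tail_x = tail_px[, 1], tail_y = tail_px[, 2],
                          head_conf = 1, tail_conf = 1,
                          timestamp_s = (seq_len(n) - 1) / arena$fps)
    truth <- data.frame(frame = stream$frame, x_m = pos[, 1], y_m = pos[, 2],
                        heading_deg = heading,
                        cumrot_deg = heading - heading[1])
    list(stream = stream, truth = truth)
  })
}

#' Corrupt a pose stream with confidence dropouts and positional jitter
#'
#' Emulates occlusions and tracker noise: a fraction of frames (Bernoulli
#' per frame at `dropout_rate`) receive confidences drawn uniformly below
#' the gate value, so they fail the confidence gate; the remaining frames
#' get i.i.d. Gaussian jitter on both keypoints. Confidences are untouched
#' when `dropout_rate` is 0, coordinates when `jitter_sd_px` is 0.
#'
#' @param stream a [pose_stream].
#' @param dropout_rate fraction of dropped frames, in [0, 1).
#' @param jitter_sd_px Gaussian jitter SD in pixels.
#' @param gate confidence value the dropouts fall below, default 0.9.
#' @param seed integer seed.
#' @return A corrupted [pose_stream].
#' @export
corrupt_poses <- function(stream, dropout_rate = 0, jitter_sd_px = 0,
                          gate = 0.9, seed = 1L) {
  stopifnot(dropout_rate >= 0, dropout_rate < 1)
  if (dropout_rate == 0 && jitter_sd_px == 0) return(stream)
  n <- nrow(stream)
  with_seed(seed, {
    drop <- stats::runif(n) < dropout_rate
    if (any(drop)) {
      stream$head_conf[drop] <- stats::runif(sum(drop), 0, gate)
      stream$tail_conf[drop] <- stats::runif(sum(drop), 0, gate)
    }
    keep <- !drop
    if (jitter_sd_px > 0 && any(keep)) {
      k <- sum(keep)
      stream$head_x[keep] <- stream$head_x[keep] + stats::rnorm(k, 0, jitter_sd_px)
      stream$head_y[keep] <- stream$head_y[keep] + stats::rnorm(k, 0, jitter_sd_px)
      stream$tail_x[keep] <- stream$tail_x[keep] + stats::rnorm(k, 0, jitter_sd_px)
      stream$tail_y[keep] <- stream$tail_y[keep] + stats::rnorm(k, 0, jitter_sd_px)
    }
    stream
  })
}

#' Generate a dual-illumination calcium movie with known truth
#'
#' Interleaved blue/green stack emulating alternating-illumination
#' wide-field imaging. Blue frames carry exponential-kernel calcium
#' transients from Gaussian-footprint cells plus a shared multiplicative
#' hemodynamic artifact; green frames carry the hemodynamic artifact only.
#' A fixed number `round(outlier_frac * T)` of frames are zeroed (LED
#' dropout), putting their mean intensity far outside either channel
#' cluster. Per-frame rigid integer shifts up to `max_shift_px` are applied
#' as toroidal shifts (a synthetic-data simplification that makes planted
#' shifts exactly recoverable); the first frame is unshifted.
#'
#' @param shape `c(T, H, W)`; T must be even.
#' @param n_cells number of synthetic cells, default 6.
#' @param transient_tau_s calcium decay time constant in seconds, default 1.
#' @param hemo_amp hemodynamic artifact amplitude as a fraction of baseline,
#'   default 0.05.
#' @param outlier_frac fraction of outlier frames, default 0 (the system's
#'   observed rate is about 0.0004).
#' @param max_shift_px maximum rigid shift in pixels, default 0.
#' @param blue_mean,green_mean baseline channel intensities; must differ.
#' @param noise_sd additive Gaussian noise SD, default 2.
#' @param pattern_amp relative SD of a static smooth multiplicative
#'   baseline pattern shared by both channels (emulating vasculature and
#'   uneven illumination; it is what anchors motion correction), default
#'   0.1.
#' @param event_rate_hz per-cell transient rate, default 0.2.
#' @param amp transient amplitude as a fraction of baseline, default 0.2.
#' @param fps_total interleaved acquisition rate, default 30 (15 per channel).
#' @param seed integer seed.
#' @return `list(movie = dual_channel_movie, truth = list(...))`. Truth
#'   holds the per-frame channel labels, outlier positions, planted shifts,
#'   the brain mask, per-cell and mask-mean calcium time courses (per
#'   channel sample), and the hemodynamic time course.
#' @export
generate_movie <- function(shape = c(200, 32, 32), n_cells = 6,
                           transient_tau_s = 1, hemo_amp = 0.05,
                           outlier_frac = 0, max_shift_px = 0,
                           blue_mean = 200, green_mean = 80,
                           noise_sd = 2, pattern_amp = 0.1,
                           event_rate_hz = 0.2, amp = 0.2,
                           fps_total = 30, seed = 1L) {
  Tn <- shape[1]; H <- shape[2]; W <- shape[3]
  if (Tn %% 2 != 0) stop("frame count must be even (alternating channels)")
  if (blue_mean == green_mean)
    stop("blue_mean must differ from green_mean (channel separability)")
  fps_ch <- fps_total / 2
  nch <- Tn %/% 2
  with_seed(seed, {
    # brain mask: centered disk
    yy <- matrix(seq_len(H), H, W); xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    mask <- ((yy - (H + 1) / 2)^2 + (xx - (W + 1) / 2)^2) <= (0.42 * min(H, W))^2
    # cell footprints (Gaussian blobs inside the mask)
    sig <- min(H, W) / 12
    cells <- matrix(0, H * W, n_cells)
    idx_in <- which(mask)
    centers <- idx_in[sample.int(length(idx_in), n_cells)]
    for (k in seq_len(n_cells)) {
      cy <- (centers[k] - 1) %% H + 1; cx <- (centers[k] - 1) %/% H + 1
      fp <- exp(-(((yy - cy)^2 + (xx - cx)^2) / (2 * sig^2)))
      fp[!mask] <- 0
      cells[, k] <- as.vector(fp / max(fp))
    }
    # per-cell event trains convolved with exponential decay
    kern <- exp(-(0:ceiling(5 * transient_tau_s * fps_ch)) / (transient_tau_s * fps_ch))
    traces <- matrix(0, nch, n_cells)
    for (k in seq_len(n_cells)) {
      ev <- stats::rbinom(nch, 1, min(1, event_rate_hz / fps_ch))
      tr <- stats::convolve(ev, rev(kern), type = "open")[seq_len(nch)]
      traces[, k] <- tr
    }
    # static multiplicative baseline pattern (vasculature/vignetting stand-in)
    pattern <- matrix(1, H, W)
    if (pattern_amp > 0) {
      g <- stats::dnorm(-4:4, 0, 2); g <- g / sum(g)
      raw <- conv2_same(matrix(stats::rnorm(H * W), H, W), outer(g, g))
      pattern <- 1 + pattern_amp * raw / stats::sd(raw)
      pattern <- pmax(pattern, 0.2)
    }
    # shared hemodynamic artifact: slow sinusoid + smoothed noise
    tt <- (seq_len(nch) - 1) / fps_ch
    hemo <- if (hemo_amp > 0) {
      flen <- min(15, nch)
      raw <- sin(2 * pi * 0.3 * tt) + 0.5 * as.numeric(
        stats::filter(stats::rnorm(nch), rep(1 / flen, flen), sides = 2,
                      circular = TRUE))
      hemo_amp * raw / stats::sd(raw)
    } else rep(0, nch)
    frames <- array(0, c(Tn, H, W))
    labels <- rep(c("blue", "green"), nch)
    shifts <- matrix(0L, Tn, 2)
    if (max_shift_px > 0 && Tn > 1)
      shifts[-1, ] <- matrix(sample((-as.integer(max_shift_px)):as.integer(max_shift_px),
                                    2 * (Tn - 1), replace = TRUE), ncol = 2)
    ca_field <- cells %*% t(traces) * amp   # (H*W) x nch
    for (t in seq_len(Tn)) {
      j <- (t + 1) %/% 2
      base <- if (labels[t] == "blue") {
        blue_mean * pattern * (1 + matrix(ca_field[, j], H, W)) * (1 + hemo[j])
      } else {
        green_mean * pattern * (1 + hemo[j])
      }
      fr <- base + matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
      if (any(shifts[t, ] != 0)) fr <- roll_matrix(fr, shifts[t, 1], shifts[t, 2])
      frames[t, , ] <- pmax(fr, 0)
    }
    n_out <- round(outlier_frac * Tn)
    out_idx <- integer(0)
    if (n_out > 0) {
      out_idx <- sort(sample.int(Tn - 1, n_out) + 1L)  # never the template frame
      for (t in out_idx) frames[t, , ] <- 0
      labels[out_idx] <- "outlier"
    }
    movie <- dual_channel_movie(frames, fps_total = fps_total)
    truth <- list(labels = labels, outliers = out_idx, shifts = shifts,
                  mask = mask, pattern = pattern,
                  cell_footprints = cells, cell_traces = traces,
                  calcium_mean = as.numeric(colMeans(ca_field[as.vector(mask), ,
                                                              drop = FALSE])),
                  hemo = hemo, fps_channel = fps_ch)
    list(movie = movie, truth = truth)
  })
}

# toroidal shift of a matrix by (dy, dx); positive dy moves content down
roll_matrix <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  m[((seq_len(H) - 1 - dy) %% H) + 1, ((seq_len(W) - 1 - dx) %% W) + 1, drop = FALSE]
}
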