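#' Commutation epochs
#'
#' @param start_frame,end_frame integer half-open frame ranges.
#' @param direction `"CW"` or `"CCW"` per epoch.
#' @param magnitude_deg rotation magnitude per epoch in degrees.
#' @return A data.frame of class `epoch_table`.
#' @export
epoch_table <- function(start_frame, end_frame, direction = "CW",
                        magnitude_deg = NA_real_) {
  stopifnot(all(end_frame > start_frame))
  d <- data.frame(start_frame = as.integer(start_frame),
                  end_frame = as.integer(end_frame),
                  direction = rep_len(direction, length(start_frame)),
                  magnitude_deg = rep_len(magnitude_deg, length(start_frame)))
  d <- d[order(d$start_frame), ]
  if (nrow(d) > 1 && any(d$start_frame[-1] < d$end_frame[-nrow(d)]))
    stop("epochs overlap")
  class(d) <- c("epoch_table", "data.frame")
  d
}

#' Epochs from a closed-loop run log
#'
#' Turns each rotation command in a [run_closed_loop] log into a
#' commutation epoch lasting `|rotate_deg| / rotation_speed_dps` seconds.
#'
#' @param log a `run_log`.
#' @param fps frame rate of the trace the epochs will index into.
#' @param rotation_speed_dps motor speed, default 100 deg/s.
#' @return An [epoch_table].
#' @export
epochs_from_run_log <- function(log, fps, rotation_speed_dps = 100) {
  cm <- log$commands[log$commands$kind == "rotate_by", ]
  if (!nrow(cm)) stop("no rotation commands in run log")
  dur <- ceiling(abs(cm$rotate_deg) / rotation_speed_dps * fps)
  epoch_table(cm$frame, cm$frame + pmax(1, dur),
              direction = ifelse(cm$rotate_deg >= 0, "CW", "CCW"),
              magnitude_deg = abs(cm$rotate_deg))
}

#' Extract ROI-mean traces from a processed movie
#'
#' @param dff a `dff_movie` (from [run_calcium_pipeline]) or a
#'   `T x H x W` array.
#' @param roi_masks named list of logical `H x W` masks (e.g. atlas
#'   regions); each must contain at least one in-brain pixel.
#' @return Named list of `roi_trace` objects (`roi_name`, `series`, `fps`).
#' @export
extract_roi_traces <- function(dff, roi_masks) {
  arr <- if (inherits(dff, "dff_movie")) dff$dff else dff
  fps <- if (inherits(dff, "dff_movie")) dff$fps_channel else NA_real_
  brain <- if (inherits(dff, "dff_movie")) dff$mask else NULL
  d <- dim(arr)
  m <- matrix(arr, d[1], d[2] * d[3])
  out <- lapply(names(roi_masks), function(nm) {
    rm_ <- roi_masks[[nm]]
    stopifnot(identical(dim(rm_), d[2:3]))
    sel <- as.vector(rm_ & (brain %||% TRUE))
    if (!any(sel)) stop("empty ROI (no in-mask pixels): ", nm)
    structure(list(roi_name = nm,
                   series = rowMeans(m[, sel, drop = FALSE]),
                   fps = fps),
              class = "roi_trace")
  })
  names(out) <- names(roi_masks)
  out
}

#' Peri-event time histogram (event-aligned average)
#'
#' Averages the trace in a window around each epoch onset. Events whose
#' window does not fit inside the trial are dropped with a warning.
#'
#' @param trace an `roi_trace` (or numeric vector with `fps` given).
#' @param epochs an [epoch_table].
#' @param window_s `c(pre, post)` seconds around onset; default
#'   `c(2, 10)` (long enough to cover a 720-degree rotation at ~100 deg/s).
#' @param fps sampling rate, taken from the trace when available.
#' @return A list of class `peth`: `time_s`, `mean_trace`, `n_events`,
#'   `event_matrix` (events x timepoints).
#' @export
peth <- function(trace, epochs, window_s = c(2, 10), fps = NULL) {
  series <- if (inherits(trace, "roi_trace")) trace$series else trace
  fps <- fps %||% (if (inherits(trace, "roi_trace")) trace$fps else NULL)
  if (is.null(fps) || !is.finite(fps)) stop("fps required")
  pre <- round(window_s[1] * fps); post <- round(window_s[2] * fps)
  n <- length(series)
  on <- epochs$start_frame + 1L  # epochs are 0-based frames
  ok <- (on - pre) >= 1 & (on + post) <= n
  if (any(!ok)) warning(sum(!ok), " event(s) too close to the trial edge dropped")
  on <- on[ok]
  if (!length(on)) stop("zero usable events")
  idx <- outer(on, (-pre):post, `+`)
  em <- matrix(series[idx], nrow = length(on))
  structure(list(time_s = ((-pre):post) / fps,
                 mean_trace = colMeans(em),
                 n_events = length(on), event_matrix = em,
                 window_frames = c(pre, post)),
            class = "peth")
}

#' Bootstrap null distribution for a PETH
#'
#' Draws `n_boot` surrogate PETHs: each surrogate averages `n_events`
#' windows whose onsets are drawn uniformly at random (with replacement)
#' from the whole trial, matching the real event count so the surrogate
#' and real averages share the same sampling variance. Returns the
#' per-timepoint mean and SD over surrogates, plus the surrogate matrix
#' for empirical tail probabilities.
#'
#' @param trace an `roi_trace` or numeric vector.
#' @param window_frames `c(pre, post)` window in frames.
#' @param n_events events per surrogate group, default 10.
#' @param n_boot number of surrogates, default 1000.
#' @param exclude optional epoch_table whose frames are excluded from
#'   onset draws (default NULL: draw from the entire trial, events
#'   included).
#' @param seed integer seed.
#' @return A list of class `peth_null`: `null_mean`, `null_sd`
#'   (population SD over surrogates), `surrogates` (n_boot x timepoints).
#' @export
bootstrap_null <- function(trace, window_frames, n_events = 10,
                           n_boot = 1000, exclude = NULL, seed = 1L) {
  series <- if (inherits(trace, "roi_trace")) trace$series else trace
  pre <- window_frames[1]; post <- window_frames[2]
  n <- length(series)
  if (n <= pre + post + 1) stop("trial shorter than the PETH window")
  valid <- (pre + 1):(n - post)
  if (!is.null(exclude)) {
    bad <- unlist(mapply(seq, exclude$start_frame + 1L, exclude$end_frame,
                         SIMPLIFY = FALSE))
    valid <- setdiff(valid, bad)
    if (!length(valid)) stop("exclusion leaves no valid onsets")
  }
  with_seed(seed, {
    wlen <- pre + post + 1
    on <- valid[sample.int(length(valid), n_boot * n_events, replace = TRUE)]
    idx <- outer(on, (-pre):post, `+`)
    M <- matrix(series[idx], n_boot * n_events, wlen)
    sur <- rowsum(M, rep(seq_len(n_boot), each = n_events)) / n_events
    mu <- colMeans(sur)
    sdv <- sqrt(colMeans(sur^2) - mu^2)
    structure(list(null_mean = mu, null_sd = sdv, surrogates = sur,
                   n_events = n_events, n_boot = n_boot),
              class = "peth_null")
  })
}

#' Bonferroni-corrected significance flags for a PETH
#'
#' Per timepoint, the empirical two-sided bootstrap tail probability of
#' the observed PETH value under the surrogate distribution is compared
#' against `alpha / m_tests`. The tail probability uses the add-one
#' estimator `(1 + #{|surrogate - null_mean| >= |observed - null_mean|})
#' / (n_boot + 1)`. An SD-threshold approximation (flag when the deviation
#' exceeds the normal quantile of the corrected level times the null SD)
#' is available as a variant.
#'
#' @param p a `peth`.
#' @param null a `peth_null` computed on the same window.
#' @param alpha family-wise level, default 0.05.
#' @param m_tests number of tests corrected for; defaults to the number
#'   of timepoints in the window (multiply by the ROI count upstream when
#'   correcting across ROIs).
#' @param method `"empirical"` (default) or `"sd"`.
#' @return Logical vector of per-timepoint significance flags.
#' @export
flag_significance <- function(p, null, alpha = 0.05, m_tests = NULL,
                              method = c("empirical", "sd")) {
  method <- match.arg(method)
  m_tests <- m_tests %||% length(p$mean_trace)
  stopifnot(m_tests >= 1)
  dev <- abs(p$mean_trace - null$null_mean)
  level <- alpha / m_tests
  if (method == "empirical") {
    sdev <- abs(sweep(null$surrogates, 2, null$null_mean))
    pvals <- (1 + colSums(sdev >= rep(dev, each = nrow(sdev)))) /
      (nrow(sdev) + 1)
    pvals < level
  } else {
    z <- stats::qnorm(1 - level / 2)
    dev > z * pmax(null$null_sd, .Machine$double.eps)
  }
}

#' Write an epoch table or PETH result to disk
#'
#' @param epochs an [epoch_table]; written as CSV.
#' @param p a `peth`; written with its null and flags as CSV.
#' @param null,flags optional null and significance columns for the PETH.
#' @param path output path.
#' @return `path`, invisibly.
#' @name perievent_io
NULL

#' @rdname perievent_io
#' @export
write_epochs_csv <- function(epochs, path) {
  utils::write.csv(as.data.frame(epochs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname perievent_io
#' @export
read_epochs_csv <- function(path) {
  d <- utils::read.csv(path)
  epoch_table(d$start_frame, d$end_frame, d$direction, d$magnitude_deg)
}

#' @rdname perievent_io
#' @export
write_peth_csv <- function(p, path, null = NULL, flags = NULL) {
  d <- data.frame(time_s = p$time_s, mean = p$mean_trace)
  if (!is.null(null)) { d$null_mean <- null$null_mean; d$null_sd <- null$null_sd }
  if (!is.null(flags)) d$significant <- flags
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
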