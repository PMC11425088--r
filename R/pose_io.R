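#' Construct a pose stream
#'
#' A pose stream is the controller's only sensory input: one row per camera
#' frame, holding head and tailbase keypoint coordinates (image pixels,
#' x right, y down, origin top-left) with per-point tracker confidences.
#'
#' Missing or non-finite coordinates are treated as confidence 0 rather than
#' errors, since pose trackers emit NaN on occluded keypoints; such frames
#' fall to the confidence gate downstream.
#'
#' @param frame integer frame indices, strictly increasing, >= 0.
#' @param head_x,head_y,tail_x,tail_y keypoint coordinates in pixels.
#' @param head_conf,tail_conf tracker likelihoods in [0, 1].
#' @param timestamp_s optional per-frame timestamps in seconds.
#' @return A `data.frame` of class `pose_stream` with columns `frame`,
#'   `timestamp_s`, `head_x`, `head_y`, `head_conf`, `tail_x`, `tail_y`,
#'   `tail_conf`.
#' @export
pose_stream <- function(frame, head_x, head_y, tail_x, tail_y,
                        head_conf = 1, tail_conf = 1, timestamp_s = NULL) {
  n <- length(frame)
  frame <- as.integer(frame)
  if (n > 1 && any(diff(frame) <= 0))
    stop("pose stream error: frame indices must be strictly increasing")
  if (any(frame < 0)) stop("pose stream error: negative frame index")
  df <- data.frame(
    frame = frame,
    timestamp_s = if (is.null(timestamp_s)) rep(NA_real_, n) else as.numeric(timestamp_s),
    head_x = as.numeric(head_x), head_y = as.numeric(head_y),
    head_conf = rep_len(as.numeric(head_conf), n),
    tail_x = as.numeric(tail_x), tail_y = as.numeric(tail_y),
    tail_conf = rep_len(as.numeric(tail_conf), n)
  )
  # non-finite keypoints -> confidence 0 (gated out), coordinates zeroed
  bad_h <- !is.finite(df$head_x) | !is.finite(df$head_y)
  bad_t <- !is.finite(df$tail_x) | !is.finite(df$tail_y)
  df$head_conf[bad_h] <- 0; df$head_x[bad_h] <- 0; df$head_y[bad_h] <- 0
  df$tail_conf[bad_t] <- 0; df$tail_x[bad_t] <- 0; df$tail_y[bad_t] <- 0
  if (any(df$head_conf < 0 | df$head_conf > 1 | df$tail_conf < 0 | df$tail_conf > 1))
    stop("pose stream error: confidences must lie in [0, 1]")
  class(df) <- c("pose_stream", "data.frame")
  df
}

#' Describe a behavioral arena
#'
#' @param kind one of `"circular"`, `"linear"`, `"open_field"`.
#' @param size_m arena diameter or track length in meters.
#' @param px_per_m camera scale in pixels per meter.
#' @param fps camera frame rate in frames per second (behavioral cameras in
#'   this system run at roughly 6-10 fps).
#' @return A list of class `arena_spec`.
#' @export
arena_spec <- function(kind = c("circular", "linear", "open_field"),
                       size_m, px_per_m, fps) {
  kind <- match.arg(kind)
  stopifnot(size_m > 0, px_per_m > 0, fps > 0, fps <= 1000)
  structure(list(kind = kind, size_m = size_m, px_per_m = px_per_m, fps = fps),
            class = "arena_spec")
}

#' Read a pose CSV
#'
#' Accepts two dialects: the DeepLabCut-style triple-header CSV (rows
#' `scorer`, `bodyparts`, `coords`; per-bodypart `x`/`y`/`likelihood`
#' columns) and a plain long-format CSV with columns
#' `frame,x_head,y_head,conf_head,x_tail,y_tail,conf_tail`.
#'
#' @param path path to the CSV file.
#' @param head_alias,tail_alias bodypart names accepted for the head and
#'   tailbase keypoints (DLC dialect only).
#' @return A [pose_stream].
#' @examples
#' f <- system.file("extdata", "synthetic_poses_dlc.csv", package = "activecomm")
#' head(read_pose_csv(f))
#' @export
read_pose_csv <- function(path, head_alias = c("head", "Head"),
                          tail_alias = c("tailbase", "tail_base", "Tailbase")) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (grepl("^scorer", first)) {
    read_pose_csv_dlc(path, head_alias, tail_alias)
  } else {
    d <- utils::read.csv(path, check.names = FALSE)
    need <- c("frame", "x_head", "y_head", "conf_head", "x_tail", "y_tail", "conf_tail")
    miss <- setdiff(need, names(d))
    if (length(miss))
      stop("pose CSV format error: missing column(s) ", paste(miss, collapse = ", "))
    pose_stream(d$frame, d$x_head, d$y_head, d$x_tail, d$y_tail,
                d$conf_head, d$conf_tail,
                timestamp_s = if ("timestamp_s" %in% names(d)) d$timestamp_s else NULL)
  }
}

read_pose_csv_dlc <- function(path, head_alias, tail_alias) {
  hdr <- readLines(path, n = 3L)
  bodyparts <- strsplit(hdr[2], ",", fixed = TRUE)[[1]][-1]
  coords <- strsplit(hdr[3], ",", fixed = TRUE)[[1]][-1]
  d <- utils::read.csv(path, skip = 3L, header = FALSE)
  col_of <- function(aliases, coord) {
    i <- which(bodyparts %in% aliases & coords == coord)
    if (!length(i))
      stop("pose CSV format error: no '", coord, "' column for bodypart '",
           aliases[1], "'")
    i[1] + 1L  # +1 for the leading frame-index column
  }
  pose_stream(
    frame = d[[1]],
    head_x = d[[col_of(head_alias, "x")]],
    head_y = d[[col_of(head_alias, "y")]],
    tail_x = d[[col_of(tail_alias, "x")]],
    tail_y = d[[col_of(tail_alias, "y")]],
    head_conf = d[[col_of(head_alias, "likelihood")]],
    tail_conf = d[[col_of(tail_alias, "likelihood")]]
  )
}

#' Write a pose stream to CSV
#'
#' @param stream a [pose_stream].
#' @param path output path.
#' @param dialect `"dlc"` for the triple-header DeepLabCut dialect or
#'   `"long"` for the plain long format.
#' @param digits number of significant digits written (round-trips exceed
#'   6-decimal fidelity at the default).
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(stream, path, dialect = c("dlc", "long"), digits = 10) {
  dialect <- match.arg(dialect)
  fmt <- function(x) formatC(x, digits = digits, format = "g")
  if (dialect == "dlc") {
    lines <- c(
      paste(c("scorer", rep("activecomm", 6)), collapse = ","),
      paste(c("bodyparts", rep("head", 3), rep("tailbase", 3)), collapse = ","),
      paste(c("coords", rep(c("x", "y", "likelihood"), 2)), collapse = ","),
      paste(stream$frame, fmt(stream$head_x), fmt(stream$head_y),
            fmt(stream$head_conf), fmt(stream$tail_x), fmt(stream$tail_y),
            fmt(stream$tail_conf), sep = ",")
    )
    writeLines(lines, path)
  } else {
    d <- data.frame(frame = stream$frame,
                    x_head = fmt(stream$head_x), y_head = fmt(stream$head_y),
                    conf_head = fmt(stream$head_conf),
                    x_tail = fmt(stream$tail_x), y_tail = fmt(stream$tail_y),
                    conf_tail = fmt(stream$tail_conf))
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Confidence gate for a pose sample
#'
#' A frame is accepted only when both keypoint confidences are strictly
#' above the threshold (the system gates at 0.9 so that occluded frames do
#' not corrupt the heading accumulator).
#'
#' @param head_conf,tail_conf tracker likelihoods in [0, 1] (vectorized).
#' @param conf_threshold gate in [0, 1]; default 0.9.
#' @return Logical: accepted?
#' @export
gate_sample <- function(head_conf, tail_conf, conf_threshold = 0.9) {
  stopifnot(conf_threshold >= 0, conf_threshold <= 1)
  head_conf > conf_threshold & tail_conf > conf_threshold
}

#' Read an annotation CSV
#'
#' Manual ground-truth annotations: columns
#' `frame,x_head,y_head,x_tail,y_tail`, one record per annotated frame.
#'
#' @param path path to the annotation CSV.
#' @return A data.frame with those columns.
#' @export
read_annotation_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("frame", "x_head", "y_head", "x_tail", "y_tail")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("annotation CSV format error: missing column(s) ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(d$frame)) stop("annotation error: duplicate frame indices")
  d[need]
}
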