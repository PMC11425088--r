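#' Match a predicted keypoint against ground truth
#'
#' A prediction matches when its Euclidean distance to the manual
#' annotation is within the radius (inclusive). The evaluation protocol
#' uses a 10-pixel radius.
#'
#' @param pred_xy,true_xy length-2 pixel coordinates (or 2-column matrices).
#' @param radius_px match radius in pixels, default 10.
#' @return Logical: within radius?
#' @export
match_prediction <- function(pred_xy, true_xy, radius_px = 10) {
  stopifnot(radius_px > 0)
  p <- rbind(pred_xy); a <- rbind(true_xy)
  sqrt(rowSums((p - a)^2)) <= radius_px
}

#' Radius-thresholded precision and sensitivity against manual annotations
#'
#' Per annotated frame, a single-point prediction is a true positive when
#' it is confident (above the gate) and within the radius of the
#' annotation; confident but outside the radius counts as a false
#' positive; below the confidence gate (or missing) counts as a false
#' negative. Precision = TP/(TP+FP), sensitivity = TP/(TP+FN). With this
#' bookkeeping a one-point-per-frame tracker can score differently on the
#' two metrics.
#'
#' @param preds a [pose_stream].
#' @param annotations data.frame from [read_annotation_csv] (columns
#'   `frame`, `x_head`, `y_head`, `x_tail`, `y_tail`).
#' @param radius_px match radius, default 10 px.
#' @param conf_threshold confidence gate, default 0.9.
#' @param bodypart `"head"` or `"tailbase"`.
#' @return A list of class `eval_result`: `precision`, `sensitivity`
#'   (NA when undefined), `n_tp`, `n_fp`, `n_fn`, `radius_px`.
#' @export
precision_sensitivity <- function(preds, annotations, radius_px = 10,
                                  conf_threshold = 0.9,
                                  bodypart = c("head", "tailbase")) {
  bodypart <- match.arg(bodypart)
  i <- match(annotations$frame, preds$frame)
  if (anyNA(i))
    stop("alignment error: annotated frame(s) ",
         paste(annotations$frame[is.na(i)], collapse = ", "),
         " absent from predictions")
  if (bodypart == "head") {
    px <- preds$head_x[i]; py <- preds$head_y[i]; conf <- preds$head_conf[i]
    ax <- annotations$x_head; ay <- annotations$y_head
  } else {
    px <- preds$tail_x[i]; py <- preds$tail_y[i]; conf <- preds$tail_conf[i]
    ax <- annotations$x_tail; ay <- annotations$y_tail
  }
  confident <- conf > conf_threshold
  within <- sqrt((px - ax)^2 + (py - ay)^2) <= radius_px
  tp <- sum(confident & within)
  fp <- sum(confident & !within)
  fn <- sum(!confident)
  structure(list(
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    n_tp = tp, n_fp = fp, n_fn = fn, radius_px = radius_px),
    class = "eval_result")
}

#' Fraction of frames below the confidence gate
#'
#' The quantity used to compare pose models trained on different amounts
#' of labeled data: the fraction of frames whose head or tailbase
#' confidence falls at or below the gate (default 0.9).
#'
#' @param stream a [pose_stream].
#' @param conf_threshold confidence gate, default 0.9.
#' @return Fraction in [0, 1].
#' @export
fraction_below_accuracy <- function(stream, conf_threshold = 0.9) {
  if (nrow(stream) == 0) stop("empty pose stream")
  mean(!gate_sample(stream$head_conf, stream$tail_conf, conf_threshold))
}

#' Mean and sample SD of inference latencies
#'
#' @param latencies_ms numeric vector of per-frame inference times (ms).
#' @return `c(mean = , sd = )`; SD is the sample (n-1) standard deviation,
#'   0 for a single observation.
#' @export
latency_summary <- function(latencies_ms) {
  if (!length(latencies_ms)) stop("empty latency list")
  s <- if (length(latencies_ms) > 1) stats::sd(latencies_ms) else 0
  c(mean = mean(latencies_ms), sd = s)
}
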