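# Independent oracles used across tests.

# Signed angular difference via atan2 unwrapping: angle of each vector in
# the y-down image frame, difference wrapped to (-180, 180]. Antiparallel
# pairs map to +180 by the same convention as the implementation.
atan2_delta_oracle <- function(v_prev, v_curr) {
  d <- (atan2(v_curr[2], v_curr[1]) - atan2(v_prev[2], v_prev[1])) * 180 / pi
  d <- d %% 360
  if (d > 180) d <- d - 360
  if (isTRUE(all.equal(d, -180))) d <- 180
  d
}

random_unit_vectors <- function(n, seed) {
  set.seed(seed)
  th <- runif(n, 0, 2 * pi)
  cbind(cos(th), sin(th))
}

# A prediction/annotation pair with planted TP (match, confident), FP
# (confident but displaced beyond the radius) and FN (unconfident) frames.
make_eval_fixture <- function(n_tp, n_fp, n_fn, radius = 10) {
  n <- n_tp + n_fp + n_fn
  truth_x <- seq(100, by = 50, length.out = n)
  pred_x <- truth_x
  if (n_fp > 0) pred_x[n_tp + seq_len(n_fp)] <- truth_x[n_tp + seq_len(n_fp)] + radius + 5
  conf <- rep(0.99, n)
  if (n_fn > 0) conf[n_tp + n_fp + seq_len(n_fn)] <- 0.3
  preds <- pose_stream(0:(n - 1), pred_x, 50, pred_x - 30, 80,
                       head_conf = conf, tail_conf = conf)
  ann <- data.frame(frame = 0:(n - 1), x_head = truth_x, y_head = 50,
                    x_tail = truth_x - 30, y_tail = 80)
  list(preds = preds, ann = ann)
}

# A pirouette stream with exactly `step_deg` of heading change per frame.
pirouette_stream <- function(total_deg, step_deg = 2, fps = 10,
                             body_px = 60, center = c(200, 200)) {
  heading <- seq(0, total_deg, by = step_deg * sign(total_deg))
  th <- heading * pi / 180
  n <- length(heading)
  pose_stream(frame = seq_len(n) - 1L,
              head_x = center[1] + body_px / 2 * cos(th),
              head_y = center[2] + body_px / 2 * sin(th),
              tail_x = center[1] - body_px / 2 * cos(th),
              tail_y = center[2] - body_px / 2 * sin(th),
              timestamp_s = (seq_len(n) - 1) / fps)
}
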