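# Sign convention, shared by generator, controller and stage simulator:
# image coordinates are y-down, and a rotation that looks clockwise in the
# displayed image is POSITIVE. With y down, heading angle = atan2(y, x)
# increases clockwise, so cross_z = x1*y2 - y1*x2 > 0 means CW.

#' Controller configuration
#'
#' Parameters of the active-commutation algorithm: confidence gate, pose
#' estimation stride, cumulative-rotation trigger threshold, linear-track
#' segmentation, and motor speeds for the stage simulator.
#'
#' @param rotation_threshold_deg cumulative heading change (degrees) that
#'   triggers a compensatory rotation. Presets used in practice: 90 (active
#'   place avoidance, Barnes maze) and 225 (linear maze).
#' @param conf_threshold confidence gate, default 0.9.
#' @param stride frames between pose estimates, default 5 (the controller
#'   only needs an estimate once every five frames).
#' @param n_segments number of virtual linear-track segments, default 8.
#' @param track_length_m linear track length in meters, default 1.2.
#' @param rotation_speed_dps commutator motor speed, default 100 deg/s.
#' @param translation_speed_mps stage translation speed, default 0.2 m/s.
#' @return A list of class `controller_config`.
#' @export
controller_config <- function(rotation_threshold_deg = 90,
                              conf_threshold = 0.9,
                              stride = 5L,
                              n_segments = 8L,
                              track_length_m = 1.2,
                              rotation_speed_dps = 100,
                              translation_speed_mps = 0.2) {
  stopifnot(rotation_threshold_deg > 0, rotation_threshold_deg <= 360,
            conf_threshold >= 0, conf_threshold <= 1,
            stride >= 1, n_segments >= 1, track_length_m > 0,
            rotation_speed_dps > 0, translation_speed_mps > 0)
  structure(list(rotation_threshold_deg = rotation_threshold_deg,
                 conf_threshold = conf_threshold,
                 stride = as.integer(stride),
                 n_segments = as.integer(n_segments),
                 track_length_m = track_length_m,
                 rotation_speed_dps = rotation_speed_dps,
                 translation_speed_mps = translation_speed_mps),
            class = "controller_config")
}

#' Heading direction vector from the two keypoints
#'
#' @param head_xy,tail_xy numeric length-2 pixel coordinates.
#' @return Unit vector head - tail, normalized.
#' @export
heading_vector <- function(head_xy, tail_xy) {
  v <- as.numeric(head_xy) - as.numeric(tail_xy)
  n <- sqrt(sum(v^2))
  if (!is.finite(n) || n == 0)
    stop("degenerate pose: head and tailbase coincide")
  v / n
}

#' Signed frame-to-frame heading change
#'
#' Magnitude from the dot product, direction (CW vs CCW) from the z
#' component of the cross product. Returns degrees in (-180, 180], positive
#' clockwise in the (y-down) image view. Exactly antiparallel vectors return
#' +180 by convention.
#'
#' @param v_prev,v_curr unit heading vectors.
#' @return Signed angle in degrees.
#' @export
signed_delta_deg <- function(v_prev, v_curr) {
  for (v in list(v_prev, v_curr))
    if (abs(sum(v^2) - 1) > 1e-6)
      stop("signed_delta_deg: inputs must be unit vectors")
  d <- max(-1, min(1, sum(v_prev * v_curr)))
  cz <- v_prev[1] * v_curr[2] - v_prev[2] * v_curr[1]
  # magnitude = arccos(dot), computed as atan2(|cross|, dot) for numerical
  # stability near 0 and 180 deg
  mag <- atan2(abs(cz), d) * 180 / pi
  if (cz > 0) mag else if (cz < 0) -mag else if (d >= 0) 0 else 180
}

#' Initial controller state
#'
#' @return A list of class `heading_state`: last accepted unit heading
#'   vector (NULL until the first accepted frame), the cumulative signed
#'   rotation since the last compensation, total accumulated rotation,
#'   frames since the last estimate, and the current track segment.
#' @export
heading_state <- function() {
  structure(list(last_vec = NULL, cumulative_deg = 0, total_deg = 0,
                 frames_since_estimate = .Machine$integer.max,
                 current_segment = NA_integer_,
                 last_accept_time_s = NA_real_),
            class = "heading_state")
}

#' One controller step: accumulate heading, maybe command a rotation
#'
#' A sample is processed only when at least `stride` frames have elapsed
#' since the last estimate, the sample passes the confidence gate, and the
#' pose is non-degenerate; otherwise the state advances and the command is
#' `"none"`. When processed, the signed delta between the last accepted
#' heading and the current one is added to the accumulator; once the
#' accumulator's magnitude reaches the rotation threshold, a `rotate_by`
#' command carrying the full accumulated signed angle is emitted and the
#' accumulator resets to zero (keeping long-run cable twist centered on
#' zero). Gated gaps pause accumulation: the delta is taken across the gap,
#' which assumes under 180 degrees of net rotation in between; gaps longer
#' than 1 s raise a warning.
#'
#' @param state a `heading_state`.
#' @param sample one pose-stream row (list/data.frame with `head_x`,
#'   `head_y`, `tail_x`, `tail_y`, `head_conf`, `tail_conf`, optionally
#'   `timestamp_s`).
#' @param config a [controller_config].
#' @return `list(state = , command = )` where command is
#'   `motor_command("none")` or `motor_command("rotate_by", rotate_deg=)`.
#' @export
update_heading <- function(state, sample, config) {
  state$frames_since_estimate <-
    if (state$frames_since_estimate >= .Machine$integer.max) state$frames_since_estimate
    else state$frames_since_estimate + 1L
  cmd <- motor_command("none")
  if (state$frames_since_estimate < config$stride)
    return(list(state = state, command = cmd))
  if (!isTRUE(gate_sample(sample$head_conf, sample$tail_conf, config$conf_threshold)))
    return(list(state = state, command = cmd))
  v <- tryCatch(heading_vector(c(sample$head_x, sample$head_y),
                               c(sample$tail_x, sample$tail_y)),
                error = function(e) NULL)
  if (is.null(v)) return(list(state = state, command = cmd))
  ts <- if (!is.null(sample$timestamp_s)) sample$timestamp_s else NA_real_
  if (!is.null(state$last_vec)) {
    if (is.finite(ts) && is.finite(state$last_accept_time_s) &&
        ts - state$last_accept_time_s > 1)
      warning("heading gap exceeds 1 s; delta across gap assumes <180 deg net rotation")
    delta <- signed_delta_deg(state$last_vec, v)
    state$cumulative_deg <- state$cumulative_deg + delta
    state$total_deg <- state$total_deg + delta
    # 1e-9 deg tolerance absorbs floating-point accumulation error at the
    # threshold so exact-construction streams trigger where intended
    if (abs(state$cumulative_deg) >= config$rotation_threshold_deg - 1e-9) {
      cmd <- motor_command("rotate_by", rotate_deg = state$cumulative_deg)
      state$cumulative_deg <- 0
    }
  }
  state$last_vec <- v
  state$last_accept_time_s <- ts
  state$frames_since_estimate <- 0L
  list(state = state, command = cmd)
}

#' Linear-track segment occupancy
#'
#' Half-open binning `floor(x_m / (track_length / n_segments))`; a head
#' exactly at the far end is clamped into the last segment. Positions
#' outside the track beyond a 1-pixel tolerance are an error (the physical
#' stage has limit switches; the virtual track has hard ends).
#'
#' @param head_x_px head x coordinate in pixels.
#' @param arena an [arena_spec] with `kind = "linear"`.
#' @param n_segments number of segments, default 8.
#' @return 0-based segment index in `[0, n_segments)`.
#' @export
segment_index <- function(head_x_px, arena, n_segments = 8L) {
  if (arena$kind != "linear") stop("segment_index requires a linear arena")
  x_m <- head_x_px / arena$px_per_m
  tol_m <- 1 / arena$px_per_m
  if (x_m < -tol_m || x_m > arena$size_m + tol_m)
    stop("out-of-arena position: x = ", signif(x_m, 4), " m")
  x_m <- min(max(x_m, 0), arena$size_m)
  seg <- floor(x_m / (arena$size_m / n_segments))
  as.integer(min(seg, n_segments - 1L))
}

#' Segment center in meters
#' @param seg 0-based segment index.
#' @param track_length_m track length.
#' @param n_segments number of segments.
#' @return x coordinate of the segment center in meters.
#' @export
segment_center_m <- function(seg, track_length_m = 1.2, n_segments = 8L) {
  (seg + 0.5) * track_length_m / n_segments
}

#' One translation-compensation step
#'
#' When the gated head position crosses into a new segment, command the
#' stage to the new segment's center so the commutator stays directly above
#' the mouse. No hysteresis by default: each boundary crossing commands a
#' move.
#'
#' @param state a `heading_state` (tracks `current_segment`).
#' @param sample one pose-stream row.
#' @param arena linear [arena_spec].
#' @param config a [controller_config].
#' @return `list(state = , command = )`.
#' @export
update_translation <- function(state, sample, arena, config) {
  cmd <- motor_command("none")
  if (!isTRUE(gate_sample(sample$head_conf, sample$tail_conf, config$conf_threshold)))
    return(list(state = state, command = cmd))
  seg <- tryCatch(segment_index(sample$head_x, arena, config$n_segments),
                  error = function(e) NA_integer_)
  if (is.na(seg)) return(list(state = state, command = cmd))
  if (!is.na(state$current_segment) && seg != state$current_segment)
    cmd <- motor_command("translate_to",
                         target_x_m = segment_center_m(seg, config$track_length_m,
                                                       config$n_segments))
  state$current_segment <- seg
  list(state = state, command = cmd)
}

#' Motor command
#'
#' @param kind `"none"`, `"rotate_by"` (signed degrees, CW positive) or
#'   `"translate_to"` (target x in meters, a segment center).
#' @param rotate_deg,target_x_m the payload for the corresponding kind.
#' @return A list of class `motor_command`.
#' @export
motor_command <- function(kind = c("none", "rotate_by", "translate_to"),
                          rotate_deg = NULL, target_x_m = NULL) {
  kind <- match.arg(kind)
  if (kind == "rotate_by" && is.null(rotate_deg))
    stop("rotate_by requires rotate_deg")
  if (kind == "translate_to" && is.null(target_x_m))
    stop("translate_to requires target_x_m")
  structure(list(kind = kind, rotate_deg = rotate_deg, target_x_m = target_x_m),
            class = "motor_command")
}

#' Initial stage state
#'
#' The simulated commutator stage: unwrapped slip-ring angle, x position,
#' and a FIFO queue of commands still executing. Cable twist is accounted
#' as mouse cumulative heading minus commutator angle.
#'
#' @param x_m initial stage x position in meters.
#' @return A list of class `stage_state`.
#' @export
stage_state <- function(x_m = 0) {
  structure(list(angle_deg = 0, x_m = x_m, queue = list(), busy = FALSE,
                 time_s = 0),
            class = "stage_state")
}

#' Advance the stage simulator by one time step
#'
#' Constant-speed motor model, no acceleration ramp: rotation progresses
#' toward the commanded angle at up to `rotation_speed_dps`, translation at
#' up to `translation_speed_mps` with clamping at the track ends (the
#' limit-switch model). Commands arriving while a motion is executing are
#' queued FIFO.
#'
#' @param stage a [stage_state].
#' @param command a [motor_command] issued at the start of the step (or
#'   `NULL`).
#' @param dt_s step duration in seconds.
#' @param config a [controller_config].
#' @return Updated `stage_state`.
#' @export
step_stage <- function(stage, command = NULL, dt_s, config) {
  stopifnot(dt_s > 0)
  if (!is.null(command) && command$kind != "none")
    stage$queue <- c(stage$queue, list(command))
  budget <- dt_s
  while (budget > 0 && length(stage$queue)) {
    cmd <- stage$queue[[1]]
    if (cmd$kind == "rotate_by") {
      remaining <- cmd$rotate_deg
      step <- sign(remaining) * min(abs(remaining), config$rotation_speed_dps * budget)
      stage$angle_deg <- stage$angle_deg + step
      budget <- budget - abs(step) / config$rotation_speed_dps
      remaining <- remaining - step
      if (abs(remaining) < 1e-12) stage$queue <- stage$queue[-1]
      else stage$queue[[1]]$rotate_deg <- remaining
    } else if (cmd$kind == "translate_to") {
      target <- min(max(cmd$target_x_m, 0), config$track_length_m)  # limit switches
      remaining <- target - stage$x_m
      step <- sign(remaining) * min(abs(remaining), config$translation_speed_mps * budget)
      stage$x_m <- stage$x_m + step
      budget <- budget - abs(step) / config$translation_speed_mps
      if (abs(target - stage$x_m) < 1e-12) stage$queue <- stage$queue[-1]
    } else {
      stage$queue <- stage$queue[-1]
    }
  }
  stage$busy <- length(stage$queue) > 0
  stage$time_s <- stage$time_s + dt_s
  stage
}

#' Replay a pose stream through the full closed loop
#'
#' Deterministic replay of the active mode: per frame, the heading
#' controller and (on linear arenas) the translation controller consume the
#' gated pose sample, emitted commands are queued on the simulated stage,
#' and the stage advances by one camera frame interval. The cable-twist
#' trace is the controller's total accumulated heading minus the commutator
#' angle.
#'
#' @param stream a [pose_stream].
#' @param arena an [arena_spec].
#' @param config a [controller_config].
#' @return A list of class `run_log`: per-frame data.frame `frames`
#'   (cumulative heading, commutator angle and x, twist, busy flag) and a
#'   data.frame `commands` (frame, kind, payload).
#' @export
run_closed_loop <- function(stream, arena, config = controller_config()) {
  n <- nrow(stream)
  dt <- 1 / arena$fps
  hs <- heading_state()
  st <- stage_state(x_m = if (arena$kind == "linear")
    stream$head_x[1] / arena$px_per_m else 0)
  out <- data.frame(frame = stream$frame, total_heading_deg = 0,
                    cumulative_deg = 0, commutator_angle_deg = 0,
                    commutator_x_m = 0, twist_deg = 0, busy = FALSE)
  cmds <- list()
  for (i in seq_len(n)) {
    s <- stream[i, ]
    up <- update_heading(hs, s, config)
    hs <- up$state
    frame_cmds <- list(up$command)
    if (arena$kind == "linear") {
      tr <- update_translation(hs, s, arena, config)
      hs <- tr$state
      frame_cmds <- c(frame_cmds, list(tr$command))
    }
    for (cmd in frame_cmds) {
      if (cmd$kind == "none") next
      cmds[[length(cmds) + 1L]] <- data.frame(
        frame = stream$frame[i], kind = cmd$kind,
        rotate_deg = if (is.null(cmd$rotate_deg)) NA_real_ else cmd$rotate_deg,
        target_x_m = if (is.null(cmd$target_x_m)) NA_real_ else cmd$target_x_m)
      st$queue <- c(st$queue, list(cmd))  # enqueue; motion happens in the step
    }
    st <- step_stage(st, NULL, dt_s = dt, config = config)
    out$total_heading_deg[i] <- hs$total_deg
    out$cumulative_deg[i] <- hs$cumulative_deg
    out$commutator_angle_deg[i] <- st$angle_deg
    out$commutator_x_m[i] <- st$x_m
    out$twist_deg[i] <- hs$total_deg - st$angle_deg
    out$busy[i] <- st$busy
  }
  commands <- if (length(cmds)) do.call(rbind, cmds) else
    data.frame(frame = integer(), kind = character(),
               rotate_deg = numeric(), target_x_m = numeric())
  structure(list(frames = out, commands = commands,
                 residual_deg = hs$cumulative_deg,
                 final_state = hs, final_stage = st),
            class = "run_log")
}

#' Write a run log as JSON lines plus a command CSV
#'
#' One JSON record per frame; commands additionally as CSV. The ASCII live
#' protocol mirror ("R <deg>" / "T <x_mm>") is included in the command
#' table for interoperability with the wireless command link.
#'
#' @param log a `run_log`.
#' @param jsonl_path path for JSON-lines per-frame records.
#' @param commands_csv_path optional path for the command CSV.
#' @return `jsonl_path`, invisibly.
#' @export
write_run_log <- function(log, jsonl_path, commands_csv_path = NULL) {
  rows <- lapply(seq_len(nrow(log$frames)), function(i)
    jsonlite::toJSON(as.list(log$frames[i, ]), auto_unbox = TRUE, digits = NA))
  writeLines(unlist(rows), jsonl_path)
  if (!is.null(commands_csv_path)) {
    cm <- log$commands
    cm$protocol <- ifelse(cm$kind == "rotate_by",
                          sprintf("R %.6f", cm$rotate_deg),
                          sprintf("T %.3f", cm$target_x_m * 1000))
    utils::write.csv(cm, commands_csv_path, row.names = FALSE, quote = FALSE)
  }
  invisible(jsonl_path)
}
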