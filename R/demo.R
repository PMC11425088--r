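#' Load and validate a run configuration
#'
#' YAML configuration with `arena`, `controller`, `pipeline`, `peth`
#' sub-sections plus `seed` and `out_dir`. Unknown keys anywhere in the
#' schema are rejected before any computation.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  schema <- list(
    top = c("arena", "controller", "pipeline", "peth", "seed", "out_dir"),
    arena = c("kind", "size_m", "px_per_m", "fps"),
    controller = c("rotation_threshold_deg", "conf_threshold", "stride",
                   "n_segments", "track_length_m", "rotation_speed_dps",
                   "translation_speed_mps"),
    pipeline = c("bin_fraction", "dff_method", "baseline", "low_hz", "high_hz",
                 "order", "ripple_db", "smooth_px", "outlier_sd", "fps_total"),
    peth = c("window_s", "n_boot", "alpha"))
  check <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra))
      stop("config schema violation in '", where, "': unknown key(s) ",
           paste(extra, collapse = ", "))
  }
  check(cfg, schema$top, "top level")
  for (s in c("arena", "controller", "pipeline", "peth"))
    if (!is.null(cfg[[s]])) check(cfg[[s]], schema[[s]], s)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$out_dir <- cfg$out_dir %||% "."
  class(cfg) <- "run_config"
  cfg
}

config_arena <- function(cfg) {
  a <- cfg$arena %||% list()
  arena_spec(kind = a$kind %||% "circular", size_m = a$size_m %||% 0.345,
             px_per_m = a$px_per_m %||% 1000, fps = a$fps %||% 10)
}

config_controller <- function(cfg) {
  ctl <- cfg$controller %||% list()
  do.call(controller_config, ctl)
}

#' End-to-end closed-loop demonstration
#'
#' Generates a scripted two-full-turn clockwise pirouette in a circular
#' arena and a monotone traverse of a 1.2 m linear track, runs both
#' through the controller and stage simulator, and writes a reproducible
#' artifact bundle: per-frame run logs (JSON lines), command CSVs, and a
#' twist-trace CSV. Everything is a pure function of config + seed.
#'
#' @param config a `run_config` (or path to one).
#' @param quiet suppress the summary printout.
#' @return Invisibly, a list with the two run logs and the output paths.
#' @export
demo_closed_loop <- function(config = read_run_config(list()), quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  arena <- config_arena(config)
  ctl <- config_controller(config)

  # 361 frames at 10 fps: exactly 2 deg of heading change per frame, so the
  # 90-deg threshold divides the 720-deg pirouette into 8 equal commands
  pir <- generate_trajectory(arena, duration_s = 36.1, n_full_turns = 2,
                             seed = config$seed)
  log_rot <- run_closed_loop(pir$stream, arena, ctl)
  p1 <- file.path(config$out_dir, "pirouette_runlog.jsonl")
  write_run_log(log_rot, p1, file.path(config$out_dir, "pirouette_commands.csv"))

  track <- arena_spec("linear", size_m = ctl$track_length_m,
                      px_per_m = arena$px_per_m, fps = arena$fps)
  n <- 120
  xs <- seq(0, ctl$track_length_m, length.out = n) * track$px_per_m
  traverse <- pose_stream(frame = seq_len(n) - 1L, head_x = xs, head_y = 50,
                          tail_x = xs - 60, tail_y = 50,
                          timestamp_s = (seq_len(n) - 1) / track$fps)
  log_tr <- run_closed_loop(traverse, track, ctl)
  p2 <- file.path(config$out_dir, "traverse_runlog.jsonl")
  write_run_log(log_tr, p2, file.path(config$out_dir, "traverse_commands.csv"))

  tw <- file.path(config$out_dir, "pirouette_twist.csv")
  utils::write.csv(log_rot$frames[, c("frame", "twist_deg")], tw,
                   row.names = FALSE, quote = FALSE)
  nrot <- sum(log_rot$commands$kind == "rotate_by")
  ntr <- sum(log_tr$commands$kind == "translate_to")
  if (!quiet)
    message("pirouette: ", nrot, " rotation commands, net ",
            round(sum(log_rot$commands$rotate_deg, na.rm = TRUE) +
                    log_rot$residual_deg, 3),
            " deg; traverse: ", ntr, " translation commands")
  invisible(list(rotation_log = log_rot, translation_log = log_tr,
                 paths = c(p1, p2, tw)))
}

#' End-to-end calcium demonstration
#'
#' Generates a synthetic dual-illumination movie with known calcium and
#' hemodynamic structure, runs the full preprocessing chain, extracts ROI
#' traces, builds peri-event averages around synthetic commutation epochs
#' and their bootstrap null, and writes PETH CSVs plus a QC report
#' (outlier counts, shift traces).
#'
#' @param config a `run_config` (or path to one).
#' @param planted_effect add an event-locked transient to the trace before
#'   the PETH (demonstrates a detectable effect); default FALSE mirrors
#'   the no-artifact regime.
#' @param quiet suppress the summary printout.
#' @return Invisibly: pipeline output, PETH, null, flags, QC path.
#' @export
demo_calcium <- function(config = read_run_config(list()),
                         planted_effect = FALSE, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pl <- config$pipeline %||% list()
  gen <- generate_movie(shape = c(1200, 32, 32), n_cells = 5,
                        hemo_amp = 0.05, outlier_frac = 0.005,
                        max_shift_px = 2, fps_total = pl$fps_total %||% 30,
                        seed = config$seed)
  pipe <- run_calcium_pipeline(gen$movie, mask = gen$truth$mask,
                               bin_fraction = pl$bin_fraction %||% 0.8,
                               ripple_db = pl$ripple_db %||% 0.2)
  roi <- list(cortex = matrix(TRUE, dim(pipe$dff)[2], dim(pipe$dff)[3]))
  tr <- extract_roi_traces(pipe, roi)$cortex
  nch <- length(tr$series)
  pe <- config$peth %||% list()
  # window kept short enough that the Bonferroni level alpha/m stays above
  # the empirical p-value resolution 1/(n_boot+1)
  win_s <- pe$window_s %||% c(1, 2)
  wf <- round(win_s * pipe$fps_channel)
  n_events <- 10
  with_seed(config$seed + 1L, {
    grid <- seq(wf[1] + 1, nch - wf[2] - 11, by = 12)  # spacing keeps epochs disjoint
    onsets <- sort(sample(grid, n_events))
  })
  if (planted_effect) {
    for (o in onsets) {
      k <- seq(0, min(wf[2], nch - o))
      tr$series[o + k] <- tr$series[o + k] + 5 * exp(-k / (pipe$fps_channel))
    }
  }
  ep <- epoch_table(onsets - 1L, onsets + 9L, direction = "CW",
                    magnitude_deg = 720)
  p <- peth(tr, ep, window_s = win_s)
  null <- bootstrap_null(tr, p$window_frames, n_events = p$n_events,
                         n_boot = pe$n_boot %||% 1000,
                         seed = config$seed + 2L)
  flags <- flag_significance(p, null, alpha = pe$alpha %||% 0.05)
  peth_path <- file.path(config$out_dir, "peth_cortex.csv")
  write_peth_csv(p, peth_path, null = null, flags = flags)
  write_epochs_csv(ep, file.path(config$out_dir, "epochs.csv"))
  qc <- list(n_outlier_frames = pipe$qc$n_outliers,
             true_outlier_frames = length(gen$truth$outliers),
             n_flat_pixels = pipe$qc$n_flat_pixels,
             max_abs_shift_px = max(abs(rbind(pipe$shifts_blue,
                                              pipe$shifts_green))),
             n_significant_timepoints = sum(flags))
  qc_path <- file.path(config$out_dir, "qc_report.json")
  writeLines(jsonlite::toJSON(qc, auto_unbox = TRUE, pretty = TRUE), qc_path)
  utils::write.csv(data.frame(frame = seq_len(nrow(pipe$shifts_blue)),
                              dy = pipe$shifts_blue[, 1],
                              dx = pipe$shifts_blue[, 2]),
                   file.path(config$out_dir, "shift_trace_blue.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!quiet)
    message("calcium demo: ", qc$n_outlier_frames, " outlier frames flagged (",
            qc$true_outlier_frames, " injected), ",
            qc$n_significant_timepoints, " significant PETH timepoints")
  invisible(list(pipeline = pipe, peth = p, null = null, flags = flags,
                 qc = qc, paths = c(peth_path, qc_path)))
}
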