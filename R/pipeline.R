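#' Default pipeline configuration
#'
#' All tunable parameters of the scoring pipeline in one list, echoed
#' into every report for auditability. Merge a YAML file over these
#' defaults with [read_config()].
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(
    joint = "right_knee",            # driving joint for segmentation/scoring
    buffer = NULL,                   # bbox margin px; NULL = 5% of frame
    visibility_threshold = 0.5,
    max_gap = 5,                     # frames bridged by interpolation
    smooth_window = 5,               # odd; 1 disables smoothing
    min_prominence = NULL,           # degrees; NULL = 20% of observed range
    min_distance = NULL,             # frames;  NULL = 0.25 s * fps
    min_valid_fraction = 0.8,
    max_jitter = 30,                 # degrees per frame
    max_lag = NULL,                  # frames;  NULL = 25% of window length
    weights = c(1, 1),               # (w_sim, w_rep)
    tolerance = 5,                   # degrees, feedback threshold
    rounding = "integer"
  )
}

#' Read a pipeline configuration file
#'
#' Reads a YAML file and merges it over [default_config()]; unknown keys
#' are an error so typos cannot silently fall back to defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(cfg, user)
}

prepare_sequence <- function(seq, cfg) {
  rep_ <- validate_sequence(seq)
  if (!rep_$ok) {
    bad <- rep_$issues[rep_$issues$severity == "error", , drop = FALSE]
    stop("input failed validation: ", bad$code[1], " - ", bad$message[1])
  }
  px <- to_pixel(seq)
  fill_low_visibility(px, cfg$visibility_threshold, cfg$max_gap)
}

#' Score a user motion against a reference motion
#'
#' The full comparison pipeline: validate -> pixel conversion ->
#' visibility gap filling -> joint-angle extraction (on pixel
#' coordinates) -> repetition segmentation on both sequences ->
#' repetition-count error (reference count as the actual) -> ordinal
#' pairing with peak-aligned padding -> per-pair DTW distance and NCC
#' `R_max` on standardized windows -> similarity `S` -> composite Action
#' Score -> per-joint kinematic comparison and feedback.
#'
#' @param user_seq,ref_seq [pose_sequence()]s.
#' @param config Configuration list (see [default_config()]); `config$joint`
#'   names the exercised joint whose trajectory drives segmentation.
#' @param joints Joint-definition table.
#' @return An `action_report`: scores, per-repetition detail, repetition
#'   sets, kinematic summaries, feedback, and the configuration echo.
#' @export
score_motion <- function(user_seq, ref_seq, config = default_config(),
                         joints = default_joints()) {
  jd <- joints[[config$joint]]
  if (is.null(jd)) stop("unknown driving joint: ", config$joint)

  upx <- prepare_sequence(user_seq, config)
  rpx <- prepare_sequence(ref_seq, config)
  us <- angle_series(upx, jd)
  rs <- angle_series(rpx, jd)

  ureps <- segment_repetitions(us, config$min_prominence, config$min_distance,
                               config$smooth_window)
  rreps <- segment_repetitions(rs, config$min_prominence, config$min_distance,
                               config$smooth_window)
  ureps <- filter_stable(ureps, us, config$min_valid_fraction, config$max_jitter)
  rreps <- filter_stable(rreps, rs, config$min_valid_fraction, config$max_jitter)
  if (rreps$detected_count < 1) stop("no repetition detected in the reference sequence")
  err <- count_error(ureps$detected_count, rreps$detected_count)

  pairs <- align_repetitions(ureps, rreps, us, rs)
  per_rep <- lapply(seq_along(pairs), function(i) {
    pu <- standardize(pairs[[i]]$user)$values
    pr <- standardize(pairs[[i]]$reference)$values
    nc <- ncc(pu, pr, config$max_lag)
    dt <- dtw_align(pu, pr)
    data.frame(rep = i, r_max = nc$r_max, best_lag = nc$best_lag,
               dtw_distance = dt$distance)
  })
  per_rep <- do.call(rbind, per_rep)

  S <- similarity_score(per_rep$r_max)
  score <- action_score(S, err, config$weights, per_rep_rmax = per_rep$r_max)

  usum <- summarize_repetitions(us, ureps)
  rsum <- summarize_repetitions(rs, rreps)
  cmp <- compare_joint(usum, rsum, jd$name, config$tolerance)

  structure(list(
    joint = jd$name,
    score = score,
    similarity = S,
    rep_error = err,
    per_rep = per_rep,
    user_reps = ureps, ref_reps = rreps,
    user_summary = usum, ref_summary = rsum,
    comparison = cmp,
    feedback = feedback_report(list(cmp), config$rounding),
    config = config
  ), class = "action_report")
}

#' @export
print.action_report <- function(x, ...) {
  cat(sprintf("<action_report> joint %s\n", x$joint))
  print(x$score)
  cat(sprintf("  reps: user %d vs reference %d\n",
              x$user_reps$detected_count, x$ref_reps$detected_count))
  cat("  ", x$comparison$feedback_text, "\n", sep = "")
  invisible(x)
}

#' Serialize an action report to JSON
#'
#' Structured JSON with per-repetition `R_max`/lag/DTW distance, the
#' similarity, repetition counts, combined score, feedback table, and a
#' full configuration echo.
#'
#' @param report An `action_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_report <- function(report, path) {
  doc <- list(
    joint = report$joint,
    combined_score = report$score$combined,
    similarity = report$similarity,
    rep_error_percent = report$rep_error$error_percent,
    detected_reps_user = report$user_reps$detected_count,
    detected_reps_reference = report$ref_reps$detected_count,
    per_repetition = report$per_rep,
    user_summary = report$user_summary[c("rom", "rom_sd", "theta_max",
                                         "theta_min", "mean_velocity",
                                         "velocity_sd", "n_reps")],
    reference_summary = report$ref_summary[c("rom", "rom_sd", "theta_max",
                                             "theta_min", "mean_velocity",
                                             "velocity_sd", "n_reps")],
    feedback = report$feedback$table,
    config = report$config
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", pretty = TRUE)
  invisible(path)
}
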