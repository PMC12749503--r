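with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic exercise motion
#'
#' Describes a ground-truth-known motion: one or more joints driven
#' through raised-cosine repetition cycles, rendered through a planar
#' skeleton into the 33-landmark layout, optionally corrupted with
#' Gaussian keypoint jitter, shared global drift and visibility-dropout
#' bursts. The known parameters are the recovery targets for every
#' pipeline test.
#'
#' @param exercise Free-text exercise label.
#' @param joints List of driven joints, each a list with `joint` (name in
#'   the joints table), `baseline` (trough angle, degrees), `rom`
#'   (degrees), `n_reps`, and optional `phase` (radians).
#' @param fps Frames per second.
#' @param duration Seconds; default allows 1.5 s per repetition of the
#'   busiest joint (minimum 3 s), a typical physiotherapy tempo.
#' @param noise_sigma I.i.d. Gaussian jitter sd per coordinate, in
#'   normalized units (fraction of frame size).
#' @param dropout_prob Per-frame, per-landmark probability that a
#'   visibility-dropout burst starts.
#' @param dropout_burst Mean burst length in frames (geometric).
#' @param drift_amplitude Shared sinusoidal global drift amplitude, pixels.
#' @param seed Integer seed for all corruption randomness.
#' @return A `synthetic_motion_spec`.
#' @export
synthetic_motion_spec <- function(exercise = "synthetic",
                                  joints = list(list(joint = "right_knee",
                                                     baseline = 90, rom = 60,
                                                     n_reps = 5)),
                                  fps = 60, duration = NULL,
                                  noise_sigma = 0, dropout_prob = 0,
                                  dropout_burst = 3, drift_amplitude = 0,
                                  seed = NULL) {
  for (j in joints) {
    if (is.null(j$joint)) stop("each driven joint needs a 'joint' name")
    if (j$rom < 0) stop("rom must be >= 0 (joint ", j$joint, ")")
    if (j$n_reps < 0) stop("n_reps must be >= 0 (joint ", j$joint, ")")
  }
  if (fps <= 0) stop("fps must be > 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (dropout_prob < 0 || dropout_prob > 1) stop("dropout_prob must be in [0, 1]")
  if (is.null(duration)) {
    duration <- max(3, 1.5 * max(vapply(joints, function(j) j$n_reps, numeric(1))))
  }
  if (duration * fps < 3) stop("duration * fps must be >= 3")
  structure(list(exercise = exercise, joints = joints, fps = fps,
                 duration = duration, noise_sigma = noise_sigma,
                 dropout_prob = dropout_prob, dropout_burst = dropout_burst,
                 drift_amplitude = drift_amplitude, seed = seed),
            class = "synthetic_motion_spec")
}

#' Raised-cosine repetition trajectory
#'
#' `theta(t) = baseline + (rom/2) * (1 - cos(2 pi n_reps t / T + phase))`
#' over `t in [0, T]`: exactly `n_reps` maxima inside the interval, with
#' the trajectory starting and ending at the trough (`theta_min =
#' baseline`, `theta_max = baseline + rom`). Starting at the trough makes
#' trough-peak-trough segmentation exact at the sequence boundaries,
#' which a pure sine would not.
#'
#' @param baseline Trough angle, degrees.
#' @param rom Range of motion, degrees (`>= 0`).
#' @param n_reps Number of repetitions (`>= 0`; 0 gives a constant).
#' @param fps Frames per second.
#' @param duration Seconds (`duration * fps >= 3`).
#' @param phase Phase offset in radians.
#' @return Numeric vector of angles, one per frame.
#' @export
generate_angle_trajectory <- function(baseline, rom, n_reps, fps, duration,
                                      phase = 0) {
  if (rom < 0 || n_reps < 0 || fps <= 0 || duration * fps < 3)
    stop("invalid trajectory parameters")
  t <- seq(0, round(duration * fps)) / fps
  baseline + (rom / 2) * (1 - cos(2 * pi * n_reps * t / duration + phase))
}

#' Planar skeleton template
#'
#' A static standing pose for all 33 landmarks, built from standard
#' anthropometric segment proportions (fractions of stature) read from
#' the shipped configuration (`inst/extdata/skeleton.yaml`), scaled to a
#' given pixel stature and centered in the frame. Also carries, for each
#' drivable joint, the set of landmarks rigidly attached to its distal
#' segment and the proximal-to-distal drive order.
#'
#' @param width,height Frame size in pixels.
#' @param stature Body height in pixels.
#' @param config Optional path to an alternative proportions YAML.
#' @return A `skeleton_template`: `base` (33 x 2 pixel matrix),
#'   `subtrees` (named list of 0-based landmark indices), `drive_order`,
#'   `width`, `height`.
#' @export
skeleton_template <- function(width = 1280, height = 720, stature = 600,
                              config = NULL) {
  if (is.null(config)) config <- system.file("extdata", "skeleton.yaml",
                                             package = "kinescore")
  pr <- yaml::read_yaml(config)$proportions
  S <- stature
  cx <- width / 2
  ground <- (height + S) / 2
  yof <- function(frac) ground - S * frac    # image y grows downward

  P <- matrix(NA_real_, 33, 2)
  rownames(P) <- landmark_names()
  set <- function(nm, x, y) P[nm, ] <<- c(x, y)

  set("nose", cx, yof(pr$nose_height))
  for (side in c("left", "right")) {
    sg <- if (side == "left") 1 else -1      # left of the subject drawn at +x
    set(paste0(side, "_eye_inner"), cx + sg * 0.010 * S, yof(pr$eye_height))
    set(paste0(side, "_eye"),       cx + sg * 0.020 * S, yof(pr$eye_height))
    set(paste0(side, "_eye_outer"), cx + sg * 0.030 * S, yof(pr$eye_height))
    set(paste0(side, "_ear"),       cx + sg * 0.040 * S, yof(pr$ear_height))
    set(paste0("mouth_", side),     cx + sg * 0.013 * S, yof(pr$mouth_height))

    shx <- cx + sg * pr$shoulder_halfwidth * S
    shy <- yof(pr$shoulder_height)
    set(paste0(side, "_shoulder"), shx, shy)
    # arms hang with slight outward abduction so no base triplet degenerates
    a <- pr$arm_hang_angle * pi / 180
    dirx <- sg * sin(a); diry <- cos(a)
    elb <- c(shx + dirx * pr$upper_arm * S, shy + diry * pr$upper_arm * S)
    set(paste0(side, "_elbow"), elb[1], elb[2])
    wri <- elb + c(dirx, diry) * pr$forearm * S
    set(paste0(side, "_wrist"), wri[1], wri[2])
    set(paste0(side, "_pinky"), wri[1] + dirx * pr$hand * S, wri[2] + diry * pr$hand * S)
    set(paste0(side, "_index"), wri[1] + dirx * pr$hand * S * 0.95,
        wri[2] + diry * pr$hand * S * 0.95)
    set(paste0(side, "_thumb"), wri[1] + dirx * pr$hand * S * 0.6,
        wri[2] + diry * pr$hand * S * 0.6)

    hx <- cx + sg * pr$hip_halfwidth * S
    set(paste0(side, "_hip"), hx, yof(pr$hip_height))
    set(paste0(side, "_knee"), hx, yof(pr$knee_height))
    set(paste0(side, "_ankle"), hx, yof(pr$ankle_height))
    set(paste0(side, "_heel"), hx - sg * 0.02 * S, ground)
    set(paste0(side, "_foot_index"), hx + sg * pr$foot_length * S * 0.6, ground)
  }

  arm_l <- landmark_index(c("left_wrist", "left_pinky", "left_index", "left_thumb"))
  arm_r <- landmark_index(c("right_wrist", "right_pinky", "right_index", "right_thumb"))
  leg_l <- landmark_index(c("left_ankle", "left_heel", "left_foot_index"))
  leg_r <- landmark_index(c("right_ankle", "right_heel", "right_foot_index"))
  subtrees <- list(
    left_shoulder = c(landmark_index("left_elbow"), arm_l),
    right_shoulder = c(landmark_index("right_elbow"), arm_r),
    left_elbow = arm_l,
    right_elbow = arm_r,
    left_hip_sagittal = c(landmark_index("left_knee"), leg_l),
    left_hip_frontal = c(landmark_index("left_knee"), leg_l),
    right_hip_sagittal = c(landmark_index("right_knee"), leg_r),
    right_hip_frontal = c(landmark_index("right_knee"), leg_r),
    left_knee = leg_l,
    right_knee = leg_r
  )
  structure(list(base = P, subtrees = subtrees,
                 drive_order = c("left_shoulder", "right_shoulder",
                                 "left_hip_sagittal", "right_hip_sagittal",
                                 "left_hip_frontal", "right_hip_frontal",
                                 "left_elbow", "right_elbow",
                                 "left_knee", "right_knee"),
                 width = width, height = height),
            class = "skeleton_template")
}

#' Render driven joint angles through the skeleton
#'
#' Forward kinematics in a single plane: for each frame, every driven
#' joint's distal subtree is rotated about the joint's vertex so that the
#' measured triplet angle equals the assigned angle (the rotation keeps
#' the limb on its current side, so re-measuring with [angle_series()]
#' recovers the driving angles exactly). Undriven landmarks hold the
#' static pose. Output is normalized by the frame size into a
#' [pose_sequence()] with visibility 1 everywhere.
#'
#' @param angles Named list: joint name -> numeric vector of angles
#'   (degrees), all the same length.
#' @param skeleton A [skeleton_template()].
#' @param fps Frames per second for the output sequence.
#' @param joints Joint-definition table (default [default_joints()]).
#' @return A [pose_sequence()].
#' @export
forward_kinematics <- function(angles, skeleton, fps = 60,
                               joints = default_joints()) {
  unknown <- setdiff(names(angles), names(skeleton$subtrees))
  if (length(unknown)) stop("no subtree defined for joint(s): ",
                            paste(unknown, collapse = ", "))
  n <- unique(vapply(angles, length, integer(1)))
  if (length(n) != 1) stop("all angle trajectories must have the same length")

  X <- matrix(rep(skeleton$base[, 1], each = n), n, 33)
  Y <- matrix(rep(skeleton$base[, 2], each = n), n, 33)
  for (jn in intersect(skeleton$drive_order, names(angles))) {
    trip <- joints[[jn]]$triplet + 1L
    sub <- skeleton$subtrees[[jn]] + 1L
    p <- trip[1]; v <- trip[2]
    ax <- X[, p] - X[, v]; ay <- Y[, p] - Y[, v]
    bx <- X[, trip[3]] - X[, v]; by <- Y[, trip[3]] - Y[, v]
    phi0 <- atan2(ax * by - ay * bx, ax * bx + ay * by)
    s <- ifelse(phi0 == 0, 1, sign(phi0))
    delta <- s * rad(angles[[jn]]) - phi0
    cd <- cos(delta); sd_ <- sin(delta)
    for (k in sub) {
      rx <- X[, k] - X[, v]; ry <- Y[, k] - Y[, v]
      X[, k] <- X[, v] + cd * rx - sd_ * ry
      Y[, k] <- Y[, v] + sd_ * rx + cd * ry
    }
  }
  pose_sequence(X / skeleton$width, Y / skeleton$height,
                matrix(1, n, 33), skeleton$width, skeleton$height, fps)
}

#' Corrupt a pose sequence with realistic disturbances
#'
#' Adds (i) i.i.d. Gaussian jitter per landmark coordinate, (ii) a shared
#' slow sinusoidal global drift — a whole-skeleton translation, to which
#' joint angles are invariant — and (iii) visibility-dropout bursts
#' (Bernoulli onset per landmark-frame, geometric burst length). Fully
#' seeded and reproducible via `spec$seed`.
#'
#' @param seq A [pose_sequence()].
#' @param spec A [synthetic_motion_spec()] carrying the corruption
#'   parameters and seed.
#' @return The corrupted [pose_sequence()].
#' @export
corrupt <- function(seq, spec) {
  n <- n_frames(seq)
  if (n == 0) return(seq)
  with_seed(spec$seed, {
    if (spec$drift_amplitude > 0) {
      t <- (seq_len(n) - 1) / seq$fps
      dx <- spec$drift_amplitude / seq$width * sin(2 * pi * 0.2 * t)
      dy <- spec$drift_amplitude / seq$height * cos(2 * pi * 0.2 * t)
      seq$x <- seq$x + dx
      seq$y <- seq$y + dy
    }
    if (spec$noise_sigma > 0) {
      seq$x <- seq$x + matrix(stats::rnorm(n * 33, 0, spec$noise_sigma), n, 33)
      seq$y <- seq$y + matrix(stats::rnorm(n * 33, 0, spec$noise_sigma), n, 33)
    }
    if (spec$dropout_prob > 0) {
      onset <- matrix(stats::runif(n * 33) < spec$dropout_prob, n, 33)
      for (j in seq_len(33)) {
        for (i in which(onset[, j])) {
          len <- 1L + stats::rgeom(1, 1 / max(1, spec$dropout_burst))
          seq$visibility[i:min(n, i + len - 1L), j] <- 0
        }
      }
    }
    seq
  })
}

#' Generate a full synthetic motion
#'
#' Trajectory generation + forward kinematics + corruption in one call.
#'
#' @param spec A [synthetic_motion_spec()].
#' @param skeleton A [skeleton_template()] (default standard proportions).
#' @param joints Joint table (default [default_joints()]).
#' @return A [pose_sequence()].
#' @export
generate_motion <- function(spec, skeleton = skeleton_template(),
                            joints = default_joints()) {
  angles <- lapply(spec$joints, function(j) {
    generate_angle_trajectory(j$baseline, j$rom, j$n_reps, spec$fps,
                              spec$duration, phase = j$phase %||% 0)
  })
  names(angles) <- vapply(spec$joints, function(j) j$joint, character(1))
  seq <- forward_kinematics(angles, skeleton, fps = spec$fps, joints = joints)
  corrupt(seq, spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a user/reference sequence pair
#'
#' Two sequences rendered through the same skeleton; any intended
#' discrepancy (different ROM, repetition count, tempo, corruption) is
#' exactly the difference between the two specs, giving ground truth for
#' end-to-end tests.
#'
#' @param user_spec,ref_spec [synthetic_motion_spec()]s.
#' @param skeleton Shared [skeleton_template()].
#' @param joints Joint table.
#' @return List with `user` and `reference` [pose_sequence()]s.
#' @export
make_pair <- function(user_spec, ref_spec, skeleton = skeleton_template(),
                      joints = default_joints()) {
  list(user = generate_motion(user_spec, skeleton, joints),
       reference = generate_motion(ref_spec, skeleton, joints))
}
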