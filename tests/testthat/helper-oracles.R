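# Independent oracles and small fixture builders used across the suite.

# Brute-force DTW: enumerate every monotone warping path (steps (1,0),
# (0,1), (1,1)) recursively and take the minimum accumulated squared cost.
# Feasible for series lengths <= 8; stays independent of dtw_align().
brute_force_dtw <- function(p, d) {
  n <- length(p); m <- length(d)
  best <- new.env()
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(best[[key]])) return(best[[key]])
    cost <- (p[i] - d[j])^2
    val <- if (i == 1 && j == 1) cost else {
      prev <- Inf
      if (i > 1) prev <- min(prev, rec(i - 1, j))
      if (j > 1) prev <- min(prev, rec(i, j - 1))
      if (i > 1 && j > 1) prev <- min(prev, rec(i - 1, j - 1))
      cost + prev
    }
    best[[key]] <- val
    val
  }
  sqrt(rec(n, m))
}

# Signed-angle oracle: atan2(|cross|, dot), independent of the arccos route.
atan2_angle <- function(p, v, d) {
  a <- p - v; b <- d - v
  atan2(abs(a[1] * b[2] - a[2] * b[1]), sum(a * b)) * 180 / pi
}

# A static standing pose: the default skeleton's base replicated n times.
static_pose_sequence <- function(n = 10, fps = 30) {
  sk <- skeleton_template()
  x <- matrix(rep(sk$base[, 1] / sk$width, each = n), n, 33)
  y <- matrix(rep(sk$base[, 2] / sk$height, each = n), n, 33)
  pose_sequence(x, y, matrix(1, n, 33), sk$width, sk$height, fps)
}

# Wrap a bare angle trajectory as a joint_angle_series (unit tests that
# exercise segmentation/summarization without rendering a skeleton).
as_angle_series <- function(angles, fps = 30, joint = "right_knee",
                            valid = NULL) {
  structure(list(joint = default_joints()[[joint]],
                 angles = angles,
                 valid = if (is.null(valid)) is.finite(angles) else valid,
                 fps = fps),
            class = "joint_angle_series")
}

# Minimal hand-built pixel sequence: landmarks at given coordinates.
pixel_seq_from_matrices <- function(X, Y, visibility = NULL,
                                    width = 1280, height = 720, fps = 30) {
  if (is.null(visibility)) visibility <- matrix(1, nrow(X), ncol(X))
  structure(list(X = X, Y = Y, visibility = visibility,
                 valid = matrix(TRUE, nrow(X), ncol(X)),
                 width = width, height = height, fps = fps),
            class = "pixel_sequence")
}

# A tiny valid pose sequence with all 33 landmarks, coordinates in [0,1].
tiny_pose_sequence <- function(n = 2, width = 1280, height = 720, fps = 60,
                               seed = 42) {
  set.seed(seed)
  x <- matrix(runif(n * 33, 0.2, 0.8), n, 33)
  y <- matrix(runif(n * 33, 0.2, 0.8), n, 33)
  vis <- matrix(runif(n * 33, 0.6, 1), n, 33)
  pose_sequence(x, y, vis, width, height, fps)
}
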