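#' Construct a pose sequence
#'
#' A pose sequence holds per-frame normalized landmark coordinates for the
#' 33-landmark topology plus video metadata. Coordinates follow the image
#' convention: `x` is a fraction of frame width, `y` a fraction of frame
#' height with y increasing downward. `z` (relative depth) is carried
#' through I/O untouched but unused by all downstream computation, which is
#' strictly planar.
#'
#' @param x,y Numeric matrices, frames x 33, normalized coordinates.
#' @param visibility Numeric matrix, frames x 33, confidences in `[0, 1]`.
#' @param width,height Frame dimensions in pixels.
#' @param fps Frame rate (frames per second).
#' @param z Optional frames x 33 matrix of relative depths.
#' @param frame_index Optional integer vector of 0-based frame ordinals;
#'   defaults to `0:(n-1)`.
#' @return A `pose_sequence` object.
#' @export
pose_sequence <- function(x, y, visibility, width, height, fps,
                          z = NULL, frame_index = NULL) {
  x <- as.matrix(x); y <- as.matrix(y); visibility <- as.matrix(visibility)
  n <- nrow(x)
  if (is.null(frame_index)) frame_index <- if (n > 0) 0:(n - 1L) else integer(0)
  structure(
    list(x = x, y = y, z = if (!is.null(z)) as.matrix(z) else NULL,
         visibility = visibility,
         width = as.numeric(width), height = as.numeric(height),
         fps = as.numeric(fps),
         frame_index = as.integer(frame_index)),
    class = "pose_sequence"
  )
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf("<pose_sequence> %d frames, %dx%d px, %.3g fps%s\n",
              n_frames(x), round(x$width), round(x$height), x$fps,
              if (is.null(x$z)) "" else ", with z"))
  invisible(x)
}

#' Number of frames in a sequence
#' @param seq A `pose_sequence`, `pixel_sequence` or `normalized_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) {
  m <- if (!is.null(seq$x)) seq$x else seq$X
  nrow(m)
}

issue_row <- function(frame, landmark, code, severity, message) {
  data.frame(frame = frame, landmark = landmark, code = code,
             severity = severity, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a pose sequence
#'
#' Checks every declared invariant — landmark count, coordinate finiteness,
#' visibility range, monotone frame indices, metadata positivity — and
#' reports all violations without mutating the sequence. Coordinates
#' slightly outside `[0, 1]` (a landmark leaving the frame) are flagged as
#' warnings, not errors.
#'
#' @param seq A [pose_sequence()].
#' @return A `validation_report`: list with `ok` (no error-severity issue)
#'   and `issues` (data frame with columns frame, landmark, code, severity,
#'   message; frame/landmark are 0-based, `NA` where not applicable).
#' @export
validate_sequence <- function(seq) {
  issues <- list()
  add <- function(...) issues[[length(issues) + 1L]] <<- issue_row(...)

  if (!is.finite(seq$width) || seq$width <= 0)
    add(NA, NA, "metadata", "error", "width must be > 0")
  if (!is.finite(seq$height) || seq$height <= 0)
    add(NA, NA, "metadata", "error", "height must be > 0")
  if (!is.finite(seq$fps) || seq$fps <= 0)
    add(NA, NA, "metadata", "error", "fps must be > 0")

  if (ncol(seq$x) != 33L || ncol(seq$y) != 33L || ncol(seq$visibility) != 33L)
    add(NA, NA, "landmark_count", "error",
        sprintf("expected 33 landmarks, found %d", ncol(seq$x)))

  n <- n_frames(seq)
  if (n > 1 && any(diff(seq$frame_index) <= 0))
    add(which(diff(seq$frame_index) <= 0)[1], NA, "frame_index", "error",
        "frame indices must be strictly increasing")

  if (n > 0 && ncol(seq$x) == 33L) {
    bad <- which(!is.finite(seq$x) | !is.finite(seq$y), arr.ind = TRUE)
    for (k in seq_len(nrow(bad)))
      add(bad[k, 1] - 1L, bad[k, 2] - 1L, "nonfinite_coordinate", "error",
          "coordinate is not finite")
    vb <- which(!is.finite(seq$visibility) | seq$visibility < 0 | seq$visibility > 1,
                arr.ind = TRUE)
    for (k in seq_len(nrow(vb)))
      add(vb[k, 1] - 1L, vb[k, 2] - 1L, "visibility_range", "error",
          sprintf("visibility %.4g outside [0, 1]", seq$visibility[vb[k, 1], vb[k, 2]]))
    fin <- is.finite(seq$x) & is.finite(seq$y)
    oob <- which(fin & (seq$x < -0.5 | seq$x > 1.5 | seq$y < -0.5 | seq$y > 1.5),
                 arr.ind = TRUE)
    # values mildly outside [0,1] are tolerated silently; gross excursions flagged
    for (k in seq_len(nrow(oob)))
      add(oob[k, 1] - 1L, oob[k, 2] - 1L, "coordinate_out_of_frame", "warning",
          "normalized coordinate far outside [0, 1]")
  }

  issues <- if (length(issues)) do.call(rbind, issues) else
    issue_row(integer(0), integer(0), character(0), character(0), character(0))
  structure(list(ok = !any(issues$severity == "error"), issues = issues),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> ok = %s, %d issue(s)\n", x$ok, nrow(x$issues)))
  if (nrow(x$issues)) print(utils::head(x$issues, 20))
  invisible(x)
}
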