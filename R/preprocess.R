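#' Convert normalized coordinates to pixels
#'
#' Maps each landmark's normalized coordinates to absolute pixel positions,
#' `X = x * width`, `Y = y * height`. Visibility is passed through
#' unchanged; every landmark starts out valid.
#'
#' @param seq A [pose_sequence()].
#' @return A `pixel_sequence`: list with frames x 33 matrices `X`, `Y`,
#'   `visibility`, a logical `valid` matrix, and `width`, `height`, `fps`.
#' @export
to_pixel <- function(seq) {
  if (!is.finite(seq$width) || seq$width <= 0 || !is.finite(seq$height) || seq$height <= 0)
    stop("width and height must be positive")
  structure(
    list(X = seq$x * seq$width, Y = seq$y * seq$height,
         visibility = seq$visibility,
         valid = is.finite(seq$x) & is.finite(seq$y),
         width = seq$width, height = seq$height, fps = seq$fps),
    class = "pixel_sequence"
  )
}

#' @export
print.pixel_sequence <- function(x, ...) {
  cat(sprintf("<pixel_sequence> %d frames, %dx%d px, %.3g fps\n",
              nrow(x$X), round(x$width), round(x$height), x$fps))
  invisible(x)
}

new_bounding_box <- function(min_x, min_y, max_x, max_y, buffer) {
  if (min_x >= max_x || min_y >= max_y) stop("degenerate bounding box")
  structure(list(min_x = min_x, min_y = min_y, max_x = max_x, max_y = max_y,
                 buffer = buffer),
            class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box> (%.1f, %.1f) - (%.1f, %.1f), buffer %.1f\n",
              x$min_x, x$min_y, x$max_x, x$max_y, x$buffer))
  invisible(x)
}

box_from_points <- function(X, Y, buffer, width, height) {
  new_bounding_box(
    min_x = max(0, min(X) - buffer),
    min_y = max(0, min(Y) - buffer),
    max_x = min(width, max(X) + buffer),
    max_y = min(height, max(Y) + buffer),
    buffer = buffer
  )
}

#' Bounding box of a single frame
#'
#' The box spans the extreme horizontal and vertical positions of the
#' landmarks that pass the visibility threshold, expanded by a buffer so
#' limb movement near the edges is not truncated, and clamped to the frame.
#'
#' @param seq A `pixel_sequence`.
#' @param frame 1-based frame number.
#' @param buffer Margin in pixels (default 5% of the larger frame dimension).
#' @param visibility_threshold Minimum visibility for a landmark to count.
#' @return A `bounding_box`.
#' @export
frame_bounding_box <- function(seq, frame, buffer = NULL, visibility_threshold = 0.5) {
  if (is.null(buffer)) buffer <- 0.05 * max(seq$width, seq$height)
  if (buffer < 0) stop("buffer must be >= 0")
  keep <- seq$valid[frame, ] & seq$visibility[frame, ] >= visibility_threshold
  if (!any(keep)) {
    stop(sprintf("degenerate frame %d: no landmark passes visibility threshold %.2f",
                 frame, visibility_threshold))
  }
  box_from_points(seq$X[frame, keep], seq$Y[frame, keep], buffer, seq$width, seq$height)
}

#' Fixed maximum bounding box over a whole sequence
#'
#' The union of all per-frame boxes (elementwise min of minima, max of
#' maxima). Using one fixed box as the normalization frame removes the
#' frame-to-frame jitter that per-frame boxes re-introduce when keypoint
#' detection wobbles. Frames where no landmark passes the threshold are
#' skipped; if every frame is degenerate an error is raised.
#'
#' @inheritParams frame_bounding_box
#' @return A `bounding_box` containing every per-frame box.
#' @export
max_bounding_box <- function(seq, buffer = NULL, visibility_threshold = 0.5) {
  n <- nrow(seq$X)
  if (n == 0) stop("empty sequence")
  if (is.null(buffer)) buffer <- 0.05 * max(seq$width, seq$height)
  keep <- seq$valid & seq$visibility >= visibility_threshold
  if (!any(keep)) stop("all frames degenerate: no landmark ever passes the visibility threshold")
  box_from_points(seq$X[keep], seq$Y[keep], buffer, seq$width, seq$height)
}

#' Normalize pixel coordinates to a bounding box
#'
#' Re-anchors every landmark to the top-left corner of the (fixed) box:
#' `X_final = (X - min_x) / box_width`, `Y_final = (Y - min_y) /
#' box_height`. Landmarks inside the box land in the unit square.
#'
#' @param seq A `pixel_sequence`.
#' @param box A `bounding_box`, typically from [max_bounding_box()].
#' @return A `normalized_sequence` (same fields as a pixel sequence plus
#'   the `box` used; `X`/`Y` now dimensionless).
#' @export
normalize_to_box <- function(seq, box) {
  bw <- box$max_x - box$min_x
  bh <- box$max_y - box$min_y
  if (bw <= 0 || bh <= 0) stop("zero-width or zero-height bounding box")
  structure(
    list(X = (seq$X - box$min_x) / bw, Y = (seq$Y - box$min_y) / bh,
         visibility = seq$visibility, valid = seq$valid,
         box = box, fps = seq$fps, width = seq$width, height = seq$height),
    class = "normalized_sequence"
  )
}

#' @export
print.normalized_sequence <- function(x, ...) {
  cat(sprintf("<normalized_sequence> %d frames, box %.0fx%.0f px, %.3g fps\n",
              nrow(x$X), x$box$max_x - x$box$min_x, x$box$max_y - x$box$min_y, x$fps))
  invisible(x)
}

fill_matrix_gaps <- function(X, Y, visibility, valid, threshold, max_gap) {
  n <- nrow(X)
  for (j in seq_len(ncol(X))) {
    bad <- !valid[, j] | visibility[, j] < threshold
    if (!any(bad)) next
    r <- rle(bad)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      a <- starts[k] - 1L   # last good frame before the run (0 if none)
      b <- ends[k] + 1L     # first good frame after the run
      if (a >= 1L && b <= n && r$lengths[k] <= max_gap) {
        span <- starts[k]:ends[k]
        w <- (span - a) / (b - a)
        X[span, j] <- X[a, j] + w * (X[b, j] - X[a, j])
        Y[span, j] <- Y[a, j] + w * (Y[b, j] - Y[a, j])
        valid[span, j] <- TRUE
      } else {
        valid[starts[k]:ends[k], j] <- FALSE
      }
    }
  }
  list(X = X, Y = Y, valid = valid)
}

#' Fill short low-visibility gaps by interpolation
#'
#' Landmarks whose visibility drops below `threshold` are replaced by
#' linear interpolation between the nearest passing frames when the gap is
#' at most `max_gap` frames. Longer gaps (and gaps touching the sequence
#' boundary) are marked invalid so downstream stages can exclude them.
#'
#' @param seq A `pixel_sequence` or `normalized_sequence`.
#' @param threshold Visibility threshold (default 0.5).
#' @param max_gap Longest gap, in frames, that will be bridged (default 5).
#' @return A sequence of the same class with gaps filled and `valid` updated.
#' @export
fill_low_visibility <- function(seq, threshold = 0.5, max_gap = 5) {
  f <- fill_matrix_gaps(seq$X, seq$Y, seq$visibility, seq$valid, threshold, max_gap)
  seq$X <- f$X; seq$Y <- f$Y; seq$valid <- f$valid
  seq
}

#' Centered moving-average smoothing
#'
#' Smooths a numeric series with a centered moving average of odd width.
#' At the boundaries the window is truncated to the available samples, so
#' the output has the same length as the input and `window = 1` is the
#' identity. `NA`s are ignored within each window.
#'
#' @param x Numeric vector.
#' @param window Odd window width in frames, `>= 1`.
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_series <- function(x, window = 5) {
  if (length(window) != 1 || !is.finite(window) || window < 1 || window %% 2 == 0)
    stop("window must be an odd positive integer")
  window <- as.integer(window)
  if (window == 1L) return(x)
  n <- length(x)
  half <- window %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)   # truncate at the edges
    hi <- min(n, i + half)
    w <- x[lo:hi]
    out[i] <- if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }
  out
}
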