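#' Read a pose-keypoint JSON file
#'
#' Reads the structured JSON produced by 33-landmark pose extraction. The
#' envelope has top-level keys `Timeline` (with `Items`, the per-frame
#' records), `TotalNumberOfFrames`, `Width`, `Height` and `AverageFPS`;
#' each frame record carries a 0-based `Index` and 33 `Landmarks`, each
#' with `x`, `y`, optional `z`, and `visibility`. The machine-readable
#' schema ships at `system.file("extdata", "pose-schema.json", package =
#' "kinescore")`.
#'
#' @param path Path to a JSON file.
#' @return A [pose_sequence()].
#' @export
read_pose_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)

  for (key in c("Timeline", "TotalNumberOfFrames", "Width", "Height", "AverageFPS")) {
    if (is.null(raw[[key]])) stop("schema error: missing required key '", key, "'")
  }
  if (is.null(raw$Timeline$Items)) stop("schema error: missing required key 'Timeline.Items'")

  items <- raw$Timeline$Items
  n <- length(items)
  x <- y <- z <- vis <- matrix(NA_real_, n, 33)
  idx <- integer(n)
  has_z <- FALSE
  for (i in seq_len(n)) {
    fr <- items[[i]]
    lms <- fr$Landmarks
    if (is.null(lms) || length(lms) != 33L) {
      stop(sprintf("structural error: frame %d has %d landmarks (expected 33)",
                   i - 1L, length(lms)))
    }
    idx[i] <- if (!is.null(fr$Index)) as.integer(fr$Index) else i - 1L
    for (j in seq_len(33L)) {
      lm <- lms[[j]]
      if (!is.numeric(lm$x) || !is.numeric(lm$y)) {
        stop(sprintf("parse error: non-numeric coordinate at frame %d, landmark %d",
                     i - 1L, j - 1L))
      }
      x[i, j] <- lm$x
      y[i, j] <- lm$y
      vis[i, j] <- if (!is.null(lm$visibility)) as.numeric(lm$visibility) else 1
      if (!is.null(lm$z)) { z[i, j] <- as.numeric(lm$z); has_z <- TRUE }
    }
  }
  pose_sequence(x, y, vis,
                width = raw$Width, height = raw$Height, fps = raw$AverageFPS,
                z = if (has_z) z else NULL, frame_index = idx)
}

#' Write a pose sequence to JSON
#'
#' Inverse of [read_pose_json()]: the emitted file re-reads to an equal
#' sequence (coordinates at full double precision) and follows the shipped
#' schema exactly.
#'
#' @param seq A valid [pose_sequence()] (checked with [validate_sequence()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pose_json <- function(seq, path) {
  rep_ <- validate_sequence(seq)
  if (!rep_$ok) {
    bad <- rep_$issues[rep_$issues$severity == "error", , drop = FALSE]
    stop("refusing to write invalid sequence: ", bad$code[1], " - ", bad$message[1])
  }
  n <- n_frames(seq)
  items <- vector("list", n)
  for (i in seq_len(n)) {
    lms <- vector("list", 33L)
    for (j in seq_len(33L)) {
      lm <- list(x = seq$x[i, j], y = seq$y[i, j])
      if (!is.null(seq$z) && is.finite(seq$z[i, j])) lm$z <- seq$z[i, j]
      lm$visibility <- seq$visibility[i, j]
      lms[[j]] <- lm
    }
    items[[i]] <- list(Index = seq$frame_index[i], Landmarks = lms)
  }
  doc <- list(
    Timeline = list(Items = items),
    TotalNumberOfFrames = n,
    Width = seq$width,
    Height = seq$height,
    AverageFPS = seq$fps
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Path to the shipped pose JSON schema
#' @return Filesystem path of the machine-readable schema document.
#' @export
pose_schema_path <- function() {
  system.file("extdata", "pose-schema.json", package = "kinescore")
}
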