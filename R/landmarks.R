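#' The 33-landmark pose topology
#'
#' Names of the 33 anatomical landmarks in the standard full-body pose
#' topology, in index order. Landmark indices used throughout the package
#' (joint triplets, exports) are 0-based to match the on-disk JSON schema;
#' in-memory matrices use the corresponding 1-based R column.
#'
#' @return Character vector of length 33 (landmark 0 first).
#' @export
landmark_names <- function() {
  c("nose",
    "left_eye_inner", "left_eye", "left_eye_outer",
    "right_eye_inner", "right_eye", "right_eye_outer",
    "left_ear", "right_ear",
    "mouth_left", "mouth_right",
    "left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow",
    "left_wrist", "right_wrist",
    "left_pinky", "right_pinky",
    "left_index", "right_index",
    "left_thumb", "right_thumb",
    "left_hip", "right_hip",
    "left_knee", "right_knee",
    "left_ankle", "right_ankle",
    "left_heel", "right_heel",
    "left_foot_index", "right_foot_index")
}

#' Look up a landmark's 0-based index by name
#' @param name Landmark name (see [landmark_names()]).
#' @return Integer 0-based index.
#' @export
landmark_index <- function(name) {
  idx <- match(name, landmark_names())
  if (anyNA(idx)) stop("unknown landmark name: ", paste(name[is.na(idx)], collapse = ", "))
  idx - 1L
}

#' Define a joint as a landmark triplet
#'
#' A joint angle is measured at the `vertex` landmark between the limb
#' vectors pointing to the `proximal` and `distal` landmarks.
#'
#' @param name Joint label, e.g. `"right_elbow"`.
#' @param proximal,vertex,distal 0-based landmark indices.
#' @param plane Anatomical plane label (`"sagittal"` or `"frontal"`),
#'   used for reporting only.
#' @return A `joint_definition` object.
#' @export
joint_definition <- function(name, proximal, vertex, distal, plane = "sagittal") {
  idx <- as.integer(c(proximal, vertex, distal))
  if (length(unique(idx)) != 3L) stop("joint triplet must use three distinct landmarks")
  if (any(idx < 0L | idx > 32L)) stop("landmark indices must be in [0, 32]")
  structure(
    list(name = as.character(name), triplet = idx, plane = as.character(plane)),
    class = "joint_definition"
  )
}

#' @export
print.joint_definition <- function(x, ...) {
  nm <- landmark_names()[x$triplet + 1L]
  cat(sprintf("<joint_definition> %s (%s): %s -> %s -> %s\n",
              x$name, x$plane, nm[1], nm[2], nm[3]))
  invisible(x)
}

#' Default joint-triplet table
#'
#' The default set of tracked joints. The mapping of joint names to landmark
#' triplets is a configuration, not an anatomical absolute: it is shipped as
#' an editable CSV (`system.file("extdata", "joints.csv", package =
#' "kinescore")`) so a clinician can redefine triplets per protocol.
#'
#' Conventions: elbow = (shoulder, elbow, wrist); shoulder = (hip, shoulder,
#' elbow); hip sagittal = (shoulder, hip, knee); hip frontal =
#' (contralateral hip, hip, knee); knee = (hip, knee, ankle).
#'
#' @param path Optional path to an alternative joints CSV with columns
#'   `name, proximal, vertex, distal, plane` (0-based indices).
#' @return Named list of [joint_definition()] objects.
#' @export
default_joints <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "joints.csv", package = "kinescore")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "proximal", "vertex", "distal", "plane")
  if (!all(need %in% names(tab))) {
    stop("joints table must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    joint_definition(tab$name[i], tab$proximal[i], tab$vertex[i], tab$distal[i], tab$plane[i])
  })
  names(out) <- tab$name
  out
}
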