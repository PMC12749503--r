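deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

#' Joint angle at a vertex landmark
#'
#' Angle between the limb vectors `a = proximal - vertex` and
#' `b = distal - vertex`, computed with the cosine rule
#' `theta = arccos(a . b / (|a| |b|))` and returned in degrees, in
#' `[0, 180]`. The angle is invariant under translation, rotation and
#' uniform positive scaling of the three points, which is what makes
#' angular features robust to camera placement and subject size.
#'
#' @param p_proximal,p_vertex,p_distal Numeric length-2 points `(x, y)`.
#' @return Angle in degrees.
#' @export
joint_angle <- function(p_proximal, p_vertex, p_distal) {
  a <- p_proximal - p_vertex
  b <- p_distal - p_vertex
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("degenerate geometry: zero-length limb vector")
  # clamp against rounding before arccos
  deg(acos(max(-1, min(1, sum(a * b) / (na * nb)))))
}

angle_cols <- function(seq, triplet) {
  # vectorized over frames; triplet is 0-based
  p <- triplet[1] + 1L; v <- triplet[2] + 1L; d <- triplet[3] + 1L
  ax <- seq$X[, p] - seq$X[, v]; ay <- seq$Y[, p] - seq$Y[, v]
  bx <- seq$X[, d] - seq$X[, v]; by <- seq$Y[, d] - seq$Y[, v]
  na <- sqrt(ax^2 + ay^2); nb <- sqrt(bx^2 + by^2)
  cosv <- (ax * bx + ay * by) / (na * nb)
  ang <- deg(acos(pmax(-1, pmin(1, cosv))))
  list(angles = ang, degenerate = !is.finite(cosv))
}

#' Per-frame joint-angle series
#'
#' Computes the angle of one joint on every frame. By default angles are
#' measured on pixel coordinates (or any isotropic scaling of them):
#' anisotropic box-normalized coordinates distort angles, so the
#' box-normalized representation is reserved for trajectory-level
#' comparison, not for angle measurement.
#'
#' @param seq A `pixel_sequence` (recommended) or `normalized_sequence`.
#' @param joint A [joint_definition()].
#' @return A `joint_angle_series`: list with `joint`, `angles` (degrees,
#'   `NA` where invalid), `valid` (logical), `fps`.
#' @export
angle_series <- function(seq, joint) {
  n <- nrow(seq$X)
  if (n == 0) stop("empty sequence")
  ac <- angle_cols(seq, joint$triplet)
  tripcols <- joint$triplet + 1L
  valid <- rowSums(!seq$valid[, tripcols, drop = FALSE]) == 0 & !ac$degenerate
  angles <- ac$angles
  angles[!valid] <- NA_real_
  structure(list(joint = joint, angles = angles, valid = valid, fps = seq$fps),
            class = "joint_angle_series")
}

#' @export
print.joint_angle_series <- function(x, ...) {
  cat(sprintf("<joint_angle_series> %s: %d frames (%d valid), %.3g fps\n",
              x$joint$name, length(x$angles), sum(x$valid), x$fps))
  invisible(x)
}

#' Range of motion of an angle series
#'
#' `ROM = theta_max - theta_min` over the valid frames.
#'
#' @param series A `joint_angle_series`.
#' @return A `kinematic_summary` with `rom`, `theta_max`, `theta_min`
#'   (degrees).
#' @export
range_of_motion <- function(series) {
  a <- series$angles[series$valid]
  if (length(a) == 0) stop("no valid frame in angle series")
  structure(list(rom = max(a) - min(a), theta_max = max(a), theta_min = min(a)),
            class = "kinematic_summary")
}

#' @export
print.kinematic_summary <- function(x, ...) {
  cat(sprintf("<kinematic_summary> ROM %.2f deg (max %.2f, min %.2f)\n",
              x$rom, x$theta_max, x$theta_min))
  if (!is.null(x$mean_velocity))
    cat(sprintf("  mean |velocity| %.2f deg/s\n", x$mean_velocity))
  invisible(x)
}

#' Angular velocity by central differences
#'
#' `v(t) = (theta(t+1) - theta(t-1)) / (2 dt)` on interior frames, with
#' one-sided differences at the first and last frame; `dt = 1/fps`. The
#' central stencil halves high-frequency noise relative to forward
#' differences and is exact for affine trajectories.
#'
#' @param series A `joint_angle_series`.
#' @return A `velocity_series`: `values` in degrees/second (`NA` where any
#'   stencil frame is invalid) and `fps`.
#' @export
angular_velocity <- function(series) {
  th <- series$angles
  n <- length(th)
  if (n < 3) stop("need at least 3 frames for velocity estimation")
  dt <- 1 / series$fps
  v <- rep(NA_real_, n)
  v[1] <- (th[2] - th[1]) / dt
  v[n] <- (th[n] - th[n - 1]) / dt
  i <- 2:(n - 1)
  v[i] <- (th[i + 1] - th[i - 1]) / (2 * dt)
  structure(list(values = v, fps = series$fps), class = "velocity_series")
}

#' Standardize a series to zero mean and unit variance
#'
#' `X'' = (X - mu) / sigma` with the population standard deviation
#' (divisor `n`). A constant series carries no shape information for
#' correlation, so it maps to all zeros with `constant = TRUE` rather than
#' raising.
#'
#' @param x Numeric series, length `>= 2` (`NA`s dropped from the moments).
#' @return A `standardized_series`: `values`, `mu`, `sigma`, `constant`.
#' @export
standardize <- function(x) {
  if (length(x) < 2) stop("series must have length >= 2")
  xs <- x[is.finite(x)]
  mu <- mean(xs)
  sigma <- sqrt(mean((xs - mu)^2))   # population sd
  if (sigma == 0) {
    return(structure(list(values = rep(0, length(x)), mu = mu, sigma = 0,
                          constant = TRUE),
                     class = "standardized_series"))
  }
  structure(list(values = (x - mu) / sigma, mu = mu, sigma = sigma,
                 constant = FALSE),
            class = "standardized_series")
}

#' Per-repetition kinematic summary
#'
#' Computes each accepted repetition's ROM and mean absolute angular
#' velocity, then aggregates across repetitions as mean and sample
#' standard deviation (divisor `n - 1`, the convention for summarizing a
#' sample of repetitions; contrast the population divisor used by
#' [standardize()] for signal conditioning). A single repetition reports
#' `sd = 0` with `single_rep = TRUE`.
#'
#' @param series A `joint_angle_series`.
#' @param reps A `repetition_set` from [segment_repetitions()].
#' @return A `kinematic_summary` with `rom`, `rom_sd`, `mean_velocity`,
#'   `velocity_sd`, `n_reps`, `per_rep` (data frame), `single_rep`.
#' @export
summarize_repetitions <- function(series, reps) {
  seg <- reps$segments[reps$segments$accepted, , drop = FALSE]
  if (nrow(seg) == 0) stop("no accepted repetition to summarize")
  vel <- angular_velocity(series)$values
  per <- lapply(seq_len(nrow(seg)), function(k) {
    span <- seg$start_frame[k]:seg$end_frame[k]
    a <- series$angles[span]
    a <- a[is.finite(a)]
    v <- vel[span]
    data.frame(rep = k,
               rom = max(a) - min(a),
               theta_max = max(a), theta_min = min(a),
               mean_abs_velocity = mean(abs(v), na.rm = TRUE))
  })
  per <- do.call(rbind, per)
  single <- nrow(per) == 1L
  structure(list(
    rom = mean(per$rom),
    rom_sd = if (single) 0 else stats::sd(per$rom),
    theta_max = mean(per$theta_max),
    theta_min = mean(per$theta_min),
    mean_velocity = mean(per$mean_abs_velocity),
    velocity_sd = if (single) 0 else stats::sd(per$mean_abs_velocity),
    n_reps = nrow(per), per_rep = per, single_rep = single
  ), class = "kinematic_summary")
}

# Read the signal value at an extremum by fitting a local quadratic around
# the anchor frame (window +/- h, clipped at the ends). The fit's vertex
# value is used when the vertex falls inside the window; otherwise the
# fitted value at the anchor. A quadratic matches the local curvature, so
# unlike a moving average this read-off has no systematic apex bias.
quadratic_extreme <- function(a, center, h) {
  lo <- max(1L, center - h); hi <- min(length(a), center + h)
  t <- (lo:hi) - center
  y <- a[lo:hi]
  # an anchor at the series edge is itself a cycle extremum, so the signal
  # is locally symmetric about it: mirror the observed side to make the
  # read-off point central (an edge read of a one-sided fit would carry
  # nearly the full per-frame noise)
  if (center - lo < h && hi - center >= 2L) {
    keep <- t > 0
    t <- c(-rev(t[keep]), t)
    y <- c(rev(y[keep]), y)
  } else if (hi - center < h && center - lo >= 2L) {
    keep <- t < 0
    t <- c(t, -rev(t[keep]))
    y <- c(y, rev(y[keep]))
  }
  if (length(unique(t)) < 3) return(a[center])
  fit <- stats::lm.fit(cbind(1, t, t^2), y)$coefficients
  if (is.na(fit[3]) || fit[3] == 0) return(unname(fit[1]))
  tv <- -fit[2] / (2 * fit[3])
  # only trust the vertex when it lies inside the fitted data span
  # (one-sided boundary windows would otherwise extrapolate)
  if (tv >= min(t) && tv <= max(t)) unname(fit[1] + fit[2] * tv + fit[3] * tv^2)
  else unname(fit[1])
}

#' Noise-robust ROM estimate anchored at detected cycle extremes
#'
#' The plain max-min excursion of [range_of_motion()] is the right reading
#' of ROM for clean trajectories, but on noisy keypoint data the maximum
#' of hundreds of jittered samples is biased upward (and the minimum
#' downward) purely by order statistics. This estimator instead reads the
#' angle at the detected repetition peaks and at the segment boundary
#' troughs via a local quadratic fit (about 0.15 s of frames on either
#' side), and averages across repetitions — one sample per extreme per
#' cycle, so neither the order-statistics inflation nor a moving-average
#' apex bias enters.
#'
#' @param series A `joint_angle_series`.
#' @param reps A `repetition_set` segmented from the same series.
#' @param fit_halfwidth Half-width of the quadratic fit window in frames;
#'   default one eighth of the mean detected repetition period, so the
#'   window scales with the movement's own timescale and the local
#'   quadratic remains a faithful model of the apex.
#' @return A `kinematic_summary` with `rom`, `theta_max`, `theta_min`.
#' @export
estimate_rom <- function(series, reps, fit_halfwidth = NULL) {
  seg <- reps$segments
  if (nrow(seg) == 0) stop("no repetition to anchor the ROM estimate")
  if (is.null(fit_halfwidth)) {
    period <- mean(seg$end_frame - seg$start_frame)
    fit_halfwidth <- max(2L, round(period / 8))
  }
  a <- bridge_na(series$angles)
  peaks <- seg$peak_frame
  troughs <- unique(c(seg$start_frame, seg$end_frame))
  # anchor only on extremes whose frames were actually observed; a dropout
  # burst at a boundary would otherwise leak its bridged value into the mean
  ok_p <- peaks[series$valid[peaks]]
  ok_t <- troughs[series$valid[troughs]]
  if (length(ok_p)) peaks <- ok_p
  if (length(ok_t)) troughs <- ok_t
  theta_max <- mean(vapply(peaks, function(p) quadratic_extreme(a, p, fit_halfwidth),
                           numeric(1)))
  theta_min <- mean(vapply(troughs, function(p) quadratic_extreme(a, p, fit_halfwidth),
                           numeric(1)))
  structure(list(rom = theta_max - theta_min, theta_max = theta_max,
                 theta_min = theta_min),
            class = "kinematic_summary")
}

#' Export per-frame angle and velocity tables
#'
#' Writes a CSV with columns `frame` (0-based, file convention), `time_s`,
#' `joint`, `angle_deg`, `velocity_deg_s`, `valid` for one or more joints.
#'
#' @param seq A `pixel_sequence`.
#' @param joints Named list of [joint_definition()]s.
#' @param path Output CSV path.
#' @return The table, invisibly.
#' @export
export_angle_csv <- function(seq, joints, path) {
  rows <- lapply(joints, function(j) {
    s <- angle_series(seq, j)
    v <- angular_velocity(s)
    data.frame(frame = seq_along(s$angles) - 1L,
               time_s = (seq_along(s$angles) - 1L) / s$fps,
               joint = j$name,
               angle_deg = s$angles,
               velocity_deg_s = v$values,
               valid = s$valid)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
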