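local_maxima <- function(x) {
  # indices of strict local maxima; plateau peaks resolve to the plateau midpoint
  n <- length(x)
  if (n < 3) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L   # walk the plateau
      if (j < n && x[j + 1L] < x[i]) {
        out <- c(out, (i + j) %/% 2L)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

peak_prominence <- function(x, peak) {
  # topographic prominence: on each side, walk to the nearest sample higher
  # than the peak (or the series end); the base is the minimum en route.
  # prominence = peak height - the higher of the two bases.
  h <- x[peak]
  n <- length(x)
  left <- x[seq_len(peak)]
  higher_l <- which(left > h)
  lo_l <- if (length(higher_l)) max(higher_l) + 1L else 1L
  base_l <- min(left[lo_l:peak])
  right <- x[peak:n]
  higher_r <- which(right > h)
  hi_r <- if (length(higher_r)) min(higher_r) - 1L else length(right)
  base_r <- min(right[1:hi_r])
  h - max(base_l, base_r)
}

#' Detect peaks in a numeric series
#'
#' Local maxima filtered by topographic prominence and a minimum
#' inter-peak distance. Plateau peaks resolve to the plateau midpoint.
#' When two candidates fall within `min_distance` of each other, the more
#' prominent one survives.
#'
#' @param x Numeric series (length `>= 3`; `NA`s are bridged by linear
#'   interpolation before detection).
#' @param min_prominence Minimum prominence, in the units of `x`.
#' @param min_distance Minimum separation between kept peaks, in frames.
#' @return Strictly increasing integer vector of peak indices (1-based);
#'   may be empty.
#' @export
detect_peaks <- function(x, min_prominence = 0, min_distance = 1) {
  if (length(x) < 3) stop("series must have length >= 3")
  x <- bridge_na(x)
  cand <- local_maxima(x)
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(p) peak_prominence(x, p), numeric(1))
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(integer(0))
  # enforce min_distance greedily by decreasing prominence
  ord <- order(-prom, cand)
  chosen <- integer(0)
  for (k in ord) {
    if (!length(chosen) || all(abs(chosen - cand[k]) >= min_distance)) {
      chosen <- c(chosen, cand[k])
    }
  }
  sort(chosen)
}

bridge_na <- function(x) {
  if (!anyNA(x)) return(x)
  ok <- which(is.finite(x))
  if (length(ok) < 2) return(x)
  x[-ok] <- stats::approx(ok, x[ok], xout = seq_along(x)[-ok], rule = 2)$y
  x
}

#' Segment an angle trajectory into repetitions
#'
#' Peaks in the angle trajectory mark the midpoint of each repetition;
#' troughs — found by running the same peak detector on the negated
#' (inverted) signal — mark repetition boundaries. Each repetition spans
#' trough -> peak -> trough; the sequence boundaries act as virtual
#' troughs for the first and last repetitions so that recordings that
#' start or stop mid-hold are not silently dropped.
#'
#' @param series A `joint_angle_series`.
#' @param min_prominence Minimum peak prominence in degrees; default 20\%
#'   of the observed (smoothed) signal range.
#' @param min_distance Minimum inter-peak separation in frames; default
#'   `0.25 s * fps`.
#' @param smooth_window Odd moving-average window applied before detection
#'   (default 5; use 1 to disable).
#' @return A `repetition_set`: `segments` data frame (`start_frame`,
#'   `peak_frame`, `end_frame`, `accepted`, `boundary`), `detected_count`,
#'   `joint`, plus the detection parameters used.
#' @export
segment_repetitions <- function(series, min_prominence = NULL, min_distance = NULL,
                                smooth_window = 5) {
  x <- smooth_series(bridge_na(series$angles), smooth_window)
  if (all(!is.finite(x))) stop("angle series has no valid span")
  if (is.null(min_distance)) min_distance <- max(1L, round(0.25 * series$fps))
  rng <- max(x) - min(x)
  if (is.null(min_prominence)) min_prominence <- 0.2 * rng
  n <- length(x)

  if (rng == 0) {
    segs <- data.frame(start_frame = integer(0), peak_frame = integer(0),
                       end_frame = integer(0), accepted = logical(0),
                       boundary = logical(0))
  } else {
    peaks <- detect_peaks(x, min_prominence, min_distance)
    troughs <- detect_peaks(-x, min_prominence, min_distance)
    segs <- lapply(peaks, function(p) {
      before <- troughs[troughs < p]
      after <- troughs[troughs > p]
      data.frame(start_frame = if (length(before)) max(before) else 1L,
                 peak_frame = p,
                 end_frame = if (length(after)) min(after) else n,
                 accepted = TRUE,
                 boundary = !length(before) || !length(after))
    })
    segs <- if (length(segs)) do.call(rbind, segs) else
      data.frame(start_frame = integer(0), peak_frame = integer(0),
                 end_frame = integer(0), accepted = logical(0),
                 boundary = logical(0))
  }
  structure(list(segments = segs, detected_count = nrow(segs),
                 joint = series$joint$name,
                 min_prominence = min_prominence, min_distance = min_distance,
                 smooth_window = smooth_window),
            class = "repetition_set")
}

#' @export
print.repetition_set <- function(x, ...) {
  cat(sprintf("<repetition_set> %s: %d repetition(s), %d accepted\n",
              x$joint, x$detected_count, sum(x$segments$accepted)))
  if (nrow(x$segments)) print(x$segments)
  invisible(x)
}

#' Repetition-count error
#'
#' Percentage deviation between detected and actual repetition counts,
#' `|detected - actual| / actual * 100`.
#'
#' @param detected,actual Integer counts; `actual >= 1`.
#' @return A `count_error`: `detected`, `actual`, `error_percent`.
#' @export
count_error <- function(detected, actual) {
  if (actual < 1) stop("actual repetition count must be >= 1")
  structure(list(detected = as.integer(detected), actual = as.integer(actual),
                 error_percent = abs(detected - actual) / actual * 100),
            class = "count_error")
}

#' @export
print.count_error <- function(x, ...) {
  cat(sprintf("<count_error> detected %d / actual %d -> %.1f%%\n",
              x$detected, x$actual, x$error_percent))
  invisible(x)
}

pad_to_peak <- function(values, peak_off, target_peak_off, target_len) {
  # edge-value padding so the peak lands at target_peak_off in a
  # target_len-long window
  left <- target_peak_off - peak_off
  if (left > 0) values <- c(rep(values[1], left), values)
  right <- target_len - length(values)
  if (right > 0) values <- c(values, rep(values[length(values)], right))
  values
}

#' Pair user and reference repetitions
#'
#' Pairs repetitions ordinally (i-th with i-th) up to the smaller count —
#' the repetition-by-repetition comparison the scoring stage needs. Within
#' each pair the shorter angle window is edge-value padded so both windows
#' share one length with their peaks index-aligned.
#'
#' @param user_reps,ref_reps `repetition_set`s.
#' @param user_series,ref_series The `joint_angle_series` each set was
#'   segmented from.
#' @return A `repetition_pairs` object: list of pairs, each with `user`,
#'   `reference` (equal-length numeric windows), `peak_index`; attribute
#'   `unmatched` counts surplus repetitions on the longer side.
#' @export
align_repetitions <- function(user_reps, ref_reps, user_series, ref_series) {
  if (user_reps$detected_count == 0) stop("user repetition set is empty")
  if (ref_reps$detected_count == 0) stop("reference repetition set is empty")
  m <- min(user_reps$detected_count, ref_reps$detected_count)
  pairs <- vector("list", m)
  for (i in seq_len(m)) {
    su <- user_reps$segments[i, ]; sr <- ref_reps$segments[i, ]
    wu <- bridge_na(user_series$angles[su$start_frame:su$end_frame])
    wr <- bridge_na(ref_series$angles[sr$start_frame:sr$end_frame])
    pu <- su$peak_frame - su$start_frame   # 0-based offset within window
    pr <- sr$peak_frame - sr$start_frame
    peak_off <- max(pu, pr)
    tail_len <- max(length(wu) - pu, length(wr) - pr)
    target_len <- peak_off + tail_len
    pairs[[i]] <- list(
      user = pad_to_peak(wu, pu, peak_off, target_len),
      reference = pad_to_peak(wr, pr, peak_off, target_len),
      peak_index = peak_off + 1L
    )
  }
  structure(pairs, class = "repetition_pairs",
            unmatched = abs(user_reps$detected_count - ref_reps$detected_count))
}

#' Filter repetitions for biomechanical stability
#'
#' Counting uses every detected repetition, but biomechanical summaries
#' (ROM, velocity) should only use stable, complete movement cycles. A
#' repetition is accepted when (i) at least `min_valid_fraction` of its
#' frames are valid, (ii) it spans a full trough-peak-trough cycle — both
#' endpoint angles sit in the lower half of the segment's excursion, so
#' clean boundary repetitions that start or end exactly at a trough still
#' count — and (iii) no frame-to-frame angle jump exceeds `max_jitter`.
#' Rejected repetitions keep their place in the set (they still count).
#'
#' @param reps A `repetition_set`.
#' @param series The source `joint_angle_series`.
#' @param min_valid_fraction Minimum fraction of valid frames (default 0.8).
#' @param max_jitter Largest tolerated frame-to-frame jump, degrees
#'   (default 30).
#' @return The `repetition_set` with updated `accepted` flags.
#' @export
filter_stable <- function(reps, series, min_valid_fraction = 0.8, max_jitter = 30) {
  segs <- reps$segments
  for (k in seq_len(nrow(segs))) {
    span <- segs$start_frame[k]:segs$end_frame[k]
    a <- series$angles[span]
    ok_valid <- mean(series$valid[span]) >= min_valid_fraction
    af <- a[is.finite(a)]
    ok_cycle <- FALSE
    ok_jitter <- FALSE
    if (length(af) >= 3) {
      lo <- min(af); hi <- max(af)
      half <- lo + 0.5 * (hi - lo)
      ends <- a[c(1, length(a))]
      ok_cycle <- all(is.finite(ends)) && all(ends <= half)
      jumps <- abs(diff(af))
      ok_jitter <- !length(jumps) || max(jumps) <= max_jitter
    }
    segs$accepted[k] <- ok_valid && ok_cycle && ok_jitter
  }
  reps$segments <- segs
  reps
}

#' Export repetition segments as CSV
#'
#' Columns `rep_index`, `start_frame`, `peak_frame`, `end_frame`
#' (0-based, file convention), `accepted`.
#'
#' @param reps A `repetition_set`.
#' @param path Output CSV path.
#' @return The table, invisibly.
#' @export
export_segments_csv <- function(reps, path) {
  s <- reps$segments
  tab <- data.frame(rep_index = seq_len(nrow(s)),
                    start_frame = s$start_frame - 1L,
                    peak_frame = s$peak_frame - 1L,
                    end_frame = s$end_frame - 1L,
                    accepted = s$accepted)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
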