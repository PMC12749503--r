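test_that("peak detection honours prominence, distance and plateaus", {
  expect_identical(detect_peaks(1:20), integer(0))
  expect_identical(detect_peaks(20:1), integer(0))

  # 5-cycle sinusoid: peaks at the analytic maxima +/- 1 frame
  n <- 500
  t <- seq(0, 1, length.out = n)
  x <- sin(2 * pi * 5 * t)
  pk <- detect_peaks(x, min_prominence = 0.5, min_distance = 20)
  truth <- sapply(1:5, function(k) which.min(abs(t - (4 * k - 3) / 20)))
  expect_length(pk, 5)
  expect_true(all(abs(pk - truth) <= 1))

  # two candidates 2 frames apart with min_distance 10: the more prominent wins
  x <- c(0, 0, 5, 1, 3, 0, 0, 0, 0, 0, 0, 0)
  pk <- detect_peaks(x, min_prominence = 0.5, min_distance = 10)
  expect_identical(pk, 3L)

  # plateau peak resolves to the midpoint
  x <- c(0, 1, 4, 4, 4, 1, 0)
  expect_identical(detect_peaks(x, 1, 1), 4L)
})

test_that("segmentation finds trough-peak-trough cycles with virtual boundary troughs", {
  fps <- 30
  expect_equal(segment_repetitions(as_angle_series(rep(90, 40), fps))$detected_count, 0L)

  # one clean cycle
  one <- generate_angle_trajectory(70, 80, 1, fps, 1.5)
  r <- segment_repetitions(as_angle_series(one, fps), smooth_window = 1)
  expect_equal(r$detected_count, 1L)
  expect_equal(r$segments$peak_frame, which.max(one))
  expect_equal(r$segments$start_frame, 1L)
  expect_equal(r$segments$end_frame, length(one))

  # N repetitions recovered exactly for N in 1..10 under low noise
  set.seed(5)
  for (N in 1:10) {
    tr <- generate_angle_trajectory(90, 70, N, fps, N * 1.5) + rnorm((N * 1.5) * fps + 1, 0, 0.5)
    r <- segment_repetitions(as_angle_series(tr, fps))
    expect_equal(r$detected_count, N)
  }
})

test_that("segments are ordered, non-overlapping, and each contains its peak", {
  set.seed(9)
  for (k in 1:10) {
    N <- sample(2:8, 1)
    fps <- sample(c(30, 60), 1)
    tr <- generate_angle_trajectory(runif(1, 40, 100), runif(1, 30, 110),
                                    N, fps, N * 1.2) +
      rnorm(round(N * 1.2 * fps) + 1, 0, 1)
    r <- segment_repetitions(as_angle_series(tr, fps))
    s <- r$segments
    expect_true(all(s$start_frame <= s$peak_frame & s$peak_frame <= s$end_frame))
    if (nrow(s) > 1) {
      expect_true(all(diff(s$peak_frame) > 0))
      expect_true(all(s$start_frame[-1] >= s$end_frame[-nrow(s)]))
    }
  }
})

test_that("counting is invariant to positive affine transforms of the angle signal", {
  fps <- 30
  tr <- generate_angle_trajectory(90, 60, 4, fps, 6)
  base <- segment_repetitions(as_angle_series(tr, fps))$detected_count
  for (a in c(0.2, 3)) {
    for (b in c(-40, 100)) {
      got <- segment_repetitions(as_angle_series(a * tr + b, fps))$detected_count
      expect_equal(got, base)
    }
  }
})

test_that("count_error reproduces the percentage-deviation formula", {
  expect_equal(count_error(9, 10)$error_percent, 10.0)
  expect_equal(round_for_report(count_error(14, 15)$error_percent, "one_decimal"), 6.7)
  expect_equal(count_error(7, 7)$error_percent, 0)
  expect_error(count_error(5, 0), ">= 1")
})

test_that("repetition pairing is ordinal with peak-aligned edge padding", {
  fps <- 30
  s <- as_angle_series(generate_angle_trajectory(80, 60, 3, fps, 3), fps)
  r <- segment_repetitions(s, smooth_window = 1)
  pairs <- align_repetitions(r, r, s, s)
  expect_length(pairs, 3)
  for (p in pairs) {
    expect_identical(p$user, p$reference)
    expect_equal(which.max(p$user), p$peak_index)
  }

  # user rep shorter than reference: padded to common length, peaks aligned
  su <- as_angle_series(generate_angle_trajectory(80, 60, 1, fps, 40 / fps), fps)
  sr <- as_angle_series(generate_angle_trajectory(80, 60, 1, fps, 60 / fps), fps)
  ru <- segment_repetitions(su, smooth_window = 1)
  rr <- segment_repetitions(sr, smooth_window = 1)
  p <- align_repetitions(ru, rr, su, sr)[[1]]
  expect_equal(length(p$user), length(p$reference))
  expect_equal(which.max(p$user), which.max(p$reference))
  # padding replicates edge values
  expect_equal(p$user[1], su$angles[1])
  expect_equal(p$user[length(p$user)], su$angles[length(su$angles)])

  # 3 user reps vs 4 reference reps: 3 pairs, surplus reported
  s4 <- as_angle_series(generate_angle_trajectory(80, 60, 4, fps, 4), fps)
  r4 <- segment_repetitions(s4, smooth_window = 1)
  pr <- align_repetitions(r, r4, s, s4)
  expect_length(pr, 3)
  expect_equal(attr(pr, "unmatched"), 1L)

  empty <- segment_repetitions(as_angle_series(rep(1, 40), fps))
  expect_error(align_repetitions(empty, r, s, s), "user")
  expect_error(align_repetitions(r, empty, s, s), "reference")
})

test_that("stability filtering keeps clean cycles and rejects corrupted ones", {
  fps <- 30
  s <- as_angle_series(generate_angle_trajectory(80, 70, 5, fps, 5), fps)
  r <- filter_stable(segment_repetitions(s, smooth_window = 1), s)
  expect_true(all(r$segments$accepted))
  expect_equal(r$detected_count, 5L)   # rejected reps would still count

  # a rep with 40% of frames dropped fails the 0.8 valid-fraction gate
  s2 <- s
  seg <- segment_repetitions(s2, smooth_window = 1)$segments[2, ]
  span <- seg$start_frame:seg$end_frame
  drop <- span[seq_len(floor(0.4 * length(span)))]
  s2$valid[drop] <- FALSE
  s2$angles[drop] <- NA
  r2 <- filter_stable(segment_repetitions(s2), s2, min_valid_fraction = 0.8)
  expect_false(r2$segments$accepted[2])

  # 15 generated reps, 8 corrupted by dropout on their descending limbs
  # (peaks and troughs survive bridging) -> 7 accepted, 15 still counted
  s15 <- as_angle_series(generate_angle_trajectory(80, 70, 15, fps, 15), fps)
  segs <- segment_repetitions(s15, smooth_window = 1)$segments
  for (k in c(1, 3, 5, 7, 9, 11, 13, 15)) {
    drop <- (segs$peak_frame[k] + 2L):(segs$end_frame[k] - 2L)
    s15$valid[drop] <- FALSE
    s15$angles[drop] <- NA
  }
  r15 <- filter_stable(segment_repetitions(s15), s15)
  expect_equal(r15$detected_count, 15L)
  expect_equal(sum(r15$segments$accepted), 7L)
})

test_that("segment CSV export uses 0-based frame columns", {
  fps <- 30
  s <- as_angle_series(generate_angle_trajectory(80, 60, 2, fps, 2), fps)
  r <- segment_repetitions(s, smooth_window = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  export_segments_csv(r, f)
  got <- utils::read.csv(f)
  expect_identical(names(got),
                   c("rep_index", "start_frame", "peak_frame", "end_frame", "accepted"))
  expect_equal(got$start_frame[1], 0L)
  expect_equal(got$peak_frame, r$segments$peak_frame - 1L)
})
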