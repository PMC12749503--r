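test_that("pixel conversion is exact multiplication with boundary identities", {
  x <- matrix(0.5, 1, 33); y <- matrix(0.5, 1, 33)
  x[1, 1] <- 0.25; y[1, 1] <- 0.1
  x[1, 2] <- 0; x[1, 3] <- 1
  seq <- pose_sequence(x, y, matrix(1, 1, 33), 640, 480, 30)
  px <- to_pixel(seq)
  expect_equal(px$X[1, 1], 160)
  expect_equal(px$Y[1, 1], 48)
  expect_equal(px$X[1, 2], 0)
  expect_equal(px$X[1, 3], 640)

  seq2 <- pose_sequence(matrix(0.5, 1, 33), matrix(0.5, 1, 33),
                        matrix(1, 1, 33), 1280, 720, 60)
  expect_equal(to_pixel(seq2)$X[1, 5], 640)
})

test_that("frame bounding box spans visible extremes plus buffer", {
  # a single visible landmark
  X <- matrix(300, 1, 33); Y <- matrix(300, 1, 33)
  vis <- matrix(0, 1, 33)
  X[1, 1] <- 100; Y[1, 1] <- 100; vis[1, 1] <- 1
  seq <- pixel_seq_from_matrices(X, Y, vis)
  box <- frame_bounding_box(seq, 1, buffer = 10)
  expect_equal(c(box$min_x, box$min_y, box$max_x, box$max_y), c(90, 90, 110, 110))

  # two visible extremes, zero buffer
  X[1, 2] <- 10; Y[1, 2] <- 20; X[1, 3] <- 50; Y[1, 3] <- 80
  vis[1, 2:3] <- 1; vis[1, 1] <- 0
  seq <- pixel_seq_from_matrices(X, Y, vis)
  box <- frame_bounding_box(seq, 1, buffer = 0)
  expect_equal(c(box$min_x, box$min_y, box$max_x, box$max_y), c(10, 20, 50, 80))

  # 33 random landmarks vs brute-force min/max oracle
  set.seed(7)
  X <- matrix(runif(33, 100, 500), 1); Y <- matrix(runif(33, 100, 500), 1)
  seq <- pixel_seq_from_matrices(X, Y)
  box <- frame_bounding_box(seq, 1, buffer = 5)
  expect_equal(box$min_x, min(X) - 5)
  expect_equal(box$max_y, max(Y) + 5)

  # degenerate frame: nothing visible
  seq <- pixel_seq_from_matrices(X, Y, matrix(0, 1, 33))
  expect_error(frame_bounding_box(seq, 1), "degenerate")
})

test_that("the fixed maximum box is the union of per-frame boxes", {
  # identical frames: equals the single-frame box
  X <- matrix(rep(seq(200, 520, length.out = 33), each = 4), 4, 33)
  Y <- matrix(rep(seq(150, 470, length.out = 33), each = 4), 4, 33)
  seq <- pixel_seq_from_matrices(X, Y)
  mb <- max_bounding_box(seq, buffer = 5)
  fb <- frame_bounding_box(seq, 1, buffer = 5)
  expect_equal(mb[c("min_x", "min_y", "max_x", "max_y")],
               fb[c("min_x", "min_y", "max_x", "max_y")])

  # 50-frame rightward drift: union equals the global min/max oracle and
  # contains every per-frame box
  drift <- seq(0, 200, length.out = 50)
  Xd <- outer(drift, seq(200, 400, length.out = 33), `+`)
  Yd <- matrix(rep(seq(150, 470, length.out = 33), each = 50), 50, 33)
  seqd <- pixel_seq_from_matrices(Xd, Yd)
  mbd <- max_bounding_box(seqd, buffer = 5)
  expect_equal(mbd$min_x, min(Xd) - 5)
  expect_equal(mbd$max_x, max(Xd) + 5)
  for (i in c(1, 25, 50)) {
    fbi <- frame_bounding_box(seqd, i, buffer = 5)
    expect_gte(fbi$min_x, mbd$min_x)
    expect_lte(fbi$max_x, mbd$max_x)
    expect_gte(fbi$min_y, mbd$min_y)
    expect_lte(fbi$max_y, mbd$max_y)
  }
})

test_that("box normalization maps corners and centre of the box to the unit square", {
  X <- matrix(300, 1, 33); Y <- matrix(300, 1, 33)
  X[1, 1] <- 100; Y[1, 1] <- 50     # top-left corner
  X[1, 2] <- 500; Y[1, 2] <- 650    # bottom-right corner
  X[1, 3] <- 300; Y[1, 3] <- 350    # centre
  seq <- pixel_seq_from_matrices(X, Y)
  box <- structure(list(min_x = 100, min_y = 50, max_x = 500, max_y = 650,
                        buffer = 0), class = "bounding_box")
  nm <- normalize_to_box(seq, box)
  expect_equal(c(nm$X[1, 1], nm$Y[1, 1]), c(0, 0))
  expect_equal(c(nm$X[1, 2], nm$Y[1, 2]), c(1, 1))
  expect_equal(c(nm$X[1, 3], nm$Y[1, 3]), c(0.5, 0.5))
  expect_error(normalize_to_box(seq, structure(
    list(min_x = 1, min_y = 1, max_x = 1, max_y = 5, buffer = 0),
    class = "bounding_box")), "zero-width")
})

test_that("fixed-box normalization keeps a static subject perfectly still despite outlier jitter", {
  # static pose everywhere except one outlier landmark (index 33, the
  # right-most/bottom-most one) jittering outward, so per-frame boxes resize
  set.seed(1)
  n <- 30
  X <- matrix(rep(seq(300, 500, length.out = 33), each = n), n, 33)
  Y <- matrix(rep(seq(200, 560, length.out = 33), each = n), n, 33)
  X[, 33] <- X[, 33] + abs(rnorm(n, 0, 25))
  Y[, 33] <- Y[, 33] + abs(rnorm(n, 0, 25))
  seq <- pixel_seq_from_matrices(X, Y)

  fixed <- normalize_to_box(seq, max_bounding_box(seq, buffer = 5))
  still <- setdiff(1:33, 33)
  expect_equal(max(apply(fixed$X[, still], 2, stats::var)), 0)
  expect_equal(max(apply(fixed$Y[, still], 2, stats::var)), 0)

  # per-frame boxes, by contrast, re-anchor and make still landmarks move
  perframe_x <- sapply(seq_len(n), function(i) {
    b <- frame_bounding_box(seq, i, buffer = 5)
    (seq$X[i, 1] - b$min_x) / (b$max_x - b$min_x)
  })
  expect_gt(stats::var(perframe_x), 0)
})

test_that("low-visibility gaps are bridged linearly up to max_gap", {
  n <- 7
  X <- matrix(100, n, 33); Y <- matrix(200, n, 33)
  vis <- matrix(1, n, 33)
  seq <- pixel_seq_from_matrices(X, Y, vis)

  # all visible: no-op
  out <- fill_low_visibility(seq)
  expect_identical(out$X, seq$X)
  expect_true(all(out$valid))

  # one dropped frame between identical neighbours: filled with their value
  seq$visibility[4, 5] <- 0.1
  out <- fill_low_visibility(seq, threshold = 0.5)
  expect_equal(out$X[4, 5], 100)
  expect_true(out$valid[4, 5])

  # dropped frame between 0.2 and 0.4 (one frame apart each): filled 0.3
  seq$X[, 5] <- 0.2; seq$X[5, 5] <- 0.4; seq$X[3, 5] <- 0.2
  seq$X[4, 5] <- 999
  out <- fill_low_visibility(seq, threshold = 0.5)
  expect_equal(out$X[4, 5], 0.3)

  # gap longer than max_gap: marked invalid, not filled
  seq2 <- pixel_seq_from_matrices(matrix(100, 10, 33), matrix(200, 10, 33))
  seq2$visibility[3:9, 2] <- 0
  out <- fill_low_visibility(seq2, max_gap = 5)
  expect_false(any(out$valid[3:9, 2]))
  # boundary gap (no earlier anchor) also invalid
  seq2$visibility[1:2, 3] <- 0
  out <- fill_low_visibility(seq2, max_gap = 5)
  expect_false(any(out$valid[1:2, 3]))
})

test_that("moving-average smoothing truncates at edges and window 1 is the identity", {
  x <- c(4, 1, 7, 2, 9)
  expect_identical(smooth_series(x, 1), x)
  expect_equal(smooth_series(rep(3, 10), 5), rep(3, 10))
  expect_equal(smooth_series(c(0, 3, 0), 3), c(1.5, 1, 1.5))
  expect_error(smooth_series(x, 4), "odd")
  expect_error(smooth_series(x, 0), "odd")
})
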