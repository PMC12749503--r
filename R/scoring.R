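#' Dynamic time warping between two series
#'
#' Classic dynamic-programming DTW with squared pointwise cost and the
#' symmetric step set \{(1,0), (0,1), (1,1)\}, no window constraint. The
#' reported distance is the square root of the accumulated squared cost
#' along the optimal warping path, so on the diagonal path of two
#' equal-length series it reduces to their Euclidean distance — which the
#' warping can only improve on. The path is recovered by backtracking with
#' a deterministic tie-break: diagonal first, then a step in the first
#' series.
#'
#' DTW is not a metric (no triangle inequality), but it is symmetric and
#' `dtw(x, x)` is zero with a purely diagonal path.
#'
#' @param p,d Non-empty numeric series (user/patient and
#'   demonstration/reference, by convention).
#' @return A `dtw_result`: `distance` and `path` (two-column matrix of
#'   1-based index pairs from `(1, 1)` to `(n, m)`).
#' @export
dtw_align <- function(p, d) {
  n <- length(p); m <- length(d)
  if (n == 0 || m == 0) stop("dtw inputs must be non-empty")
  acc <- matrix(Inf, n + 1L, m + 1L)
  acc[1L, 1L] <- 0
  for (i in seq_len(n)) {
    ci <- (p[i] - d)^2
    row_prev <- acc[i, ]
    row_cur <- acc[i + 1L, ]
    for (j in seq_len(m)) {
      row_cur[j + 1L] <- ci[j] + min(row_prev[j], row_prev[j + 1L], row_cur[j])
    }
    acc[i + 1L, ] <- row_cur
  }
  # backtrack; prefer diagonal, then a step in the first series
  path <- matrix(NA_integer_, n + m, 2L)
  k <- 0L
  i <- n; j <- m
  while (i > 1L || j > 1L) {
    k <- k + 1L
    path[k, ] <- c(i, j)
    if (i > 1L && j > 1L && acc[i, j] <= acc[i, j + 1L] && acc[i, j] <= acc[i + 1L, j]) {
      i <- i - 1L; j <- j - 1L
    } else if (i > 1L && (j == 1L || acc[i, j + 1L] <= acc[i + 1L, j])) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  path[k + 1L, ] <- c(1L, 1L)
  path <- path[(k + 1L):1L, , drop = FALSE]
  structure(list(distance = sqrt(acc[n + 1L, m + 1L]), path = path),
            class = "dtw_result")
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("<dtw_result> distance %.4g, path length %d\n",
              x$distance, nrow(x$path)))
  invisible(x)
}

#' Normalized cross-correlation across time lags
#'
#' `R(tau) = sum_t (X(t) - mu_X)(Y(t + tau) - mu_Y) / (sigma_X sigma_Y)`,
#' evaluated over the overlapping support for each lag, normalized by the
#' overlap length, with full-series population moments. The maximum over
#' lags, `R_max`, measures shape similarity in `[-1, 1]`: 1 is a perfect
#' positive correlation, -1 a perfect inversion, 0 no correlation.
#'
#' A constant signal has no shape to correlate, so either `sigma = 0`
#' yields `r_max = 0` with `constant = TRUE` rather than an error.
#'
#' A positive `best_lag` of `s` means `y` lags `x` by `s` frames
#' (`y(t) = x(t - s)` peaks at `tau = s`).
#'
#' @param x,y Equal-length numeric series (use
#'   [resample_to_common_length()] first if needed).
#' @param max_lag Largest lag magnitude evaluated; default 25% of the
#'   series length.
#' @return An `ncc_result`: `r_max`, `best_lag`, `lags`, `curve`,
#'   `constant`.
#' @export
ncc <- function(x, y, max_lag = NULL) {
  if (length(x) != length(y)) stop("ncc requires equal-length series; resample first")
  n <- length(x)
  if (n < 2) stop("series must have length >= 2")
  if (is.null(max_lag)) max_lag <- floor(0.25 * n)
  max_lag <- min(max_lag, n - 1L)
  mx <- mean(x); my <- mean(y)
  sx <- sqrt(mean((x - mx)^2)); sy <- sqrt(mean((y - my)^2))
  lags <- (-max_lag):max_lag
  if (sx == 0 || sy == 0) {
    return(structure(list(r_max = 0, best_lag = 0L, lags = lags,
                          curve = rep(0, length(lags)), constant = TRUE),
                     class = "ncc_result"))
  }
  xd <- x - mx; yd <- y - my
  curve <- vapply(lags, function(tau) {
    if (tau >= 0) { t1 <- 1:(n - tau); t2 <- t1 + tau } else { t2 <- 1:(n + tau); t1 <- t2 - tau }
    sum(xd[t1] * yd[t2]) / (sx * sy * length(t1))
  }, numeric(1))
  best <- which.max(curve)
  structure(list(r_max = curve[best], best_lag = lags[best],
                 lags = lags, curve = curve, constant = FALSE),
            class = "ncc_result")
}

#' @export
print.ncc_result <- function(x, ...) {
  cat(sprintf("<ncc_result> r_max %.4f at lag %d%s\n", x$r_max, x$best_lag,
              if (x$constant) " (constant signal)" else ""))
  invisible(x)
}

#' Resample two series onto a common length
#'
#' Linearly interpolates both series onto `max(length(x), length(y))`
#' uniformly spaced samples; a series already at the target length is
#' returned unchanged.
#'
#' @param x,y Non-empty numeric series.
#' @return List with elements `x` and `y` of equal length.
#' @export
resample_to_common_length <- function(x, y) {
  if (!length(x) || !length(y)) stop("inputs must be non-empty")
  n <- max(length(x), length(y))
  up <- function(v) {
    if (length(v) == n) return(v)
    if (length(v) == 1) return(rep(v, n))
    stats::approx(seq(0, 1, length.out = length(v)), v,
                  xout = seq(0, 1, length.out = n))$y
  }
  list(x = up(x), y = up(y))
}

#' Aggregate similarity across repetitions
#'
#' `S = mean(R_max)` over the per-repetition maximum cross-correlations.
#'
#' @param per_rep_rmax Non-empty numeric vector of per-repetition `R_max`.
#' @return The similarity `S`.
#' @export
similarity_score <- function(per_rep_rmax) {
  if (!length(per_rep_rmax)) stop("no repetitions to average")
  mean(per_rep_rmax)
}

#' Composite Action Score
#'
#' Blends trajectory similarity with repetition-count accuracy into a
#' 0-100 score:
#' `combined = 100 * (w_sim * max(S, 0) + w_rep * max(1 - err/100, 0)) /
#' (w_sim + w_rep)`.
#' Anti-correlated motion contributes nothing rather than going negative.
#' The blend itself is a design choice of this package (the similarity and
#' count components are standard; their combination is not canonical), so
#' every component is reported separately and the weights are echoed to
#' keep the composite auditable.
#'
#' @param S Similarity from [similarity_score()].
#' @param rep_error A [count_error()] or a bare error percentage.
#' @param weights Two nonnegative weights `(w_sim, w_rep)`, sum `> 0`.
#' @param per_rep_rmax Optional vector stored on the result for reporting.
#' @return An `action_score`: `similarity`, `rep_error_percent`,
#'   `combined`, `weights`, `per_rep_rmax`.
#' @export
action_score <- function(S, rep_error, weights = c(1, 1), per_rep_rmax = NULL) {
  err <- if (inherits(rep_error, "count_error")) rep_error$error_percent else rep_error
  if (length(weights) != 2 || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be two nonnegative numbers with positive sum")
  combined <- 100 * (weights[1] * max(S, 0) + weights[2] * max(1 - err / 100, 0)) /
    sum(weights)
  structure(list(similarity = S, rep_error_percent = err, combined = combined,
                 weights = weights, per_rep_rmax = per_rep_rmax),
            class = "action_score")
}

#' @export
print.action_score <- function(x, ...) {
  cat(sprintf("<action_score> combined %.1f / 100 (S = %.3f, rep error %.1f%%)\n",
              x$combined, x$similarity, x$rep_error_percent))
  invisible(x)
}
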