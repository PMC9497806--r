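# Series characterization: persistence (rescaled-range Hurst exponent),
# stationarity (windowed drift with a permutation threshold), nonlinearity
# (IAAFT surrogate test), and chaos (Rosenstein largest Lyapunov exponent).

series_values <- function(series) {
  if (inherits(series, "composite_series")) series$values
  else if (inherits(series, "reference_signal")) series$values
  else as.numeric(series)
}

# ---------------------------------------------------------------------------
# Hurst exponent (rescaled-range analysis)
# ---------------------------------------------------------------------------

# Per-window rescaled range: range of cumulative mean-deviations over the
# sample standard deviation.
.rs_statistic <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(NA_real_)
  y <- cumsum(x - mean(x))
  (max(y) - min(y)) / s
}

# Anis-Lloyd expected value of R/S_n under iid Gaussian input, used to
# remove the well-known upward small-sample bias of the plain R/S slope.
.anis_lloyd_expectation <- function(n) {
  pref <- if (n <= 340) {
    exp(lgamma((n - 1) / 2) - lgamma(n / 2)) / sqrt(pi) * (n - 0.5) / n
  } else {
    (n - 0.5) / n / sqrt(n * pi / 2)
  }
  i <- seq_len(n - 1)
  pref * sum(sqrt((n - i) / i))
}

#' Classify a Hurst exponent estimate
#'
#' `H < 0.5` is anti-persistent (anti-correlated increments), `H ~ 0.5`
#' random (Brownian-like), `0.5 < H <= 1` persistent (long-range positive
#' correlation). Because an estimate is never exactly 0.5, values within
#' `tol` of 0.5 are labelled random.
#'
#' @param H estimate in `[0, 1]`.
#' @param tol half-width of the "random" band around 0.5.
#' @return `"anti-persistent"`, `"random"` or `"persistent"`.
#' @export
classify_hurst <- function(H, tol = 0.05) {
  if (abs(H - 0.5) <= tol) "random"
  else if (H < 0.5) "anti-persistent"
  else "persistent"
}

#' Rescaled-range (R/S) Hurst exponent
#'
#' For log-spaced window sizes `n` from `min_window` to `length/2`, the
#' series is cut into non-overlapping windows, the rescaled range `R/S` is
#' computed per window and averaged, and `H` is the OLS slope of
#' `log mean(R/S)` on `log n` (the scaling law `E[R/S_n] = c * n^H`). The
#' default applies the Anis-Lloyd finite-sample correction,
#' `H = 1/2 + slope of (log R/S_n - log E_0[R/S_n])` where `E_0` is the
#' expectation under iid Gaussian input; the plain uncorrected slope is
#' available with `correction = "none"` and is biased upward by roughly
#' 0.05 at these lengths.
#'
#' @param series numeric vector (or `composite_series` / `reference_signal`).
#' @param min_window smallest window size (>= 4 recommended).
#' @param n_scales number of log-spaced window sizes.
#' @param correction `"anis-lloyd"` (default) or `"none"`.
#' @return Object of class `hurst_result`: `H`, `log_c` (intercept of the
#'   uncorrected fit), `window_sizes`, `mean_rs`, `r2`, `classification`,
#'   `correction`, `clipped` (TRUE if H was clipped into `[0, 1]`).
#' @examples
#' set.seed(1)
#' hurst_rs(rnorm(2048))$classification
#' @export
hurst_rs <- function(series, min_window = 8, n_scales = 12,
                     correction = c("anis-lloyd", "none")) {
  correction <- match.arg(correction)
  x <- series_values(series)
  N <- length(x)
  if (N < 4 * min_window) degenerate_error("series too short for R/S analysis")
  ns <- unique(round(exp(seq(log(min_window), log(N / 2),
                             length.out = n_scales))))
  mean_rs <- vapply(ns, function(n) {
    k <- N %/% n
    vals <- vapply(seq_len(k), function(j) {
      .rs_statistic(x[((j - 1) * n + 1):(j * n)])
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(mean_rs) & mean_rs > 0
  if (sum(ok) < 4) degenerate_error("series is (locally) constant; R/S undefined")
  ns <- ns[ok]; mean_rs <- mean_rs[ok]
  plain <- stats::lm(log(mean_rs) ~ log(ns))
  if (correction == "anis-lloyd") {
    e0 <- vapply(ns, .anis_lloyd_expectation, numeric(1))
    fit <- stats::lm(I(log(mean_rs) - log(e0)) ~ log(ns))
    H <- 0.5 + unname(stats::coef(fit)[2])
    r2 <- summary(fit)$r.squared
  } else {
    fit <- plain
    H <- unname(stats::coef(fit)[2])
    r2 <- summary(fit)$r.squared
  }
  clipped <- H < 0 || H > 1
  H_cl <- min(max(H, 0), 1)
  structure(
    list(H = H_cl, H_raw = H, log_c = unname(stats::coef(plain)[1]),
         window_sizes = ns, mean_rs = mean_rs, r2 = r2,
         classification = classify_hurst(H_cl), correction = correction,
         clipped = clipped),
    class = "hurst_result"
  )
}

#' @export
print.hurst_result <- function(x, ...) {
  cat(sprintf("<hurst_result> H = %.3f (%s; %s correction, r2 = %.3f, %d scales)\n",
              x$H, x$classification, x$correction, x$r2, length(x$window_sizes)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Stationarity
# ---------------------------------------------------------------------------

.drift_statistic <- function(x, n_segments) {
  L <- length(x) %/% n_segments
  xs <- x[seq_len(L * n_segments)]
  blocks <- matrix(xs, nrow = L)
  bm <- colMeans(blocks)
  bv <- apply(blocks, 2, stats::var)
  t_mean <- max(abs(bm - mean(xs))) / (stats::sd(xs) / sqrt(L))
  t_var <- max(abs(bv - stats::var(xs))) / (stats::var(xs) * sqrt(2 / (L - 1)))
  max(t_mean, t_var)
}

#' Windowed-drift stationarity test
#'
#' Splits the series into `n_segments` equal blocks and measures the maximum
#' standardized drift of block means and block variances from their global
#' values. The null distribution (no temporal structure in block membership)
#' is calibrated by permuting the sample order; the series is flagged
#' non-stationary when the observed statistic exceeds the `1 - alpha`
#' permutation quantile. This is a generic concept-level check of whether
#' first/second-moment structure changes over time, not a reimplementation
#' of any particular published routine.
#'
#' @param series numeric vector (or composite/reference object).
#' @param n_segments number of equal blocks (>= 2).
#' @param alpha significance level.
#' @param n_perm number of permutations (>= 199 recommended).
#' @param seed seed for the permutation draw.
#' @return Object of class `stationarity_result`: `statistic`, `threshold`,
#'   `nonstationary`, `n_segments`, `alpha`.
#' @export
stationarity_test <- function(series, n_segments = 10, alpha = 0.05,
                              n_perm = 199, seed = 1) {
  x <- series_values(series)
  if (n_segments < 2) arg_error("n_segments must be >= 2")
  if (length(x) < 2 * n_segments) arg_error("too few points per block")
  obs <- .drift_statistic(x, n_segments)
  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      .drift_statistic(sample(x), n_segments)
    }, numeric(1))
  })
  thr <- stats::quantile(perm_stats, 1 - alpha, type = 7, names = FALSE)
  structure(
    list(statistic = obs, threshold = thr, nonstationary = obs > thr,
         n_segments = n_segments, alpha = alpha),
    class = "stationarity_result"
  )
}

# ---------------------------------------------------------------------------
# IAAFT surrogates and the nonlinearity test
# ---------------------------------------------------------------------------

#' Iterative amplitude-adjusted Fourier transform (IAAFT) surrogate
#'
#' Produces a surrogate with exactly the original amplitude distribution
#' (same sorted values) and a power spectrum matched to the original within
#' iteration tolerance, by alternating spectrum substitution and
#' rank-ordering from a seeded random initial shuffle. The iteration stops
#' when the rank permutation stabilizes or after `max_iter` sweeps.
#'
#' @param series numeric vector, length >= 16.
#' @param max_iter maximum number of iterations.
#' @param seed seed for the initial shuffle.
#' @return Numeric surrogate vector of the same length.
#' @export
iaaft_surrogate <- function(series, max_iter = 100, seed = 1) {
  x <- series_values(series)
  n <- length(x)
  if (n < 16) arg_error("series must have length >= 16")
  amp_sorted <- sort(x)
  target_mod <- Mod(stats::fft(x))
  s <- with_seed(seed, sample(x))
  prev_rank <- integer(0)
  for (it in seq_len(max_iter)) {
    ph <- Arg(stats::fft(s))
    s <- Re(stats::fft(complex(modulus = target_mod, argument = ph),
                       inverse = TRUE)) / n
    rk <- rank(s, ties.method = "first")
    s <- amp_sorted[rk]
    if (identical(rk, prev_rank)) break
    prev_rank <- rk
  }
  s
}

# Third-order time-reversal asymmetry; zero in expectation for any
# time-reversible (e.g. linear Gaussian) process.
.time_reversal_asymmetry <- function(x, lag = 1) {
  d <- x[-seq_len(lag)] - x[seq_len(length(x) - lag)]
  mean(d^3) / mean(d^2)^1.5
}

# Zeroth-order local nonlinear prediction error in a 2D lag embedding:
# predict x[t+1] by the value following the nearest (non-adjacent) lag
# vector; report RMS error over the series sd.
.nonlinear_prediction_error <- function(x, lag = 1) {
  n <- length(x)
  emb <- cbind(x[1:(n - lag - 1)], x[(1 + lag):(n - 1)])
  target <- x[(lag + 2):n]
  m <- nrow(emb)
  err <- vapply(seq_len(m), function(i) {
    d2 <- (emb[, 1] - emb[i, 1])^2 + (emb[, 2] - emb[i, 2])^2
    d2[max(1, i - lag):min(m, i + lag)] <- Inf
    j <- which.min(d2)
    target[j] - target[i]
  }, numeric(1))
  sqrt(mean(err^2)) / stats::sd(x)
}

#' Surrogate-data test for nonlinearity
#'
#' Tests the null hypothesis that the series is a realization of a linear
#' Gaussian stochastic process (up to a static amplitude transform) by
#' comparing a discriminating statistic on the series against its
#' distribution over IAAFT surrogates. The two-sided rank test rejects when
#' the observed value falls at an extreme rank of the pooled set: with
#' `n_surrogates = 19` and `alpha = 0.05`, only ranks 1 and 20 reject.
#'
#' @param series numeric vector.
#' @param n_surrogates number of IAAFT surrogates (>= 19).
#' @param alpha two-sided significance level.
#' @param statistic `"time_reversal_asymmetry"` (default) or
#'   `"nonlinear_prediction_error"`.
#' @param seed seed; surrogate `i` uses `seed + i`.
#' @param max_iter IAAFT iteration cap.
#' @return Object of class `surrogate_test_result`: `statistic_name`,
#'   `observed`, `surrogate_values`, `rank`, `rejected`, `alpha`,
#'   `n_surrogates`.
#' @export
nonlinearity_test <- function(series, n_surrogates = 99, alpha = 0.05,
                              statistic = c("time_reversal_asymmetry",
                                            "nonlinear_prediction_error"),
                              seed = 1, max_iter = 100) {
  statistic <- match.arg(statistic)
  if (n_surrogates < 19) arg_error("n_surrogates must be >= 19")
  x <- series_values(series)
  stat_fun <- switch(statistic,
    time_reversal_asymmetry = .time_reversal_asymmetry,
    nonlinear_prediction_error = .nonlinear_prediction_error
  )
  observed <- stat_fun(x)
  sv <- vapply(seq_len(n_surrogates), function(i) {
    stat_fun(iaaft_surrogate(x, max_iter = max_iter, seed = seed + i))
  }, numeric(1))
  pooled <- c(observed, sv)
  rk <- rank(pooled, ties.method = "first")[1]
  m <- n_surrogates + 1
  k <- ceiling(alpha / 2 * m)
  rejected <- rk <= k || rk >= m + 1 - k
  structure(
    list(statistic_name = statistic, observed = observed,
         surrogate_values = sv, rank = as.integer(rk), rejected = rejected,
         alpha = alpha, n_surrogates = n_surrogates),
    class = "surrogate_test_result"
  )
}

# ---------------------------------------------------------------------------
# Largest Lyapunov exponent (Rosenstein et al. nearest-neighbor divergence)
# ---------------------------------------------------------------------------

# Mean period in samples from the power spectrum's mean frequency.
.mean_period <- function(x) {
  n <- length(x)
  spec <- Mod(stats::fft(x - mean(x)))[2:(n %/% 2)]^2
  f <- (1:(n %/% 2 - 1)) / n
  mf <- sum(f * spec) / sum(spec)
  if (!is.finite(mf) || mf <= 0) return(n %/% 4)
  max(1L, as.integer(round(1 / mf)))
}

#' Largest Lyapunov exponent by the Rosenstein nearest-neighbor method
#'
#' Embeds the series with `(D, tau)`, pairs every point with its nearest
#' neighbor at temporal separation greater than the Theiler window, tracks
#' the log Euclidean separation of each pair for `max_steps` steps, averages
#' the log divergence over pairs, and estimates the exponent as the OLS
#' slope of the mean log-divergence curve over `fit_range`. Nearby
#' trajectories of a chaotic system separate as `d(t) = C * exp(LyE * t)`,
#' so a positive slope indicates chaos, ~0 a stable limit cycle, and a
#' negative slope a stable fixed point.
#'
#' The default fit window spans half to two mean periods (clipped to
#' `max_steps`): for chaotic flows the first part of the divergence curve
#' (roughly one orbit) is a transient in which neighbor separations rotate
#' onto the locally most unstable direction and the apparent slope runs
#' well above the true exponent; the linear scaling region follows it and
#' precedes saturation.
#'
#' @param series numeric vector.
#' @param D embedding dimension.
#' @param tau delay in samples.
#' @param theiler exclusion window for neighbor search, in samples; default
#'   is the series' mean period (from the mean power-spectral frequency).
#' @param max_steps divergence horizon in samples.
#' @param fit_range integer `c(from, to)` in steps (0-based); default half
#'   to two mean periods, clipped to `max_steps` (see Details).
#' @param frame_rate optional sampling rate; when given, `lye` is per
#'   second, otherwise per sample.
#' @return Object of class `lyapunov_result`: `lye`, `divergence_curve`
#'   (mean log divergence per step), `fit_range`, `D_used`, `tau_used`,
#'   `units` (`"per sample"` or `"per second"`).
#' @export
rosenstein_lye <- function(series, D, tau, theiler = NULL, max_steps = 100,
                           fit_range = NULL, frame_rate = NULL) {
  x <- series_values(series)
  if (stats::sd(x) == 0) degenerate_error("constant series has no divergence")
  emb <- delay_embed(x, D, tau)
  Y <- emb$points
  M <- nrow(Y)
  if (M < max_steps + 2) arg_error("embedded series too short for max_steps")
  if (is.null(theiler)) theiler <- .mean_period(x)

  dm <- as.matrix(stats::dist(Y))
  idx <- seq_len(M)
  for (i in idx) {
    lo <- max(1, i - theiler); hi <- min(M, i + theiler)
    dm[i, lo:hi] <- Inf
  }
  # neighbors must also leave room to track forward
  usable <- M - max_steps
  if (usable < 2) arg_error("max_steps too large for series length")
  nn <- apply(dm[seq_len(usable), seq_len(usable), drop = FALSE], 1, which.min)
  has_nn <- is.finite(dm[cbind(seq_len(usable), nn)])
  if (mean(has_nn) < 0.5) {
    degenerate_error("no admissible nearest neighbor for most points")
  }
  ref <- which(has_nn)
  nnr <- nn[ref]

  curve <- vapply(0:max_steps, function(k) {
    d <- sqrt(rowSums((Y[ref + k, , drop = FALSE] -
                         Y[nnr + k, , drop = FALSE])^2))
    d <- d[d > 0]
    if (!length(d)) return(NA_real_)
    mean(log(d))
  }, numeric(1))

  if (is.null(fit_range)) {
    period <- .mean_period(x)
    lo <- min(round(period / 2), max(0, max_steps - 10))
    hi <- max(min(2 * period, max_steps), lo + 10)
    fit_range <- c(lo, min(hi, max_steps))
  }
  ks <- fit_range[1]:fit_range[2]
  yfit <- curve[ks + 1]
  keep <- is.finite(yfit)
  slope <- unname(stats::coef(stats::lm(yfit[keep] ~ ks[keep]))[2])
  units <- "per sample"
  if (!is.null(frame_rate)) {
    slope <- slope * frame_rate
    units <- "per second"
  }
  structure(
    list(lye = slope, divergence_curve = curve, fit_range = fit_range,
         D_used = D, tau_used = tau, theiler = theiler, units = units,
         n_pairs = length(ref)),
    class = "lyapunov_result"
  )
}

#' @export
print.lyapunov_result <- function(x, ...) {
  cat(sprintf("<lyapunov_result> LyE = %.4f %s (D = %d, tau = %d, fit %d..%d)\n",
              x$lye, x$units, x$D_used, x$tau_used, x$fit_range[1],
              x$fit_range[2]))
  invisible(x)
}
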