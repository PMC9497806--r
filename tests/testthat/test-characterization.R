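test_that("Hurst estimator is exactly scale- and shift-invariant", {
  set.seed(10)
  x <- rnorm(2048)
  h0 <- hurst_rs(x)
  h1 <- hurst_rs(3.7 * x - 42)
  expect_equal(h0$H, h1$H, tolerance = 1e-12)
  expect_equal(h0$mean_rs, h1$mean_rs, tolerance = 1e-10)
})

test_that("Hurst estimator centres near 0.5 on white noise and classifies", {
  est <- vapply(1:10, function(s) {
    set.seed(s)
    hurst_rs(rnorm(4096))$H
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.5), 0.05)
  expect_equal(classify_hurst(0.72), "persistent")
  expect_equal(classify_hurst(0.30), "anti-persistent")
  expect_equal(classify_hurst(0.51), "random")
  expect_error(hurst_rs(rep(1, 4096)), class = "pirodyn_degenerate_error")
  expect_error(hurst_rs(rnorm(20)), class = "pirodyn_degenerate_error")
})

test_that("uncorrected R/S slope agrees with an independent implementation", {
  skip_if_not_installed("pracma")
  x <- generate_reference_signal("fgn", 4096, list(H_target = 0.7),
                                 seed = 11)$values
  ours <- hurst_rs(x, correction = "none")$H
  theirs <- pracma::hurstexp(x, display = FALSE)$Hs
  expect_lt(abs(ours - theirs), 0.1)
})

test_that("stationarity test flags trends but not iid noise", {
  set.seed(1)
  trend <- seq(0, 5, length.out = 1000) + rnorm(1000, sd = 0.2)
  expect_true(stationarity_test(trend, seed = 1)$nonstationary)

  rejections <- vapply(1:20, function(s) {
    set.seed(s)
    stationarity_test(rnorm(600), seed = s)$nonstationary
  }, logical(1))
  expect_lte(sum(rejections), 3)  # nominal 5% level, allow sampling slack

  expect_error(stationarity_test(rnorm(15), n_segments = 10),
               class = "pirodyn_argument_error")
})

test_that("composite pirouette series is non-stationary", {
  comp <- build_composite(make_normalized_cohort(10, seed = 3), seed = 3)
  red <- quantile_reduce(comp$y)
  expect_true(stationarity_test(red$values, seed = 1)$nonstationary)
})

test_that("IAAFT surrogates keep the value multiset and the spectrum", {
  set.seed(8)
  # AR(1) test series
  x <- as.numeric(stats::arima.sim(list(ar = 0.8), 1024))
  s1 <- iaaft_surrogate(x, seed = 1)
  expect_identical(sort(s1), sort(x))
  spec_x <- Mod(fft(x))[2:512]
  spec_s <- Mod(fft(s1))[2:512]
  rel_err <- sqrt(sum((spec_s - spec_x)^2) / sum(spec_x^2))
  expect_lt(rel_err, 0.05)

  s2 <- iaaft_surrogate(x, seed = 2)
  expect_false(identical(s1, s2))
  expect_identical(sort(s2), sort(x))

  expect_error(iaaft_surrogate(rnorm(8)), class = "pirodyn_argument_error")
})

test_that("surrogate nonlinearity test has correct size and power", {
  # under the null (linear Gaussian AR(1)): few rejections. With 99
  # surrogates and alpha = 0.05 the exact two-sided size is 6/100, so over
  # 20 runs more than 4 rejections has probability < 0.005.
  rejections <- vapply(1:20, function(s) {
    set.seed(s)
    x <- as.numeric(stats::arima.sim(list(ar = 0.6), 512))
    nonlinearity_test(x, n_surrogates = 99, seed = s * 1000)$rejected
  }, logical(1))
  expect_lte(mean(rejections), 0.20)

  # under the alternative (logistic map): rejected
  lg <- generate_reference_signal("logistic", 512, list(r = 4), seed = 3)
  res <- nonlinearity_test(lg$values, n_surrogates = 99, seed = 1)
  expect_true(res$rejected)
  expect_gte(res$rank, 1)
  expect_lte(res$rank, 100)
})

test_that("rank rule with 19 surrogates rejects only at the extremes", {
  set.seed(4)
  x <- as.numeric(stats::arima.sim(list(ar = 0.5), 256))
  res <- nonlinearity_test(x, n_surrogates = 19, alpha = 0.05, seed = 9)
  expect_identical(res$rejected, res$rank %in% c(1L, 20L))
})

test_that("Lyapunov exponent is ~0 for a limit cycle, > 0 for chaos", {
  sine <- generate_reference_signal("sine", 4000, list(period = 25))$values
  ls <- rosenstein_lye(sine, D = 2, tau = 6)
  expect_lt(abs(ls$lye), 0.05)
  expect_equal(ls$units, "per sample")

  lor <- generate_reference_signal("lorenz", 5000, list(dt = 0.02),
                                   seed = 0)$values[, 1]
  ll <- rosenstein_lye(lor, D = 3, tau = 6, max_steps = 150)
  expect_gt(ll$lye, 0)

  # per-second units scale by the frame rate
  ls2 <- rosenstein_lye(sine, D = 2, tau = 6, frame_rate = 100)
  expect_equal(ls2$lye, ls$lye * 100, tolerance = 1e-12)
  expect_equal(ls2$units, "per second")

  expect_error(rosenstein_lye(rep(1, 1000), D = 2, tau = 5),
               class = "pirodyn_degenerate_error")
})

test_that("time-reversed chaotic input still yields a finite curve", {
  lor <- generate_reference_signal("lorenz", 3000, list(dt = 0.02),
                                   seed = 1)$values[, 1]
  lrev <- rosenstein_lye(rev(lor), D = 3, tau = 6, max_steps = 80)
  expect_true(all(is.finite(lrev$divergence_curve)))
})
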