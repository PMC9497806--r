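test_that("AMI is near zero for iid noise and maximal at lag 0", {
  set.seed(6)
  x <- rnorm(4000)
  am <- average_mutual_information(x, max_lag = 50)
  expect_lt(max(am$ami[-1]), 0.05)
  expect_equal(which.max(am$ami), 1)

  expect_error(average_mutual_information(rep(2, 500)),
               class = "pirodyn_degenerate_error")
  expect_error(average_mutual_information(rnorm(50), max_lag = 60),
               class = "pirodyn_argument_error")
})

test_that("AMI of the Lorenz x-coordinate has its first minimum in the known band", {
  # at dt = 0.01 the first AMI minimum sits near 0.1-0.3 time units
  lor <- generate_reference_signal("lorenz", 4000, list(dt = 0.01),
                                   seed = 0)$values[, 1]
  am <- average_mutual_information(lor, max_lag = 60)
  fm <- as.integer(select_delay(am, "first_minimum"))
  oe <- as.integer(select_delay(am, "one_over_e"))
  expect_gte(fm, 8)
  expect_lte(fm, 30)
  expect_lte(oe, fm)
})

test_that("AMI is exactly symmetric under time reversal", {
  set.seed(12)
  x <- cumsum(rnorm(1500))
  a_fwd <- average_mutual_information(x, max_lag = 30)
  a_rev <- average_mutual_information(rev(x), max_lag = 30)
  expect_equal(a_fwd$ami, a_rev$ami, tolerance = 1e-12)
})

test_that("delay selection follows the 1/e and first-minimum criteria", {
  curve <- c(1.0, 0.5, 0.3, 0.35)
  expect_equal(as.integer(select_delay(curve, "one_over_e")), 2L)
  expect_equal(as.integer(select_delay(curve, "first_minimum")), 2L)

  rising <- c(1.0, 0.9, 0.95, 1.1, 1.2)
  lag <- select_delay(rising, "one_over_e")
  expect_equal(as.integer(lag), 4L)
  expect_true(attr(lag, "warning_flag"))

  # both criteria met at the same lag
  both <- c(1.0, 0.8, 0.2, 0.6)
  expect_equal(as.integer(select_delay(both, "one_over_e")),
               as.integer(select_delay(both, "first_minimum")))
})

test_that("global delay is the rounded mean with ties away from zero", {
  expect_equal(global_delay(list(x = 10, y = 20, z = 30)), 20L)
  expect_equal(global_delay(list(x = 7)), 7L)
  expect_equal(global_delay(list(x = 5, y = 6)), 6L)
})

test_that("FNN recovers known embedding dimensions", {
  sine <- generate_reference_signal("sine", 2000, list(period = 100))$values
  fs <- false_nearest_neighbors(sine, tau = 25, max_dim = 6)
  expect_equal(fs$selected_D, 2L)
  expect_true(all(fs$fnn_percentages >= 0 & fs$fnn_percentages <= 100))

  lor <- generate_reference_signal("lorenz", 3000, list(dt = 0.01),
                                   seed = 0)$values
  fx <- false_nearest_neighbors(lor[, 1], tau = 11, max_dim = 6)
  expect_equal(fx$selected_D, 3L)
  expect_lt(fx$fnn_percentages[["3"]], 1)

  # the true 3D state needs no extra delay coordinates (global mode)
  fg <- false_nearest_neighbors(lor, tau = 11, max_dim = 4)
  expect_equal(fg$mode, "global")
  expect_lte(fg$selected_D, 3L)

  # iid noise never settles: argmin fallback flagged
  set.seed(3)
  fn <- false_nearest_neighbors(rnorm(800), tau = 1, max_dim = 5)
  expect_true(fn$warning_flag)
})

test_that("FNN is monotone non-increasing for noiseless deterministic input", {
  sine <- generate_reference_signal("sine", 1500, list(period = 80))$values
  fs <- false_nearest_neighbors(sine, tau = 20, max_dim = 5)
  expect_true(all(diff(fs$fnn_percentages) <= 1e-9))
  lor <- generate_reference_signal("lorenz", 2000, list(dt = 0.02),
                                   seed = 2)$values[, 1]
  fl <- false_nearest_neighbors(lor, tau = 6, max_dim = 5)
  expect_true(all(diff(fl$fnn_percentages) <= 1e-9))
})

test_that("delay embedding builds the exact delay vectors", {
  emb <- delay_embed(1:5, D = 3, tau = 1)
  expect_equal(emb$points, rbind(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))

  e2 <- delay_embed(1:10, D = 2, tau = 2)
  expect_equal(nrow(e2$points), 8)

  x <- rnorm(40)
  e1 <- delay_embed(x, D = 1, tau = 7)
  expect_equal(e1$points[, 1], x)

  expect_error(delay_embed(1:10, D = 4, tau = 4),
               class = "pirodyn_argument_error")
})

test_that("embedded point count is N - (D - 1) * tau over random tuples", {
  set.seed(99)
  for (i in 1:50) {
    N <- sample(20:200, 1)
    D <- sample(1:5, 1)
    tau <- sample(1:10, 1)
    if (N <= (D - 1) * tau) next
    emb <- delay_embed(rnorm(N), D, tau)
    expect_equal(nrow(emb$points), N - (D - 1) * tau)
    expect_equal(ncol(emb$points), D)
  }
})

test_that("multivariate delay estimation aggregates per-coordinate delays", {
  comp <- build_composite(make_normalized_cohort(5, seed = 2), seed = 2)
  mat <- vapply(comp, `[[`, numeric(1500), "values")
  de <- estimate_delays(mat, max_lag = 60)
  expect_length(de$per_column_tau, 3)
  expect_equal(de$global_tau, global_delay(de$per_column_tau))
  expect_true(all(de$per_column_tau >= 1))
})
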