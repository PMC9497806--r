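test_that("resampling hits the target length and preserves structure", {
  tr <- generate_pirouette_cohort(1, "jazz", "LKNE",
                                  length_range = c(137, 137), seed = 1)[[1]]
  out <- resample_to_fixed_length(tr, 300)
  expect_equal(nrow(out$frames), 300)
  # endpoints preserved exactly
  expect_equal(out$frames[1, ], tr$frames[1, ], ignore_attr = TRUE)
  expect_equal(out$frames[300, ], tr$frames[137, ], ignore_attr = TRUE)

  ramp <- seq(0, 1, length.out = 300)
  expect_equal(resample_to_fixed_length(ramp, 300), ramp, tolerance = 1e-12)

  const <- rep(5, 101)
  expect_equal(resample_to_fixed_length(const, 300), rep(5, 300),
               tolerance = 1e-12)

  expect_error(resample_to_fixed_length(matrix(1, 1, 3), 300),
               class = "pirodyn_argument_error")
})

test_that("normalization scales every coordinate to unit max magnitude", {
  tr <- dancer_trial(cbind(seq(-2, 2, length.out = 50),
                           seq(0.2, 1, length.out = 50),
                           rep(0.5, 50)), 1, "LKNE", "jazz")
  nt <- normalize_by_max(tr)
  expect_equal(unname(apply(abs(nt$values), 2, max)), c(1, 1, 1),
               tolerance = 1e-12)
  expect_equal(unname(nt$scale_factors), c(2, 1, 0.5), tolerance = 1e-12)
  # already-normalized column is unchanged
  expect_equal(nt$values[, 2], tr$frames[, 2], ignore_attr = TRUE)

  zero <- dancer_trial(cbind(1:10, 0, 1:10), 1, "LKNE", "jazz")
  expect_error(normalize_by_max(zero), class = "pirodyn_degenerate_error")
})

test_that("composite construction shuffles, flips even blocks, concatenates", {
  normed <- make_normalized_cohort(15)
  comps <- build_composite(normed, seed = 11)
  expect_named(comps, c("x", "y", "z"))
  for (c in comps) {
    expect_equal(length(c$values), 15 * 300)
    expect_false(c$reduced)
    expect_setequal(c$permutation, 1:15)
  }

  # two trials, identity permutation: A then reversed B
  two <- make_normalized_cohort(2, seed = 5)
  cc <- build_composite(two, permutation = c(1, 2))
  expect_equal(cc$x$values, c(two[[1]]$values[, "x"],
                              rev(two[[2]]$values[, "x"])))
  expect_equal(cc$x$flipped_positions, 2L)

  single <- build_composite(make_normalized_cohort(1, seed = 2))
  expect_equal(length(single$y$values), 300)
  expect_length(single$y$flipped_positions, 0)

  mixed <- c(make_normalized_cohort(1, landmark = "LKNE"),
             make_normalized_cohort(1, landmark = "CoM"))
  expect_error(build_composite(mixed), class = "pirodyn_argument_error")
})

test_that("flipping even blocks is an involution and conserves values", {
  normed <- make_normalized_cohort(6, seed = 9)
  comp <- build_composite(normed, permutation = 1:6)
  # un-flip by re-reversing even blocks: recovers plain concatenation
  v <- comp$z$values
  blocks <- split(v, rep(1:6, each = 300))
  unflipped <- unlist(lapply(seq_along(blocks), function(i) {
    if (i %% 2 == 0) rev(blocks[[i]]) else blocks[[i]]
  }), use.names = FALSE)
  plain <- unlist(lapply(normed, function(tr) tr$values[, "z"]),
                  use.names = FALSE)
  expect_equal(unflipped, plain)
  # shuffle is measure-preserving: multiset of values conserved
  shuffled <- build_composite(normed, seed = 123)
  expect_equal(sort(shuffled$z$values), sort(plain))
})

test_that("quantile reduction drops the sub-quantile tail, order preserved", {
  set.seed(42)
  v <- runif(4500)
  kept <- quantile_reduce(v, 0.1)
  expect_equal(length(kept), sum(v >= quantile(v, 0.1, type = 7)))
  expect_equal(length(kept), 4050)
  # temporal order of survivors preserved
  expect_equal(kept, v[v >= quantile(v, 0.1, type = 7)])

  expect_equal(quantile_reduce(rep(3, 100), 0.1), rep(3, 100))
  expect_equal(quantile_reduce(v, 0), v)

  # idempotence on a composite object
  comp <- build_composite(make_normalized_cohort(5), seed = 1)$x
  once <- quantile_reduce(comp, 0.1)
  twice <- quantile_reduce(once, 0.1)
  expect_identical(once$values, twice$values)
  expect_true(once$reduced)
  # retains at least (1 - p_low) of the samples
  expect_gte(length(once$values), 0.9 * length(comp$values))

  expect_error(quantile_reduce(v, 1), class = "pirodyn_argument_error")
})
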