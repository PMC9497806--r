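test_that("recurrence matrix matches the brute-force construction", {
  set.seed(31)
  for (i in 1:10) {
    P <- matrix(rnorm(3 * 50), ncol = 3)
    rm <- recurrence_matrix(P, radius_fraction = runif(1, 0.05, 0.5))
    expect_identical(unname(rm$indicator),
                     oracle_recurrence(P, rm$radius / rm$diameter))
  }
})

test_that("recurrence matrix conventions: symmetry, LOI, boundary radius", {
  P <- matrix(c(0, 1, 100), ncol = 1)
  rm <- recurrence_matrix(P, radius_fraction = 0.02)  # r = 2
  expect_equal(rm$radius, 2)
  expect_true(rm$indicator[1, 2] && rm$indicator[2, 1])
  expect_false(any(rm$indicator[1:2, 3]))
  expect_true(all(diag(rm$indicator)))
  expect_true(isSymmetric(rm$indicator))

  # identical points recur regardless of radius (Heaviside(0) = 1)
  Q <- rbind(c(1, 1), c(5, 5), c(1, 1))
  rq <- recurrence_matrix(Q, radius_fraction = 1e-6)
  expect_true(rq$indicator[1, 3])

  expect_error(recurrence_matrix(matrix(1, 5, 2)),
               class = "pirodyn_degenerate_error")
})

test_that("line histograms match a brute-force run-length scanner", {
  set.seed(17)
  for (i in 1:30) {
    n <- sample(10:30, 1)
    R <- matrix(runif(n * n) < runif(1, 0.1, 0.6), n, n)
    R <- R | t(R); diag(R) <- TRUE
    rm <- structure(list(indicator = R, N = n, radius = 1, diameter = 10,
                         norm = "euclidean", radius_rule = "fixed"),
                    class = "recurrence_matrix")
    h <- line_histograms(rm)
    o <- oracle_line_histograms(R)
    expect_equal(sort(rep(as.integer(names(h$diagonal)), h$diagonal)),
                 sort(o$diagonal))
    expect_equal(sort(rep(as.integer(names(h$vertical)), h$vertical)),
                 sort(o$vertical))
  }
})

test_that("RQA measures agree exactly with brute-force oracles", {
  set.seed(53)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    d <- sample(1:3, 1)
    P <- matrix(rnorm(n * d), ncol = d)
    rf <- runif(1, 0.05, 0.6)
    rm <- recurrence_matrix(P, radius_fraction = rf)
    m <- rqa_measures(rm)
    R <- oracle_recurrence(P, rf)
    o <- oracle_rqa(R, oracle_line_histograms(R))
    expect_equal(m$rec, o$rec, tolerance = 1e-12)
    expect_equal(m$det, o$det, tolerance = 1e-12)
    expect_identical(m$lmax, o$lmax)
    expect_equal(m$ent, o$ent, tolerance = 1e-12)
    expect_equal(m$lam, o$lam, tolerance = 1e-12)
    expect_equal(m$tt, o$tt, tolerance = 1e-12)
  }
})

test_that("REC spans 0 to 100 with the boundary cases realized", {
  # all points within radius: REC = 100
  P <- matrix(c(0, 0.001, 0.002, 0.0021), ncol = 1)
  rm_all <- recurrence_matrix(P, radius_fraction = 1)
  m_all <- rqa_measures(rm_all)
  expect_equal(m_all$rec, 100)

  # no off-diagonal recurrences: REC = DET = LMAX = 0
  Q <- matrix(c(0, 1, 3, 7, 20), ncol = 1)
  rm_none <- recurrence_matrix(Q, radius_fraction = 1e-4)
  m_none <- rqa_measures(rm_none)
  expect_equal(m_none$rec, 0)
  expect_equal(m_none$det, 0)
  expect_equal(m_none$lmax, 0L)
  expect_equal(m_none$ent, 0)
  expect_equal(m_none$tt, 0)
})

test_that("hand-built matrix reproduces DET, LMAX and ENT by the formulas", {
  # 8x8 with one upper-triangle diagonal line of length 3 and one of length 2
  R <- diag(8) > 0
  for (o in 0:2) R[1 + o, 4 + o] <- TRUE     # length-3 line on offset 3
  for (o in 0:1) R[5 + o, 7 + o] <- TRUE     # length-2 line on offset 2
  R <- R | t(R)
  rm <- structure(list(indicator = R, N = 8, radius = 1, diameter = 10,
                       norm = "euclidean", radius_rule = "fixed"),
                  class = "recurrence_matrix")
  m <- rqa_measures(rm)
  expect_equal(m$det, 100)
  expect_equal(m$lmax, 3L)
  expect_equal(m$ent, log(2), tolerance = 1e-12)
})

test_that("REC is monotone non-decreasing in the radius fraction", {
  set.seed(4)
  P <- matrix(rnorm(80), ncol = 2)
  recs <- vapply(c(0.01, 0.05, 0.1, 0.3, 0.6, 1), function(rf) {
    rqa_measures(recurrence_matrix(P, rf))$rec
  }, numeric(1))
  expect_true(all(diff(recs) >= 0))
})

test_that("noiseless periodic embeddings are highly deterministic", {
  for (N in c(400, 800)) {
    sig <- sin(2 * pi * (1:N) / 25)
    emb <- delay_embed(sig, D = 2, tau = 6)
    m <- rqa_analysis(emb, radius_fraction = 0.02)
    expect_gte(m$det, 99)
    if (N == 400) lmax_small <- m$lmax else expect_gt(m$lmax, lmax_small)
  }
})

test_that("diagonal point totals are conserved against the matrix", {
  set.seed(77)
  P <- matrix(rnorm(120), ncol = 2)
  rm <- recurrence_matrix(P, radius_fraction = 0.3)
  h <- line_histograms(rm)
  total_pts <- sum(as.integer(names(h$diagonal)) * h$diagonal)
  expect_equal(total_pts, sum(rm$indicator[upper.tri(rm$indicator)]))
})
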