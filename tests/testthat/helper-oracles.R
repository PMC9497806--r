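# Independent brute-force oracles, deliberately written as directly as
# possible (double loops, explicit scans) so they share no code path with
# the implementation they check.

# Recurrence matrix by explicit double loop over point pairs.
oracle_recurrence <- function(P, radius_fraction) {
  n <- nrow(P)
  dmax <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dmax <- max(dmax, sqrt(sum((P[i, ] - P[j, ])^2)))
  }
  r <- radius_fraction * dmax
  R <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    R[i, j] <- sqrt(sum((P[i, ] - P[j, ])^2)) <= r
  }
  R
}

# Diagonal / vertical run-length histograms over the upper triangle by
# explicit element-wise scanning.
oracle_line_histograms <- function(R) {
  n <- nrow(R)
  diag_runs <- integer(0)
  for (k in seq_len(n - 1)) {
    run <- 0L
    for (i in seq_len(n - k)) {
      if (R[i, i + k]) {
        run <- run + 1L
      } else if (run > 0) {
        diag_runs <- c(diag_runs, run); run <- 0L
      }
    }
    if (run > 0) diag_runs <- c(diag_runs, run)
  }
  vert_runs <- integer(0)
  for (j in 2:n) {
    run <- 0L
    for (i in seq_len(j - 1)) {
      if (R[i, j]) {
        run <- run + 1L
      } else if (run > 0) {
        vert_runs <- c(vert_runs, run); run <- 0L
      }
    }
    if (run > 0) vert_runs <- c(vert_runs, run)
  }
  list(diagonal = diag_runs, vertical = vert_runs)
}

# RQA measures recomputed straight from the raw run lists.
oracle_rqa <- function(R, runs, l_min = 2, v_min = 2) {
  n <- nrow(R)
  rec_cells <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (R[i, j]) rec_cells <- rec_cells + 1L
  }
  dl <- runs$diagonal; vl <- runs$vertical
  det <- if (sum(dl) > 0) 100 * sum(dl[dl >= l_min]) / sum(dl) else 0
  lmax <- if (length(dl)) max(dl) else 0L
  keep <- dl[dl >= l_min]
  ent <- if (length(keep)) {
    p <- as.numeric(table(keep)) / length(keep)
    -sum(p * log(p))
  } else 0
  lam <- if (sum(vl) > 0) 100 * sum(vl[vl >= v_min]) / sum(vl) else 0
  vk <- vl[vl >= v_min]
  tt <- if (length(vk)) mean(vk) else 0
  list(rec = 100 * rec_cells / (n * (n - 1) / 2), det = det,
       lmax = as.integer(lmax), ent = ent, lam = lam, tt = tt)
}

# Convex hull volume in 3D by brute-force facet enumeration: a triplet is a
# hull facet iff all remaining points lie (weakly) on one side of its plane.
# O(n^4); for small n only.
oracle_hull_volume <- function(P, tol = 1e-12) {
  n <- nrow(P)
  centroid <- colMeans(P)
  vol <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- P[i, ]; b <- P[j, ]; c_ <- P[k, ]
    nrm <- c((b[2]-a[2])*(c_[3]-a[3]) - (b[3]-a[3])*(c_[2]-a[2]),
             (b[3]-a[3])*(c_[1]-a[1]) - (b[1]-a[1])*(c_[3]-a[3]),
             (b[1]-a[1])*(c_[2]-a[2]) - (b[2]-a[2])*(c_[1]-a[1]))
    if (sum(nrm^2) < tol) next
    d <- as.vector(sweep(P, 2, a) %*% nrm)
    if (all(d <= tol) || all(d >= -tol)) {
      # facet; add signed tetrahedron volume w.r.t. centroid
      v <- abs(det(rbind(a - centroid, b - centroid, c_ - centroid))) / 6
      vol <- vol + v
    }
  }
  vol
}

# Benettin twin-trajectory largest Lyapunov exponent for the Lorenz system
# (RK4 integration with periodic renormalization of the separation).
oracle_lorenz_lye <- function(n_renorm = 1500, dt = 0.01, steps_per = 10,
                              d0 = 1e-8) {
  step <- function(s) {
    f <- function(u) c(10 * (u[2] - u[1]), u[1] * (28 - u[3]) - u[2],
                       u[1] * u[2] - 8 / 3 * u[3])
    k1 <- f(s); k2 <- f(s + dt / 2 * k1); k3 <- f(s + dt / 2 * k2)
    k4 <- f(s + dt * k3)
    s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  s <- c(1, 1, 20)
  for (i in 1:4000) s <- step(s)
  p <- s + c(d0, 0, 0)
  acc <- 0
  for (i in seq_len(n_renorm)) {
    for (k in seq_len(steps_per)) { s <- step(s); p <- step(p) }
    d <- sqrt(sum((p - s)^2))
    acc <- acc + log(d / d0)
    p <- s + (p - s) * d0 / d
  }
  acc / (n_renorm * steps_per * dt)
}

# Shorthand for building a normalized cohort.
make_normalized_cohort <- function(n = 15, task = "jazz", landmark = "LKNE",
                                   seed = 7, ...) {
  cohort <- generate_pirouette_cohort(n, task, landmark, seed = seed, ...)
  lapply(cohort, function(tr) normalize_by_max(resample_to_fixed_length(tr)))
}
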