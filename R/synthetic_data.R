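# Synthetic pirouette cohorts and reference signals with known dynamics.
#
# Real single-turn pirouette recordings are short (one to two revolutions,
# ~100-250 frames at 100 Hz) and are not publicly available, so every
# downstream stage is exercised on synthetic analogues: a quasi-periodic
# single-turn waveform with subject-level variability for the cohort, and
# canonical signals (fGn, Lorenz, logistic map, ...) as oracles for the
# estimators.

#' Construct a dancer trial object
#'
#' A trial holds one subject's 3D trajectory of a single landmark during one
#' pirouette: an `n x 3` matrix with columns `x` (anterior-posterior),
#' `y` (inferior-superior) and `z` (mediolateral).
#'
#' @param frames numeric `n x 3` matrix, columns ordered x, y, z.
#' @param subject_id integer subject identifier.
#' @param landmark `"CoM"` (body centre of mass) or `"LKNE"` (left-knee
#'   lateral epicondyle marker).
#' @param task `"classic"` or `"jazz"` pirouette.
#' @param frame_rate sampling rate in Hz.
#' @return An object of class `dancer_trial`.
#' @export
dancer_trial <- function(frames, subject_id, landmark = c("LKNE", "CoM"),
                         task = c("jazz", "classic"), frame_rate = 100) {
  landmark <- match.arg(landmark)
  task <- match.arg(task)
  frames <- as.matrix(frames)
  if (ncol(frames) != 3) arg_error("frames must have 3 columns (x, y, z)")
  if (!all(is.finite(frames))) arg_error("frames must be finite")
  colnames(frames) <- c("x", "y", "z")
  structure(
    list(frames = frames, subject_id = as.integer(subject_id),
         landmark = landmark, task = task, frame_rate = frame_rate),
    class = "dancer_trial"
  )
}

#' @export
print.dancer_trial <- function(x, ...) {
  cat(sprintf("<dancer_trial> subject %d, %s, %s pirouette: %d frames @ %g Hz\n",
              x$subject_id, x$landmark, x$task, nrow(x$frames), x$frame_rate))
  invisible(x)
}

# Baseline oscillation amplitudes (arbitrary length units) per landmark and
# task. The supporting-knee marker sweeps a wider horizontal arc than the
# centre of mass; the classic pirouette (extended knee, full releve) has a
# larger range of motion than the jazz variant on demi-plie, mirroring the
# kinematic contrast between the two techniques.
.pirouette_amplitudes <- function(landmark, task) {
  base <- switch(landmark,
    LKNE = c(x = 0.06, y = 0.04, z = 0.05),
    CoM  = c(x = 0.03, y = 0.05, z = 0.02)
  )
  if (task == "classic") base * c(1.5, 1.25, 1.5) else base
}

#' Generate a synthetic cohort of single-turn pirouette trials
#'
#' Emulates a motion-capture cohort: each subject contributes one landmark
#' trajectory over a single turn, with trial length drawn uniformly from
#' `length_range`. The base waveform is one dominant oscillation per trial
#' (a single revolution): sinusoidal anterior-posterior (`x`) and
#' mediolateral (`z`) sway in quadrature under a smooth onset/offset
#' envelope, and a rise-and-fall vertical (`y`) excursion. Subjects differ
#' by a random per-coordinate amplitude factor (within +/-20%), a random
#' phase offset, and additive iid Gaussian noise.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param task,landmark trial labels, see [dancer_trial()].
#' @param length_range integer vector `c(min, max)` of admissible trial
#'   lengths in frames; both ends >= 2.
#' @param noise_sd standard deviation of the additive Gaussian noise, in the
#'   same (arbitrary) length units as the waveform amplitudes.
#' @param seed integer seed; identical arguments and seed give bit-identical
#'   cohorts.
#' @param frame_rate sampling rate in Hz.
#' @return A list of `n_subjects` [dancer_trial()] objects.
#' @examples
#' cohort <- generate_pirouette_cohort(15, "jazz", "LKNE", seed = 7)
#' range(vapply(cohort, function(tr) nrow(tr$frames), integer(1)))
#' @export
generate_pirouette_cohort <- function(n_subjects, task = c("jazz", "classic"),
                                      landmark = c("LKNE", "CoM"),
                                      length_range = c(101L, 250L),
                                      noise_sd = 0.01, seed = 1,
                                      frame_rate = 100) {
  task <- match.arg(task)
  landmark <- match.arg(landmark)
  if (length(n_subjects) != 1 || n_subjects < 1) {
    arg_error("n_subjects must be a positive count")
  }
  length_range <- as.integer(round(length_range))
  if (length(length_range) != 2 || length_range[1] > length_range[2] ||
      length_range[1] < 2) {
    arg_error("length_range must be an interval within [2, Inf)")
  }
  if (noise_sd < 0) arg_error("noise_sd must be >= 0")

  amp <- .pirouette_amplitudes(landmark, task)
  with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      n <- if (length_range[1] == length_range[2]) length_range[1] else
        sample(length_range[1]:length_range[2], 1L)
      s <- seq(0, 1, length.out = n)          # normalized turn phase
      a <- amp * stats::runif(3, 0.8, 1.2)    # subject amplitude variation
      phi <- stats::runif(1, -pi / 4, pi / 4) # subject phase offset
      env <- sin(pi * s)^2                    # smooth onset/offset envelope
      x <- a["x"] * env * sin(2 * pi * s + phi)
      z <- a["z"] * env * cos(2 * pi * s + phi)
      y <- a["y"] * sin(pi * s)^2             # rise onto releve and back down
      fr <- cbind(x = x, y = y, z = z)
      if (noise_sd > 0) {
        fr <- fr + matrix(stats::rnorm(3 * n, sd = noise_sd), ncol = 3)
      }
      dancer_trial(fr, subject_id = i, landmark = landmark, task = task,
                   frame_rate = frame_rate)
    })
  })
}

#' Generate a reference signal with known dynamics
#'
#' Canonical test signals for the characterization and embedding estimators:
#' \describe{
#'   \item{`sine`}{`A * sin(2*pi*t/period)`, `t = 0, 1, ...`; params
#'     `period` (default 25), `A` (default 1).}
#'   \item{`white_noise`}{iid Gaussian, param `sd` (default 1).}
#'   \item{`fgn`}{fractional Gaussian noise with Hurst parameter
#'     `H_target` via exact circulant (Davies-Harte) synthesis; spectral
#'     synthesis fallback if the circulant embedding is not nonnegative.}
#'   \item{`brownian`}{cumulative sum of iid Gaussian increments.}
#'   \item{`lorenz`}{Lorenz system integrated with `deSolve`; params
#'     `sigma` (10), `rho` (28), `beta` (8/3), `dt` (0.01), `burn`
#'     (transient samples discarded, 500). Returns an `n x 3` matrix.}
#'   \item{`logistic`}{iterates of `r * x * (1 - x)`; params `r` (4),
#'     `x0` (drawn uniform if absent).}
#' }
#'
#' @param kind signal type, one of the labels above.
#' @param length number of samples returned (>= 2).
#' @param params named list of generator parameters (see above).
#' @param seed integer seed; output is reproducible given
#'   `(kind, params, seed)`.
#' @return An object of class `reference_signal` with elements `kind`,
#'   `values` (vector, or matrix for `lorenz`), `params`, `seed`.
#' @examples
#' s <- generate_reference_signal("sine", 100, list(period = 25))
#' max(abs(s$values))
#' @export
generate_reference_signal <- function(kind, length, params = list(), seed = 1) {
  kinds <- c("sine", "white_noise", "fgn", "brownian", "lorenz", "logistic")
  if (!kind %in% kinds) {
    arg_error("unknown signal kind '", kind, "'; expected one of: ",
              paste(kinds, collapse = ", "))
  }
  if (length < 2) arg_error("length must be >= 2")
  n <- as.integer(length)
  values <- with_seed(seed, switch(kind,
    sine = {
      period <- params$period %||% 25
      A <- params$A %||% 1
      A * sin(2 * pi * (seq_len(n) - 1) / period)
    },
    white_noise = stats::rnorm(n, sd = params$sd %||% 1),
    fgn = {
      H <- params$H_target %||% arg_error("fgn requires params$H_target")
      if (H <= 0 || H >= 1) arg_error("H_target must be in (0, 1)")
      .fgn_davies_harte(n, H)
    },
    brownian = cumsum(stats::rnorm(n, sd = params$sd %||% 1)),
    lorenz = .lorenz_series(n, params),
    logistic = {
      r <- params$r %||% 4
      x <- numeric(n)
      x[1] <- params$x0 %||% stats::runif(1, 0.1, 0.9)
      for (i in seq_len(n - 1)) x[i + 1] <- r * x[i] * (1 - x[i])
      x
    }
  ))
  structure(list(kind = kind, values = values, params = params, seed = seed),
            class = "reference_signal")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact fGn synthesis by circulant embedding of the autocovariance
# (Davies-Harte). Falls back to spectral (FFT filter) synthesis when the
# circulant eigenvalues are not all nonnegative (does not occur for the fGn
# autocovariance at the lengths used here, but kept as a guard).
.fgn_davies_harte <- function(n, H) {
  g <- function(k) 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                            abs(k - 1)^(2 * H))
  m <- 2L * n
  acv <- g(0:n)
  circ <- c(acv, acv[n:2])
  lam <- Re(stats::fft(circ))
  if (any(lam < -1e-10)) return(.fgn_spectral(n, H))
  lam[lam < 0] <- 0
  z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
  z[1] <- complex(real = stats::rnorm(1) * sqrt(2), imaginary = 0)
  z[n + 1] <- complex(real = stats::rnorm(1) * sqrt(2), imaginary = 0)
  z[(n + 2):m] <- Conj(z[n:2])
  w <- stats::fft(sqrt(lam / (2 * m)) * z)
  Re(w[1:n])
}

# Approximate spectral synthesis: shape white noise by the fGn spectral
# density |f|^{-(2H-1)} (used only as a fallback).
.fgn_spectral <- function(n, H) {
  m <- 2L * n
  f <- seq_len(m %/% 2) / m
  s <- f^(-(2 * H - 1) / 2)
  phases <- stats::runif(length(s), 0, 2 * pi)
  spec <- complex(modulus = s, argument = phases)
  full <- c(0, spec, Conj(rev(spec[-length(spec)])))
  x <- Re(stats::fft(full, inverse = TRUE))[1:n]
  as.numeric(scale(x))
}

.lorenz_series <- function(n, params) {
  sigma <- params$sigma %||% 10
  rho <- params$rho %||% 28
  beta <- params$beta %||% 8 / 3
  dt <- params$dt %||% 0.01
  burn <- params$burn %||% 500L
  y0 <- c(x = 1 + stats::rnorm(1, sd = 1e-3),
          y = 1 + stats::rnorm(1, sd = 1e-3),
          z = 20 + stats::rnorm(1, sd = 1e-3))
  times <- seq(0, (n + burn - 1) * dt, by = dt)
  deriv <- function(t, state, p) {
    with(as.list(state), list(c(
      sigma * (y - x),
      x * (rho - z) - y,
      x * y - beta * z
    )))
  }
  out <- deSolve::ode(y0, times, deriv, parms = NULL, method = "ode45",
                      rtol = 1e-9, atol = 1e-9)
  unname(as.matrix(out[(burn + 1):(burn + n), c("x", "y", "z")]))
}

#' Write a trial to CSV
#'
#' One file per trial, columns `frame,x,y,z`, 6-decimal fixed point, named
#' `<task>_<landmark>_S<subject_id>.csv`.
#'
#' @param trial a [dancer_trial()].
#' @param dir output directory (created if missing).
#' @return The path written, invisibly.
#' @export
write_trial_csv <- function(trial, dir) {
  stopifnot(inherits(trial, "dancer_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, sprintf("%s_%s_S%d.csv", trial$task, trial$landmark,
                                 trial$subject_id))
  df <- data.frame(frame = seq_len(nrow(trial$frames)),
                   x = sprintf("%.6f", trial$frames[, "x"]),
                   y = sprintf("%.6f", trial$frames[, "y"]),
                   z = sprintf("%.6f", trial$frames[, "z"]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial CSV written by [write_trial_csv()]
#'
#' Accepts comma- or tab-delimited files with columns `frame,x,y,z`; task,
#' landmark and subject id are parsed from the filename pattern
#' `<task>_<landmark>_S<id>.csv` unless supplied.
#'
#' @param path file path.
#' @param task,landmark,subject_id optional overrides for the
#'   filename-encoded metadata.
#' @param frame_rate sampling rate in Hz.
#' @return A [dancer_trial()].
#' @export
read_trial_csv <- function(path, task = NULL, landmark = NULL,
                           subject_id = NULL, frame_rate = 100) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("x", "y", "z")
  if (!all(need %in% names(df))) arg_error("trial file must have x,y,z columns")
  base <- sub("\\.(csv|tsv)$", "", basename(path))
  m <- regmatches(base, regexec("^([a-z]+)_([A-Za-z]+)_S([0-9]+)$", base))[[1]]
  if (length(m) == 4) {
    task <- task %||% m[2]
    landmark <- landmark %||% m[3]
    subject_id <- subject_id %||% as.integer(m[4])
  }
  dancer_trial(as.matrix(df[, need]), subject_id = subject_id %||% 1L,
               landmark = landmark %||% "LKNE", task = task %||% "jazz",
               frame_rate = frame_rate)
}
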