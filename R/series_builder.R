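# Group-level composite series construction.
#
# Single-turn trials are far too short for attractor reconstruction, so the
# cohort's trials are pooled into one long series per coordinate: resample
# every trial to a fixed length, normalize each coordinate by its maximum
# absolute value, shuffle the trial order (seeded), time-reverse the trials
# at even positions so consecutive blocks join end-to-start without jumps,
# concatenate, and finally drop the samples below a low quantile to curb
# impulsive troughs.

#' Resample a trial to a fixed number of samples
#'
#' Each coordinate is linearly interpolated onto `m` evenly spaced abscissae
#' spanning the original frame index range; endpoints are preserved exactly.
#'
#' @param trial a [dancer_trial()] (or plain numeric matrix / vector).
#' @param m target length (default 300).
#' @return The same type as the input, with `m` rows.
#' @export
resample_to_fixed_length <- function(trial, m = 300) {
  if (m < 2) arg_error("m must be >= 2")
  resample_mat <- function(mat) {
    n <- nrow(mat)
    if (n < 2) arg_error("need at least 2 frames to resample")
    xout <- seq(1, n, length.out = m)
    apply(mat, 2, function(col) stats::approx(seq_len(n), col, xout)$y)
  }
  if (inherits(trial, "dancer_trial")) {
    out <- trial
    out$frames <- resample_mat(trial$frames)
    colnames(out$frames) <- c("x", "y", "z")
    out
  } else if (is.matrix(trial)) {
    resample_mat(trial)
  } else {
    drop(resample_mat(matrix(as.numeric(trial), ncol = 1)))
  }
}

#' Normalize each coordinate by its maximum absolute value
#'
#' Divides every column by its own `max(abs(.))`, so each normalized
#' coordinate attains a maximum magnitude of exactly 1. "Maximal value" is
#' taken as maximum absolute value since kinematic coordinates can be
#' negative; the scale factors are recorded for provenance.
#'
#' @param trial a [dancer_trial()], typically already resampled.
#' @return An object of class `normalized_trial`: `values` (matrix with unit
#'   per-column max magnitude), `scale_factors`, plus the trial metadata.
#' @export
normalize_by_max <- function(trial) {
  stopifnot(inherits(trial, "dancer_trial"))
  sf <- apply(abs(trial$frames), 2, max)
  if (any(sf == 0)) {
    degenerate_error("cannot normalize: coordinate(s) ",
                     paste(names(sf)[sf == 0], collapse = ","), " are all zero")
  }
  structure(
    list(values = sweep(trial$frames, 2, sf, "/"),
         scale_factors = sf, subject_id = trial$subject_id,
         landmark = trial$landmark, task = trial$task),
    class = "normalized_trial"
  )
}

#' Build composite group-level series (one per coordinate)
#'
#' Shuffles the trials with a seeded uniform random permutation,
#' time-reverses the trials at even (1-based) positions in the shuffled
#' order so that the concatenated signal loops smoothly, and concatenates
#' each coordinate into one long vector.
#'
#' @param trials list of [normalize_by_max()] outputs sharing landmark and
#'   task.
#' @param seed integer seed for the shuffle.
#' @param permutation optional explicit ordering (indices into `trials`),
#'   bypassing the seeded shuffle; used for deterministic construction.
#' @return A named list with one `composite_series` per coordinate
#'   (`x`, `y`, `z`). Each carries `values`, `n_trials`, `permutation`
#'   (subject ids in concatenation order), `flipped_positions`, `reduced`
#'   flag and `seed`.
#' @export
build_composite <- function(trials, seed = 1, permutation = NULL) {
  if (length(trials) < 1) arg_error("need at least one trial")
  stopifnot(all(vapply(trials, inherits, logical(1), "normalized_trial")))
  lm <- unique(vapply(trials, `[[`, character(1), "landmark"))
  tk <- unique(vapply(trials, `[[`, character(1), "task"))
  if (length(lm) != 1 || length(tk) != 1) {
    arg_error("all trials must share landmark and task")
  }
  k <- length(trials)
  perm <- if (is.null(permutation)) {
    with_seed(seed, sample.int(k))
  } else {
    if (!setequal(permutation, seq_len(k))) {
      arg_error("permutation must be a bijection on 1..", k)
    }
    as.integer(permutation)
  }
  flipped <- seq_len(k)[seq_len(k) %% 2 == 0]
  ids <- vapply(trials, `[[`, integer(1), "subject_id")
  out <- lapply(c(x = "x", y = "y", z = "z"), function(coord) {
    blocks <- lapply(seq_len(k), function(pos) {
      v <- trials[[perm[pos]]]$values[, coord]
      if (pos %% 2 == 0) rev(v) else v
    })
    structure(
      list(coordinate = coord, values = unlist(blocks, use.names = FALSE),
           n_trials = k, permutation = ids[perm],
           flipped_positions = flipped, reduced = FALSE, seed = seed,
           landmark = lm, task = tk),
      class = "composite_series"
    )
  })
  out
}

#' @export
print.composite_series <- function(x, ...) {
  cat(sprintf("<composite_series> %s %s coordinate %s: %d samples from %d trials%s\n",
              x$task, x$landmark, x$coordinate, length(x$values), x$n_trials,
              if (x$reduced) " (quantile-reduced)" else ""))
  invisible(x)
}

#' Remove samples below a low quantile of a composite series
#'
#' Computes the empirical `p_low` quantile (type-7, interpolated order
#' statistics) of the series and drops samples strictly below it, keeping
#' survivors in temporal order. This trims impulsive troughs while
#' preserving the dynamics (a literal quantile transform would sort the
#' series and destroy them). A `composite_series` that has already been
#' reduced is returned unchanged (the quantile of the survivors would
#' otherwise creep upward on every application), making the operation
#' idempotent.
#'
#' @param series a `composite_series` (or plain numeric vector).
#' @param p_low lower tail probability in `[0, 1)`; `0` is the identity.
#' @return The reduced series, same type as the input, `reduced` flag set.
#' @export
quantile_reduce <- function(series, p_low = 0.1) {
  if (p_low < 0 || p_low >= 1) arg_error("p_low must be in [0, 1)")
  if (inherits(series, "composite_series") && isTRUE(series$reduced)) {
    return(series)
  }
  reduce <- function(v) {
    if (p_low == 0) return(v)
    q <- stats::quantile(v, p_low, type = 7, names = FALSE)
    keep <- v >= q
    if (sum(keep) < 2) degenerate_error("quantile reduction leaves < 2 samples")
    v[keep]
  }
  if (inherits(series, "composite_series")) {
    series$values <- reduce(series$values)
    series$reduced <- TRUE
    series
  } else {
    reduce(as.numeric(series))
  }
}
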