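# Takens delay embedding: delay selection by average mutual information,
# dimension selection by false nearest neighbors, and the embedding itself.
# Both a "global" setting (delay/dimension estimated jointly from the 3D
# series) and a "directional" setting (per coordinate) are supported.

#' Average mutual information (AMI) curve
#'
#' Estimates the mutual information (in nats) between `x(t)` and
#' `x(t + lag)` for lags `0..max_lag` from a 2D histogram with equiprobable
#' marginal bins (rank-based binning; bin count defaults to
#' `max(8, floor(N^(1/3)))`). With equiprobable bins the estimate is exactly
#' symmetric under time reversal (the joint table transposes).
#'
#' @param series numeric vector.
#' @param max_lag largest lag evaluated.
#' @param n_bins number of marginal bins; `NULL` for the default rule.
#' @return Object of class `ami_curve`: `lags`, `ami` (nats), `n_bins`.
#' @export
average_mutual_information <- function(series, max_lag = 100, n_bins = NULL) {
  x <- series_values(series)
  N <- length(x)
  if (N <= max_lag + 1) arg_error("series must be longer than max_lag + 1")
  if (stats::sd(x) == 0) degenerate_error("constant series carries no information")
  if (is.null(n_bins)) n_bins <- max(8L, floor(N^(1 / 3)))
  b <- ceiling(rank(x, ties.method = "first") * n_bins / N)
  ami <- vapply(0:max_lag, function(lag) {
    n <- N - lag
    joint <- table(factor(b[seq_len(n)], levels = seq_len(n_bins)),
                   factor(b[(1 + lag):N], levels = seq_len(n_bins)))
    p <- joint / n
    px <- rowSums(p); py <- colSums(p)
    nz <- p > 0
    sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
  }, numeric(1))
  structure(list(lags = 0:max_lag, ami = ami, n_bins = n_bins),
            class = "ami_curve")
}

#' Select a delay from an AMI curve
#'
#' `"one_over_e"` picks the smallest lag whose AMI drops below
#' `AMI(0) / e`; `"first_minimum"` picks the smallest strict local minimum.
#' If the criterion is never met, the largest lag is returned with attribute
#' `warning_flag = TRUE`.
#'
#' @param ami an [average_mutual_information()] result (or plain numeric
#'   curve starting at lag 0).
#' @param criterion `"one_over_e"` (default) or `"first_minimum"`.
#' @return Integer lag (>= 1) with attribute `warning_flag`.
#' @export
select_delay <- function(ami, criterion = c("one_over_e", "first_minimum")) {
  criterion <- match.arg(criterion)
  curve <- if (inherits(ami, "ami_curve")) ami$ami else as.numeric(ami)
  if (length(curve) < 2) arg_error("AMI curve needs >= 2 points")
  max_lag <- length(curve) - 1L
  lag <- NA_integer_
  if (criterion == "one_over_e") {
    hit <- which(curve < curve[1] / exp(1))
    hit <- hit[hit > 1]
    if (length(hit)) lag <- hit[1] - 1L
  } else {
    for (i in 2:(length(curve) - 1)) {
      if (curve[i] < curve[i - 1] && curve[i] < curve[i + 1]) {
        lag <- i - 1L
        break
      }
    }
  }
  if (is.na(lag)) {
    out <- max_lag
    attr(out, "warning_flag") <- TRUE
  } else {
    out <- max(1L, lag)
    attr(out, "warning_flag") <- FALSE
  }
  out
}

#' Combine per-coordinate delays into a global delay
#'
#' The global delay is the arithmetic mean of the per-coordinate delays,
#' rounded to the nearest integer with ties away from zero, floored at 1.
#'
#' @param per_column_tau named numeric vector or list of per-coordinate lags.
#' @return Integer global lag.
#' @export
global_delay <- function(per_column_tau) {
  taus <- unlist(per_column_tau, use.names = FALSE)
  if (!length(taus)) arg_error("need at least one delay")
  max(1L, as.integer(round_half_away(mean(taus))))
}

#' Estimate delays for a multivariate series
#'
#' Runs [average_mutual_information()] and [select_delay()] on each column
#' and aggregates with [global_delay()].
#'
#' @param mat numeric matrix (columns = coordinates) or vector.
#' @param max_lag,n_bins passed to [average_mutual_information()].
#' @param criterion passed to [select_delay()].
#' @return Object of class `delay_estimate`: `per_column_tau`, `global_tau`,
#'   `ami_curves`, `criterion`.
#' @export
estimate_delays <- function(mat, max_lag = 100, n_bins = NULL,
                            criterion = "one_over_e") {
  if (!is.matrix(mat)) mat <- matrix(series_values(mat), ncol = 1)
  cols <- colnames(mat) %||% paste0("V", seq_len(ncol(mat)))
  curves <- lapply(seq_len(ncol(mat)), function(j) {
    average_mutual_information(mat[, j], max_lag = max_lag, n_bins = n_bins)
  })
  names(curves) <- cols
  taus <- vapply(curves, function(cv) as.integer(select_delay(cv, criterion)),
                 integer(1))
  structure(
    list(per_column_tau = taus, global_tau = global_delay(taus),
         ami_curves = curves, criterion = criterion),
    class = "delay_estimate"
  )
}

# Build the delay-coordinate matrix for a (possibly multivariate) series at
# dimension d: columns are all coordinates at lags 0, tau, ..., (d-1)*tau.
.embed_blocks <- function(mat, d, tau) {
  N <- nrow(mat)
  M <- N - (d - 1) * tau
  if (M < 2) arg_error("series too short to embed at this dimension")
  do.call(cbind, lapply(0:(d - 1), function(j) {
    mat[(1 + j * tau):(j * tau + M), , drop = FALSE]
  }))
}

#' False-nearest-neighbor embedding dimension selection
#'
#' Classic Kennel criterion: for each trial dimension `D`, each embedded
#' point's nearest neighbor is declared false if the distance added by the
#' next embedding coordinate exceeds `Rtol` times the current neighbor
#' distance, or if the expanded distance exceeds `Atol` times the series'
#' standard deviation (attractor size). Neighbor pairs at (numerically)
#' zero distance — exact repeats, as in noiseless periodic signals — are
#' judged by the absolute `Atol` criterion alone, since the distance ratio
#' is undefined for them. The selected dimension is the smallest `D` whose
#' FNN percentage drops to `threshold` or below; if none qualifies the
#' argmin is returned with `warning_flag = TRUE`. The default threshold of
#' 1% is strict enough to resolve low-dimensional chaotic flows (a scalar
#' Lorenz coordinate retains a few percent false neighbors in 2 dimensions
#' and needs 3). Multivariate input (an `n x 3` matrix) is embedded jointly
#' — all coordinates at each lag — giving the global-mode estimate.
#'
#' @param series numeric vector (directional mode) or matrix (global mode).
#' @param tau delay in samples.
#' @param max_dim largest embedding dimension examined.
#' @param Rtol,Atol Kennel false-neighbor tolerances.
#' @param threshold acceptance level for the FNN percentage (percent).
#' @return Object of class `dimension_estimate`: `fnn_percentages` (named by
#'   dimension), `selected_D`, `mode`, `threshold`, `warning_flag`.
#' @export
false_nearest_neighbors <- function(series, tau, max_dim = 10, Rtol = 10,
                                    Atol = 2, threshold = 1) {
  mat <- if (is.matrix(series)) series else
    matrix(series_values(series), ncol = 1)
  mode <- if (ncol(mat) > 1) "global" else "directional"
  N <- nrow(mat)
  if (N - max_dim * tau < 10) arg_error("series too short for max_dim at this tau")
  sd_all <- stats::sd(as.numeric(mat))
  fnn <- vapply(seq_len(max_dim), function(d) {
    Yd <- .embed_blocks(mat, d, tau)
    Yd1 <- .embed_blocks(mat, d + 1, tau)
    M <- nrow(Yd1)                      # points that survive in d+1 as well
    Yd <- Yd[seq_len(M), , drop = FALSE]
    dm <- as.matrix(stats::dist(Yd))
    diag(dm) <- Inf
    nn <- apply(dm, 1, which.min)
    dd <- dm[cbind(seq_len(M), nn)]
    extra_cols <- (ncol(Yd1) - ncol(mat) + 1):ncol(Yd1)
    delta <- sqrt(rowSums((Yd1[seq_len(M), extra_cols, drop = FALSE] -
                             Yd1[nn, extra_cols, drop = FALSE])^2))
    dnew <- sqrt(dd^2 + delta^2)
    zero_dd <- dd <= 1e-8 * sd_all        # exact repeats: ratio undefined
    false_nb <- (!zero_dd & delta / pmax(dd, .Machine$double.eps) > Rtol) |
      (dnew / sd_all > Atol)
    100 * mean(false_nb)
  }, numeric(1))
  names(fnn) <- seq_len(max_dim)
  below <- which(fnn <= threshold)
  if (length(below)) {
    selected <- below[1]
    warn <- FALSE
  } else {
    selected <- which.min(fnn)
    warn <- TRUE
  }
  structure(
    list(fnn_percentages = fnn, selected_D = as.integer(selected),
         mode = mode, threshold = threshold, warning_flag = warn),
    class = "dimension_estimate"
  )
}

#' Delay-coordinate embedding
#'
#' Maps a scalar series to state vectors
#' `y(t) = (x(t), x(t + tau), ..., x(t + (D - 1) tau))`; the trajectory has
#' `N - (D - 1) * tau` points.
#'
#' @param series numeric vector of length `N > (D - 1) * tau`.
#' @param D embedding dimension (>= 1).
#' @param tau delay in samples (>= 1).
#' @param mode optional label (`"global"` / `"directional"`) carried as
#'   provenance.
#' @return Object of class `embedded_trajectory`: `points`
#'   (`(N - (D-1) tau) x D` matrix), `D`, `tau`, `source_length`, `mode`.
#' @examples
#' delay_embed(1:5, D = 3, tau = 1)$points
#' @export
delay_embed <- function(series, D, tau, mode = NA_character_) {
  x <- series_values(series)
  N <- length(x)
  if (D < 1 || tau < 1) arg_error("D and tau must be >= 1")
  if (N <= (D - 1) * tau) arg_error("need N > (D - 1) * tau to embed")
  M <- N - (D - 1) * tau
  pts <- vapply(0:(D - 1), function(j) x[(1 + j * tau):(j * tau + M)],
                numeric(M))
  pts <- matrix(pts, nrow = M, ncol = D)
  structure(
    list(points = pts, D = as.integer(D), tau = as.integer(tau),
         source_length = N, mode = mode),
    class = "embedded_trajectory"
  )
}

#' @export
print.embedded_trajectory <- function(x, ...) {
  cat(sprintf("<embedded_trajectory> %d points in %d dims (tau = %d, N = %d)\n",
              nrow(x$points), x$D, x$tau, x$source_length))
  invisible(x)
}
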