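# Recurrence quantification analysis: thresholded recurrence matrix, line
# histograms over the upper triangle (the line of identity and lower
# triangle are redundant by symmetry and excluded), and the six classical
# measures REC, DET, LMAX, ENT, LAM, TT.

#' Recurrence matrix of an embedded trajectory
#'
#' `R[i, j] = 1` iff `||x_i - x_j|| <= r` (Euclidean norm; Heaviside
#' convention with equality recurrent). The radius is a fixed fraction of
#' the maximum phase-space diameter, computed exactly over all pairs.
#'
#' @param points an [delay_embed()] result or numeric matrix of states.
#' @param radius_fraction radius as a fraction of the maximal pairwise
#'   distance (default 0.01, i.e. 1%).
#' @return Object of class `recurrence_matrix`: `indicator` (logical N x N),
#'   `radius`, `diameter`, `norm`, `N`, `radius_rule`.
#' @export
recurrence_matrix <- function(points, radius_fraction = 0.01) {
  P <- as_point_matrix(points)
  if (nrow(P) < 2) arg_error("need at least 2 points")
  if (radius_fraction <= 0) arg_error("radius_fraction must be > 0")
  dm <- as.matrix(stats::dist(P))
  diameter <- max(dm)
  if (diameter == 0) degenerate_error("all points identical; diameter is zero")
  r <- radius_fraction * diameter
  structure(
    list(indicator = dm <= r, radius = r, diameter = diameter,
         norm = "euclidean", N = nrow(P),
         radius_rule = sprintf("%g%% of max diameter", 100 * radius_fraction)),
    class = "recurrence_matrix"
  )
}

#' @export
print.recurrence_matrix <- function(x, ...) {
  cat(sprintf("<recurrence_matrix> %d x %d, r = %.4g (%s), density %.2f%%\n",
              x$N, x$N, x$radius, x$radius_rule,
              100 * mean(x$indicator[upper.tri(x$indicator)])))
  invisible(x)
}

#' Diagonal and vertical line-length histograms
#'
#' Scans the upper triangle of the recurrence matrix (line of identity
#' excluded): diagonal lines are maximal runs of recurrent cells along each
#' super-diagonal, vertical lines are maximal runs within each column
#' restricted to rows above the diagonal. Runs truncated by the matrix
#' border count at their observed length.
#'
#' @param rm a [recurrence_matrix()].
#' @return Object of class `line_histograms`: `diagonal` and `vertical`
#'   (named integer vectors mapping line length to count), `region`.
#' @export
line_histograms <- function(rm) {
  stopifnot(inherits(rm, "recurrence_matrix"))
  R <- rm$indicator
  N <- rm$N
  run_lengths <- function(v) {
    if (!length(v)) return(integer(0))
    r <- rle(v)
    r$lengths[r$values]
  }
  diag_runs <- unlist(lapply(seq_len(N - 1), function(k) {
    run_lengths(R[cbind(seq_len(N - k), seq_len(N - k) + k)])
  }), use.names = FALSE)
  vert_runs <- unlist(lapply(2:N, function(j) {
    run_lengths(R[seq_len(j - 1), j])
  }), use.names = FALSE)
  to_hist <- function(runs) {
    if (!length(runs)) return(stats::setNames(integer(0), character(0)))
    tb <- table(runs)
    stats::setNames(as.integer(tb), names(tb))
  }
  structure(
    list(diagonal = to_hist(diag_runs), vertical = to_hist(vert_runs),
         region = "upper_triangle_loi_excluded", N = N),
    class = "line_histograms"
  )
}

.hist_lengths <- function(h) as.integer(names(h))

#' The six recurrence quantification measures
#'
#' From a recurrence matrix and its line histograms (upper triangle, line of
#' identity excluded):
#' \describe{
#'   \item{REC}{percentage of recurrent cells. Default normalization divides
#'     by the number of upper-triangle cells `N(N-1)/2`, so REC spans the
#'     full 0-100% range; `normalization = "full_matrix"` divides the full
#'     symmetric count (diagonal included) by `N^2` instead.}
#'   \item{DET}{percentage of recurrent points on diagonal lines of length
#'     >= `l_min`: `100 * sum(l P(l), l >= l_min) / sum(l P(l), l >= 1)`.}
#'   \item{LMAX}{length of the longest diagonal line.}
#'   \item{ENT}{Shannon entropy (nats) of the distribution of diagonal line
#'     lengths `>= l_min`: `p_l = P(l) / N_l` with `N_l` the number of such
#'     lines.}
#'   \item{LAM}{as DET, on vertical lines with `v_min`.}
#'   \item{TT}{trapping time: mean length of vertical lines `>= v_min`.}
#' }
#' Ratios with zero denominators are defined as 0.
#'
#' @param rm a [recurrence_matrix()].
#' @param hist optional precomputed [line_histograms()].
#' @param l_min,v_min minimum diagonal / vertical line lengths (both 2, the
#'   smallest run that constitutes a line segment).
#' @param normalization REC denominator convention, see above.
#' @return Object of class `rqa_measures` with fields `rec`, `det`, `lmax`,
#'   `ent`, `lam`, `tt`, `l_min`, `v_min`, `n_points`.
#' @export
rqa_measures <- function(rm, hist = NULL, l_min = 2, v_min = 2,
                         normalization = c("upper_triangle", "full_matrix")) {
  stopifnot(inherits(rm, "recurrence_matrix"))
  normalization <- match.arg(normalization)
  if (is.null(hist)) hist <- line_histograms(rm)
  N <- rm$N
  rec_cells <- sum(rm$indicator[upper.tri(rm$indicator)])
  rec <- if (normalization == "upper_triangle") {
    100 * rec_cells / (N * (N - 1) / 2)
  } else {
    100 * (2 * rec_cells + N) / N^2
  }

  dl <- .hist_lengths(hist$diagonal); dc <- unname(hist$diagonal)
  tot_diag_pts <- sum(dl * dc)
  long <- dl >= l_min
  det <- if (tot_diag_pts > 0) 100 * sum(dl[long] * dc[long]) / tot_diag_pts else 0
  lmax <- if (length(dl)) max(dl) else 0L
  n_lines <- sum(dc[long])
  ent <- if (n_lines > 0) {
    p <- dc[long] / n_lines
    -sum(p * log(p))
  } else 0

  vl <- .hist_lengths(hist$vertical); vc <- unname(hist$vertical)
  tot_vert_pts <- sum(vl * vc)
  vlong <- vl >= v_min
  lam <- if (tot_vert_pts > 0) 100 * sum(vl[vlong] * vc[vlong]) / tot_vert_pts else 0
  n_vlines <- sum(vc[vlong])
  tt <- if (n_vlines > 0) sum(vl[vlong] * vc[vlong]) / n_vlines else 0

  structure(
    list(rec = rec, det = det, lmax = as.integer(lmax), ent = ent,
         lam = lam, tt = tt, l_min = l_min, v_min = v_min, n_points = N,
         normalization = normalization),
    class = "rqa_measures"
  )
}

#' @export
print.rqa_measures <- function(x, ...) {
  cat(sprintf(
    "<rqa_measures> REC %.2f%%  DET %.2f%%  LMAX %d  ENT %.3f  LAM %.2f%%  TT %.2f (N = %d)\n",
    x$rec, x$det, x$lmax, x$ent, x$lam, x$tt, x$n_points))
  invisible(x)
}

#' Run the full RQA chain on an embedded trajectory
#'
#' Convenience wrapper: [recurrence_matrix()] then [line_histograms()] then
#' [rqa_measures()].
#'
#' @inheritParams recurrence_matrix
#' @inheritParams rqa_measures
#' @return An `rqa_measures` object.
#' @export
rqa_analysis <- function(points, radius_fraction = 0.01, l_min = 2, v_min = 2,
                         normalization = "upper_triangle") {
  rm <- recurrence_matrix(points, radius_fraction)
  rqa_measures(rm, l_min = l_min, v_min = v_min, normalization = normalization)
}
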