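# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the RNG, runs `expr`, and restores the caller's `.Random.seed`,
#' so seeded package functions never perturb the user's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

#' Stop with a classed argument error
#' @noRd
arg_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("pirodyn_argument_error", "error")))
}

#' Stop with a classed degenerate-input error
#' @noRd
degenerate_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("pirodyn_degenerate_error", "error")))
}

#' Round half away from zero
#' @noRd
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Coerce an embedded trajectory or plain matrix to a numeric matrix
#' @noRd
as_point_matrix <- function(points) {
  if (inherits(points, "embedded_trajectory")) points <- points$points
  if (is.data.frame(points)) points <- as.matrix(points)
  if (!is.matrix(points)) points <- matrix(as.numeric(points), ncol = 1)
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) arg_error("points must be finite")
  points
}
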