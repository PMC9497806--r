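# Attractor geometry: convex-hull volume of embedded trajectories and the
# percentage-difference convention used to compare attractors and RQA
# measures between settings.
#
# The 3D convex hull is computed by an incremental quickhull written here
# (no hull library is part of the package's dependency set); 2D inputs use
# grDevices::chull + the shoelace formula, 1D inputs reduce to the range.

# ---------------------------------------------------------------------------
# quickhull (3D)
# ---------------------------------------------------------------------------

# Signed distance of points `p` (n x 3) from the plane of face (a, b, c),
# positive on the side of the (right-handed) normal.
.face_dist <- function(p, a, b, c) {
  nrm <- c(
    (b[2] - a[2]) * (c[3] - a[3]) - (b[3] - a[3]) * (c[2] - a[2]),
    (b[3] - a[3]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[3] - a[3]),
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  )
  sweep(p, 2, a) %*% nrm
}

# Convex hull of n x 3 points by quickhull; returns list(faces = k x 3 index
# matrix with outward orientation, vertices = unique vertex indices).
.quickhull3d <- function(P, eps) {
  n <- nrow(P)
  # initial extremes: farthest pair among axis extremes
  ext <- unique(c(apply(P, 2, which.min), apply(P, 2, which.max)))
  if (length(ext) < 2) degenerate_error("degenerate point set (no extent)")
  best <- c(ext[1], ext[2]); bd <- -1
  for (i in ext) for (j in ext) {
    d <- sum((P[i, ] - P[j, ])^2)
    if (d > bd) { bd <- d; best <- c(i, j) }
  }
  i1 <- best[1]; i2 <- best[2]
  if (bd <= eps^2) degenerate_error("degenerate point set (all points coincide)")
  # third point: farthest from the line i1-i2
  ab <- P[i2, ] - P[i1, ]
  rel <- sweep(P, 2, P[i1, ])
  cr2 <- (rel[, 2] * ab[3] - rel[, 3] * ab[2])^2 +
    (rel[, 3] * ab[1] - rel[, 1] * ab[3])^2 +
    (rel[, 1] * ab[2] - rel[, 2] * ab[1])^2
  i3 <- which.max(cr2)
  if (sqrt(cr2[i3]) / sqrt(sum(ab^2)) <= eps) {
    degenerate_error("degenerate point set (collinear)")
  }
  # fourth point: farthest from the plane i1-i2-i3
  dists <- .face_dist(P, P[i1, ], P[i2, ], P[i3, ])
  i4 <- which.max(abs(dists))
  if (abs(dists[i4]) <= eps) degenerate_error("degenerate point set (coplanar)")

  faces <- list()       # each: list(v = c(i,j,k) outward-oriented, outside = idx)
  tet <- c(i1, i2, i3, i4)
  centroid <- colMeans(P[tet, , drop = FALSE])
  mk_face <- function(i, j, k, candidates) {
    d_cent <- .face_dist(matrix(centroid, 1), P[i, ], P[j, ], P[k, ])[1]
    if (d_cent > 0) { tmp <- j; j <- k; k <- tmp }  # flip to outward
    d <- .face_dist(P[candidates, , drop = FALSE], P[i, ], P[j, ], P[k, ])
    list(v = c(i, j, k), outside = candidates[d > eps])
  }
  all_idx <- seq_len(n)
  combs <- list(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  for (cm in combs) faces[[length(faces) + 1]] <- mk_face(cm[1], cm[2], cm[3], all_idx)

  repeat {
    fi <- which(vapply(faces, function(f) length(f$outside) > 0, logical(1)))
    if (!length(fi)) break
    fidx <- fi[1]
    f <- faces[[fidx]]
    d <- .face_dist(P[f$outside, , drop = FALSE],
                    P[f$v[1], ], P[f$v[2], ], P[f$v[3], ])
    apex <- f$outside[which.max(d)]
    # visible faces: positive signed distance from apex
    vis <- vapply(faces, function(g) {
      .face_dist(P[apex, , drop = FALSE],
                 P[g$v[1], ], P[g$v[2], ], P[g$v[3], ])[1] > eps
    }, logical(1))
    vis_faces <- faces[vis]
    # horizon: edges of visible faces shared with at most one visible face
    edges <- do.call(rbind, lapply(vis_faces, function(g) {
      rbind(g$v[c(1, 2)], g$v[c(2, 3)], g$v[c(3, 1)])
    }))
    keys <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[keys %in% names(which(table(keys) == 1)), , drop = FALSE]
    pool <- unique(c(unlist(lapply(vis_faces, `[[`, "outside")), apex))
    pool <- setdiff(pool, apex)
    faces <- faces[!vis]
    hull_pts <- unique(unlist(lapply(faces, `[[`, "v")))
    interior <- if (length(hull_pts) >= 1) {
      colMeans(P[unique(c(hull_pts, f$v, apex)), , drop = FALSE])
    } else centroid
    for (e in seq_len(nrow(horizon))) {
      i <- horizon[e, 1]; j <- horizon[e, 2]; k <- apex
      d_int <- .face_dist(matrix(interior, 1), P[i, ], P[j, ], P[k, ])[1]
      if (d_int > 0) { tmp <- i; i <- j; j <- tmp }
      dcand <- if (length(pool)) {
        .face_dist(P[pool, , drop = FALSE], P[i, ], P[j, ], P[k, ])
      } else numeric(0)
      faces[[length(faces) + 1]] <- list(v = c(i, j, k),
                                         outside = pool[dcand > eps])
    }
  }
  fv <- do.call(rbind, lapply(faces, `[[`, "v"))
  list(faces = fv, vertices = sort(unique(as.vector(fv))))
}

# Hull volume as the sum of signed tetrahedra from an interior reference
# point to each outward-oriented face.
.hull_volume_from_faces <- function(P, faces) {
  ref <- colMeans(P[sort(unique(as.vector(faces))), , drop = FALSE])
  vols <- vapply(seq_len(nrow(faces)), function(r) {
    a <- P[faces[r, 1], ] - ref
    b <- P[faces[r, 2], ] - ref
    c_ <- P[faces[r, 3], ] - ref
    (a[1] * (b[2] * c_[3] - b[3] * c_[2]) -
       a[2] * (b[1] * c_[3] - b[3] * c_[1]) +
       a[3] * (b[1] * c_[2] - b[2] * c_[1])) / 6
  }, numeric(1))
  # outward orientation w.r.t. an interior point makes every term >= 0
  sum(abs(vols))
}

# ---------------------------------------------------------------------------
# public surface
# ---------------------------------------------------------------------------

#' Convex-hull volume of an embedded trajectory
#'
#' Computes the volume of the convex hull of the reconstructed attractor.
#' Trajectories embedded in more than 3 dimensions are projected onto their
#' first 3 embedding coordinates (phase spaces are presented and compared in
#' 3D); 2D input yields the hull area and 1D input the range, with
#' `dimension_used` recording which was computed.
#'
#' @param points an [delay_embed()] result or a plain numeric matrix.
#' @param source optional list/character tag (landmark, task, coordinate,
#'   mode) carried through for reporting.
#' @return Object of class `hull_summary`: `volume`, `n_vertices`,
#'   `dimension_used`, `source`.
#' @examples
#' cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
#' convex_hull_volume(cube)$volume
#' @export
convex_hull_volume <- function(points, source = NULL) {
  P <- as_point_matrix(points)
  if (ncol(P) > 3) P <- P[, 1:3, drop = FALSE]
  d <- ncol(P)
  scale <- max(abs(P), 1e-12)
  eps <- 1e-10 * scale
  if (nrow(P) < d + 1) arg_error("need at least dimension + 1 points")
  if (d == 1) {
    vol <- diff(range(P[, 1]))
    if (vol <= 0) degenerate_error("degenerate 1D point set")
    nv <- 2L
  } else if (d == 2) {
    h <- grDevices::chull(P[, 1], P[, 2])
    if (length(h) < 3) degenerate_error("degenerate (collinear) 2D point set")
    xs <- P[h, 1]; ys <- P[h, 2]
    vol <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
    if (vol <= eps^2) degenerate_error("degenerate (collinear) 2D point set")
    nv <- length(h)
  } else {
    hull <- .quickhull3d(P, eps)
    vol <- .hull_volume_from_faces(P, hull$faces)
    nv <- length(hull$vertices)
  }
  structure(
    list(volume = vol, n_vertices = nv, dimension_used = d, source = source),
    class = "hull_summary"
  )
}

#' Percentage difference with the smaller value as denominator
#'
#' `100 * |a - b| / min(a, b)`. This convention (denominator = the smaller
#' of the two) is the one under which per-cell differences between the
#' global- and directional-setting recurrence measures aggregate exactly to
#' the published setting-difference summaries; it is used throughout,
#' including for hull-volume comparisons. Symmetric, nonnegative, zero iff
#' `a == b`.
#'
#' @param a,b positive reals.
#' @return Percentage difference (percent).
#' @examples
#' percentage_difference(8.61, 8.08)
#' @export
percentage_difference <- function(a, b) {
  if (any(c(a, b) <= 0) || any(!is.finite(c(a, b)))) {
    arg_error("percentage_difference requires positive finite inputs")
  }
  100 * abs(a - b) / pmin(a, b)
}
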