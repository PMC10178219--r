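#' Pairwise C-alpha distances over a labeled point set
#'
#' Computes all n(n-1)/2 unique Euclidean distances. When labels are
#' generic residue ids the pair is stored with the canonically smaller id
#' first (helix, BW, GPCRdb order); otherwise plain lexicographic order is
#' used.
#'
#' @param points data frame with a label column (`generic_id` or `label`)
#'   and coordinate columns `x`, `y`, `z`.
#' @return data frame with columns `id_a`, `id_b`, `distance` (Angstrom).
#' @export
pairwise_distances <- function(points) {
  lab <- point_labels(points)
  if (anyDuplicated(lab)) stop("duplicate labels in point set")
  n <- length(lab)
  if (n < 2L) stop("need at least 2 points")
  xyz <- as.matrix(points[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  key <- tryCatch(generic_order_key(lab), error = function(e) lab)
  ord <- order(key)
  lab <- lab[ord]
  xyz <- xyz[ord, , drop = FALSE]
  ij <- utils::combn(n, 2L)
  d <- sqrt(rowSums((xyz[ij[1L, ], , drop = FALSE] -
                     xyz[ij[2L, ], , drop = FALSE])^2))
  data.frame(id_a = lab[ij[1L, ]], id_b = lab[ij[2L, ]], distance = d,
             stringsAsFactors = FALSE)
}

point_labels <- function(points) {
  col <- intersect(c("generic_id", "label", "id"), names(points))
  if (!length(col)) stop("point set needs a 'generic_id' or 'label' column")
  as.character(points[[col[1L]]])
}

#' Count residue pairs connecting different helices
#'
#' @param pairs data frame as returned by [pairwise_distances()], with
#'   generic-id labels.
#' @return integer count of pairs whose two ids lie on different TM helices.
#' @export
count_interhelix_pairs <- function(pairs) {
  ha <- generic_parts(pairs$id_a)$helix
  hb <- generic_parts(pairs$id_b)$helix
  sum(ha != hb)
}

# Rank (affine dimension) check used by the volume and RMSD routines.
coord_rank <- function(xyz, tol = 1e-8) {
  c0 <- sweep(xyz, 2L, colMeans(xyz))
  s <- svd(c0, nu = 0L, nv = 0L)$d
  sum(s > tol * max(s[1L], 1))
}

#' Convex-hull volume of a 3D point set
#'
#' Exact facet-enumeration computation: every supporting plane through three
#' points with all remaining points on one side is a hull facet plane; the
#' coplanar points of each facet are triangulated through their 2D hull and
#' the volume is accumulated as facet-area times centroid-plane distance
#' over three. Handles degenerate facets (four or more coplanar hull
#' vertices, e.g. cube faces) exactly.
#'
#' @param xyz numeric matrix (n x 3), n >= 4.
#' @param tol coplanarity tolerance in Angstrom (rank and side tests).
#' @return volume in cubic Angstrom.
#' @export
convex_hull_volume <- function(xyz, tol = 1e-8) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 4L) stop("degenerate geometry: need at least 4 points")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (coord_rank(xyz, tol) < 3L) {
    stop("degenerate geometry: points are coplanar or collinear")
  }
  n <- nrow(xyz)
  ctr <- colMeans(xyz)
  scale <- max(1, max(abs(sweep(xyz, 2L, ctr))))
  trip <- utils::combn(n, 3L)
  planes <- list()
  seen <- character()
  vol <- 0
  for (k in seq_len(ncol(trip))) {
    i <- trip[1L, k]; j <- trip[2L, k]; l <- trip[3L, k]
    nrm <- cross3(xyz[j, ] - xyz[i, ], xyz[l, ] - xyz[i, ])
    nn <- sqrt(sum(nrm^2))
    if (nn < tol * scale^2) next  # collinear triple
    nrm <- nrm / nn
    d <- drop((xyz %*% nrm) - sum(nrm * xyz[i, ]))
    side_tol <- tol * scale
    if (all(d <= side_tol)) {
      # outward already
    } else if (all(d >= -side_tol)) {
      nrm <- -nrm
      d <- -d
    } else {
      next  # points on both sides: not a supporting plane
    }
    on_plane <- which(abs(d) <= side_tol)
    key <- paste(round(c(nrm, sum(nrm * xyz[i, ])), 6L), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    # triangulate the facet polygon in-plane
    pts <- xyz[on_plane, , drop = FALSE]
    b1 <- pts[2L, ] - pts[1L, ]
    b1 <- b1 / sqrt(sum(b1^2))
    b2 <- cross3(nrm, b1)
    uv <- cbind(drop(sweep(pts, 2L, pts[1L, ]) %*% b1),
                drop(sweep(pts, 2L, pts[1L, ]) %*% b2))
    hull <- grDevices::chull(uv[, 1L], uv[, 2L])
    hu <- uv[hull, , drop = FALSE]
    area <- abs(sum(hu[, 1L] * hu[c(2:nrow(hu), 1L), 2L] -
                    hu[c(2:nrow(hu), 1L), 1L] * hu[, 2L])) / 2
    h <- abs(sum(nrm * (ctr - pts[1L, ])))
    vol <- vol + area * h / 3
  }
  vol
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Pocket volume from a labeled point set
#'
#' The orthosteric pocket volume is the volume enclosed by the C-alpha atoms
#' of the surrogate pocket residues, computed as the Delaunay/convex-hull
#' volume of the point set (the sum of Delaunay simplex volumes of a point
#' set equals its convex-hull volume).
#'
#' @param points data frame with label and `x`,`y`,`z` columns (as from
#'   [resolve_residues()]), or a bare n x 3 coordinate matrix.
#' @return volume in cubic Angstrom (strictly positive).
#' @export
pocket_volume <- function(points) {
  xyz <- if (is.matrix(points)) points
         else as.matrix(points[, c("x", "y", "z")])
  convex_hull_volume(xyz)
}

#' Delaunay tessellation volume (independent route)
#'
#' Brute-force Delaunay tessellation by the empty-circumsphere criterion:
#' every 4-point subset whose circumsphere contains no other input point is
#' a Delaunay simplex; their volumes are summed. Quartic in n — intended for
#' small point sets and as an independent cross-check of
#' [convex_hull_volume()]. Cospherical degeneracies (5+ points on one
#' sphere) are not resolved and may double-count; use the hull route for
#' such inputs.
#'
#' @param xyz numeric matrix (n x 3), n >= 4, points in general position.
#' @param tol relative tolerance of the in-sphere test.
#' @return volume in cubic Angstrom.
#' @export
delaunay_volume <- function(xyz, tol = 1e-9) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (n < 4L) stop("degenerate geometry: need at least 4 points")
  if (coord_rank(xyz) < 3L) {
    stop("degenerate geometry: points are coplanar or collinear")
  }
  quad <- utils::combn(n, 4L)
  vol <- 0
  for (k in seq_len(ncol(quad))) {
    q <- quad[, k]
    p <- xyz[q, , drop = FALSE]
    a <- 2 * (p[2:4, , drop = FALSE] -
              matrix(p[1L, ], 3L, 3L, byrow = TRUE))
    rhs <- rowSums(p[2:4, , drop = FALSE]^2) - sum(p[1L, ]^2)
    det_a <- det(a)
    if (abs(det_a) < 1e-12) next  # coplanar quadruple: no simplex
    ctr <- solve(a, rhs)
    r2 <- sum((p[1L, ] - ctr)^2)
    others <- xyz[-q, , drop = FALSE]
    if (nrow(others)) {
      d2 <- rowSums(sweep(others, 2L, ctr)^2)
      if (any(d2 < r2 * (1 - tol))) next  # circumsphere not empty
    }
    v <- abs(det(rbind(p[2L, ] - p[1L, ], p[3L, ] - p[1L, ],
                       p[4L, ] - p[1L, ]))) / 6
    vol <- vol + v
  }
  vol
}

#' Tetrahedron volume from its six edge lengths
#'
#' Cayley-Menger determinant volume. Edge order follows the vertex
#' convention (d12, d13, d14, d23, d24, d34).
#'
#' @param edges numeric vector of 6 positive lengths (Angstrom).
#' @return volume in cubic Angstrom.
#' @export
tetra_volume_from_edges <- function(edges) {
  if (length(edges) != 6L || any(!is.finite(edges)) || any(edges <= 0)) {
    stop("edges must be 6 positive lengths (d12,d13,d14,d23,d24,d34)")
  }
  e2 <- edges^2
  cm <- matrix(c(
    0,     1,     1,     1,     1,
    1,     0,     e2[1], e2[2], e2[3],
    1,     e2[1], 0,     e2[4], e2[5],
    1,     e2[2], e2[4], 0,     e2[6],
    1,     e2[3], e2[5], e2[6], 0
  ), 5L, 5L, byrow = TRUE)
  disc <- det(cm) / 288
  if (disc <= 0) {
    stop("non-realizable edge set: Cayley-Menger discriminant is not positive")
  }
  sqrt(disc)
}

#' Optimal-superposition RMSD between two labeled point sets
#'
#' Least-squares rigid superposition (Kabsch algorithm; proper rotations
#' only, determinant +1) of the points of `a` onto the points of `b`,
#' matched by label, followed by the root-mean-square deviation.
#'
#' @param a,b data frames with a label column and `x`,`y`,`z` columns; both
#'   must carry the same label set (order may differ).
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(a, b) {
  la <- point_labels(a); lb <- point_labels(b)
  if (anyDuplicated(la) || anyDuplicated(lb)) stop("duplicate labels")
  if (length(la) != length(lb) || !setequal(la, lb)) {
    stop("label mismatch between point sets")
  }
  A <- as.matrix(a[, c("x", "y", "z")])
  B <- as.matrix(b[match(la, lb), c("x", "y", "z")])
  if (nrow(A) < 3L) stop("need at least 3 points for superposition")
  if (coord_rank(A) < 2L || coord_rank(B) < 2L) {
    stop("degenerate geometry: collinear point set")
  }
  Ac <- sweep(A, 2L, colMeans(A))
  Bc <- sweep(B, 2L, colMeans(B))
  s <- svd(crossprod(Ac, Bc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Ar <- Ac %*% t(R)
  sqrt(mean(rowSums((Ar - Bc)^2)))
}
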