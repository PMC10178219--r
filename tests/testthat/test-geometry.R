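test_that("pairwise distances: counts, 3-4-5 triangle, and norm oracle", {
  pts <- data.frame(label = c("a", "b"), x = c(0, 3), y = c(0, 4), z = 0)
  pd <- pairwise_distances(pts)
  expect_equal(pd$distance, 5)

  pts <- random_labeled_points(10, seed = 21)
  pd <- pairwise_distances(pts)
  expect_equal(nrow(pd), 45L)
  # direct norm oracle
  for (r in seq_len(nrow(pd))) {
    a <- pts[pts$label == pd$id_a[r], c("x", "y", "z")]
    b <- pts[pts$label == pd$id_b[r], c("x", "y", "z")]
    expect_equal(pd$distance[r], sqrt(sum((a - b)^2)))
  }
  expect_error(pairwise_distances(pts[1, , drop = FALSE]), "at least 2")
  dup <- pts; dup$label[2] <- dup$label[1]
  expect_error(pairwise_distances(dup), "duplicate")
})

test_that("inter-helix pair counting matches brute-force enumeration", {
  ids <- c("2.57x56", "2.60x59", "3.28x28", "3.37x37")
  pts <- data.frame(generic_id = ids, x = rnorm(4), y = rnorm(4), z = rnorm(4))
  pd <- pairwise_distances(pts)
  expect_equal(nrow(pd), 6L)
  expect_equal(count_interhelix_pairs(pd), 4L)

  one <- data.frame(generic_id = c("5.38x39", "5.46x461", "5.47x47"),
                    x = 1:3, y = 0, z = 0)
  expect_equal(count_interhelix_pairs(pairwise_distances(one)), 0L)

  set.seed(8)
  ids <- sprintf("%d.%02dx%02d", sample(1:7, 20, TRUE), 10:29, 10:29)
  pts <- data.frame(generic_id = ids, x = rnorm(20), y = rnorm(20),
                    z = rnorm(20))
  pd <- pairwise_distances(pts)
  helix <- as.integer(substr(ids, 1, 1))
  brute <- 0L
  for (i in 1:19) for (j in (i + 1):20) {
    if (helix[i] != helix[j]) brute <- brute + 1L
  }
  expect_equal(count_interhelix_pairs(pd), brute)
})

test_that("convex hull volume is exact on closed-form solids", {
  # unit cube plus centroid and a face center: hull is the unit cube
  cube <- rbind(as.matrix(expand.grid(0:1, 0:1, 0:1)),
                c(0.5, 0.5, 0.5), c(0.5, 0.5, 0))
  expect_equal(convex_hull_volume(cube), 1, tolerance = 1e-12)

  a <- 2.5  # regular tetrahedron, edge a: V = a^3 / (6 sqrt(2))
  tet <- rbind(c(0, 0, 0), c(a, 0, 0), c(a / 2, a * sqrt(3) / 2, 0),
               c(a / 2, a / (2 * sqrt(3)), a * sqrt(2 / 3)))
  expect_equal(convex_hull_volume(tet), a^3 / (6 * sqrt(2)),
               tolerance = 1e-12)
})

test_that("degenerate point sets raise rather than returning a volume", {
  expect_error(convex_hull_volume(matrix(rnorm(9), 3, 3)), "at least 4")
  flat <- cbind(matrix(rnorm(20), 10, 2), 0)
  expect_error(convex_hull_volume(flat), "coplanar|collinear")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(convex_hull_volume(line), "coplanar|collinear")
})

test_that("hull volume matches a Monte-Carlo membership oracle", {
  pts <- as.matrix(random_labeled_points(10, seed = 31)[, c("x", "y", "z")])
  v <- convex_hull_volume(pts)
  v_mc <- mc_hull_volume(pts, n_samples = 2e5, seed = 99)
  expect_lt(abs(v - v_mc) / v, 0.01)
})

test_that("Delaunay simplex-sum volume equals the convex-hull volume", {
  for (seed in 1:20) {
    pts <- as.matrix(random_labeled_points(10, seed = seed)[, c("x", "y", "z")])
    expect_equal(delaunay_volume(pts), convex_hull_volume(pts),
                 tolerance = 1e-9)
  }
})

test_that("pocket volume is rigid-motion invariant and scales cubically", {
  pts <- random_labeled_points(10, seed = 41)
  v <- pocket_volume(pts)
  moved <- apply_rigid(pts, random_rigid_motion(seed = 42))
  expect_equal(pocket_volume(moved), v, tolerance = 1e-9)
  for (s in c(0.7, 1.3, 2.0)) {
    scaled <- pts
    scaled[, c("x", "y", "z")] <- scaled[, c("x", "y", "z")] * s
    expect_equal(pocket_volume(scaled), v * s^3, tolerance = 1e-9)
  }
})

test_that("Cayley-Menger volume: closed form, non-realizable edges, coordinate oracle", {
  expect_equal(tetra_volume_from_edges(rep(1, 6)), 1 / (6 * sqrt(2)),
               tolerance = 1e-12)
  expect_error(tetra_volume_from_edges(c(1, 1, 1, 1, 1, 10)),
               "non-realizable")
  expect_error(tetra_volume_from_edges(rep(1, 5)), "6 positive")

  for (seed in 1:25) {
    set.seed(seed)
    p <- matrix(rnorm(12) * 6, 4, 3)
    d <- function(i, j) sqrt(sum((p[i, ] - p[j, ])^2))
    edges <- c(d(1, 2), d(1, 3), d(1, 4), d(2, 3), d(2, 4), d(3, 4))
    v_det <- abs(det(rbind(p[2, ] - p[1, ], p[3, ] - p[1, ],
                           p[4, ] - p[1, ]))) / 6
    expect_equal(tetra_volume_from_edges(edges), v_det, tolerance = 1e-9)
  }
})

test_that("tetrahedron-2 reference edges embed consistently with coordinates", {
  # embed the 6 reference medians of tetrahedron 2 as coordinates, then
  # confirm the determinant volume of the embedding equals the
  # Cayley-Menger volume of the edges
  ref <- reference_edge_medians()
  edges <- ref$median[ref$tetra == 2]
  v_cm <- tetra_volume_from_edges(edges)
  # coordinate embedding: v1 at origin, v2 on x, v3 in xy-plane
  d12 <- edges[1]; d13 <- edges[2]; d14 <- edges[3]
  d23 <- edges[4]; d24 <- edges[5]; d34 <- edges[6]
  p1 <- c(0, 0, 0); p2 <- c(d12, 0, 0)
  x3 <- (d12^2 + d13^2 - d23^2) / (2 * d12)
  y3 <- sqrt(d13^2 - x3^2)
  p3 <- c(x3, y3, 0)
  x4 <- (d12^2 + d14^2 - d24^2) / (2 * d12)
  y4 <- (d13^2 + d14^2 - d34^2 - 2 * x3 * x4) / (2 * y3)
  z4 <- sqrt(d14^2 - x4^2 - y4^2)
  p4 <- c(x4, y4, z4)
  v_embed <- abs(det(rbind(p2 - p1, p3 - p1, p4 - p1))) / 6
  expect_equal(v_cm, v_embed, tolerance = 1e-9)
})

test_that("superposition RMSD: identity, rigid invariance, symmetry, perturbation", {
  pts <- random_labeled_points(10, seed = 51)
  expect_equal(superpose_rmsd(pts, pts), 0)
  moved <- apply_rigid(pts, random_rigid_motion(seed = 52))
  expect_lt(superpose_rmsd(pts, moved), 1e-9)
  # shuffled row order must not matter (matched by label)
  expect_lt(superpose_rmsd(pts, moved[sample(nrow(moved)), ]), 1e-9)

  pert <- moved
  pert$x[1] <- pert$x[1] + 1.5
  r1 <- superpose_rmsd(pts, pert)
  expect_gt(r1, 0)
  expect_equal(superpose_rmsd(pert, pts), r1, tolerance = 1e-9)

  bad <- pts; bad$label[1] <- "zz"
  expect_error(superpose_rmsd(pts, bad), "label mismatch")
})

test_that("superposition RMSD matches independent oracles", {
  pts <- random_labeled_points(8, seed = 61)
  pert <- apply_rigid(pts, random_rigid_motion(seed = 62))
  set.seed(63)
  pert[, c("x", "y", "z")] <- pert[, c("x", "y", "z")] +
    matrix(rnorm(24, 0, 0.8), 8, 3)
  r_pkg <- superpose_rmsd(pts, pert)

  # independent library oracle
  a <- as.vector(t(as.matrix(pts[, c("x", "y", "z")])))
  b <- as.vector(t(as.matrix(pert[, c("x", "y", "z")])))
  r_bio3d <- bio3d::rmsd(a, b, fit = TRUE)  # bio3d rounds to 3 decimals
  expect_lt(abs(r_pkg - r_bio3d), 1e-3)

  # numerical-minimization oracle over rotation angles + translation
  A <- as.matrix(pts[, c("x", "y", "z")])
  B <- as.matrix(pert[, c("x", "y", "z")])
  obj <- function(par) {
    cx <- cos(par[1]); sx <- sin(par[1])
    cy <- cos(par[2]); sy <- sin(par[2])
    cz <- cos(par[3]); sz <- sin(par[3])
    R <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx)) %*%
         rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy)) %*%
         rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    Ar <- sweep(A %*% t(R), 2, par[4:6], `+`)
    sqrt(mean(rowSums((Ar - B)^2)))
  }
  best <- Inf
  for (s in 1:8) {
    set.seed(s)
    o <- stats::optim(c(runif(3, -pi, pi), rnorm(3, 0, 5)), obj,
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  expect_equal(r_pkg, best, tolerance = 1e-4)
})
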