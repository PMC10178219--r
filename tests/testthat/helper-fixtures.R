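# Shared fixture builders. All synthetic; deterministic under the given seed.

# Minimal hand-written three-residue PDB (plus optional water) for parser
# unit tests.
three_residue_pdb <- function(with_water = FALSE) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  CA  GLY A   2       3.800   1.500   0.500  1.00  0.00           C",
    "ATOM      5  CA  SER A   3       6.100   3.200   1.200  1.00  0.00           C"
  )
  if (with_water) {
    lines <- c(lines,
      "HETATM    6  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O")
  }
  paste(c(lines, "END"), collapse = "\n")
}

# Independent Monte-Carlo hull-volume oracle: half-spaces enumerated directly
# in the test (all-triples supporting-plane test), membership by half-space
# satisfaction, volume by rejection sampling in the bounding box.
mc_hull_volume <- function(xyz, n_samples = 2e5, seed = 99) {
  set.seed(seed)
  n <- nrow(xyz)
  planes <- list()
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    v1 <- xyz[j, ] - xyz[i, ]
    v2 <- xyz[k, ] - xyz[i, ]
    nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
             v1[3] * v2[1] - v1[1] * v2[3],
             v1[1] * v2[2] - v1[2] * v2[1])
    if (sqrt(sum(nrm^2)) < 1e-10) next
    d <- drop(xyz %*% nrm) - sum(nrm * xyz[i, ])
    if (all(d <= 1e-9)) {
      planes[[length(planes) + 1]] <- c(nrm, sum(nrm * xyz[i, ]))
    } else if (all(d >= -1e-9)) {
      planes[[length(planes) + 1]] <- c(-nrm, -sum(nrm * xyz[i, ]))
    }
  }
  P <- do.call(rbind, planes)
  lo <- apply(xyz, 2, min); hi <- apply(xyz, 2, max)
  pts <- cbind(runif(n_samples, lo[1], hi[1]),
               runif(n_samples, lo[2], hi[2]),
               runif(n_samples, lo[3], hi[3]))
  inside <- rep(TRUE, n_samples)
  for (r in seq_len(nrow(P))) {
    inside <- inside & (drop(pts %*% P[r, 1:3]) <= P[r, 4] + 1e-9)
  }
  prod(hi - lo) * mean(inside)
}

# The worked ADRB1 tetrahedron constraint example: pose pairs and reference
# distances (A = 3, B = 0.7, D = -8).
adrb1_example_edges <- function() {
  data.frame(
    pose_i = c(66, 66, 66, 98, 98, 176),
    pose_j = c(98, 176, 308, 176, 308, 308),
    A = 3, B = 0.7,
    C = c(23.7864, 25.6431, 19.5077, 19.0209, 26.8934, 22.3116),
    D = -8
  )
}

adrb1_example_lines <- function() {
  c("AtomPair CA 66 CA 98 SCALARWEIGHTEDFUNC 3 SUMFUNC 2 HARMONIC 23.7864 0.7 CONSTANTFUNC -8",
    "AtomPair CA 66 CA 176 SCALARWEIGHTEDFUNC 3 SUMFUNC 2 HARMONIC 25.6431 0.7 CONSTANTFUNC -8",
    "AtomPair CA 66 CA 308 SCALARWEIGHTEDFUNC 3 SUMFUNC 2 HARMONIC 19.5077 0.7 CONSTANTFUNC -8",
    "AtomPair CA 98 CA 176 SCALARWEIGHTEDFUNC 3 SUMFUNC 2 HARMONIC 19.0209 0.7 CONSTANTFUNC -8",
    "AtomPair CA 98 CA 308 SCALARWEIGHTEDFUNC 3 SUMFUNC 2 HARMONIC 26.8934 0.7 CONSTANTFUNC -8",
    "AtomPair CA 176 CA 308 SCALARWEIGHTEDFUNC 3 SUMFUNC 2 HARMONIC 22.3116 0.7 CONSTANTFUNC -8")
}

# Typeset-damaged spelling of the same example (collapsed spacing), as it
# appears in print reproductions of such files.
adrb1_damaged_lines <- function() {
  gsub("CA (\\d+) CA (\\d+)", "CA\\1 CA \\2",
       gsub("SUMFUNC 2 HARMONIC", "SUMFUNC2HARMONIC",
            gsub("CONSTANTFUNC -8", "CONSTANTFUNC-8",
                 adrb1_example_lines())))
}

random_labeled_points <- function(n, seed, scale = 8) {
  set.seed(seed)
  data.frame(label = sprintf("p%02d", seq_len(n)),
             x = rnorm(n) * scale, y = rnorm(n) * scale, z = rnorm(n) * scale,
             stringsAsFactors = FALSE)
}

random_rigid_motion <- function(seed) {
  set.seed(seed)
  ang <- runif(3, -pi, pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0),
              c(-sin(ang[2]), 0, cos(ang[2])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
              c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  list(R = Rx %*% Ry %*% Rz, t = runif(3, -20, 20))
}

apply_rigid <- function(points, motion) {
  xyz <- as.matrix(points[, c("x", "y", "z")]) %*% t(motion$R)
  xyz <- sweep(xyz, 2, motion$t, `+`)
  out <- points
  out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
  out
}
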