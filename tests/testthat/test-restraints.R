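test_that("parameter sampling is seeded-deterministic and respects all ranges", {
  set.seed(17)
  p1 <- sample_params()
  set.seed(17)
  p2 <- sample_params()
  expect_identical(p1, p2)

  set.seed(101)
  draws <- replicate(1000, sample_params(), simplify = FALSE)
  A <- vapply(draws, `[[`, 1, "A")
  B <- vapply(draws, `[[`, 1, "B")
  s <- vapply(draws, `[[`, 1, "s")
  D <- vapply(draws, `[[`, 1, "D")
  expect_true(all(A %in% 2:4))
  expect_true(all(B >= 0.4 & B <= 0.8))
  expect_true(all(abs(B * 10 - round(B * 10)) < 1e-9))  # 0.1 grid
  expect_true(all(s >= 1.03 & s <= 1.07))
  expect_true(all(D %in% -10:-1))
  # empirical mean of s near the range center
  expect_gt(mean(s), 1.045)
  expect_lt(mean(s), 1.055)
  # range endpoints attainable for the discrete parameters
  expect_setequal(unique(A), 2:4)
  expect_setequal(unique(D), -10:-1)
})

test_that("restraint potential has minimum A*D at d == C and is even around C", {
  p <- list(A = 3, B = 0.7, s = 1.05, D = -8)
  expect_equal(restraint_score(23.7864, p, 23.7864), -24)
  expect_equal(restraint_score(23.7864 + 0.7, p, 23.7864), 3 * (1 - 8))
  set.seed(5)
  for (delta in runif(10, 0, 5)) {
    expect_equal(restraint_score(20 + delta, p, 20),
                 restraint_score(20 - delta, p, 20), tolerance = 1e-12)
    expect_gte(restraint_score(20 + delta, p, 20),
               restraint_score(20, p, 20))
  }
  expect_error(restraint_score(10, list(A = 3, B = 0, D = -8), 10), "B")
  expect_error(restraint_score(-1, p, 10), ">= 0")
  expect_error(restraint_score(1, p, 0), "C")
})

test_that("knowledge-base mode with unit scale reproduces the reference medians", {
  b <- make_bundle()
  rset <- build_restraint_set(b$map, b$model, seed = 1, fixed_s = 1.0)
  ref <- reference_edge_medians()
  expect_equal(rset$tetra1$edges$C, ref$median[ref$tetra == 1])
  expect_equal(rset$tetra2$edges$C, ref$median[ref$tetra == 2])
  # the (4.57x57, 5.46x461) edge carries the short inter-helix median
  e4 <- rset$tetra2$edges[4, ]
  expect_equal(c(e4$id_a, e4$id_b), c("4.57x57", "5.46x461"))
  expect_equal(e4$C, 10.76)
})

test_that("template mode sets C to scale times the measured distance", {
  b <- make_bundle()
  rset <- build_restraint_set(b$map, b$model, mode = "template",
                              seed = 2, fixed_s = 1.05)
  for (t in c("tetra1", "tetra2")) {
    res <- resolve_residues(b$map, b$model, rset[[t]]$vertex_ids)
    eij <- cbind(c(1, 1, 1, 2, 2, 3), c(2, 3, 4, 3, 4, 4))
    d <- vapply(seq_len(6), function(k) {
      sqrt(sum((unlist(res[eij[k, 1], c("x", "y", "z")]) -
                unlist(res[eij[k, 2], c("x", "y", "z")]))^2))
    }, 1)
    expect_equal(rset[[t]]$edges$C, 1.05 * d, tolerance = 1e-12)
  }
})

test_that("restraint building is deterministic under a seed and C/d_ref stays in range", {
  b <- make_bundle()
  r1 <- build_restraint_set(b$map, b$model, seed = 42)
  r2 <- build_restraint_set(b$map, b$model, seed = 42)
  expect_identical(write_constraint_file(r1), write_constraint_file(r2))
  expect_identical(r1$tetra1$params, r2$tetra1$params)
  for (seed in 1:20) {
    r <- build_restraint_set(b$map, b$model, seed = seed)
    for (t in c("tetra1", "tetra2")) {
      ratio <- r[[t]]$edges$C / r[[t]]$edges$d_ref
      expect_true(all(ratio >= 1.03 & ratio <= 1.07))
      # six edges of a tetrahedron share one parameter set
      expect_length(unique(r[[t]]$edges$C / r[[t]]$edges$d_ref), 1L)
    }
  }
})

test_that("missing vertices and missing reference distances are reported by name", {
  b <- make_bundle()
  map2 <- b$map[b$map$generic_id != "3.40x40", ]
  class(map2) <- class(b$map)
  expect_error(build_restraint_set(map2, b$model), "3.40x40")
  ref <- reference_edge_medians()
  expect_error(
    build_restraint_set(b$map, b$model, ref = ref[-1, ], seed = 1),
    "no reference distance"
  )
})

test_that("constraint files are written in the exact dialect", {
  txt <- write_constraint_file(adrb1_example_edges())
  expect_identical(txt, paste0(paste(adrb1_example_lines(),
                                     collapse = "\n"), "\n"))
  b <- make_bundle()
  rset <- build_restraint_set(b$map, b$model, seed = 9)
  lines <- strsplit(write_constraint_file(rset), "\n")[[1]]
  expect_length(lines, 12L)
  expect_true(all(grepl(
    "^AtomPair CA \\d+ CA \\d+ SCALARWEIGHTEDFUNC \\d SUMFUNC 2 HARMONIC \\d+\\.\\d{4} \\d\\.\\d CONSTANTFUNC -\\d+$",
    lines)))
})

test_that("parsing tolerates typeset-collapsed spacing and rejects unknown functions", {
  parsed <- parse_constraint_file(paste(adrb1_damaged_lines(),
                                        collapse = "\n"))
  expect_equal(nrow(parsed), 6L)
  expect_true(all(parsed$A == 3))
  expect_true(all(parsed$B == 0.7))
  expect_true(all(parsed$D == -8))
  expect_equal(parsed$C, adrb1_example_edges()$C)
  expect_equal(parsed$pose_i, adrb1_example_edges()$pose_i)

  expect_equal(nrow(parse_constraint_file("")), 0L)
  bad <- sub("HARMONIC", "HARMONIQUE", adrb1_example_lines()[3])
  expect_error(
    parse_constraint_file(paste(c(adrb1_example_lines()[1:2], bad),
                                collapse = "\n")),
    "line 3"
  )
})

test_that("write -> parse -> write is a fixed point", {
  b <- make_bundle()
  for (seed in c(1, 7, 23)) {
    rset <- build_restraint_set(b$map, b$model, seed = seed)
    t1 <- write_constraint_file(rset)
    t2 <- write_constraint_file(parse_constraint_file(t1))
    expect_identical(t2, t1)
  }
})

test_that("scoring a restraint set sums twelve per-edge scores", {
  b <- make_bundle()
  # template mode with s = 1: the model sits exactly at every reference
  rset <- build_restraint_set(b$map, b$model, mode = "template",
                              seed = 3, fixed_s = 1.0)
  sc <- score_restraint_set(b$model, rset)
  p1 <- rset$tetra1$params; p2 <- rset$tetra2$params
  expect_equal(sc$total, 6 * p1$A * p1$D + 6 * p2$A * p2$D,
               tolerance = 1e-9)
  expect_equal(nrow(sc$breakdown), 12L)
  # independent per-edge recomputation on a perturbed model
  m2 <- scale_pocket(b$model, 1.02)
  sc2 <- score_restraint_set(m2, rset)
  manual <- 0
  for (ti in 1:2) {
    t <- rset[[paste0("tetra", ti)]]
    for (k in 1:6) {
      xi <- m2$residues[m2$residues$pose == t$edges$pose_i[k],
                        c("x", "y", "z")]
      xj <- m2$residues[m2$residues$pose == t$edges$pose_j[k],
                        c("x", "y", "z")]
      d <- sqrt(sum((xi - xj)^2))
      manual <- manual +
        t$params$A * (((d - t$edges$C[k]) / t$params$B)^2 + t$params$D)
    }
  }
  expect_equal(sc2$total, manual, tolerance = 1e-9)
})

test_that("restraint manifests record seed, parameters and vertices", {
  b <- make_bundle()
  rset <- build_restraint_set(b$map, b$model, seed = 77)
  f <- withr::local_tempfile(fileext = ".json")
  restraint_manifest(rset, f)
  man <- jsonlite::read_json(f)
  expect_equal(man$seed, 77L)
  expect_length(man$tetra, 2L)
  expect_equal(unlist(man$tetra[[1]]$vertex_ids),
               rset$tetra1$vertex_ids)
  expect_equal(man$tetra[[2]]$params$A, rset$tetra2$params$A)
})
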