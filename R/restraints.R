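#' Reference edge medians of the two pocket tetrahedrons
#'
#' Median C-alpha distances of the twelve tetrahedron edges over the
#' knowledge base of inactive class A GPCR structures. These ship with the
#' package as the default reference distances for knowledge-base restraint
#' generation; they are a curated census statistic, not recomputable from
#' bundled inputs.
#'
#' @return data frame `tetra`, `id_a`, `id_b`, `median` (Angstrom), edges
#'   ordered (v1v2, v1v3, v1v4, v2v3, v2v4, v3v4) within each tetrahedron.
#' @export
reference_edge_medians <- function() {
  df <- data.frame(
    tetra = rep(1:2, each = 6L),
    id_a = c("2.60x59", "2.60x59", "2.60x59", "3.40x40", "3.40x40", "5.38x39",
             "2.65x64", "2.65x64", "2.65x64", "4.57x57", "4.57x57", "5.46x461"),
    id_b = c("3.40x40", "5.38x39", "7.32x31", "5.38x39", "7.32x31", "7.32x31",
             "4.57x57", "5.46x461", "6.48x48", "5.46x461", "6.48x48", "6.48x48"),
    median = c(22.50, 24.25, 18.78, 17.94, 25.35, 20.30,
               23.08, 25.35, 19.92, 10.76, 17.34, 11.23),
    stringsAsFactors = FALSE
  )
  df
}

#' Sample a restraint parameter set
#'
#' Draws one parameter set from the calibrated ranges: weight `A` uniform on
#' \{2, 3, 4\}; harmonic steepness `B` uniform on \[0.4, 0.8\] on a 0.1
#' grid; reference-distance scale `s` uniform on \[1.03, 1.07\] (the
#' reference distance is inflated 3-7% over the measured C-alpha distance,
#' which counteracts pocket shrinkage); constant offset `D` uniform on the
#' integers -10..-1. Continuous sampling of `B` is available via
#' `grid = FALSE`. Uses R's global RNG: seed with [set.seed()] for
#' reproducibility.
#'
#' @param grid sample `B` on the 0.1 grid (default) or continuously.
#' @return a `restraint_params` list with elements `A`, `B`, `s`, `D`.
#' @export
sample_params <- function(grid = TRUE) {
  A <- sample(2:4, 1L)
  B <- if (grid) round(stats::runif(1L, 0.4, 0.8), 1L)
       else stats::runif(1L, 0.4, 0.8)
  s <- stats::runif(1L, 1.03, 1.07)
  D <- sample(-10:-1, 1L)
  structure(list(A = A, B = B, s = s, D = D), class = "restraint_params")
}

#' @export
print.restraint_params <- function(x, ...) {
  cat(sprintf("<restraint_params> A=%d B=%.1f s=%.4f D=%d\n",
              x$A, x$B, x$s, x$D))
  invisible(x)
}

#' Evaluate the tetrahedral distance-restraint potential
#'
#' The scalar-weighted harmonic-plus-constant potential applied to one
#' restrained atom pair:
#' \deqn{f(d) = A \left( \left(\frac{d - C}{B}\right)^2 + D \right)}
#' with measured distance `d`, reference distance `C`, weight `A`,
#' steepness `B` and offset `D`. The minimum value `A * D` (negative for
#' all sampled parameter sets) is attained at `d == C`.
#'
#' @param d measured distance(s), Angstrom.
#' @param params a `restraint_params` list (fields `A`, `B`, `D`).
#' @param C reference distance, Angstrom (> 0).
#' @return score value(s).
#' @export
restraint_score <- function(d, params, C) {
  if (any(d < 0)) stop("measured distance must be >= 0")
  if (C <= 0) stop("reference distance C must be > 0")
  if (params$B <= 0) stop("steepness B must be > 0")
  params$A * (((d - C) / params$B)^2 + params$D)
}

#' Build a two-tetrahedron restraint set
#'
#' Resolves the eight tetrahedron vertex positions to pose numbers, samples
#' one parameter set per tetrahedron (the six edges of a tetrahedron share
#' parameters; the two tetrahedrons may differ), and sets each edge's
#' reference distance `C = s * d_ref`. In `"knowledge-base"` mode `d_ref`
#' is the bundled (or supplied) census median for the edge; in `"template"`
#' mode it is the C-alpha distance measured in the supplied structure.
#'
#' @param map a `residue_map`.
#' @param model a `structure_model`.
#' @param pocket pocket definition (default [default_pocket_definition()]).
#' @param mode `"knowledge-base"` or `"template"`.
#' @param ref optional reference-distance table (columns `id_a`, `id_b`,
#'   `median`) overriding the bundled medians in knowledge-base mode.
#' @param seed optional integer seed applied before parameter sampling;
#'   recorded on the returned set.
#' @param fixed_s testing override: use this scale for every edge instead
#'   of the sampled `s`.
#' @param fixed_params testing override: list of two `restraint_params`
#'   used instead of sampling.
#' @return a `restraint_set`: list with `tetra1`, `tetra2` (each holding
#'   `vertex_ids`, `vertex_pose`, `edges` data frame `id_a`, `id_b`,
#'   `pose_i`, `pose_j`, `d_ref`, `C`, and `params`) and `seed`.
#' @export
build_restraint_set <- function(map, model,
                                pocket = default_pocket_definition(),
                                mode = c("knowledge-base", "template"),
                                ref = NULL, seed = NULL,
                                fixed_s = NULL, fixed_params = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ref)) ref <- reference_edge_medians()
  tetra_one <- function(ids, params) {
    res <- resolve_residues(map, model, ids)
    eij <- cbind(c(1L, 1L, 1L, 2L, 2L, 3L), c(2L, 3L, 4L, 3L, 4L, 4L))
    d_ref <- numeric(6L)
    for (k in seq_len(6L)) {
      i <- eij[k, 1L]; j <- eij[k, 2L]
      if (mode == "template") {
        d_ref[k] <- sqrt(sum((unlist(res[i, c("x", "y", "z")]) -
                              unlist(res[j, c("x", "y", "z")]))^2))
      } else {
        a <- res$generic_id[i]; b <- res$generic_id[j]
        hitf <- which(ref$id_a == a & ref$id_b == b)
        hitr <- which(ref$id_a == b & ref$id_b == a)
        hit <- c(hitf, hitr)
        if (!length(hit)) {
          stop("no reference distance for edge (", a, ", ", b, ")")
        }
        d_ref[k] <- ref$median[hit[1L]]
      }
    }
    s_use <- if (!is.null(fixed_s)) fixed_s else params$s
    list(
      vertex_ids = res$generic_id,
      vertex_pose = res$pose,
      edges = data.frame(
        id_a = res$generic_id[eij[, 1L]], id_b = res$generic_id[eij[, 2L]],
        pose_i = res$pose[eij[, 1L]], pose_j = res$pose[eij[, 2L]],
        d_ref = d_ref, C = s_use * d_ref,
        stringsAsFactors = FALSE
      ),
      params = params
    )
  }
  p1 <- if (!is.null(fixed_params)) fixed_params[[1L]] else sample_params()
  p2 <- if (!is.null(fixed_params)) fixed_params[[2L]] else sample_params()
  structure(
    list(tetra1 = tetra_one(pocket$tetra1, p1),
         tetra2 = tetra_one(pocket$tetra2, p2),
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "restraint_set"
  )
}

#' @export
print.restraint_set <- function(x, ...) {
  cat("<restraint_set> seed =", x$seed, "\n")
  for (t in c("tetra1", "tetra2")) {
    p <- x[[t]]$params
    cat(sprintf("  %s: %s | A=%d B=%.1f s=%.4f D=%d\n", t,
                paste(x[[t]]$vertex_ids, collapse = " "),
                p$A, p$B, p$s, p$D))
  }
  invisible(x)
}

#' Score a structure against a restraint set
#'
#' Sums the restraint potential over the twelve edges, measuring each
#' restrained C-alpha distance in the model.
#'
#' @param model a `structure_model`.
#' @param rset a `restraint_set`.
#' @return list with `total` and `breakdown` (data frame `tetra`, `pose_i`,
#'   `pose_j`, `C`, `d`, `score`).
#' @export
score_restraint_set <- function(model, rset) {
  rows <- list()
  for (ti in 1:2) {
    t <- rset[[paste0("tetra", ti)]]
    xi <- ca_coords(model, t$edges$pose_i)
    xj <- ca_coords(model, t$edges$pose_j)
    d <- sqrt(rowSums((xi - xj)^2))
    sc <- vapply(seq_len(6L), function(k) {
      restraint_score(d[k], t$params, t$edges$C[k])
    }, 1)
    rows[[ti]] <- data.frame(tetra = ti, pose_i = t$edges$pose_i,
                             pose_j = t$edges$pose_j, C = t$edges$C,
                             d = d, score = sc)
  }
  breakdown <- do.call(rbind, rows)
  list(total = sum(breakdown$score), breakdown = breakdown)
}

constraint_lines <- function(edges) {
  sprintf(paste("AtomPair CA %d CA %d SCALARWEIGHTEDFUNC %d SUMFUNC 2",
                "HARMONIC %.4f %.1f CONSTANTFUNC %d"),
          edges$pose_i, edges$pose_j, edges$A, edges$C, edges$B, edges$D)
}

#' Write a Rosetta constraint file
#'
#' Emits the AtomPair constraint dialect, one line per restrained edge:
#' `AtomPair CA <i> CA <j> SCALARWEIGHTEDFUNC <A> SUMFUNC 2 HARMONIC <C>
#' <B> CONSTANTFUNC <D>` with single spaces, `C` printed to 4 decimals,
#' `B` to 1 decimal, `A` and `D` as integers, and a trailing newline.
#' The HARMONIC arguments follow standard Rosetta function syntax: center
#' `C` first, then steepness `B`. For a `restraint_set` the six tetra-1
#' edges precede the six tetra-2 edges.
#'
#' @param x a `restraint_set`, or an edge data frame with columns
#'   `pose_i`, `pose_j`, `A`, `B`, `C`, `D` (as from
#'   [parse_constraint_file()]).
#' @param path optional output file.
#' @return the constraint text (single string); invisibly when `path`
#'   is given.
#' @export
write_constraint_file <- function(x, path = NULL) {
  edges <- if (inherits(x, "restraint_set")) {
    do.call(rbind, lapply(1:2, function(ti) {
      t <- x[[paste0("tetra", ti)]]
      data.frame(pose_i = t$edges$pose_i, pose_j = t$edges$pose_j,
                 A = t$params$A, B = t$params$B, C = t$edges$C,
                 D = t$params$D)
    }))
  } else {
    x
  }
  txt <- paste0(paste(constraint_lines(edges), collapse = "\n"), "\n")
  if (!is.null(path)) {
    cat(txt, file = path)
    return(invisible(txt))
  }
  txt
}

#' Parse a Rosetta constraint file (AtomPair harmonic dialect)
#'
#' Recovers pose pairs and (A, B, C, D) per line. Tolerates collapsed
#' spacing around tokens (`CA66`, `SUMFUNC2HARMONIC`, `CONSTANTFUNC-8`),
#' which appears in typeset copies of such files; normalized single-space
#' output is always emitted by [write_constraint_file()]. Any other
#' function name or malformed line is an error reporting the line number.
#'
#' @param x path to a constraint file, or its text.
#' @return data frame `pose_i`, `pose_j`, `A`, `B`, `C`, `D`, one row per
#'   constraint line (zero rows for empty input).
#' @export
parse_constraint_file <- function(x) {
  lines <- read_text_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  rx <- paste0("^\\s*AtomPair\\s+CA\\s*([0-9]+)\\s+CA\\s*([0-9]+)\\s+",
               "SCALARWEIGHTEDFUNC\\s*(-?[0-9.]+)\\s+SUMFUNC\\s*2\\s*",
               "HARMONIC\\s+(-?[0-9.]+)\\s+(-?[0-9.]+)\\s+",
               "CONSTANTFUNC\\s*(-?[0-9.]+)\\s*$")
  out <- data.frame(pose_i = integer(), pose_j = integer(), A = numeric(),
                    B = numeric(), C = numeric(), D = numeric())
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec(rx, lines[i]))[[1L]]
    if (length(m) != 7L) {
      stop("malformed constraint line ", i, ": ", sQuote(trimws(lines[i])))
    }
    v <- as.numeric(m[-1L])
    out[nrow(out) + 1L, ] <- list(as.integer(v[1L]), as.integer(v[2L]),
                                  v[3L], v[5L], v[4L], v[6L])
  }
  out
}

#' Restraint-set manifest
#'
#' JSON-serializable record of a restraint set: seed, per-tetrahedron
#' parameters, vertex generic ids and resolved pose numbers.
#'
#' @param rset a `restraint_set`.
#' @param path optional path; when given the manifest is written as JSON.
#' @return the manifest list, invisibly when `path` is given.
#' @export
restraint_manifest <- function(rset, path = NULL) {
  man <- list(
    seed = rset$seed,
    tetra = lapply(1:2, function(ti) {
      t <- rset[[paste0("tetra", ti)]]
      list(vertex_ids = t$vertex_ids, vertex_pose = t$vertex_pose,
           params = t$params[c("A", "B", "s", "D")])
    })
  )
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(man))
  }
  man
}
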