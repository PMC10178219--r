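#' Generate an idealized seven-transmembrane C-alpha bundle
#'
#' Builds a download-free test structure: seven ideal alpha-helices
#' (textbook geometry, rise 1.5 Angstrom per residue, twist 100 degrees per
#' residue, C-alpha radius 2.3 Angstrom) with their axes on a circle, which
#' leaves a central cavity emulating the orthosteric pocket. All bundled
#' pocket positions (surrogates, tetrahedron vertices) are planted at fixed
#' indices on their helix and an accompanying residue map resolves them.
#' Coordinates are deterministic for a given seed; `jitter_sd > 0` adds
#' seeded Gaussian noise so that ensembles of distinct structures can be
#' generated.
#'
#' The default `pocket_radius` of 8.2 Angstrom places the surrogate
#' C-alpha hull volume near 2600 cubic Angstrom, the typical inactive
#' class A pocket volume.
#'
#' @param pocket_radius radius of the helix-axis circle, Angstrom.
#' @param residues_per_helix residues per helix (>= 10).
#' @param rise helix rise per residue, Angstrom.
#' @param twist helix twist per residue, degrees.
#' @param ca_radius C-alpha distance from the helix axis, Angstrom.
#' @param jitter_sd standard deviation of per-coordinate Gaussian jitter,
#'   Angstrom (0 = ideal geometry).
#' @param seed RNG seed for the jitter.
#' @param label model label.
#' @return list with `model` (a `structure_model`), `map` (a
#'   `residue_map` resolving every planted id) and `pocket`
#'   ([default_pocket_definition()]).
#' @export
make_bundle <- function(pocket_radius = 8.2, residues_per_helix = 28,
                        rise = 1.5, twist = 100, ca_radius = 2.3,
                        jitter_sd = 0, seed = 1, label = "bundle") {
  stopifnot(pocket_radius > 0, residues_per_helix >= 10)
  n <- as.integer(residues_per_helix)
  rows <- vector("list", 7L)
  for (h in 1:7) {
    ah <- 2 * pi * (h - 1) / 7
    axis <- pocket_radius * c(cos(ah), sin(ah))
    i <- seq_len(n)
    phi <- (i - 1) * twist * pi / 180 + ah + pi  # residue 1 faces the cavity
    rows[[h]] <- data.frame(
      helix = h,
      chain = "A",
      resno = (h - 1L) * n + i,
      icode = "",
      resname = "ALA",
      x = axis[1L] + ca_radius * cos(phi),
      y = axis[2L] + ca_radius * sin(phi),
      z = (i - 1) * rise,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, rows)
  if (jitter_sd > 0) {
    set.seed(seed)
    res$x <- res$x + stats::rnorm(nrow(res), 0, jitter_sd)
    res$y <- res$y + stats::rnorm(nrow(res), 0, jitter_sd)
    res$z <- res$z + stats::rnorm(nrow(res), 0, jitter_sd)
  }
  res$pose <- seq_len(nrow(res))
  helix_col <- res$helix
  res <- res[, c("chain", "resno", "icode", "resname", "pose", "x", "y", "z")]
  rownames(res) <- NULL

  model <- structure(list(
    label = label,
    residues = res,
    atoms = data.frame(pose = res$pose, atom = "CA", element = "C",
                       x = res$x, y = res$y, z = res$z,
                       stringsAsFactors = FALSE),
    hetero = data.frame(group = character(), resname = character(),
                        chain = character(), resno = integer(),
                        atom = character(), element = character(),
                        x = numeric(), y = numeric(), z = numeric(),
                        stringsAsFactors = FALSE)
  ), class = "structure_model")

  pocket <- default_pocket_definition()
  parts <- generic_parts(pocket$extended)
  map_rows <- list()
  for (h in sort(unique(parts$helix))) {
    ph <- parts[parts$helix == h, , drop = FALSE]
    ph <- ph[order(ph$bw), , drop = FALSE]
    k <- nrow(ph)
    # spread the planted positions over the extracellular (upper) half
    idx <- unique(round(seq(ceiling(n * 0.45), n - 2L, length.out = k)))
    while (length(idx) < k) idx <- sort(unique(c(idx, max(idx) + 1L)))
    helix_res <- res[helix_col == h, , drop = FALSE]
    map_rows[[length(map_rows) + 1L]] <- data.frame(
      generic_id = ph$id,
      chain = "A",
      resseq = helix_res$resno[idx[seq_len(k)]],
      icode = "",
      stringsAsFactors = FALSE
    )
  }
  map <- do.call(rbind, map_rows)
  rownames(map) <- NULL
  attr(map, "receptor") <- label
  class(map) <- c("residue_map", "data.frame")

  list(model = model, map = map, pocket = pocket)
}

#' Emit a residue map as TSV text
#'
#' @param map a `residue_map`.
#' @param path optional output file.
#' @return the TSV text; invisibly when `path` is given.
#' @export
write_residue_map <- function(map, path = NULL) {
  lines <- c("generic_id\tchain\tresseq\ticode",
             sprintf("%s\t%s\t%d\t%s", map$generic_id, map$chain,
                     map$resseq, map$icode))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(txt))
  }
  txt
}

#' Radially scale a structure about the pocket centroid
#'
#' Scales all coordinates about a fixed center, emulating pocket shrinkage
#' or expansion; the pocket volume scales exactly as `factor^3`.
#'
#' @param model a `structure_model`.
#' @param factor scale factor (> 0).
#' @param center 3-vector; default is the centroid of all C-alpha atoms.
#' @return the scaled `structure_model`.
#' @export
scale_pocket <- function(model, factor, center = NULL) {
  stopifnot(factor > 0)
  if (is.null(center)) {
    center <- colMeans(as.matrix(model$residues[, c("x", "y", "z")]))
  }
  sc <- function(df) {
    df$x <- center[1L] + factor * (df$x - center[1L])
    df$y <- center[2L] + factor * (df$y - center[2L])
    df$z <- center[3L] + factor * (df$z - center[3L])
    df
  }
  model$residues <- sc(model$residues)
  if (!is.null(model$atoms) && nrow(model$atoms)) model$atoms <- sc(model$atoms)
  if (!is.null(model$hetero) && nrow(model$hetero)) {
    model$hetero <- sc(model$hetero)
  }
  model
}

#' Plant a synthetic ligand touching chosen pocket residues
#'
#' Places one hetero atom per target residue at `contact_distance` from the
#' residue's C-alpha, so that contact detection at the standard 3.5
#' Angstrom cutoff recovers exactly the target set. For each target the
#' placement direction is chosen deterministically from a fixed spherical
#' grid as the direction maximizing clearance from all non-target residues
#' (candidates are ranked by closeness to the pocket-center direction on
#' ties). Errors if no direction keeps every non-target residue farther
#' than 3.5 Angstrom (infeasible placement, e.g. targets too buried).
#'
#' @param model a `structure_model`.
#' @param target_ids generic ids of the residues the ligand must touch.
#' @param map a `residue_map` resolving the targets.
#' @param contact_distance atom placement distance, Angstrom (default 3.0,
#'   inside the 3.5 detection radius).
#' @return hetero-group data frame (columns as `model$hetero`) ready to be
#'   passed to [detect_pocket_residues()] or appended to the model.
#' @export
plant_ligand <- function(model, target_ids, map, contact_distance = 3.0) {
  if (!length(target_ids)) stop("empty target list")
  res <- resolve_residues(map, model, target_ids)
  ctr <- colMeans(as.matrix(res[, c("x", "y", "z")]))
  other <- model$residues[!model$residues$pose %in% res$pose, , drop = FALSE]
  om <- as.matrix(other[, c("x", "y", "z")])
  # fixed Fibonacci sphere: deterministic candidate directions
  k <- seq_len(400L)
  ga <- pi * (3 - sqrt(5))
  zc <- 1 - (2 * k - 1) / 400
  rc <- sqrt(pmax(1 - zc^2, 0))
  dirs <- cbind(rc * cos(ga * k), rc * sin(ga * k), zc)
  pos <- t(vapply(seq_len(nrow(res)), function(i) {
    ca <- unlist(res[i, c("x", "y", "z")])
    cand <- sweep(dirs * contact_distance, 2L, ca, `+`)
    clear <- if (nrow(om)) {
      d2 <- outer(rowSums(cand^2), rep(1, nrow(om))) +
            outer(rep(1, nrow(cand)), rowSums(om^2)) - 2 * cand %*% t(om)
      sqrt(pmax(apply(d2, 1L, min), 0))
    } else rep(Inf, nrow(cand))
    u <- ctr - ca
    nu <- sqrt(sum(u^2))
    inward <- if (nu < 1e-6) rep(0, nrow(cand)) else drop(dirs %*% (u / nu))
    best <- order(-round(clear, 6L), -inward)[1L]
    cand[best, ]
  }, numeric(3L)))
  lig <- data.frame(
    group = "LIG_X_1", resname = "LIG", chain = "X", resno = 1L,
    atom = sprintf("C%d", seq_len(nrow(pos))), element = "C",
    x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
    stringsAsFactors = FALSE
  )
  if (nrow(other)) {
    d2 <- outer(rowSums(om^2), rep(1, nrow(pos))) +
          outer(rep(1, nrow(om)), rowSums(pos^2)) - 2 * om %*% t(pos)
    if (min(d2) <= 3.5^2) {
      stop("infeasible ligand placement: a non-target residue is within 3.5 A")
    }
  }
  lig
}

#' Generate a synthetic model ensemble with a controlled volume
#' distribution
#'
#' Draws `n` model records with pocket volumes from a normal law and
#' independent total and interface scores, plus a parseable Rosetta score
#' table. Defaults emulate a 100-model comparative-modeling ensemble with
#' the typical inactive class A pocket volume distribution (2600 +/- 200
#' cubic Angstrom).
#'
#' @param n number of models.
#' @param median_target center of the volume distribution, cubic Angstrom.
#' @param sd standard deviation of the volume distribution.
#' @param seed RNG seed.
#' @return list with `records` (data frame `label`, `volume`,
#'   `total_score`, `interface_score`) and `score_text` (Rosetta score
#'   table).
#' @export
make_ensemble <- function(n = 100, median_target = 2600, sd = 200, seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  labels <- sprintf("model_%04d", seq_len(n))
  volumes <- stats::rnorm(n, median_target, sd)
  total <- stats::rnorm(n, -350, 20)
  iface <- stats::rnorm(n, -4, 3)
  records <- data.frame(label = labels, volume = volumes,
                        total_score = total, interface_score = iface,
                        stringsAsFactors = FALSE)
  score_text <- paste0(paste(c(
    "SCORE: total_score interface_delta_X description",
    sprintf("SCORE: %12.3f %12.3f %s", total, iface, labels)
  ), collapse = "\n"), "\n")
  list(records = records, score_text = score_text)
}
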