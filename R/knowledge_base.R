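#' Aggregate pairwise distance statistics over a structure set
#'
#' For every unordered pair of the requested generic positions, measures the
#' C-alpha distance in each structure that resolves both members and
#' records the per-pair count, median, mean and standard deviation. The
#' median of an even count is the mean of the two middle values; the
#' standard deviation is the population form (n denominator) — a
#' descriptive statistic over the census of available structures
#' (`sd_form = "sample"` switches to the n-1 form). Structures that resolve
#' only part of the id list still contribute to the pairs they can resolve.
#'
#' @param samples list of `list(model = <structure_model>, map =
#'   <residue_map>)` entries.
#' @param ids generic residue ids defining the pairs.
#' @param sd_form `"population"` (default) or `"sample"`.
#' @return a `distance_stats` data frame: `id_a`, `id_b`, `n`, `median`,
#'   `mean`, `sd` (Angstrom).
#' @export
aggregate_distance_stats <- function(samples, ids,
                                     sd_form = c("population", "sample")) {
  sd_form <- match.arg(sd_form)
  if (!length(samples)) stop("empty sample set")
  ids <- parse_generic_id(ids)
  acc <- new.env(parent = emptyenv())
  used <- 0L
  for (s in samples) {
    have <- tryCatch(
      unclass(ids)[unclass(ids) %in% s$map$generic_id],
      error = function(e) character()
    )
    res <- tryCatch(resolve_residues(s$map, s$model, have),
                    error = function(e) NULL)
    if (is.null(res) || nrow(res) < 2L) {
      warning("structure ", sQuote(s$model$label),
              " resolves fewer than 2 ids; skipped")
      next
    }
    used <- used + 1L
    pd <- pairwise_distances(res)
    keys <- paste(pd$id_a, pd$id_b, sep = "~")
    for (i in seq_along(keys)) {
      acc[[keys[i]]] <- c(acc[[keys[i]]], pd$distance[i])
    }
  }
  if (!used) stop("no structure in the sample set resolved the ids")
  keys <- ls(acc)
  stat1 <- function(v) {
    n <- length(v)
    mu <- mean(v)
    s2 <- if (sd_form == "population") mean((v - mu)^2)
          else if (n > 1L) sum((v - mu)^2) / (n - 1L) else 0
    c(n = n, median = stats::median(v), mean = mu, sd = sqrt(s2))
  }
  m <- t(vapply(keys, function(k) stat1(acc[[k]]), numeric(4L)))
  parts <- strsplit(keys, "~", fixed = TRUE)
  out <- data.frame(
    id_a = vapply(parts, `[`, "", 1L),
    id_b = vapply(parts, `[`, "", 2L),
    n = as.integer(m[, "n"]),
    median = m[, "median"], mean = m[, "mean"], sd = m[, "sd"],
    stringsAsFactors = FALSE
  )
  out <- out[order(generic_order_key(out$id_a), generic_order_key(out$id_b)), ]
  rownames(out) <- NULL
  class(out) <- c("distance_stats", "data.frame")
  out
}

#' Detect pocket residues by ligand contact
#'
#' A residue is a pocket residue when its minimum heavy-atom to
#' ligand-heavy-atom distance is within the cutoff radius (closed ball:
#' the boundary distance counts as a contact). Hydrogens are excluded on
#' both sides. When the model carries only C-alpha atoms the test falls
#' back to C-alpha distances with a warning.
#'
#' @param model a `structure_model`.
#' @param ligand a hetero group: data frame with `x`,`y`,`z` and `element`
#'   columns (e.g. one group of `model$hetero`).
#' @param cutoff contact radius in Angstrom (default 3.5).
#' @param map optional `residue_map` used to annotate contacts with their
#'   generic residue id.
#' @return a `contact_report` data frame: `chain`, `resseq`, `icode`,
#'   `resname`, `pose`, `min_distance`, `generic_id` (NA when unmapped),
#'   sorted by pose; attributes `structure` and `cutoff`.
#' @export
detect_pocket_residues <- function(model, ligand, cutoff = 3.5, map = NULL) {
  if (is.null(ligand) || !nrow(ligand)) stop("empty ligand")
  lig <- ligand[!ligand$element %in% c("H", "D"), , drop = FALSE]
  if (!nrow(lig)) stop("empty ligand (no heavy atoms)")
  at <- model$atoms
  ca_only <- is.null(at) || !nrow(at) || all(at$atom == "CA")
  if (ca_only) {
    if (is.null(at) || !nrow(at)) {
      at <- data.frame(pose = model$residues$pose, atom = "CA",
                       element = "C", x = model$residues$x,
                       y = model$residues$y, z = model$residues$z,
                       stringsAsFactors = FALSE)
    }
    warning("model carries C-alpha atoms only; contact detection uses C-alpha distances")
  }
  at <- at[!at$element %in% c("H", "D"), , drop = FALSE]
  ra <- as.matrix(at[, c("x", "y", "z")])
  la <- as.matrix(lig[, c("x", "y", "z")])
  d2 <- outer(rowSums(ra^2), rep(1, nrow(la))) +
        outer(rep(1, nrow(ra)), rowSums(la^2)) - 2 * ra %*% t(la)
  dmin_atom <- sqrt(pmax(apply(d2, 1L, min), 0))
  dmin <- tapply(dmin_atom, at$pose, min)
  poses <- as.integer(names(dmin))
  hit <- dmin <= cutoff
  res <- model$residues
  ridx <- match(poses[hit], res$pose)
  out <- data.frame(
    chain = res$chain[ridx], resseq = res$resno[ridx],
    icode = res$icode[ridx], resname = res$resname[ridx],
    pose = res$pose[ridx], min_distance = as.numeric(dmin[hit]),
    generic_id = NA_character_, stringsAsFactors = FALSE
  )
  if (!is.null(map) && nrow(out)) {
    key <- paste(out$chain, out$resseq, out$icode, sep = "|")
    mkey <- paste(map$chain, map$resseq, map$icode, sep = "|")
    hitm <- match(key, mkey)
    out$generic_id <- ifelse(is.na(hitm), NA_character_,
                             map$generic_id[hitm])
  }
  out <- out[order(out$pose), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "structure") <- model$label
  attr(out, "cutoff") <- cutoff
  class(out) <- c("contact_report", "data.frame")
  out
}

#' Rank pocket residues by contact frequency across structures
#'
#' Tallies how often each generic position appears as a ligand contact
#' across a set of contact reports — the census behind selecting the most
#' frequently ligand-facing pocket residues. Unmapped contacts (NA generic
#' id) are ignored with a warning.
#'
#' @param reports list of `contact_report` objects.
#' @return data frame `generic_id`, `count`, descending by count, ties
#'   broken by canonical generic-id order.
#' @export
rank_residue_frequency <- function(reports) {
  ids <- unlist(lapply(reports, function(r) r$generic_id), use.names = FALSE)
  if (!length(ids)) {
    return(data.frame(generic_id = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  if (anyNA(ids)) {
    warning(sum(is.na(ids)), " unmapped contact(s) ignored")
    ids <- ids[!is.na(ids)]
  }
  if (!length(ids)) {
    return(data.frame(generic_id = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(ids)
  out <- data.frame(generic_id = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, generic_order_key(out$generic_id)), ]
  rownames(out) <- NULL
  out
}

#' Write / read a distance-statistics table as TSV
#'
#' Columns `id_a`, `id_b`, `n`, `median`, `mean`, `sd`; distances printed
#' with 4 decimals.
#'
#' @param stats a `distance_stats` data frame.
#' @param path output path.
#' @export
write_distance_stats <- function(stats, path) {
  out <- stats
  for (cl in c("median", "mean", "sd")) out[[cl]] <- sprintf("%.4f", out[[cl]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_stats
#' @param x path to a stats TSV, or its text.
#' @export
read_distance_stats <- function(x) {
  lines <- read_text_lines(x)
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE)
  need <- c("id_a", "id_b", "median")
  if (!all(need %in% names(df))) {
    stop("distance-stats table must have columns: ",
         paste(need, collapse = ", "))
  }
  class(df) <- c("distance_stats", "data.frame")
  df
}
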