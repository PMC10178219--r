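#' Default HETATM exclusion set
#'
#' Waters, common ions and cryoprotectants excluded from hetero groups by
#' default. Membrane lipids and detergents are deliberately not excluded:
#' they sometimes occupy the orthosteric pocket and are then legitimate
#' "ligands" for contact detection.
#'
#' @export
DEFAULT_HET_EXCLUDE <- c("HOH", "DOD", "NA", "CL", "K", "MG", "ZN", "CA",
                         "SO4", "PO4", "GOL", "EDO", "PEG")

#' Read a PDB-format structure into a uniform model
#'
#' Parses ATOM/HETATM records into a `structure_model`: ordered polymer
#' residues with C-alpha coordinates and Rosetta-style pose numbering
#' (1..N in file order), optional full heavy-atom lists, and hetero groups.
#' Only the first MODEL of a multi-model file is read.
#'
#' @param pdb path to a PDB file, or PDB text (single string or character
#'   vector of lines).
#' @param label model label; defaults to the file name (or `"structure"`).
#' @param chain chain policy: `"first"` (first chain with >= 100 polymer
#'   residues, falling back to the first chain with any polymer residues —
#'   GPCR entries often carry fusion partners on other chains), `"all"`, or
#'   an explicit one-character chain id.
#' @param altloc alternate-location policy: `"first"` (keep the first
#'   record of each atom; deterministic default) or `"occupancy"` (keep the
#'   highest-occupancy record, first on ties).
#' @param het_exclude hetero residue names to drop; `character(0)` disables
#'   exclusion.
#' @param strict if `TRUE`, a polymer residue without a C-alpha atom is an
#'   error instead of a dropped-with-warning residue.
#' @return a `structure_model`: list with `label`, `residues` (data frame:
#'   `chain`, `resno`, `icode`, `resname`, `pose`, `x`, `y`, `z`), `atoms`
#'   (heavy atoms incl. C-alpha: `pose`, `atom`, `element`, `x`, `y`, `z`)
#'   and `hetero` (one row per hetero atom: `group`, `resname`, `chain`,
#'   `resno`, `atom`, `element`, `x`, `y`, `z`).
#' @export
read_structure <- function(pdb, label = NULL,
                           chain = "first",
                           altloc = c("first", "occupancy"),
                           het_exclude = DEFAULT_HET_EXCLUDE,
                           strict = FALSE) {
  altloc <- match.arg(altloc)
  if (is.null(label)) {
    label <- if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
      sub("\\.[^.]*$", "", basename(pdb))
    } else "structure"
  }
  lines <- read_text_lines(pdb)

  # first MODEL only
  mstart <- grep("^MODEL ", lines)
  if (length(mstart)) {
    mend <- grep("^ENDMDL", lines)
    end <- if (length(mend)) mend[1L] else length(lines)
    lines <- lines[seq_len(end)]
  }

  rec <- substr(lines, 1L, 6L)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  rec <- trimws(rec[keep])
  if (!any(rec == "ATOM")) stop("no ATOM records: empty structure")

  fx <- function(a, b) substr(lines, a, b)
  atoms <- data.frame(
    record = rec,
    name = trimws(fx(13L, 16L)),
    alt = fx(17L, 17L),
    resname = trimws(fx(18L, 20L)),
    chain = fx(22L, 22L),
    resno = as.integer(fx(23L, 26L)),
    icode = trimws(fx(27L, 27L)),
    x = as.numeric(fx(31L, 38L)),
    y = as.numeric(fx(39L, 46L)),
    z = as.numeric(fx(47L, 54L)),
    occ = suppressWarnings(as.numeric(fx(55L, 60L))),
    element = trimws(fx(77L, 78L)),
    stringsAsFactors = FALSE
  )
  atoms$occ[is.na(atoms$occ)] <- 1
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z) || anyNA(atoms$resno)) {
    stop("unparsable coordinate or residue fields in PDB input")
  }
  blank <- !nzchar(atoms$element)
  if (any(blank)) {
    # element column absent in minimal files: derive from the atom name
    atoms$element[blank] <- sub("^[0-9']*([A-Za-z]).*$", "\\1",
                                atoms$name[blank])
  }
  atoms$element <- toupper(atoms$element)

  # altloc resolution per atom site
  site <- paste(atoms$record, atoms$chain, atoms$resno, atoms$icode,
                atoms$resname, atoms$name, sep = "|")
  ord <- if (altloc == "occupancy") {
    order(site, -atoms$occ, seq_len(nrow(atoms)))
  } else {
    order(site, seq_len(nrow(atoms)))
  }
  first_of_site <- !duplicated(site[ord])
  keep_idx <- sort(ord[first_of_site])
  atoms <- atoms[keep_idx, , drop = FALSE]

  poly <- atoms[atoms$record == "ATOM", , drop = FALSE]
  het <- atoms[atoms$record == "HETATM", , drop = FALSE]

  # chain selection
  if (identical(chain, "all")) {
    sel_chains <- unique(poly$chain)
  } else if (identical(chain, "first")) {
    counts <- vapply(split(paste(poly$resno, poly$icode), poly$chain),
                     function(k) length(unique(k)), 1L)
    counts <- counts[unique(poly$chain)]  # file order
    big <- names(counts)[counts >= 100L]
    sel_chains <- if (length(big)) big[1L] else names(counts)[1L]
  } else {
    sel_chains <- chain
    if (!any(poly$chain %in% sel_chains)) {
      stop("no polymer residues on chain ", sQuote(chain))
    }
  }
  poly <- poly[poly$chain %in% sel_chains, , drop = FALSE]
  if (!nrow(poly)) stop("no ATOM records after chain selection: empty structure")

  rkey <- paste(poly$chain, poly$resno, poly$icode, sep = "|")
  first_rows <- !duplicated(rkey)
  resdf <- poly[first_rows, c("chain", "resno", "icode", "resname"),
                drop = FALSE]
  ca <- poly[poly$name == "CA" & poly$element != "H", , drop = FALSE]
  cakey <- paste(ca$chain, ca$resno, ca$icode, sep = "|")
  m <- match(paste(resdf$chain, resdf$resno, resdf$icode, sep = "|"), cakey)
  if (anyNA(m)) {
    noca <- resdf[is.na(m), , drop = FALSE]
    msg <- paste0(noca$resname, " ", noca$chain, noca$resno, noca$icode,
                  collapse = ", ")
    if (strict) stop("residue(s) without C-alpha: ", msg)
    warning("dropping residue(s) without C-alpha: ", msg)
    resdf <- resdf[!is.na(m), , drop = FALSE]
    m <- m[!is.na(m)]
  }
  resdf$pose <- seq_len(nrow(resdf))
  resdf$x <- ca$x[m]
  resdf$y <- ca$y[m]
  resdf$z <- ca$z[m]
  rownames(resdf) <- NULL

  heavy <- poly[!poly$element %in% c("H", "D"), , drop = FALSE]
  hkey <- paste(heavy$chain, heavy$resno, heavy$icode, sep = "|")
  hpose <- resdf$pose[match(hkey, paste(resdf$chain, resdf$resno, resdf$icode,
                                        sep = "|"))]
  heavy <- heavy[!is.na(hpose), , drop = FALSE]
  atomdf <- data.frame(pose = hpose[!is.na(hpose)],
                       atom = heavy$name, element = heavy$element,
                       x = heavy$x, y = heavy$y, z = heavy$z,
                       stringsAsFactors = FALSE)
  rownames(atomdf) <- NULL

  if (length(het_exclude)) {
    het <- het[!het$resname %in% het_exclude, , drop = FALSE]
  }
  hetdf <- data.frame(
    group = if (nrow(het)) paste(het$resname, het$chain, het$resno, sep = "_")
            else character(),
    resname = het$resname, chain = het$chain, resno = het$resno,
    atom = het$name, element = het$element,
    x = het$x, y = het$y, z = het$z,
    stringsAsFactors = FALSE
  )
  rownames(hetdf) <- NULL

  structure(list(label = label, residues = resdf, atoms = atomdf,
                 hetero = hetdf),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model> ", x$label, ": ", nrow(x$residues),
      " residues (pose 1..", nrow(x$residues), "), ",
      length(unique(x$hetero$group)), " hetero group(s)\n", sep = "")
  invisible(x)
}

#' C-alpha coordinate matrix of a structure model
#'
#' @param model a `structure_model`.
#' @param poses optional pose numbers to extract (in order).
#' @return numeric matrix with one row per residue and columns x, y, z.
#' @export
ca_coords <- function(model, poses = NULL) {
  res <- model$residues
  if (!is.null(poses)) {
    idx <- match(poses, res$pose)
    if (anyNA(idx)) stop("pose number(s) absent from model: ",
                         paste(poses[is.na(idx)], collapse = ", "))
    res <- res[idx, , drop = FALSE]
  }
  m <- as.matrix(res[, c("x", "y", "z")])
  rownames(m) <- res$pose
  m
}

pdb_atom_line <- function(record, serial, name, resname, chain, resno, icode,
                          x, y, z, element) {
  namefield <- ifelse(nchar(name) < 4L,
                      sprintf(" %-3s", name), sprintf("%-4s", name))
  sprintf("%-6s%5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, namefield, resname, chain, resno,
          ifelse(nzchar(icode), icode, " "), x, y, z, 1, 0, element)
}

#' Write a structure model as PDB text
#'
#' Emits ATOM records for every stored heavy atom (C-alpha only if that is
#' all the model carries), a TER record, then HETATM records for hetero
#' groups. Re-reading the output reproduces residues and coordinates at PDB
#' precision (3 decimals).
#'
#' @param model a `structure_model`.
#' @param path optional output file; when given, the text is written there.
#' @return the PDB text (single string, trailing newline), invisibly when
#'   `path` is given.
#' @export
write_structure <- function(model, path = NULL) {
  res <- model$residues
  if (is.null(res) || !nrow(res)) stop("cannot write an empty structure model")
  at <- model$atoms
  if (is.null(at) || !nrow(at)) {
    at <- data.frame(pose = res$pose, atom = "CA", element = "C",
                     x = res$x, y = res$y, z = res$z,
                     stringsAsFactors = FALSE)
  }
  ridx <- match(at$pose, res$pose)
  at <- at[order(ridx, seq_len(nrow(at))), , drop = FALSE]
  ridx <- match(at$pose, res$pose)
  lines <- pdb_atom_line("ATOM", seq_len(nrow(at)), at$atom,
                         res$resname[ridx], res$chain[ridx], res$resno[ridx],
                         res$icode[ridx], at$x, at$y, at$z, at$element)
  n <- nrow(at)
  last <- nrow(res)
  lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d", n + 1L,
                            res$resname[last], res$chain[last],
                            res$resno[last]))
  het <- model$hetero
  if (!is.null(het) && nrow(het)) {
    lines <- c(lines,
               pdb_atom_line("HETATM", n + 1L + seq_len(nrow(het)), het$atom,
                             het$resname, het$chain, het$resno, "",
                             het$x, het$y, het$z, het$element))
  }
  lines <- c(lines, "END")
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(txt))
  }
  txt
}

#' Read a Rosetta score table
#'
#' Parses the `score.sc` dialect: whitespace-delimited lines beginning with
#' `SCORE:`, the first such line being the header, with a `description`
#' column holding the model label. Columns whose cells are all numeric are
#' parsed as reals; others are kept as text.
#'
#' @param x path to a score file, or its text.
#' @return data frame, one row per model, with a `description` column.
#'   Duplicate labels keep the last row (with a warning).
#' @export
read_score_table <- function(x) {
  lines <- read_text_lines(x)
  sl <- grep("^SCORE:", lines, value = TRUE)
  if (!length(sl)) stop("score-table format error: no SCORE: header line")
  toks <- strsplit(trimws(sub("^SCORE:", "", sl)), "\\s+")
  header <- toks[[1L]]
  if (!"description" %in% header) {
    stop("score-table format error: header lacks a description column")
  }
  rows <- toks[-1L]
  rows <- rows[vapply(rows, length, 1L) > 0L]
  if (!length(rows)) {
    out <- as.data.frame(matrix(character(), 0L, length(header)),
                         stringsAsFactors = FALSE)
    names(out) <- header
    return(out)
  }
  bad <- vapply(rows, length, 1L) != length(header)
  if (any(bad)) stop("score-table format error: row/header length mismatch")
  m <- do.call(rbind, rows)
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- header
  for (j in setdiff(names(out), "description")) {
    num <- suppressWarnings(as.numeric(out[[j]]))
    if (!anyNA(num)) out[[j]] <- num
  }
  dup <- duplicated(out$description, fromLast = TRUE)
  if (any(dup)) {
    warning("duplicate model label(s) in score table; keeping last: ",
            paste(unique(out$description[dup]), collapse = ", "))
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
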