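#' Parse Ballesteros-Weinstein / GPCRdb generic residue numbers
#'
#' Generic residue numbers identify structurally equivalent positions across
#' class A GPCRs. The Ballesteros-Weinstein (BW) part is `helix.position`
#' (e.g. `2.57`); the GPCRdb extension appends an `x`-separated structural
#' position that corrects for helix bulges and gaps (e.g. `2.57x56`).
#'
#' Accepted input spellings are the machine form `"2.57x56"`, the typeset
#' form `"2.57 × 56"` (with the multiplication glyph and optional
#' whitespace), and the bare BW form `"2.57"`, in which case the GPCRdb
#' position defaults to the BW position.
#'
#' @param x character vector of tokens.
#' @return a `generic_id` vector (canonical `"h.bbxgg"` strings).
#' @examples
#' parse_generic_id("2.57x56")
#' parse_generic_id("5.46 × 461")
#' @export
parse_generic_id <- function(x) {
  x <- as.character(x)
  rx <- "^\\s*([0-9])\\.([0-9]+)(?:\\s*[x×]\\s*([0-9]+))?\\s*$"
  m <- regmatches(x, regexec(rx, x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed generic residue id: ", paste(sQuote(x[bad]), collapse = ", "))
  }
  helix <- as.integer(vapply(m, `[`, "", 2L))
  bw <- as.integer(vapply(m, `[`, "", 3L))
  gp <- vapply(m, `[`, "", 4L)
  gpcrdb <- ifelse(gp == "", bw, suppressWarnings(as.integer(gp)))
  if (any(helix < 1L | helix > 8L)) {
    stop("helix number outside 1..8 in generic id: ",
         paste(sQuote(x[helix < 1L | helix > 8L]), collapse = ", "))
  }
  if (any(bw < 1L) || any(gpcrdb < 1L)) {
    stop("generic id positions must be >= 1")
  }
  ids <- sprintf("%d.%02dx%02d", helix, bw, gpcrdb)
  structure(ids, class = "generic_id")
}

#' @export
print.generic_id <- function(x, ...) {
  cat("<generic_id> ", paste(unclass(x), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
`[.generic_id` <- function(x, i) structure(unclass(x)[i], class = "generic_id")

#' @export
as.character.generic_id <- function(x, ...) unclass(x)

#' Split generic ids into helix / BW / GPCRdb components
#'
#' @param ids a `generic_id` vector or character vector of parseable tokens.
#' @return data frame with columns `id`, `helix`, `bw`, `gpcrdb`.
#' @export
generic_parts <- function(ids) {
  ids <- parse_generic_id(ids)
  m <- regmatches(unclass(ids), regexec("^([0-9])\\.([0-9]+)x([0-9]+)$", unclass(ids)))
  data.frame(
    id = unclass(ids),
    helix = as.integer(vapply(m, `[`, "", 2L)),
    bw = as.integer(vapply(m, `[`, "", 3L)),
    gpcrdb = as.integer(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}

# Canonical sort key: helix, then BW position, then GPCRdb position.
generic_order_key <- function(ids) {
  p <- generic_parts(ids)
  sprintf("%d.%03d.%03d", p$helix, p$bw, p$gpcrdb)
}

#' Canonical ordering of generic residue ids
#'
#' Orders by helix, then BW position, then GPCRdb position. Used for
#' deterministic pair canonicalization and tie-breaking.
#'
#' @param ids a `generic_id` or character vector.
#' @return the ids, sorted, as a `generic_id` vector.
#' @export
sort_generic <- function(ids) {
  ids <- parse_generic_id(ids)
  ids[order(generic_order_key(ids))]
}

#' The bundled orthosteric pocket definition
#'
#' Returns the canonical class A pocket positions used throughout the
#' package:
#' \describe{
#'   \item{surrogates}{the 10 positions on TM2/3/5/6/7 whose C-alpha atoms
#'     span the pocket volume polytope (the highest and lowest pocket-lining
#'     position on each of the five helices; TM1 and TM4 do not surround the
#'     pocket).}
#'   \item{tetra1, tetra2}{the two 4-vertex sets defining the tetrahedral
#'     distance-restraint geometry.}
#'   \item{extended}{the pocket-lining positions named in the bundled
#'     knowledge base (a partial default, nominally 34 positions in the full
#'     census; users studying the full set supply their own definition file).}
#' }
#'
#' @return list with elements `surrogates`, `tetra1`, `tetra2`, `extended`,
#'   each a `generic_id` vector.
#' @export
default_pocket_definition <- function() {
  surrogates <- parse_generic_id(c(
    "2.57x56", "2.65x64", "3.28x28", "3.37x37", "5.38x39",
    "5.47x47", "6.51x51", "6.58x58", "7.32x31", "7.43x42"
  ))
  tetra1 <- parse_generic_id(c("2.60x59", "3.40x40", "5.38x39", "7.32x31"))
  tetra2 <- parse_generic_id(c("2.65x64", "4.57x57", "5.46x461", "6.48x48"))
  extended <- sort_generic(unique(c(
    unclass(surrogates), unclass(tetra1), unclass(tetra2)
  )))
  list(surrogates = surrogates, tetra1 = tetra1, tetra2 = tetra2,
       extended = extended)
}

#' Read a pocket-definition file
#'
#' One generic id per line; optional section headers `[surrogates]`,
#' `[tetra1]`, `[tetra2]`, `[extended]`; `#` starts a comment. Lines before
#' any header go to `extended`. Missing sections fall back to the bundled
#' defaults.
#'
#' @param x path to a definition file, or its text.
#' @return a pocket-definition list as from [default_pocket_definition()].
#' @export
read_pocket_definition <- function(x) {
  lines <- read_text_lines(x)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  def <- default_pocket_definition()
  section <- "extended"
  acc <- list(surrogates = character(), tetra1 = character(),
              tetra2 = character(), extended = character())
  for (ln in lines) {
    hdr <- regmatches(ln, regexec("^\\[(\\w+)\\]$", ln))[[1]]
    if (length(hdr) == 2L) {
      if (!hdr[2L] %in% names(acc)) {
        stop("unknown pocket-definition section: [", hdr[2L], "]")
      }
      section <- hdr[2L]
    } else {
      acc[[section]] <- c(acc[[section]], ln)
    }
  }
  for (s in names(acc)) {
    if (length(acc[[s]])) def[[s]] <- parse_generic_id(acc[[s]])
  }
  for (s in c("tetra1", "tetra2")) {
    if (length(def[[s]]) != 4L || anyDuplicated(unclass(def[[s]]))) {
      stop("section [", s, "] must contain 4 distinct generic ids")
    }
  }
  def
}

#' Load a per-receptor generic-number mapping table
#'
#' The mapping table resolves generic residue ids to author numbering for one
#' receptor (obtainable from the GPCRdb generic-numbering annotation). TSV
#' with header columns `generic_id`, `chain`, `resseq` and optionally
#' `icode`; `#` lines are comments.
#'
#' @param x path to the TSV, or its text.
#' @param receptor optional receptor label stored on the map.
#' @return a `residue_map`: data frame with columns `generic_id`, `chain`,
#'   `resseq`, `icode`.
#' @export
load_residue_map <- function(x, receptor = "") {
  lines <- read_text_lines(x)
  lines <- lines[!grepl("^\\s*#", lines)]
  if (!length(lines)) stop("empty residue map")
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("generic_id", "chain", "resseq")
  if (!all(need %in% names(df))) {
    stop("residue map must have columns: ", paste(need, collapse = ", "))
  }
  if (!"icode" %in% names(df)) df$icode <- ""
  df$icode[is.na(df$icode)] <- ""
  df$generic_id <- unclass(parse_generic_id(df$generic_id))
  df$resseq <- as.integer(df$resseq)
  if (anyNA(df$resseq)) stop("non-integer resseq in residue map")
  if (anyDuplicated(df$generic_id)) {
    stop("duplicate generic_id in residue map: ",
         paste(unique(df$generic_id[duplicated(df$generic_id)]), collapse = ", "))
  }
  author <- paste(df$chain, df$resseq, df$icode, sep = "|")
  if (anyDuplicated(author)) {
    stop("residue map is not injective: two generic ids map to the same residue")
  }
  out <- df[, c("generic_id", "chain", "resseq", "icode")]
  attr(out, "receptor") <- receptor
  class(out) <- c("residue_map", "data.frame")
  out
}

#' Resolve generic residue ids to pose numbers and coordinates
#'
#' @param map a `residue_map` from [load_residue_map()].
#' @param model a `structure_model` from [read_structure()].
#' @param ids generic ids to resolve; output order equals input order.
#' @return data frame with columns `generic_id`, `pose`, `x`, `y`, `z`
#'   (C-alpha coordinates, Angstrom).
#' @export
resolve_residues <- function(map, model, ids) {
  ids <- parse_generic_id(ids)
  res <- model$residues
  if (!length(ids)) {
    return(data.frame(generic_id = character(), pose = integer(),
                      x = numeric(), y = numeric(), z = numeric(),
                      stringsAsFactors = FALSE))
  }
  pos <- match(unclass(ids), map$generic_id)
  if (anyNA(pos)) {
    stop("generic id not present in residue map: ",
         paste(unclass(ids)[is.na(pos)], collapse = ", "))
  }
  key_model <- paste(res$chain, res$resno, res$icode, sep = "|")
  key_map <- paste(map$chain[pos], map$resseq[pos], map$icode[pos], sep = "|")
  ridx <- match(key_map, key_model)
  if (anyNA(ridx)) {
    stop("mapped residue missing from structure for generic id: ",
         paste(unclass(ids)[is.na(ridx)], collapse = ", "))
  }
  data.frame(
    generic_id = unclass(ids),
    pose = res$pose[ridx],
    x = res$x[ridx], y = res$y[ridx], z = res$z[ridx],
    stringsAsFactors = FALSE
  )
}

# Accept either a file path or text (single string with newlines, or a
# character vector of lines) and return lines.
read_text_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}
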