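#' Median pocket volume of an ensemble
#'
#' Middle order statistic; for an even count, the mean of the two middle
#' values.
#'
#' @param volumes numeric vector of volumes (cubic Angstrom), non-empty.
#' @export
median_volume <- function(volumes) {
  if (!length(volumes)) stop("empty volume list")
  stats::median(volumes)
}

#' Filter a model ensemble by pocket volume
#'
#' Models whose pocket volume lies within the band around the ensemble
#' median pass; the rest are filtered out. The band boundary is inclusive,
#' and the default +/- 200 cubic Angstrom matches the natural pocket-size
#' variation observed across experimental structures of a receptor. The
#' median is taken over all input records of one receptor ensemble.
#'
#' @param records data frame with columns `label` and `volume` (and
#'   optionally scores).
#' @param band half-width of the acceptance band in cubic Angstrom.
#' @return a `filter_outcome`: list with `median_volume`, `band`,
#'   `passing` (labels), `selected` (filled by [select_best()]) and the
#'   input `records`.
#' @export
filter_by_volume <- function(records, band = 200) {
  if (!nrow(records)) stop("empty ensemble")
  if (anyNA(records$volume)) stop("all records must carry volumes")
  med <- median_volume(records$volume)
  pass <- abs(records$volume - med) <= band
  structure(list(median_volume = med, band = band,
                 passing = records$label[pass],
                 selected = character(), k = NA_integer_,
                 records = records),
            class = "filter_outcome")
}

#' @export
print.filter_outcome <- function(x, ...) {
  cat(sprintf("<filter_outcome> median %.1f A^3, band +/-%g: %d/%d pass",
              x$median_volume, x$band, length(x$passing), nrow(x$records)))
  if (length(x$selected)) {
    cat("; selected:", paste(x$selected, collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Select the best-scoring filtered models
#'
#' Orders the filter-passing models by total score (ascending; lower is
#' better), ties broken lexicographically by label, and returns the first
#' `k`.
#'
#' @param outcome a `filter_outcome`.
#' @param scores named numeric vector of total scores, or a data frame with
#'   `description`/`label` and `total_score` columns (e.g. from
#'   [read_score_table()]).
#' @param k number of models to select (default 5).
#' @return character vector of selected labels (also recorded on the
#'   outcome's `selected` field via attribute-free copy semantics: use the
#'   return value).
#' @export
select_best <- function(outcome, scores, k = 5L) {
  if (is.data.frame(scores)) {
    labcol <- intersect(c("description", "label"), names(scores))[1L]
    sc <- stats::setNames(scores$total_score, scores[[labcol]])
  } else {
    sc <- scores
  }
  miss <- setdiff(outcome$passing, names(sc))
  if (length(miss)) {
    stop("missing score for passing model(s): ", paste(miss, collapse = ", "))
  }
  v <- sc[outcome$passing]
  ord <- order(v, names(v))
  utils::head(names(v)[ord], k)
}

#' Classify a pocket-volume difference against a reference
#'
#' A volume difference within the band is within the natural pocket-size
#' variation observed for experimental structures of one receptor; beyond
#' the band the pocket deviates (shrunken for negative differences,
#' enlarged for positive); beyond three times the band the pocket
#' construction is considered failed. Boundaries are inclusive toward the
#' milder category.
#'
#' @param delta volume difference(s), model minus reference, cubic
#'   Angstrom.
#' @param band natural-variation half-width (default 200).
#' @return data frame `delta`, `category`
#'   (`within_natural_variation` / `deviating` / `failed`), `direction`
#'   (`shrunken` / `enlarged` / `none`).
#' @export
classify_volume_difference <- function(delta, band = 200) {
  if (band <= 0) stop("band must be > 0")
  a <- abs(delta)
  category <- ifelse(a <= band, "within_natural_variation",
                     ifelse(a <= 3 * band, "deviating", "failed"))
  direction <- ifelse(category == "within_natural_variation", "none",
                      ifelse(delta < 0, "shrunken", "enlarged"))
  data.frame(delta = delta, category = category, direction = direction,
             stringsAsFactors = FALSE)
}

#' Pocket volumes along a structure series
#'
#' Computes the surrogate pocket volume for every structure of an ordered
#' series (e.g. the snapshots of an iterative relax trajectory, where the
#' pocket typically shrinks over the first few steps and then plateaus).
#'
#' @param series named list of `structure_model`s (names are the labels),
#'   or list of `list(label=, model=)` pairs.
#' @param map a `residue_map` valid for every structure.
#' @param pocket pocket definition; the `surrogates` ids are used.
#' @return data frame `label`, `volume`, input order preserved.
#' @export
trajectory_volumes <- function(series, map,
                               pocket = default_pocket_definition()) {
  if (!length(series)) {
    return(data.frame(label = character(), volume = numeric(),
                      stringsAsFactors = FALSE))
  }
  get1 <- function(i) {
    el <- series[[i]]
    if (inherits(el, "structure_model")) {
      lab <- if (!is.null(names(series)) && nzchar(names(series)[i])) {
        names(series)[i]
      } else el$label
      list(label = lab, model = el)
    } else {
      el
    }
  }
  out <- lapply(seq_along(series), function(i) {
    e <- get1(i)
    v <- tryCatch(
      pocket_volume(resolve_residues(map, e$model, pocket$surrogates)),
      error = function(err) {
        stop("volume failed for structure ", sQuote(e$label), ": ",
             conditionMessage(err), call. = FALSE)
      }
    )
    data.frame(label = e$label, volume = v, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Count successful docking cases from interface scores
#'
#' A docking pose counts as successful when its interface score is at or
#' below the cutoff (default -6 Rosetta energy units, i.e. "-6 REU or
#' lower").
#'
#' @param scores numeric vector of interface scores (REU).
#' @param cutoff success threshold (default -6).
#' @return integer count.
#' @export
count_docking_successes <- function(scores, cutoff = -6) {
  sum(scores <= cutoff)
}
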