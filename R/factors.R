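# WLOGSY and STD factors.
#
# The per-proton WLOGSY factor compares WaterLOGSY intensities of a ligand
# with (I+) and without (I-) the protein receptor:
#
#     WLOGSY factor = |I+ - I-| / |I-|
#
# after both spectra have been scaled so the reference proton (strongest
# free-state WaterLOGSY peak) has unit magnitude in each. The factor set is
# then normalised with its largest value at 100%; the smallest normalised
# factor marks the most solvent-exposed proton. STD factors are
# R = (I_STD / I_1D) x 100, normalised the same way.

#' Select the reference proton of a free-ligand WaterLOGSY table
#'
#' The reference is the proton with the strongest (largest magnitude)
#' WaterLOGSY intensity in the absence of protein; ties break
#' lexicographically by proton id.
#'
#' @param free An [intensity_table()] with `protein_present = FALSE`.
#' @return A proton id.
#' @export
select_reference_proton <- function(free) {
  stopifnot(inherits(free, "intensity_table"))
  if (isTRUE(free$protein_present[1]))
    stop_data("reference selection requires the free-ligand (no protein) table")
  if (all(free$intensity == 0))
    stop_data("all-zero free table: no reference proton can be selected")
  ord <- order(-abs(free$intensity), free$proton_id)
  free$proton_id[ord[1]]
}

#' Scale a free/bound WaterLOGSY table pair to a common reference
#'
#' Each table is divided by the magnitude of its own reference-proton
#' intensity, so the reference has unit magnitude in both spectra and
#' relative intensities become comparable; signs are preserved.
#'
#' @param free,bound Matched [intensity_table()]s over the same protons.
#' @param ref Reference proton id (default: [select_reference_proton()]
#'   applied to `free`).
#' @return A list with scaled elements `free` and `bound`.
#' @export
scale_spectra_pair <- function(free, bound, ref = select_reference_proton(free)) {
  for (nm in c("free", "bound")) {
    tbl <- get(nm)
    iref <- intensities_of(tbl, ref)
    if (iref == 0)
      stop_data("reference proton ", ref, " has zero intensity in the ",
                nm, " table; scaling undefined")
    tbl$intensity <- tbl$intensity / abs(iref)
    assign(nm, tbl)
  }
  list(free = free, bound = bound, reference = ref)
}

#' Raw WLOGSY factor
#'
#' `|i_plus - i_minus| / |i_minus|` for intensities measured with
#' (`i_plus`) and without (`i_minus`) the protein. Vectorised.
#'
#' @param i_plus,i_minus Signed intensities (after pair scaling).
#' @param epsilon Denominator guard, relative to the reference magnitude
#'   (unit after scaling).
#' @param proton_id Optional labels used in error messages.
#' @return Non-negative numeric factor(s).
#' @export
wlogsy_factor_raw <- function(i_plus, i_minus, epsilon = 1e-12,
                              proton_id = NULL) {
  bad <- abs(i_minus) <= epsilon
  if (any(bad)) {
    who <- if (!is.null(proton_id)) paste(proton_id[bad], collapse = ", ")
           else paste(which(bad), collapse = ", ")
    stop_numeric("WLOGSY factor undefined (|I-| <= epsilon) for proton ", who)
  }
  abs(i_plus - i_minus) / abs(i_minus)
}

normalize_factor_set <- function(raw) {
  m <- max(raw)
  if (m == 0) rep(0, length(raw)) else 100 * raw / m
}

new_factor_set <- function(proton_id, raw, kind, reference,
                           ligand_id = "ligand", protein_id = "") {
  df <- data.frame(proton_id = proton_id, raw = raw,
                   normalized_pct = normalize_factor_set(raw),
                   stringsAsFactors = FALSE)
  structure(df, class = c("factor_set", "data.frame"),
            kind = kind, reference = reference,
            ligand_id = ligand_id, protein_id = protein_id)
}

#' @export
print.factor_set <- function(x, ...) {
  cat(sprintf("<factor_set> %s, reference %s\n",
              attr(x, "kind"), attr(x, "reference")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Compute the per-proton WLOGSY factor set of a free/bound pair
#'
#' Selects the reference proton, scales both tables by their own reference
#' magnitude (unless `rescale = FALSE`), applies the raw factor formula
#' per proton and normalises the set with the maximum at 100%. A degenerate
#' all-zero raw set normalises to all 0% rather than erroring.
#'
#' @param free WaterLOGSY [intensity_table()] without protein.
#' @param bound WaterLOGSY [intensity_table()] with protein, same protons
#'   and mixing time.
#' @param rescale Scale both tables to the reference proton first
#'   (the convention under which textbook worked examples are reproduced);
#'   `FALSE` uses raw intensities.
#' @param epsilon Relative denominator guard.
#' @return A `factor_set` data frame (`proton_id`, `raw`,
#'   `normalized_pct`) with attributes `kind = "WLOGSY"` and `reference`.
#' @export
wlogsy_factors <- function(free, bound, rescale = TRUE, epsilon = 1e-12) {
  check_matched_pair(free, bound, "WLOGSY")
  if (!isTRUE(all.equal(free$mixing_time_s[1], bound$mixing_time_s[1])))
    stop_data("free and bound tables were recorded at different mixing times")
  ref <- select_reference_proton(free)
  if (rescale) {
    sc <- scale_spectra_pair(free, bound, ref)
    free <- sc$free; bound <- sc$bound
  }
  protons <- free$proton_id
  f <- intensities_of(free, protons)
  b <- intensities_of(bound, protons)
  raw <- wlogsy_factor_raw(b, f, epsilon = epsilon * abs(f[[ref]]),
                           proton_id = protons)
  new_factor_set(protons, raw, kind = "WLOGSY", reference = ref,
                 ligand_id = bound$ligand_id[1],
                 protein_id = bound$protein_id[1])
}

#' Compute the per-proton STD factor set
#'
#' `R = (I_STD / I_1D) x 100` per proton, then normalised with the largest
#' factor at 100%.
#'
#' @param std STD [intensity_table()].
#' @param oned Reference 1D [intensity_table()] over the same protons.
#' @param epsilon Relative denominator guard (fraction of the strongest
#'   1D magnitude).
#' @return A `factor_set` with `kind = "STD"`; the reference attribute is
#'   the proton with the largest raw STD factor.
#' @export
std_factors <- function(std, oned, epsilon = 1e-12) {
  stopifnot(inherits(std, "intensity_table"), inherits(oned, "intensity_table"))
  protons <- std$proton_id
  if (!setequal(protons, oned$proton_id))
    stop_data("STD and 1D tables cover different protons")
  s <- intensities_of(std, protons)
  o <- intensities_of(oned, protons)
  floor_ <- epsilon * max(abs(o))
  bad <- abs(o) <= floor_
  if (any(bad))
    stop_numeric("STD factor undefined (zero 1D intensity) for proton ",
                 paste(protons[bad], collapse = ", "))
  raw <- 100 * abs(s) / abs(o)
  ref <- protons[order(-raw, protons)][1]
  new_factor_set(protons, raw, kind = "STD", reference = ref,
                 ligand_id = std$ligand_id[1], protein_id = std$protein_id[1])
}

check_matched_pair <- function(free, bound, experiment) {
  stopifnot(inherits(free, "intensity_table"), inherits(bound, "intensity_table"))
  if (free$experiment[1] != experiment || bound$experiment[1] != experiment)
    stop_data("expected a pair of ", experiment, " tables")
  if (isTRUE(free$protein_present[1]) || !isTRUE(bound$protein_present[1]))
    stop_data("expected free (no protein) and bound (with protein) tables, ",
              "in that order")
  if (!setequal(free$proton_id, bound$proton_id))
    stop_data("free and bound tables cover different protons: ",
              paste(union(setdiff(free$proton_id, bound$proton_id),
                          setdiff(bound$proton_id, free$proton_id)),
                    collapse = ", "))
  invisible(TRUE)
}

#' Serialise a factor set
#'
#' Writes `<prefix>.tsv` (proton_id, raw, normalized_pct, kind, reference)
#' and `<prefix>.json`.
#'
#' @param fs A `factor_set`.
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_factor_set <- function(fs, prefix) {
  stopifnot(inherits(fs, "factor_set"))
  tsv <- paste0(prefix, ".tsv"); json <- paste0(prefix, ".json")
  df <- as.data.frame(fs)
  df$kind <- attr(fs, "kind"); df$reference <- attr(fs, "reference")
  utils::write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(kind = attr(fs, "kind"), reference = attr(fs, "reference"),
         ligand_id = attr(fs, "ligand_id"), protein_id = attr(fs, "protein_id"),
         factors = as.data.frame(fs)),
    json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, json))
}
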