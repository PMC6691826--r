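# Mixing-time series analysis.
#
# Protein-mediated WaterLOGSY transfer relies on spin diffusion and builds
# up slowly, so structural analysis uses long mixing times (~1.5 s).
# Chemical exchange through ligand labile protons remains efficient at
# short mixing times; a proton within ~5 Angstrom of an exchangeable proton
# therefore gains *relative* intensity as the mixing time drops, and its
# apparent solvent exposure at short mixing times is an artifact.

#' Assemble a mixing-time series
#'
#' @param tables List of WaterLOGSY [intensity_table()]s of the same sample
#'   at two or more distinct mixing times (the standard protocol records
#'   1.5, 0.75 and 0.25 s).
#' @param reference Reference proton id; default = proton with the
#'   strongest intensity at the longest mixing time.
#' @return An object of class `mixing_series` (tables sorted by decreasing
#'   mixing time).
#' @export
mixing_series <- function(tables, reference = NULL) {
  if (!is.list(tables) || length(tables) < 2)
    stop_data("series required: provide intensity tables at >= 2 mixing times")
  lapply(tables, function(t) stopifnot(inherits(t, "intensity_table")))
  times <- vapply(tables, function(t) t$mixing_time_s[1], numeric(1))
  if (anyNA(times) || any(duplicated(times)))
    stop_data("each table needs a distinct mixing_time_s")
  ord <- order(times, decreasing = TRUE)
  tables <- tables[ord]; times <- times[ord]
  protons <- tables[[1]]$proton_id
  for (t in tables[-1])
    if (!setequal(t$proton_id, protons))
      stop_data("tables in a mixing series must cover the same protons")
  if (is.null(reference)) {
    longest <- tables[[1]]
    reference <- longest$proton_id[order(-abs(longest$intensity),
                                         longest$proton_id)][1]
  }
  if (!reference %in% protons)
    stop_data("reference proton ", reference, " not present in the series")
  structure(list(tables = tables, mixing_times_s = times,
                 reference = reference,
                 ligand_id = tables[[1]]$ligand_id[1],
                 protein_id = tables[[1]]$protein_id[1]),
            class = "mixing_series")
}

#' @export
print.mixing_series <- function(x, ...) {
  cat(sprintf("<mixing_series> %d mixing times (%s s), reference %s\n",
              length(x$mixing_times_s),
              paste(x$mixing_times_s, collapse = ", "), x$reference))
  invisible(x)
}

#' Per-proton intensity ratios to the reference across mixing times
#'
#' `r(tau_m) = I_proton(tau_m) / I_ref(tau_m)`; being a ratio within each
#' spectrum, the profile is invariant to uniform rescaling of any single
#' table.
#'
#' @param series A [mixing_series()].
#' @return Numeric matrix, protons x mixing times (columns named by the
#'   mixing time in seconds, decreasing).
#' @export
relative_profile <- function(series) {
  stopifnot(inherits(series, "mixing_series"))
  protons <- series$tables[[1]]$proton_id
  prof <- vapply(series$tables, function(tbl) {
    iref <- intensities_of(tbl, series$reference)
    if (iref == 0)
      stop_numeric("reference proton ", series$reference,
                   " has zero intensity at mixing time ",
                   tbl$mixing_time_s[1], " s")
    intensities_of(tbl, protons) / iref
  }, numeric(length(protons)))
  prof <- matrix(prof, nrow = length(protons),
                 dimnames = list(protons, format(series$mixing_times_s)))
  prof
}

#' Flag protons whose relative intensity grows at short mixing times
#'
#' The labile-proton artifact is directional: a proton is flagged when its
#' relative intensity at the shortest mixing time exceeds the value at the
#' longest by more than `trend_tol` (fractional). The recommended mixing
#' time for structural analysis is always the longest available, where
#' protein-mediated spin diffusion dominates over exchange transfer.
#'
#' @param profile Matrix from [relative_profile()] (columns ordered by
#'   decreasing mixing time).
#' @param trend_tol Fractional increase that counts as a trend.
#' @return A list with `flags` (named logical), `recommended_mixing_time_s`
#'   (largest mixing time) and `table` (per-proton ratios and flag).
#' @export
exchange_influence_flags <- function(profile, trend_tol = 0.15) {
  if (is.null(dim(profile)) || ncol(profile) < 2)
    stop_data("series required: profiles at >= 2 mixing times")
  r_long <- profile[, 1]
  r_short <- profile[, ncol(profile)]
  flags <- (r_short - r_long) > trend_tol * abs(r_long)
  times <- suppressWarnings(as.numeric(colnames(profile)))
  rec <- if (anyNA(times)) NA_real_ else max(times)
  tbl <- data.frame(proton_id = rownames(profile),
                    ratio_longest = unname(r_long),
                    ratio_shortest = unname(r_short),
                    flagged = unname(flags),
                    stringsAsFactors = FALSE)
  list(flags = flags, recommended_mixing_time_s = rec, table = tbl)
}

#' Cross-check exchange flags against labile-proximity annotations
#'
#' A flagged proton should carry a `near_labile` (or `is_labile`)
#' annotation and vice versa; discordant protons either reveal a missing
#' annotation or an unexplained mixing-time trend.
#'
#' @param flags Named logical vector (from [exchange_influence_flags()]).
#' @param assignments A [proton_assignments()] table.
#' @return A list with `table` (per-proton flag, annotation, concordance)
#'   and `discordant` proton ids.
#' @export
cross_check_assignments <- function(flags, assignments) {
  assignments <- validate_assignments(as.data.frame(assignments))
  protons <- names(flags)
  i <- match(protons, assignments$proton_id)
  if (anyNA(i))
    stop_data("no assignment for proton ",
              paste(protons[is.na(i)], collapse = ", "))
  annotated <- assignments$near_labile[i] | assignments$is_labile[i]
  tbl <- data.frame(proton_id = protons, flagged = unname(flags),
                    near_labile = annotated,
                    concordant = unname(flags) == annotated,
                    stringsAsFactors = FALSE)
  list(table = tbl, discordant = tbl$proton_id[!tbl$concordant])
}

#' Read a mixing-series manifest
#'
#' The manifest is a CSV/TSV with columns `path` (intensity-table file,
#' relative paths resolved against the manifest location) and
#' `mixing_time_s`.
#'
#' @param path Manifest file.
#' @param reference Optional reference proton id.
#' @return A [mixing_series()].
#' @export
read_mixing_series <- function(path, reference = NULL) {
  man <- read_delim_auto(path)
  if (!all(c("path", "mixing_time_s") %in% names(man)))
    stop_data("series manifest needs columns: path, mixing_time_s")
  base <- dirname(normalizePath(path))
  tables <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    tbl <- read_intensity_table(p)
    tbl$mixing_time_s <- as.numeric(man$mixing_time_s[i])
    tbl
  })
  mixing_series(tables, reference = reference)
}
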