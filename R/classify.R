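# Case classification and epitope mapping.
#
# A free/bound WaterLOGSY pair falls into one of four canonical scenarios:
#   Case 1 - every peak flips sign with unchanged relative intensity
#            (nonspecific binding, full burial, or no specifically exposed
#            proton; the three explanations cannot be told apart).
#   Case 2 - every peak flips sign but at least one is relatively weaker:
#            that proton is solvent-exposed.
#   Case 3 - mixed signs (typical of low-molecular-weight receptors with
#            reduced spin diffusion); negative-staying protons are exposed.
#   Case 4 - no peak flips sign (large ligand/protein ratio on a small
#            receptor); protons with unchanged intensity are exposed,
#            attenuated ones are buried.
# In every non-degenerate case the smallest normalised WLOGSY factor marks
# the most solvent-exposed proton.

EXPOSURE_LEVELS <- c("exposed", "intermediate", "buried", "no_call")

CASE1_NOTE <- paste("multiple binding orientations, full burial, or no",
                    "specifically exposed proton; indistinguishable from",
                    "WaterLOGSY alone")

#' Per-proton sign pattern of a free/bound pair
#'
#' Compares the sign of each proton's intensity between the scaled free and
#' bound tables. A proton is `flipped` when the signs are opposite and both
#' magnitudes clear the noise floor, `same` when the signs agree, and
#' `ambiguous` when either magnitude is at or below the floor.
#'
#' @param free,bound Matched WaterLOGSY [intensity_table()]s (scaled; the
#'   tables are rescaled to the reference proton when `rescale = TRUE`).
#' @param noise_floor Fraction of the reference magnitude below which an
#'   intensity is indistinguishable from noise.
#' @param rescale Scale the pair to the free-state reference proton first.
#' @return Named character vector in `{"flipped","same","ambiguous"}`.
#' @export
sign_pattern <- function(free, bound, noise_floor = 0.05, rescale = TRUE) {
  check_matched_pair(free, bound, "WLOGSY")
  ref <- select_reference_proton(free)
  if (rescale) {
    sc <- scale_spectra_pair(free, bound, ref)
    free <- sc$free; bound <- sc$bound
  }
  floor_ <- noise_floor * abs(intensities_of(free, ref))
  protons <- free$proton_id
  f <- intensities_of(free, protons)
  b <- intensities_of(bound, protons)
  out <- ifelse(abs(f) <= floor_ | abs(b) <= floor_, "ambiguous",
                ifelse(sign(f) == sign(b), "same", "flipped"))
  stats::setNames(out, protons)
}

#' Classify a free/bound pair into Case 1-4
#'
#' The four predicates partition the non-degenerate pattern space:
#' Case 1 = all flipped with uniform (within `uniformity_tol` of 100%)
#' normalised factors; Case 2 = all flipped with at least one factor below
#' `100 - uniformity_tol`; Case 3 = mixed signs; Case 4 = no flips.
#' Ambiguous protons are excluded from the predicates; an all-ambiguous
#' pattern raises an error advising more protein or more scans.
#'
#' @param patterns Output of [sign_pattern()].
#' @param factors Matching `factor_set` from [wlogsy_factors()].
#' @param uniformity_tol Percent tolerance for "uniform" factors.
#' @return A list of class `case_label` with elements `value` (1-4) and
#'   `rationale`.
#' @export
classify_case <- function(patterns, factors, uniformity_tol = 10) {
  stopifnot(inherits(factors, "factor_set"))
  pats <- patterns[patterns != "ambiguous"]
  if (length(pats) == 0)
    stop_data("all protons are below the noise floor; no classification ",
              "possible - consider higher protein concentration or more scans")
  pct <- stats::setNames(factors$normalized_pct, factors$proton_id)[names(pats)]
  all_flipped <- all(pats == "flipped")
  all_same <- all(pats == "same")
  if (all_flipped && all(pct >= 100 - uniformity_tol)) {
    value <- 1L
    rationale <- paste0("all peaks flip sign with uniform factors (min ",
                        sprintf("%.3g", min(pct)), "%): ", CASE1_NOTE)
  } else if (all_flipped) {
    value <- 2L
    rationale <- paste0("all peaks flip sign; proton(s) ",
                        paste(names(pct)[pct < 100 - uniformity_tol],
                              collapse = ", "),
                        " show reduced relative intensity (solvent-exposed)")
  } else if (all_same) {
    value <- 4L
    rationale <- paste("no peak flips sign (large ligand/protein ratio or",
                       "low-MW receptor); attenuated protons are buried")
  } else {
    value <- 3L
    rationale <- paste0("mixed signs: proton(s) ",
                        paste(names(pats)[pats == "same"], collapse = ", "),
                        " keep the free-state sign (solvent-exposed; typical",
                        " of low-MW receptors with reduced spin diffusion)")
  }
  structure(list(value = value, rationale = rationale), class = "case_label")
}

#' @export
print.case_label <- function(x, ...) {
  cat(sprintf("Case %d: %s\n", x$value, x$rationale))
  invisible(x)
}

#' Call per-proton solvent exposure from normalised WLOGSY factors
#'
#' Case 1 yields `no_call` for every proton (binding has no differential
#' effect). For Cases 2-4 a proton is `exposed` when its normalised factor
#' is below `exposed_cut`, `buried` at or above `buried_cut`, and
#' `intermediate` otherwise.
#'
#' @param case A `case_label` from [classify_case()].
#' @param factors The matching `factor_set`.
#' @param exposed_cut,buried_cut Percent thresholds.
#' @return Named character vector of exposure calls.
#' @export
call_exposure <- function(case, factors, exposed_cut = 80, buried_cut = 95) {
  stopifnot(inherits(case, "case_label"), inherits(factors, "factor_set"))
  if (exposed_cut > buried_cut)
    stop_usage("exposed_cut must not exceed buried_cut")
  pct <- stats::setNames(factors$normalized_pct, factors$proton_id)
  if (case$value == 1L)
    return(stats::setNames(rep("no_call", length(pct)), names(pct)))
  out <- ifelse(pct < exposed_cut, "exposed",
                ifelse(pct >= buried_cut, "buried", "intermediate"))
  stats::setNames(out, names(pct))
}

#' Build an epitope map from a free/bound WaterLOGSY pair
#'
#' Runs the full per-pair pipeline: factor computation, sign-pattern
#' analysis, case classification, exposure calls, and (optionally) STD
#' reconciliation and labile-proton annotation.
#'
#' @param free,bound Matched WaterLOGSY [intensity_table()]s.
#' @param std,oned Optional STD and reference 1D tables for
#'   [reconcile_std()].
#' @param assignments Optional [proton_assignments()]; labile flags are
#'   copied into the map.
#' @param noise_floor,uniformity_tol,exposed_cut,buried_cut,agree_tol
#'   Thresholds, see the respective operations.
#' @param rescale Passed to [wlogsy_factors()] / [sign_pattern()].
#' @return An object of class `epitope_map`: list with `ligand_id`,
#'   `protein_id`, `case`, `table` (per-proton data frame), `notes`.
#' @export
map_epitope <- function(free, bound, std = NULL, oned = NULL,
                        assignments = NULL, noise_floor = 0.05,
                        uniformity_tol = 10, exposed_cut = 80,
                        buried_cut = 95, agree_tol = 20, rescale = TRUE) {
  factors <- wlogsy_factors(free, bound, rescale = rescale)
  patterns <- sign_pattern(free, bound, noise_floor = noise_floor,
                           rescale = rescale)
  case <- classify_case(patterns, factors, uniformity_tol = uniformity_tol)
  exposure <- call_exposure(case, factors, exposed_cut = exposed_cut,
                            buried_cut = buried_cut)
  protons <- factors$proton_id
  tbl <- data.frame(proton_id = protons,
                    wlogsy_normalized_pct = factors$normalized_pct,
                    sign_pattern = unname(patterns[protons]),
                    exposure = unname(exposure[protons]),
                    std_normalized_pct = NA_real_,
                    std_agrees = NA,
                    exchange_flag = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(assignments)) {
    i <- match(protons, assignments$proton_id)
    tbl$exchange_flag <- assignments$near_labile[i] | assignments$is_labile[i]
  }
  notes <- character(0)
  if (case$value == 1L) notes <- c(notes, paste0("Case 1 ambiguity: ", CASE1_NOTE))
  map <- structure(list(ligand_id = bound$ligand_id[1],
                        protein_id = bound$protein_id[1],
                        case = case, table = tbl, notes = notes,
                        reference = attr(factors, "reference"),
                        thresholds = list(noise_floor = noise_floor,
                                          uniformity_tol = uniformity_tol,
                                          exposed_cut = exposed_cut,
                                          buried_cut = buried_cut,
                                          agree_tol = agree_tol)),
                   class = "epitope_map")
  if (!is.null(std)) {
    if (is.null(oned))
      stop_usage("STD reconciliation requires the reference 1D table")
    map <- reconcile_std(map, std_factors(std, oned), agree_tol = agree_tol)
  }
  map
}

#' @export
print.epitope_map <- function(x, ...) {
  cat(sprintf("<epitope_map> %s%s\n", x$ligand_id,
              if (nzchar(x$protein_id)) paste0(" / ", x$protein_id) else ""))
  print(x$case)
  print.data.frame(x$table, ...)
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}

#' Reconcile a WaterLOGSY epitope map with STD factors
#'
#' Per proton the normalised WLOGSY and STD factors agree when they differ
#' by at most `agree_tol` percentage points. When STD calls a proton
#' exposed but WaterLOGSY does not, the map gains a recommendation to
#' repeat the WaterLOGSY at several mixing times (labile-proton suspicion);
#' a WaterLOGSY proton with no STD counterpart is noted as a possible
#' bound-water signal.
#'
#' @param map An `epitope_map`.
#' @param std_fs A `factor_set` of kind `"STD"`.
#' @param agree_tol Agreement tolerance in percentage points.
#' @param exposed_cut Threshold used for the STD-side exposure reading.
#' @return The annotated `epitope_map`.
#' @export
reconcile_std <- function(map, std_fs, agree_tol = 20, exposed_cut = 80) {
  stopifnot(inherits(map, "epitope_map"), inherits(std_fs, "factor_set"))
  std_pct <- stats::setNames(std_fs$normalized_pct, std_fs$proton_id)
  tbl <- map$table
  i <- match(tbl$proton_id, names(std_pct))
  tbl$std_normalized_pct <- unname(std_pct[tbl$proton_id])
  tbl$std_agrees <- abs(tbl$wlogsy_normalized_pct - tbl$std_normalized_pct) <=
    agree_tol
  no_std <- tbl$proton_id[is.na(i)]
  if (length(no_std) > 0)
    map$notes <- c(map$notes,
                   paste0("WaterLOGSY signal for ",
                          paste(no_std, collapse = ", "),
                          " has no STD counterpart: possible bound water",
                          " molecule"))
  std_exposed <- !is.na(tbl$std_normalized_pct) &
    tbl$std_normalized_pct < exposed_cut
  wl_exposed <- tbl$exposure == "exposed"
  suspicious <- std_exposed & !wl_exposed
  if (any(suspicious))
    map$notes <- c(map$notes,
                   paste0("proton(s) ",
                          paste(tbl$proton_id[suspicious], collapse = ", "),
                          " exposed by STD but not by WaterLOGSY: repeat",
                          " WaterLOGSY at long and short mixing times",
                          " (labile-proton suspicion)"))
  map$table <- tbl
  map
}

#' Compare the factor sets of two ligand analogues
#'
#' For weak-affinity ligands, the difference between normalised WLOGSY
#' factors of corresponding protons in two analogues reports whether a
#' chemical modification altered the binding mode.
#'
#' @param a,b `factor_set`s of the two analogues.
#' @param mapping Named character vector mapping proton ids of `a` to the
#'   corresponding ids of `b`; defaults to identity over the shared ids.
#' @param agree_tol Percentage-point threshold above which a shared proton
#'   counts as changed.
#' @return A list with `table` (per-proton a/b factors and signed
#'   difference b - a), `verdict` (`"binding mode altered"` /
#'   `"binding mode unchanged"`) and `changed` proton ids.
#' @export
compare_analogues <- function(a, b, mapping = NULL, agree_tol = 20) {
  stopifnot(inherits(a, "factor_set"), inherits(b, "factor_set"))
  if (is.null(mapping)) {
    shared <- intersect(a$proton_id, b$proton_id)
    mapping <- stats::setNames(shared, shared)
  }
  known_a <- names(mapping) %in% a$proton_id
  known_b <- mapping %in% b$proton_id
  drop <- !(known_a & known_b)
  if (any(drop)) {
    warning("unmapped proton(s) excluded from analogue comparison: ",
            paste(names(mapping)[drop], collapse = ", "), call. = FALSE)
    mapping <- mapping[!drop]
  }
  if (length(mapping) == 0)
    stop_data("no comparable protons between the two analogues")
  pa <- stats::setNames(a$normalized_pct, a$proton_id)[names(mapping)]
  pb <- stats::setNames(b$normalized_pct, b$proton_id)[unname(mapping)]
  diff_ <- unname(pb) - unname(pa)
  tbl <- data.frame(proton_a = names(mapping), proton_b = unname(mapping),
                    pct_a = unname(pa), pct_b = unname(pb),
                    difference = diff_, changed = abs(diff_) > agree_tol,
                    stringsAsFactors = FALSE)
  list(table = tbl,
       verdict = if (any(tbl$changed)) "binding mode altered"
                 else "binding mode unchanged",
       changed = tbl$proton_a[tbl$changed])
}
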