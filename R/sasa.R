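# Solvent-accessible surface area and comparison with WLOGSY factors.
#
# Per-proton SASA from a protonated complex structure provides an
# independent, structure-based reading of solvent exposure: protons with
# weak WLOGSY factors should be the most solvent-accessible ones, so the
# rank correlation between normalised factor and SASA is expected to be
# negative.

VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
DEFAULT_RADIUS <- 1.70

#' Build a structure model from atom data
#'
#' @param atom_name Atom names (e.g. `"H1"`, `"CA"`).
#' @param element Element symbols; missing entries are inferred from the
#'   atom name (with a warning).
#' @param x,y,z Coordinates (Angstrom).
#' @param is_ligand Logical: atom belongs to the ligand.
#' @param resid Residue/ligand tag.
#' @return Data frame of class `structure_model` with van der Waals radii
#'   assigned (H 1.20, C 1.70, N 1.55, O 1.52, S 1.80 Angstrom).
#' @export
structure_model <- function(atom_name, element = NA, x, y, z,
                            is_ligand = FALSE, resid = "") {
  element <- toupper(as.character(element))
  guess <- is.na(element) | element == "" | element == "NA"
  if (any(guess)) {
    element[guess] <- toupper(sub("^[0-9']*([A-Za-z]).*$", "\\1",
                                  atom_name[guess]))
    warning("element inferred from atom name for ",
            sum(guess), " atom(s)", call. = FALSE)
  }
  radius <- unname(VDW_RADII[element])
  radius[is.na(radius)] <- DEFAULT_RADIUS
  df <- data.frame(atom_name = as.character(atom_name), element = element,
                   resid = resid, x = as.numeric(x), y = as.numeric(y),
                   z = as.numeric(z), radius = radius,
                   is_ligand = is_ligand, stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(df[, c("x", "y", "z")]))))
    stop_data("non-finite coordinates in structure")
  class(df) <- c("structure_model", "data.frame")
  df
}

#' Parse a PDB file into a structure model
#'
#' ATOM records are treated as protein, HETATM records (excluding waters)
#' as ligand unless `ligand_resid` selects a residue name explicitly.
#' Ligand hydrogens must be present: factors are per-proton quantities and
#' SASA is computed on the hydrogen atoms themselves.
#'
#' @param path PDB file.
#' @param ligand_resid Optional residue name(s) identifying the ligand.
#' @return A [structure_model()].
#' @export
parse_structure <- function(path, ligand_resid = NULL) {
  if (!file.exists(path)) stop_usage("no such file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  is_lig <- if (is.null(ligand_resid)) {
    at$type == "HETATM" & !(at$resid %in% c("HOH", "WAT", "DOD"))
  } else at$resid %in% ligand_resid
  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  model <- structure_model(atom_name = at$elety, element = elem,
                           x = at$x, y = at$y, z = at$z,
                           is_ligand = is_lig, resid = at$resid)
  if (!any(model$is_ligand & model$element == "H"))
    stop_data("no ligand hydrogens found: protonate the structure upstream ",
              "(per-proton SASA is computed on explicit hydrogens)")
  model
}

# Deterministic quasi-uniform unit sphere point set (golden spiral).
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA with a rolling probe: each atom's solvent sphere of
#' radius `r_vdw + probe` is sampled with a fixed golden-spiral point set
#' and the accessible fraction is the share of points outside every
#' neighbouring solvent sphere. Deterministic for a given `n_points`.
#'
#' @param model A [structure_model()].
#' @param probe Probe radius (Angstrom, default 1.4 = water).
#' @param n_points Sphere sample points per atom (default 960).
#' @return Named numeric vector of per-atom SASA (Angstrom^2), in atom
#'   order, names = atom names.
#' @export
shrake_rupley <- function(model, probe = 1.4, n_points = 960) {
  stopifnot(inherits(model, "structure_model"))
  xyz <- as.matrix(model[, c("x", "y", "z")])
  rs <- model$radius + probe
  n <- nrow(xyz)
  pts <- golden_spiral_points(n_points)
  sasa <- numeric(n)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rs[i] + rs)^2 & seq_len(n) != i)
    p <- sweep(pts * rs[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (p[acc, 1] - xyz[j, 1])^2 + (p[acc, 2] - xyz[j, 2])^2 +
        (p[acc, 3] - xyz[j, 3])^2
      acc[acc] <- dj2 >= rs[j]^2
    }
    sasa[i] <- 4 * pi * rs[i]^2 * sum(acc) / n_points
  }
  stats::setNames(sasa, model$atom_name)
}

#' Per-ligand-proton SASA
#'
#' Convenience wrapper: [shrake_rupley()] on the full model, returning
#' only the ligand hydrogen atoms (per-proton accessibility; the hydrogen
#' atom alone, not its heavy-atom group).
#'
#' @inheritParams shrake_rupley
#' @return Named numeric vector over ligand hydrogens.
#' @export
ligand_proton_sasa <- function(model, probe = 1.4, n_points = 960) {
  s <- shrake_rupley(model, probe = probe, n_points = n_points)
  keep <- model$is_ligand & model$element == "H"
  if (!any(keep)) stop_data("model contains no ligand hydrogens")
  s[keep]
}

#' Compare WLOGSY factors with solvent accessibility
#'
#' Spearman rank correlation between normalised factors and per-proton
#' SASA. Weak factors should coincide with large SASA, so a consistent
#' data set yields a negative correlation; positive correlations are
#' flagged as inconsistent. Constant SASA (or factors) makes the rank
#' correlation undefined and is reported as not applicable.
#'
#' @param factors A `factor_set`.
#' @param sasa Named numeric vector of per-proton SASA (Angstrom^2);
#'   names matched against `factors$proton_id` (>= 3 shared protons
#'   required).
#' @return List with `spearman_rho`, `consistent` (rho < 0),
#'   `applicable`, and the per-proton `table`.
#' @export
factor_vs_sasa <- function(factors, sasa) {
  stopifnot(inherits(factors, "factor_set"))
  shared <- intersect(factors$proton_id, names(sasa))
  if (length(shared) < 3)
    stop_data("factor/SASA comparison requires >= 3 shared protons (got ",
              length(shared), ")")
  pct <- stats::setNames(factors$normalized_pct, factors$proton_id)[shared]
  sa <- sasa[shared]
  tbl <- data.frame(proton_id = shared, normalized_pct = unname(pct),
                    sasa_A2 = unname(sa), stringsAsFactors = FALSE)
  if (stats::sd(sa) == 0 || stats::sd(pct) == 0)
    return(list(spearman_rho = NA_real_, consistent = NA,
                applicable = FALSE, table = tbl,
                note = "constant SASA or factors: rank correlation not applicable"))
  rho <- stats::cor(pct, sa, method = "spearman")
  list(spearman_rho = rho, consistent = rho < 0, applicable = TRUE,
       table = tbl,
       note = if (rho >= 0)
         "positive factor/SASA correlation: inconsistent with solvent-exposure reading"
       else NULL)
}

#' Geometric structure model of a simulated spin system
#'
#' Maps a [spin_system()] to a [structure_model()] for SASA analysis:
#' ligand protons become ligand hydrogens, protein proxy protons become
#' protein carbons (their attached heavy atoms), labile sites become
#' ligand oxygens; the water pseudo-spin is not a structural atom.
#'
#' @param sys A [spin_system()].
#' @return A [structure_model()].
#' @export
as_structure_model <- function(sys) {
  stopifnot(inherits(sys, "spin_system"))
  s <- sys$sites[sys$sites$kind != "water", , drop = FALSE]
  element <- c(ligand_proton = "H", protein_proton = "C", labile = "O")[s$kind]
  structure_model(atom_name = s$site_id, element = element,
                  x = s$x, y = s$y, z = s$z,
                  is_ligand = s$kind %in% c("ligand_proton", "labile"),
                  resid = ifelse(s$kind == "protein_proton", "PRO", "LIG"))
}
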