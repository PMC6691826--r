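# Solomon-equation relaxation-matrix simulator.
#
# A toy ligand-protein-water spin system is propagated under the Solomon
# equations dM/dt = -R M for the magnetisation deviations from thermal
# equilibrium. The rate matrix R combines:
#   * homonuclear dipolar cross-relaxation sigma(r, tau_c) and
#     auto-relaxation rho(r, tau_c) between proton pairs (1/r^6 law,
#     Lorentzian spectral densities), and
#   * chemical exchange k_ex between ligand labile protons and water.
# Bulk water is one pseudo-spin with a large reservoir weight: the rest of
# the system barely depletes it, and its deviation decays with T1(water).
#
# The WaterLOGSY experiment inverts the water magnetisation; after a mixing
# time the ligand deviations are read out and displayed so that
# protein-mediated (slow-tumbling, negative-NOE) transfer gives positive
# peaks and direct bulk-water (fast-tumbling, positive-NOE) transfer gives
# negative peaks - the standard display convention for binder/non-binder
# discrimination.

# (mu0/(4 pi))^2 * gammaH^4 * hbar^2 / 10, in Angstrom^6 s^-2: the
# homonuclear dipolar prefactor, giving O(1-10) s^-1 rates at 2-3 A for
# correlation times of tens of ns.
DIPOLAR_K <- 5.6957e10

SITE_KINDS <- c("ligand_proton", "protein_proton", "water", "labile")

#' Lorentzian spectral density
#'
#' `J(omega) = tau_c / (1 + (omega tau_c)^2)`: the Fourier intensity of
#' isotropic rotational diffusion at correlation time `tau_c`.
#'
#' @param omega Angular frequency (rad/s), vectorised.
#' @param tau_c Rotational correlation time (s), > 0.
#' @return Spectral density in seconds.
#' @export
spectral_density <- function(omega, tau_c) {
  if (any(tau_c <= 0)) stop_data("tau_c must be > 0")
  tau_c / (1 + (omega * tau_c)^2)
}

#' Homonuclear dipolar cross-relaxation rate
#'
#' `sigma = K/r^6 * (6 J(2 omega) - J(omega = 0))`. The sign encodes the
#' NOE regime: positive for fast tumbling (`omega tau_c < sqrt(5)/2`),
#' negative for slow tumbling - the physical origin of the WaterLOGSY sign
#' dichotomy between free and protein-bound ligands.
#'
#' @param r_angstrom Internuclear distance in Angstrom (>= 1).
#' @param tau_c Correlation time (s).
#' @param field_mhz Proton Larmor frequency (MHz).
#' @return Rate in s^-1.
#' @export
cross_relaxation_rate <- function(r_angstrom, tau_c, field_mhz = 600) {
  if (any(r_angstrom < 1))
    stop_data("internuclear distance below 1 Angstrom is unphysical")
  omega <- 2 * pi * field_mhz * 1e6
  (DIPOLAR_K / r_angstrom^6) *
    (6 * spectral_density(2 * omega, tau_c) - spectral_density(0, tau_c))
}

#' Homonuclear dipolar auto-relaxation rate
#'
#' `rho = K/r^6 * (6 J(2 omega) + 3 J(omega) + J(0))`, the leakage a spin
#' experiences from one dipolar partner.
#'
#' @inheritParams cross_relaxation_rate
#' @return Rate in s^-1.
#' @export
auto_relaxation_rate <- function(r_angstrom, tau_c, field_mhz = 600) {
  if (any(r_angstrom < 1))
    stop_data("internuclear distance below 1 Angstrom is unphysical")
  omega <- 2 * pi * field_mhz * 1e6
  (DIPOLAR_K / r_angstrom^6) *
    (6 * spectral_density(2 * omega, tau_c) +
       3 * spectral_density(omega, tau_c) + spectral_density(0, tau_c))
}

#' Equilibrium bound fraction of a two-state binding equilibrium
#'
#' Exact quadratic solution of `P + L <-> PL` for the fraction of total
#' ligand in the complex.
#'
#' @param L_uM,P_uM Total ligand and protein concentrations (micromolar).
#' @param K_D_uM Dissociation constant (micromolar).
#' @return `[PL]/[L]_total` in `[0, 1]`.
#' @export
bound_fraction <- function(L_uM, P_uM, K_D_uM) {
  if (any(L_uM <= 0) || any(P_uM < 0) || any(K_D_uM <= 0))
    stop_data("concentrations must be positive (protein may be zero)")
  s <- L_uM + P_uM + K_D_uM
  pl <- (s - sqrt(s^2 - 4 * L_uM * P_uM)) / 2
  pmin(pmax(pl / L_uM, 0), 1)
}

#' Define a spin site
#'
#' @param site_id Unique label.
#' @param x,y,z Coordinates in Angstrom.
#' @param kind One of `"ligand_proton"`, `"protein_proton"`, `"water"`,
#'   `"labile"` (a ligand exchangeable proton).
#' @param k_ex_s Chemical-exchange rate with water (s^-1); only labile
#'   sites may have `k_ex_s > 0`.
#' @return One-row data frame.
#' @export
spin_site <- function(site_id, x, y, z, kind, k_ex_s = 0) {
  kind <- match.arg(kind, SITE_KINDS)
  if (k_ex_s < 0) stop_data("k_ex_s must be >= 0")
  if (k_ex_s > 0 && kind != "labile")
    stop_data("k_ex_s > 0 is only meaningful for labile sites")
  data.frame(site_id = site_id, x = x, y = y, z = z, kind = kind,
             k_ex_s = k_ex_s, stringsAsFactors = FALSE)
}

#' Assemble a spin system
#'
#' The simulator's description of one ligand-protein-water sample.
#'
#' @param sites Data frame of [spin_site()] rows with distinct positions.
#' @param tau_c_free Rotational correlation time of the free ligand (s).
#' @param tau_c_bound Correlation time of the complex (s); must exceed
#'   `tau_c_free`.
#' @param field_mhz Proton Larmor frequency (default 600).
#' @param ligand_conc_uM,protein_conc_uM Total concentrations (micromolar;
#'   defaults 400 and 20, i.e. a 20:1 ligand:protein ratio).
#' @param K_D_uM Dissociation constant (micromolar; default 330, a typical
#'   fragment affinity).
#' @param water_T1_s Longitudinal relaxation time of bulk water (s).
#' @param water_relative_pool Reservoir weight of the water pseudo-spin;
#'   back-transfer into water is scaled by its inverse.
#' @param hydration_distance_A Effective water-proton distance used for the
#'   isotropic solvation of the free ligand and for the immobilised
#'   hydration shell of the protein surface (Angstrom).
#' @param leak_s External relaxation leak added to every proton's
#'   auto-relaxation (s^-1).
#' @param ligand_id,protein_id Identifiers carried into emitted tables.
#' @return An object of class `spin_system`.
#' @export
spin_system <- function(sites, tau_c_free = 1e-10, tau_c_bound = 2e-8,
                        field_mhz = 600, ligand_conc_uM = 400,
                        protein_conc_uM = 20, K_D_uM = 330,
                        water_T1_s = 3.0, water_relative_pool = 1e4,
                        hydration_distance_A = 3.0, leak_s = 0.1,
                        ligand_id = "ligand", protein_id = "protein") {
  sites <- as.data.frame(sites)
  need <- c("site_id", "x", "y", "z", "kind", "k_ex_s")
  if (!all(need %in% names(sites)))
    stop_data("sites need columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(sites$site_id))
    stop_data("duplicate site_id in spin system")
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  if (anyDuplicated(round(xyz, 6)))
    stop_data("duplicate coordinates in spin system")
  if (!(tau_c_bound > tau_c_free && tau_c_free > 0))
    stop_data("need tau_c_bound > tau_c_free > 0")
  if (ligand_conc_uM <= 0 || protein_conc_uM < 0 || K_D_uM <= 0)
    stop_data("concentrations and K_D must be positive")
  structure(list(sites = sites, tau_c_free = tau_c_free,
                 tau_c_bound = tau_c_bound, field_mhz = field_mhz,
                 ligand_conc_uM = ligand_conc_uM,
                 protein_conc_uM = protein_conc_uM, K_D_uM = K_D_uM,
                 water_T1_s = water_T1_s,
                 water_relative_pool = water_relative_pool,
                 hydration_distance_A = hydration_distance_A,
                 leak_s = leak_s, ligand_id = ligand_id,
                 protein_id = protein_id),
            class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  k <- table(factor(x$sites$kind, levels = SITE_KINDS))
  cat(sprintf(paste0("<spin_system> %d sites (%s), tau_c %g/%g ns, %g MHz, ",
                     "L=%g uM P=%g uM K_D=%g uM\n"),
              nrow(x$sites),
              paste(sprintf("%d %s", as.integer(k), names(k)), collapse = ", "),
              x$tau_c_free * 1e9, x$tau_c_bound * 1e9, x$field_mhz,
              x$ligand_conc_uM, x$protein_conc_uM, x$K_D_uM))
  invisible(x)
}

# Pairwise coupling rules. Water-proton pairs are motionally limited by the
# bulk-water interaction (tau_c_free, geometric distance when bound,
# isotropic hydration distance when free); water-protein couplings stand
# for the immobilised surface/binding-site water (hydration distance at
# tau_c_bound). Everything else is geometric dipolar coupling at the
# state's correlation time.
pair_rule <- function(kind_i, kind_j, r_geom, sys, mode) {
  is_w <- kind_i == "water" | kind_j == "water"
  other <- ifelse(kind_i == "water", kind_j, kind_i)
  lig <- c("ligand_proton", "labile")
  r <- r_geom; tau <- NA_real_; zero <- FALSE
  if (is_w) {
    if (other == "protein_proton") {
      r <- sys$hydration_distance_A; tau <- sys$tau_c_bound
    } else {
      tau <- sys$tau_c_free
      if (mode %in% c("free", "free_presence")) r <- sys$hydration_distance_A
    }
  } else if (kind_i == "protein_proton" && kind_j == "protein_proton") {
    tau <- sys$tau_c_bound
  } else if (kind_i %in% lig && kind_j %in% lig) {
    tau <- if (mode == "bound") sys$tau_c_bound else sys$tau_c_free
  } else {  # ligand-protein pair
    if (mode == "free_presence") zero <- TRUE
    tau <- sys$tau_c_bound
  }
  list(r = r, tau = tau, zero = zero)
}

build_matrix_core <- function(sys, mode) {
  sites <- sys$sites
  if (mode == "free")
    sites <- sites[sites$kind != "protein_proton", , drop = FALSE]
  n <- nrow(sites)
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  R <- matrix(0, n, n, dimnames = list(sites$site_id, sites$site_id))
  rho_sum <- numeric(n)
  iw <- which(sites$kind == "water")
  pool <- sys$water_relative_pool
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    rule <- pair_rule(sites$kind[i], sites$kind[j],
                      sqrt(sum((xyz[i, ] - xyz[j, ])^2)), sys, mode)
    if (rule$zero) next
    sig <- cross_relaxation_rate(rule$r, rule$tau, sys$field_mhz)
    rho <- auto_relaxation_rate(rule$r, rule$tau, sys$field_mhz)
    R[i, j] <- R[i, j] + sig
    R[j, i] <- R[j, i] + sig
    rho_sum[i] <- rho_sum[i] + rho
    rho_sum[j] <- rho_sum[j] + rho
  }
  # reservoir scaling of all dipolar back-transfer into water + water T1
  for (w in iw) {
    notw <- setdiff(seq_len(n), iw)
    R[w, notw] <- R[w, notw] / pool
    R[w, w] <- R[w, w] + 1 / sys$water_T1_s + rho_sum[w] / pool
  }
  # chemical exchange labile <-> water (already reservoir-weighted)
  lab <- which(sites$k_ex_s > 0)
  for (i in lab) for (w in iw) {
    k <- sites$k_ex_s[i]
    R[i, i] <- R[i, i] + k
    R[i, w] <- R[i, w] - k
    R[w, w] <- R[w, w] + k / pool
    R[w, i] <- R[w, i] - k / pool
  }
  notw <- setdiff(seq_len(n), iw)
  diag(R)[notw] <- diag(R)[notw] + rho_sum[notw] + sys$leak_s
  structure(list(R = R, sites = sites, mode = mode, p_bound = NA_real_),
            class = "relaxation_matrix")
}

#' Build the Solomon relaxation matrix of a spin system
#'
#' Basis order = row order of `sys$sites` (protein sites dropped in the
#' free state); row/column names are the site ids. The
#' `"population_averaged"` state is the fast-exchange average
#' `p_b R_bound + (1 - p_b) R_free`, with the free-state matrix taken in
#' the presence of the (still slowly tumbling, water-coupled) protein but
#' with ligand-protein couplings switched off, and `p_b` from
#' [bound_fraction()].
#'
#' @param sys A [spin_system()].
#' @param state `"population_averaged"`, `"free"` or `"bound"`.
#' @return An object of class `relaxation_matrix` (elements `R`, `sites`,
#'   `mode`, `p_bound`).
#' @export
build_relaxation_matrix <- function(sys,
                                    state = c("population_averaged",
                                              "free", "bound")) {
  state <- match.arg(state)
  stopifnot(inherits(sys, "spin_system"))
  if (state == "free") return(build_matrix_core(sys, "free"))
  if (state == "bound") return(build_matrix_core(sys, "bound"))
  p_b <- bound_fraction(sys$ligand_conc_uM, sys$protein_conc_uM, sys$K_D_uM)
  b <- build_matrix_core(sys, "bound")
  f <- build_matrix_core(sys, "free_presence")
  structure(list(R = p_b * b$R + (1 - p_b) * f$R, sites = b$sites,
                 mode = "population_averaged", p_bound = p_b),
            class = "relaxation_matrix")
}

#' @export
print.relaxation_matrix <- function(x, ...) {
  cat(sprintf("<relaxation_matrix> %d sites, state %s", nrow(x$R), x$mode))
  if (!is.na(x$p_bound)) cat(sprintf(", p_bound = %.4f", x$p_bound))
  cat("\n")
  invisible(x)
}

#' Propagate magnetisation deviations under a relaxation matrix
#'
#' Solves `dM/dt = -R M` by matrix exponential: `M(tau) = expm(-R tau) M0`.
#' Deterministic; `tau_mix = 0` returns the initial deviation exactly.
#'
#' @param mat A `relaxation_matrix` (or plain square matrix).
#' @param initial_deviation Numeric vector in the matrix basis.
#' @param tau_mix Mixing time in seconds (>= 0).
#' @return Named numeric vector of deviations at `tau_mix`.
#' @export
propagate <- function(mat, initial_deviation, tau_mix) {
  R <- if (inherits(mat, "relaxation_matrix")) mat$R else as.matrix(mat)
  if (length(initial_deviation) != nrow(R))
    stop_data("initial deviation length does not match the matrix basis")
  if (tau_mix < 0) stop_data("tau_mix must be >= 0")
  if (tau_mix == 0)
    return(stats::setNames(as.numeric(initial_deviation), rownames(R)))
  out <- as.numeric(Matrix::expm(-R * tau_mix) %*% initial_deviation)
  stats::setNames(out, rownames(R))
}

#' Simulate a WaterLOGSY spectrum as a per-proton intensity table
#'
#' Initial condition: water deviation inverted (-1), every other site at
#' equilibrium. After `tau_mix` the ligand-proton deviations are read out
#' and displayed with the conventional sign (protein-mediated transfer
#' positive, free-ligand bulk-water transfer negative). With
#' `with_protein = FALSE` the free-state matrix (protein sites removed) is
#' used; otherwise the population-averaged matrix.
#'
#' @param sys A [spin_system()] with at least one water site and one
#'   ligand proton.
#' @param tau_mix Mixing time in seconds (protocol values: 1.5, 0.75,
#'   0.25).
#' @param with_protein Simulate the sample with the protein receptor.
#' @return An [intensity_table()] over the ligand protons (labile sites
#'   are exchange-dominated and not reported).
#' @export
simulate_waterlogsy <- function(sys, tau_mix = 1.5, with_protein = TRUE) {
  stopifnot(inherits(sys, "spin_system"))
  if (!any(sys$sites$kind == "water"))
    stop_data("spin system has no water site")
  if (!any(sys$sites$kind == "ligand_proton"))
    stop_data("spin system has no ligand proton")
  mat <- build_relaxation_matrix(sys, if (with_protein) "population_averaged"
                                      else "free")
  m0 <- stats::setNames(numeric(nrow(mat$R)), rownames(mat$R))
  m0[mat$sites$kind == "water"] <- -1
  m <- propagate(mat, m0, tau_mix)
  keep <- mat$sites$kind == "ligand_proton"
  intensity_table(-m[keep], proton_id = mat$sites$site_id[keep],
                  experiment = "WLOGSY", protein_present = with_protein,
                  mixing_time_s = tau_mix, ligand_id = sys$ligand_id,
                  protein_id = if (with_protein) sys$protein_id else "")
}

#' Simulate an STD experiment (simplified saturation model)
#'
#' Protein spins are clamped at full saturation (deviation -1) for the
#' whole saturation period; the ligand/water subsystem relaxes towards the
#' corresponding steady state, and the transferred saturation on each
#' ligand proton is reported together with a unit reference 1D table for
#' [std_factors()]. Transfer is larger for protons closer to protein sites
#' (1/r^6).
#'
#' @param sys A [spin_system()] with protein sites.
#' @param sat_time Saturation time in seconds (default 2).
#' @return List with `std` and `oned` [intensity_table()]s.
#' @export
simulate_std <- function(sys, sat_time = 2) {
  stopifnot(inherits(sys, "spin_system"))
  if (!any(sys$sites$kind == "protein_proton"))
    stop_data("STD simulation requires protein sites (bound-state geometry)")
  mat <- build_relaxation_matrix(sys, "population_averaged")
  ip <- which(mat$sites$kind == "protein_proton")
  rest <- setdiff(seq_len(nrow(mat$R)), ip)
  A <- mat$R[rest, rest, drop = FALSE]
  b <- rowSums(mat$R[rest, ip, drop = FALSE])  # source: -R[rest,P] %*% (-1)
  m <- if (sat_time == 0) numeric(length(rest)) else {
    x_star <- solve(A, b)
    as.numeric(x_star - Matrix::expm(-A * sat_time) %*% x_star)
  }
  names(m) <- rownames(A)
  keep <- mat$sites$kind[rest] == "ligand_proton"
  protons <- mat$sites$site_id[rest][keep]
  list(std = intensity_table(-m[keep], proton_id = protons,
                             experiment = "STD", protein_present = TRUE,
                             mixing_time_s = sat_time,
                             ligand_id = sys$ligand_id,
                             protein_id = sys$protein_id),
       oned = intensity_table(rep(1, length(protons)), proton_id = protons,
                              experiment = "ONED", protein_present = TRUE,
                              mixing_time_s = NA_real_,
                              ligand_id = sys$ligand_id,
                              protein_id = sys$protein_id))
}

#' Canonical three-proton worked-example fixtures
#'
#' The four textbook free/bound scenarios for a three-proton ligand, with
#' both spectra already scaled to the reference proton H1: Case 1 every
#' peak flips sign unchanged; Case 2 H3 flips but halves; Case 3 H3 keeps
#' its negative sign at half intensity; Case 4 nothing flips and H3
#' halves.
#'
#' @return Named list (`case1`..`case4`) of lists with elements `free`,
#'   `bound` ([intensity_table()]s) and `case` (expected label).
#' @export
make_case_fixtures <- function() {
  protons <- c("H1", "H2", "H3")
  free_int <- c(-1, -1, -1)
  bounds <- list(case1 = c(1, 1, 1), case2 = c(1, 1, 0.5),
                 case3 = c(1, 1, -0.5), case4 = c(-1, -1, -0.5))
  out <- lapply(seq_along(bounds), function(i) {
    id <- names(bounds)[i]
    list(free = intensity_table(free_int, proton_id = protons,
                                experiment = "WLOGSY",
                                protein_present = FALSE, mixing_time_s = 1.5,
                                ligand_id = id),
         bound = intensity_table(bounds[[i]], proton_id = protons,
                                 experiment = "WLOGSY",
                                 protein_present = TRUE, mixing_time_s = 1.5,
                                 ligand_id = id, protein_id = "receptor"),
         case = i)
  })
  stats::setNames(out, names(bounds))
}

#' Draw a random toy protein-ligand complex with known exposure truth
#'
#' Builds a spin system in which one ligand proton is engineered as the
#' most solvent-exposed: it points towards the water pseudo-spin while the
#' remaining protons face a pocket of protein proxy protons (each placed
#' 2.5-4.5 Angstrom from a buried proton). Concentrations follow the
#' fragment-screening regime: 400 uM ligand, ligand:protein ratio drawn in
#' 20:1-200:1, K_D log-uniform in 10-1000 uM, and the complex correlation
#' time uniform in 10-30 ns.
#'
#' @param seed Optional integer seed (local RNG state).
#' @param n_ligand Number of non-labile ligand protons (>= 3).
#' @param n_protein Number of protein proxy protons (default drawn in
#'   5..50).
#' @param labile Add a labile site 2.5 Angstrom from the exposed proton.
#' @param k_ex_s Exchange rate of that labile site (s^-1).
#' @return List with `system` ([spin_system()]), `exposed` (proton id of
#'   the engineered most-exposed proton) and `buried` (the remaining ids).
#' @export
random_toy_complex <- function(seed = NULL, n_ligand = 4, n_protein = NULL,
                               labile = FALSE, k_ex_s = 20) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (n_ligand < 3) stop_data("need at least 3 ligand protons")
  if (is.null(n_protein)) n_protein <- sample(5:50, 1)
  # exposed proton on the solvent (+z) side, the rest on a ring below
  jit <- function(n) stats::rnorm(n, 0, 0.2)
  k <- n_ligand - 1
  ang <- 2 * pi * seq_len(k) / k
  lig <- rbind(c(0, 0, 3),
               cbind(2.5 * cos(ang), 2.5 * sin(ang), rep(-0.5, k)))
  lig <- lig + cbind(jit(n_ligand), jit(n_ligand), jit(n_ligand))
  labels <- paste0("H", seq_len(n_ligand))
  perm <- sample(n_ligand)          # detach exposure truth from label order
  lig <- lig[order(perm), , drop = FALSE]
  exposed <- labels[perm[1]]
  # protein proxies: anchored below randomly chosen buried protons
  buried_xyz <- lig[labels != exposed, , drop = FALSE]
  placed <- lig
  prot <- matrix(NA_real_, n_protein, 3)
  for (i in seq_len(n_protein)) {
    anchor <- buried_xyz[sample(nrow(buried_xyz), 1), ]
    repeat {
      d <- stats::runif(1, 2.5, 4.5)
      u <- c(stats::rnorm(2), -abs(stats::rnorm(1)) - 0.3)
      u <- u / sqrt(sum(u^2))
      p <- anchor + d * u
      sep <- sqrt(rowSums(sweep(placed, 2, p)^2))
      if (p[3] < 0.5 && all(sep >= 1.5)) break
    }
    prot[i, ] <- p
    placed <- rbind(placed, p)
  }
  sites <- rbind(
    data.frame(site_id = labels, x = lig[, 1], y = lig[, 2], z = lig[, 3],
               kind = "ligand_proton", k_ex_s = 0),
    data.frame(site_id = paste0("P", seq_len(n_protein)),
               x = prot[, 1], y = prot[, 2], z = prot[, 3],
               kind = "protein_proton", k_ex_s = 0),
    data.frame(site_id = "W", x = 0, y = 0, z = 6, kind = "water",
               k_ex_s = 0))
  if (labile) {
    ex_xyz <- lig[labels == exposed, ]
    sites <- rbind(sites,
                   data.frame(site_id = "X1", x = ex_xyz[1] + 2.5,
                              y = ex_xyz[2], z = ex_xyz[3], kind = "labile",
                              k_ex_s = k_ex_s))
  }
  ratio <- stats::runif(1, 20, 200)
  sys <- spin_system(sites,
                     tau_c_free = 1e-10,
                     tau_c_bound = stats::runif(1, 1e-8, 3e-8),
                     ligand_conc_uM = 400,
                     protein_conc_uM = 400 / ratio,
                     K_D_uM = exp(stats::runif(1, log(10), log(1000))))
  list(system = sys, exposed = exposed, buried = setdiff(labels, exposed))
}

#' Deterministic demonstration complex for mixing-time analysis
#'
#' A three-proton ligand bound to a large receptor (50 ns correlation
#' time) under standard fragment-screening conditions (400 uM ligand,
#' 20 uM protein, K_D 330 uM). Protons H2 and H3 sit in a pocket of proxy
#' protons; H1 faces the solvent at the pocket rim, so it is the
#' solvent-exposed proton (smallest factor) at long mixing time. With
#' `with_labile = TRUE` an exchangeable site sits 2.5 Angstrom from H1:
#' exchange transfer remains efficient at short mixing times while
#' protein-mediated spin diffusion does not, so H1's relative intensity
#' grows as the mixing time drops and its apparent exposure is corrupted.
#' Without the labile site every proton is fed by the same protein
#' pathway and the relative intensities are mixing-time independent.
#'
#' @param with_labile Include the labile neighbour of H1.
#' @param k_ex_s Exchange rate of the labile site (s^-1).
#' @return A [spin_system()].
#' @export
demo_mixing_system <- function(with_labile = TRUE, k_ex_s = 20) {
  sites <- rbind(
    spin_site("H1", 0, 0, 3, "ligand_proton"),
    spin_site("H2", 2.5, 0, -0.5, "ligand_proton"),
    spin_site("H3", -2.5, 0, -0.5, "ligand_proton"),
    # pocket proxies cradling H2/H3
    spin_site("P1", 2.5, 0, -3.2, "protein_proton"),
    spin_site("P2", -2.5, 0, -3.2, "protein_proton"),
    spin_site("P3", 4.6, 0, -1.6, "protein_proton"),
    spin_site("P4", -4.6, 0, -1.6, "protein_proton"),
    spin_site("P5", 0, 2.8, -1.5, "protein_proton"),
    spin_site("P6", 0, -2.8, -1.5, "protein_proton"),
    spin_site("P7", 2.0, 2.0, -4.5, "protein_proton"),
    spin_site("P8", -2.0, -2.0, -4.5, "protein_proton"),
    # rim proxies giving the exposed H1 weak protein contact
    spin_site("P9", 1.8, 1.8, 1.2, "protein_proton"),
    spin_site("P10", -1.8, -1.8, 1.2, "protein_proton"),
    spin_site("W", 0, 0, 6, "water"))
  if (with_labile)
    sites <- rbind(sites, spin_site("X1", 0, 2.5, 3, "labile",
                                    k_ex_s = k_ex_s))
  spin_system(sites, tau_c_free = 1e-10, tau_c_bound = 5e-8,
              ligand_conc_uM = 400, protein_conc_uM = 20, K_D_uM = 330,
              ligand_id = if (with_labile) "labile_demo" else "plain_demo",
              protein_id = "large_receptor")
}

#' Write a spin system to JSON
#'
#' @param sys A [spin_system()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spin_system <- function(sys, path) {
  stopifnot(inherits(sys, "spin_system"))
  jsonlite::write_json(unclass(sys), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read a spin system from JSON
#'
#' @param path File written by [write_spin_system()].
#' @return A [spin_system()].
#' @export
read_spin_system <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(spin_system, x)
}
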