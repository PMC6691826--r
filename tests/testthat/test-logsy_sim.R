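test_that("spectral density has the Lorentzian closed form", {
  expect_equal(spectral_density(0, 1e-9), 1e-9)
  tau <- 2.5e-9
  expect_equal(spectral_density(1 / tau, tau), tau / 2)
  om <- seq(0, 1e10, length.out = 200)
  expect_true(all(diff(spectral_density(om, 5e-9)) < 0))
})

test_that("cross-relaxation changes sign at omega*tau_c = sqrt(5)/2", {
  omega <- 2 * pi * 600e6
  root <- uniroot(function(tc) cross_relaxation_rate(2, tc, 600),
                  interval = c(1e-11, 1e-8), tol = 1e-20)$root
  expect_equal(root * omega, sqrt(5) / 2, tolerance = 1e-6)
  # r^-6 law and the slow-tumbling sign
  expect_equal(cross_relaxation_rate(4, 1e-8) / cross_relaxation_rate(2, 1e-8),
               1 / 64)
  expect_lt(cross_relaxation_rate(2.5, 2e-8, 600), 0)
  expect_gt(cross_relaxation_rate(2.5, 1e-10, 600), 0)
  expect_error(cross_relaxation_rate(0.5, 1e-9), "unphysical",
               class = "wlogsy_data_error")
})

test_that("bound fraction solves the binding quadratic exactly", {
  expect_equal(bound_fraction(400, 0, 330), 0)
  expect_lt(bound_fraction(400, 20, 1e9), 1e-6)
  # independent bisection oracle on the mass-action residual
  # f(pl) = (L - pl)(P - pl)/K - pl, monotone from +LP/K to -min(L,P)
  bisect_pl <- function(L, P, K) {
    lo <- 0; hi <- min(L, P)
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if ((L - mid) * (P - mid) / K - mid > 0) lo <- mid else hi <- mid
    }
    mid / L
  }
  for (prm in list(c(400, 20, 330), c(400, 2, 1500), c(100, 50, 10))) {
    expect_equal(bound_fraction(prm[1], prm[2], prm[3]),
                 bisect_pl(prm[1], prm[2], prm[3]), tolerance = 1e-10)
  }
  # bounds respected
  set.seed(3)
  p <- bound_fraction(runif(50, 1, 1000), runif(50, 0.1, 100),
                      runif(50, 1, 5000))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("relaxation matrices match an independent pairwise loop", {
  set.seed(5)
  for (rep in 1:5) {
    xyz <- matrix(runif(18, 0, 8), 6, 3)
    while (min(dist(xyz)) < 1.6) xyz <- matrix(runif(18, 0, 8), 6, 3)
    sites <- data.frame(site_id = paste0("H", 1:6),
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        kind = "ligand_proton", k_ex_s = 0)
    # a free-state system with no water: pure dipolar block at tau_c_free
    sys <- spin_system(rbind(sites,
                             data.frame(site_id = "W", x = 50, y = 50, z = 50,
                                        kind = "water", k_ex_s = 0)),
                       tau_c_free = 3e-9, tau_c_bound = 2e-8, leak_s = 0.1)
    R <- build_relaxation_matrix(sys, "free")$R[1:6, 1:6]
    oracle <- brute_force_dipolar_matrix(xyz, 3e-9, 600, leak = 0.1)
    # water at 50 A contributes the hydration-shell coupling to the diagonal
    # and off-diagonal water column only; the proton block must match the
    # brute-force loop up to that uniform hydration auto-relaxation term
    hyd <- auto_relaxation_rate(sys$hydration_distance_A, 3e-9, 600)
    expect_equal(unname(R - diag(hyd, 6)), oracle, tolerance = 1e-12)
  }
})

test_that("dipolar blocks are symmetric and exchange conserves weighted total", {
  sys <- demo_mixing_system(TRUE, k_ex_s = 25)
  mat <- build_relaxation_matrix(sys, "population_averaged")
  R <- mat$R
  notw <- which(mat$sites$kind != "water")
  expect_equal(R[notw, notw], t(R[notw, notw]))
  # k_ex-only limit: weighted deviation (pool * water + labile) is conserved
  sites <- rbind(spin_site("X1", 0, 0, 0, "labile", k_ex_s = 10),
                 spin_site("W", 0, 0, 100, "water"))
  s2 <- spin_system(sites, tau_c_free = 1e-10, tau_c_bound = 2e-8,
                    water_T1_s = 1e12, leak_s = 0, water_relative_pool = 500)
  R2 <- build_relaxation_matrix(s2, "bound")$R  # geometric water distance
  # strip the (negligible but nonzero) long-range dipolar part
  R2[abs(R2) < 1e-9] <- 0
  w <- c(1, 500)  # labile weight 1, water pool weight 500
  expect_equal(as.numeric(w %*% R2), c(0, 0), tolerance = 1e-9)
  m <- propagate(R2, c(1, 0), 0.3)
  expect_equal(sum(m * w), 1, tolerance = 1e-6)
})

test_that("propagation matches the two-spin closed form and an ODE oracle", {
  # closed form, 1e-10 relative
  rho1 <- 1.3; rho2 <- 0.7; sigma <- -0.9
  R <- two_spin_matrix(rho1, rho2, sigma)
  m0 <- c(1, -0.25)
  for (t in c(0.1, 0.5, 1.5)) {
    expect_equal(propagate(R, m0, t),
                 two_spin_closed_form(rho1, rho2, sigma, m0, t),
                 tolerance = 1e-10)
  }
  expect_equal(propagate(R, m0, 0), m0)  # exact at tau = 0

  # adaptive ODE oracle on random 8-spin systems, 1e-8 relative
  skip_if_not_installed("deSolve")
  set.seed(9)
  for (rep in 1:4) {
    A <- matrix(rnorm(64, sd = 0.5), 8, 8)
    A <- (A + t(A)) / 2
    diag(A) <- abs(diag(A)) + rowSums(abs(A)) # diagonally dominant, stable
    m0 <- rnorm(8)
    got <- propagate(A, m0, 0.8)
    ode <- deSolve::ode(y = m0, times = c(0, 0.8),
                        func = function(t, y, p) list(-as.numeric(A %*% y)),
                        rtol = 1e-12, atol = 1e-14)
    expect_equal(unname(got), unname(ode[2, -1]), tolerance = 1e-8)
  }
})

test_that("WaterLOGSY signs discriminate free from bound ligands", {
  tc <- random_toy_complex(seed = 101)
  free <- simulate_waterlogsy(tc$system, 1.5, with_protein = FALSE)
  expect_true(all(free$intensity < 0))      # fast tumbling: negative peaks

  # bound-dominated regime: slow tumbling, high occupancy
  sys_hi <- tc$system
  sys_hi$protein_conc_uM <- 400; sys_hi$K_D_uM <- 1
  bound <- simulate_waterlogsy(sys_hi, 1.5, with_protein = TRUE)
  pocket <- intersect(tc$buried, bound$proton_id)
  expect_true(all(bound$intensity[bound$proton_id %in% pocket] > 0))
})

test_that("bound intensity grows with the receptor correlation time", {
  tc <- random_toy_complex(seed = 77)
  mag <- vapply(c(5e-9, 2e-8, 8e-8), function(tcb) {
    sys <- tc$system; sys$tau_c_bound <- tcb
    b <- simulate_waterlogsy(sys, 1.5, TRUE)
    max(abs(b$intensity[b$proton_id %in% tc$buried]))
  }, numeric(1))
  expect_true(all(diff(mag) > 0))
})

test_that("matrix state limits behave: p_b = 0 reduces to the free matrix", {
  tc <- random_toy_complex(seed = 13)
  sys <- tc$system
  sys$protein_conc_uM <- 1e-12   # vanishing occupancy
  avg <- build_relaxation_matrix(sys, "population_averaged")
  fre <- build_relaxation_matrix(sys, "free")
  # the ligand/water block reduces to the free matrix (the water diagonal
  # keeps its protein-hydration leak, which exists with or without binding)
  lig <- avg$sites$site_id[avg$sites$kind %in% c("ligand_proton", "labile")]
  ids <- c(lig, avg$sites$site_id[avg$sites$kind == "water"])
  expect_equal(avg$R[lig, ids], fre$R[lig, ids], tolerance = 1e-6)
  # two-spin reduction: off-diagonal equals the cross-relaxation rate
  s2 <- spin_system(rbind(spin_site("H1", 0, 0, 0, "ligand_proton"),
                          spin_site("H2", 0, 0, 2.5, "ligand_proton"),
                          spin_site("W", 0, 0, 60, "water")),
                    tau_c_free = 4e-9, tau_c_bound = 2e-8)
  Rf <- build_relaxation_matrix(s2, "free")$R
  expect_equal(Rf["H1", "H2"], cross_relaxation_rate(2.5, 4e-9, 600))
})

test_that("the engineered exposed proton earns the smallest factor end-to-end", {
  hits <- 0; n <- 40
  for (s in 1:n) {
    tc <- random_toy_complex(seed = 4000 + s)
    free <- simulate_waterlogsy(tc$system, 1.5, FALSE)
    bound <- simulate_waterlogsy(tc$system, 1.5, TRUE)
    fs <- wlogsy_factors(free, bound, rescale = FALSE)
    hits <- hits + (fs$proton_id[which.min(fs$normalized_pct)] == tc$exposed)
  }
  expect_gte(hits / n, 0.95)
})

test_that("STD transfer follows protein proximity and vanishes at zero time", {
  sys <- demo_mixing_system(with_labile = FALSE)
  res <- simulate_std(sys, sat_time = 2)
  s <- setNames(res$std$intensity, res$std$proton_id)
  expect_gt(s[["H2"]], s[["H1"]])    # pocket proton gets more saturation
  expect_gt(s[["H3"]], s[["H1"]])
  expect_true(all(s > 0))
  z <- simulate_std(sys, sat_time = 0)
  expect_equal(z$std$intensity, rep(0, 3))
  expect_error(simulate_std(spin_system(
    rbind(spin_site("H1", 0, 0, 0, "ligand_proton"),
          spin_site("W", 0, 0, 3, "water"))), 2),
    "protein", class = "wlogsy_data_error")

  # STD-based and WaterLOGSY-based exposure agree on the demo complex
  wl <- wlogsy_factors(simulate_waterlogsy(sys, 1.5, FALSE),
                       simulate_waterlogsy(sys, 1.5, TRUE), rescale = FALSE)
  st <- std_factors(res$std, res$oned)
  expect_equal(wl$proton_id[which.min(wl$normalized_pct)],
               st$proton_id[which.min(st$normalized_pct)])
})

test_that("spin systems validate and serialise", {
  expect_error(spin_system(rbind(spin_site("A", 0, 0, 0, "ligand_proton"),
                                 spin_site("B", 0, 0, 0, "water"))),
               "duplicate coordinates", class = "wlogsy_data_error")
  expect_error(spin_site("X", 0, 0, 0, "ligand_proton", k_ex_s = 5),
               "labile", class = "wlogsy_data_error")
  expect_error(spin_system(spin_site("A", 0, 0, 0, "ligand_proton"),
                           tau_c_free = 1e-8, tau_c_bound = 1e-9),
               "tau_c", class = "wlogsy_data_error")
  sys <- demo_mixing_system(TRUE)
  p <- withr::local_tempfile(fileext = ".json")
  write_spin_system(sys, p)
  back <- read_spin_system(p)
  expect_equal(back$sites, sys$sites)
  expect_equal(back$tau_c_bound, sys$tau_c_bound)
  expect_error(simulate_waterlogsy(spin_system(
    rbind(spin_site("H1", 0, 0, 0, "ligand_proton"),
          spin_site("H2", 0, 0, 2.5, "ligand_proton"))), 1.5, FALSE),
    "water", class = "wlogsy_data_error")
})
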