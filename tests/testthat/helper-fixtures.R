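# Shared fixture builders (everything generated in code; no binary files).

wl_table <- function(intensity, protein_present = FALSE, tau = 1.5,
                     protons = paste0("H", seq_along(intensity)), ...) {
  intensity_table(intensity, proton_id = protons, experiment = "WLOGSY",
                  protein_present = protein_present, mixing_time_s = tau, ...)
}

# Lorentzian line of unit area: (1/pi) * gamma / ((x - x0)^2 + gamma^2)
lorentzian <- function(x, x0, gamma, area = 1) {
  area * (gamma / pi) / ((x - x0)^2 + gamma^2)
}

# A tiny two-spin Solomon system (no water bookkeeping) for closed-form
# propagation checks.
two_spin_matrix <- function(rho1, rho2, sigma) {
  matrix(c(rho1, sigma, sigma, rho2), 2, 2)
}

# Closed-form solution of dM/dt = -R M for the symmetric 2x2 Solomon
# matrix, via eigen decomposition worked by hand.
two_spin_closed_form <- function(rho1, rho2, sigma, m0, t) {
  mean_r <- (rho1 + rho2) / 2
  delta <- (rho1 - rho2) / 2
  mu <- sqrt(delta^2 + sigma^2)
  l1 <- mean_r + mu; l2 <- mean_r - mu
  # eigenvectors of [[rho1, sigma], [sigma, rho2]]
  v1 <- c(delta + mu, sigma); v2 <- c(delta - mu, sigma)
  V <- cbind(v1 / sqrt(sum(v1^2)), v2 / sqrt(sum(v2^2)))
  coef <- solve(V, m0)
  as.numeric(V %*% (coef * exp(-c(l1, l2) * t)))
}

# Independent brute-force relaxation-matrix builder for random geometries:
# plain pairwise loop over proton sites only (no water, no exchange),
# mirroring the documented dipolar rules at a single correlation time.
brute_force_dipolar_matrix <- function(xyz, tau_c, field_mhz, leak = 0.1) {
  n <- nrow(xyz)
  R <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      R[i, j] <- cross_relaxation_rate(r, tau_c, field_mhz)
      R[i, i] <- R[i, i] + auto_relaxation_rate(r, tau_c, field_mhz)
    }
  }
  diag(R) <- diag(R) + leak
  R
}
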