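# Shared fixtures and independent oracles for the test suite.

# A portal tree with round millimeter dimensions, any anatomy type.
make_tree <- function(anatomy_type = 1,
                      sv_diameter = 0.012, sv_length = 0.100,
                      sv_tortuosity = 1.3) {
  p <- default_vessel_params()
  p$diameters["SV"] <- sv_diameter
  p$lengths["SV"] <- sv_length
  p$tortuosities["SV"] <- sv_tortuosity
  build_tree(p$diameters, p$lengths, p$tortuosities, anatomy_type)
}

# Assemble a WSS field directly from areas (cm^2) and stresses (Pa),
# bypassing the hemodynamics pipeline.
make_field <- function(areas_cm2, tau_pa) {
  stopifnot(length(areas_cm2) == length(tau_pa))
  n <- length(areas_cm2)
  structure(list(strips = data.frame(
    segment_id = rep("X", n),
    axial_position = (seq_len(n) - 0.5) / n,
    width_m = rep(1e-3, n), radius_m = rep(5e-3, n),
    area_m2 = areas_cm2 / 1e4, tau_w_pa = tau_pa
  )), class = "wss_field")
}

# Independent brute-force ALWSS oracle: explicit strip-by-strip scan.
brute_alwss_cm2 <- function(field, threshold) {
  kept <- numeric(0)
  for (i in seq_len(nrow(field$strips))) {
    if (field$strips$tau_w_pa[i] < threshold)
      kept <- c(kept, field$strips$area_m2[i])
  }
  sum(kept) * 1e4
}

# Independent AUC oracle: Mann-Whitney with midranks (ties weighted 0.5).
mann_whitney_auc <- function(scores, labels) {
  r <- rank(scores, ties.method = "average")
  n1 <- as.numeric(sum(labels == 1))
  n0 <- as.numeric(sum(labels == 0))
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Poiseuille wall shear stress, the Newtonian closed form.
poiseuille_tau_w <- function(Q, R, mu) 4 * mu * Q / (pi * R^3)

newtonian_params <- function(mu = 0.0035)
  carreau_params(mu0 = mu, mu_inf = mu, lambda_s = 0, n = 1)

# Power-law fluid emulated by a Carreau fit deep in its power-law regime.
powerlaw_params <- function(K, n, lambda_s = 10)
  carreau_params(mu0 = K / lambda_s^(n - 1), mu_inf = 1e-9,
                 lambda_s = lambda_s, n = n)

powerlaw_tau_w <- function(Q, R, K, n)
  K * (Q * (3 * n + 1) / (n * pi * R^3))^n
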