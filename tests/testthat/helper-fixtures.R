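# shared fixtures and independent oracles for the test suite

fix_medium <- function(I = 0.1) ionic_medium(I)
fix_dpps <- function() charged_interface(-0.35)
fix_sphere600 <- function() dielectric_sphere(7, 10, 600)

# independent transfer-matrix (characteristic matrix) reflectivity oracle;
# sharp interfaces, same conventions as the Parratt implementation but a
# completely different formalism
tmm_reflectivity <- function(q, d, rho, rho_front, rho_back) {
  vapply(q, function(qi) {
    k0 <- qi / 2
    kz <- sqrt(as.complex(k0^2 - 4 * pi * (c(rho, rho_back) - rho_front)))
    kz <- c(complex(real = k0), kz)
    n <- length(d)
    M <- diag(2) + 0i
    for (j in 1:(n + 1)) {
      k1 <- kz[j]; k2 <- kz[j + 1]
      r <- (k1 - k2) / (k1 + k2)
      t <- 2 * k1 / (k1 + k2)
      I_mat <- matrix(c(1, r, r, 1), 2, 2) / t
      M <- M %*% I_mat
      if (j <= n) {
        ph <- exp(1i * kz[j + 1] * d[j])
        M <- M %*% matrix(c(1 / ph, 0, 0, ph), 2, 2)
      }
    }
    Mod(M[2, 1] / M[1, 1])^2
  }, numeric(1))
}

# standard two-contrast synthetic fixture: charged-bilayer truth at 10 mM
# with a 30 Angstrom exclusion distance embedded
standard_truth <- function(seed = 1) {
  med <- ionic_medium(0.01)
  kapA <- med$kappa * 1e-10
  # E0 such that the half-density distance sits 30 A off the hydrophobic
  # interface (z0 is t_h/2 = 4.5 A above it)
  E0 <- log(2) * exp(2 * kapA * (30 - 4.5))
  make_ssblm_truth("DOPC_DOPS", ionic_strength = 0.01, E0 = E0,
                   seed = seed)
}

standard_fit_spec <- function() {
  list(free = c("d_w", "t_t", "E0", "c_inf", "rho_b_1", "rho_b_2"),
       lower = c(d_w = 0, t_t = 12, E0 = 0, c_inf = 0,
                 rho_b_1 = 5.5e-6, rho_b_2 = -0.8e-6),
       upper = c(d_w = 30, t_t = 18, E0 = 20, c_inf = 0.3,
                 rho_b_1 = 6.4e-6, rho_b_2 = 0.7e-6))
}

# simulate both contrasts and fit; used by the recovery studies
standard_fit <- function(truth, seed_data, seed_fit, nsteps = 150,
                         perturb = TRUE) {
  ccd <- simulate_reflectivity(truth, "D2O", seed = seed_data)
  cch <- simulate_reflectivity(truth, "H2O", seed = seed_data + 5000)
  curves <- list(reduce_counts(ccd), reduce_counts(cch))
  template <- truth[setdiff(names(truth),
                            c("medium", "lipid", "mw", "seed"))]
  template$rho_solvent_1 <- 6.3e-6
  template$rho_solvent_2 <- -0.4e-6
  if (perturb) {
    template$d_w <- 10; template$t_t <- 14
    template$E0 <- 2; template$c_inf <- 0.07
  }
  fs <- standard_fit_spec()
  joint_fit(curves, template, fs$free, fs$lower, fs$upper,
            nwalkers = 12, nsteps = nsteps, seed = seed_fit, slab = 1)
}

truth_exclusion <- function(truth) {
  p <- truth[setdiff(names(truth), c("medium", "lipid", "mw", "seed"))]
  m <- composition_model(p, z = c(0, 1))
  prof <- peg_exclusion_profile(p$c_inf, p$kappa, m$z0, p$E0)
  exclusion_distance(prof, hydrophobic_z = m$z_hydrophobic)
}
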