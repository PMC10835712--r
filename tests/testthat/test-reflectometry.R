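test_that("wavevector conversion", {
  expect_equal(wavevector_q(5, 1), 0.043865, tolerance = 1e-4)
  expect_equal(wavevector_q(10, 1), wavevector_q(5, 1) / 2)
  expect_lt(wavevector_q(5, 1e-8), 1e-8)
  expect_error(wavevector_q(-1, 1), "positive")
  expect_error(wavevector_q(5, 95), "degrees")
})

test_that("slab reflectivity matches the Fresnel closed form and unitarity", {
  q <- seq(0.004, 0.3, by = 0.002)
  rf <- fresnel_reflectivity(q, 2.069e-6, 6.36e-6)
  # a 'structure' with the same SLD as the backing is no structure at all
  r1 <- reflectivity_slabs(q, d = 25, rho = 6.36e-6,
                           rho_front = 2.069e-6, rho_back = 6.36e-6)
  expect_equal(r1, rf, tolerance = 1e-12)
  # total reflection band: R = 1 below the critical edge
  qc <- sqrt(16 * pi * (6.36e-6 - 2.069e-6))
  expect_equal(r1[q < 0.95 * qc], rep(1, sum(q < 0.95 * qc)),
               tolerance = 1e-6)
  # zero contrast everywhere: no reflection
  r0 <- reflectivity_slabs(q, d = 25, rho = 4e-6, rho_front = 4e-6,
                           rho_back = 4e-6)
  expect_equal(r0, rep(0, length(q)))
  # unitarity for a random rough stack
  set.seed(1)
  rr <- reflectivity_slabs(q, d = runif(4, 5, 60), rho = runif(4, -1e-6, 7e-6),
                           rho_front = 2.069e-6, rho_back = 6.36e-6,
                           sigma = runif(5, 0, 4))
  expect_true(all(rr <= 1 & rr >= 0))
})

test_that("Parratt recursion matches an independent transfer-matrix oracle", {
  q <- exp(seq(log(0.006), log(0.35), length.out = 120))
  set.seed(42)
  for (rep in 1:5) {
    d <- runif(5, 5, 80)
    rho <- runif(5, -0.5e-6, 7e-6)
    rf <- runif(1, 1e-6, 3e-6)
    rb <- runif(1, -0.5e-6, 6.5e-6)
    ours <- reflectivity_slabs(q, d, rho, rf, rb)
    oracle <- tmm_reflectivity(q, d, rho, rf, rb)
    expect_equal(ours, oracle, tolerance = 1e-10)
  }
})

test_that("symmetric stacks are invariant under slab-order reversal", {
  q <- seq(0.01, 0.3, by = 0.005)
  d <- c(20, 35, 20)
  rho <- c(5e-6, 1e-6, 5e-6)
  a <- reflectivity_slabs(q, d, rho, 3e-6, 3e-6)
  b <- reflectivity_slabs(q, rev(d), rev(rho), 3e-6, 3e-6)
  expect_equal(a, b, tolerance = 1e-14)
})

test_that("Fresnel normalization flags, ratios and round-trips", {
  q <- seq(0.01, 0.3, by = 0.005)
  rf <- fresnel_reflectivity(q, 2.069e-6, 6.36e-6)
  curve <- list(Q = q, R = rf, dR = 0.01 * rf)
  norm <- fresnel_normalize(curve, 2.069e-6, 6.36e-6)
  expect_equal(norm$R, rep(1, length(q)))
  expect_false(any(norm$flagged))
  # round trip
  expect_equal(norm$R * rf, curve$R)
  # a bilayer model oscillates about 1 on the Fresnel scale
  truth <- make_ssblm_truth("DOPC")
  p <- truth[setdiff(names(truth), c("medium", "lipid", "mw", "seed"))]
  mdl <- composition_model(p)
  Rm <- model_reflectivity(mdl, q)
  ratio <- Rm / fresnel_reflectivity(q, 2.069e-6, mdl$rho_bulk)
  expect_gt(max(ratio), 1.1)
  expect_lt(min(ratio), 0.9)
})

test_that("resolution smearing: identity, flat preservation, fringe damping", {
  q <- seq(0.01, 0.3, by = 0.001)
  R <- exp(-((q - 0.1) / 0.01)^2) + 0.1
  expect_equal(smear_resolution(q, R, 0), R)
  flat <- rep(0.25, length(q))
  expect_equal(smear_resolution(q, flat, 0.025 * q), flat)
  sm <- smear_resolution(q, R, 0.025 * q)
  expect_lt(max(sm), max(R))
  # smeared fringes of a real slab model have smaller amplitude
  Rs <- reflectivity_slabs(q, d = 40, rho = 6.3e-6, rho_front = 2.069e-6,
                           rho_back = -0.56e-6)
  sms <- smear_resolution(q, Rs, 0.025 * q)
  win <- q > 0.15
  expect_lt(stats::sd(log(sms[win])), stats::sd(log(Rs[win])))
})

test_that("PEG exclusion profile: limits and exclusion distance", {
  prof <- peg_exclusion_profile(0.1, 1 / (2 * 9.6), 0, 2)
  # E0 = 0: bulk fraction everywhere
  flat <- peg_exclusion_profile(0.1, 0.05, 0, 0)
  expect_equal(peg_volume_fraction(flat, c(-10, 0, 50)), rep(0.1, 3))
  # far field recovers the bulk fraction
  expect_equal(peg_volume_fraction(prof, 500), 0.1)
  # at z0 the fraction is c_inf exp(-E0)
  one <- peg_exclusion_profile(0.2, 0.05, 10, 1)
  expect_equal(peg_volume_fraction(one, 10), 0.2 * exp(-1))
  # worked value: E0 = 2, Debye length 9.6 A, z0 = 0 -> 5.09 A
  expect_equal(exclusion_distance(peg_exclusion_profile(0.1, 1 / 9.6, 0, 2)),
               5.087, tolerance = 1e-3)
  # closed form equals the numerical root to 0.01 A over a parameter sweep
  for (E0 in c(0.8, 2, 5, 20, 100)) {
    for (kap in c(0.03, 0.1, 0.3)) {
      pr <- peg_exclusion_profile(0.1, kap, 12, E0)
      expect_equal(exclusion_distance(pr, 5),
                   exclusion_distance(pr, 5, numeric = TRUE),
                   tolerance = 0.01)
    }
  }
  # monotone in E0; boundary case E0 = ln 2 is the plane of charge itself
  e <- vapply(c(1, 2, 4, 8), function(E0)
    exclusion_distance(peg_exclusion_profile(0.1, 0.05, 0, E0)), numeric(1))
  expect_true(all(diff(e) > 0))
  expect_equal(exclusion_distance(peg_exclusion_profile(0.1, 0.05, 7,
                                                        log(2) + 1e-12)),
               7, tolerance = 1e-6)
  expect_error(exclusion_distance(peg_exclusion_profile(0.1, 0.05, 0, 0.5)),
               "below resolution")
})

test_that("composition model conserves volume occupancy and tracks solvent", {
  truth <- make_ssblm_truth("DOPC_DOPS")
  p <- truth[setdiff(names(truth), c("medium", "lipid", "mw", "seed"))]
  mdl <- composition_model(p)
  # occupancy partition: everything sums to 1 at every z
  expect_equal(rowSums(mdl$phi), rep(1, length(mdl$z)), tolerance = 1e-9)
  expect_true(all(mdl$phi >= -1e-12))
  # geometry markers
  expect_equal(mdl$z0, mdl$z_hydrophobic + p$t_h / 2)
  # an over-packed bilayer is rejected
  bad <- p; bad$t_t <- 5
  expect_error(composition_model(bad), "occupancy")
  # nSLD far from the wall is the PEG-depressed bulk, below pure solvent
  far <- mdl$nsld[length(mdl$nsld)]
  expect_lt(far, p$rho_solvent)
  expect_equal(far, mdl$rho_bulk, tolerance = 1e-3)
})

test_that("nSLD values from scattering lengths and linear mixing", {
  # heavy water from its scattering length sum and bulk density
  v_d2o <- molecular_volume(20.0276, 1.105)
  expect_equal(sld_from_b_volume(19.145, v_d2o), 6.36e-6, tolerance = 0.005)
  # zero-volume component contributes nothing: mixing is linear in phi
  expect_equal(0.5 * 0.7e-6 + 0.5 * 6.36e-6, 3.53e-6)
  expect_error(sld_from_b_volume(19.1, -3), "positive")
})
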