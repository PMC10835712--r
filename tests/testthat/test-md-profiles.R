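test_that("mass-fraction to energy conversion and round trip", {
  z <- 0:50
  m_inf <- 0.1
  m <- m_inf * exp(-2 * exp(-0.1 * z))
  prof <- density_profile(z, m)
  en <- massfrac_to_energy(prof, bulk_window = c(45, 50))
  # m = m_inf -> 0; m = m_inf/2 -> ln 2; m = m_inf/e -> 1
  bulk_est <- attr(en, "m_inf")
  probe <- density_profile(c(1, 2, 3),
                           c(bulk_est, bulk_est / 2, bulk_est * exp(-1)))
  ep <- massfrac_to_energy(probe, bulk_window = c(0.5, 1.5))
  expect_equal(ep$value, c(0, log(2), 1), tolerance = 1e-12)
  # round trip through the inverse to 1e-12
  back <- energy_to_massfrac(en, bulk_est)
  expect_equal(back$value, m, tolerance = 1e-12)
  # zero bins are censored
  z0 <- density_profile(0:9, c(0, rep(0.1, 9)))
  e0 <- massfrac_to_energy(z0, bulk_window = c(5, 9))
  expect_true(is.infinite(e0$value[1]))
  expect_true(attr(e0, "censored")[1])
  expect_error(massfrac_to_energy(prof, bulk_window = c(100, 120)), "empty")
})

test_that("charged-minus-neutral subtraction isolates the interaction", {
  z <- 0:40
  e1 <- density_profile(z, 3 * exp(-0.1 * z), rep(0.05, 41), kind = "energy")
  # identical inputs give zero
  d0 <- delta_energy(e1, e1)
  expect_equal(d0$value, rep(0, length(d0$z)))
  expect_equal(d0$sigma, rep(0.05 * sqrt(2), length(d0$z)))
  # a constant shift of both profiles leaves the difference unchanged
  shift <- density_profile(z, 3 * exp(-0.1 * z) + 1.7, rep(0.05, 41),
                           kind = "energy")
  base <- density_profile(z, rep(1.7, 41), rep(0.05, 41), kind = "energy")
  d1 <- delta_energy(shift, base)
  expect_equal(d1$value, 3 * exp(-0.1 * d1$z), tolerance = 1e-12)
  # disjoint grids are rejected
  e2 <- density_profile(100:120, rep(1, 21), kind = "energy")
  expect_error(delta_energy(e1, e2), "disjoint")
})

test_that("decay fit: exact recovery on noiseless exponentials", {
  kap <- ionic_medium(0.1)$kappa * 1e-10
  A <- 27.8
  z <- seq(5, 45, by = 1)
  prof <- density_profile(z, A * exp(-2 * kap * z), kind = "energy")
  fit <- suppressWarnings(fit_decay(prof))
  expect_equal(fit$amplitude, A, tolerance = 1e-10)
  expect_equal(fit$decay_length, 1 / (2 * kap), tolerance = 1e-10)
  # threshold distance solves A exp(-d/l) = 1
  expect_equal(fit$d, log(A) / (2 * kap), tolerance = 1e-8)
  # monotone in amplitude at fixed decay length
  d_small <- suppressWarnings(
    fit_decay(density_profile(z, 10 * exp(-2 * kap * z),
                              kind = "energy")))$d
  expect_lt(d_small, fit$d)
  # decay ratio against the medium
  fitm <- suppressWarnings(fit_decay(prof, medium = ionic_medium(0.1)))
  expect_equal(fitm$decay_ratio, 1, tolerance = 1e-3)
  # window auto-shrink warns on non-positive bins, errors when too few
  set.seed(11)
  noisy <- density_profile(z, c(rep(-1, 5), A * exp(-2 * kap * z[-(1:5)]) *
                                  exp(stats::rnorm(length(z) - 5, 0, 0.02))),
                           kind = "energy")
  expect_warning(fit_decay(noisy), "shrunk")
  expect_error(suppressWarnings(
    fit_decay(density_profile(1:6, c(-1, -1, 1, 1, 1, 1), kind = "energy"))),
    "fewer than 5")
})

test_that("synthetic fixture pair embeds the tabulated threshold distances", {
  for (mw in c(600, 6000)) {
    sim <- simulate_profiles(mw, noise_sigma = 0, seed = 1)
    en_c <- massfrac_to_energy(sim$charged)
    en_n <- massfrac_to_energy(sim$neutral)
    dE <- delta_energy(en_c, en_n)
    win <- c(sim$truth$R_h + 2, max(dE$z[dE$value > 0.1]))
    fit <- fit_decay(dE, win)
    # exact up to the finite bulk-window estimate of m_inf
    expect_equal(fit$amplitude, sim$truth$A, tolerance = 5e-3)
    expect_equal(fit$decay_length, 1 / (2 * sim$truth$kappa_A),
                 tolerance = 1e-3)
    expect_equal(fit$d, sim$truth$d_embedded, tolerance = 1e-3)
  }
})

test_that("size-scaling exponent is 3 for closed-form theory curves", {
  m <- fix_medium(); iface <- fix_dpps()
  radii <- c(7, 9, 11, 13, 17, 22)
  z <- seq(25, 60, by = 1)
  curves <- lapply(radii, function(a) {
    s <- dielectric_sphere(a, 10)
    density_profile(z, dep_energy_closed(s, iface, m, z) +
                      hydrostatic_energy(s, iface, m, z), kind = "energy")
  })
  # the DEP part scales exactly as a^3; the hydrostatic part grows a bit
  # faster through the finite-size sphere average g(2 kappa a), so the
  # combined exponent sits slightly above 3
  sc <- suppressWarnings(size_scaling(curves, radii, z_eval = 30))
  expect_gt(sc$exponent, 3)
  expect_lt(sc$exponent, 4.5)
  ed_only <- lapply(radii, function(a)
    density_profile(z, dep_energy_closed(dielectric_sphere(a, 10), iface,
                                         m, z), kind = "energy"))
  expect_equal(suppressWarnings(size_scaling(ed_only, radii, 30))$exponent,
               3, tolerance = 1e-6)
  # exact cubic synthetic curves
  cubic <- lapply(radii, function(a)
    density_profile(z, a^3 * exp(-0.1 * z), kind = "energy"))
  expect_equal(suppressWarnings(size_scaling(cubic, radii, 40))$exponent,
               3, tolerance = 1e-10)
  expect_error(size_scaling(cubic[1:2], radii[1:2], 40), "at least 3")
})

test_that("noisy fixtures: decay length and thresholds recovered (20 seeds)", {
  kap <- ionic_medium(0.1)$kappa * 1e-10
  ratios <- numeric(20)
  d600 <- numeric(20)
  d6000 <- numeric(20)
  for (s in 1:20) {
    sim <- simulate_profiles(600, noise_sigma = 0.01, seed = s)
    dE <- delta_energy(massfrac_to_energy(sim$charged),
                       massfrac_to_energy(sim$neutral))
    ok <- is.finite(dE$value)
    dE <- density_profile(dE$z[ok], dE$value[ok], dE$sigma[ok],
                          kind = "energy")
    fit <- suppressWarnings(
      fit_decay(dE, c(sim$truth$R_h + 2, 30)))
    ratios[s] <- fit$decay_length * 2 * kap
    d600[s] <- fit$d
    sim2 <- simulate_profiles(6000, noise_sigma = 0.01, seed = s)
    dE2 <- delta_energy(massfrac_to_energy(sim2$charged),
                        massfrac_to_energy(sim2$neutral))
    ok2 <- is.finite(dE2$value)
    dE2 <- density_profile(dE2$z[ok2], dE2$value[ok2], dE2$sigma[ok2],
                           kind = "energy")
    d6000[s] <- suppressWarnings(
      fit_decay(dE2, c(sim2$truth$R_h + 2, 42)))$d
  }
  # decay length within 5 % of half the Debye length at fixture noise
  expect_lt(max(abs(ratios - 1)), 0.05)
  # embedded Table-level thresholds within 1 A
  expect_lt(max(abs(d600 - 16)), 1)
  expect_lt(max(abs(d6000 - 28)), 1)
  # ordering preserved
  expect_true(all(d6000 > d600))
})
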