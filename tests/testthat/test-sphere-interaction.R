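test_that("Clausius-Mossotti factor: value, zero and conducting limits", {
  m <- fix_medium()
  expect_equal(clausius_mossotti(fix_sphere600(), m), -0.41018,
               tolerance = 1e-4)
  expect_equal(clausius_mossotti(dielectric_sphere(7, 78.5), m), 0)
  expect_equal(clausius_mossotti(dielectric_sphere(7, 1e9), m), 1,
               tolerance = 1e-6)
})

test_that("closed-form DEP energy: prefactor, decay and brute-force check", {
  m <- fix_medium(); iface <- fix_dpps(); s <- fix_sphere600()
  kT <- thermal_energy(m$temperature)
  z <- seq(7, 40, by = 0.5)
  ED <- dep_energy_closed(s, iface, m, z)
  expect_true(all(ED > 0))
  # log-slope is exactly -2 kappa
  slopes <- diff(log(ED)) / diff(z)
  expect_equal(slopes, rep(-2 * m$kappa * 1e-10, length(slopes)),
               tolerance = 1e-9)
  # sigma = 0 gives identically zero
  expect_equal(dep_energy_closed(s, charged_interface(0), m, z),
               rep(0, length(z)))
  expect_error(dep_energy_closed(s, iface, m, 5), "intersects")
  # prefactor of order tens of kBT for the PEG600/DPPS configuration
  expect_gt(dep_prefactor(s, iface, m) / kT, 10)
  expect_lt(dep_prefactor(s, iface, m) / kT, 100)
  # brute force: E_D(z) = -integral of the classical DEP force from z to
  # infinity, with F = 2 pi a^3 eps CM d(E^2)/dz for the linearized field
  a <- 7e-10; cm <- clausius_mossotti(s, m)
  E0 <- iface$sigma / m$eps   # linearized surface field
  # repulsive force (positive, away from the wall) for cm < 0
  Fz <- function(zm) 2 * pi * a^3 * m$eps * cm *
    (-2 * m$kappa) * E0^2 * exp(-2 * m$kappa * zm)
  for (zi in c(10, 20)) {
    brute <- stats::integrate(Fz, zi * 1e-10, zi * 1e-10 + 60 / m$kappa,
                              rel.tol = 1e-10)$value
    expect_equal(dep_energy_closed(s, iface, m, zi), brute / kT,
                 tolerance = 1e-6)
  }
})

test_that("hydrostatic energy: quadrature vs closed form, point limit, decay", {
  m <- fix_medium(); iface <- fix_dpps(); s <- fix_sphere600()
  kT <- thermal_energy(m$temperature)
  z <- seq(7, 35, by = 1)
  EH <- hydrostatic_energy(s, iface, m, z)
  # matches the analytic sphere-average prefactor form
  expect_equal(EH, hydrostatic_prefactor(s, iface, m) / kT *
                 exp(-2 * m$kappa * z * 1e-10), tolerance = 1e-6)
  # log-slope -2 kappa within 1 %
  fit <- stats::lm(log(EH) ~ z)
  expect_equal(-unname(stats::coef(fit)[2]), 2 * m$kappa * 1e-10,
               tolerance = 0.01)
  expect_equal(hydrostatic_energy(s, charged_interface(0), m, z),
               rep(0, length(z)))
  # point-sphere limit: E_H -> V * Pi(z) within 1 %
  tiny <- dielectric_sphere(0.5, 10)
  zi <- 20
  Pi_z <- iface$sigma^2 * exp(-2 * m$kappa * zi * 1e-10) / (2 * m$eps)
  V <- 4 / 3 * pi * (0.5e-10)^3
  expect_equal(hydrostatic_energy(tiny, iface, m, zi), V * Pi_z / kT,
               tolerance = 0.01)
})

test_that("interaction curve: totals, decay constant, sign and size scaling", {
  m <- fix_medium(); iface <- fix_dpps(); s <- fix_sphere600()
  z <- seq(7, 45, by = 0.5)
  cur <- interaction_curve(s, iface, m, z)
  expect_equal(cur$E_total, cur$E_D + cur$E_H)
  expect_equal(cur$decay_constant, 2 * m$kappa * 1e-10, tolerance = 1e-6)
  # independent of the sign of the charge
  cur_pos <- interaction_curve(s, charged_interface(0.35), m, z)
  expect_equal(cur$E_total, cur_pos$E_total)
  # closed-form energies at fixed z scale as a^3 (R_h^3)
  radii <- c(7, 9, 11, 13, 17, 22)
  at30 <- vapply(radii, function(a)
    dep_energy_closed(dielectric_sphere(a, 10), iface, m, 30), numeric(1))
  fit <- stats::lm(log(at30) ~ log(radii))
  expect_equal(unname(stats::coef(fit)[2]), 3, tolerance = 1e-6)
  # point-limit hydrostatic energy scales the same way
  at30h <- vapply(c(1, 2, 3), function(a)
    hydrostatic_energy(dielectric_sphere(a, 10), iface, m, 30), numeric(1))
  fith <- stats::lm(log(at30h) ~ log(c(1, 2, 3)))
  expect_equal(unname(stats::coef(fith)[2]), 3, tolerance = 0.01)
})

test_that("depletion distance: exponential oracle, threshold shift, errors", {
  m <- fix_medium(); iface <- fix_dpps(); s <- fix_sphere600()
  z <- seq(7, 60, by = 0.25)
  cur <- interaction_curve(s, iface, m, z)
  # pure exponential: threshold A exp(-2 kappa z0) returns z0
  twokap <- 2 * m$kappa * 1e-10
  A <- (cur$K_D + cur$K_H) / thermal_energy(m$temperature)
  z0 <- 25
  d <- depletion_distance(cur, A * exp(-twokap * z0))$d
  expect_equal(d, z0, tolerance = 0.01)
  # doubling the threshold decreases d by ln 2 / (2 kappa)
  d1 <- depletion_distance(cur, 0.5)$d
  d2 <- depletion_distance(cur, 1.0)$d
  expect_equal(d1 - d2, log(2) / twokap, tolerance = 0.02)
  expect_equal(depletion_distance(cur)$d_star, depletion_distance(cur)$d - 7)
  expect_error(depletion_distance(cur, 1e6), "no crossing")
  # d increases monotonically with MW across the packaged radii
  ds <- vapply(c(600, 1000, 1540, 2000, 3400, 6000), function(mw) {
    g <- peg_geometry(mw)
    sp <- dielectric_sphere(g$R_h, 10, mw)
    zz <- seq(g$R_h, 90, by = 0.25)
    depletion_distance(interaction_curve(sp, iface, m, zz))$d
  }, numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("PEG geometry table and monomer-count rule", {
  mws <- c(600, 1000, 1540, 2000, 3400, 6000)
  geo <- lapply(mws, peg_geometry)
  expect_equal(vapply(geo, `[[`, numeric(1), "R_h"),
               c(7, 9, 11, 13, 17, 22))
  expect_equal(vapply(geo, `[[`, integer(1), "n_monomers"),
               c(13L, 22L, 35L, 45L, 77L, 136L))
  expect_equal(peg_geometry(1200)$R_h,
               exp(stats::approx(log(c(1000, 1540)), log(c(9, 11)),
                                 xout = log(1200))$y))
  expect_error(peg_geometry(-5), "positive")
})

test_that("Maxwell-stress backend matches the closed form in its limits", {
  m <- fix_medium(); iface <- fix_dpps(); s <- fix_sphere600()
  z <- seq(8, 30, by = 2)
  st <- dep_energy_stress(s, iface, m, z)
  cl <- dep_energy_closed(s, iface, m, z)
  # full solution exceeds the classical estimate in the experimental regime
  expect_true(all(st$E_D >= cl))
  # sigma = 0: no force anywhere
  z0 <- dep_energy_stress(s, charged_interface(0), m, z)
  expect_equal(z0$E_total, rep(0, length(z)))
  # weak-field small-sphere regime (kappa a = 0.1, psi-tilde = 0.2):
  # agreement with the closed form within 10 %
  aw <- 7
  kap <- 0.1 / (aw * 1e-10)
  kT <- thermal_energy(298.15)
  Iw <- kap^2 * m$eps * kT / (2 * 1e3 * sdep_constants$NAv *
                                sdep_constants$e^2)
  mw <- ionic_medium(Iw)
  sigw <- 0.2 * kT / sdep_constants$e * mw$eps * mw$kappa
  ifw <- charged_interface(sigw)
  zw <- seq(21, 91, by = 14)
  stw <- dep_energy_stress(s, ifw, mw, zw)
  clw <- dep_energy_closed(s, ifw, mw, zw)
  expect_equal(stw$E_D, clw, tolerance = 0.1)
  # stress-backend force is consistent with -dE/dz (finite differences)
  zf <- c(12, 12.5)
  stf <- dep_energy_stress(s, iface, m, zf)
  dEdz <- diff(stf$E_total) / diff(zf) * thermal_energy(m$temperature) / 1e-10
  expect_equal(mean(stf$force_total), -dEdz, tolerance = 0.02)
})

test_that("discussion estimates: thermal force scale and magnitudes", {
  m <- fix_medium(); iface <- fix_dpps(); s <- fix_sphere600()
  est <- discussion_estimates(s, iface, m)
  expect_equal(est$thermal_force_pN, 2.94, tolerance = 0.01)
  # thermal force halves when R_h doubles
  est2 <- discussion_estimates(dielectric_sphere(14), iface, m)
  expect_equal(est2$thermal_force_pN, est$thermal_force_pN / 2)
  # hydrostatic force on the sphere is of pN order (order-of-magnitude)
  expect_gt(est$hydrostatic_force_pN, 1)
  expect_lt(est$hydrostatic_force_pN, 100)
  expect_equal(est$ion_excess_at_debye_M, 0.681, tolerance = 1e-3)
  expect_equal(est$vant_hoff_pressure_MPa, 1.68, tolerance = 0.01)
})
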