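#' Dielectric-sphere model of a neutral polymer coil
#'
#' The polymer (e.g. a PEG coil) is idealised as a homogeneous neutral
#' sphere of radius equal to its hydrodynamic radius and low interior
#' permittivity.
#'
#' @param radius Hydrodynamic radius R_h in Angstrom (> 0).
#' @param rel_permittivity Interior relative permittivity eps_p/eps0
#'   (default 10, the conventional low-polarizability value for PEG).
#' @param mw Optional molecular weight in Da.
#' @return An object of class `dielectric_sphere`.
#' @export
dielectric_sphere <- function(radius, rel_permittivity = 10, mw = NULL) {
  if (radius <= 0) stop("radius must be positive (Angstrom)")
  if (rel_permittivity <= 0) stop("rel_permittivity must be positive")
  structure(list(radius = radius, rel_permittivity = rel_permittivity,
                 mw = mw), class = "dielectric_sphere")
}

#' Clausius-Mossotti factor
#'
#' (eps_p - eps_w) / (eps_p + 2 eps_w): the effective-polarizability factor
#' of dielectrophoresis. Negative when the particle is less polarizable
#' than the solvent, i.e. the particle is pushed toward weaker fields.
#'
#' @param sphere A [dielectric_sphere()].
#' @param medium An [ionic_medium()].
#' @return Dimensionless factor in (-0.5, 1).
#' @export
clausius_mossotti <- function(sphere, medium) {
  stopifnot(inherits(sphere, "dielectric_sphere"),
            inherits(medium, "ionic_medium"))
  ep <- sphere$rel_permittivity
  ew <- medium$rel_permittivity
  (ep - ew) / (ep + 2 * ew)
}

# hydrodynamic radii (Angstrom) of PEG coils by molecular weight,
# literature consensus values
.peg_rh_table <- c(`600` = 7, `1000` = 9, `1540` = 11, `2000` = 13,
                   `3400` = 17, `6000` = 22)

#' PEG geometry from molecular weight
#'
#' Returns the hydrodynamic radius (from a packaged lookup table, with
#' log-log interpolation between tabulated molecular weights) and the
#' monomer count n minimising |44.05 n + 18.02 - MW| (ethylene oxide
#' repeat mass plus water end groups).
#'
#' @param mw Molecular weight in Da (> 0).
#' @return List with elements `R_h` (Angstrom) and `n_monomers` (integer).
#' @export
peg_geometry <- function(mw) {
  if (!is.numeric(mw) || length(mw) != 1L || !is.finite(mw) || mw <= 0)
    stop("mw must be a single positive number (Da)")
  tab_mw <- as.numeric(names(.peg_rh_table))
  if (mw %in% tab_mw) {
    rh <- unname(.peg_rh_table[as.character(mw)])
  } else {
    if (mw < min(tab_mw) || mw > max(tab_mw))
      stop("mw outside the supported range [", min(tab_mw), ", ", max(tab_mw), "]")
    rh <- exp(stats::approx(log(tab_mw), log(.peg_rh_table), xout = log(mw))$y)
  }
  n <- max(1L, round((mw - 18.02) / 44.05))
  cand <- c(n - 1L, n, n + 1L)
  cand <- cand[cand >= 1L]
  n <- cand[which.min(abs(44.05 * cand + 18.02 - mw))]
  list(R_h = rh, n_monomers = as.integer(n))
}

#' Lipid membrane surface-charge presets
#'
#' Charge densities computed from headgroup area per unit charge: DPPS
#' (1 e-/46 A^2), DPTAP (1 e+/69.8 A^2), zwitterionic DPPC/DOPC (0).
#' The 1:1 mixed DOPC bilayers used in reflectometry carry half the
#' charge of the pure charged lipid.
#'
#' @param lipid One of `"DPPS"`, `"DPTAP"`, `"DPPC"`, `"DOPC"`,
#'   `"DOPC_DOPS"`, `"DOPC_DOTAP"` (case-insensitive).
#' @return A [charged_interface()] at `plane_position = 0`.
#' @export
lipid_preset <- function(lipid) {
  key <- toupper(lipid)
  sigma <- switch(key,
    DPPS       = sigma_from_area_per_charge(46, -1),
    DPTAP      = sigma_from_area_per_charge(69.8, +1),
    DPPC       = 0,
    DOPC       = 0,
    DOPC_DOPS  = sigma_from_area_per_charge(46, -1) / 2,
    DOPC_DOTAP = sigma_from_area_per_charge(69.8, +1) / 2,
    stop("unsupported lipid preset: ", lipid)
  )
  charged_interface(sigma)
}

#' Linearized (Debye-Hueckel) surface potential
#'
#' psi0 = sigma / (eps kappa), the surface potential under the linearized
#' double-layer boundary condition. The sphere-interaction energies use
#' this convention consistently, so that both prefactors carry sigma^2
#' without the Grahame saturation; see the methods vignette for why.
#'
#' @param interface A [charged_interface()].
#' @param medium An [ionic_medium()].
#' @return Potential in volts.
#' @export
dh_surface_potential <- function(interface, medium) {
  interface$sigma / (medium$eps * medium$kappa)
}

# sphere volume-average factor for an exp(-c z) integrand over a ball:
# <exp(-c (z'-z))>_ball = 3 (c a cosh(c a) - sinh(c a)) / (c a)^3
.ball_average_factor <- function(ca) {
  ifelse(ca < 1e-6, 1 + ca^2 / 10, 3 * (ca * cosh(ca) - sinh(ca)) / ca^3)
}

#' Closed-form dielectrophoretic free energy
#'
#' E_D(z) = K_D exp(-2 kappa z) with
#' K_D = -2 pi a^3 CM sigma^2 / eps_w, the classical point-dipole DEP
#' energy in the linearized exponentially decaying double-layer field.
#' Positive (repulsive) for a low-permittivity sphere.
#'
#' @param sphere A [dielectric_sphere()].
#' @param interface A [charged_interface()].
#' @param medium An [ionic_medium()].
#' @param z Centre-of-sphere distances from the plane of charge, Angstrom;
#'   must satisfy z >= radius (the sphere may not intersect the plane).
#' @return Energies in units of k_B T, one per `z`.
#' @export
dep_energy_closed <- function(sphere, interface, medium, z) {
  if (any(z < sphere$radius))
    stop("z < sphere radius: sphere intersects the charged plane")
  K_D <- dep_prefactor(sphere, interface, medium)
  kT <- thermal_energy(medium$temperature)
  K_D * exp(-2 * medium$kappa * z * .A_to_m) / kT
}

#' Closed-form DEP prefactor K_D in joules
#' @inheritParams dep_energy_closed
#' @return K_D in joules.
#' @export
dep_prefactor <- function(sphere, interface, medium) {
  a <- sphere$radius * .A_to_m
  cm <- clausius_mossotti(sphere, medium)
  -2 * pi * a^3 * cm * interface$sigma^2 / medium$eps
}

#' Closed-form hydrostatic prefactor K_H in joules
#'
#' K_H = (2 pi / 3) a^3 sigma^2 g(2 kappa a) / eps_w, the sphere-volume
#' integral of the linearized counterion excess pressure
#' Pi(z) = sigma^2 exp(-2 kappa z) / (2 eps_w).
#'
#' @inheritParams dep_energy_closed
#' @return K_H in joules.
#' @export
hydrostatic_prefactor <- function(sphere, interface, medium) {
  a <- sphere$radius * .A_to_m
  g <- .ball_average_factor(2 * medium$kappa * a)
  (2 * pi / 3) * a^3 * interface$sigma^2 * g / medium$eps
}

#' Counterion-pressure (hydrostatic) free energy
#'
#' The osmotic excess pressure of the double layer integrated over the
#' volume excluded by the sphere, by Gauss-Legendre quadrature over the
#' sphere cross-sections (node count doubled until successive estimates
#' agree to 0.1 percent). In the default `"linearized"` mode the pressure
#' is Pi(z) = sigma^2 exp(-2 kappa z) / (2 eps_w) (Debye-Hueckel
#' convention, matching [dep_energy_closed()]); `"vant_hoff"` instead uses
#' the ideal osmotic pressure of the full Boltzmann ion excess under the
#' `linear_decay` potential convention of [ion_excess()].
#'
#' @inheritParams dep_energy_closed
#' @param mode `"linearized"` (default) or `"vant_hoff"`.
#' @return Energies in k_B T, one per `z`.
#' @export
hydrostatic_energy <- function(sphere, interface, medium, z,
                               mode = c("linearized", "vant_hoff")) {
  mode <- match.arg(mode)
  if (any(z < sphere$radius))
    stop("z < sphere radius: sphere intersects the charged plane")
  a <- sphere$radius * .A_to_m
  kT <- thermal_energy(medium$temperature)
  pressure <- if (mode == "linearized") {
    function(zm) interface$sigma^2 * exp(-2 * medium$kappa * zm) /
      (2 * medium$eps)
  } else {
    function(zm) {
      ex <- ion_excess(interface, medium, zm / .A_to_m, mode = "linear_decay")
      osmotic_pressure_vant_hoff(ex, medium)
    }
  }
  vapply(z * .A_to_m, function(zc) {
    nn <- 16
    prev <- NA_real_
    repeat {
      gl <- pracma::gaussLegendre(nn, -a, a)
      integ <- sum(gl$w * pressure(zc + gl$x) * pi * (a^2 - gl$x^2))
      if (!is.na(prev) && abs(integ - prev) <= 1e-3 * abs(integ)) break
      if (nn > 512) break
      prev <- integ
      nn <- nn * 2
    }
    integ / kT
  }, numeric(1))
}

# ---- multipole machinery for the Maxwell-stress backend -------------------

# modified spherical Bessel functions of the first and second kind,
# i_n(x) = sqrt(pi/(2x)) I_{n+1/2}(x), k_n(x) = sqrt(pi/(2x)) K_{n+1/2}(x),
# with derivatives from the standard recurrences
.msbessel <- function(nmax, x) {
  n <- 0:nmax
  fac <- sqrt(pi / (2 * x))
  i_n <- fac * besselI(x, n + 0.5)
  k_n <- fac * besselK(x, n + 0.5)
  ip <- c(i_n[2], i_n[1:nmax] - ((2:(nmax + 1)) / x) * i_n[-1])
  kp <- c(-k_n[2], -k_n[1:nmax] - ((2:(nmax + 1)) / x) * k_n[-1])
  list(i = i_n, k = k_n, ip = ip, kp = kp)
}

# Legendre polynomials P_n(x) and theta-derivatives dP_n/dtheta at
# x = cos(theta); returns (nmax+1) x length(x) matrices
.legendre_table <- function(nmax, x) {
  m <- length(x)
  P <- matrix(0, nmax + 1, m)
  P[1, ] <- 1
  if (nmax >= 1) P[2, ] <- x
  if (nmax >= 2) for (n in 2:nmax)
    P[n + 1, ] <- ((2 * n - 1) * x * P[n, ] - (n - 1) * P[n - 1, ]) / n
  sinth <- sqrt(pmax(0, 1 - x^2))
  dP <- matrix(0, nmax + 1, m)
  if (nmax >= 1) for (n in 1:nmax) {
    # (1-x^2) P_n'(x) = n (P_{n-1} - x P_n); dP/dtheta = -sin(theta) P_n'(x)
    num <- n * (P[n, ] - x * P[n + 1, ])
    dP[n + 1, ] <- -num / ifelse(sinth < 1e-12, Inf, sinth)
  }
  list(P = P, dP = dP)
}

# forces on the sphere at one centre distance zc (m) by integrating the
# stress over the sphere surface; returns c(field part, pressure part) in N
.stress_forces <- function(zc, a, kappa, psi0, eps_w, eps_p, nmax, nodes) {
  ka <- kappa * a
  bes <- .msbessel(nmax, ka)
  n <- 0:nmax
  alpha <- psi0 * exp(-kappa * zc) * (2 * n + 1) * (-1)^n
  # per-mode matching of potential and normal displacement on r = a:
  #   alpha i_n + B k_n = A;  eps_w kappa (alpha i_n' + B k_n') = eps_p n A / a
  det <- eps_w * kappa * bes$kp - eps_p * n * bes$k / a
  B <- alpha * (eps_p * n * bes$i / a - eps_w * kappa * bes$ip) / det
  A <- eps_w * kappa * alpha * (bes$kp * bes$i - bes$k * bes$ip) / det
  gl <- pracma::gaussLegendre(nodes, -1, 1)
  x <- gl$x
  leg <- .legendre_table(nmax, x)
  co_psi <- alpha * bes$i + B * bes$k
  co_er <- -kappa * (alpha * bes$ip + B * bes$kp)
  psi <- as.vector(co_psi %*% leg$P)
  Er <- as.vector(co_er %*% leg$P)
  Eth <- as.vector((-co_psi / a) %*% leg$dP)
  sinth <- sqrt(pmax(0, 1 - x^2))
  f_field <- eps_w * (0.5 * (Er^2 - Eth^2) * x - Er * Eth * sinth)
  Pi_s <- 0.5 * eps_w * kappa^2 * psi^2
  F_field <- 2 * pi * a^2 * sum(gl$w * f_field)
  F_pres <- -2 * pi * a^2 * sum(gl$w * Pi_s * x)
  c(F_field, F_pres)
}

#' Maxwell-stress dielectrophoretic free energy (numerical backend)
#'
#' Solves the linearized Poisson-Boltzmann scattering problem of the
#' dielectric, ion-excluding sphere in the exponentially decaying
#' double-layer field (multipole expansion: modified spherical Bessel
#' functions outside, Laplace harmonics inside, potential and displacement
#' matched on the sphere surface), integrates the full stress tensor --
#' electric Maxwell stress plus the linearized osmotic pressure of the
#' perturbed ion cloud -- over the sphere surface to obtain the total
#' normal force, and converts force to free energy by integrating from
#' infinity. The dielectrophoretic component is reported as the total
#' stress-tensor energy minus the unperturbed-fluid hydrostatic energy
#' [hydrostatic_energy()]; in the weak-field, small kappa*a limit this
#' definition reduces exactly to the classical [dep_energy_closed()].
#'
#' Truncation (multipole order and surface nodes) is doubled until the
#' energies change by less than `tol`; failure to converge is an error.
#'
#' @inheritParams dep_energy_closed
#' @param tol Relative convergence tolerance for truncation refinement
#'   (default 0.02).
#' @return List with `z` (Angstrom), `E_D`, `E_H`, `E_total` (k_B T),
#'   and `force_total` (N) at the requested distances.
#' @export
dep_energy_stress <- function(sphere, interface, medium, z, tol = 0.02) {
  if (any(z <= sphere$radius))
    stop("z must exceed the sphere radius for the stress backend")
  a <- sphere$radius * .A_to_m
  kappa <- medium$kappa
  eps_w <- medium$eps
  eps_p <- sphere$rel_permittivity * sdep_constants$eps0
  psi0 <- dh_surface_potential(interface, medium)
  kT <- thermal_energy(medium$temperature)
  if (interface$sigma == 0) {
    zero <- rep(0, length(z))
    return(list(z = z, E_D = zero, E_H = zero, E_total = zero,
                force_total = zero))
  }
  # integration grid: requested z plus extension for the tail
  zmax <- max(z) * .A_to_m + 6 / kappa
  grid <- sort(unique(c(z * .A_to_m,
                        seq(min(z) * .A_to_m, zmax, by = 0.25 / kappa), zmax)))
  total_on_grid <- function(nmax, nodes) {
    vapply(grid, function(zc)
      sum(.stress_forces(zc, a, kappa, psi0, eps_w, eps_p, nmax, nodes)),
      numeric(1))
  }
  nmax <- 16; nodes <- 32
  F_prev <- total_on_grid(nmax, nodes)
  converged <- FALSE
  for (step in 1:4) {
    nmax <- nmax * 2; nodes <- nodes * 2
    F_cur <- total_on_grid(nmax, nodes)
    rel <- max(abs(F_cur - F_prev) / pmax(abs(F_cur), max(abs(F_cur)) * 1e-6))
    if (rel < tol) { converged <- TRUE; break }
    F_prev <- F_cur
  }
  if (!converged)
    stop("stress backend failed to converge: last truncation nmax=", nmax,
         " nodes=", nodes)
  # energy by trapezoid on the grid plus exponential tail beyond zmax
  Ftot <- F_cur
  n <- length(grid)
  seg <- (Ftot[-1] + Ftot[-n]) / 2 * diff(grid)
  E <- c(rev(cumsum(rev(seg))), 0) + Ftot[n] / (2 * kappa)
  E_tot_kT <- stats::approx(grid, E, xout = z * .A_to_m)$y / kT
  E_H <- hydrostatic_energy(sphere, interface, medium, z, "linearized")
  list(z = z, E_D = E_tot_kT - E_H, E_H = E_H, E_total = E_tot_kT,
       force_total = stats::approx(grid, Ftot, xout = z * .A_to_m)$y)
}

#' Combined interaction free-energy curve
#'
#' Builds E_D(z), E_H(z) and their sum for a sphere near a charged plane,
#' using either the closed-form backend (default) or the Maxwell-stress
#' multipole backend for the dielectrophoretic part.
#'
#' @inheritParams dep_energy_closed
#' @param backend `"closed"` (default) or `"stress"`.
#' @param hydro_mode Passed to [hydrostatic_energy()].
#' @return An object of class `interaction_curve`: list with `z` (Angstrom),
#'   `E_D`, `E_H`, `E_total` (k_B T), prefactors `K_D`, `K_H` (J), the
#'   fitted `decay_constant` (1/Angstrom) of E_total, and the sphere
#'   radius `R_h` (Angstrom).
#' @export
interaction_curve <- function(sphere, interface, medium, z,
                              backend = c("closed", "stress"),
                              hydro_mode = "linearized") {
  backend <- match.arg(backend)
  z <- sort(z)
  E_H <- hydrostatic_energy(sphere, interface, medium, z, hydro_mode)
  if (backend == "closed") {
    E_D <- dep_energy_closed(sphere, interface, medium, z)
  } else {
    E_D <- dep_energy_stress(sphere, interface, medium, z)$E_D
  }
  E_tot <- E_D + E_H
  pos <- E_tot > 0 & is.finite(E_tot)
  decay <- if (sum(pos) >= 2) {
    -unname(stats::coef(stats::lm(log(E_tot[pos]) ~ z[pos]))[2])
  } else NA_real_
  structure(list(z = z, E_D = E_D, E_H = E_H, E_total = E_tot,
                 K_D = dep_prefactor(sphere, interface, medium),
                 K_H = hydrostatic_prefactor(sphere, interface, medium),
                 decay_constant = decay, R_h = sphere$radius,
                 backend = backend),
            class = "interaction_curve")
}

#' Depletion distance: where the interaction energy crosses a threshold
#'
#' Solves E_total(z) = threshold on a monotone interaction curve by
#' bracketed bisection (on log energy, linearly interpolated) to 0.01
#' Angstrom.
#'
#' @param curve An [interaction_curve()] (E_total monotone decreasing).
#' @param threshold Energy threshold in k_B T (default 1).
#' @return List with `d` (centre distance, Angstrom) and `d_star`
#'   (`d - R_h`, the width of the polymer-free layer beyond the sphere
#'   radius).
#' @export
depletion_distance <- function(curve, threshold = 1) {
  stopifnot(inherits(curve, "interaction_curve"))
  if (threshold <= 0) stop("threshold must be positive")
  z <- curve$z
  E <- curve$E_total
  if (any(E <= 0)) stop("E_total must be positive over the grid")
  if (threshold > max(E) || threshold < min(E))
    stop("no crossing: threshold outside the range of E_total on the grid")
  f <- stats::approxfun(z, log(E) - log(threshold))
  root <- stats::uniroot(f, range(z), tol = 0.01)$root
  list(d = root, d_star = root - curve$R_h)
}

#' Randomized thermal force scale
#'
#' k_B T / (2 R_h): the thermal force scale against which the double-layer
#' repulsion is compared.
#'
#' @param medium An [ionic_medium()].
#' @param R_h Hydrodynamic radius in Angstrom.
#' @return Force in newtons.
#' @export
thermal_force <- function(medium, R_h) {
  thermal_energy(medium$temperature) / (2 * R_h * .A_to_m)
}

#' Order-of-magnitude chain for the double-layer repulsion
#'
#' Reproduces the rough-estimate chain for a sphere near a charged
#' membrane: Debye length, Grahame surface potential, ion excess one Debye
#' length out (linear-decay convention), its van't Hoff pressure, the
#' osmotic pressure gradient (force per unit volume) and resulting force
#' on the sphere, the thermal force, and the squared-field gradient at
#' 5, 10 and 15 Angstrom (nonlinear Gouy-Chapman profile).
#'
#' @inheritParams dep_energy_closed
#' @return Named list of the estimates with units in the names.
#' @export
discussion_estimates <- function(sphere, interface, medium) {
  lD_nm <- debye_length(medium)
  lD_A <- lD_nm * 10
  psi0 <- grahame_potential(interface, medium)
  excess <- ion_excess(interface, medium, lD_A, mode = "linear_decay")
  Pi <- osmotic_pressure_vant_hoff(excess, medium)
  # d(Pi)/dz at one Debye length, van't Hoff on the Boltzmann excess under
  # the linear-decay potential
  kT <- thermal_energy(medium$temperature)
  pt <- sdep_constants$e * potential_profile(interface, medium, lD_A,
                                             "linear_decay") / kT
  c0 <- medium$ionic_strength
  dPi_dz <- 2 * c0 * 1e3 * sdep_constants$Rgas * medium$temperature *
    abs(sinh(pt)) * medium$kappa * abs(pt)   # Pa/m, magnitude
  V_sphere <- 4 / 3 * pi * (sphere$radius * .A_to_m)^3
  gE2 <- field_gradient_sq(interface, medium, c(5, 10, 15), "nonlinear_gc")
  list(
    debye_length_nm = lD_nm,
    surface_potential_V = psi0,
    ion_excess_at_debye_M = excess,
    vant_hoff_pressure_MPa = Pi / 1e6,
    pressure_gradient_pN_per_nm3 = dPi_dz * 1e12 / 1e27,
    hydrostatic_force_pN = dPi_dz * V_sphere * 1e12,
    thermal_force_pN = thermal_force(medium, sphere$radius) * 1e12,
    grad_E2_V2_per_m3 = stats::setNames(gE2, c("5A", "10A", "15A"))
  )
}
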