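#' Scattering wavevector from wavelength and grazing angle
#'
#' Q = 4 pi sin(theta) / lambda.
#'
#' @param wavelength Neutron wavelength in Angstrom (> 0).
#' @param theta Grazing angle in degrees, 0 < theta < 90.
#' @return Q in 1/Angstrom.
#' @export
wavevector_q <- function(wavelength, theta) {
  if (any(wavelength <= 0)) stop("wavelength must be positive")
  if (any(theta <= 0 | theta >= 90)) stop("theta must be in (0, 90) degrees")
  4 * pi * sin(theta * pi / 180) / wavelength
}

#' Constant-relative-width Q grid
#'
#' Geometric Q grid with bin width a fixed fraction of the bin centre
#' (default 2.5 percent), the binning used for time-of-flight specular
#' reflectivity.
#'
#' @param qmin,qmax Grid limits in 1/Angstrom.
#' @param frac Fractional bin width (default 0.025).
#' @return List with `Q` (bin centres) and `dQ` (FWHM resolution widths,
#'   `frac * Q`).
#' @export
q_grid_tof <- function(qmin = 0.008, qmax = 0.379, frac = 0.025) {
  n <- ceiling(log(qmax / qmin) / log(1 + frac))
  Q <- qmin * (1 + frac)^(0:n)
  Q <- Q[Q <= qmax * (1 + frac / 2)]
  list(Q = Q, dQ = frac * Q)
}

#' Specular reflectivity of a slab stack
#'
#' Recursive thin-film (Parratt) calculation with Nevot-Croce roughness
#' damping, computed in compiled code.
#'
#' @param q Ascending wavevector grid (1/Angstrom).
#' @param d Layer thicknesses (Angstrom), fronting to backing order.
#' @param rho Layer scattering length densities (1/Angstrom^2).
#' @param rho_front,rho_back Semi-infinite fronting/backing SLDs.
#' @param sigma Interfacial roughness (Angstrom), one per interface
#'   (`length(d) + 1`); default 0.
#' @return Reflectivity values R(Q), clamped to at most 1.
#' @export
reflectivity_slabs <- function(q, d, rho, rho_front, rho_back,
                               sigma = rep(0, length(d) + 1)) {
  if (is.unsorted(q, strictly = TRUE)) stop("q must be strictly ascending")
  abeles_cpp(q, as.numeric(d), as.numeric(rho), rho_front, rho_back,
             as.numeric(sigma))
}

#' Fresnel reflectivity of a single ideal interface
#'
#' @param q Wavevector grid (1/Angstrom).
#' @param rho_front,rho_back SLDs of the two half-spaces (1/Angstrom^2).
#' @return R_F(Q).
#' @export
fresnel_reflectivity <- function(q, rho_front, rho_back) {
  k0 <- q / 2
  k1 <- sqrt(as.complex(k0^2 - 4 * pi * (rho_back - rho_front)))
  Mod((k0 - k1) / (k0 + k1))^2
}

#' Normalize a reflectivity curve to the Fresnel reflectivity
#'
#' Divides R (and its uncertainty, multiplicatively) by the reflectivity
#' of a hypothetical single substrate/solution interface, to emphasise
#' interfacial structure.
#'
#' @param curve A list with at least `Q` and `R` (optionally `dR`).
#' @param substrate_sld,solvent_sld SLDs of the reference interface.
#' @return The curve with `R` (and `dR`) replaced by the Fresnel ratio and
#'   a logical `flagged` marking points where R_F vanished.
#' @export
fresnel_normalize <- function(curve, substrate_sld, solvent_sld) {
  rf <- fresnel_reflectivity(curve$Q, substrate_sld, solvent_sld)
  bad <- rf <= 0
  rf[bad] <- NA_real_
  curve$R <- curve$R / rf
  if (!is.null(curve$dR)) curve$dR <- curve$dR / rf
  curve$flagged <- bad
  curve
}

#' Gaussian resolution smearing of a reflectivity curve
#'
#' Convolves R(Q) with a Gaussian of FWHM dQ (sigma = dQ/2.355), using
#' linear interpolation of the tabulated curve over a +/- 3 sigma window;
#' near the ends of the grid the truncated kernel is renormalized
#' (one-sided smearing).
#'
#' @param q Ascending Q grid (1/Angstrom).
#' @param R Reflectivity values on `q`.
#' @param dQ Resolution FWHM, scalar or per-point vector. Zero returns
#'   `R` unchanged.
#' @param n_nodes Number of kernel nodes (default 21).
#' @return Smeared reflectivity on `q`.
#' @export
smear_resolution <- function(q, R, dQ, n_nodes = 21) {
  if (all(dQ <= 0)) return(R)
  nq <- length(q)
  sig <- rep(dQ, length.out = nq) / 2.3548200450309493
  t <- seq(-3, 3, length.out = n_nodes)
  w <- exp(-t^2 / 2)
  qq <- outer(sig, t) + q            # nq x n_nodes evaluation points
  inside <- qq >= q[1] & qq <= q[nq]
  ri <- matrix(NA_real_, nq, n_nodes)
  ri[inside] <- stats::approx(q, R, xout = qq[inside])$y
  wm <- matrix(w, nq, n_nodes, byrow = TRUE)
  wm[!inside] <- 0
  out <- rowSums(ri * wm, na.rm = TRUE) / rowSums(wm)
  out[sig <= 0] <- R[sig <= 0]
  out
}

#' Molecular volume from mass and bulk density
#'
#' @param mass_Da Molecular mass in daltons.
#' @param density Bulk mass density in g/cm^3.
#' @return Volume per molecule in Angstrom^3.
#' @export
molecular_volume <- function(mass_Da, density) {
  if (any(mass_Da <= 0) || any(density <= 0))
    stop("mass and density must be positive")
  mass_Da / (density * sdep_constants$NAv) * 1e24
}

#' Scattering length density from summed coherent scattering length
#'
#' rho = b / V with b in femtometres (1 fm = 1e-5 Angstrom) and V in
#' Angstrom^3.
#'
#' @param b_fm Summed coherent scattering length per formula unit (fm).
#' @param volume_A3 Molecular volume (Angstrom^3).
#' @return SLD in 1/Angstrom^2.
#' @export
sld_from_b_volume <- function(b_fm, volume_A3) {
  if (any(volume_A3 <= 0)) stop("molecular volume must be positive")
  b_fm * 1e-5 / volume_A3
}

# ---- composition-space model ---------------------------------------------

# reference scattering length densities (1/A^2) and molecular volumes (A^3)
# for the supported bilayer components; editable literature defaults
.sld_refs <- list(
  silicon = 2.069e-6,
  sio2 = 3.47e-6,
  d2o = 6.36e-6,
  h2o = -0.56e-6,
  peg = 0.7e-6,            # constant PEG nSLD
  headgroup = 1.88e-6,     # phosphocholine-like, b = 60.1 fm / 319 A^3
  tails = -0.30e-6         # di-acyl chains
)

.lipid_volumes <- list(V_tails = 972, V_head = 319)  # A^3 per lipid

#' PEG exclusion profile parameters
#'
#' The Boltzmann-weighted polymer volume fraction profile
#' c(z) = c_inf * exp(-E0 * exp(-2 kappa (z - z0))): far from the surface
#' the fraction is the bulk value `c_inf`; at the plane of charge `z0` the
#' polymer carries energy `E0` (k_B T) and is depleted accordingly, with
#' the exp(-2 kappa z) decay of the double-layer interaction.
#'
#' @param c_inf Bulk polymer volume fraction in `[0, 1]`.
#' @param kappa Inverse Debye length in 1/Angstrom (> 0).
#' @param z0 Position of the plane of charge (Angstrom).
#' @param E0 Interaction strength at z0 in k_B T (>= 0).
#' @return An object of class `peg_exclusion_profile`.
#' @export
peg_exclusion_profile <- function(c_inf, kappa, z0, E0) {
  if (c_inf < 0 || c_inf > 1) stop("c_inf must be in [0, 1]")
  if (kappa <= 0) stop("kappa must be positive")
  if (E0 < 0) stop("E0 must be non-negative")
  structure(list(c_inf = c_inf, kappa = kappa, z0 = z0, E0 = E0),
            class = "peg_exclusion_profile")
}

#' Evaluate the PEG volume fraction profile
#'
#' @param profile A [peg_exclusion_profile()].
#' @param z Positions in Angstrom.
#' @return Volume fractions (of the space available to solution) at `z`.
#' @export
peg_volume_fraction <- function(profile, z) {
  stopifnot(inherits(profile, "peg_exclusion_profile"))
  profile$c_inf *
    exp(-profile$E0 * exp(-2 * profile$kappa * (z - profile$z0)))
}

#' Exclusion distance of a fitted PEG profile
#'
#' The distance from the hydrophobic interface (outer lipid tails /
#' headgroup boundary) at which the polymer density reaches half its bulk
#' value: z_half = z0 + ln(E0 / ln 2) / (2 kappa), shifted to the
#' hydrophobic-interface origin. Requires E0 > ln 2 (otherwise the profile
#' never drops to half density and the exclusion region is below
#' resolution).
#'
#' @param profile A [peg_exclusion_profile()].
#' @param hydrophobic_z Position of the hydrophobic interface in the same
#'   coordinates as `profile$z0` (default 0).
#' @param numeric If `TRUE`, solve by bisection instead of the closed form
#'   (used for cross-checking; both agree to 0.01 Angstrom).
#' @return Distance in Angstrom.
#' @export
exclusion_distance <- function(profile, hydrophobic_z = 0, numeric = FALSE) {
  stopifnot(inherits(profile, "peg_exclusion_profile"))
  if (profile$E0 <= log(2))
    stop("exclusion below resolution: E0 <= ln 2, no half-density crossing")
  z_half <- profile$z0 + log(profile$E0 / log(2)) / (2 * profile$kappa)
  if (numeric) {
    f <- function(z) peg_volume_fraction(profile, z) - profile$c_inf / 2
    lo <- profile$z0
    hi <- z_half + 20 / profile$kappa
    z_half <- stats::uniroot(f, c(lo, hi), tol = 1e-4)$root
  }
  z_half - hydrophobic_z
}

# error-function box profile: volume fraction phi0 between z1 and z2 with
# gaussian-smeared edges of width sigma
.erf_box <- function(z, z1, z2, phi0, sigma) {
  if (sigma <= 0) return(phi0 * as.numeric(z >= z1 & z <= z2))
  phi0 * (stats::pnorm((z - z1) / sigma) - stats::pnorm((z - z2) / sigma))
}

#' Composition-space model of a supported bilayer with a PEG solution
#'
#' Arranges the molecular components of a solid-supported bilayer --
#' substrate oxide, inner and outer headgroups, acyl chains -- as
#' error-function-edged boxes along z (measured from the Si/oxide
#' interface, increasing into the solution), adds the PEG exclusion
#' profile scaled by the space not occupied by other components, and fills
#' the remainder with solvent.
#'
#' Lipid occupancies follow from the area per lipid `A_L`, the bilayer
#' completeness `coverage` and the packaged molecular volumes, so the
#' total bilayer volume per unit area, `2 * coverage * (V_tails + V_head)
#' / A_L`, is independent of the thickness parameters (volume
#' conservation by construction).
#'
#' @param pars Named list: `t_ox` (oxide thickness), `sig_sub` (substrate
#'   roughness), `d_w` (water gap), `t_h` (headgroup thickness per
#'   leaflet), `t_t` (tail thickness per leaflet), `A_L` (area per lipid,
#'   Angstrom^2), `coverage`, `sig_bil` (bilayer roughness), `c_inf`,
#'   `E0`, `kappa` (1/Angstrom), `rho_solvent` (solvent SLD, 1/Angstrom^2).
#'   All lengths in Angstrom.
#' @param z Evaluation grid (Angstrom); default 0.5-Angstrom steps
#'   spanning the structure plus 80 Angstrom of solution.
#' @return An object of class `composition_model`: list with `z`,
#'   occupancy matrix `phi` (columns oxide, heads_in, tails, heads_out,
#'   peg, solvent), `nsld`, geometry markers `z_hydrophobic` (outer
#'   tails/heads boundary), `z0` (plane of charge), and the input `pars`.
#' @export
composition_model <- function(pars, z = NULL) {
  p <- pars
  vol <- .lipid_volumes
  phi_t <- p$coverage * vol$V_tails / (p$A_L * p$t_t)
  phi_h <- p$coverage * vol$V_head / (p$A_L * p$t_h)
  if (phi_t > 1 + 1e-9 || phi_h > 1 + 1e-9)
    stop("model infeasible: component occupancy exceeds 1")
  z_ox2 <- p$t_ox
  z_hi1 <- z_ox2 + p$d_w
  z_hi2 <- z_hi1 + p$t_h
  z_ta2 <- z_hi2 + 2 * p$t_t
  z_ho2 <- z_ta2 + p$t_h
  z0 <- z_ta2 + p$t_h / 2          # plane of charge at outer headgroup centre
  # extend far enough that the polymer profile reaches bulk (residual
  # depletion energy below ~1e-3 kBT)
  z_ext <- max(70, log(max(p$E0, 1) / 1e-3) / (2 * p$kappa) + p$t_h)
  if (is.null(z)) z <- seq(0, z_ho2 + z_ext, by = 0.5)
  # the oxide extends through z = 0 into the substrate; the rough Si|oxide
  # interface itself is handled as a Nevot-Croce factor on the fronting
  # boundary in model_reflectivity()
  phi_ox <- .erf_box(z, -6 * p$sig_sub - 2, z_ox2, 1, p$sig_sub)
  phi_hin <- .erf_box(z, z_hi1, z_hi2, phi_h, p$sig_bil)
  phi_ta <- .erf_box(z, z_hi2, z_ta2, phi_t, p$sig_bil)
  phi_hout <- .erf_box(z, z_ta2, z_ho2, phi_h, p$sig_bil)
  occupied <- phi_ox + phi_hin + phi_ta + phi_hout
  if (any(occupied > 1 + 1e-9))
    stop("model infeasible: total occupancy exceeds 1")
  occupied <- pmin(occupied, 1)
  prof <- peg_exclusion_profile(p$c_inf, p$kappa, z0, p$E0)
  phi_peg <- peg_volume_fraction(prof, z) * (1 - occupied)
  phi_sol <- 1 - occupied - phi_peg
  phi <- cbind(oxide = phi_ox, heads_in = phi_hin, tails = phi_ta,
               heads_out = phi_hout, peg = phi_peg, solvent = phi_sol)
  nsld <- phi_ox * .sld_refs$sio2 +
    (phi_hin + phi_hout) * .sld_refs$headgroup +
    phi_ta * .sld_refs$tails +
    phi_peg * .sld_refs$peg +
    phi_sol * p$rho_solvent
  structure(list(z = z, phi = phi, nsld = nsld,
                 z_hydrophobic = z_ta2, z0 = z0, pars = p,
                 peg_profile = prof,
                 rho_bulk = (1 - p$c_inf) * p$rho_solvent +
                   p$c_inf * .sld_refs$peg),
            class = "composition_model")
}

#' Average nSLD profile of a composition model
#'
#' @param model A [composition_model()].
#' @return Data frame with `z` (Angstrom) and `nsld` (1/Angstrom^2).
#' @export
nsld_profile <- function(model) {
  stopifnot(inherits(model, "composition_model"))
  data.frame(z = model$z, nsld = model$nsld)
}

#' Forward reflectivity of a composition model
#'
#' Discretizes the continuous nSLD profile into thin slabs (interfacial
#' roughness is already encoded in the error-function edges, so the
#' microslabs themselves are sharp), computes the specular reflectivity
#' with silicon fronting and the bulk solution backing, and applies
#' Gaussian resolution smearing.
#'
#' @param model A [composition_model()].
#' @param q Ascending Q grid (1/Angstrom).
#' @param dQ Resolution FWHM (scalar or per-point); 0 for none.
#' @param slab Microslab thickness in Angstrom (default 0.5).
#' @return Reflectivity values on `q`.
#' @export
model_reflectivity <- function(model, q, dQ = 0, slab = 0.5) {
  z <- model$z
  rho_back <- model$rho_bulk
  # microslabs of width `slab` across the interfacial structure, widening
  # geometrically (up to 4 Angstrom) through the smooth polymer tail; the
  # slab edges move continuously with the model parameters, so the
  # reflectivity is a smooth function of them
  zmax <- max(z)
  z_fine <- min(model$z0 + model$pars$t_h + 15, zmax)
  # fixed slab counts with widths scaling continuously with the model
  # geometry, so the reflectivity is a smooth function of the parameters
  n_fine <- ceiling(90 / slab)
  n_tail <- 14L
  r <- 1.3
  w0 <- (zmax - z_fine) * (r - 1) / (r^n_tail - 1)
  edges <- c(seq(0, z_fine, length.out = n_fine + 1),
             z_fine + w0 * cumsum(r^(0:(n_tail - 1))))
  d_m <- diff(edges)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  rho_m <- stats::approx(z, model$nsld, xout = mid, rule = 2)$y
  nsig <- rep(0, length(d_m) + 1)
  nsig[1] <- model$pars$sig_sub   # rough Si|oxide fronting interface
  if (any(dQ > 0)) {
    # extend the Q grid so edge points can be smeared symmetrically
    sig <- rep(dQ, length.out = length(q)) / 2.3548
    lo <- max(q[1] - 3.2 * sig[1], 1e-4)
    hi <- q[length(q)] + 3.2 * sig[length(q)]
    qex <- exp(seq(log(lo), log(hi), length.out = 1.3 * length(q)))
    Rex <- abeles_cpp(qex, d_m, rho_m, .sld_refs$silicon, rho_back, nsig)
    gauss_smear_cpp(qex, Rex, q, sig)
  } else {
    abeles_cpp(q, d_m, rho_m, .sld_refs$silicon, rho_back, nsig)
  }
}
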