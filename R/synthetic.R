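#' Ground-truth generator for synthetic reflectometry experiments
#'
#' Builds a plausible solid-supported bilayer structure (native oxide,
#' hydration gap, two leaflets) bathed in a PEG solution, with the PEG
#' exclusion parameters tied to the double-layer theory for the chosen
#' lipid preset: kappa from the ionic strength and, unless overridden,
#' E0 = (K_D + K_H) / k_B T for a PEG600-sized sphere at the preset's
#' surface charge density. Neutral presets get a small steric-only
#' baseline E0.
#'
#' @param lipid `"DOPC"`, `"DOPC_DOPS"` or `"DOPC_DOTAP"`.
#' @param wt_pct_peg Nominal PEG weight percent of the solution (default
#'   9.1, i.e. a 10:1 solvent:PEG preparation).
#' @param ionic_strength Ionic strength in mol/L (default 0.11, the
#'   100 mM KCl + 10 mM tris buffer).
#' @param mw PEG molecular weight (default 600).
#' @param E0 Optional override of the interaction strength (k_B T), e.g.
#'   to embed a prescribed exclusion distance in a recovery study.
#' @param seed Integer seed stored with the truth; fully determines any
#'   simulated data drawn from it.
#' @return An object of class `ground_truth`: the [composition_model()]
#'   parameter list plus `medium`, `lipid`, `mw` and `seed`. The solvent
#'   SLD is set per contrast at simulation time.
#' @export
make_ssblm_truth <- function(lipid = c("DOPC", "DOPC_DOPS", "DOPC_DOTAP"),
                                  wt_pct_peg = 9.1, ionic_strength = 0.11,
                                  mw = 600, E0 = NULL, seed = 1) {
  lipid <- match.arg(lipid)
  medium <- ionic_medium(ionic_strength)
  interface <- lipid_preset(lipid)
  geom <- peg_geometry(mw)
  sphere <- dielectric_sphere(geom$R_h, 10, mw)
  if (is.null(E0)) {
    E0 <- if (interface$sigma == 0) 0.8 else {
      (dep_prefactor(sphere, interface, medium) +
         hydrostatic_prefactor(sphere, interface, medium)) /
        thermal_energy(medium$temperature)
    }
  }
  # bulk volume fraction from weight percent and the PEG/solvent densities
  c_inf <- wt_pct_peg / 100 * (1.105 / 1.13)
  pars <- list(t_ox = 15, sig_sub = 3, d_w = 8, t_h = 9, t_t = 14.5,
               A_L = 70, coverage = 0.95, sig_bil = 2.5,
               c_inf = c_inf, E0 = E0,
               kappa = medium$kappa * 1e-10,   # 1/Angstrom
               rho_solvent = .sld_refs$d2o)
  structure(c(pars, list(medium = medium, lipid = lipid, mw = mw,
                         seed = seed)),
            class = c("ground_truth", "list"))
}

.contrast_sld <- function(contrast) {
  switch(contrast,
         D2O = .sld_refs$d2o,
         H2O = .sld_refs$h2o,
         # water mixture contrast-matched to PEG: the polymer (and hence
         # its exclusion profile) becomes nearly invisible
         D2O_H2O_mix = .sld_refs$peg,
         stop("unsupported contrast: ", contrast))
}

#' Simulate specular count data for a ground truth
#'
#' Computes the smeared forward reflectivity of the truth on the
#' 0.008-0.379 1/Angstrom grid with 2.5 percent bins, converts it to
#' expected counts and draws Poisson samples, together with two
#' off-specular background channels. The incident intensity is `n0`
#' counts per bin, so the specular counts are about `n0` in the
#' total-reflection band and fall off Fresnel-like (as Q^-4) above it,
#' until the incoherent background -- a fraction `bg` of the incident
#' intensity -- takes over at high Q, as in measured data.
#'
#' @param truth A [make_ssblm_truth()] object.
#' @param contrast `"D2O"`, `"H2O"` or `"D2O_H2O_mix"`.
#' @param n0 Incident-count scale per bin at low Q (default 1e6).
#' @param bg Background level in reflectivity units (default 1e-6).
#' @param noise If `FALSE`, expected (noiseless) intensities are returned
#'   instead of Poisson draws.
#' @param seed Optional integer overriding `truth$seed`.
#' @return A count curve: list with `Q`, `I`, `I_off_lo`, `I_off_hi`,
#'   `I0`, `dQ`, plus attributes `R_true` (the noiseless smeared
#'   reflectivity) and `contrast`.
#' @export
simulate_reflectivity <- function(truth, contrast = "D2O", n0 = 1e6,
                                  bg = 1e-6, noise = TRUE, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  grid <- q_grid_tof()
  p <- truth[setdiff(names(truth), c("medium", "lipid", "mw", "seed"))]
  p$rho_solvent <- .contrast_sld(contrast)
  model <- composition_model(p)
  R_true <- model_reflectivity(model, grid$Q, grid$dQ)
  I0 <- rep(n0, length(grid$Q))
  mu_spec <- R_true * I0
  mu_bg <- bg * I0
  if (noise) {
    set.seed(if (is.null(seed)) truth$seed else seed)
    I <- stats::rpois(length(grid$Q), mu_spec + mu_bg)
    lo <- stats::rpois(length(grid$Q), mu_bg)
    hi <- stats::rpois(length(grid$Q), mu_bg)
  } else {
    I <- mu_spec + mu_bg; lo <- mu_bg; hi <- mu_bg
  }
  out <- list(Q = grid$Q, I = I, I_off_lo = lo, I_off_hi = hi,
              I0 = I0, dQ = grid$dQ)
  attr(out, "R_true") <- R_true
  attr(out, "contrast") <- contrast
  out
}

#' Simulate a charged/neutral pair of polymer density profiles
#'
#' The neutral-membrane profile is a smooth steric step,
#' m_n(z) = m_inf * Phi((z - R_h) / w); the charged-membrane profile
#' multiplies it by the Boltzmann factor exp(-A exp(-2 kappa z)) with the
#' amplitude A = exp(2 kappa d) chosen so that the charged-minus-neutral
#' free-energy difference crosses 1 k_B T exactly at the tabulated
#' depletion distance d for that molecular weight (16-28 Angstrom for
#' PEG600-PEG6000 at 0.1 M). Gaussian noise of standard deviation
#' `noise_sigma * m_inf` is added per bin.
#'
#' @param mw PEG molecular weight, one of 600, 1000, 1540, 2000, 3400,
#'   6000.
#' @param lipid Charged lipid preset for kappa bookkeeping (default
#'   `"DPPS"`); the embedded decay always uses `ionic_strength`.
#' @param ionic_strength mol/L (default 0.1).
#' @param noise_sigma Relative noise level (default 0.01).
#' @param seed Integer seed.
#' @param m_inf Bulk mass fraction (default 0.1, a 10 percent w/w
#'   solution).
#' @param z Bin-centre grid in Angstrom (default 0-80 in 1-Angstrom
#'   steps).
#' @return List with `charged` and `neutral` [density_profile()]s and a
#'   `truth` list (`A`, `kappa_A`, `d_embedded`).
#' @export
simulate_profiles <- function(mw, lipid = "DPPS", ionic_strength = 0.1,
                              noise_sigma = 0.01, seed = 1, m_inf = 0.1,
                              z = seq(0, 80, by = 1)) {
  d_table <- c(`600` = 16, `1000` = 18, `1540` = 20, `2000` = 22,
               `3400` = 26, `6000` = 28)
  key <- as.character(mw)
  if (!key %in% names(d_table)) stop("mw must be one of ",
                                     paste(names(d_table), collapse = ", "))
  d_emb <- unname(d_table[key])
  medium <- ionic_medium(ionic_strength)
  kap <- medium$kappa * 1e-10
  geom <- peg_geometry(mw)
  A <- exp(2 * kap * d_emb)
  m_neutral <- m_inf * stats::pnorm((z - geom$R_h) / 2)
  m_charged <- m_neutral * exp(-A * exp(-2 * kap * z))
  set.seed(seed)
  sig <- noise_sigma * m_inf
  noisy <- function(m) pmax(m + stats::rnorm(length(z), 0, sig), 0)
  ch <- if (noise_sigma > 0) noisy(m_charged) else m_charged
  ne <- if (noise_sigma > 0) noisy(m_neutral) else m_neutral
  list(charged = density_profile(z, ch, rep(sig, length(z))),
       neutral = density_profile(z, ne, rep(sig, length(z))),
       truth = list(A = A, kappa_A = kap, d_embedded = d_emb,
                    R_h = geom$R_h, m_inf = m_inf))
}
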