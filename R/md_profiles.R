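#' Tabulated density or free-energy profile
#'
#' @param z Ascending bin-centre grid in Angstrom (distance from the
#'   average z-position of the lipid charge).
#' @param value Mass fractions (>= 0) or free energies (k_B T).
#' @param sigma Optional per-bin 1-sigma uncertainties.
#' @param kind `"mass_fraction"` or `"energy"`.
#' @return An object of class `density_profile`.
#' @export
density_profile <- function(z, value, sigma = NULL,
                            kind = c("mass_fraction", "energy")) {
  kind <- match.arg(kind)
  if (is.unsorted(z, strictly = TRUE)) stop("z grid must be ascending")
  if (length(value) != length(z)) stop("value and z lengths differ")
  if (kind == "mass_fraction" && any(value < 0))
    stop("mass fractions must be non-negative")
  if (!is.null(sigma) && length(sigma) != length(z))
    stop("sigma and z lengths differ")
  structure(list(z = z, value = value, sigma = sigma, kind = kind),
            class = "density_profile")
}

#' Convert a mass-fraction profile to a free-energy profile
#'
#' E(z) = -ln(m(z) / m_inf) in k_B T, with the bulk value m_inf estimated
#' as the mean over a bulk window (default: the outermost 20 percent of
#' the z range). Bins with zero mass fraction become +Inf and are flagged
#' as censored. Uncertainties propagate as sigma_E = sigma_m / m.
#'
#' @param profile A mass-fraction [density_profile()].
#' @param bulk_window Length-2 z range used to estimate m_inf; `NULL` for
#'   the default outermost 20 percent.
#' @return An energy [density_profile()] with attributes `m_inf` and
#'   `censored` (logical per bin).
#' @export
massfrac_to_energy <- function(profile, bulk_window = NULL) {
  stopifnot(inherits(profile, "density_profile"),
            profile$kind == "mass_fraction")
  z <- profile$z
  if (is.null(bulk_window))
    bulk_window <- c(max(z) - 0.2 * diff(range(z)), max(z))
  in_bulk <- z >= bulk_window[1] & z <= bulk_window[2]
  if (!any(in_bulk)) stop("empty bulk window")
  m_inf <- mean(profile$value[in_bulk])
  if (m_inf <= 0) stop("bulk mass fraction must be positive")
  censored <- profile$value <= 0
  E <- -log(profile$value / m_inf)
  sig <- if (is.null(profile$sigma)) NULL else
    ifelse(censored, Inf, profile$sigma / profile$value)
  out <- density_profile(z, E, sig, kind = "energy")
  attr(out, "m_inf") <- m_inf
  attr(out, "censored") <- censored
  out
}

#' Invert a free-energy profile back to mass fractions
#'
#' m(z) = m_inf exp(-E(z)); inverse of [massfrac_to_energy()], used for
#' round-trip validation.
#'
#' @param profile An energy [density_profile()].
#' @param m_inf Bulk mass fraction.
#' @return A mass-fraction [density_profile()].
#' @export
energy_to_massfrac <- function(profile, m_inf) {
  stopifnot(inherits(profile, "density_profile"), profile$kind == "energy")
  density_profile(profile$z, m_inf * exp(-profile$value),
                  kind = "mass_fraction")
}

#' Charged-minus-neutral free-energy difference
#'
#' Interpolates both energy profiles onto the intersection of their z
#' ranges (the coarser grid) and subtracts the neutral-membrane energy,
#' isolating the charge-induced interaction. Uncertainties add in
#' quadrature.
#'
#' @param charged,neutral Energy [density_profile()]s.
#' @return An energy [density_profile()] of Delta E(z).
#' @export
delta_energy <- function(charged, neutral) {
  stopifnot(inherits(charged, "density_profile"),
            inherits(neutral, "density_profile"),
            charged$kind == "energy", neutral$kind == "energy")
  lo <- max(min(charged$z), min(neutral$z))
  hi <- min(max(charged$z), max(neutral$z))
  if (lo >= hi) stop("profiles have disjoint z ranges")
  z <- sort(unique(c(charged$z[charged$z >= lo & charged$z <= hi],
                     neutral$z[neutral$z >= lo & neutral$z <= hi])))
  Ec <- stats::approx(charged$z, charged$value, xout = z)$y
  En <- stats::approx(neutral$z, neutral$value, xout = z)$y
  sig <- NULL
  if (!is.null(charged$sigma) && !is.null(neutral$sigma)) {
    sc <- stats::approx(charged$z, charged$sigma, xout = z)$y
    sn <- stats::approx(neutral$z, neutral$sigma, xout = z)$y
    sig <- sqrt(sc^2 + sn^2)
  }
  density_profile(z, Ec - En, sig, kind = "energy")
}

#' Exponential-decay fit of an interaction free-energy profile
#'
#' Fits Delta E(z) = A exp(-z / l) by weighted least squares on
#' log Delta E (weights (value/sigma)^2, i.e. inverse variance of the
#' log). Non-positive bins inside the window are dropped with a warning
#' (window auto-shrink); fewer than 5 surviving points is an error.
#' Reports the amplitude, the decay length l with standard error, the
#' threshold distance d solving A exp(-d/l) = threshold with its
#' propagated uncertainty, and -- when a `medium` is supplied -- the
#' ratio of l to half the Debye length.
#'
#' @param profile An energy [density_profile()] of Delta E.
#' @param fit_window Length-2 z range; `NULL` uses the full grid.
#' @param threshold Threshold energy in k_B T (default 1).
#' @param medium Optional [ionic_medium()] for the decay-length ratio.
#' @return List with `amplitude`, `decay_length`, `decay_length_se`,
#'   `d`, `d_se`, `n_points`, and `decay_ratio` (l / (kappa^-1 / 2),
#'   NA without a medium).
#' @export
fit_decay <- function(profile, fit_window = NULL, threshold = 1,
                      medium = NULL) {
  stopifnot(inherits(profile, "density_profile"), profile$kind == "energy")
  z <- profile$z; v <- profile$value
  if (is.null(fit_window)) fit_window <- range(z)
  sel <- z >= fit_window[1] & z <= fit_window[2] & is.finite(v)
  if (any(v[sel] <= 0)) {
    warning("non-positive values in fit window dropped (window shrunk)")
    sel <- sel & v > 0
  }
  if (sum(sel) < 5) stop("fewer than 5 usable points in the fit window")
  zz <- z[sel]; vv <- v[sel]
  w <- if (!is.null(profile$sigma)) {
    s <- profile$sigma[sel]
    ifelse(is.finite(s) & s > 0, (vv / s)^2, 0)
  } else rep(1, length(zz))
  if (all(w == 0)) w <- rep(1, length(zz))   # noiseless input: unweighted
  fit <- stats::lm(log(vv) ~ zz, weights = w)
  co <- stats::coef(fit)
  V <- stats::vcov(fit)
  A <- exp(co[1])
  slope <- co[2]                      # = -1/l
  l <- -1 / slope
  l_se <- sqrt(V[2, 2]) / slope^2
  # d = (log A - log threshold) / (-slope); delta method on (a, b)
  d <- (co[1] - log(threshold)) / (-slope)
  grad <- c(1 / (-slope), (co[1] - log(threshold)) / slope^2)
  d_se <- sqrt(drop(t(grad) %*% V %*% grad))
  ratio <- if (is.null(medium)) NA_real_ else
    l / (1 / (medium$kappa * 1e-10) / 2)
  list(amplitude = unname(A), decay_length = unname(l),
       decay_length_se = unname(l_se), d = unname(d), d_se = unname(d_se),
       n_points = sum(sel), decay_ratio = unname(ratio))
}

#' Size scaling of the interaction energy with hydrodynamic radius
#'
#' Power-law exponent of Delta E evaluated at a common distance versus
#' R_h, from the slope of log Delta E against log R_h.
#'
#' @param curves List of energy [density_profile()]s (Delta E), one per
#'   molecular weight.
#' @param R_h Hydrodynamic radii (Angstrom), one per curve.
#' @param z_eval Evaluation distance in Angstrom.
#' @return List with `exponent`, `se` and the per-curve `values`.
#' @export
size_scaling <- function(curves, R_h, z_eval) {
  if (length(curves) < 3) stop("need at least 3 molecular weights")
  if (length(R_h) != length(curves)) stop("R_h and curves lengths differ")
  vals <- vapply(curves, function(p)
    stats::approx(p$z, p$value, xout = z_eval)$y, numeric(1))
  if (any(!is.finite(vals) | vals <= 0))
    stop("Delta E must be positive and finite at z_eval for all curves")
  fit <- stats::lm(log(vals) ~ log(R_h))
  list(exponent = unname(stats::coef(fit)[2]),
       se = sqrt(stats::vcov(fit)[2, 2]),
       values = vals)
}
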