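#' Order-of-magnitude report for a charged membrane in salt solution
#'
#' Runs the full chain of desk-scale double-layer estimates for a given
#' configuration and returns them as a labelled table: Debye length,
#' Grahame surface potential, lipid charge-density conversions, ion
#' excess one Debye length out, its van't Hoff pressure, the thermal and
#' hydrostatic force scales for a PEG600-sized sphere, and the
#' squared-field gradient at 5/10/15 Angstrom. Deterministic: identical
#' configurations give byte-identical tables.
#'
#' @param config Named list with `sigma_C_per_m2`, `ionic_strength_M`,
#'   `temperature_K` (default 298.15), `rel_permittivity` (default 78.5)
#'   and `R_h_A` (default 7).
#' @return Data frame with columns `quantity`, `value`, `units`,
#'   `produced_by`.
#' @export
run_discussion_chain <- function(config) {
  cfg <- utils::modifyList(
    list(temperature_K = 298.15, rel_permittivity = 78.5, R_h_A = 7),
    config)
  medium <- ionic_medium(cfg$ionic_strength_M, cfg$temperature_K,
                         cfg$rel_permittivity)
  interface <- charged_interface(cfg$sigma_C_per_m2)
  sphere <- dielectric_sphere(cfg$R_h_A)
  est <- discussion_estimates(sphere, interface, medium)
  sig_dpps <- sigma_from_area_per_charge(46, -1)
  sig_dptap <- sigma_from_area_per_charge(69.8, +1)
  data.frame(
    quantity = c("debye_length", "surface_potential",
                 "sigma_DPPS", "sigma_DPTAP",
                 "ion_excess_at_debye", "vant_hoff_pressure",
                 "pressure_gradient", "hydrostatic_force",
                 "thermal_force",
                 "grad_E2_5A", "grad_E2_10A", "grad_E2_15A"),
    value = c(est$debye_length_nm, est$surface_potential_V,
              abs(sig_dpps), sig_dptap,
              est$ion_excess_at_debye_M, est$vant_hoff_pressure_MPa,
              est$pressure_gradient_pN_per_nm3, est$hydrostatic_force_pN,
              est$thermal_force_pN,
              est$grad_E2_V2_per_m3[1], est$grad_E2_V2_per_m3[2],
              est$grad_E2_V2_per_m3[3]),
    units = c("nm", "V", "C/m^2", "C/m^2", "M", "MPa", "pN/nm^3", "pN",
              "pN", "V^2/m^3", "V^2/m^3", "V^2/m^3"),
    produced_by = c("debye_length", "grahame_potential",
                    "sigma_from_area_per_charge",
                    "sigma_from_area_per_charge",
                    "ion_excess", "osmotic_pressure_vant_hoff",
                    "discussion_estimates", "discussion_estimates",
                    "thermal_force",
                    "field_gradient_sq", "field_gradient_sq",
                    "field_gradient_sq"),
    stringsAsFactors = FALSE
  )
}

#' Read a reduced reflectivity curve from 4-column text
#'
#' Whitespace-separated columns Q, R, dR, dQ; lines starting with `#`
#' (including ORSO-style headers) are ignored.
#'
#' @param path File path.
#' @return List with `Q`, `R`, `dR`, `dQ`.
#' @export
read_reflectivity <- function(path) {
  tab <- utils::read.table(path, comment.char = "#")
  if (ncol(tab) < 4) stop("expected 4 columns: Q R dR dQ")
  list(Q = tab[[1]], R = tab[[2]], dR = tab[[3]], dQ = tab[[4]])
}

#' Write a reduced reflectivity curve as 4-column text
#'
#' @param curve List with `Q`, `R`, `dR`, `dQ`.
#' @param path File path.
#' @param header Optional comment lines (written prefixed with `#`).
#' @export
write_reflectivity <- function(curve, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  writeLines("# Q(1/A) R dR dQ(FWHM)", con)
  utils::write.table(
    data.frame(Q = curve$Q, R = curve$R, dR = curve$dR,
               dQ = rep(curve$dQ, length.out = length(curve$Q))),
    con, row.names = FALSE, col.names = FALSE)
}

#' Read a tabulated profile (z, value[, sigma]) from delimited text
#'
#' @param path File path.
#' @param kind Passed to [density_profile()].
#' @return A [density_profile()].
#' @export
read_profile <- function(path, kind = "mass_fraction") {
  tab <- utils::read.table(path, comment.char = "#")
  density_profile(tab[[1]], tab[[2]],
                  sigma = if (ncol(tab) >= 3) tab[[3]],
                  kind = kind)
}

#' Write a density profile as TSV
#'
#' @param profile A [density_profile()].
#' @param path File path.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(z_A = profile$z, value = profile$value)
  if (!is.null(profile$sigma)) df$sigma <- profile$sigma
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}
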