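#!/usr/bin/env Rscript
# Post-processing of (synthetic) polymer mass-fraction profiles near
# charged and neutral membranes: free-energy conversion, charged-minus-
# neutral subtraction, exponential-decay fits, 1 kBT threshold distances
# and the size-scaling exponent.
#
# Writes results/md_decay_fits.tsv. Seeded and fast.

library(sdep)

dir.create("results", showWarnings = FALSE)
medium <- ionic_medium(0.1)
kap <- medium$kappa * 1e-10
mws <- c(600, 1000, 1540, 2000, 3400, 6000)

rows <- list(); curves <- list(); radii <- numeric(0)
for (mw in mws) {
  sim <- simulate_profiles(mw, noise_sigma = 0.01, seed = 42 + mw)
  dE <- delta_energy(massfrac_to_energy(sim$charged),
                     massfrac_to_energy(sim$neutral))
  ok <- is.finite(dE$value)
  dE <- density_profile(dE$z[ok], dE$value[ok], dE$sigma[ok], kind = "energy")
  hi <- max(dE$z[dE$value > 0.1 & dE$z > sim$truth$R_h])
  fit <- suppressWarnings(fit_decay(dE, c(sim$truth$R_h + 2, hi),
                                    medium = medium))
  rows[[length(rows) + 1]] <- data.frame(
    mw = mw, R_h_A = sim$truth$R_h, d_embedded_A = sim$truth$d_embedded,
    d_fit_A = fit$d, d_se_A = fit$d_se,
    decay_length_A = fit$decay_length,
    decay_over_half_debye = fit$decay_ratio)
  curves[[length(curves) + 1]] <- dE
  radii <- c(radii, sim$truth$R_h)
}
tab <- do.call(rbind, rows)
write.table(format(tab, digits = 4), "results/md_decay_fits.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("Exponential-decay fits of charged-minus-neutral free energies:\n")
print(tab, digits = 3, row.names = FALSE)

sc <- size_scaling(curves, radii, z_eval = 24)
cat(sprintf("\nThe 1 kBT distance grows from %.1f to %.1f A between the lightest\nand heaviest chains and the fitted decay lengths sit within a few\npercent of half the Debye length (%.2f A). The interaction amplitude\ngrows as R_h^%.2f (+/- %.2f) at fixed distance: the fixtures embed the\nsimulation-derived threshold table, whose amplitudes rise somewhat more\nslowly than the strict cubic law of the rigid-sphere theory (see\n02_theory_curves.R, where the closed-form curves scale exactly as\nR_h^3).\n",
            min(tab$d_fit_A), max(tab$d_fit_A), 1 / (2 * kap),
            sc$exponent, sc$se))
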