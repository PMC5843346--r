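#!/usr/bin/env Rscript
# Geometric observables of a simulated adsorption trajectory: z_L-P descent,
# dipole elevation above the membrane plane, and bound-state histograms over
# the final 70% window. Writes results/adsorption_series.csv and
# results/bound_histograms.csv.

suppressMessages(library(memdipole))
dir.create("results", showWarnings = FALSE)

cat("== Adsorption run: 400 D dipolar body, +200 mV, 100 mM NaCl ==\n")
b <- two_pole_body(400, 0, D_t = 0.1, D_r = 0.05)
fld <- field_model(200, salt_mM = 100, plane_z = 0)
sim <- simulate_bd(b, fld, 3e4, 0.01, seed = 301, z0 = 4, record_every = 30)
dirs <- memdipole:::sim_dipole_dirs(b, sim)
theta <- 90 - acos(pmin(1, pmax(-1, dirs[, 3]))) * 180 / pi  # elevation
series <- data.frame(time_ns = sim$time, z_nm = sim$z,
                     theta_deg = theta, energy_kjmol = sim$energy)
write.csv(series, "results/adsorption_series.csv", row.names = FALSE)
cat(sprintf("  descent: z = %.2f nm at t = 0 to mean %.2f nm over last 70%%\n",
            sim$z[1], mean(sim$z[sim$time >= 0.3 * max(sim$time)])))
cat(sprintf("  final-window dipole elevation: %.1f deg (field-aligned)\n",
            mean(theta[sim$time >= 0.3 * max(sim$time)])))

hz <- bound_window_histogram(sim$time, sim$z, bins = 40)
ht <- bound_window_histogram(sim$time, theta, bins = 40)
hist_df <- rbind(
  data.frame(observable = "z_lp_nm",
             mid = (hz$bin_edges[-1] + hz$bin_edges[-length(hz$bin_edges)]) / 2,
             density = hz$density),
  data.frame(observable = "theta_deg",
             mid = (ht$bin_edges[-1] + ht$bin_edges[-length(ht$bin_edges)]) / 2,
             density = ht$density))
write.csv(hist_df, "results/bound_histograms.csv", row.names = FALSE)

cat("\n== Cross-check against a scripted reference trajectory ==\n")
mem <- make_membrane_frames(64, plane_z = 3, jitter = 0.03,
                            z_script = seq(4.5, 2, length.out = 50),
                            theta_script = seq(-10, -70, length.out = 50),
                            seed = 302)
obs <- trajectory_observables(mem$traj, mem$protein_indices, mem$p_indices)
err <- max(abs(obs$z_lp - mem$truth$z))
cat(sprintf("  recovered scripted z_L-P ramp with max error %.3g nm (P-plane jitter 0.03 nm)\n",
            err))
cat("\nwrote results/adsorption_series.csv, results/bound_histograms.csv\n")
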