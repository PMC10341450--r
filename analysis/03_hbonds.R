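#!/usr/bin/env Rscript
# Hydrogen-bond statistics and lifetimes: per-frame probe-water bond
# counts, bond probabilities, and the strict-persistence autocorrelation
# with its bi-exponential lifetime fit.  The probe's Markov ground truth
# (dwell 30 ps, occupancy 1/3) is recorded next to the recovered values;
# the short toy replicas give the exact per-frame indicator, while the
# lifetime statistics are computed at analysis length (160 ns x 3) from
# the same kinetics.

suppressPackageStartupMessages(library(channelflow))

models <- c("0000", "1000c")
n_replicas <- 3
dir.create("results/hbonds", recursive = TRUE, showWarnings = FALSE)

stat_rows <- list()
for (m in models) {
  for (r in seq_len(n_replicas)) {
    stem <- sprintf("scratch/synthetic/%s_rep%d", m, r)
    top <- read_structure(paste0(stem, ".psf"))$topology
    traj <- read_trajectory(paste0(stem, ".dcd"), top)
    ser <- residue_water_hbond_stats(traj,
                                     data.frame(chain = "P", resid = 1001))
    truth <- jsonlite::read_json(paste0(stem, "_truth.json"),
                                 simplifyVector = TRUE)
    stat_rows[[paste(m, r)]] <- data.frame(
      model = m, replica = r,
      mean_bonds = ser$mean_count, bond_probability = ser$probability,
      truth_occupancy = truth$true_occupancy,
      indicator_mismatches = sum(ser$h != truth$probe_h))
  }
}
stats <- do.call(rbind, stat_rows)
write.csv(stats, "results/hbonds/probe_water_stats.csv", row.names = FALSE)
cat("probe-water bond indicator mismatches vs ground truth:",
    sum(stats$indicator_mismatches), "\n")

# lifetimes at analysis length: 160 ns x 3 replicas, dt = 2 ps
life_rows <- lapply(1:3, function(r) {
  g <- generate_hbond_series(1 / 60, 1 / 30, 2, 80000, seed = 4200 + r)
  ac <- hbond_autocorrelation(g$h, dt = 2)
  lf <- fit_lifetime(ac)
  data.frame(replica = r, A = lf$A, tau1 = lf$tau1, B = lf$B,
             tau2 = lf$tau2, tau = lf$tau, determined = lf$determined)
})
life <- do.call(rbind, life_rows)
write.csv(life, "results/hbonds/lifetimes.csv", row.names = FALSE)
st <- replica_average(life$tau)
cat(sprintf("fitted H-bond lifetime: %s ps (true dwell 30 ps)\n",
            format_pm(st$mean, st$se)))
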