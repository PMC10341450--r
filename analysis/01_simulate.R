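#!/usr/bin/env Rscript
# Build the study's synthetic systems: toy channel trajectories with known
# per-slice water occupancy, a probe residue with known hydrogen-bond
# kinetics, and (for the hydronium models) a stationary H3O+ at its
# labelled height.  Three replicas per protonation model, written to
# scratch/ as PDB + PSF + DCD + ground-truth JSON for the later stages.

suppressPackageStartupMessages(library(channelflow))

models <- c("0000", "1000c")   # one plain model, one with H3O+ at height c
n_replicas <- 3
base_seed <- 20260928

dir.create("scratch/synthetic", recursive = TRUE, showWarnings = FALSE)

for (m in models) {
  pm <- parse_model_code(m)
  for (r in seq_len(n_replicas)) {
    spec <- synthetic_channel_spec(
      n_frames = 500, frame_interval = 2,
      per_slice_waters = rep(10L, 15), n_bulk_waters = 50,
      hydronium = if (is.na(pm$hydronium_position)) NA_character_
      else pm$hydronium_position,
      probes = data.frame(label = "probe1", k_on = 1 / 60, k_off = 1 / 30),
      seed = base_seed + 100 * match(m, models) + r)
    sys <- generate_system(spec)
    paths <- write_system(sys, "scratch/synthetic",
                          name = sprintf("%s_rep%d", m, r))
    cat(sprintf(
      "model %s replica %d: %d atoms, %d frames, %d channel waters%s\n",
      m, r, nrow(sys$traj$topology), n_frames(sys$traj),
      sum(spec$per_slice_waters),
      if (!is.na(spec$hydronium))
        sprintf(", H3O+ at z = %.1f A", sys$truth$hydronium_z) else ""))
  }
}
cat("wrote", length(models) * n_replicas, "systems to scratch/synthetic\n")
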