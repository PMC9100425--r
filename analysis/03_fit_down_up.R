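#!/usr/bin/env Rscript
# Step 3: flexible-fitting campaign of the DOWN-UP state model against the
# preprocessed reference frame (which was generated from the down-down
# state): 3 Langevin replicas under V_protein + V_stage + V_AFM.

library(afmflex)
href <- read_image("results/reference_cropped.grid")
toy <- make_toy_complex()
topo <- toy_topology(toy$reference_down_up)

start <- perturb_structure(toy$reference_down_up,
                           translation = 2 * c(3, 3, 2) / sqrt(22),
                           jitter_sd = 0.2, seed = 31)
cfg <- run_config(n_steps = 6e4, record_interval = 300, n_replicas = 3,
                  seed = 41)
fit <- run_fitting_campaign(start, topo, href, cfg)
print(fit)

for (r in seq_along(fit$trajectories))
  write_trajectory_records(fit$trajectories[[r]],
                           sprintf("results/fit_down_up_replica%d.csv", r))
write_cg_pdb(fit$best$structure, "results/fit_down_up_best.pdb")
write_image(fit$best$image, "results/fit_down_up_best.grid")
dir.create("scratch", showWarnings = FALSE)
saveRDS(fit, "scratch/fit_down_up.rds") # large binary: scratch only
cat(sprintf("Best c.s. %.4f (replica %d); per-replica maxima: %s\n",
            fit$best$cs, fit$best$replica,
            paste(sprintf("%.4f", fit$per_replica_max), collapse = ", ")))
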