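test_that("equal seeds give bitwise-identical trajectories", {
  tc <- toy_cache()
  href <- make_cropped_reference(tc$toy$reference_down_up, seed = 5)
  cfg <- run_config(n_steps = 3000, record_interval = 100, seed = 17)
  bias <- list(h_ref = href, mask = NULL)
  tr1 <- run_langevin(tc$toy$reference_down_up, tc$tu, cfg, bias = bias,
                      stream = 2)
  tr2 <- run_langevin(tc$toy$reference_down_up, tc$tu, cfg, bias = bias,
                      stream = 2)
  expect_identical(tr1$records$cs, tr2$records$cs)
  expect_identical(tr1$final$coords, tr2$final$coords)
  # a different stream is a different trajectory
  tr3 <- run_langevin(tc$toy$reference_down_up, tc$tu, cfg, bias = bias,
                      stream = 3)
  expect_false(identical(tr1$records$cs, tr3$records$cs))
})

test_that("zero-temperature dynamics descend the potential", {
  tc <- toy_cache()
  start <- perturb_structure(tc$toy$reference_down_up, jitter_sd = 0.15,
                             seed = 8)
  cfg <- run_config(n_steps = 4000, record_interval = 200, k_bias = 0,
                    temperature = 0, seed = 8)
  tr <- run_langevin(start, tc$tu, cfg)
  pot <- tr$records$e_protein + tr$records$e_stage
  expect_true(all(diff(pot) <= 1e-6))
})

test_that("the reference state only wobbles under its own potential", {
  # thermal stability run: bead localization by ~5 kT contact wells bounds
  # the superposed RMSD at the nm scale; sustained growth would mean escape
  tc <- toy_cache()
  fil <- which(tc$toy$complex$chain %in% c("actinA", "actinB"))
  cfg <- run_config(n_steps = 5e4, record_interval = 500, k_bias = 0,
                    seed = 9)
  tr <- run_langevin(tc$toy$complex, tc$tu, cfg,
                     restraints = position_restraints(tc$toy$complex, fil,
                                                      k = 0.2))
  rms <- sapply(seq_len(nrow(tr$records)), function(i)
    rmsd(snapshot_structure(tr, i), tc$toy$reference_down_up,
         superpose = TRUE))
  expect_lt(mean(rms), 1.5)
  expect_lt(max(rms), 3)
})

test_that("temperature estimation requires enough records", {
  tc <- toy_cache()
  cfg <- run_config(n_steps = 1000, record_interval = 100, k_bias = 0,
                    seed = 4)
  tr <- run_langevin(tc$toy$reference_down_up, tc$tu, cfg)
  expect_error(temperature_estimate(tr), "100 records")
})

test_that("a frozen run reports zero temperature", {
  s <- cg_structure(rbind(c(0, 0, 5), c(1, 0, 5)))
  topo <- build_topology(s, contact_cutoff = 0.1)
  cfg <- run_config(n_steps = 2e4, record_interval = 100, k_bias = 0,
                    temperature = 0, seed = 4, stage_epsilon = 0)
  tr <- run_langevin(s, topo, cfg)
  expect_lt(temperature_estimate(tr), 1e-8)
})

test_that("a thermalized bonded pair satisfies equipartition", {
  s <- cg_structure(rbind(c(0, 0, 5), c(1, 0, 5)))
  topo <- build_topology(s, contact_cutoff = 0.1)
  cfg <- run_config(n_steps = 2e5, record_interval = 100, k_bias = 0,
                    seed = 3, stage_epsilon = 0)
  tr <- run_langevin(s, topo, cfg)
  t_est <- temperature_estimate(tr)
  expect_gt(t_est, 285)
  expect_lt(t_est, 315)
  # doubling the friction leaves the estimate unchanged within tolerance
  cfg2 <- cfg; cfg2$friction <- 2 * cfg$friction
  t_est2 <- temperature_estimate(run_langevin(s, topo, cfg2))
  expect_lt(abs(t_est2 - t_est), 15)
})

test_that("biased fitting shows a rising-then-saturating similarity trend", {
  tc <- toy_cache()
  href <- make_cropped_reference(tc$toy$reference_down_up, seed = 5)
  start <- perturbed_start(tc$toy$reference_down_up, seed = 12)
  fil <- which(start$chain %in% c("actinA", "actinB"))
  cfg <- run_config(n_steps = 6e4, record_interval = 300, seed = 13)
  tr <- run_langevin(start, tc$tu, cfg, bias = list(h_ref = href),
                     restraints = position_restraints(start, fil, k = 0.2))
  cs <- tr$records$cs
  blocks <- sapply(split(cs, ceiling(seq_along(cs) / 25)), mean)
  sat <- max(blocks)
  rising <- blocks < sat - 0.005
  if (any(rising)) {
    upto <- max(which(rising))
    if (upto > 1)
      expect_true(all(diff(blocks[1:upto]) > -0.002))
  }
  expect_gt(sat, cs[1])
})

test_that("aborted replicas surface as a dynamics error with a snapshot", {
  # a structure rendering to zero on the mask aborts immediately
  tc <- toy_cache()
  href <- make_cropped_reference(tc$toy$reference_down_up, seed = 5)
  far <- tc$toy$reference_down_up
  far$coords[, 1] <- far$coords[, 1] + 500
  cfg <- run_config(n_steps = 1000, record_interval = 100, seed = 3)
  err <- tryCatch(
    run_langevin(far, tc$tu, cfg, bias = list(h_ref = href)),
    afmflex_dynamics_error = function(e) e)
  expect_s3_class(err, "afmflex_dynamics_error")
  expect_true(is.matrix(err$snapshot))
})
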