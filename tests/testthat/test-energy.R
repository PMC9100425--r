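test_that("a 3-bead linear chain yields 2 bonds, 1 straight angle, 0 contacts", {
  s <- cg_structure(rbind(c(0, 0, 0), c(0.38, 0, 0), c(0.76, 0, 0)))
  topo <- build_topology(s)
  expect_equal(nrow(topo$bonds), 2L)
  expect_equal(topo$bonds$r0, c(0.38, 0.38), tolerance = 1e-12)
  expect_equal(nrow(topo$angles), 1L)
  expect_equal(topo$angles$th0, pi, tolerance = 1e-9)
  expect_equal(nrow(topo$contacts), 0L)
})

test_that("chains with a single bead get no bonded terms, with a warning", {
  s <- cg_structure(rbind(c(0, 0, 1), c(5, 0, 1), c(5.4, 0, 1)),
                    chain = c("A", "B", "B"))
  expect_warning(topo <- build_topology(s), "chain A")
  expect_equal(nrow(topo$bonds), 1L)
})

test_that("native-contact extraction matches a brute-force pair scan", {
  tc <- toy_cache()
  s <- tc$toy$reference_down_up
  cutoff <- s$meta$build_args$contact_cutoff
  n <- n_beads(s)
  count <- 0L
  for (i in 1:(n - 1))
    for (j in (i + 1):n) {
      d <- sqrt(sum((s$coords[i, ] - s$coords[j, ])^2))
      elig <- s$chain[i] != s$chain[j] || abs(s$resid[i] - s$resid[j]) >= 3
      if (d < cutoff && elig) count <- count + 1L
    }
  expect_equal(nrow(tc$tu$contacts), count)
})

test_that("the reference conformation is an energy minimum of its topology", {
  tc <- toy_cache()
  ref <- tc$toy$reference_down_up
  e0 <- protein_energy_forces(ref, tc$tu)$energy
  expect_lt(max(abs(protein_energy_forces(ref, tc$tu)$forces)), 1e-8)
  for (seed in 1:100) {
    pert <- perturb_structure(ref, jitter_sd = 0.05, seed = seed)
    expect_gt(protein_energy_forces(pert, tc$tu)$energy, e0)
  }
})

test_that("a stretched bond follows the closed-form harmonic energy", {
  s <- cg_structure(rbind(c(0, 0, 5), c(1, 0, 5)))
  topo <- build_topology(s, bond_k = 7)
  for (d in c(0.05, 0.2, -0.1)) {
    s2 <- s; s2$coords[2, 1] <- 1 + d
    expect_equal(protein_energy_forces(s2, topo)$energy, 7 * d^2,
                 tolerance = 1e-12)
  }
})

test_that("protein forces match central finite differences", {
  tc <- toy_cache()
  h <- 1e-6
  for (cfg_seed in 1:6) {
    s <- perturb_structure(tc$toy$reference_down_up, jitter_sd = 0.08,
                           seed = 40 + cfg_seed)
    F <- protein_energy_forces(s, tc$tu)$forces
    set.seed(cfg_seed)
    for (t in 1:5) {
      b <- sample(n_beads(s), 1); d <- sample(3, 1)
      sp <- s; sp$coords[b, d] <- sp$coords[b, d] + h
      sm <- s; sm$coords[b, d] <- sm$coords[b, d] - h
      fd <- -(protein_energy_forces(sp, tc$tu)$energy -
              protein_energy_forces(sm, tc$tu)$energy) / (2 * h)
      expect_lt(abs(F[b, d] - fd), 1e-5 * max(0.1, abs(fd)))
    }
  }
})

test_that("isolated-system forces carry no net translation or torque", {
  tc <- toy_cache()
  for (seed in 1:5) {
    s <- perturb_structure(tc$toy$reference_down_up, jitter_sd = 0.1,
                           seed = 60 + seed)
    F <- protein_energy_forces(s, tc$tu)$forces
    expect_lt(max(abs(colSums(F))), 1e-8)
    ctr <- colMeans(s$coords)
    r <- sweep(s$coords, 2, ctr)
    torque <- colSums(cbind(r[, 2] * F[, 3] - r[, 3] * F[, 2],
                            r[, 3] * F[, 1] - r[, 1] * F[, 3],
                            r[, 1] * F[, 2] - r[, 2] * F[, 1]))
    expect_lt(max(abs(torque)), 1e-7)
  }
})

test_that("the stage wall has its minimum -eps at z = sigma and decays away", {
  s1 <- cg_structure(rbind(c(0, 0, 1.3), c(5, 0, 1.3)), radius = 0.4)
  p <- stage_params(epsilon = 0.25, sigma = 1.3)
  out <- stage_energy_forces(s1, p)
  expect_equal(out$energy, -2 * 0.25, tolerance = 1e-12)
  expect_lt(max(abs(out$forces)), 1e-12)
  far <- cg_structure(rbind(c(0, 0, 1e5)), radius = 0.4)
  expect_lt(abs(stage_energy_forces(far, p)$energy), 1e-25)
})

test_that("stage forces are vertical and match finite differences", {
  set.seed(70)
  zs <- runif(12, 0.8, 5)
  s <- cg_structure(cbind(runif(12), runif(12), zs), radius = 1)
  p <- stage_params(epsilon = 0.2, sigma = 1.1)
  out <- stage_energy_forces(s, p)
  expect_true(all(out$forces[, 1:2] == 0))
  h <- 1e-6
  for (b in 1:12) {
    sp <- s; sp$coords[b, 3] <- zs[b] + h
    sm <- s; sm$coords[b, 3] <- zs[b] - h
    fd <- -(stage_energy_forces(sp, p)$energy -
            stage_energy_forces(sm, p)$energy) / (2 * h)
    expect_lt(abs(out$forces[b, 3] - fd), 1e-6 * max(0.1, abs(fd)))
  }
})

test_that("beads below the stage cap get finite energy and forces", {
  s <- cg_structure(rbind(c(0, 0, 0.05)), radius = 1)
  expect_message(out <- stage_energy_forces(s, stage_params(0.2, 1)),
                 "cap")
  expect_true(all(is.finite(c(out$energy, out$forces))))
})

test_that("restraints vanish at zero multiplier and at equilibrium", {
  s <- cg_structure(rbind(c(0, 0, 1), c(3, 0, 1)))
  rs <- restraint_set(pairs = data.frame(i = 1, j = 2, k = 5, d0 = 1),
                      schedule = c(0, 1))
  expect_equal(restraint_energy_forces(s, rs, 1L)$energy, 0)
  rs2 <- restraint_set(pairs = data.frame(i = 1, j = 2, k = 5, d0 = 3),
                       schedule = 1)
  out <- restraint_energy_forces(s, rs2, 1L)
  expect_equal(out$energy, 0)
  expect_lt(max(abs(out$forces)), 1e-12)
  # energy follows 0.5 k_eff (d - d0)^2
  rs3 <- restraint_set(pairs = data.frame(i = 1, j = 2, k = 5, d0 = 2),
                       schedule = c(0.2, 0.4, 0.6, 0.8, 1.0))
  expect_equal(restraint_energy_forces(s, rs3, 3L)$energy,
               0.5 * (0.6 * 5) * (3 - 2)^2, tolerance = 1e-12)
})

test_that("the five-step schedule drives the restrained bead to its target", {
  tc <- toy_cache()
  s0 <- tc$toy$reference_down_up
  tip <- which(s0$chain == "myoT")[29] # stalk end
  target <- s0$coords[tip, ] + c(0, -6, 4)
  rs <- restraint_set(anchors = data.frame(bead = tip, x = target[1],
                                           y = target[2], z = target[3],
                                           k = 2, d0 = 0))
  med_dist <- sapply(1:5, function(stage) {
    median(sapply(1:3, function(seed) {
      cfg <- run_config(n_steps = 6000, record_interval = 1000, k_bias = 0,
                        seed = seed)
      tr <- run_langevin(s0, tc$tu, cfg, restraints = rs,
                         restraint_stage = stage)
      sqrt(sum((tr$final$coords[tip, ] - target)^2))
    }))
  })
  expect_true(all(diff(med_dist) < 0))
})

test_that("switching to the same reference reproduces the topology", {
  tc <- toy_cache()
  again <- switch_reference(tc$tu, tc$toy$reference_down_up)
  expect_equal(again$bonds, tc$tu$bonds)
  expect_equal(again$angles, tc$tu$angles)
  expect_equal(again$contacts, tc$tu$contacts)
})

test_that("switching states changes lever contacts but not filament terms", {
  tc <- toy_cache()
  td <- switch_reference(tc$tu, tc$toy$reference_down_down)
  s <- tc$toy$reference_down_up
  fil <- which(s$chain %in% s$meta$filament_chains)
  fil_only <- function(topo)
    topo$contacts[topo$contacts$i %in% fil & topo$contacts$j %in% fil, ]
  expect_equal(fil_only(td), fil_only(tc$tu))
  lever <- s$meta$lead_neck_beads
  lever_set <- function(topo)
    topo$contacts[topo$contacts$i %in% lever | topo$contacts$j %in% lever,
                  c("i", "j")]
  expect_false(isTRUE(all.equal(lever_set(td), lever_set(tc$tu))))
  # mismatched layouts are rejected
  bad <- cg_structure(s$coords[1:10, ], radius = s$radius[1:10],
                      chain = s$chain[1:10])
  expect_error(switch_reference(tc$tu, bad), "mismatch")
})

test_that("dynamics under a switched topology relaxes toward the new state", {
  tc <- toy_cache()
  td <- switch_reference(tc$tu, tc$toy$reference_down_down)
  fil <- which(tc$toy$complex$chain %in% c("actinA", "actinB"))
  cfg <- run_config(n_steps = 5e4, record_interval = 500, k_bias = 0,
                    seed = 3)
  tr <- run_langevin(tc$toy$reference_down_up, td, cfg,
                     restraints = position_restraints(
                       tc$toy$reference_down_up, fil, k = 0.2))
  d_new <- rmsd(tr$final, tc$toy$reference_down_down, superpose = TRUE)
  d_old <- rmsd(tr$final, tc$toy$reference_down_up, superpose = TRUE)
  expect_lt(d_new, d_old)
})
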