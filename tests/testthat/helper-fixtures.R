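# Fixtures are built in code: tiny PDB files, random structures/images, an
# independent (untruncated, pure-R) smoothed renderer used as oracle, and a
# minimal fit_result stand-in for distribution-level tests.

write_tiny_pdb <- function(path, chains) {
  # chains: named list, each an n x 3 matrix of CA coordinates in Angstrom
  lines <- character(0)
  serial <- 0L
  for (ch in names(chains)) {
    xyz <- chains[[ch]]
    for (i in seq_len(nrow(xyz))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, ch, i, xyz[i, 1], xyz[i, 2], xyz[i, 3]))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

random_structure <- function(n, seed, xr = c(0, 12), yr = c(0, 9),
                             zr = c(0.5, 4), radius = 0.38) {
  set.seed(seed)
  cg_structure(cbind(runif(n, xr[1], xr[2]), runif(n, yr[1], yr[2]),
                     runif(n, zr[1], zr[2])), radius = radius)
}

random_image <- function(nx, ny, seed, lo = -1, hi = 5, dx = 1.5) {
  set.seed(seed)
  afm_image(matrix(runif(nx * ny, lo, hi), ny, nx), dx = dx)
}

# untruncated pure-R smoothed renderer (independent oracle)
r_render_smooth <- function(s, grid, sx, sy, gamma) {
  H <- matrix(0, grid$ny, grid$nx)
  ztop <- s$coords[, 3] + s$radius
  for (j in seq_len(grid$ny)) {
    yp <- grid$y0 + (j - 1) * grid$dy
    for (i in seq_len(grid$nx)) {
      xp <- grid$x0 + (i - 1) * grid$dx
      a <- ztop / gamma - (s$coords[, 1] - xp)^2 / (2 * sx^2) -
        (s$coords[, 2] - yp)^2 / (2 * sy^2)
      M <- max(0, a)
      H[j, i] <- gamma * (M + log(exp(-M) + sum(exp(a - M))))
    }
  }
  afm_image(H, dx = grid$dx, dy = grid$dy, x0 = grid$x0, y0 = grid$y0)
}

# minimal fit_result carrying only what distribution-level code reads
fake_fit <- function(cs_by_replica, label = "state") {
  trajs <- lapply(cs_by_replica, function(v)
    list(records = data.frame(step = seq_along(v), cs = v)))
  h <- afm_image(matrix(1, 2, 2))
  structure(list(label = label, trajectories = trajs,
                 h_ref = h, mask = NULL,
                 config = run_config(n_steps = 10, record_interval = 1,
                                     n_replicas = length(cs_by_replica)),
                 template = NULL),
            class = "fit_result")
}

# shared toy complex and topologies (built once per test run)
toy_cache <- local({
  env <- new.env()
  function() {
    if (is.null(env$toy)) {
      env$toy <- make_toy_complex()
      env$tu <- toy_topology(env$toy$reference_down_up)
      env$td <- toy_topology(env$toy$reference_down_down)
    }
    list(toy = env$toy, tu = env$tu, td = env$td)
  }
})

# standard frame masks (1-based inclusive pixel indices on the 80 x 40 frame)
stage_mask_frame <- function() region_mask(43, 80, 30, 39)
fit_mask_frame <- function() region_mask(26, 65, 1, 30)
neck_mask_frame <- function() region_mask(33, 57, 12, 23)
# the neck mask re-indexed on the image cropped to the fitting region
neck_mask_cropped <- function() region_mask(33 - 25, 57 - 25, 12, 23)

# preprocessed (leveled, cropped) reference from a structure, default noise
make_cropped_reference <- function(structure, seed = 1) {
  img <- make_reference_image(structure, method = "smooth",
                              params = renderer_params(),
                              corruption = image_corruption_spec(seed = seed))
  pl <- fit_stage_plane(img, stage_mask_frame())
  crop_region(level_image(img, pl), fit_mask_frame())
}

# standard 2 nm offset + 0.2 nm jitter starting point for fitting tests
perturbed_start <- function(structure, seed) {
  off <- 2 * c(3, 3, 2) / sqrt(sum(c(3, 3, 2)^2))
  perturb_structure(structure, translation = off, jitter_sd = 0.2, seed = seed)
}
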