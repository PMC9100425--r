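test_that("an empty structure renders an all-zero image with a warning", {
  s <- cg_structure(matrix(numeric(0), 0, 3))
  p <- renderer_params(grid = image_grid(nx = 5, ny = 4, dx = 1))
  expect_warning(img <- render_smooth(s, p), "empty")
  expect_true(all(img$heights == 0))
  expect_warning(imgc <- render_collision(s, p), "empty")
  expect_true(all(imgc$heights == 0))
})

test_that("the smooth renderer approaches the bead top in the sharp limit", {
  # one bead directly over the pixel (2,2) center of a 1 nm grid
  s <- cg_structure(rbind(c(1, 1, 2)), radius = 0.38)
  p <- renderer_params(sigma_x = 1e-3, sigma_y = 1e-3, gamma = 1e-4,
                       grid = image_grid(nx = 3, ny = 3, dx = 1))
  img <- render_smooth(s, p)
  expect_equal(img$heights[2, 2], 2.38, tolerance = 1e-3)
})

test_that("the collision renderer reproduces closed-form sphere contacts", {
  # point tip directly above the bead: apex height z + r
  s <- cg_structure(rbind(c(2, 2, 3)), radius = 0.5)
  p0 <- renderer_params(tip_radius = 0, grid = image_grid(5, 5, dx = 1))
  expect_equal(render_collision(s, p0)$heights[3, 3], 3.5)
  # laterally out of reach: no contribution
  expect_equal(render_collision(s, p0)$heights[3, 4], 0) # d = 1 > r = 0.5
  # spherical tip, lateral offset: h = z - R + sqrt((R + r)^2 - d^2)
  s2 <- cg_structure(rbind(c(3, 3, 4), c(6, 3, 2)), radius = c(1, 0.8))
  p2 <- renderer_params(tip_radius = 2, grid = image_grid(8, 6, dx = 1))
  H <- render_collision(s2, p2)$heights
  # pixel (i=3, j=4) has center (2, 3): lateral d = 1 from bead 1
  expect_equal(H[4, 3], 4 - 2 + sqrt((2 + 1)^2 - 1^2), tolerance = 1e-9)
  h_a <- 4 - 2 + sqrt(9 - 4)            # bead 1 seen from (5,3), d = 2
  h_b <- 2 - 2 + sqrt((2 + 0.8)^2 - 1)  # bead 2 seen from (5,3), d = 1
  expect_equal(H[4, 6], max(h_a, h_b), tolerance = 1e-9)
})

test_that("smooth and collision images agree in the sharp limit", {
  # lateral positions snapped to pixel centers: the soft-max limit equals
  # the bead-top height exactly at the pixel under each bead, which is the
  # point-tip contact height there
  grid <- image_grid(nx = 12, ny = 10, dx = 1.875)
  set.seed(42)
  for (rep in 1:4) {
    ix <- sample(12, 50, replace = TRUE)
    iy <- sample(10, 50, replace = TRUE)
    s <- cg_structure(cbind((ix - 1) * grid$dx, (iy - 1) * grid$dy,
                            runif(50, 0.5, 4)), radius = 0.38)
    # gamma/sigma^2 = 10 nm^-1: the subtractive lateral penalty
    # gamma d^2/(2 sigma^2) exceeds every bead-top height already at the
    # nearest neighboring pixel, so the soft-max truly sharpens
    ps <- renderer_params(sigma_x = 0.01, sigma_y = 0.01, gamma = 1e-3,
                          grid = grid)
    pc <- renderer_params(tip_radius = 0, grid = grid)
    d <- abs(render_smooth(s, ps)$heights - render_collision(s, pc)$heights)
    expect_lt(max(d), 0.02)
  }
})

test_that("kernel truncation error stays below 1e-6 nm at default widths", {
  s <- random_structure(40, seed = 3, xr = c(0, 15), yr = c(0, 10))
  grid <- image_grid(nx = 10, ny = 7, dx = 1.5)
  p <- renderer_params(grid = grid)
  got <- render_smooth(s, p)
  oracle <- r_render_smooth(s, grid, p$sigma_x, p$sigma_y, p$gamma)
  expect_lt(max(abs(got$heights - oracle$heights)), 1e-6)
})

test_that("rendering is invariant under bead reordering and joint translation", {
  s <- random_structure(30, seed = 4)
  grid <- image_grid(nx = 9, ny = 8, dx = 1.5)
  p <- renderer_params(grid = grid)
  img <- render_smooth(s, p)
  perm <- sample(30)
  s2 <- cg_structure(s$coords[perm, ], radius = s$radius[perm])
  expect_equal(render_smooth(s2, p)$heights, img$heights)
  shift <- c(3.7, -2.1, 0)
  s3 <- s; s3$coords <- sweep(s3$coords, 2, shift, "+")
  grid3 <- image_grid(nx = 9, ny = 8, dx = 1.5,
                      x0 = grid$x0 + shift[1], y0 = grid$y0 + shift[2])
  expect_equal(render_smooth(s3, renderer_params(grid = grid3))$heights,
               img$heights, tolerance = 1e-12)
})

test_that("raising a bead never lowers any pixel (soft-max monotonicity)", {
  s <- random_structure(25, seed = 6)
  p <- renderer_params(grid = image_grid(nx = 9, ny = 7, dx = 1.5))
  base <- render_smooth(s, p)$heights
  for (b in c(1, 12, 25)) {
    s2 <- s; s2$coords[b, 3] <- s2$coords[b, 3] + 0.7
    expect_true(all(render_smooth(s2, p)$heights >= base - 1e-12))
  }
})

test_that("bias energy is k(1 - c.s.) with exact special cases", {
  s <- random_structure(20, seed = 7)
  p <- renderer_params(grid = image_grid(nx = 8, ny = 6, dx = 1.5))
  href <- render_smooth(s, p)
  # perfect match: zero energy, stationary forces
  e <- afm_bias_energy(s, href, NULL, k = 50, p)
  expect_equal(as.numeric(e), 0, tolerance = 1e-12)
  expect_lt(max(abs(afm_bias_forces(s, href, NULL, 50, p))), 1e-6 * 50)
  # bias off
  expect_equal(as.numeric(afm_bias_energy(s, href, NULL, 0, p)), 0)
  # composition with the similarity example: cs 24/25, k 100 -> energy 4
  expect_equal(100 * (1 - cs_value(afm_image(matrix(c(3, 4), 1, 2)),
                                   afm_image(matrix(c(4, 3), 1, 2)))), 4)
  # agreement with the similarity module on a non-trivial pair
  other <- random_image(8, 6, seed = 8, lo = 0, hi = 4)
  e2 <- afm_bias_energy(s, other, NULL, k = 10, p)
  expect_equal(as.numeric(e2),
               10 * (1 - cs_value(render_smooth(s, p), other)),
               tolerance = 1e-10)
})

test_that("bias forces are exactly linear in k", {
  s <- random_structure(15, seed = 9)
  p <- renderer_params(grid = image_grid(nx = 7, ny = 6, dx = 1.5))
  href <- random_image(7, 6, seed = 10, lo = 0, hi = 4)
  f1 <- afm_bias_forces(s, href, NULL, 100, p)
  f2 <- afm_bias_forces(s, href, NULL, 200, p)
  expect_equal(f2, 2 * f1, tolerance = 1e-12)
})

test_that("bias forces match central finite differences", {
  p <- renderer_params(grid = image_grid(nx = 8, ny = 6, dx = 1.5))
  href <- random_image(8, 6, seed = 20, lo = 0, hi = 4)
  h <- 1e-5
  for (cfg_seed in 1:10) {
    s <- random_structure(20, seed = 300 + cfg_seed)
    F <- afm_bias_forces(s, href, NULL, 100, p)
    set.seed(cfg_seed)
    for (t in 1:3) {
      b <- sample(20, 1); d <- sample(3, 1)
      sp <- s; sp$coords[b, d] <- sp$coords[b, d] + h
      sm <- s; sm$coords[b, d] <- sm$coords[b, d] - h
      fd <- -(as.numeric(afm_bias_energy(sp, href, NULL, 100, p)) -
              as.numeric(afm_bias_energy(sm, href, NULL, 100, p))) / (2 * h)
      expect_lt(abs(F[b, d] - fd), 1e-4 * max(0.01, abs(fd)))
    }
  }
})

test_that("a structure rendering to zero on the mask is rejected", {
  s <- cg_structure(rbind(c(100, 100, 2), c(101, 100, 2)), radius = 0.4)
  p <- renderer_params(grid = image_grid(nx = 5, ny = 5, dx = 1))
  href <- random_image(5, 5, seed = 21, lo = 1, hi = 2, dx = 1)
  expect_error(afm_bias_energy(s, href, NULL, 10, p), "similarity undefined")
})
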