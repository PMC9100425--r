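test_that("the two reference states share bead counts and chain layout", {
  tc <- toy_cache()
  u <- tc$toy$reference_down_up
  d <- tc$toy$reference_down_down
  expect_equal(n_beads(u), n_beads(d))
  expect_identical(u$chain, d$chain)
  expect_identical(u$resid, d$resid)
  expect_identical(u$radius, d$radius)
  # only the leading neck differs
  moved <- which(rowSums(abs(u$coords - d$coords)) > 1e-12)
  expect_setequal(moved, u$meta$lead_neck_beads)
})

test_that("state renders differ in the neck region, agree on the filament", {
  tc <- toy_cache()
  rp <- renderer_params(grid = image_grid())
  iu <- render_smooth(tc$toy$reference_down_up, rp)
  id <- render_smooth(tc$toy$reference_down_down, rp)
  expect_lt(cs_value(iu, id, neck_mask_frame()), 0.99)
  expect_gt(cs_value(iu, id, region_mask(26, 33, 20, 28)), 0.999)
})

test_that("filament strands step by the specified rise along the axis", {
  spec <- toy_complex_spec(rise = 2.75)
  toy <- make_toy_complex(spec)
  s <- toy$complex
  for (ch in s$meta$filament_chains) {
    x <- s$coords[s$chain == ch, 1]
    expect_equal(diff(x), rep(2.75, length(x) - 1), tolerance = 1e-9)
  }
})

test_that("binding sites outside the filament are rejected", {
  expect_error(make_toy_complex(toy_complex_spec(binding_leading = 40)),
               "binding site")
})

test_that("generators are pure functions of spec and seed", {
  t1 <- make_toy_complex()
  t2 <- make_toy_complex()
  expect_identical(t1$reference_down_down$coords,
                   t2$reference_down_down$coords)
  cor <- image_corruption_spec(noise_sd = 0.4, parachute_prob = 0.5, seed = 7)
  i1 <- make_reference_image(t1$complex, corruption = cor)
  i2 <- make_reference_image(t2$complex, corruption = cor)
  expect_identical(i1$heights, i2$heights)
  p1 <- perturb_structure(t1$complex, rotation = 10, jitter_sd = 0.3, seed = 5)
  p2 <- perturb_structure(t2$complex, rotation = 10, jitter_sd = 0.3, seed = 5)
  expect_identical(p1$coords, p2$coords)
})

test_that("an uncorrupted reference image equals the plain render", {
  tc <- toy_cache()
  p <- renderer_params(tip_radius = 2.6)
  img <- make_reference_image(tc$toy$complex, params = p, corruption = NULL)
  p$grid <- afmflex::image_grid()
  expect_equal(img$heights, render_collision(tc$toy$complex, p)$heights)
  # default frame geometry: 80 x 40 pixels at 1.875 nm
  expect_equal(c(img$nx, img$ny, img$dx), c(80, 40, 1.875))
})

test_that("stage pixels of a corrupted image carry the injected noise level", {
  tc <- toy_cache()
  cor <- image_corruption_spec() # noise SD 0.53 nm
  img <- make_reference_image(tc$toy$reference_down_down, method = "smooth",
                              params = renderer_params(), corruption = cor)
  lev <- level_image(img, stage_plane(cor$tilt_a, cor$tilt_b, cor$offset_c))
  stage_px <- lev$heights[30:39, 43:80]
  expect_equal(length(stage_px), 380L)
  expect_lt(abs(sd(stage_px) - 0.53) / 0.53, 0.10)
})

test_that("the injected stage plane is recovered within 3 standard errors", {
  tc <- toy_cache()
  cor <- image_corruption_spec(seed = 3)
  img <- make_reference_image(tc$toy$reference_down_down, method = "smooth",
                              params = renderer_params(), corruption = cor)
  pl <- fit_stage_plane(img, stage_mask_frame())
  # independent least-squares fit with standard errors
  ctr <- pixel_centers(img)
  df <- expand.grid(y = ctr$y[30:39], x = ctr$x[43:80])
  df$z <- as.vector(img$heights[30:39, 43:80])
  fit <- summary(lm(z ~ x + y, df))$coefficients
  expect_lt(abs(pl$a - cor$tilt_a), 3 * fit["x", "Std. Error"])
  expect_lt(abs(pl$b - cor$tilt_b), 3 * fit["y", "Std. Error"])
  expect_lt(abs(pl$c - cor$offset_c), 3 * fit["(Intercept)", "Std. Error"])
})

test_that("parachuting streaks decay along the scan direction", {
  tc <- toy_cache()
  cor0 <- image_corruption_spec(tilt_a = 0, tilt_b = 0, offset_c = 0,
                                noise_sd = 0, parachute_prob = 0, seed = 2)
  cor1 <- cor0; cor1$parachute_prob <- 1
  base <- make_reference_image(tc$toy$complex, corruption = cor0)
  streaked <- make_reference_image(tc$toy$complex, corruption = cor1)
  extra <- streaked$heights - base$heights
  expect_gt(sum(extra > 0.01), 0)
  expect_true(all(extra >= -1e-12)) # streaks only add height
})

test_that("zero-argument perturbation is the identity, translation is rigid", {
  s <- random_structure(50, seed = 14)
  expect_identical(perturb_structure(s)$coords, s$coords)
  tr <- perturb_structure(s, translation = c(1, 0, 0))
  expect_equal(as.matrix(dist(tr$coords)), as.matrix(dist(s$coords)),
               tolerance = 1e-12)
  rot <- perturb_structure(s, rotation = 35)
  expect_equal(as.matrix(dist(rot$coords)), as.matrix(dist(s$coords)),
               tolerance = 1e-9)
})

test_that("jitter RMSD follows the chi expectation sd * sqrt(3)", {
  s <- random_structure(600, seed = 15, xr = c(0, 100), yr = c(0, 100),
                        zr = c(0, 100))
  for (sd_j in c(0.1, 0.3)) {
    p <- perturb_structure(s, jitter_sd = sd_j, seed = 16)
    expect_lt(abs(rmsd(p, s) - sd_j * sqrt(3)) / (sd_j * sqrt(3)), 0.10)
  }
})

test_that("the default synthetic frame reproduces the measurement geometry", {
  tc <- toy_cache()
  img <- make_reference_image(tc$toy$reference_down_up, method = "smooth",
                              params = renderer_params())
  expect_equal(img$nx * img$dx, 150)
  expect_equal(img$ny * img$dy, 75)
  # the stage margin used for plane fitting holds no molecule signal
  clean <- make_reference_image(tc$toy$reference_down_up, method = "smooth",
                                params = renderer_params(),
                                corruption = NULL)
  expect_lt(max(clean$heights[30:39, 43:80]), 1e-6)
  # the molecule lies inside the 40 x 30 fitting region
  inside <- clean$heights[1:30, 26:65]
  expect_gt(max(inside), 5)
  total <- sum(clean$heights^2)
  expect_gt(sum(inside^2) / total, 0.95)
})
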