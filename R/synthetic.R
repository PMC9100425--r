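# Ground-truth toy systems: a two-strand helical filament plus a two-headed
# motor (icosahedral-shell heads, bead-rod necks and stalk) in two lever-arm
# states, and experimental-like corrupted reference images. Geometric, not
# biological: the inference method depends on the shape difference between
# states, not on any particular protein's geometry.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specification of the toy filament-motor complex
#'
#' Defaults reproduce the reference measurement geometry: the filament spans
#' the 40 x 30-pixel fitting region of an 80 x 40-pixel frame at 1.875
#' nm/pixel, the motor necks reach into the neck-inference region, and the
#' stage margin stays empty for plane fitting.
#'
#' @param filament_beads beads per strand (2 strands).
#' @param rise axial spacing between consecutive beads of a strand (nm).
#' @param twist helical twist per bead (degrees).
#' @param head_beads beads per head (icosahedral shell + center).
#' @param neck_beads beads per neck rod.
#' @param binding_trailing,binding_leading strand-1 bead indices (1-based)
#'   the two heads attach to.
#' @param hinge_angle lever-arm hinge rotation (degrees) between the "up"
#'   and "down" conformations of the leading neck, about a fixed hinge axis
#'   through the leading head center; must be >= 30 so the two states render
#'   visibly distinct neck shapes. `NULL` (default) uses the full geometric
#'   swing that lands the down lever along the filament (about 140 degrees).
#' @param seed integer seed (the builder is deterministic given the spec).
#' @export
toy_complex_spec <- function(filament_beads = 26, rise = 2.75, twist = 30,
                             head_beads = 13, neck_beads = 12,
                             binding_trailing = 8, binding_leading = 17,
                             hinge_angle = NULL, seed = 1) {
  if (!is.null(hinge_angle) && hinge_angle < 30)
    stop("hinge_angle must be >= 30 degrees for visibly distinct states")
  if (head_beads < 13) stop("head_beads must be >= 13 (shell + center)")
  list(filament_beads = as.integer(filament_beads), rise = rise,
       twist = twist, strand_count = 2L,
       head_beads = as.integer(head_beads),
       neck_beads = as.integer(neck_beads),
       binding_trailing = as.integer(binding_trailing),
       binding_leading = as.integer(binding_leading),
       hinge_angle = hinge_angle, seed = as.integer(seed))
}

icosahedron_vertices <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, p, 0), c(1, p, 0), c(-1, -p, 0), c(1, -p, 0),
             c(0, -1, p), c(0, 1, p), c(0, -1, -p), c(0, 1, -p),
             c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1))
  v / sqrt(1 + p^2)
}

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues rotation matrix about a unit axis
rot_axis <- function(axis, deg) {
  a <- deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Build the toy filament-motor complex in both lever-arm states
#'
#' Returns the assembled simulated configuration (`complex`, identical to
#' the down-up reference) and the two reference conformations. The two
#' references share an identical bead count and chain layout and differ
#' only in the leading neck, which is rotated by `spec$hinge_angle` about a
#' hinge axis through the leading head center — the lever-arm up vs down
#' conformations of the leading head.
#'
#' @param spec a [toy_complex_spec()].
#' @return list with `complex`, `reference_down_up`, `reference_down_down`
#'   (all [cg_structure()]s).
#' @export
make_toy_complex <- function(spec = toy_complex_spec()) {
  nb <- spec$filament_beads
  if (spec$binding_trailing < 1 || spec$binding_trailing > nb ||
      spec$binding_leading < 1 || spec$binding_leading > nb)
    stop("binding site outside the filament range")

  # --- filament: two-strand helix along x, resting on the stage ----------
  fil_r <- 3.2; helix_A <- 1.2; y_f <- 45; x_start <- 48
  z_f <- fil_r + helix_A
  strand <- function(s) {
    b <- seq_len(nb) - 1
    phase <- spec$twist * b * pi / 180 + s * pi
    cbind(x_start + b * spec$rise,
          y_f + helix_A * cos(phase),
          z_f + helix_A * sin(phase))
  }
  filA <- strand(0); filB <- strand(1)

  # --- heads: icosahedral shells over the binding sites ------------------
  shell_r <- 2.0; head_rad <- 1.0
  head_offset <- c(0, -1.8, 3.0)
  extra <- spec$head_beads - 13L
  head_at <- function(center) {
    v <- icosahedron_vertices() * shell_r
    pts <- rbind(c(0, 0, 0), v)
    if (extra > 0) { # extra beads interpolate on the shell, deterministic
      th <- (seq_len(extra)) * 2.399963 # golden angle
      zz <- 1 - 2 * (seq_len(extra)) / (extra + 1)
      rr <- sqrt(pmax(0, 1 - zz^2))
      pts <- rbind(pts, shell_r * cbind(rr * cos(th), rr * sin(th), zz))
    }
    sweep(pts, 2, center, "+")
  }
  ctr_T <- filA[spec$binding_trailing, ] + head_offset
  ctr_L <- filA[spec$binding_leading, ] + head_offset
  headT <- head_at(ctr_T); headL <- head_at(ctr_L)

  # --- necks: bead rods from each head; stalk from the trailing neck -----
  # Both necks of the up state meet at a dimerization junction J (as the
  # two lever arms of a walking two-head-bound motor do), so the up
  # conformation is latched there by native contacts; the down lever is
  # swung forward to hug the filament, where its own state's topology
  # latches it with neck-filament contacts. Each state is thereby held by
  # a specific interface, not just by hinge stiffness.
  neck_rad <- 0.6; neck_start <- 3.0; neck_sp <- 1.2
  rod <- function(from, dir, n, start, sp) {
    dir <- dir / sqrt(sum(dir^2))
    t(vapply(seq_len(n), function(i) from + (start + (i - 1) * sp) * dir,
             numeric(3)))
  }
  J <- c((ctr_T[1] + ctr_L[1]) / 2, y_f - 12, 4.2)
  dir_trail <- J - ctr_T
  dir_lead_up <- (J - ctr_L) / sqrt(sum((J - ctr_L)^2))
  # forward, filament-hugging target of the down lever
  tgt <- c(ctr_L[1] + 16, y_f - 2, 6)
  dir_fwd <- (tgt - ctr_L) / sqrt(sum((tgt - ctr_L)^2))
  hinge_axis <- vcross(dir_lead_up, dir_fwd)
  hinge_axis <- hinge_axis / sqrt(sum(hinge_axis^2))
  full_angle <- acos(sum(dir_lead_up * dir_fwd)) * 180 / pi
  hinge_angle <- if (is.null(spec$hinge_angle)) full_angle else spec$hinge_angle
  if (hinge_angle < 30)
    stop("hinge_angle must be >= 30 degrees for visibly distinct states")
  dir_lead_down <- rot_axis(hinge_axis, hinge_angle) %*% dir_lead_up
  neckT <- rod(ctr_T, dir_trail, spec$neck_beads, neck_start, neck_sp)
  neckL_up <- rod(ctr_L, dir_lead_up, spec$neck_beads, neck_start, neck_sp)
  neckL_down <- rod(ctr_L, as.vector(dir_lead_down), spec$neck_beads,
                    neck_start, neck_sp)
  stalk <- rod(neckT[spec$neck_beads, ], c(0, 0, 1), 4L, neck_sp, neck_sp)

  # each motor half is one bonded chain (head shell -> neck rod [-> stalk]),
  # so angle terms at the head-neck junction give the lever-arm hinge a
  # well-defined orientation; the two states differ only in the neckL beads
  assemble <- function(neckL, label) {
    coords <- rbind(filA, filB, headT, neckT, stalk, headL, neckL)
    nT <- spec$head_beads + spec$neck_beads + 4L
    nL <- spec$head_beads + spec$neck_beads
    radius <- c(rep(fil_r, 2 * nb),
                rep(head_rad, spec$head_beads), rep(neck_rad, spec$neck_beads),
                rep(neck_rad, 4L),
                rep(head_rad, spec$head_beads), rep(neck_rad, spec$neck_beads))
    chain <- c(rep("actinA", nb), rep("actinB", nb),
               rep("myoT", nT), rep("myoL", nL))
    s <- cg_structure(coords, radius = radius, chain = chain, label = label)
    s$meta <- list(filament_chains = c("actinA", "actinB"),
                   motor_chains = c("myoT", "myoL"),
                   lead_neck_beads = 2L * nb + nT + spec$head_beads +
                     seq_len(spec$neck_beads),
                   build_args = list(contact_cutoff = 6.5, contact_eps = 3,
                                     contact_width = 0.6, bond_k = 10,
                                     angle_k = 10))
    s
  }
  list(complex = assemble(neckL_up, "down_up"),
       reference_down_up = assemble(neckL_up, "down_up"),
       reference_down_down = assemble(neckL_down, "down_down"))
}

#' Image corruption specification
#'
#' Emulates the systematic and random defects of a measured HS-AFM frame: a
#' slightly tilted stage plane (below 1 degree by default, matching typical
#' measured tilts), i.i.d. Gaussian pixel noise with the measured stage-noise
#' level of 0.53 nm, and optional exponential "parachuting" streaks trailing
#' (+x, the scan direction) off molecule edges.
#'
#' @param tilt_a,tilt_b stage plane slopes (dimensionless, per-nm).
#' @param offset_c stage plane offset (nm).
#' @param noise_sd Gaussian pixel-noise SD (nm), default 0.53.
#' @param parachute_prob probability per scan line of one streak.
#' @param parachute_decay streak decay length (nm).
#' @param seed integer seed.
#' @export
image_corruption_spec <- function(tilt_a = 0.00348, tilt_b = -0.00003,
                                  offset_c = 7.215, noise_sd = 0.53,
                                  parachute_prob = 0, parachute_decay = 3,
                                  seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (parachute_prob < 0 || parachute_prob > 1)
    stop("parachute_prob must be in [0, 1]")
  list(tilt_a = tilt_a, tilt_b = tilt_b, offset_c = offset_c,
       noise_sd = noise_sd, parachute_prob = parachute_prob,
       parachute_decay = parachute_decay, seed = as.integer(seed))
}

#' Generate an experimental-like reference AFM image
#'
#' Renders the structure (hard-collision tip model by default, spherical tip
#' radius 2.6 nm — the tip size corresponding to the smoothed renderer's
#' default 0.5 nm widths) and adds the corruption terms: the stage plane
#' `a x + b y + c`, i.i.d. Gaussian pixel noise, and optional parachuting
#' streaks. Deterministic given `corruption$seed`.
#'
#' @param structure a [cg_structure()].
#' @param grid an [image_grid()].
#' @param params a [renderer_params()]; its `grid` is replaced by `grid`.
#' @param method `"collision"` (default) or `"smooth"`.
#' @param corruption an [image_corruption_spec()], or `NULL` for none.
#' @return an `afm_image`.
#' @export
make_reference_image <- function(structure, grid = image_grid(),
                                 params = renderer_params(tip_radius = 2.6),
                                 method = c("collision", "smooth"),
                                 corruption = image_corruption_spec()) {
  method <- match.arg(method)
  params$grid <- grid_of(grid)
  img <- if (method == "collision") render_collision(structure, params)
         else render_smooth(structure, params)
  if (is.null(corruption)) return(img)
  H <- img$heights
  ctr <- pixel_centers(img)
  P <- outer(ctr$y, ctr$x, function(y, x)
    corruption$tilt_a * x + corruption$tilt_b * y + corruption$offset_c)
  with_seed(corruption$seed, {
    if (corruption$parachute_prob > 0) {
      thr <- 1 # nm: "molecule present" height threshold for edge detection
      for (j in seq_len(img$ny)) {
        if (stats::runif(1) >= corruption$parachute_prob) next
        row <- H[j, ]
        edges <- which(row[-img$nx] > thr & row[-1] <= thr)
        if (length(edges) == 0) next
        e <- edges[sample.int(length(edges), 1)]
        k <- seq_len(img$nx - e)
        H[j, e + k] <- H[j, e + k] +
          row[e] * exp(-k * img$dx / corruption$parachute_decay)
      }
    }
    if (corruption$noise_sd > 0)
      H <- H + matrix(rnorm(length(H), 0, corruption$noise_sd),
                      nrow(H), ncol(H))
  })
  afm_image(H + P, dx = img$dx, dy = img$dy, x0 = img$x0, y0 = img$y0)
}

#' Rigid-transform and jitter a structure
#'
#' Applies a rigid translation and a rotation about the z axis through the
#' structure's centroid, then i.i.d. Gaussian jitter per coordinate.
#' Deterministic given `seed`; with all-zero arguments it is the identity.
#'
#' @param structure a [cg_structure()].
#' @param translation length-3 translation (nm).
#' @param rotation angle about z (degrees).
#' @param jitter_sd per-coordinate Gaussian jitter SD (nm).
#' @param seed integer seed.
#' @return the perturbed `cg_structure`.
#' @export
perturb_structure <- function(structure, translation = c(0, 0, 0),
                              rotation = 0, jitter_sd = 0, seed = 1) {
  X <- structure$coords
  if (rotation != 0) {
    ctr <- colMeans(X)
    a <- rotation * pi / 180
    R <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    X <- sweep(sweep(X, 2, ctr) %*% t(R), 2, ctr, "+")
  }
  X <- sweep(X, 2, translation, "+")
  if (jitter_sd > 0)
    X <- X + with_seed(seed, matrix(rnorm(length(X), 0, jitter_sd),
                                    nrow(X), ncol(X)))
  out <- structure
  out$coords <- X
  out
}
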