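#' Image grid geometry
#'
#' Grid geometry without heights, used to tell a renderer where to evaluate.
#' The default is the measurement geometry of the reference frame: 80 x 40
#' pixels at 1.875 nm/pixel (150 x 75 nm^2).
#'
#' @param nx,ny pixel counts.
#' @param dx,dy pixel spacing (nm).
#' @param x0,y0 center of pixel (1, 1) in nm.
#' @export
image_grid <- function(nx = 80, ny = 40, dx = 1.875, dy = dx, x0 = 0, y0 = 0) {
  if (nx < 1 || ny < 1 || dx <= 0 || dy <= 0) stop("invalid grid")
  list(nx = as.integer(nx), ny = as.integer(ny), dx = dx, dy = dy,
       x0 = x0, y0 = y0)
}

grid_of <- function(g) {
  if (inherits(g, "afm_image"))
    list(nx = g$nx, ny = g$ny, dx = g$dx, dy = g$dy, x0 = g$x0, y0 = g$y0)
  else g
}

#' Renderer parameters
#'
#' `sigma_x` and `sigma_y` set the lateral range of the smoothed kernel and
#' `gamma` the degree of smoothing in z; `tip_radius` is used only by the
#' collision renderer (a spherical tip; 0 means an ideal point tip). The
#' lateral widths 0.5 nm correspond to a tip radius of about 2.6 nm.
#'
#' @param sigma_x,sigma_y lateral widths (nm), > 0.
#' @param gamma vertical softness (nm), > 0.
#' @param tip_radius spherical tip radius (nm), >= 0 (collision only).
#' @param grid an [image_grid()] or an `afm_image` whose geometry to reuse.
#' @export
renderer_params <- function(sigma_x = 0.5, sigma_y = 0.5, gamma = 0.1,
                            tip_radius = 0, grid = image_grid()) {
  if (sigma_x <= 0 || sigma_y <= 0 || gamma <= 0)
    stop("sigma_x, sigma_y, gamma must be > 0")
  if (tip_radius < 0) stop("tip_radius must be >= 0")
  structure(list(sigma_x = sigma_x, sigma_y = sigma_y, gamma = gamma,
                 tip_radius = tip_radius, grid = grid_of(grid)),
            class = "renderer_params")
}

#' Smoothed (differentiable) pseudo-AFM image
#'
#' Computes per pixel the log-sum-exp soft maximum
#' `H_p = gamma * log(1 + sum_i exp((z_i + r_i)/gamma
#'        - (x_i - x_p)^2/(2 sigma_x^2) - (y_i - y_p)^2/(2 sigma_y^2)))`,
#' a smooth, everywhere non-negative surrogate of the tip-contact height:
#' infinitely differentiable in the bead coordinates (which is what lets the
#' bias potential exert forces), reducing as `gamma, sigma -> 0` to the
#' tallest bead top `z_i + r_i` over beads at the pixel, floored at 0 (the
#' `+1` term is the stage floor). Any smooth soft-maximum with these limits
#' is a conformant renderer; this is the package's canonical one. The
#' lateral kernel support is truncated per bead where a term's exponent
#' falls 20 below the stage baseline (truncation error below 1e-6 nm).
#'
#' @param structure a [cg_structure()] (an empty structure yields an all-zero
#'   image with a warning).
#' @param params a [renderer_params()].
#' @return an `afm_image` on `params$grid`.
#' @export
render_smooth <- function(structure, params) {
  g <- params$grid
  if (n_beads(structure) == 0L) {
    warning("empty structure: rendered image is all zero")
    return(afm_image(matrix(0, g$ny, g$nx), dx = g$dx, dy = g$dy,
                     x0 = g$x0, y0 = g$y0))
  }
  H <- cpp_render_smooth(structure$coords, structure$radius,
                         g$nx, g$ny, g$dx, g$dy, g$x0, g$y0,
                         params$sigma_x, params$sigma_y, params$gamma)
  afm_image(H, dx = g$dx, dy = g$dy, x0 = g$x0, y0 = g$y0)
}

#' Hard-collision pseudo-AFM image
#'
#' Each pixel's height is the lowest tip-apex position at which a sphere of
#' radius `tip_radius` descending on the pixel's vertical line first touches
#' any bead (sphere-tip / sphere-sample contact), floored at 0:
#' `H_p = max_i (z_i - R + sqrt((R + r_i)^2 - d_i^2))` over beads with
#' lateral distance `d_i < R + r_i`. With `tip_radius = 0` this is the sharp
#' limit of [render_smooth()] at pixels directly under a bead.
#'
#' @inheritParams render_smooth
#' @return an `afm_image` on `params$grid`.
#' @export
render_collision <- function(structure, params) {
  g <- params$grid
  if (n_beads(structure) == 0L) {
    warning("empty structure: rendered image is all zero")
    return(afm_image(matrix(0, g$ny, g$nx), dx = g$dx, dy = g$dy,
                     x0 = g$x0, y0 = g$y0))
  }
  H <- cpp_render_collision(structure$coords, structure$radius,
                            g$nx, g$ny, g$dx, g$dy, g$x0, g$y0,
                            params$tip_radius)
  afm_image(H, dx = g$dx, dy = g$dy, x0 = g$x0, y0 = g$y0)
}

mask0 <- function(mask, image) {
  m <- check_mask(mask, image)
  c(m$x_first - 1L, m$x_last - 1L, m$y_first - 1L, m$y_last - 1L)
}

bias_call <- function(structure, h_ref, mask, k, params) {
  if (k < 0) stop("k must be >= 0")
  m <- mask0(mask, h_ref)
  out <- cpp_bias_energy_forces(structure$coords, structure$radius,
                                h_ref$heights, h_ref$dx, h_ref$dy,
                                h_ref$x0, h_ref$y0,
                                m[1], m[2], m[3], m[4],
                                k, params$sigma_x, params$sigma_y,
                                params$gamma)
  if (is.na(out$cs)) stop("similarity undefined: image all-zero on the mask")
  out
}

#' AFM bias energy `V_AFM = k (1 - c.s.)`
#'
#' The cosine similarity is taken between the smoothed pseudo-AFM image of
#' `structure` (rendered on the reference image's grid) and `h_ref`, over
#' `mask`. The value lies in `[0, 2k]` and is 0 exactly when the images are
#' proportional on the mask.
#'
#' @param structure a [cg_structure()].
#' @param h_ref reference `afm_image` (leveled and cropped as appropriate).
#' @param mask a [region_mask()] or `NULL` for the whole image.
#' @param k bias strength (>= 0).
#' @param params a [renderer_params()] (its `grid` is ignored; the reference
#'   image's geometry is used).
#' @return energy (numeric scalar); attribute `"cs"` carries the similarity.
#' @export
afm_bias_energy <- function(structure, h_ref, mask = NULL, k, params) {
  out <- bias_call(structure, h_ref, mask, k, params)
  structure(out$energy, cs = out$cs)
}

#' Per-bead forces of the AFM bias potential
#'
#' The analytic negative gradient of [afm_bias_energy()] with respect to the
#' bead coordinates, finite everywhere and exactly linear in `k`.
#'
#' @inheritParams afm_bias_energy
#' @return an `n x 3` matrix of forces (energy / nm).
#' @export
afm_bias_forces <- function(structure, h_ref, mask = NULL, k, params) {
  bias_call(structure, h_ref, mask, k, params)$forces
}
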