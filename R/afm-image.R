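#' AFM height image
#'
#' A rectangular grid of heights (nm) with pixel spacing and origin. Heights
#' are stored as an `ny x nx` matrix: `heights[j, i]` is the pixel with
#' 1-based x index `i` and y index `j`. Pixel (i, j) refers to the pixel
#' *center* at `(origin_x + (i-1) dx, origin_y + (j-1) dy)` in nm.
#'
#' @param heights `ny x nx` numeric matrix of heights in nm.
#' @param dx,dy pixel spacing in nm (default 1.875, the spacing of an
#'   80 x 40 pixel frame covering 150 x 75 nm^2).
#' @param x0,y0 position (nm) of the center of pixel (1, 1).
#' @return an object of class `afm_image`.
#' @export
afm_image <- function(heights, dx = 1.875, dy = dx, x0 = 0, y0 = 0) {
  heights <- as.matrix(heights)
  if (!all(is.finite(heights))) stop("afm_image: heights must be finite")
  if (dx <= 0 || dy <= 0) stop("afm_image: pixel spacing must be > 0")
  structure(list(heights = heights, dx = dx, dy = dy, x0 = x0, y0 = y0,
                 nx = ncol(heights), ny = nrow(heights)),
            class = "afm_image")
}

#' @export
print.afm_image <- function(x, ...) {
  cat(sprintf("<afm_image> %d x %d px (%.5g x %.5g nm), heights %.3g..%.3g nm\n",
              x$nx, x$ny, x$nx * x$dx, x$ny * x$dy,
              min(x$heights), max(x$heights)))
  invisible(x)
}

#' Pixel-center coordinates of an image
#'
#' @param image an `afm_image`.
#' @return list with numeric vectors `x` (length nx) and `y` (length ny), nm.
#' @export
pixel_centers <- function(image) {
  list(x = image$x0 + (seq_len(image$nx) - 1) * image$dx,
       y = image$y0 + (seq_len(image$ny) - 1) * image$dy)
}

#' Rectangular pixel-region mask (1-based inclusive)
#'
#' Pixel indices follow the field convention of counting from 1, e.g. the
#' stage margin "43rd-80th pixels in X, 30th-39th in Y" of an 80 x 40 frame
#' is `region_mask(43, 80, 30, 39)`.
#'
#' @param x_first,x_last,y_first,y_last 1-based inclusive pixel indices.
#' @export
region_mask <- function(x_first, x_last, y_first, y_last) {
  m <- structure(list(x_first = as.integer(x_first), x_last = as.integer(x_last),
                      y_first = as.integer(y_first), y_last = as.integer(y_last)),
                 class = "region_mask")
  if (m$x_first < 1L || m$y_first < 1L || m$x_first > m$x_last ||
      m$y_first > m$y_last)
    stop("region_mask: need 1 <= first <= last in both directions")
  m
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> x %d:%d, y %d:%d (%d px)\n", x$x_first, x$x_last,
              x$y_first, x$y_last, mask_n_pixels(x)))
  invisible(x)
}

mask_n_pixels <- function(m) {
  (m$x_last - m$x_first + 1L) * (m$y_last - m$y_first + 1L)
}

check_mask <- function(mask, image) {
  if (is.null(mask))
    return(region_mask(1L, image$nx, 1L, image$ny))
  if (mask$x_last > image$nx || mask$y_last > image$ny)
    stop(sprintf("mask (x %d:%d, y %d:%d) out of bounds for %d x %d image",
                 mask$x_first, mask$x_last, mask$y_first, mask$y_last,
                 image$nx, image$ny))
  mask
}

mask_values <- function(image, mask) {
  image$heights[mask$y_first:mask$y_last, mask$x_first:mask$x_last]
}

# ---------------------------------------------------------------------------
# Plain-text grid format (self-describing header + ny rows of nx values)
# ---------------------------------------------------------------------------

#' Write an AFM image to the plain-text grid format
#'
#' The format is a self-describing header (`nx`, `ny`, `pixel_dx`,
#' `pixel_dy`, `origin_x`, `origin_y`) followed by `ny` whitespace-separated
#' rows of `nx` heights in nm; row 1 is y index 1. `write_image` then
#' [read_image()] reproduces the image to full double precision.
#'
#' @param image an `afm_image`.
#' @param path output path.
#' @export
write_image <- function(image, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# afmflex height grid v1",
               paste("nx", image$nx), paste("ny", image$ny),
               paste("pixel_dx", sprintf("%.17g", image$dx)),
               paste("pixel_dy", sprintf("%.17g", image$dy)),
               paste("origin_x", sprintf("%.17g", image$x0)),
               paste("origin_y", sprintf("%.17g", image$y0))), con)
  for (j in seq_len(image$ny))
    writeLines(paste(sprintf("%.17g", image$heights[j, ]), collapse = " "), con)
  invisible(path)
}

#' Read an AFM image from the plain-text grid format
#'
#' @param path path to a file written by [write_image()] (or by hand in the
#'   same format).
#' @return an `afm_image`.
#' @export
read_image <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  hdr <- list()
  need <- c("nx", "ny", "pixel_dx", "pixel_dy", "origin_x", "origin_y")
  i <- 1L
  while (i <= length(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) == 2L && parts[1] %in% need) {
      hdr[[parts[1]]] <- as.numeric(parts[2])
      i <- i + 1L
    } else break
  }
  missing <- setdiff(need, names(hdr))
  if (length(missing) > 0)
    stop("grid header missing key(s): ", paste(missing, collapse = ", "))
  nx <- as.integer(hdr$nx); ny <- as.integer(hdr$ny)
  rows <- lines[i:length(lines)]
  if (length(rows) != ny)
    stop(sprintf("expected %d data rows, found %d", ny, length(rows)))
  H <- matrix(NA_real_, ny, nx)
  for (j in seq_len(ny)) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(rows[j]), "\\s+")[[1]]))
    if (length(vals) != nx)
      stop(sprintf("row %d (line %d): expected %d values, found %d",
                   j, i + j - 1L, nx, length(vals)))
    if (anyNA(vals))
      stop(sprintf("row %d (line %d): non-numeric cell", j, i + j - 1L))
    H[j, ] <- vals
  }
  afm_image(H, dx = hdr$pixel_dx, dy = hdr$pixel_dy,
            x0 = hdr$origin_x, y0 = hdr$origin_y)
}

# ---------------------------------------------------------------------------
# Stage plane estimation and leveling
# ---------------------------------------------------------------------------

#' Stage plane z = a x + b y + c (x, y in nm)
#'
#' Slopes are dimensionless (nm height per nm lateral); for accepted
#' experimental-like images `atan(a)` and `atan(b)` stay below 1 degree.
#'
#' @param a,b plane slopes.
#' @param c plane offset (nm).
#' @export
stage_plane <- function(a, b, c) {
  if (!all(is.finite(c(a, b, c)))) stop("stage_plane: coefficients must be finite")
  structure(list(a = a, b = b, c = c), class = "stage_plane")
}

#' @export
print.stage_plane <- function(x, ...) {
  cat(sprintf("<stage_plane> z = %.5g x + %.5g y + %.5g nm (tilt %.3f, %.3f deg)\n",
              x$a, x$b, x$c, atan(x$a) * 180 / pi, atan(x$b) * 180 / pi))
  invisible(x)
}

#' Least-squares stage plane over a pixel region
#'
#' Fits `z = a x + b y + c` over the masked pixel centers (x, y in nm) by
#' linear least squares, mirroring the standard preprocessing step that
#' estimates the (slightly tilted) mica stage surface from a margin region of
#' the frame.
#'
#' @param image an `afm_image`.
#' @param mask a [region_mask()] covering the stage margin; `NULL` for the
#'   whole image.
#' @return a [stage_plane()].
#' @export
fit_stage_plane <- function(image, mask = NULL) {
  mask <- check_mask(mask, image)
  if ((mask$x_first == mask$x_last && mask$y_first == mask$y_last) ||
      mask_n_pixels(mask) < 3L)
    stop("plane underdetermined")
  ctr <- pixel_centers(image)
  xs <- ctr$x[mask$x_first:mask$x_last]
  ys <- ctr$y[mask$y_first:mask$y_last]
  X <- rep(xs, each = length(ys))
  Y <- rep(ys, times = length(xs))
  Z <- as.vector(mask_values(image, mask)) # column-major: y fastest
  A <- cbind(1, X, Y)
  qrA <- qr(A)
  if (qrA$rank < 3L) stop("plane underdetermined")
  beta <- unname(qr.coef(qrA, Z))
  stage_plane(a = beta[2], b = beta[3], c = beta[1])
}

#' Level an image by subtracting a stage plane
#'
#' Subtracts `a x + b y + c` at every pixel center so the estimated stage
#' surface becomes z = 0. Subtraction (rather than a frame rotation) is exact
#' enough below 1 degree of tilt and preserves the pixel grid.
#'
#' @param image an `afm_image`.
#' @param plane a [stage_plane()].
#' @return the leveled `afm_image` (same geometry).
#' @export
level_image <- function(image, plane) {
  ctr <- pixel_centers(image)
  P <- outer(ctr$y, ctr$x, function(y, x) plane$a * x + plane$b * y + plane$c)
  afm_image(image$heights - P, dx = image$dx, dy = image$dy,
            x0 = image$x0, y0 = image$y0)
}

#' Crop an image to a pixel region
#'
#' The cropped image's origin is shifted so every retained pixel center keeps
#' its absolute nm coordinates.
#'
#' @param image an `afm_image`.
#' @param mask a [region_mask()] within bounds.
#' @return the cropped `afm_image`.
#' @export
crop_region <- function(image, mask) {
  mask <- check_mask(mask, image)
  afm_image(mask_values(image, mask), dx = image$dx, dy = image$dy,
            x0 = image$x0 + (mask$x_first - 1L) * image$dx,
            y0 = image$y0 + (mask$y_first - 1L) * image$dy)
}

# ---------------------------------------------------------------------------
# Cosine similarity
# ---------------------------------------------------------------------------

#' Cosine similarity between two height images
#'
#' The normalized inner product over the masked pixels:
#' `sum(H1 H2) / sqrt(sum(H1^2) sum(H2^2))`. It is symmetric, invariant to
#' positive rescaling of either image, bounded in `[-1, 1]` (and in `[0, 1]`
#' when both images are non-negative on the mask). An image that is
#' identically zero on the mask makes the ratio undefined and raises an
#' error; this nearly always signals a misconfigured mask.
#'
#' @param h_sim,h_ref `afm_image`s sharing grid geometry.
#' @param mask a [region_mask()] or `NULL` for the whole image.
#' @return a `similarity_score` with fields `value`, `mask`, `n_pixels`.
#' @export
cosine_similarity <- function(h_sim, h_ref, mask = NULL) {
  if (h_sim$nx != h_ref$nx || h_sim$ny != h_ref$ny)
    stop("images must share grid geometry")
  whole <- is.null(mask)
  mask <- check_mask(mask, h_sim)
  a <- as.vector(mask_values(h_sim, mask))
  b <- as.vector(mask_values(h_ref, mask))
  sa <- sum(a * a); sb <- sum(b * b)
  if (sa == 0 || sb == 0) stop("similarity undefined: image all-zero on the mask")
  structure(list(value = sum(a * b) / sqrt(sa * sb),
                 mask = if (whole) "whole" else mask,
                 n_pixels = length(a)),
            class = "similarity_score")
}

#' @export
print.similarity_score <- function(x, ...) {
  cat(sprintf("<similarity_score> %.6f over %d px\n", x$value, x$n_pixels))
  invisible(x)
}

#' Numeric value of a cosine similarity
#' @param h_sim,h_ref,mask as in [cosine_similarity()].
#' @export
cs_value <- function(h_sim, h_ref, mask = NULL) {
  cosine_similarity(h_sim, h_ref, mask)$value
}
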