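#' Loop centering and raster-area definition
#'
#' Finds the cryoloop in on-axis microscope images, centers its tip on the
#' beam, determines the face angle (the goniometer angle at which the
#' loop's largest face is perpendicular to the X-rays) by cosine fitting of
#' silhouette pixel counts, and circumscribes the loop edge with the
#' rectangle used for 2D raster scanning.
#'
#' @name loop_centering
NULL

# Separable Gaussian blur with replicate (row-normalized) edge handling.
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  band_mat <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-d^2 / (2 * sigma^2))
    k[d > ceiling(3 * sigma)] <- 0
    k / rowSums(k)
  }
  band_mat(nrow(mat)) %*% mat %*% t(band_mat(ncol(mat)))
}

# Otsu's threshold on a numeric matrix in [0, 1].
otsu_threshold <- function(mat, nbins = 256L) {
  h <- tabulate(pmin(pmax(floor(mat * nbins) + 1L, 1L), nbins), nbins)
  p <- h / sum(h)
  levels <- (seq_len(nbins) - 0.5) / nbins
  w0 <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[nbins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  levels[which.max(between)]
}

#' Binarize a background-subtracted microscope image
#'
#' Subtracts the background image, applies Gaussian blurring, and
#' thresholds; pixels above threshold are "true pixels" marking object
#' presence.
#'
#' @param image,background `microscope_image`s of identical shape and pixel
#'   size; `background` is captured with no sample in view.
#' @param blur_sigma Gaussian blur sd in pixels.
#' @param threshold Intensity threshold; `NULL` selects Otsu's threshold on
#'   the blurred difference image (falling back to half the maximum when
#'   the difference is nearly empty).
#' @return A `binary_image`: list with logical `mask`, `pixel_size`,
#'   `beam_center`, `omega` and `provenance` (blur sigma and threshold).
#' @export
binarize <- function(image, background, blur_sigma = 2, threshold = NULL) {
  if (!identical(dim(image$pixels), dim(background$pixels)) ||
      image$pixel_size != background$pixel_size) {
    stop("image and background must share shape and pixel size")
  }
  diffs <- gaussian_blur(image$pixels - background$pixels, blur_sigma)
  if (is.null(threshold)) {
    threshold <- if (max(diffs) <= 1e-6) 0.5 else otsu_threshold(pmax(diffs, 0))
  }
  structure(
    list(mask = diffs > threshold, pixel_size = image$pixel_size,
         beam_center = image$beam_center, omega = image$omega,
         provenance = list(blur_sigma = blur_sigma, threshold = threshold)),
    class = "binary_image"
  )
}

# Leftmost true pixel; among column ties the row closest to the beam row.
mask_tip <- function(bin) {
  w <- which(bin$mask, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("empty mask: no true pixels")
  jmin <- min(w[, 2])
  rows <- w[w[, 2] == jmin, 1]
  c(row = rows[which.min(abs(rows - bin$beam_center[1]))], col = jmin)
}

mask_cog <- function(bin) {
  w <- which(bin$mask, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("empty mask: no true pixels")
  colMeans(w)
}

#' Search for the loop by staged horizontal translation
#'
#' Examines binarized images at omega 0, 45, 90 and 135 degrees; when no
#' true pixels are found at any angle the sample is translated horizontally
#' by `factor` times the image width and the examination repeats, at most
#' `iterations` times. An empty holder is a normal not-found outcome.
#'
#' @param gonio A [virtual_gonio()] (or any object with `capture(omega)`,
#'   `background(omega)` and `translate(dy_lab, dz, omega)` functions).
#' @param factor Translation as a multiple of the horizontal image width.
#' @param iterations Maximum number of translations attempted.
#' @param direction -1 translates the sample toward -Z (brings a loop
#'   parked beyond the +Z image edge into view), +1 the opposite.
#' @param blur_sigma,threshold Passed to [binarize()].
#' @return List with `found` (logical), `translation` (total signed
#'   horizontal translation, um) and `iterations` used.
#' @export
search_loop <- function(gonio, factor = 1.5, iterations = 2L, direction = -1,
                        blur_sigma = 2, threshold = NULL) {
  width_um <- ncol(gonio$capture(0)$pixels) * gonio$camera$pixel_size
  total <- 0
  any_true <- function() {
    for (om in c(0, 45, 90, 135)) {
      b <- binarize(gonio$capture(om), gonio$background(om), blur_sigma,
                    threshold)
      if (any(b$mask)) return(TRUE)
    }
    FALSE
  }
  for (it in 0:iterations) {
    if (any_true()) {
      return(list(found = TRUE, translation = total, iterations = it))
    }
    if (it == iterations) break
    step <- direction * factor * width_um
    gonio$translate(dz = step)
    total <- total + step
  }
  list(found = FALSE, translation = total, iterations = iterations)
}

#' Center the loop tip on the beam
#'
#' At each angle in `angles` (default 0, 45, 90 degrees, applied
#' sequentially) the leftmost true pixel -- the loop tip -- is translated
#' to the beam-center column and the center of gravity of all true pixels
#' to the beam-center row. Horizontal moves fix the rotation-axis
#' coordinate; vertical moves at two angles 90 degrees apart fix both
#' remaining sample-frame coordinates.
#'
#' @inheritParams search_loop
#' @param angles Omega angles of the sequential passes, degrees.
#' @return A `centering_result`: list with `translation` (total
#'   sample-frame offset applied, um), `converged` (tip within `tol_px`
#'   pixels of the beam center column at every pass angle on re-capture),
#'   `iterations` and `tol_px`.
#' @export
center_tip <- function(gonio, angles = c(0, 45, 90), blur_sigma = 2,
                       threshold = NULL, tol_px = 2) {
  start <- gonio$offset()
  ps <- gonio$camera$pixel_size
  for (om in angles) {
    b <- binarize(gonio$capture(om), gonio$background(om), blur_sigma,
                  threshold)
    tip <- mask_tip(b)
    cog <- mask_cog(b)
    dz <- (b$beam_center[2] - tip["col"]) * ps
    dy <- (cog[1] - b$beam_center[1]) * ps # row surplus -> sample is low
    gonio$translate(dy_lab = dy, dz = dz, omega = om)
  }
  converged <- TRUE
  for (om in angles) {
    b <- binarize(gonio$capture(om), gonio$background(om), blur_sigma,
                  threshold)
    tip <- mask_tip(b)
    if (abs(tip["col"] - b$beam_center[2]) > tol_px) converged <- FALSE
  }
  structure(
    list(translation = gonio$offset() - start, converged = converged,
         iterations = length(angles), tol_px = tol_px),
    class = "centering_result"
  )
}

#' Face angle from silhouette pixel counts by cosine fitting
#'
#' Fits N(theta) = A + B cos(2 (theta - phi)) to the true-pixel counts at
#' omega 0, 45, 90 and 135 degrees (least squares, exact for noise-free
#' cosine data). The loop looks smallest at the fitted minimizing angle;
#' the face angle is 90 degrees from it, reported in \[0, 180).
#'
#' @param counts Four nonnegative true-pixel counts at 0/45/90/135 degrees.
#' @return Face angle in degrees, with the fit coefficients attached as
#'   attribute `"fit"` (A, B, phi = fitted maximizing angle).
#' @export
find_face_angle <- function(counts) {
  if (length(counts) != 4L) stop("need counts at omega 0, 45, 90, 135")
  if (any(counts < 0)) stop("counts must be nonnegative")
  a_hat <- mean(counts)
  c_hat <- (counts[1] - counts[3]) / 2
  s_hat <- (counts[2] - counts[4]) / 2
  b_hat <- sqrt(c_hat^2 + s_hat^2)
  if (b_hat <= 1e-9 * max(a_hat, 1)) {
    stop("degenerate silhouette counts: no angular modulation")
  }
  phi <- mod180(atan2(s_hat, c_hat) / 2 * 180 / pi) # maximizing angle
  # minimum at phi + 90; the face angle is 90 deg past the minimum
  structure(mod180(phi), fit = c(A = a_hat, B = b_hat, phi = phi))
}

#' Circumscribe the loop silhouette with the raster-scan rectangle
#'
#' The bounding rectangle of the true pixels at the face angle is converted
#' to micrometres, divided by the raster beam sizes (grid step equals beam
#' size) with ceiling division, and optionally clipped horizontally to a
#' user-defined loop size measured from the tip.
#'
#' @param bin A `binary_image` captured at the face angle.
#' @param beam Beam (and grid) size c(horizontal, vertical), um.
#' @param user_loop_size Optional horizontal cap, um, measured from the
#'   tip; also sets the recommended post-centering leftward shift of half
#'   this length.
#' @param omega Face angle the rectangle applies at, degrees.
#' @return A `raster_area`: list with `origin` (sample-frame coordinate of
#'   the top-left grid center, um), `n_h`, `n_v`, `step_h`, `step_v`,
#'   `omega` and `shift_left`.
#' @export
define_raster_area <- function(bin, beam = c(10, 15), user_loop_size = NULL,
                               omega = bin$omega) {
  w <- which(bin$mask, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("empty mask: no true pixels")
  ps <- bin$pixel_size
  z_left <- (min(w[, 2]) - 0.5 - bin$beam_center[2]) * ps
  z_right <- (max(w[, 2]) + 0.5 - bin$beam_center[2]) * ps
  y_top <- (bin$beam_center[1] - (min(w[, 1]) - 0.5)) * ps
  y_bot <- (bin$beam_center[1] - (max(w[, 1]) + 0.5)) * ps
  shift_left <- 0
  clipped <- FALSE
  if (!is.null(user_loop_size) && z_right - z_left > user_loop_size) {
    z_right <- z_left + user_loop_size
    shift_left <- user_loop_size / 2
    clipped <- TRUE
  }
  n_h <- if (clipped) {
    # the scanned span must not exceed the user cap
    max(1L, as.integer(floor((z_right - z_left) / beam[1] + 1e-9)))
  } else {
    max(1L, as.integer(ceiling((z_right - z_left) / beam[1] - 1e-9)))
  }
  n_v <- max(1L, as.integer(ceiling((y_top - y_bot) / beam[2] - 1e-9)))
  structure(
    list(
      origin = c(0, y_top - beam[2] / 2, z_left + beam[1] / 2),
      n_h = n_h, n_v = n_v, step_h = beam[1], step_v = beam[2],
      omega = omega, shift_left = shift_left
    ),
    class = "raster_area"
  )
}

#' @export
print.raster_area <- function(x, ...) {
  cat(sprintf(
    "<raster_area %d x %d grids, step %g x %g um, omega %.1f deg>\n",
    x$n_h, x$n_v, x$step_h, x$step_v, x$omega))
  invisible(x)
}

#' Sample-frame centers of every grid of a raster area
#'
#' @param area A `raster_area`.
#' @return (n_v * n_h) x 3 matrix of coordinates in row-major order (row 1
#'   left to right, then row 2, ...), with attributes `n_v`, `n_h`.
#' @export
raster_grid_centers <- function(area) {
  ij <- expand.grid(j = seq_len(area$n_h), i = seq_len(area$n_v))
  out <- cbind(
    area$origin[1],
    area$origin[2] - (ij$i - 1) * area$step_v,
    area$origin[3] + (ij$j - 1) * area$step_h
  )
  attr(out, "n_v") <- area$n_v
  attr(out, "n_h") <- area$n_h
  out
}

#' Full centering sequence: search, tip centering, face angle, raster area
#'
#' Runs the whole loop-centering pipeline against a (virtual) goniometer:
#' staged search, sequential tip centering at 0/45/90 degrees, four-point
#' cosine fit for the face angle, and circumscription of the silhouette at
#' the face angle. With a user loop size set, the loop is finally shifted
#' left along the rotation axis by half that size so the scanned region
#' centers on the beam.
#'
#' @inheritParams search_loop
#' @param beam Raster beam size c(horizontal, vertical), um.
#' @param user_loop_size Optional utilized loop size, um.
#' @return List with `found`, `search`, `centering`, `face_angle`, `area`.
#' @export
center_loop <- function(gonio, beam = c(10, 15), user_loop_size = NULL,
                        blur_sigma = 2, threshold = NULL) {
  found <- search_loop(gonio, blur_sigma = blur_sigma, threshold = threshold)
  if (!found$found) {
    return(list(found = FALSE, search = found, centering = NULL,
                face_angle = NA_real_, area = NULL))
  }
  ctr <- center_tip(gonio, blur_sigma = blur_sigma, threshold = threshold)
  counts <- vapply(c(0, 45, 90, 135), function(om) {
    sum(binarize(gonio$capture(om), gonio$background(om), blur_sigma,
                 threshold)$mask)
  }, numeric(1))
  face <- find_face_angle(counts)
  if (!is.null(user_loop_size)) {
    gonio$translate(dz = -user_loop_size / 2)
  }
  bin <- binarize(gonio$capture(face), gonio$background(face), blur_sigma,
                  threshold)
  area <- define_raster_area(bin, beam = beam, user_loop_size = user_loop_size,
                             omega = as.numeric(face))
  list(found = TRUE, search = found, centering = ctr,
       face_angle = as.numeric(face), area = area)
}
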