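#' Virtual beamline: ground-truth samples and simulated measurements
#'
#' The virtual beamline replaces every hardware-facing measurement of an
#' automated microcrystallography endstation with a pure function of a
#' ground-truth sample description: on-axis microscope images of the
#' cryoloop, raster-scan diffraction spot responses, and vertical scan
#' responses. All downstream planners (centering, spot finding, scheme
#' planning, dose budgeting) can thereby be exercised and validated against
#' known truth without a goniometer or detector.
#'
#' Coordinate conventions: sample-frame coordinates are (x, y, z) in
#' micrometres. The goniometer rotation axis is Z (horizontal, the image
#' horizontal direction; loop tip points toward -Z, i.e. left in the image);
#' the X-ray beam travels along lab X; lab Y is vertical. Rotating the
#' sample frame about Z by omega degrees maps sample to lab coordinates.
#' The beam passes through the lab origin, which projects to the camera's
#' beam-center pixel.
#'
#' @name virtual_beamline
NULL

#' Describe a crystal with known position, size and diffracting power
#'
#' Crystals are axis-aligned boxes in the sample frame, which keeps
#' beam/crystal overlap fractions analytic.
#'
#' @param center Sample-frame center, length-3 numeric (x, y, z) in um.
#' @param half_extents Half sizes in um as (along rotation axis z,
#'   vertical y, depth x). All must be positive.
#' @param diffraction_power Expected number of low-resolution spots for a
#'   fully illuminated raster grid (dimensionless, >= 0).
#' @return An object of class `crystal_truth`.
#' @export
crystal_truth <- function(center, half_extents, diffraction_power) {
  stopifnot(length(center) == 3L, length(half_extents) == 3L)
  if (any(half_extents <= 0)) stop("crystal half_extents must be positive")
  if (diffraction_power < 0) stop("diffraction_power must be >= 0")
  structure(
    list(
      center = as.numeric(center),
      half_extents = as.numeric(half_extents), # (hz, hy, hx)
      diffraction_power = as.numeric(diffraction_power)
    ),
    class = "crystal_truth"
  )
}

#' Describe the ground-truth cryoloop geometry
#'
#' The loop is modelled as a thin planar disk (ring plus liquid film, which
#' is what the microscope silhouette shows) whose plane contains the
#' rotation axis, plus a stem extending along +Z. The loop plane normal
#' lies in the sample-frame X-Y plane at `plane_normal_angle` degrees from
#' the beam direction; the ground-truth face angle (the omega at which the
#' silhouette is largest, i.e. the loop face is perpendicular to the beam)
#' is therefore `-plane_normal_angle` modulo 180.
#'
#' @param plane_normal_angle Degrees; sample-frame angle of the loop-plane
#'   normal from the X axis, in the X-Y plane.
#' @param outer_radius,inner_radius Ring radii in um (inner < outer).
#' @param tip_position Sample-frame coordinate of the loop tip (the -Z
#'   extreme of the ring), length-3 numeric in um.
#' @param thickness Loop material thickness in um (normal direction).
#' @param stem_width Stem width in um, in the loop plane.
#' @return An object of class `loop_truth`.
#' @export
loop_truth <- function(plane_normal_angle = 0, outer_radius = 300,
                       inner_radius = 270, tip_position = c(0, 0, 0),
                       thickness = 80, stem_width = 80) {
  if (inner_radius >= outer_radius) stop("inner radius must be < outer radius")
  if (outer_radius <= 0 || thickness <= 0 || stem_width <= 0) {
    stop("loop dimensions must be positive")
  }
  structure(
    list(
      plane_normal_angle = as.numeric(plane_normal_angle),
      outer_radius = as.numeric(outer_radius),
      inner_radius = as.numeric(inner_radius),
      tip_position = as.numeric(tip_position),
      thickness = as.numeric(thickness),
      stem_width = as.numeric(stem_width)
    ),
    class = "loop_truth"
  )
}

# Ring center: the tip is the -Z extreme of the ring, which lies in the
# loop plane (spanned by z-hat and v = (sin a, -cos a, 0)).
loop_ring_center <- function(loop) {
  loop$tip_position + c(0, 0, loop$outer_radius)
}

#' Ground-truth face angle of a loop, in [0, 180)
#'
#' The omega at which the loop plane normal is parallel to the beam, i.e.
#' the silhouette is maximal.
#' @param loop A [loop_truth()].
#' @return Degrees in [0, 180).
#' @export
loop_face_angle <- function(loop) mod180(-loop$plane_normal_angle)

#' Assemble a ground-truth virtual sample
#'
#' @param loop A [loop_truth()], or `NULL` for an empty holder.
#' @param crystals List of [crystal_truth()] objects; each crystal center
#'   must lie within the loop's bounding volume (in-plane distance from the
#'   ring center at most the outer radius, normal offset at most the loop
#'   thickness).
#' @param image_noise Gaussian sd of additive image noise (intensity units,
#'   images live in \[0, 1\]).
#' @param background Background intensity level of captured images.
#' @param seed Integer noise seed; all simulated measurements are
#'   deterministic functions of (sample, pose, seed).
#' @return An object of class `virtual_sample`.
#' @export
virtual_sample <- function(loop = loop_truth(), crystals = list(),
                           image_noise = 0, background = 0.1, seed = 1L) {
  if (!is.null(loop)) {
    a <- deg2rad(loop$plane_normal_angle)
    ctr <- loop_ring_center(loop)
    for (k in seq_along(crystals)) {
      cr <- crystals[[k]]
      d <- cr$center - ctr
      in_plane <- sqrt(d[3]^2 + (d[1] * sin(a) - d[2] * cos(a))^2)
      normal_off <- abs(d[1] * cos(a) + d[2] * sin(a))
      if (in_plane > loop$outer_radius || normal_off > loop$thickness) {
        stop(sprintf("crystal %d lies outside the loop volume", k))
      }
    }
  }
  structure(
    list(
      loop = loop, crystals = crystals,
      image_noise = as.numeric(image_noise),
      background = as.numeric(background),
      seed = as.integer(seed)
    ),
    class = "virtual_sample"
  )
}

#' Build a virtual sample from a plain-list (or JSON) specification
#'
#' @param spec A list with elements `loop` (fields of [loop_truth()]),
#'   `crystals` (list of lists with `center`, `half_extents`,
#'   `diffraction_power`), and optional `image_noise`, `background`,
#'   `seed`; or a path to a JSON file holding the same structure.
#' @return A [virtual_sample()].
#' @export
make_sample <- function(spec) {
  if (is.character(spec)) {
    spec <- jsonlite::read_json(spec, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE)
  }
  loop <- if (is.null(spec$loop)) loop_truth() else do.call(loop_truth, spec$loop)
  crystals <- lapply(spec$crystals, function(cr) {
    crystal_truth(unlist(cr$center), unlist(cr$half_extents),
                  cr$diffraction_power)
  })
  virtual_sample(
    loop = loop, crystals = crystals,
    image_noise = spec$image_noise %||% 0,
    background = spec$background %||% 0.1,
    seed = spec$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a sample specification as JSON
#' @param sample A [virtual_sample()].
#' @param path Output path.
#' @export
write_sample <- function(sample, path) {
  spec <- list(
    loop = unclass(sample$loop),
    crystals = lapply(sample$crystals, unclass),
    image_noise = sample$image_noise,
    background = sample$background,
    seed = sample$seed
  )
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Camera description for the on-axis microscope
#'
#' @param shape Image shape (rows, cols) in pixels; at least 64 x 64.
#' @param pixel_size um per pixel.
#' @param beam_center Pixel (row, col) of the X-ray position; defaults to
#'   the image center.
#' @return An object of class `zoo_camera`.
#' @export
zoo_camera <- function(shape = c(192, 256), pixel_size = 4,
                       beam_center = (shape + 1) / 2) {
  if (any(shape < 64)) stop("camera shape must be at least 64 x 64")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (beam_center[1] < 1 || beam_center[1] > shape[1] ||
      beam_center[2] < 1 || beam_center[2] > shape[2]) {
    stop("beam_center must lie inside the image")
  }
  structure(
    list(shape = as.integer(shape), pixel_size = as.numeric(pixel_size),
         beam_center = as.numeric(beam_center)),
    class = "zoo_camera"
  )
}

combine_seed <- function(a, b) {
  as.integer(((as.numeric(a) %% 59999) * 35521 + (as.numeric(b) %% 35521)) %%
               2147483647)
}

#' Capture a simulated on-axis microscope image
#'
#' Renders the loop silhouette (projection of the rotated loop disk plus
#' stem) on a uniform background with optional additive Gaussian noise.
#' The projected silhouette area varies with omega with 180-degree period
#' and is minimal when the loop plane contains the beam direction.
#'
#' @param sample A [virtual_sample()].
#' @param omega Goniometer angle, degrees.
#' @param camera A [zoo_camera()].
#' @param offset Sample-frame translation (um) applied by the goniometer.
#' @param seed Noise seed; defaults to the sample's seed.
#' @return A `microscope_image`: list with `pixels` (rows x cols intensity
#'   matrix in \[0, 1\]), `pixel_size`, `beam_center`, `omega`.
#' @export
capture_image <- function(sample, omega, camera = zoo_camera(),
                          offset = c(0, 0, 0), seed = sample$seed) {
  nr <- camera$shape[1]; nc <- camera$shape[2]; ps <- camera$pixel_size
  lab_y <- (camera$beam_center[1] - seq_len(nr)) * ps # rows increase downward
  lab_z <- (seq_len(nc) - camera$beam_center[2]) * ps
  img <- matrix(sample$background, nr, nc)
  loop <- sample$loop
  if (!is.null(loop)) {
    a <- loop$plane_normal_angle
    gamma <- deg2rad(a + omega)
    ctr <- sample_to_lab(loop_ring_center(loop) + offset, omega)
    semi_z <- loop$outer_radius
    # thin tilted plate: projected height R|cos g|, floored at the material
    # thickness so the edge-on silhouette stays visible
    semi_y <- max(loop$outer_radius * abs(cos(gamma)), loop$thickness / 2)
    zz <- matrix(lab_z, nr, nc, byrow = TRUE)
    yy <- matrix(lab_y, nr, nc)
    disk <- ((zz - ctr[3]) / semi_z)^2 + ((yy - ctr[2]) / semi_y)^2 <= 1
    stem_hw <- max((loop$stem_width / 2) * abs(cos(gamma)),
                   loop$thickness / 2)
    stem <- zz >= ctr[3] + 0.9 * semi_z & abs(yy - ctr[2]) <= stem_hw
    img[disk | stem] <- sample$background + 0.6
  }
  if (sample$image_noise > 0) {
    img <- img + with_seed(
      combine_seed(seed, round(mod360(omega) * 100)),
      matrix(stats::rnorm(nr * nc, 0, sample$image_noise), nr, nc)
    )
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  structure(
    list(pixels = img, pixel_size = ps, beam_center = camera$beam_center,
         omega = omega),
    class = "microscope_image"
  )
}

#' @export
print.microscope_image <- function(x, ...) {
  cat(sprintf("<microscope_image %d x %d px, %.3g um/px, omega %.1f deg>\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$omega))
  invisible(x)
}

#' Expected raster-scan spot counts (noise-free)
#'
#' For each grid center the expected low-resolution spot count is the sum
#' over crystals of diffraction power times the fraction of the beam
#' footprint (a top-hat rectangle extruded along the beam at angle omega)
#' whose rays intersect the crystal. Because crystals are axis-aligned
#' boxes and rotation is about Z, the crystal shadow on the detector-facing
#' plane is an exact rectangle and the fraction is a product of 1-D
#' overlaps.
#'
#' @param sample A [virtual_sample()].
#' @param grid_centers n x 3 matrix (or length-3 vector) of sample-frame
#'   coordinates (um).
#' @param omega Degrees.
#' @param beam Beam size c(horizontal, vertical) in um.
#' @param offset Sample-frame goniometer translation (um).
#' @return Numeric vector of expected counts.
#' @export
raster_expected <- function(sample, grid_centers, omega, beam = c(10, 15),
                            offset = c(0, 0, 0)) {
  if (any(beam <= 0)) stop("beam sizes must be positive")
  # grid centers live in the goniometer-corrected sample frame; crystals are
  # shifted by the accumulated offset within it
  g <- sample_to_lab(rbind_coords(grid_centers), omega)
  w <- deg2rad(omega)
  expected <- rep(0, nrow(g))
  for (cr in sample$crystals) {
    ctr <- cr$center + offset
    hz <- cr$half_extents[1]; hy <- cr$half_extents[2]; hx <- cr$half_extents[3]
    cy <- ctr[1] * sin(w) + ctr[2] * cos(w)
    hy_lab <- hx * abs(sin(w)) + hy * abs(cos(w))
    fz <- overlap_len(g[, 3] - beam[1] / 2, g[, 3] + beam[1] / 2,
                      ctr[3] - hz, ctr[3] + hz) / beam[1]
    fy <- overlap_len(g[, 2] - beam[2] / 2, g[, 2] + beam[2] / 2,
                      cy - hy_lab, cy + hy_lab) / beam[2]
    expected <- expected + cr$diffraction_power * fz * fy
  }
  expected
}

#' Simulated raster-scan spot counts (Poisson realization)
#'
#' Realized counts are Poisson draws around [raster_expected()], seeded so
#' the simulation is a pure function of (sample, pose, seed).
#'
#' @inheritParams raster_expected
#' @param seed Integer seed for the Poisson draw.
#' @return Integer vector of counts, with the expectation attached as
#'   attribute `"expected"`.
#' @export
raster_response <- function(sample, grid_centers, omega, beam = c(10, 15),
                            seed = sample$seed, offset = c(0, 0, 0)) {
  expected <- raster_expected(sample, grid_centers, omega, beam, offset)
  counts <- with_seed(combine_seed(seed, round(mod360(omega) * 100)),
                      stats::rpois(length(expected), expected))
  attr(counts, "expected") <- expected
  counts
}

#' The nine-crystal mixed-scheme demonstration sample
#'
#' A deterministic virtual sample containing nine crystals laid out so that
#' every spatial relationship required by the mixed-scheme categorizer is
#' realized: crystal 1 overlaps no other along the rotation axis; crystals
#' 2 and 3 overlap each other but with a vertical gap of at least three
#' vertical beam sizes and helical-compatible sizes; crystals 4 and 5
#' likewise but too short for helical collection; crystals 6-8 are
#' vertically closer than three beam sizes; crystal 9 is vertically well
#' separated but longer than the maximum helical size.
#'
#' @param diffraction_power Expected spots for a fully illuminated grid.
#' @return A [virtual_sample()] with 9 crystals (in list order C1..C9).
#' @export
scenario_nine_crystals <- function(diffraction_power = 60) {
  boxes <- list(
    # each row: z_min, z_max, y_min, y_max  (um, edges on a 10 um lattice)
    c(50, 110, -10, 10),    # C1 isolated, size 60
    c(150, 230, 50, 70),    # C2 overlaps C3, gap 100
    c(170, 250, -70, -50),  # C3
    c(280, 290, 50, 70),    # C4 overlaps C5, gap 100, size 10
    c(280, 290, -70, -50),  # C5
    c(330, 400, -10, 10),   # C6 cluster, gaps 30 to C7/C8
    c(350, 420, 40, 60),    # C7
    c(340, 410, -60, -40),  # C8
    c(390, 520, 110, 130)   # C9 overlaps cluster, gap >= 50, size 130
  )
  crystals <- lapply(boxes, function(b) {
    crystal_truth(
      center = c(0, (b[3] + b[4]) / 2, (b[1] + b[2]) / 2),
      half_extents = c((b[2] - b[1]) / 2, (b[4] - b[3]) / 2, 10),
      diffraction_power = diffraction_power
    )
  })
  virtual_sample(
    loop = loop_truth(plane_normal_angle = 0, outer_radius = 300,
                      inner_radius = 270, tip_position = c(0, 0, 0)),
    crystals = crystals, image_noise = 0, background = 0.1, seed = 4L
  )
}

#' A stateful virtual goniometer wrapping a sample and camera
#'
#' Models the centering stages: translations requested in lab coordinates
#' at the current omega are accumulated as a sample-frame offset (the
#' stages rotate with the spindle), so vertical moves at 0 and 90 degrees
#' center different sample-frame axes.
#'
#' @param sample A [virtual_sample()].
#' @param camera A [zoo_camera()].
#' @return An environment with functions `capture(omega)`,
#'   `translate(dy_lab, dz, omega)`, `offset()` (current sample-frame
#'   offset), and fields `sample`, `camera`.
#' @export
virtual_gonio <- function(sample, camera = zoo_camera()) {
  env <- new.env(parent = emptyenv())
  env$sample <- sample
  env$camera <- camera
  env$.offset <- c(0, 0, 0)
  env$capture <- function(omega) {
    capture_image(env$sample, omega, env$camera, offset = env$.offset)
  }
  env$background <- function(omega) {
    bare <- env$sample
    bare$loop <- NULL
    bare$crystals <- list()
    capture_image(bare, omega, env$camera, offset = env$.offset,
                  seed = combine_seed(env$sample$seed, 7919))
  }
  env$translate <- function(dy_lab = 0, dz = 0, omega = 0) {
    d <- lab_to_sample(c(0, dy_lab, 0), omega)[1, ] + c(0, 0, dz)
    env$.offset <- env$.offset + d
    invisible(env$.offset)
  }
  env$offset <- function() env$.offset
  class(env) <- "virtual_gonio"
  env
}
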