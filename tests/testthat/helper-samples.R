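# Synthetic sample generators shared across tests.

std_camera <- function() zoo_camera(c(192, 256), pixel_size = 4)

# A random loop with one isolated crystal, with ground truth attached.
random_recovery_sample <- function(seed) {
  set.seed(seed)
  alpha <- runif(1, 0, 180)
  outer <- runif(1, 250, 320)
  tip <- c(runif(1, -15, 15), runif(1, -30, 30), runif(1, -120, -20))
  loop <- loop_truth(plane_normal_angle = alpha, outer_radius = outer,
                     inner_radius = outer - 30, tip_position = tip)
  ctr <- tip + c(0, 0, outer)
  a <- alpha * pi / 180
  v <- c(sin(a), -cos(a), 0) # in-plane "height" direction
  u <- c(0, 0, 1)
  ip <- runif(2, -0.55, 0.55) * outer
  center <- ctr + ip[1] * u + ip[2] * v
  # plate-like crystal: its beam-depth extent stays below the 10 um beam,
  # the regime where quasi-3D depth recovery is well posed
  cryst <- crystal_truth(center,
                         half_extents = c(runif(1, 25, 45), runif(1, 8, 15),
                                          runif(1, 3, 5)),
                         diffraction_power = 50)
  list(sample = virtual_sample(loop, list(cryst), seed = seed),
       crystal = cryst, loop = loop,
       face_angle = loop_face_angle(loop))
}

# A loop densely packed with n small crystals for multi-wedge runs.
multi_crystal_sample <- function(n = 30, seed = 1) {
  set.seed(seed)
  loop <- loop_truth()
  ctr <- c(0, 0, 300)
  crystals <- list()
  pts <- NULL
  while (length(crystals) < n) {
    p <- c(runif(1, -10, 10), runif(1, -180, 180), runif(1, 60, 540))
    if (sqrt((p[3] - ctr[3])^2 + p[2]^2) > 250) next
    if (!is.null(pts) && any(sqrt(colSums((t(pts) - p)^2)) < 45)) next
    pts <- rbind(pts, p)
    crystals[[length(crystals) + 1L]] <-
      crystal_truth(p, half_extents = c(8, 8, 8), diffraction_power = 50)
  }
  virtual_sample(loop, crystals, seed = seed)
}

# Foreground pixel count of a noise-free capture.
silhouette_count <- function(sample, omega, camera = std_camera()) {
  img <- capture_image(sample, omega, camera)
  sum(img$pixels > sample$background + 1e-6)
}
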