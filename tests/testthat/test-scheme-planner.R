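mk_map <- function(scores, step = 10, origin = c(0, 0, 0), omega = 0) {
  structure(
    list(scores = scores, origin = origin, step_h = step, step_v = step,
         omega = omega, provenance = list()),
    class = "zoo_heatmap"
  )
}

test_that("segmentation equals connected-component labeling on random maps", {
  for (sd in 1:200) {
    set.seed(sd)
    nv <- sample(4:10, 1); nh <- sample(4:12, 1)
    m <- matrix(rpois(nv * nh, 4), nv, nh)
    thr <- sample(3:6, 1)
    regs <- segment_crystals(mk_map(m), thr)
    lab <- oracle_label_components(m > thr, 8L)
    expect_equal(length(regs), max(lab))
    got <- sort(vapply(regs, function(r) {
      paste(sort(r$members[, 1] + (r$members[, 2] - 1) * nv),
            collapse = ",")
    }, character(1)))
    expect_equal(got, labeling_sets(lab))
  }
})

test_that("segmentation orders regions by peak score and fills fields", {
  m <- matrix(0L, 5, 9)
  m[2, 2:4] <- c(20L, 35L, 22L)   # blob A, peak 35
  m[4, 7:8] <- c(50L, 18L)        # blob B, peak 50
  regs <- segment_crystals(mk_map(m), 15)
  expect_length(regs, 2L)
  expect_equal(regs[[1]]$peak_score, 50L)
  expect_equal(regs[[2]]$peak_score, 35L)
  # size along the rotation axis includes one grid step
  expect_equal(regs[[2]]$size_along_axis, (4 - 2) * 10 + 10)
  expect_equal(regs[[2]]$z_min, 10)
  expect_equal(regs[[2]]$z_max, 30)

  # uniform map below threshold: nothing
  expect_length(segment_crystals(mk_map(matrix(3L, 4, 4)), 15), 0L)
  # single grid above threshold
  m1 <- matrix(0L, 3, 3)
  m1[2, 2] <- 99L
  r1 <- segment_crystals(mk_map(m1), 15)
  expect_length(r1, 1L)
  expect_equal(nrow(r1[[1]]$members), 1L)
})

test_that("region edges pick extreme columns with deterministic ties", {
  m <- matrix(0L, 4, 9)
  m[2, 3:7] <- 20L
  r <- segment_crystals(mk_map(m), 10)[[1]]
  e <- region_edges(r)
  expect_equal(unname(e$left), c(2, 3))
  expect_equal(unname(e$right), c(2, 7))

  # L-shaped region: exhaustive min/max over members
  mL <- matrix(0L, 5, 6)
  mL[2:4, 2] <- 20L
  mL[4, 2:5] <- 20L
  rL <- segment_crystals(mk_map(mL), 10)[[1]]
  eL <- region_edges(rL)
  expect_equal(unname(eL$left[2]), min(rL$members[, 2]))
  expect_equal(unname(eL$right[2]), max(rL$members[, 2]))
  # column tie on the left edge: higher score wins, then smaller row
  h <- mk_map(mL)
  h$scores[2, 2] <- 25L
  rL2 <- segment_crystals(h, 10)[[1]]
  expect_equal(unname(region_edges(rL2, h)$left), c(2, 2))

  # single-grid region: left == right
  m1 <- matrix(0L, 3, 3)
  m1[2, 2] <- 30L
  r1 <- segment_crystals(mk_map(m1), 10)[[1]]
  e1 <- region_edges(r1)
  expect_equal(e1$left, e1$right)
})

test_that("helical scan angles straddle the face angle and clamp at 90", {
  expect_equal(helical_scan_angles(40, 0), c(start = -20, end = 20))
  expect_equal(helical_scan_angles(360, 0), c(start = -90, end = 90))
  expect_equal(helical_scan_angles(0.2, 57), c(start = 56.9, end = 57.1))
  expect_equal(helical_scan_angles(181, 10), c(start = -80, end = 100))
  expect_error(helical_scan_angles(0, 0), "positive")
})

test_that("quasi-3D edge location solves the two-projection system", {
  # crystal edge 12 um behind the raster plane: a side scan at face + 90
  # reads the depth directly
  cr <- crystal_truth(c(12, 0, 250), c(40, 10, 6), 50)
  s <- virtual_sample(loop_truth(), list(cr), seed = 3)
  scan_y <- seq(-20, 20, by = 5)
  pts <- vertical_scan_points(210, scan_y, 90)
  sc <- raster_expected(s, pts, 90, beam = c(5, 5))
  pos <- locate_edge_3d(c(0, 210), 0, 90, scan_y, sc)
  expect_lt(abs(pos[1] - 12), 5)
  expect_equal(pos[3], 210)

  # symmetric response: the lower-index maximum is chosen
  pos2 <- locate_edge_3d(c(0, 100), 0, 90, c(-5, 0, 5), c(1, 4, 4))
  expect_equal(pos2[1], 0)

  # all-zero response is an edge-not-found error
  expect_error(locate_edge_3d(c(0, 100), 0, 90, c(-5, 0, 5), c(0, 0, 0)),
               "edge not found")
  # degenerate geometry
  expect_error(locate_edge_3d(c(0, 100), 30, 30, c(-5, 0, 5), c(1, 2, 1)),
               "differ")
})

test_that("mixed-scheme categorization applies overlap, gap and size rules", {
  params <- mixed_params(min_helical = 40, max_helical = 100, v_beam = 15)

  # two crystals overlapping along the axis with a vertical gap of only
  # 2 beam sizes: both clustered
  m <- matrix(0L, 12, 10)
  m[2, 2:6] <- 50L
  m[2 + 1 + 3, 3:8] <- 50L # 3 empty rows -> gap 4 steps = 40 um < 45
  regs <- segment_crystals(mk_map(m), 15)
  cats <- vapply(categorize(regs, params), `[[`, character(1), "category")
  expect_equal(sort(cats), c("CLUSTERED", "CLUSTERED"))

  # isolated crystal with helical-compatible size: full rotation
  m2 <- matrix(0L, 5, 10)
  m2[3, 2:7] <- 50L # 6 grids -> 60 um
  cats2 <- vapply(categorize(segment_crystals(mk_map(m2), 15), params),
                  `[[`, character(1), "category")
  expect_equal(cats2, "HELICAL_FULL")

  # isolated but too short / too long
  m3 <- matrix(0L, 5, 16)
  m3[2, 2:3] <- 50L   # 20 um < 40
  m3[4, 6:18 - 2] <- 50L # 130 um > 100, no horizontal overlap with the short one?
  m3[4, 6:16] <- 50L
  m3[2, 2:3] <- 50L
  regs3 <- segment_crystals(mk_map(m3), 15)
  cats3 <- vapply(categorize(regs3, params), `[[`, character(1), "category")
  expect_setequal(cats3, c("SMALL_WEDGE", "CLUSTERED"))

  # totality and permutation invariance on random maps
  for (sd in 1:20) {
    set.seed(700 + sd)
    mr <- matrix(rpois(12 * 14, 6), 12, 14)
    regs <- segment_crystals(mk_map(mr), 8)
    if (length(regs) < 2) next
    cats_a <- vapply(categorize(regs, params), `[[`, character(1),
                     "category")
    expect_true(all(cats_a %in% c("HELICAL_FULL", "PARTIAL_HELICAL",
                                  "SMALL_WEDGE", "CLUSTERED")))
    perm <- sample(length(regs))
    cats_b <- vapply(categorize(regs[perm], params), `[[`, character(1),
                     "category")
    expect_equal(cats_b, cats_a[perm])
  }
})

test_that("the nine-crystal demonstration reproduces the expected grouping", {
  s <- scenario_nine_crystals()
  g <- virtual_gonio(s, std_camera())
  cl <- center_loop(g, beam = c(10, 10), user_loop_size = 600)
  centers <- raster_grid_centers(cl$area)
  counts <- raster_response(s, centers, cl$face_angle, c(10, 10),
                            seed = 17, offset = g$offset())
  h <- assemble_heatmap(as.numeric(counts), cl$area, serpentine = FALSE)
  regs <- segment_crystals(h, 15)
  expect_length(regs, 9L)
  asg <- categorize(regs, mixed_params())
  cats <- vapply(asg, `[[`, character(1), "category")
  expect_equal(sum(cats == "HELICAL_FULL"), 1L)
  expect_equal(sum(cats == "PARTIAL_HELICAL"), 2L)
  expect_equal(sum(cats == "SMALL_WEDGE"), 2L)
  expect_equal(sum(cats == "CLUSTERED"), 4L)

  # match regions back to ground-truth crystals by center position
  off <- g$offset()
  truth_z <- vapply(s$crystals, function(cr) cr$center[3], numeric(1)) +
    off[3]
  for (k in seq_along(asg)) {
    r <- asg[[k]]$region
    idx <- which.min(abs(truth_z - (r$z_min + r$z_max) / 2))
    want <- c("HELICAL_FULL", "PARTIAL_HELICAL", "PARTIAL_HELICAL",
              "SMALL_WEDGE", "SMALL_WEDGE", "CLUSTERED", "CLUSTERED",
              "CLUSTERED", "CLUSTERED")[idx]
    expect_equal(asg[[k]]$category, want)
  }
})

test_that("clustered regions split on a stride-2 lattice of separate crystals", {
  # 4 x 4 block with the best grid in its corner
  m <- matrix(0L, 6, 6)
  m[2:5, 2:5] <- 20L
  m[2, 2] <- 40L
  r <- segment_crystals(mk_map(m), 10)[[1]]
  got <- split_clustered(r)
  expect_equal(nrow(got), 4L)
  expect_true(all(paste(got[, 1], got[, 2]) %in%
                    c("2 2", "2 4", "4 2", "4 4")))

  # single grid returns itself
  m1 <- matrix(0L, 3, 3)
  m1[2, 2] <- 30L
  r1 <- segment_crystals(mk_map(m1), 10)[[1]]
  expect_equal(nrow(split_clustered(r1)), 1L)

  # 1 x 5 row with the best grid in the middle: stride-2 columns through it
  m2 <- matrix(0L, 3, 7)
  m2[2, 2:6] <- 20L
  m2[2, 4] <- 35L
  r2 <- segment_crystals(mk_map(m2), 10)[[1]]
  got2 <- split_clustered(r2)
  expect_equal(got2[, 2], c(2, 4, 6))

  # property: outputs lie in the region and are pairwise non-adjacent
  for (sd in 1:20) {
    set.seed(900 + sd)
    mr <- matrix(rpois(8 * 9, 5), 8, 9)
    regs <- segment_crystals(mk_map(mr), 6)
    for (r in regs) {
      sel <- split_clustered(r)
      keys <- paste(r$members[, 1], r$members[, 2])
      expect_true(all(paste(sel[, 1], sel[, 2]) %in% keys))
      if (nrow(sel) > 1) {
        dd <- as.matrix(dist(sel))
        diag(dd) <- Inf
        expect_gte(min(dd), 2) # no 8-adjacency
      }
    }
  }
})

test_that("SS-ROX planning ties oscillation to loop length and scan step", {
  p1 <- plan_ssrox(600, 300, scan_step = 10, osc_per_frame = 1,
                   v_line_spacing = 15)
  expect_equal(p1$frames_per_line, 60L)
  expect_equal(p1$osc_per_line, 60)
  expect_equal(p1$n_lines, 20L)

  expect_equal(plan_ssrox(10, 10, 10, 1, 10)$frames_per_line, 1L)

  p3 <- plan_ssrox(605, 300, 10, 0.5, 15)
  expect_equal(p3$frames_per_line, 61L)
  expect_equal(p3$osc_per_line, 30.5)

  # invariant: per-line oscillation = frames x rotation per frame
  set.seed(31)
  for (k in 1:20) {
    p <- plan_ssrox(runif(1, 50, 900), runif(1, 50, 400),
                    runif(1, 2, 25), runif(1, 0.1, 2), runif(1, 5, 30))
    expect_equal(p$osc_per_line, p$frames_per_line * p$osc_per_frame)
    expect_gte(p$n_lines * p$v_line_spacing, 0)
  }
  expect_error(plan_ssrox(0, 10, 10, 1, 10), "positive")
})

test_that("helical vectors recovered from scans match crystal edges", {
  for (k in 1:6) {
    rs <- random_recovery_sample(500 + k)
    s <- rs$sample
    res <- run_sample(zoo_params(mode = "helical", beam = c(10, 10),
                                 total_osc = 360, osc_width = 0.1),
                      s, seed = 40 + k)
    recs <- Filter(function(r) r$status == "ok", res$records)
    expect_gte(length(recs), 1L)
    r <- recs[[1]]
    off <- res$loop_offset
    cr <- rs$crystal
    left_truth <- cr$center + c(0, 0, -cr$half_extents[1]) + off
    right_truth <- cr$center + c(0, 0, cr$half_extents[1]) + off
    expect_lt(max(abs(unlist(r$vector_start) - left_truth)), 10 + 1e-9)
    expect_lt(max(abs(unlist(r$vector_end) - right_truth)), 10 + 1e-9)
  }
})
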