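#' Crystal segmentation and data-collection scheme planning
#'
#' Interprets raster heat maps: contiguous grids scoring above a threshold
#' are regarded as individual crystals; per crystal the leftmost/rightmost
#' edges along the rotation axis define the helical vector, quasi-3D
#' vertical scans at omega offsets locate edge depth, and the mixed-scheme
#' categorizer assigns each crystal to helical full rotation, partial
#' helical, small wedge or clustered collection. Serial rotation (SS-ROX)
#' scans over the whole loop are planned from the loop extents.
#'
#' @name scheme_planner
NULL

#' Parameters controlling mixed-scheme categorization
#'
#' @param min_helical,max_helical Crystal size range (along the rotation
#'   axis, um) eligible for helical collection.
#' @param vertical_gap_multiplier Horizontally overlapping crystals remain
#'   helical candidates only if their vertical gap is at least this many
#'   vertical beam sizes.
#' @param wedge_full,wedge_partial,wedge_small Total oscillation (degrees)
#'   collected per crystal in the helical-full-rotation, partial-helical
#'   and small-wedge schemes.
#' @param v_beam Vertical beam size for data collection, um.
#' @return An object of class `mixed_params`.
#' @export
mixed_params <- function(min_helical = 40, max_helical = 100,
                         vertical_gap_multiplier = 3, wedge_full = 360,
                         wedge_partial = 40, wedge_small = 5, v_beam = 15) {
  if (min_helical >= max_helical) stop("min_helical must be < max_helical")
  if (vertical_gap_multiplier <= 0) stop("multiplier must be positive")
  structure(
    list(min_helical = min_helical, max_helical = max_helical,
         vertical_gap_multiplier = vertical_gap_multiplier,
         wedge_full = wedge_full, wedge_partial = wedge_partial,
         wedge_small = wedge_small, v_beam = v_beam),
    class = "mixed_params"
  )
}

region_from_members <- function(members, heatmap) {
  scores <- heatmap$scores[members]
  peak_k <- order(-scores, members[, 1], members[, 2])[1]
  y_of <- function(i) heatmap$origin[2] - (i - 1) * heatmap$step_v
  z_of <- function(j) heatmap$origin[3] + (j - 1) * heatmap$step_h
  structure(
    list(
      members = members,
      peak = members[peak_k, ],
      peak_score = scores[peak_k],
      z_min = z_of(min(members[, 2])), z_max = z_of(max(members[, 2])),
      y_min = y_of(max(members[, 1])), y_max = y_of(min(members[, 1])),
      size_along_axis = z_of(max(members[, 2])) - z_of(min(members[, 2])) +
        heatmap$step_h,
      step_h = heatmap$step_h, step_v = heatmap$step_v,
      omega = heatmap$omega
    ),
    class = "crystal_region"
  )
}

#' @export
print.crystal_region <- function(x, ...) {
  cat(sprintf(
    "<crystal_region %d grids, z [%g, %g] um, y [%g, %g] um, peak %d>\n",
    nrow(x$members), x$z_min, x$z_max, x$y_min, x$y_max, x$peak_score))
  invisible(x)
}

#' Segment crystals on a heat map by iterative region growing
#'
#' Repeatedly takes the best-scoring unassigned grid above `threshold` and
#' flood-fills over 8-connected grids above threshold; each grown region is
#' one crystal. The result equals the 8-connected components of the
#' above-threshold mask, emitted in order of descending peak score (ties by
#' row then column of the peak).
#'
#' @param heatmap A `zoo_heatmap`.
#' @param threshold Score threshold; grids must exceed it strictly.
#' @return List of `crystal_region` objects (possibly empty).
#' @export
segment_crystals <- function(heatmap, threshold = 15) {
  if (threshold < 0) stop("threshold must be >= 0")
  good <- heatmap$scores > threshold
  assigned <- matrix(FALSE, nrow(good), ncol(good))
  regions <- list()
  repeat {
    open <- good & !assigned
    if (!any(open)) break
    w <- which(open, arr.ind = TRUE)
    sc <- heatmap$scores[open]
    best <- w[order(-sc, w[, 1], w[, 2])[1], , drop = FALSE]
    # flood fill from the best grid over the above-threshold mask
    lab <- label_components(open, connectivity = 8L)
    members <- which(lab == lab[best], arr.ind = TRUE)
    assigned[members] <- TRUE
    regions[[length(regions) + 1L]] <- region_from_members(members, heatmap)
  }
  regions
}

#' Leftmost and rightmost edge grids of a crystal region
#'
#' Left is the member grid with minimal column (along the rotation axis);
#' ties break by maximal score, then minimal row. Right analogously.
#'
#' @param region A `crystal_region`.
#' @param heatmap The heat map the region came from (for tie-breaking by
#'   score); optional, ties then break by row only.
#' @return List with `left` and `right`, each c(i, j).
#' @export
region_edges <- function(region, heatmap = NULL) {
  pick <- function(cols_target) {
    m <- region$members[region$members[, 2] == cols_target, , drop = FALSE]
    if (!is.null(heatmap)) {
      sc <- heatmap$scores[m]
      m <- m[order(-sc, m[, 1]), , drop = FALSE]
    } else {
      m <- m[order(m[, 1]), , drop = FALSE]
    }
    m[1, ]
  }
  list(left = pick(min(region$members[, 2])),
       right = pick(max(region$members[, 2])))
}

#' Start and end scan angles for helical collection
#'
#' The start-edge vertical scan is performed at half the total oscillation
#' before the face angle and the end edge half after; each offset is
#' clamped at 90 degrees when the total oscillation exceeds 180 degrees.
#'
#' @param total_osc Total oscillation of the data set, degrees (> 0).
#' @param face_angle Face angle, degrees.
#' @return c(start, end) omega in degrees.
#' @export
helical_scan_angles <- function(total_osc, face_angle) {
  if (total_osc <= 0) stop("total_osc must be positive")
  half <- min(total_osc / 2, 90)
  c(start = face_angle - half, end = face_angle + half)
}

#' Sample-frame points of a vertical 1D scan
#'
#' Points whose lab-frame vertical positions at `omega` are `y_values`, at
#' fixed rotation-axis coordinate `z` and zero lab depth.
#'
#' @param z Rotation-axis coordinate, um.
#' @param y_values Lab-vertical scan positions, um.
#' @param omega Scan angle, degrees.
#' @return length(y_values) x 3 matrix of sample-frame coordinates.
#' @export
vertical_scan_points <- function(z, y_values, omega) {
  t(vapply(y_values, function(y) {
    lab_to_sample(c(0, y, 0), omega)[1, ] + c(0, 0, z)
  }, numeric(3)))
}

#' Locate a crystal edge in 3D from a vertical scan response
#'
#' At the face angle a raster grid fixes the edge's rotation-axis
#' coordinate and its lab-vertical position; a second vertical scan at a
#' different omega fixes the remaining (beam-depth) coordinate. The
#' best-scoring scan step (ties: lower index) provides the second vertical
#' measurement, and the two linear projections are solved for the
#' sample-frame position.
#'
#' @param edge c(y, z): lab-frame vertical and rotation-axis coordinates of
#'   the edge grid at the face angle, um.
#' @param face_angle Omega of the raster scan, degrees.
#' @param scan_angle Omega of the vertical scan, degrees; must differ from
#'   `face_angle` modulo 180.
#' @param scan_y Lab-vertical positions of the scan steps, um.
#' @param scores Spot scores at the scan steps.
#' @param threshold Scores must exceed this to count as a hit.
#' @return Sample-frame coordinate c(x, y, z), um.
#' @export
locate_edge_3d <- function(edge, face_angle, scan_angle, scan_y, scores,
                           threshold = 0) {
  if (length(scan_y) != length(scores)) stop("scan_y/scores length mismatch")
  hit <- scores > threshold
  if (!any(hit)) stop("edge not found: all scan scores at or below threshold")
  best <- which(hit & scores == max(scores[hit]))[1]
  w1 <- deg2rad(face_angle); w2 <- deg2rad(scan_angle)
  det <- sin(w2 - w1)
  if (abs(det) < 1e-9) stop("scan angle must differ from the face angle")
  # x sin(w) + y cos(w) = lab y at each omega
  a <- matrix(c(sin(w1), cos(w1), sin(w2), cos(w2)), 2, 2, byrow = TRUE)
  xy <- solve(a, c(edge[1], scan_y[best]))
  c(xy[1], xy[2], edge[2])
}

#' Categorize crystal regions into the four mixed-scheme groups
#'
#' Per region: if no other region overlaps it along the rotation axis it is
#' a helical-full-rotation candidate; if every horizontally overlapping
#' region is vertically separated by at least `vertical_gap_multiplier`
#' vertical beam sizes it is a partial-helical candidate; otherwise it is
#' clustered. Helical candidates shorter than `min_helical` along the axis
#' become small-wedge; longer than `max_helical` become clustered. Every
#' region receives exactly one category, independent of region order.
#'
#' @param regions List of `crystal_region` objects.
#' @param params A [mixed_params()].
#' @return List of `scheme_assignment` objects: `region`, `category` (one
#'   of `"HELICAL_FULL"`, `"PARTIAL_HELICAL"`, `"SMALL_WEDGE"`,
#'   `"CLUSTERED"`), `wedge_total_osc` (degrees), `collection` (grid
#'   positions for small-wedge/clustered, edge grids for helical).
#' @export
categorize <- function(regions, params = mixed_params()) {
  n <- length(regions)
  iv <- function(r) { # physical extents: grid centers +- half a step
    c(zlo = r$z_min - r$step_h / 2, zhi = r$z_max + r$step_h / 2,
      ylo = r$y_min - r$step_v / 2, yhi = r$y_max + r$step_v / 2)
  }
  ivs <- lapply(regions, iv)
  lapply(seq_len(n), function(k) {
    r <- regions[[k]]
    me <- ivs[[k]]
    overl <- Filter(function(o) {
      overlap_len(me["zlo"], me["zhi"], o["zlo"], o["zhi"]) > 1e-9
    }, ivs[-k])
    cat_ <- if (length(overl) == 0L) {
      "HELICAL_FULL"
    } else {
      gaps <- vapply(overl, function(o) {
        max(0, max(o["ylo"] - me["yhi"], me["ylo"] - o["yhi"]))
      }, numeric(1))
      if (all(gaps >= params$vertical_gap_multiplier * params$v_beam)) {
        "PARTIAL_HELICAL"
      } else {
        "CLUSTERED"
      }
    }
    if (cat_ %in% c("HELICAL_FULL", "PARTIAL_HELICAL")) {
      if (r$size_along_axis < params$min_helical) cat_ <- "SMALL_WEDGE"
      if (r$size_along_axis > params$max_helical) cat_ <- "CLUSTERED"
    }
    wedge <- switch(cat_,
      HELICAL_FULL = params$wedge_full,
      PARTIAL_HELICAL = params$wedge_partial,
      SMALL_WEDGE = params$wedge_small,
      CLUSTERED = params$wedge_small
    )
    collection <- switch(cat_,
      HELICAL_FULL = region_edges(r),
      PARTIAL_HELICAL = region_edges(r),
      SMALL_WEDGE = matrix(r$peak, ncol = 2,
                           dimnames = list(NULL, c("row", "col"))),
      CLUSTERED = split_clustered(r)
    )
    structure(
      list(region = r, category = cat_, wedge_total_osc = wedge,
           collection = collection),
      class = "scheme_assignment"
    )
  })
}

#' @export
print.scheme_assignment <- function(x, ...) {
  cat(sprintf("<scheme_assignment %s, wedge %g deg, size %g um>\n",
              x$category, x$wedge_total_osc, x$region$size_along_axis))
  invisible(x)
}

#' Break a clustered region into individually collectable grids
#'
#' Assuming grids separated by one grid vertically and horizontally belong
#' to distinct crystals, returns the member grids on a stride-2 lattice in
#' both directions anchored at the region's best grid; no two returned
#' grids are 8-adjacent.
#'
#' @param region A `crystal_region`.
#' @return Matrix of grid positions (columns row, col).
#' @export
split_clustered <- function(region) {
  m <- region$members
  keep <- (m[, 1] - region$peak[1]) %% 2 == 0 &
    (m[, 2] - region$peak[2]) %% 2 == 0
  out <- m[keep, , drop = FALSE]
  colnames(out) <- c("row", "col")
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Plan a serial rotation (SS-ROX) scan over the loop
#'
#' Each scan line runs parallel to the rotation axis across the horizontal
#' loop extent while the crystal rotates continuously; the total
#' oscillation per line is the frame count (ceiling of length over scan
#' step) times the rotation width per frame. Lines tile the vertical loop
#' extent.
#'
#' @param h_len,v_len Horizontal and vertical loop extents, um.
#' @param scan_step Translation per frame along the line, um.
#' @param osc_per_frame Rotation width per frame, degrees.
#' @param v_line_spacing Vertical spacing between scan lines, um.
#' @return An `ssrox_plan`: `frames_per_line`, `osc_per_line` (degrees),
#'   `n_lines`, `line_offsets` (um below the top edge), `scan_step`,
#'   `osc_per_frame`.
#' @export
plan_ssrox <- function(h_len, v_len, scan_step = 10, osc_per_frame = 1,
                       v_line_spacing = scan_step) {
  if (any(c(h_len, v_len, scan_step, osc_per_frame, v_line_spacing) <= 0)) {
    stop("all SS-ROX planning inputs must be positive")
  }
  frames <- as.integer(ceiling(h_len / scan_step - 1e-9))
  n_lines <- as.integer(ceiling(v_len / v_line_spacing - 1e-9))
  structure(
    list(
      frames_per_line = frames,
      osc_per_line = frames * osc_per_frame,
      n_lines = n_lines,
      line_offsets = (seq_len(n_lines) - 0.5) * v_line_spacing,
      scan_step = scan_step, osc_per_frame = osc_per_frame,
      v_line_spacing = v_line_spacing
    ),
    class = "ssrox_plan"
  )
}

#' Refine crystal edges with a fine small-beam raster
#'
#' For crystals narrower than ~30 um the coarse grid is too crude to place
#' helical endpoints; a fine raster with a small beam (default 1 x 5 um)
#' around the region re-measures the leftmost and rightmost responding
#' positions.
#'
#' @param sample A [virtual_sample()] (measurement source).
#' @param region A `crystal_region`.
#' @param threshold Response threshold for a hit.
#' @param beam Fine beam size c(h, v), um.
#' @param offset Sample-frame goniometer offset, um.
#' @return List with `left` and `right`, each c(y, z) lab-frame um at the
#'   region's omega, or `NULL` if nothing responds.
#' @export
refine_region_edges <- function(sample, region, threshold = 0,
                                beam = c(1, 5), offset = c(0, 0, 0)) {
  zs <- seq(region$z_min - region$step_h / 2,
            region$z_max + region$step_h / 2, by = beam[1])
  ys <- seq(region$y_min - region$step_v / 2,
            region$y_max + region$step_v / 2, by = beam[2])
  glab <- as.matrix(expand.grid(x = 0, y = ys, z = zs))
  g <- plane_to_sample(glab, region$omega)
  resp <- raster_expected(sample, g, region$omega, beam, offset = offset)
  hit <- resp > threshold
  if (!any(hit)) return(NULL)
  gh <- glab[hit, , drop = FALSE]
  zl <- min(gh[, 3]); zr <- max(gh[, 3])
  best_at <- function(zv) {
    cand <- gh[abs(gh[, 3] - zv) < 1e-9, , drop = FALSE]
    sc <- resp[hit][abs(gh[, 3] - zv) < 1e-9]
    cand[order(-sc)[1], 2]
  }
  list(left = c(y = best_at(zl), z = zl), right = c(y = best_at(zr), z = zr))
}
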