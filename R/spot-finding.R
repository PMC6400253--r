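#' Diffraction spot finding and heat-map scoring
#'
#' A spot finder in the peakfinder8 family: per-radial-bin background
#' mean/sigma estimation with iterative outlier rejection, candidate
#' pixels above mean + SNR * sigma, 8-connected agglomeration, centroid and
#' intensity computation, and pixel-count gating. Frames are scored by the
#' number of low-resolution spots up to 5 Angstrom, the most robust
#' crystal-presence statistic because ice (~3.7 A) and lipid (~4.5 A) ring
#' artifacts fall below the cutoff. Scores are assembled into heat maps
#' and written in a plain TSV "summary" dialect.
#'
#' @name spot_finding
NULL

#' Detector geometry for resolution calculation
#'
#' @param pixel_size Pixel size, mm.
#' @param beam_center Beam center pixel (row, col).
#' @param camera_distance Crystal-to-detector distance, mm.
#' @param wavelength X-ray wavelength, Angstrom.
#' @return An object of class `detector_geometry`.
#' @export
detector_geometry <- function(pixel_size = 0.075, beam_center = c(32, 32),
                              camera_distance = 200, wavelength = 1.0) {
  if (pixel_size <= 0 || camera_distance <= 0 || wavelength <= 0) {
    stop("detector geometry values must be positive")
  }
  structure(
    list(pixel_size = pixel_size, beam_center = as.numeric(beam_center),
         camera_distance = camera_distance, wavelength = wavelength),
    class = "detector_geometry"
  )
}

#' Resolution (d-spacing) of a detector radius
#'
#' d = lambda / (2 sin(0.5 atan(r / distance))).
#'
#' @param r_mm Radial distance from the beam center, mm.
#' @param geometry A [detector_geometry()].
#' @return d-spacing in Angstrom (Inf at r = 0).
#' @export
radius_to_d <- function(r_mm, geometry) {
  geometry$wavelength / (2 * sin(0.5 * atan(r_mm / geometry$camera_distance)))
}

#' Find diffraction spots on a raster frame
#'
#' @param frame Nonnegative numeric matrix of pixel intensities (NA marks
#'   masked pixels); at least 16 x 16.
#' @param geometry A [detector_geometry()].
#' @param adc_threshold Minimum absolute intensity for candidate pixels.
#' @param min_snr Candidate pixels must exceed the radial background mean
#'   by this many background sigmas.
#' @param min_pix,max_pix Accepted connected-spot footprint size range.
#' @param bin_width Radial background bin width, pixels.
#' @param bg_iterations Background refinement iterations: pixels more than
#'   `bg_clip` sigma above their bin mean are excluded and the radial
#'   statistics recomputed, so bright peaks stop biasing the background.
#' @param bg_clip Clip level (in background sigmas) for the refinement.
#' @return A data.frame with one row per spot: `row`, `col`
#'   (intensity-weighted centroid, pixels), `intensity`
#'   (background-subtracted sum), `n_pix`, `snr` (peak pixel significance)
#'   and `d` (Angstrom), ordered by (row, col).
#' @export
find_spots <- function(frame, geometry, adc_threshold = 0, min_snr = 6,
                       min_pix = 3L, max_pix = 100L, bin_width = 1,
                       bg_iterations = 3L, bg_clip = 2) {
  if (!is.matrix(frame) || nrow(frame) < 16L || ncol(frame) < 16L) {
    stop("frame must be a matrix of at least 16 x 16 pixels")
  }
  live <- !is.na(frame)
  if (!any(live)) stop("all pixels are masked")
  if (min(frame[live]) < 0) stop("frame must be nonnegative")
  nr <- nrow(frame); nc <- ncol(frame)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  r_px <- sqrt((rr - geometry$beam_center[1])^2 +
                 (cc - geometry$beam_center[2])^2)
  bin <- as.integer(floor(r_px / bin_width)) + 1L
  nbin <- max(bin)

  bin_stats <- function(include) {
    idx <- live & include
    n <- tabulate(bin[idx], nbin)
    s <- rowsum_safe(frame[idx], bin[idx], nbin)
    m <- ifelse(n > 0, s / n, NA_real_)
    ss <- rowsum_safe(frame[idx]^2, bin[idx], nbin)
    v <- ifelse(n > 1, (ss - n * m^2) / (n - 1), NA_real_)
    sd <- sqrt(pmax(v, 0))
    sd[!is.finite(sd)] <- Inf
    m[!is.finite(m)] <- Inf
    list(mean = m, sd = sd)
  }
  include <- matrix(TRUE, nr, nc)
  st <- bin_stats(include)
  for (k in seq_len(bg_iterations)) {
    hot <- live & frame > st$mean[bin] + bg_clip * st$sd[bin]
    include <- !hot
    st <- bin_stats(include)
  }
  cand <- live & frame > st$mean[bin] + min_snr * st$sd[bin] &
    frame >= adc_threshold
  lab <- label_components(cand, connectivity = 8L)
  if (max(lab) == 0L) return(empty_spots())
  out <- lapply(seq_len(max(lab)), function(k) {
    px <- which(lab == k)
    if (length(px) < min_pix || length(px) > max_pix) return(NULL)
    w <- frame[px] - st$mean[bin[px]]
    w[w < 0] <- 0
    crow <- sum(rr[px] * w) / sum(w)
    ccol <- sum(cc[px] * w) / sum(w)
    r_mm <- sqrt((crow - geometry$beam_center[1])^2 +
                   (ccol - geometry$beam_center[2])^2) * geometry$pixel_size
    data.frame(
      row = crow, col = ccol, intensity = sum(w), n_pix = length(px),
      snr = max((frame[px] - st$mean[bin[px]]) / st$sd[bin[px]]),
      d = radius_to_d(r_mm, geometry)
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty_spots())
  out[order(out$row, out$col), , drop = FALSE]
}

empty_spots <- function() {
  data.frame(row = numeric(0), col = numeric(0), intensity = numeric(0),
             n_pix = integer(0), snr = numeric(0), d = numeric(0))
}

rowsum_safe <- function(x, g, nbin) {
  out <- numeric(nbin)
  if (length(x)) {
    s <- rowsum(x, g)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Score a frame by its low-resolution spot count
#'
#' The score is the number of spots at resolution d >= `d_min`; with the
#' default 5 Angstrom cutoff, ice-ring (~3.7 A) and lipid-ring (~4.5 A)
#' artifacts never contribute.
#'
#' @param spots A spot table from [find_spots()] (needs a `d` column).
#' @param d_min Resolution cutoff, Angstrom.
#' @return Integer score.
#' @export
score_frame <- function(spots, d_min = 5.0) {
  sum(spots$d >= d_min)
}

#' Assemble per-frame scores into a heat map
#'
#' @param scores Integer scores in acquisition order (length n_h * n_v).
#' @param area The [define_raster_area()] result the scan executed.
#' @param serpentine If `TRUE`, even-numbered scan lines were acquired
#'   right-to-left (boustrophedon) and are reversed.
#' @param provenance Optional list recording thresholds used.
#' @return A `zoo_heatmap`: list with `scores` (n_v x n_h matrix), `origin`
#'   (sample-frame um of grid (1,1) center), `step_h`, `step_v`, `omega`,
#'   `provenance`.
#' @export
assemble_heatmap <- function(scores, area, serpentine = TRUE,
                             provenance = list()) {
  if (length(scores) != area$n_h * area$n_v) {
    stop(sprintf("expected %d scores, got %d", area$n_h * area$n_v,
                 length(scores)))
  }
  m <- matrix(NA_integer_, area$n_v, area$n_h)
  for (i in seq_len(area$n_v)) {
    line <- scores[((i - 1) * area$n_h + 1):(i * area$n_h)]
    if (serpentine && i %% 2 == 0) line <- rev(line)
    m[i, ] <- line
  }
  if (all(m == round(m))) storage.mode(m) <- "integer"
  structure(
    list(scores = m, origin = area$origin, step_h = area$step_h,
         step_v = area$step_v, omega = area$omega, provenance = provenance),
    class = "zoo_heatmap"
  )
}

#' @export
print.zoo_heatmap <- function(x, ...) {
  cat(sprintf(
    "<zoo_heatmap %d x %d grids, step %g x %g um, omega %.1f deg, max score %d>\n",
    nrow(x$scores), ncol(x$scores), x$step_h, x$step_v, x$omega,
    max(x$scores)))
  invisible(x)
}

#' Grid coordinates of a heat map
#'
#' @param heatmap A `zoo_heatmap`.
#' @return data.frame with 1-based grid indices `i` (row, increasing
#'   downward), `j` (column, along the rotation axis), sample-frame `x`,
#'   `y`, `z` (um) and `score`.
#' @export
heatmap_coords <- function(heatmap) {
  nv <- nrow(heatmap$scores); nh <- ncol(heatmap$scores)
  g <- expand.grid(i = seq_len(nv), j = seq_len(nh))
  data.frame(
    i = g$i, j = g$j,
    x = heatmap$origin[1],
    y = heatmap$origin[2] - (g$i - 1) * heatmap$step_v,
    z = heatmap$origin[3] + (g$j - 1) * heatmap$step_h,
    score = heatmap$scores[cbind(g$i, g$j)]
  )
}

#' Write / read a heat map in the summary TSV dialect
#'
#' Tab-separated columns i, j, x, y, z, score with 1-based grid indices and
#' coordinates in um at 0.1 um precision; header comment lines carry omega,
#' the grid origin/step at full precision and any provenance, so the
#' round-trip is lossless.
#'
#' @param heatmap A `zoo_heatmap`.
#' @param path Output / input path.
#' @return `write_summary` returns the path invisibly; `read_summary`
#'   returns the `zoo_heatmap`.
#' @export
write_summary <- function(heatmap, path) {
  co <- heatmap_coords(heatmap)
  hdr <- c(
    "# raster-scan heat map (summary.dat dialect)",
    sprintf("# omega\t%.10g", heatmap$omega),
    sprintf("# origin\t%.10g\t%.10g\t%.10g", heatmap$origin[1],
            heatmap$origin[2], heatmap$origin[3]),
    sprintf("# step\t%.10g\t%.10g", heatmap$step_h, heatmap$step_v),
    sprintf("# provenance\t%s",
            as.character(jsonlite::toJSON(heatmap$provenance,
                                          auto_unbox = TRUE, digits = NA))),
    "# columns: i\tj\tx\ty\tz\tscore (grid indices 1-based; x/y/z um)"
  )
  body <- sprintf("%d\t%d\t%.1f\t%.1f\t%.1f\t%d", co$i, co$j, co$x, co$y,
                  co$z, co$score)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get_hdr <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, "\t"))]
    strsplit(sub(paste0("^# ", key, "\t"), "", ln[1]), "\t")[[1]]
  }
  omega <- as.numeric(get_hdr("omega"))
  origin <- as.numeric(get_hdr("origin"))
  step <- as.numeric(get_hdr("step"))
  prov <- jsonlite::fromJSON(get_hdr("provenance"), simplifyVector = TRUE)
  tab <- utils::read.table(text = body, sep = "\t", col.names =
                             c("i", "j", "x", "y", "z", "score"))
  m <- matrix(NA_integer_, max(tab$i), max(tab$j))
  m[cbind(tab$i, tab$j)] <- as.integer(tab$score)
  structure(
    list(scores = m, origin = origin, step_h = step[1], step_v = step[2],
         omega = omega, provenance = as.list(prov)),
    class = "zoo_heatmap"
  )
}

#' Select well-diffracting grids with a minimum mutual distance
#'
#' Grids whose score lies in the [min_score, max_score] window (grids above
#' the window are neglected as likely pathologies) are picked greedily by
#' descending score, skipping any grid closer than `min_distance` to an
#' already selected one; ties break by (row, col).
#'
#' @param heatmap A `zoo_heatmap`.
#' @param min_score,max_score Score window for "good" crystals.
#' @param min_distance Minimum in-plane separation between selections, um.
#' @return data.frame of selected grids: `i`, `j`, `x`, `y`, `z`, `score`.
#' @export
select_crystal_grids <- function(heatmap, min_score = 15, max_score = 100,
                                 min_distance = 0) {
  if (min_score > max_score) stop("min_score must be <= max_score")
  co <- heatmap_coords(heatmap)
  co <- co[co$score >= min_score & co$score <= max_score, , drop = FALSE]
  co <- co[order(-co$score, co$i, co$j), , drop = FALSE]
  keep <- logical(nrow(co))
  for (k in seq_len(nrow(co))) {
    sel <- co[keep, , drop = FALSE]
    if (nrow(sel) == 0L ||
        all(sqrt((sel$y - co$y[k])^2 + (sel$z - co$z[k])^2) >=
              min_distance)) {
      keep[k] <- TRUE
    }
  }
  out <- co[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Render a synthetic diffraction frame with injected Gaussian spots
#'
#' @param shape Frame shape (rows, cols).
#' @param spots data.frame with columns `row`, `col`, `height`, `sigma`
#'   (pixels); may be empty.
#' @param background Flat background level (expected counts per pixel).
#' @param seed Poisson noise seed; `NULL` renders the noise-free
#'   expectation.
#' @return Numeric matrix of counts.
#' @export
synth_frame <- function(shape = c(64, 64), spots = NULL, background = 10,
                        seed = NULL) {
  nr <- shape[1]; nc <- shape[2]
  img <- matrix(background, nr, nc)
  if (!is.null(spots) && nrow(spots) > 0) {
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    for (k in seq_len(nrow(spots))) {
      img <- img + spots$height[k] *
        exp(-((rr - spots$row[k])^2 + (cc - spots$col[k])^2) /
              (2 * spots$sigma[k]^2))
    }
  }
  if (is.null(seed)) return(img)
  with_seed(seed, matrix(stats::rpois(nr * nc, img), nr, nc))
}
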