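# Independent oracles used to cross-check the implementation.

# Connected-component labeling by iterative minimum-label propagation
# (a different algorithm from the package's queue-based flood fill).
oracle_label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0, nr, nc)
  lab[mask] <- which(mask)
  shifts <- if (connectivity == 8L) {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1), c(1, -1),
         c(1, 0), c(1, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  shift_mat <- function(m, dr, dc, fill) {
    out <- matrix(fill, nr, nc)
    ri <- max(1, 1 + dr):min(nr, nr + dr)
    ci <- max(1, 1 + dc):min(nc, nc + dc)
    out[ri, ci] <- m[ri - dr, ci - dc]
    out
  }
  repeat {
    new <- lab
    for (s in shifts) {
      nb <- shift_mat(lab, s[1], s[2], Inf)
      nb[nb == 0] <- Inf
      cand <- pmin(new, ifelse(mask, nb, Inf))
      new[mask] <- cand[mask]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  # renumber components 1..k in order of first appearance (column-major)
  ids <- unique(lab[lab > 0])
  out <- matrix(0L, nr, nc)
  for (k in seq_along(ids)) out[lab == ids[k]] <- k
  out
}

# Membership sets of a labeling, as a canonical sorted list of key strings,
# so two labelings can be compared independent of component numbering.
labeling_sets <- function(lab) {
  ids <- setdiff(unique(as.vector(lab)), 0L)
  sets <- lapply(ids, function(k) sort(which(lab == k)))
  sort(vapply(sets, function(s) paste(s, collapse = ","), character(1)))
}

# Brute-force reimplementation of the radial-background spot finder with
# explicit loops (O(N^2)-style rescan of the frame for every bin).
oracle_find_spots <- function(frame, geometry, min_snr = 6, min_pix = 3L,
                              max_pix = 100L, bin_width = 1,
                              bg_iterations = 3L, bg_clip = 2) {
  nr <- nrow(frame); nc <- ncol(frame)
  r_of <- function(i, j) sqrt((i - geometry$beam_center[1])^2 +
                                (j - geometry$beam_center[2])^2)
  binm <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    binm[i, j] <- floor(r_of(i, j) / bin_width) + 1L
  }
  excluded <- matrix(FALSE, nr, nc)
  means <- sds <- NULL
  for (it in 0:bg_iterations) {
    means <- rep(Inf, max(binm)); sds <- rep(Inf, max(binm))
    for (b in sort(unique(as.vector(binm)))) {
      vals <- frame[binm == b & !excluded]
      if (length(vals) >= 1) means[b] <- mean(vals)
      if (length(vals) >= 2) sds[b] <- stats::sd(vals)
    }
    if (it == bg_iterations) break
    excluded <- frame > means[binm] + bg_clip * sds[binm]
  }
  cand <- frame > means[binm] + min_snr * sds[binm]
  lab <- oracle_label_components(cand, 8L)
  spots <- NULL
  for (k in seq_len(max(lab))) {
    px <- which(lab == k, arr.ind = TRUE)
    if (nrow(px) < min_pix || nrow(px) > max_pix) next
    w <- pmax(frame[px] - means[binm[px]], 0)
    crow <- sum(px[, 1] * w) / sum(w)
    ccol <- sum(px[, 2] * w) / sum(w)
    r_mm <- r_of(crow, ccol) * geometry$pixel_size
    spots <- rbind(spots, data.frame(
      row = crow, col = ccol, intensity = sum(w), n_pix = nrow(px),
      d = radius_to_d(r_mm, geometry)))
  }
  if (is.null(spots)) return(spots)
  spots[order(spots$row, spots$col), , drop = FALSE]
}

# Beam/crystal overlap fraction by 0.1 um rasterization of the footprint,
# with the crystal shadow obtained from projected corner extremes rather
# than the implementation's support-function formula.
oracle_overlap_fraction <- function(crystal, grid_center, omega, beam) {
  w <- omega * pi / 180
  g_lab_y <- grid_center[1] * sin(w) + grid_center[2] * cos(w)
  g_lab_z <- grid_center[3]
  corners <- expand.grid(x = c(-1, 1) * crystal$half_extents[3],
                         y = c(-1, 1) * crystal$half_extents[2])
  lab_y <- (crystal$center[1] + corners$x) * sin(w) +
    (crystal$center[2] + corners$y) * cos(w)
  sy <- range(lab_y)
  sz <- crystal$center[3] + c(-1, 1) * crystal$half_extents[1]
  ys <- seq(g_lab_y - beam[2] / 2 + 0.01, g_lab_y + beam[2] / 2 - 0.01,
            by = 0.02)
  zs <- seq(g_lab_z - beam[1] / 2 + 0.01, g_lab_z + beam[1] / 2 - 0.01,
            by = 0.02)
  hit_y <- ys >= sy[1] & ys <= sy[2]
  hit_z <- zs >= sz[1] & zs <= sz[2]
  mean(hit_y) * mean(hit_z)
}

# Fully independent 3D ray-march overlap oracle: for each footprint ray,
# march along the beam and test point-in-box in the sample frame.
oracle_overlap_raymarch <- function(crystal, grid_center, omega, beam,
                                    ray_step = 0.25, t_step = 0.5) {
  w <- omega * pi / 180
  g_lab_y <- grid_center[1] * sin(w) + grid_center[2] * cos(w)
  g_lab_z <- grid_center[3]
  ys <- seq(g_lab_y - beam[2] / 2 + ray_step / 2,
            g_lab_y + beam[2] / 2 - ray_step / 2, by = ray_step)
  zs <- seq(g_lab_z - beam[1] / 2 + ray_step / 2,
            g_lab_z + beam[1] / 2 - ray_step / 2, by = ray_step)
  reach <- sum(abs(crystal$center[1:2])) + sum(crystal$half_extents) + 5
  ts <- seq(-reach, reach, by = t_step)
  hits <- 0L
  for (y in ys) {
    # vectorize over t for the whole z row at once
    xs <- outer(ts, rep(1, length(zs)))
    x_s <- cos(w) * xs + sin(w) * y
    y_s <- -sin(w) * xs + cos(w) * y
    inbox_xy <- abs(x_s - crystal$center[1]) <= crystal$half_extents[3] &
      abs(y_s - crystal$center[2]) <= crystal$half_extents[2]
    ray_hits_xy <- apply(inbox_xy, 2, any)
    inz <- abs(zs - crystal$center[3]) <= crystal$half_extents[1]
    hits <- hits + sum(ray_hits_xy & inz)
  }
  hits / (length(ys) * length(zs))
}

# Helical dose accumulation oracle: per-frame top-hat deposition onto a
# fine 1D grid (frame-by-frame accumulation, unlike the implementation's
# per-position center counting).
oracle_helical_profile <- function(length_um, beam_width, d_frame, n_frames,
                                   ds = 0.1) {
  s <- seq(-beam_width / 2, length_um + beam_width / 2, by = ds)
  dose <- numeric(length(s))
  for (i in seq_len(n_frames)) {
    ctr <- (i - 0.5) * length_um / n_frames
    dose[s >= ctr - beam_width / 2 & s <= ctr + beam_width / 2] <-
      dose[s >= ctr - beam_width / 2 & s <= ctr + beam_width / 2] + d_frame
  }
  list(s = s, dose = dose, peak = max(dose))
}

# Greedy minimum-distance selection by explicit exhaustive search.
oracle_select <- function(coords, scores, min_score, max_score,
                          min_distance) {
  ok <- which(scores >= min_score & scores <= max_score)
  ok <- ok[order(-scores[ok], coords$i[ok], coords$j[ok])]
  chosen <- integer(0)
  for (k in ok) {
    if (length(chosen) == 0L ||
        all(sqrt((coords$y[chosen] - coords$y[k])^2 +
                   (coords$z[chosen] - coords$z[k])^2) >= min_distance)) {
      chosen <- c(chosen, k)
    }
  }
  chosen
}
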