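# Internal helpers shared across modules.

deg2rad <- function(x) x * pi / 180

#' @keywords internal
mod360 <- function(x) x %% 360

#' Reduce an angle to [0, 180) degrees.
#' @keywords internal
mod180 <- function(x) x %% 180

# Evaluate `code` under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Rotate sample-frame coordinates into the lab frame (rotation about the
# horizontal goniometer axis Z by omega degrees). `p` is a length-3 vector
# or an n x 3 matrix with columns (x, y, z).
sample_to_lab <- function(p, omega) {
  p <- rbind_coords(p)
  w <- deg2rad(omega)
  cbind(
    p[, 1] * cos(w) - p[, 2] * sin(w),
    p[, 1] * sin(w) + p[, 2] * cos(w),
    p[, 3]
  )
}

lab_to_sample <- function(p, omega) sample_to_lab(p, -omega)

# Convert planner-frame grid points (lab-frame (y, z) in the zero-depth
# plane at angle omega, x column ignored) to sample-frame coordinates.
plane_to_sample <- function(p, omega) {
  p <- rbind_coords(p)
  out <- lab_to_sample(cbind(0, p[, 2], 0), omega)
  out[, 3] <- p[, 3]
  out
}

rbind_coords <- function(p) {
  if (is.null(dim(p))) {
    stopifnot(length(p) == 3L)
    matrix(p, nrow = 1L)
  } else {
    stopifnot(ncol(p) == 3L)
    as.matrix(p)
  }
}

# Length of the intersection of intervals [a1, a2] and [b1, b2].
overlap_len <- function(a1, a2, b1, b2) {
  pmax(0, pmin(a2, b2) - pmax(a1, b1))
}

# 8- or 4-connected component labeling of a logical matrix by queue-based
# flood fill. Returns an integer matrix; 0 marks background. Components are
# numbered in the order their first (row-major) member is encountered.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  }
  nlab <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (mask[i, j] && lab[i, j] == 0L) {
        nlab <- nlab + 1L
        queue <- matrix(c(i, j), ncol = 2L)
        lab[i, j] <- nlab
        while (nrow(queue) > 0L) {
          cur <- queue[nrow(queue), ]
          queue <- queue[-nrow(queue), , drop = FALSE]
          ni <- cur[1L] + dr
          nj <- cur[2L] + dc
          ok <- ni >= 1L & ni <= nr & nj >= 1L & nj <= nc
          ni <- ni[ok]; nj <- nj[ok]
          idx <- cbind(ni, nj)
          hit <- mask[idx] & lab[idx] == 0L
          if (any(hit)) {
            idx <- idx[hit, , drop = FALSE]
            lab[idx] <- nlab
            queue <- rbind(queue, idx)
          }
        }
      }
    }
  }
  lab
}
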