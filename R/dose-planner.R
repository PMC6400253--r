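#' Absorbed-dose estimation and exposure-condition suggestion
#'
#' Estimates the absorbed dose (MGy) delivered to a crystal under
#' stationary, helical and serial-rotation (SS-ROX) illumination using a
#' transparent thin-crystal absorption model, spreads it with a Gaussian
#' radiation-damage propagation kernel, and inverts the estimate to
#' propose the exposure time (or transmission) that exactly meets a user
#' dose budget (default 10 MGy).
#'
#' The thin-crystal model is dose = fluence x photon energy x (mu_en/rho):
#' fluence in photons/m^2 is flux x transmission x time over the beam
#' footprint area, the photon energy converts to joules, and the mass
#' energy-absorption coefficient (m^2/kg) converts deposited energy to
#' gray. Photoelectron escape and elemental composition are deliberately
#' not modelled.
#'
#' @name dose_planner
NULL

#' X-ray beam parameters
#'
#' @param size Beam size c(horizontal, vertical), um (top-hat footprint).
#' @param flux Photons per second of the unattenuated beam (transmission
#'   1); the `transmission` field scales it at dose time.
#' @param energy_kev Photon energy, keV.
#' @param transmission Attenuator transmission in (0, 1].
#' @return An object of class `beam_params`.
#' @export
beam_params <- function(size = c(10, 15), flux = 1.5e12, energy_kev = 12.4,
                        transmission = 1) {
  if (any(size <= 0)) stop("beam sizes must be positive")
  if (flux < 0) stop("flux must be >= 0")
  if (transmission <= 0 || transmission > 1) {
    stop("transmission must be in (0, 1]")
  }
  structure(
    list(size = as.numeric(size), flux = flux, energy_kev = energy_kev,
         transmission = transmission),
    class = "beam_params"
  )
}

#' Dose-model parameters
#'
#' @param mu_en_rho Mass energy-absorption coefficient, m^2/kg. The
#'   default 0.24 is a water-like value at 12.4 keV, a reasonable stand-in
#'   for a typical protein crystal.
#' @param density Crystal density, kg/m^3 (typical protein crystal ~1200).
#' @param propagation_length Gaussian sigma (um) with which deposited dose
#'   spreads through the crystal (radiation-damage propagation).
#' @return An object of class `dose_model_params`.
#' @export
dose_model_params <- function(mu_en_rho = 0.24, density = 1200,
                              propagation_length = 0) {
  if (mu_en_rho <= 0 || density <= 0) stop("model parameters must be positive")
  if (propagation_length < 0) stop("propagation length must be >= 0")
  structure(
    list(mu_en_rho = mu_en_rho, density = density,
         propagation_length = propagation_length),
    class = "dose_model_params"
  )
}

KEV_TO_J <- 1.602176634e-16

#' Stationary absorbed dose
#'
#' Linear in flux, transmission and exposure time.
#'
#' @param beam A [beam_params()].
#' @param exposure_total Total exposure time, s.
#' @param model A [dose_model_params()].
#' @return Dose in MGy.
#' @export
stationary_dose <- function(beam, exposure_total, model = dose_model_params()) {
  if (exposure_total < 0) stop("exposure time must be >= 0")
  area_m2 <- beam$size[1] * beam$size[2] * 1e-12
  if (area_m2 <= 0) stop("beam area must be positive")
  fluence <- beam$flux * beam$transmission * exposure_total / area_m2
  fluence * beam$energy_kev * KEV_TO_J * model$mu_en_rho / 1e6
}

#' Dose profile of a helical (translating-beam) collection
#'
#' The beam center translates uniformly from the vector start to end over
#' `n_frames` frames (frame i centered at start + (i - 1/2)/n of the
#' length). The dose at a point on the vector is the sum of the per-frame
#' stationary doses of every frame whose top-hat footprint covers it; the
#' interior plateau is the per-frame dose times roughly the number of
#' frame centers within one beam width. The profile is sampled at `ds` um.
#'
#' @param vector A list with `start` and `end` sample-frame coordinates
#'   (um); see [helical_vector()].
#' @param beam A [beam_params()].
#' @param frame_time Exposure time per frame, s.
#' @param n_frames Number of frames (>= 1).
#' @param model A [dose_model_params()].
#' @param ds Profile sampling interval, um.
#' @return A `dose_profile`: list with `s` (positions along the vector,
#'   um), `dose` (MGy), `peak` (MGy), `per_frame_dose` and
#'   `beam_width_travel` (um).
#' @export
helical_dose_profile <- function(vector, beam, frame_time, n_frames,
                                 model = dose_model_params(), ds = 0.1) {
  stopifnot(n_frames >= 1)
  dvec <- vector$end - vector$start
  len <- sqrt(sum(dvec^2))
  if (len <= 0) stop("helical vector has zero length")
  dirn <- dvec / len
  # width of the (h x v) lab footprint along the travel direction:
  # h spans the rotation axis (z), v the lab vertical (y)
  w <- beam$size[1] * abs(dirn[3]) + beam$size[2] * abs(dirn[2])
  if (w <= 0) w <- beam$size[1] # travel purely along the beam: h footprint
  d_frame <- stationary_dose(beam, frame_time, model)
  centers <- (seq_len(n_frames) - 0.5) * len / n_frames
  s <- seq(-w / 2, len + w / 2, by = ds)
  # half-open footprint so abutting frames tile without double counting
  dose <- vapply(s, function(p) {
    sum(p - centers >= -w / 2 & p - centers < w / 2)
  }, numeric(1)) * d_frame
  structure(
    list(s = s, dose = dose, peak = max(dose), per_frame_dose = d_frame,
         beam_width_travel = w, n_frames = n_frames),
    class = "dose_profile"
  )
}

#' Helical vector between two crystal edges
#'
#' @param start,end Sample-frame coordinates of the two edges, um.
#' @param start_omega,end_omega Scan angles the edges were located at.
#' @return A `helical_vector`.
#' @export
helical_vector <- function(start, end, start_omega = NA_real_,
                           end_omega = NA_real_) {
  if (sqrt(sum((end - start)^2)) <= 0) {
    stop("helical vector endpoints must differ")
  }
  structure(
    list(start = as.numeric(start), end = as.numeric(end),
         start_omega = start_omega, end_omega = end_omega),
    class = "helical_vector"
  )
}

#' Spread a dose profile with the damage-propagation kernel
#'
#' Convolves the profile with a Gaussian of sigma equal to the model's
#' propagation length; the support is extended so the integrated dose is
#' conserved. A zero propagation length returns the profile unchanged.
#'
#' @param profile A `dose_profile`.
#' @param model A [dose_model_params()].
#' @return A `dose_profile` on an extended support.
#' @export
spread_damage <- function(profile, model) {
  sigma <- model$propagation_length
  if (sigma <= 0) return(profile)
  ds <- profile$s[2] - profile$s[1]
  half <- ceiling(5 * sigma / ds)
  kern <- stats::dnorm(seq(-half, half) * ds, sd = sigma)
  kern <- kern / sum(kern) # discrete normalization conserves the integral
  padded <- c(numeric(half), profile$dose, numeric(half))
  sm <- stats::convolve(padded, rev(kern), type = "open")
  # "open" convolution of length n + 2*half with the kernel: trim to the
  # padded support
  sm <- sm[(half + 1):(length(sm) - half)]
  s_ext <- seq(profile$s[1] - half * ds, by = ds, length.out = length(sm))
  structure(
    list(s = s_ext, dose = sm, peak = max(sm),
         per_frame_dose = profile$per_frame_dose,
         beam_width_travel = profile$beam_width_travel,
         n_frames = profile$n_frames),
    class = "dose_profile"
  )
}

#' Suggest exposure conditions meeting a dose budget
#'
#' Returns the maximal exposure time per frame (at the given transmission),
#' or the maximal transmission (at the given time), such that the scheme's
#' peak dose equals the budget; re-estimating the dose at the returned
#' plan reproduces the budget to numerical precision. Doses are linear in
#' both knobs, so the inversion is exact.
#'
#' @param scheme `"stationary"`, `"helical"` or `"ssrox"`.
#' @param beam A [beam_params()].
#' @param budget Dose budget, MGy (> 0); default 10.
#' @param n_frames Frames per wedge / scan line.
#' @param vector For helical: a [helical_vector()]. For ssrox: the scan
#'   line is built from `line_length`.
#' @param line_length For ssrox: horizontal scan-line length, um.
#' @param model A [dose_model_params()].
#' @param optimize `"time"` or `"transmission"`.
#' @param frame_time Fixed frame time (s) when optimizing transmission.
#' @param min_frame_time Hardware floor on the frame time, s; a budget so
#'   small that even this floor exceeds it is an error naming the
#'   constraint.
#' @return An `exposure_plan`: `scheme`, `frame_time`, `transmission`,
#'   `n_frames`, `est_peak_dose` (MGy), `budget`.
#' @export
suggest_exposure <- function(scheme = c("stationary", "helical", "ssrox"),
                             beam, budget = 10, n_frames = 1L,
                             vector = NULL, line_length = NULL,
                             model = dose_model_params(),
                             optimize = c("time", "transmission"),
                             frame_time = 0.05, min_frame_time = 1e-4) {
  scheme <- match.arg(scheme)
  optimize <- match.arg(optimize)
  if (budget <= 0) stop("dose budget must be positive")
  if (scheme == "ssrox") {
    if (is.null(line_length)) stop("ssrox planning needs line_length")
    vector <- helical_vector(c(0, 0, 0), c(0, 0, line_length))
  }
  peak_at <- function(t_frame, trans) {
    b <- beam
    b$transmission <- trans
    if (scheme == "stationary") {
      stationary_dose(b, t_frame * n_frames, model)
    } else {
      helical_dose_profile(vector, b, t_frame, n_frames, model)$peak
    }
  }
  if (optimize == "time") {
    ref <- peak_at(1, beam$transmission)
    if (ref <= 0) stop("beam delivers no dose; cannot meet a budget")
    t_frame <- budget / ref
    if (t_frame < min_frame_time) {
      stop(sprintf(
        "budget %g MGy unreachable: minimum frame time %g s already delivers %g MGy",
        budget, min_frame_time, peak_at(min_frame_time, beam$transmission)))
    }
    trans <- beam$transmission
  } else {
    ref <- peak_at(frame_time, 1)
    if (ref <= 0) stop("beam delivers no dose; cannot meet a budget")
    trans <- min(1, budget / ref)
    t_frame <- frame_time
  }
  structure(
    list(scheme = scheme, frame_time = t_frame, transmission = trans,
         n_frames = as.integer(n_frames),
         est_peak_dose = peak_at(t_frame, trans), budget = budget),
    class = "exposure_plan"
  )
}

#' @export
print.exposure_plan <- function(x, ...) {
  cat(sprintf(
    "<exposure_plan %s: %.4g s/frame x %d frames, transmission %.3g, peak %.4g / budget %g MGy>\n",
    x$scheme, x$frame_time, x$n_frames, x$transmission, x$est_peak_dose,
    x$budget))
  invisible(x)
}
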