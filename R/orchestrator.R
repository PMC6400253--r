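#' Experiment orchestration: plan files, sequencing, reports
#'
#' Reads per-sample parameter rows, drives the virtual beamline through the
#' mount - center - raster - find - plan - collect sequence for each
#' data-collection mode, enforces the spot-score window, the per-loop
#' collection cap and the dose budget, and emits a machine-readable
#' collection report.
#'
#' @name orchestrator
NULL

#' Per-sample experiment parameters
#'
#' Defaults follow typical multiple-small-wedge conditions: 5 degrees total
#' oscillation in 0.1 degree frames, a 10 x 15 um beam, 10 MGy dose budget
#' per wedge, 200 mm camera distance, 600 um utilized loop size, a 15-100
#' spot-score window and at most 100 collections per loop.
#'
#' @param mode One of `"single"`, `"multi"` (small wedge), `"helical"`,
#'   `"ssrox"`, `"mixed"`.
#' @param puck_id Puck identifier.
#' @param pins Pin numbers to process.
#' @param total_osc Total oscillation per wedge, degrees.
#' @param osc_width Oscillation width per frame, degrees; must divide
#'   `total_osc` to within 1e-6.
#' @param raster_exposure Exposure time per raster frame, s.
#' @param beam Beam size c(horizontal, vertical), um.
#' @param dose_budget Dose budget per wedge, MGy.
#' @param collection_exposure Exposure time per collection frame, s.
#' @param camera_distance Detector distance, mm.
#' @param loop_size Utilized loop size, um.
#' @param spot_min,spot_max Spot-score window for good crystals.
#' @param data_dir,data_name Output naming.
#' @param max_collections Maximum number of data collections per loop.
#' @param mixed A [mixed_params()] for mixed mode.
#' @return An object of class `zoo_params`.
#' @export
zoo_params <- function(mode = "multi", puck_id = "CPS1974", pins = 1:16,
                       total_osc = 5.0, osc_width = 0.1,
                       raster_exposure = 0.02, beam = c(10, 15),
                       dose_budget = 10, collection_exposure = 0.05,
                       camera_distance = 200, loop_size = 600,
                       spot_min = 15, spot_max = 100, data_dir = ".",
                       data_name = "multi", max_collections = 100,
                       mixed = mixed_params()) {
  modes <- c("single", "multi", "helical", "ssrox", "mixed")
  if (!mode %in% modes) {
    stop(sprintf("unknown mode '%s' (expected one of %s)", mode,
                 paste(modes, collapse = ", ")))
  }
  if (osc_width <= 0) stop("oscillation width must be positive")
  nfr <- total_osc / osc_width
  if (abs(nfr - round(nfr)) > 1e-6) {
    stop("oscillation width must divide the total oscillation")
  }
  if (max_collections < 1) stop("max_collections must be >= 1")
  structure(
    list(mode = mode, puck_id = puck_id, pins = pins, total_osc = total_osc,
         osc_width = osc_width, raster_exposure = raster_exposure,
         beam = as.numeric(beam), dose_budget = dose_budget,
         collection_exposure = collection_exposure,
         camera_distance = camera_distance, loop_size = loop_size,
         spot_min = spot_min, spot_max = spot_max, data_dir = data_dir,
         data_name = data_name, max_collections = as.integer(max_collections),
         mixed = mixed),
    class = "zoo_params"
  )
}

# Documented mapping from plan-file CSV headers to zoo_params fields.
plan_header_map <- c(
  "mode" = "mode",
  "puck id" = "puck_id",
  "pin id" = "pins",
  "total oscillation per wedge" = "total_osc",
  "oscillation width" = "osc_width",
  "exposure time for raster scan" = "raster_exposure",
  "beam size" = "beam",
  "dose per wedge" = "dose_budget",
  "exposure time for data collection" = "collection_exposure",
  "camera distance" = "camera_distance",
  "loop size" = "loop_size",
  "no. of spots for good crystals" = "spot_window",
  "data directory" = "data_dir",
  "data name" = "data_name",
  "maximum no. of data collections per loop" = "max_collections"
)

parse_mode <- function(x) {
  key <- gsub("[^a-z]", "", tolower(x))
  switch(key,
    "single" = "single",
    "multi" = "multi", "smallwedge" = "multi", "multismallwedge" = "multi",
    "helical" = "helical",
    "ssrox" = "ssrox",
    "mixed" = "mixed",
    stop(sprintf("unknown mode '%s'", x))
  )
}

parse_range <- function(x) {
  nums <- as.numeric(regmatches(x, gregexpr("[0-9.]+", x))[[1]])
  if (length(nums) == 1L) nums <- c(nums, nums)
  nums[1:2]
}

#' Load a plan file (CSV with Table-style headers, or JSON)
#'
#' CSV columns are matched case-insensitively against the documented
#' header names (e.g. "Total oscillation per wedge (deg)"); any omitted
#' field falls back to the [zoo_params()] default. JSON plans are arrays
#' of objects using the `zoo_params` field names directly. Validation
#' failures name the offending row and field.
#'
#' @param path Plan file path (.csv or .json).
#' @return List of [zoo_params()] objects, one per row.
#' @export
load_plan <- function(path) {
  if (!file.exists(path)) stop("plan file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  rows <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    tab <- utils::read.csv(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    if (nrow(tab) == 0L) stop("plan file is empty")
    lapply(seq_len(nrow(tab)), function(r) {
      row <- as.list(tab[r, , drop = FALSE])
      out <- list()
      for (nm in names(row)) {
        key <- sub(" *\\(.*\\)$", "", trimws(tolower(nm)))
        fld <- plan_header_map[key]
        if (is.na(fld)) next
        val <- row[[nm]]
        out[[fld]] <- val
      }
      out
    })
  }
  lapply(seq_along(rows), function(r) {
    raw <- rows[[r]]
    args <- list()
    for (nm in names(raw)) {
      val <- raw[[nm]]
      args[[nm]] <- switch(nm,
        mode = parse_mode(val),
        pins = if (is.character(val)) {
          rg <- parse_range(val); seq(rg[1], rg[2])
        } else unlist(val),
        beam = if (is.character(val)) parse_range(val) else unlist(val),
        spot_window = NULL,
        total_osc = , osc_width = , raster_exposure = , dose_budget = ,
        collection_exposure = , camera_distance = , loop_size = ,
        max_collections = {
          v <- suppressWarnings(as.numeric(val))
          if (is.na(v)) {
            stop(sprintf("plan row %d: field '%s' is not numeric ('%s')",
                         r, nm, val))
          }
          v
        },
        val
      )
    }
    if (!is.null(raw$spot_window)) {
      win <- if (is.character(raw$spot_window)) parse_range(raw$spot_window)
             else unlist(raw$spot_window)
      args$spot_min <- win[1]
      args$spot_max <- win[2]
    }
    tryCatch(do.call(zoo_params, args), error = function(e) {
      stop(sprintf("plan row %d: %s", r, conditionMessage(e)), call. = FALSE)
    })
  })
}

#' Raster-scan grid with timing arithmetic
#'
#' The grid step equals the beam size; the per-line goniometer speed is
#' step times the detector frame rate, and the synchronization-jitter
#' positional error bound is the 2 ms trigger jitter times that speed
#' (1 um at the typical 10 um / 50 Hz conditions).
#'
#' @param area A `raster_area`.
#' @param frame_rate Detector frame rate, Hz.
#' @param jitter_s Trigger timing jitter, s.
#' @return A `raster_grid`: the area plus `frame_rate`, `scan_speed`
#'   (um/s), `serpentine`, `n_frames`, `jitter_bound_um`.
#' @export
build_raster_grid <- function(area, frame_rate = 50, jitter_s = 0.002) {
  if (frame_rate <= 0) stop("frame rate must be positive")
  speed <- area$step_h * frame_rate
  structure(
    list(area = area, frame_rate = frame_rate, scan_speed = speed,
         serpentine = TRUE, n_frames = area$n_h * area$n_v,
         jitter_bound_um = jitter_s * speed),
    class = "raster_grid"
  )
}

record_row <- function(sample_id, crystal_id, scheme, status = "ok",
                       osc_start = NA_real_, osc_end = NA_real_,
                       n_frames = NA_integer_, frame_time = NA_real_,
                       transmission = NA_real_, dose_MGy = NA_real_,
                       budget_MGy = NA_real_, position = NULL,
                       vector_start = NULL, vector_end = NULL, grid = NULL) {
  out <- list(sample_id = sample_id, crystal_id = crystal_id,
              scheme = scheme, status = status, osc_start = osc_start,
              osc_end = osc_end, n_frames = n_frames,
              frame_time = frame_time, transmission = transmission,
              dose_MGy = dose_MGy, budget_MGy = budget_MGy)
  if (!is.null(position)) out$position <- as.numeric(position)
  if (!is.null(vector_start)) out$vector_start <- as.numeric(vector_start)
  if (!is.null(vector_end)) out$vector_end <- as.numeric(vector_end)
  if (!is.null(grid)) out$grid <- as.numeric(grid)
  # drop unset scalars so reports round-trip exactly through JSON
  out[!vapply(out, function(v) length(v) == 1L && is.na(v), logical(1))]
}

# Locate both crystal edges in 3D by vertical scans at the helical scan
# angles; returns a helical_vector or NULL when a scan sees nothing.
locate_vector <- function(sample, region, heatmap, face, total_osc, beam,
                          offset, seed) {
  edges <- region_edges(region, heatmap)
  ang <- helical_scan_angles(total_osc, face)
  ends <- list()
  for (side in c("left", "right")) {
    e <- edges[[side]]
    # edge height: score-weighted centroid of the member rows in the edge
    # column (partial boundary grids score low and pull proportionally)
    rows <- region$members[region$members[, 2] == e[2], 1]
    wts <- heatmap$scores[cbind(rows, e[2])]
    ey <- heatmap$origin[2] - (sum(rows * wts) / sum(wts) - 1) *
      heatmap$step_v
    ez <- heatmap$origin[3] + (e[2] - 1) * heatmap$step_h
    om2 <- if (side == "left") ang[["start"]] else ang[["end"]]
    # predicted edge height at the scan angle, assuming the crystal sits in
    # the raster plane (zero beam depth at the face angle)
    p0 <- lab_to_sample(c(0, ey, 0), face)[1, ] + c(0, 0, ez)
    y2c <- sample_to_lab(p0, om2)[1, 2]
    scan_y <- y2c + seq(-3, 3) * heatmap$step_v
    pts <- vertical_scan_points(ez, scan_y, om2)
    sc <- raster_response(sample, pts, om2, beam,
                          seed = combine_seed(seed, round(om2 * 10)),
                          offset = offset)
    pos <- tryCatch(
      locate_edge_3d(c(ey, ez), face, om2, scan_y, as.numeric(sc)),
      error = function(e) NULL
    )
    if (is.null(pos)) return(NULL)
    ends[[side]] <- pos
  }
  if (sqrt(sum((ends$right - ends$left)^2)) <= 0) return(NULL)
  helical_vector(ends$left, ends$right, ang[["start"]], ang[["end"]])
}

#' Run the full automated sequence for one sample
#'
#' Common preparation (loop search, tip centering, face-angle
#' determination, raster scan, spot scoring) followed by the
#' scheme-specific planning of the requested mode. A sample whose loop is
#' not found yields a single `"no_loop"` record and processing continues.
#'
#' @param params A [zoo_params()].
#' @param sample A [virtual_sample()] or `NULL` (empty pin).
#' @param sample_id Identifier used in records.
#' @param seed Integer seed controlling all simulated noise.
#' @param camera A [zoo_camera()].
#' @param beam_phys A [beam_params()] describing flux and energy for dose
#'   budgeting; its size is taken from `params$beam`.
#' @param init_offset Sample-frame goniometer offset carried over from the
#'   previous pin of the same puck.
#' @return List with `records` (list of collection records), `log`
#'   (character, ISO timestamps), `loop_offset` (to carry to the next
#'   pin), plus `heatmap` and `face_angle` when preparation succeeded.
#' @export
run_sample <- function(params, sample, sample_id = "pin1", seed = 1L,
                       camera = zoo_camera(), beam_phys = NULL,
                       init_offset = c(0, 0, 0)) {
  log <- character()
  note <- function(fmt, ...) {
    log[[length(log) + 1L]] <<- sprintf("%s %s",
      format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), sprintf(fmt, ...))
  }
  if (is.null(beam_phys)) {
    beam_phys <- beam_params(size = params$beam,
                             flux = 1e10 * params$beam[1] * params$beam[2])
  } else {
    beam_phys$size <- params$beam
  }
  empty_sample <- is.null(sample) ||
    (is.null(sample$loop) && length(sample$crystals) == 0L)
  if (empty_sample) {
    note("sample %s: empty pin", sample_id)
    return(list(records = list(record_row(sample_id, NA_integer_,
                                          params$mode, status = "no_loop")),
                log = log, loop_offset = init_offset))
  }
  gonio <- virtual_gonio(sample, camera)
  gonio$.offset <- init_offset
  cl <- center_loop(gonio, beam = params$beam,
                    user_loop_size = params$loop_size)
  if (!cl$found) {
    note("sample %s: loop not found after search", sample_id)
    return(list(records = list(record_row(sample_id, NA_integer_,
                                          params$mode, status = "no_loop")),
                log = log, loop_offset = gonio$offset()))
  }
  face <- cl$face_angle
  grid <- build_raster_grid(cl$area)
  note("sample %s: centered, face angle %.1f deg, raster %d x %d at %g um/s (jitter bound %.2g um)",
       sample_id, face, cl$area$n_h, cl$area$n_v, grid$scan_speed,
       grid$jitter_bound_um)
  # grid centers are planner-frame (lab at the face angle); convert to the
  # sample frame for the measurement
  centers <- plane_to_sample(raster_grid_centers(cl$area), face)
  # acquire in serpentine order, as the goniometer would
  ord <- serpentine_order(cl$area$n_v, cl$area$n_h)
  counts <- raster_response(sample, centers[ord, , drop = FALSE], face,
                            params$beam, seed = combine_seed(seed, 11L),
                            offset = gonio$offset())
  heatmap <- assemble_heatmap(as.numeric(counts), cl$area, serpentine = TRUE,
                              provenance = list(spot_min = params$spot_min,
                                                spot_max = params$spot_max))
  offset <- gonio$offset()
  n_frames <- as.integer(round(params$total_osc / params$osc_width))
  records <- list()
  add <- function(rec) records[[length(records) + 1L]] <<- rec

  plan_stationary <- function(crystal_id, scheme, pos, grid_ij) {
    plan <- suggest_exposure("stationary", beam_phys,
                             budget = params$dose_budget,
                             n_frames = n_frames)
    add(record_row(sample_id, crystal_id, scheme,
                   osc_start = face - params$total_osc / 2,
                   osc_end = face + params$total_osc / 2,
                   n_frames = n_frames, frame_time = plan$frame_time,
                   transmission = plan$transmission,
                   dose_MGy = plan$est_peak_dose,
                   budget_MGy = params$dose_budget, position = pos,
                   grid = grid_ij))
  }
  plan_helical <- function(crystal_id, scheme, region, wedge) {
    vec <- locate_vector(sample, region, heatmap, face, wedge, params$beam,
                         offset, seed)
    if (is.null(vec)) {
      add(record_row(sample_id, crystal_id, scheme,
                     status = "edge_not_found"))
      return(invisible())
    }
    nf <- as.integer(round(wedge / params$osc_width))
    plan <- suggest_exposure("helical", beam_phys,
                             budget = params$dose_budget, n_frames = nf,
                             vector = vec)
    add(record_row(sample_id, crystal_id, scheme,
                   osc_start = vec$start_omega, osc_end = vec$end_omega,
                   n_frames = nf, frame_time = plan$frame_time,
                   transmission = plan$transmission,
                   dose_MGy = plan$est_peak_dose,
                   budget_MGy = params$dose_budget,
                   vector_start = vec$start, vector_end = vec$end))
  }
  cap_left <- function() params$max_collections - length(records)

  if (params$mode == "single" || params$mode == "multi") {
    sel <- select_crystal_grids(heatmap, params$spot_min, params$spot_max,
                                min_distance = max(params$beam))
    if (params$mode == "single") sel <- utils::head(sel, 1L)
    sel <- utils::head(sel, params$max_collections)
    for (k in seq_len(nrow(sel))) {
      plan_stationary(k, if (params$mode == "single") "single" else
        "small_wedge", c(sel$x[k], sel$y[k], sel$z[k]),
        c(sel$i[k], sel$j[k]))
    }
    note("sample %s: %d wedge(s) planned", sample_id, nrow(sel))
  } else if (params$mode == "helical") {
    regions <- segment_crystals(heatmap, params$spot_min)
    for (k in seq_along(regions)) {
      if (cap_left() <= 0L) break
      plan_helical(k, "helical", regions[[k]], params$total_osc)
    }
    note("sample %s: %d helical crystal(s)", sample_id, length(records))
  } else if (params$mode == "ssrox") {
    pl <- plan_ssrox(cl$area$n_h * cl$area$step_h,
                     cl$area$n_v * cl$area$step_v,
                     scan_step = params$beam[1],
                     osc_per_frame = params$osc_width,
                     v_line_spacing = params$beam[2])
    plan <- suggest_exposure("ssrox", beam_phys,
                             budget = params$dose_budget,
                             n_frames = pl$frames_per_line,
                             line_length = cl$area$n_h * cl$area$step_h)
    add(record_row(sample_id, 1L, "ssrox",
                   osc_start = face, osc_end = face + pl$osc_per_line,
                   n_frames = pl$frames_per_line * pl$n_lines,
                   frame_time = plan$frame_time,
                   transmission = plan$transmission,
                   dose_MGy = plan$est_peak_dose,
                   budget_MGy = params$dose_budget))
    note("sample %s: SS-ROX %d lines x %d frames, %.1f deg per line",
         sample_id, pl$n_lines, pl$frames_per_line, pl$osc_per_line)
  } else if (params$mode == "mixed") {
    regions <- segment_crystals(heatmap, params$spot_min)
    assigns <- categorize(regions, params$mixed)
    for (k in seq_along(assigns)) {
      if (cap_left() <= 0L) break
      a <- assigns[[k]]
      if (a$category %in% c("HELICAL_FULL", "PARTIAL_HELICAL")) {
        plan_helical(k, tolower(a$category), a$region, a$wedge_total_osc)
      } else if (a$category == "SMALL_WEDGE") {
        pk <- a$region$peak
        pos <- c(heatmap$origin[1],
                 heatmap$origin[2] - (pk[1] - 1) * heatmap$step_v,
                 heatmap$origin[3] + (pk[2] - 1) * heatmap$step_h)
        plan_stationary(k, "small_wedge", pos, pk)
      } else {
        grids <- a$collection
        for (g in seq_len(nrow(grids))) {
          if (cap_left() <= 0L) break
          pos <- c(heatmap$origin[1],
                   heatmap$origin[2] - (grids[g, 1] - 1) * heatmap$step_v,
                   heatmap$origin[3] + (grids[g, 2] - 1) * heatmap$step_h)
          plan_stationary(k, "clustered_small_wedge", pos, grids[g, ])
        }
      }
    }
    note("sample %s: mixed-scheme plan for %d crystal(s)", sample_id,
         length(assigns))
  }
  list(records = records, log = log, loop_offset = gonio$offset(),
       heatmap = heatmap, face_angle = face, area = cl$area,
       assignments = if (params$mode == "mixed") assigns else NULL)
}

serpentine_order <- function(n_v, n_h) {
  unlist(lapply(seq_len(n_v), function(i) {
    idx <- ((i - 1) * n_h + 1):(i * n_h)
    if (i %% 2 == 0) rev(idx) else idx
  }))
}

#' Run a multi-sample plan against a list of virtual samples
#'
#' Iterates pins in plan order; the loop position found on a pin is saved
#' and used as the starting position for the next pin of the same puck.
#'
#' @param plan List of [zoo_params()] (one per sample/pin).
#' @param samples List of [virtual_sample()] or `NULL` entries, parallel
#'   to `plan`.
#' @param seed Integer master seed.
#' @return List with `records` (flat list across samples) and `log`.
#' @export
run_plan <- function(plan, samples, seed = 1L) {
  stopifnot(length(plan) == length(samples))
  records <- list()
  log <- character()
  offset <- c(0, 0, 0)
  last_puck <- NULL
  for (k in seq_along(plan)) {
    p <- plan[[k]]
    if (!identical(p$puck_id, last_puck)) offset <- c(0, 0, 0)
    res <- run_sample(p, samples[[k]], sample_id = sprintf("pin%d", k),
                      seed = combine_seed(seed, k), init_offset = offset)
    records <- c(records, res$records)
    log <- c(log, res$log)
    offset <- res$loop_offset
    last_puck <- p$puck_id
  }
  list(records = records, log = log)
}

#' Write / read a collection report as JSON
#'
#' @param records List of collection records (see [run_sample()]).
#' @param path Output / input path.
#' @return `write_report` returns the path invisibly; `read_report` the
#'   records list.
#' @export
write_report <- function(records, path) {
  jsonlite::write_json(list(records = records), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  out$records
}
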