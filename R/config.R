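#' Study configuration
#'
#' Bundles everything a full simulation study needs: the subjects, the
#' ischemia grid (AHA segments, per-subject total radii, border-zone
#' radii), the AP endpoints, electrode counts, resolution and timing.
#' The defaults are the package's standard study: 3 subjects x 17
#' segments x 3 border zones x 5 radii = 765 ischemic setups, with
#' per-subject radius series 5-25 mm (10-30 mm for the thick-walled
#' VM-like subject).
#'
#' @param subjects List of [subject_spec()] objects.
#' @param segments AHA segments to place ischemia in.
#' @param radii_per_subject Named list of total-radius series (mm) per
#'   subject name; `NULL` selects 10-30 mm for VM-like and 5-25 mm
#'   otherwise.
#' @param bz_radii Border-zone radii (mm).
#' @param voxel_size Simulation voxel edge (mm); 2 mm keeps a full sweep
#'   tractable on a laptop, 1 mm is the accuracy setting.
#' @param n_bspm Number of body-surface lattice electrodes.
#' @param endpoints [ischemia_endpoints()].
#' @param calibration_uv Physiological 12-lead peak calibration (uV).
#' @param duration,frame_interval Beat window and frame spacing (ms).
#' @param plateau_frac AP plateau fraction, see [tmv_course()].
#' @param scenarios Acquisition scenarios to evaluate.
#' @param rng_seed Integer study seed (combined with per-subject seeds).
#' @return An object of class `study_config`.
#' @export
study_config <- function(subjects = default_subjects(),
                         segments = 1:17,
                         radii_per_subject = NULL,
                         bz_radii = c(2.8, 4.8, 9.6),
                         voxel_size = 2,
                         n_bspm = 600,
                         endpoints = ischemia_endpoints(),
                         calibration_uv = 1500,
                         duration = 500,
                         frame_interval = 2,
                         plateau_frac = 0.25,
                         scenarios = c("3-channel", "12-lead", "12+R",
                                       "12+1", "BSPM"),
                         rng_seed = 1L) {
  if (!length(subjects)) stop("at least one subject is required", call. = FALSE)
  names(subjects) <- vapply(subjects, function(s) s$name, character(1))
  if (is.null(radii_per_subject)) {
    radii_per_subject <- lapply(subjects, function(s) {
      if (s$wall_thickness_base >= 12) c(10, 15, 20, 25, 30) else c(5, 10, 15, 20, 25)
    })
  }
  segments <- as.integer(segments)
  if (any(is.na(segments)) || any(segments < 1L | segments > 17L)) {
    stop("config key segments: must be integers in 1..17", call. = FALSE)
  }
  if (any(bz_radii <= 0)) {
    stop("config key bz_radii: radii must be positive", call. = FALSE)
  }
  for (nm in names(radii_per_subject)) {
    if (any(radii_per_subject[[nm]] <= 0)) {
      stop("config key radii_per_subject (", nm, "): radii must be positive",
           call. = FALSE)
    }
  }
  bad <- setdiff(scenarios, c("3-channel", "12-lead", "12+R", "12+1", "BSPM"))
  if (length(bad)) {
    stop("config key scenarios: unknown scenario ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(inherits(endpoints, "ischemia_endpoints"))
  structure(list(subjects = subjects, segments = segments,
                 radii_per_subject = radii_per_subject, bz_radii = bz_radii,
                 voxel_size = voxel_size, n_bspm = n_bspm,
                 endpoints = endpoints, calibration_uv = calibration_uv,
                 duration = duration, frame_interval = frame_interval,
                 plateau_frac = plateau_frac, scenarios = scenarios,
                 rng_seed = as.integer(rng_seed)),
            class = "study_config")
}

#' A reduced configuration for fast full-pipeline sweeps
#'
#' One subject, 17 segments, the smallest and largest radius, one border
#' zone, 2 mm voxels and a reduced electrode lattice: 34 ischemic setups
#' that exercise every stage of the pipeline in minutes.
#'
#' @param subject Which default subject to use.
#' @param n_bspm Lattice electrodes.
#' @return A `study_config`.
#' @export
fast_study_config <- function(subject = "K-like", n_bspm = 200) {
  subs <- default_subjects()[subject]
  study_config(subjects = subs,
               radii_per_subject = stats::setNames(list(c(5, 25)), subject),
               bz_radii = 4.8, voxel_size = 2, n_bspm = n_bspm)
}

config_fields <- c("subjects", "segments", "radii_per_subject", "bz_radii",
                   "voxel_size", "n_bspm", "endpoints", "calibration_uv",
                   "duration", "frame_interval", "plateau_frac", "scenarios",
                   "rng_seed")

subject_fields <- c("name", "lv_long_axis", "lv_short_axis",
                    "wall_thickness_base", "wall_thickness_apex",
                    "rv_wall_thickness", "torso_radius", "torso_height",
                    "heart_center_offset", "heart_orientation", "include_rv",
                    "rng_seed")

#' Load / save a study configuration as YAML
#'
#' An empty (or missing-key) file yields the full default study; unknown
#' keys are rejected with the offending key named. Subjects are given as
#' a list of [subject_spec()] fields, AP endpoints as nested
#' `healthy`/`ciz` layer tables of `rmv`, `amplitude`, `apd90`, `cv`.
#' `write_config()` then `load_config()` round-trips to an identical
#' configuration.
#'
#' @param path YAML file path.
#' @return `load_config()`: a validated `study_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), config_fields)
  if (length(unknown)) {
    stop("unknown config key: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- raw
  if (!is.null(raw$subjects)) {
    args$subjects <- lapply(raw$subjects, function(s) {
      unknown <- setdiff(names(s), subject_fields)
      if (length(unknown)) {
        stop("unknown config key in subject: ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      do.call(subject_spec, s)
    })
  }
  if (!is.null(raw$endpoints)) {
    mk <- function(side) lapply(raw$endpoints[[side]],
                                function(p) do.call(ap_params, p))
    args$endpoints <- ischemia_endpoints(healthy = mk("healthy"),
                                         ciz = mk("ciz"))
  }
  do.call(study_config, args)
}

#' @rdname load_config
#' @param config A `study_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  out <- unclass(config)
  out$subjects <- lapply(config$subjects, function(s) unclass(s))
  out$endpoints <- lapply(unclass(config$endpoints), function(side) {
    lapply(side, unclass)
  })
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

#' @export
print.study_config <- function(x, ...) {
  n <- nrow(enumerate_study_grid(names(x$subjects), x$segments,
                                 x$radii_per_subject, x$bz_radii))
  cat("<study_config> ", length(x$subjects), " subject(s), ", n,
      " ischemic setups @ ", x$voxel_size, " mm, ", x$n_bspm,
      " BSPM electrodes\n", sep = "")
  invisible(x)
}
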