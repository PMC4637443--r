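#' Serialize a voxel heart to plain text
#'
#' Writes `<prefix>.csv` (one row per myocardial voxel: indices, chamber,
#' AHA segment, transmural depth, surface flags) and `<prefix>.json`
#' (grid metadata, geometry parameters, rigid transform, stimulus sites).
#' `read_voxel_heart()` reconstructs an equivalent `voxel_heart`.
#'
#' @param heart A `voxel_heart`.
#' @param prefix Path prefix (without extension).
#' @return The prefix, invisibly.
#' @export
write_voxel_heart <- function(heart, prefix) {
  stopifnot(inherits(heart, "voxel_heart"))
  df <- tibble::tibble(ix = heart$coords[, 1], iy = heart$coords[, 2],
                       iz = heart$coords[, 3], chamber = heart$chamber,
                       aha = heart$aha, depth = heart$depth,
                       endo_surface = heart$endo_surface,
                       epi_surface = heart$epi_surface)
  readr::write_csv(df, paste0(prefix, ".csv"))
  meta <- list(voxel_size = heart$voxel_size, dims = heart$dims,
               apex_base_axis = heart$apex_base_axis,
               base_center = heart$base_center,
               lv_geom = heart$lv_geom, cavity_z_min = heart$cavity_z_min,
               transform = list(rotation = as.vector(heart$transform$rotation),
                                offset = heart$transform$offset),
               stimulus = heart$stimulus,
               spec = unclass(heart$spec), units = "mm, ms")
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_voxel_heart
#' @export
read_voxel_heart <- function(prefix) {
  df <- readr::read_csv(paste0(prefix, ".csv"), show_col_types = FALSE,
                        col_types = readr::cols(ix = "i", iy = "i", iz = "i",
                                                chamber = "c", aha = "i",
                                                depth = "d",
                                                endo_surface = "l",
                                                epi_surface = "l"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  spec <- do.call(subject_spec, meta$spec[subject_fields])
  structure(list(
    voxel_size = meta$voxel_size, dims = as.integer(meta$dims),
    coords = cbind(df$ix, df$iy, df$iz), chamber = df$chamber,
    depth = df$depth, endo_surface = df$endo_surface,
    epi_surface = df$epi_surface, aha = df$aha,
    apex_base_axis = meta$apex_base_axis, base_center = meta$base_center,
    lv_geom = as.list(meta$lv_geom), cavity_z_min = meta$cavity_z_min,
    transform = list(rotation = matrix(meta$transform$rotation, 3, 3),
                     offset = meta$transform$offset),
    spec = spec,
    stimulus = list(index = as.integer(meta$stimulus$index),
                    delay = as.numeric(meta$stimulus$delay))
  ), class = "voxel_heart")
}

#' Write a study table with a JSON metadata sidecar
#'
#' @param study An `ischemia_study` or its long table.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return The path, invisibly.
#' @export
write_study_csv <- function(study, path) {
  table <- as_study_table(study)
  readr::write_csv(table, path)
  meta <- list(units = list(value = "uV (k_point_time: ms)", radius = "mm"),
               n_rows = nrow(table))
  if (inherits(study, "ischemia_study")) {
    cfg <- study$config
    meta$config <- list(voxel_size = cfg$voxel_size, n_bspm = cfg$n_bspm,
                        subjects = names(cfg$subjects),
                        bz_radii = cfg$bz_radii, rng_seed = cfg$rng_seed)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_study_csv
#' @export
read_study_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(setup_id = "c", subject = "c",
                                          transmural = "c", scenario = "c",
                                          feature = "c"))
}

# The alternating-ST record: window mean exactly zero in every lead
# (STSD = 0) while the across-lead envelope never drops below `c_uv`
# inside the K window (KPD >= c_uv). The default 48 uV makes the 13-up /
# 12-down cancellation exact in integer arithmetic (13*48 = 12*52).
alternating_st_record <- function(c_uv = 48) {
  times <- seq(0, 500, by = 2)
  a <- numeric(length(times))
  kwin <- times >= 40 & times <= 320
  a[kwin] <- c_uv * rep_len(c(1, -1), sum(kwin))
  a[times >= 110 & times <= 134] <- c_uv           # 13 samples up
  a[times >= 136 & times <= 158] <- -13 * c_uv / 12 # 12 samples down, mean 0
  b <- numeric(length(times))
  ecg_record(rbind(A = a, B = b), times = times,
             scenario_tag = "synthetic-alternating-st")
}

# A small deterministic 12-lead toy record (damped sinusoids, uV).
toy_ecg_record <- function() {
  times <- seq(0, 500, by = 2)
  leads <- c("I", "II", "III", "aVR", "aVL", "aVF", paste0("V", 1:6))
  sig <- t(vapply(seq_along(leads), function(i) {
    qrs <- 900 * sin(pi * pmax(0, pmin(1, (times - 20) / 70))) *
      cos(0.4 * i)
    twave <- 220 * sin(pi * pmax(0, pmin(1, (times - 180) / 180))) *
      sin(0.3 * i + 0.5)
    qrs + twave
  }, numeric(length(times))))
  rownames(sig) <- leads
  ecg_record(sig, times = times, scenario_tag = "synthetic-toy")
}

#' Generate deterministic test fixtures
#'
#' Writes small plain-text fixtures embodying the pipeline's edge cases:
#' a toy voxel heart (no RV, about 17^3 grid), a 12-lead toy ECG, and the
#' "alternating ST" record whose ST-window mean is exactly zero in every
#' lead while its envelope stays positive — the constructed case where
#' the K point deviation detects what the ST-segment deviation misses.
#' Output is byte-identical across runs.
#'
#' @param kind `"toy_heart"`, `"toy_ecg"` or `"alternating_st"`.
#' @param dir Output directory.
#' @return Character vector of written paths.
#' @export
make_fixtures <- function(kind = c("toy_heart", "toy_ecg", "alternating_st"),
                          dir = ".") {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  switch(kind,
    toy_heart = {
      spec <- subject_spec("toy", lv_long_axis = 30, lv_short_axis = 11,
                           wall_thickness_base = 5, wall_thickness_apex = 5,
                           include_rv = FALSE, rng_seed = 7L)
      heart <- assign_aha_segments(build_ventricles(spec, voxel_size = 2))
      prefix <- file.path(dir, "toy_heart")
      write_voxel_heart(heart, prefix)
      paste0(prefix, c(".csv", ".json"))
    },
    toy_ecg = {
      path <- file.path(dir, "toy_ecg.csv")
      write_ecg_csv(toy_ecg_record(), path)
      path
    },
    alternating_st = {
      path <- file.path(dir, "alternating_st.csv")
      write_ecg_csv(alternating_st_record(), path)
      path
    })
}
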