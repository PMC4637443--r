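#' Run a full ischemia detection study
#'
#' For every subject: builds the anatomy, places the electrodes, computes
#' the lead field, simulates one physiological (zone factor 0) beat to
#' calibrate the amplitude, then simulates every ischemic setup of the
#' study grid and extracts the ST-deviation features for every
#' acquisition scenario. Per-lattice-electrode "12-lead plus one" feature
#' values and per-lead values at the shared K point are retained so that
#' electrode optimization and per-lead sensitivity reports can be derived
#' without re-simulating. Everything is deterministic given the
#' configuration.
#'
#' @param config A [study_config()].
#' @param progress Print one line per simulated setup?
#' @return An object of class `ischemia_study` with
#'   \describe{
#'     \item{table}{long tibble: one row per (setup, scenario, feature)
#'       with columns `setup_id`, `subject`, `segment`, `total_radius`,
#'       `bz_radius`, `transmural`, `ischemic_fraction`, `scenario`,
#'       `feature`, `value`; physiological beats have
#'       `setup_id = "physio"`.}
#'     \item{optimal_electrodes}{tibble of individually and commonly
#'       optimal additional electrodes (KPD-grid-averaged objective).}
#'     \item{aux}{per-subject retained matrices (per-electrode and
#'       per-lead features, calibration factors).}
#'     \item{config}{the configuration.}
#'   }
#' @export
run_study <- function(config = study_config(), progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  grid <- enumerate_study_grid(names(config$subjects), config$segments,
                               config$radii_per_subject, config$bz_radii)
  twelve <- c("I", "II", "III", "aVR", "aVL", "aVF", paste0("V", 1:6))
  base_scen <- intersect(config$scenarios, c("3-channel", "12-lead", "12+R", "BSPM"))
  rows <- list()
  aux <- list()

  for (sname in names(config$subjects)) {
    spec <- config$subjects[[sname]]
    heart <- assign_aha_segments(build_ventricles(spec, config$voxel_size))
    electrodes <- place_electrodes(spec, config$n_bspm)
    gain <- lead_field(heart, electrodes)
    simulate <- function(zf, scale) {
      cvf <- cv_field_for(heart, zf, config$endpoints)
      act <- compute_activation(heart, cvf)
      movie <- build_tmv_movie_pf(act, zf, config$endpoints, heart,
                                  config$duration, config$frame_interval,
                                  config$plateau_frac)
      compute_bspm(movie, gain, heart, electrodes, scale = scale)
    }
    rec_raw <- simulate(0, 1)
    scale <- calibrate_gain(rec_raw, config$calibration_uv)
    rec_physio <- scale_record(rec_raw, scale)

    sub_grid <- dplyr::filter(grid, .data$subject == sname)
    cand <- electrodes$bspm_names
    n_set <- nrow(sub_grid)
    plus1 <- list(kpd = matrix(NA_real_, n_set, length(cand), dimnames = list(sub_grid$setup_id, cand)),
                  stsd = NA, k_elev = NA, physio = NULL)
    plus1$stsd <- plus1$kpd; plus1$k_elev <- plus1$kpd
    per_lead <- list(t_k_dev = numeric(n_set), t_k_elev = numeric(n_set),
                     dev = matrix(NA_real_, n_set, 12, dimnames = list(sub_grid$setup_id, twelve)),
                     elev = matrix(NA_real_, n_set, 12, dimnames = list(sub_grid$setup_id, twelve)))

    scen_rows <- function(record, id, seg, r_tot, r_bz, transm, frac) {
      purrr::map_dfr(base_scen, function(sc) {
        f <- ecg_features(extract_scenario(record, sc, electrodes))
        tibble::tibble(setup_id = id, subject = sname, segment = seg,
                       total_radius = r_tot, bz_radius = r_bz,
                       transmural = transm, ischemic_fraction = frac,
                       scenario = sc,
                       feature = c("stsd", "kpd", "k_elevation", "k_point_time"),
                       value = c(f$stsd, f$kpd, f$k_elevation, f$k_point_time))
      })
    }
    rows[[length(rows) + 1]] <-
      scen_rows(rec_physio, "physio", NA_integer_, NA_real_, NA_real_,
                NA_character_, 0)
    plus1$physio <- plus_one_features(rec_physio, twelve, cand)

    for (i in seq_len(n_set)) {
      g <- sub_grid[i, ]
      setup <- ischemia_setup(sname, g$segment, g$total_radius, g$bz_radius)
      field <- place_ischemia(heart, setup)
      rec <- simulate(field$zf, scale)
      rows[[length(rows) + 1]] <-
        scen_rows(rec, g$setup_id, g$segment, g$total_radius, g$bz_radius,
                  field$transmural_flag, ischemic_fraction(field, heart))
      p1 <- plus_one_features(rec, twelve, cand)
      plus1$kpd[i, ] <- p1$kpd; plus1$stsd[i, ] <- p1$stsd
      plus1$k_elev[i, ] <- p1$k_elev
      pl <- per_lead_at_k(rec, twelve)
      per_lead$t_k_dev[i] <- pl$t_k_dev; per_lead$t_k_elev[i] <- pl$t_k_elev
      per_lead$dev[i, ] <- pl$dev; per_lead$elev[i, ] <- pl$elev
      if (progress) {
        cat(sprintf("[%s] %s (%s)\n", sname, g$setup_id, field$transmural_flag))
      }
    }
    aux[[sname]] <- list(setup_ids = sub_grid$setup_id, candidates = cand,
                         plus1 = plus1, per_lead = per_lead, scale = scale,
                         segments = sub_grid$segment,
                         electrodes = electrodes)
  }

  study <- structure(list(table = dplyr::bind_rows(rows),
                          optimal_electrodes = NULL,
                          aux = aux, config = config),
                     class = "ischemia_study")
  if ("12+1" %in% config$scenarios) {
    study <- add_plus_one_scenario(study)
  }
  study
}

# build_tmv_movie with an explicit plateau fraction (kept out of the
# exported signature of build_tmv_movie to match the AP template default)
build_tmv_movie_pf <- function(act, zf_field, endpoints, heart, duration,
                               frame_interval, plateau_frac) {
  zf <- if (inherits(zf_field, "zone_factor_field")) zf_field$zf else zf_field
  n <- nrow(heart$coords)
  zf <- rep_len(zf, n)
  pars <- params_at(zf, heart$depth, endpoints)
  if (inherits(pars, "ap_params")) pars <- tibble::as_tibble(unclass(pars))
  times <- seq(0, duration, by = frame_interval)
  tmv <- matrix(0, n, length(times))
  for (j in seq_along(times)) {
    tmv[, j] <- tmv_course(pars, act$t_act, times[j], plateau_frac)
  }
  structure(list(tmv = tmv, times = times, frame_interval = frame_interval,
                 duration = duration), class = "tmv_movie")
}

scale_record <- function(record, k) {
  record$signals <- record$signals * k
  record
}

# Features of the "12-lead + one lattice electrode" scenario for every
# candidate electrode at once: the 13-lead envelope is the pointwise max
# of the 12-lead envelope and the candidate's unipolar signal.
plus_one_features <- function(record, twelve, cand) {
  kw <- which(record$times >= 40 - 1e-9 & record$times <= 320 + 1e-9)
  sw <- which(record$times >= 110 - 1e-9 & record$times <= 158 + 1e-9)
  s12 <- record$signals[twelve, , drop = FALSE]
  sc <- record$signals[cand, , drop = FALSE]
  env12 <- apply(abs(s12[, kw, drop = FALSE]), 2, max)
  env12e <- apply(pmax(s12[, kw, drop = FALSE], 0), 2, max)
  abs_c <- abs(sc[, kw, drop = FALSE])
  pos_c <- pmax(sc[, kw, drop = FALSE], 0)
  env_mat <- pmax(abs_c, matrix(env12, nrow(abs_c), length(kw), byrow = TRUE))
  enve_mat <- pmax(pos_c, matrix(env12e, nrow(pos_c), length(kw), byrow = TRUE))
  stsd12 <- max(abs(rowMeans(s12[, sw, drop = FALSE])))
  list(kpd = unname(apply(env_mat, 1, min)),
       k_elev = unname(apply(enve_mat, 1, min)),
       stsd = unname(pmax(abs(rowMeans(sc[, sw, drop = FALSE])), stsd12)))
}

# Per-lead 12-lead values at the K point shared across the 12-lead set
# (deviation and elevation variants each use their own shared K point).
per_lead_at_k <- function(record, twelve) {
  r12 <- record
  r12$signals <- record$signals[twelve, , drop = FALSE]
  r12$lead_names <- twelve
  kd <- k_point(r12, "deviation")
  ke <- k_point(r12, "elevation")
  jd <- which(abs(record$times - kd$time_ms) < 1e-9)
  je <- which(abs(record$times - ke$time_ms) < 1e-9)
  list(t_k_dev = kd$time_ms, t_k_elev = ke$time_ms,
       dev = abs(r12$signals[, jd]), elev = pmax(r12$signals[, je], 0))
}

# Choose the optimal additional electrodes and append the 12+1 rows.
add_plus_one_scenario <- function(study) {
  opt <- optimize_additional_electrode(study, "individual")
  common <- optimize_additional_electrode(study, "common")
  study$optimal_electrodes <- dplyr::bind_rows(opt, common)
  new_rows <- purrr::map_dfr(names(study$aux), function(sname) {
    a <- study$aux[[sname]]
    el <- opt$electrode[opt$subject == sname]
    meta <- dplyr::distinct(
      dplyr::filter(study$table, .data$subject == sname,
                    .data$setup_id != "physio"),
      .data$setup_id, .data$subject, .data$segment, .data$total_radius,
      .data$bz_radius, .data$transmural, .data$ischemic_fraction)
    meta <- meta[match(a$setup_ids, meta$setup_id), ]
    isch <- tidyr::pivot_longer(
      dplyr::mutate(meta,
                    stsd = unname(a$plus1$stsd[, el]),
                    kpd = unname(a$plus1$kpd[, el]),
                    k_elevation = unname(a$plus1$k_elev[, el])),
      cols = c("stsd", "kpd", "k_elevation"),
      names_to = "feature", values_to = "value")
    phys <- tibble::tibble(setup_id = "physio", subject = sname,
                           segment = NA_integer_, total_radius = NA_real_,
                           bz_radius = NA_real_, transmural = NA_character_,
                           ischemic_fraction = 0,
                           feature = c("stsd", "kpd", "k_elevation"),
                           value = c(a$plus1$physio$stsd[el],
                                     a$plus1$physio$kpd[el],
                                     a$plus1$physio$k_elev[el]))
    dplyr::mutate(dplyr::bind_rows(isch, phys), scenario = "12+1")
  })
  study$table <- dplyr::bind_rows(study$table, new_rows)
  study
}

#' @export
print.ischemia_study <- function(x, ...) {
  n_setup <- length(unique(x$table$setup_id[x$table$setup_id != "physio"]))
  cat("<ischemia_study> ", n_setup, " ischemic setups, ",
      length(x$aux), " subject(s), scenarios: ",
      paste(unique(x$table$scenario), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Simulate a single beat of one setup
#'
#' Convenience wrapper used for worked examples and exploration: runs the
#' whole pipeline (anatomy, activation, TMV movie, forward model,
#' calibration) for one subject and either a physiological beat
#' (`setup = NULL`) or one ischemic setup, and returns the calibrated
#' record of all leads.
#'
#' @param spec A [subject_spec()].
#' @param setup An [ischemia_setup()] or `NULL`.
#' @param voxel_size Voxel edge (mm).
#' @param n_bspm Lattice electrodes.
#' @param endpoints AP endpoints.
#' @return List with `record` (`ecg_record`, all leads), `heart`,
#'   `electrodes`, `field` (`zone_factor_field` or `NULL`) and `scale`.
#' @export
simulate_beat <- function(spec, setup = NULL, voxel_size = 2, n_bspm = 200,
                          endpoints = ischemia_endpoints()) {
  heart <- assign_aha_segments(build_ventricles(spec, voxel_size))
  electrodes <- place_electrodes(spec, n_bspm)
  gain <- lead_field(heart, electrodes)
  one <- function(zf, scale) {
    act <- compute_activation(heart, cv_field_for(heart, zf, endpoints))
    movie <- build_tmv_movie(act, zf, endpoints, heart)
    compute_bspm(movie, gain, heart, electrodes, scale = scale)
  }
  raw <- one(0, 1)
  scale <- calibrate_gain(raw)
  field <- NULL
  if (is.null(setup)) {
    record <- scale_record(raw, scale)
  } else {
    field <- place_ischemia(heart, setup)
    record <- one(field$zf, scale)
  }
  list(record = record, heart = heart, electrodes = electrodes,
       field = field, scale = scale)
}
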