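as_study_table <- function(x) {
  if (inherits(x, "ischemia_study")) return(x$table)
  if (is.data.frame(x)) return(x)
  stop("expected an ischemia_study or its study table", call. = FALSE)
}

ischemic_values <- function(table, scenario, feature) {
  sel <- dplyr::filter(table, .data$setup_id != "physio",
                       .data$scenario == !!scenario,
                       .data$feature == !!feature)
  if (!nrow(sel)) {
    stop("no rows for scenario '", scenario, "' and feature '", feature, "'",
         call. = FALSE)
  }
  sel
}

#' Threshold grids for averaged detection rates
#'
#' The STSD grid holds 54 thresholds equidistant on 24-240 uV, the KPD
#' grid 36 thresholds on 9-150 uV.
#'
#' @param grid `"stsd_grid"`, `"kpd_grid"`, or a numeric vector returned
#'   unchanged.
#' @return Numeric vector of thresholds (uV).
#' @export
threshold_grid <- function(grid) {
  if (is.numeric(grid)) {
    if (!length(grid)) stop("empty threshold grid", call. = FALSE)
    return(grid)
  }
  switch(grid,
         stsd_grid = seq(24, 240, length.out = 54),
         kpd_grid = seq(9, 150, length.out = 36),
         stop("unknown threshold grid: ", grid, call. = FALSE))
}

#' Detection rate at a threshold
#'
#' The fraction of ischemic setups whose feature value meets or exceeds
#' the threshold (the in-silico sensitivity; the detection rule is
#' inclusive).
#'
#' @param x An `ischemia_study` or its long study table.
#' @param scenario Acquisition scenario.
#' @param feature `"stsd"`, `"kpd"` or `"k_elevation"`.
#' @param threshold Threshold(s) in uV (vectorized).
#' @return Numeric vector of rates in `[0, 1]`, one per threshold.
#' @export
detection_rate <- function(x, scenario, feature, threshold) {
  if (any(threshold < 0)) stop("thresholds must be nonnegative", call. = FALSE)
  v <- ischemic_values(as_study_table(x), scenario, feature)$value
  vapply(threshold, function(tau) mean(v >= tau), numeric(1))
}

#' Grid-averaged detection rate
#'
#' Arithmetic mean of [detection_rate()] over a threshold grid,
#' summarizing sensitivity independently of a single threshold choice.
#'
#' @inheritParams detection_rate
#' @param grid See [threshold_grid()].
#' @return A single averaged rate.
#' @export
averaged_rate <- function(x, scenario, feature, grid = paste0(feature, "_grid")) {
  if (identical(grid, "k_elevation_grid")) grid <- "kpd_grid"
  mean(detection_rate(x, scenario, feature, threshold_grid(grid)))
}

#' Greatest physiological feature value (specificity anchor)
#'
#' The threshold that a detector must exceed to never flag the
#' physiological (nonischemic) simulations: the maximum feature value
#' across the physiological beats, per subject or pooled. The 1.5x
#' multiple used for the practically-motivated comparisons is reported
#' alongside.
#'
#' @inheritParams detection_rate
#' @param pooling `"across_subjects"` (default) or `"per_subject"`.
#' @return A tibble with `subject` (NA when pooled), `threshold` and
#'   `threshold_1p5` (uV).
#' @export
physiological_threshold <- function(x, scenario, feature,
                                    pooling = c("across_subjects", "per_subject")) {
  pooling <- match.arg(pooling)
  table <- as_study_table(x)
  ph <- dplyr::filter(table, .data$setup_id == "physio",
                      .data$scenario == !!scenario,
                      .data$feature == !!feature)
  if (!nrow(ph)) stop("no physiological rows for this scenario/feature", call. = FALSE)
  per <- dplyr::summarise(dplyr::group_by(ph, .data$subject),
                          threshold = max(.data$value), .groups = "drop")
  if (pooling == "per_subject") {
    dplyr::mutate(per, threshold_1p5 = 1.5 * .data$threshold)
  } else {
    tibble::tibble(subject = NA_character_, threshold = max(per$threshold),
                   threshold_1p5 = 1.5 * max(per$threshold))
  }
}

#' Optimize the position of a single additional electrode
#'
#' Chooses, among all body-surface lattice electrodes, the one whose
#' addition to the 12-lead ECG maximizes the KPD-grid-averaged detection
#' rate over the ischemic setups of one subject (`"individual"`) or of
#' all subjects pooled (`"common"`, same lattice position on every
#' torso). The chosen position is a single electrode fixed across all
#' ischemia radii, locations and border-zone extents. Ties break towards
#' the lowest electrode index.
#'
#' @param study An `ischemia_study` (with retained per-electrode data).
#' @param subject_scope `"individual"` or `"common"`.
#' @param feature Feature for the objective (default `"kpd"`).
#' @param grid Threshold grid for the objective.
#' @return Tibble with `scope`, `subject` (NA for common), `electrode`
#'   and `avg_rate`.
#' @export
optimize_additional_electrode <- function(study,
                                          subject_scope = c("individual", "common"),
                                          feature = "kpd", grid = "kpd_grid") {
  stopifnot(inherits(study, "ischemia_study"))
  subject_scope <- match.arg(subject_scope)
  taus <- threshold_grid(grid)
  mats <- lapply(study$aux, function(a) {
    m <- a$plus1[[if (feature == "k_elevation") "k_elev" else feature]]
    if (!is.matrix(m)) stop("per-electrode data missing from study", call. = FALSE)
    m
  })
  avg_rates <- function(m) {
    # mean over thresholds of the detection rate of each candidate column
    vapply(seq_len(ncol(m)), function(j) {
      mean(vapply(taus, function(tau) mean(m[, j] >= tau), numeric(1)))
    }, numeric(1))
  }
  if (subject_scope == "individual") {
    purrr::map_dfr(names(mats), function(sname) {
      r <- avg_rates(mats[[sname]])
      j <- which.max(r)
      tibble::tibble(scope = "individual", subject = sname,
                     electrode = colnames(mats[[sname]])[j], avg_rate = r[j])
    })
  } else {
    pooled <- do.call(rbind, unname(mats))
    r <- avg_rates(pooled)
    j <- which.max(r)
    tibble::tibble(scope = "common", subject = NA_character_,
                   electrode = colnames(mats[[1]])[j], avg_rate = r[j])
  }
}

#' Maximum threshold detecting at least 80% of a segment's setups
#'
#' Because the detection rate is a right-continuous step function of the
#' threshold under the inclusive detection rule, the largest threshold
#' with rate >= 0.8 is an observed feature value: the lower 20th
#' percentile of the segment's values.
#'
#' @inheritParams detection_rate
#' @param segment AHA segment (1-17).
#' @param subject Restrict to one subject (`NULL` pools all).
#' @return The threshold (uV).
#' @export
segment_threshold_80 <- function(x, scenario, feature, segment,
                                 subject = NULL) {
  sel <- ischemic_values(as_study_table(x), scenario, feature)
  sel <- dplyr::filter(sel, .data$segment == !!segment)
  if (!is.null(subject)) sel <- dplyr::filter(sel, .data$subject == !!subject)
  if (!nrow(sel)) stop("no setups in segment ", segment, call. = FALSE)
  v <- sort(sel$value)
  n <- length(v)
  v[n - ceiling(0.8 * n) + 1]
}

#' Subgroup detection-rate report
#'
#' Grid-averaged detection rates broken down by ischemia radius,
#' border-zone size, transmurality, subject, AHA segment, or single
#' 12-lead channel. The per-lead mode evaluates each lead at the K point
#' shared across the full 12-lead set, reported per AHA segment.
#'
#' @inheritParams detection_rate
#' @param by One of `"radius"`, `"bz"`, `"transmurality"`, `"subject"`,
#'   `"segment"`, `"lead"`.
#' @param grid See [threshold_grid()].
#' @param x An `ischemia_study` (required for `by = "lead"`) or a study
#'   table.
#' @return A `detection_report`: a tibble of `level` (and `lead`,
#'   `segment` for the per-lead mode) and `rate`, with the report
#'   parameters in attributes.
#' @export
subgroup_report <- function(x, by = c("radius", "bz", "transmurality",
                                      "subject", "segment", "lead"),
                            scenario = "12-lead", feature = "kpd",
                            grid = "kpd_grid") {
  by <- match.arg(by)
  taus <- threshold_grid(grid)
  if (by == "lead") {
    if (!inherits(x, "ischemia_study")) {
      stop("per-lead reports need the full ischemia_study object", call. = FALSE)
    }
    mode <- if (feature == "k_elevation") "elev" else "dev"
    out <- purrr::map_dfr(names(x$aux), function(sname) {
      a <- x$aux[[sname]]
      m <- a$per_lead[[mode]]
      tidyr::expand_grid(lead = colnames(m), segment = sort(unique(a$segments))) |>
        dplyr::mutate(rate = purrr::map2_dbl(.data$lead, .data$segment, function(l, sg) {
          v <- m[a$segments == sg, l]
          mean(vapply(taus, function(tau) mean(v >= tau), numeric(1)))
        }), subject = sname)
    })
    out <- dplyr::summarise(dplyr::group_by(out, .data$lead, .data$segment),
                            rate = mean(.data$rate), .groups = "drop")
    return(new_detection_report(out, by, scenario, feature))
  }
  sel <- ischemic_values(as_study_table(x), scenario, feature)
  key <- switch(by, radius = "total_radius", bz = "bz_radius",
                transmurality = "transmural", subject = "subject",
                segment = "segment")
  out <- dplyr::summarise(
    dplyr::group_by(sel, level = .data[[key]]),
    rate = mean(vapply(taus, function(tau) mean(.data$value >= tau), numeric(1))),
    n_setups = dplyr::n(),
    .groups = "drop")
  new_detection_report(out, by, scenario, feature)
}

new_detection_report <- function(tbl, by, scenario, feature) {
  structure(tbl, by = by, scenario = scenario, feature = feature,
            class = c("detection_report", class(tbl)))
}

#' @export
print.detection_report <- function(x, ...) {
  cat("Detection report by ", attr(x, "by"), " (scenario ",
      attr(x, "scenario"), ", feature ", attr(x, "feature"), ")\n", sep = "")
  NextMethod()
}
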