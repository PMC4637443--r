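#' Tidy an ischemia study
#'
#' @param x An `ischemia_study`.
#' @param ... Unused.
#' @return The long study table: one row per (setup, scenario, feature).
#' @export
tidy.ischemia_study <- function(x, ...) x$table

#' One-line study summary
#'
#' @param x An `ischemia_study`.
#' @param ... Unused.
#' @return One-row tibble: setup counts, resolution, electrode count and
#'   the grid-averaged 12-lead detection rates for STSD and KPD.
#' @export
glance.ischemia_study <- function(x, ...) {
  isch <- dplyr::filter(x$table, .data$setup_id != "physio")
  tibble::tibble(
    n_setups = length(unique(isch$setup_id)),
    n_subjects = length(x$aux),
    n_scenarios = length(unique(x$table$scenario)),
    voxel_size_mm = x$config$voxel_size,
    n_bspm = x$config$n_bspm,
    rate_stsd_12lead = averaged_rate(x, "12-lead", "stsd"),
    rate_kpd_12lead = averaged_rate(x, "12-lead", "kpd")
  )
}

#' @export
tidy.detection_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
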