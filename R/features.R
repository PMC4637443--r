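st_window_index <- function(record, from = 110, to = 158) {
  if (!isTRUE(record$baseline_corrected)) {
    stop("record must be baseline-corrected before feature extraction",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(record$frame_interval, 2))) {
    stop("features are defined on a 2 ms frame grid", call. = FALSE)
  }
  idx <- which(record$times >= from - 1e-9 & record$times <= to + 1e-9)
  want <- (to - from) / 2 + 1
  if (length(idx) != want) {
    stop("record does not cover the ", from, "-", to, " ms window",
         call. = FALSE)
  }
  idx
}

#' ST-segment deviation (STSD)
#'
#' For each lead, the absolute value of the mean of the 25 samples between
#' 110 ms and 158 ms (2 ms frames, inclusive ends); the feature is the
#' maximum over leads.
#'
#' @param record A baseline-corrected `ecg_record` covering 110-158 ms.
#' @return One-row tibble with `value` (uV) and `lead` (the arg-max lead).
#' @export
stsd <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  idx <- st_window_index(record)
  m <- abs(rowMeans(record$signals[, idx, drop = FALSE]))
  i <- which.max(m)
  tibble::tibble(value = unname(m[i]), lead = record$lead_names[i])
}

#' K point of a record
#'
#' For each time step between the R peak (40 ms) and the T peak (320 ms),
#' the lead with the maximum absolute value defines the envelope of
#' absolute values; the K point is the time where this envelope is
#' minimal (earliest frame on ties). In `"elevation"` mode negative
#' values are clipped to zero before the envelope is taken, so only
#' ST elevation counts.
#'
#' @param record A baseline-corrected `ecg_record` covering 40-320 ms.
#' @param mode `"deviation"` (default) or `"elevation"`.
#' @return One-row tibble with `time_ms` and `value` (uV).
#' @export
k_point <- function(record, mode = c("deviation", "elevation")) {
  stopifnot(inherits(record, "ecg_record"))
  mode <- match.arg(mode)
  if (!length(record$lead_names)) stop("record has no leads", call. = FALSE)
  idx <- st_window_index(record, 40, 320)
  w <- record$signals[, idx, drop = FALSE]
  if (mode == "elevation") w <- pmax(w, 0)
  env <- apply(abs(w), 2, max)
  j <- which.min(env)
  tibble::tibble(time_ms = record$times[idx][j], value = unname(env[j]))
}

#' K point deviation (KPD)
#'
#' The baseline deviation at the minimum of the ST-segment envelope
#' signal: `min over t of max over leads of |b(e, t)|` on the 40-320 ms
#' window.
#'
#' @inheritParams k_point
#' @return Numeric scalar (uV).
#' @export
kpd <- function(record) k_point(record, "deviation")$value

#' @rdname kpd
#' @export
k_elevation <- function(record) k_point(record, "elevation")$value

#' Single-lead deviation at a shared K point
#'
#' Evaluates one lead at a K point time that was determined on the full
#' scenario lead set, as used for per-lead sensitivity maps.
#'
#' @param record An `ecg_record` containing `lead`.
#' @param lead Lead name.
#' @param k_point_time_ms K point time determined on the full lead set.
#' @param mode `"deviation"` (absolute value) or `"elevation"` (positive
#'   part).
#' @return Numeric scalar (uV).
#' @export
per_lead_feature <- function(record, lead, k_point_time_ms,
                             mode = c("deviation", "elevation")) {
  stopifnot(inherits(record, "ecg_record"))
  mode <- match.arg(mode)
  if (!lead %in% record$lead_names) {
    stop("unknown lead: ", lead, call. = FALSE)
  }
  j <- which(abs(record$times - k_point_time_ms) < 1e-9)
  if (length(j) != 1) stop("k point time is not a frame time", call. = FALSE)
  v <- unname(record$signals[lead, j])
  if (mode == "deviation") abs(v) else max(v, 0)
}

#' All ST-deviation features of a record
#'
#' @param record A baseline-corrected `ecg_record`.
#' @return One-row tibble: `stsd`, `stsd_lead`, `kpd`, `k_elevation`,
#'   `k_point_time` (ms) and `scenario`.
#' @export
ecg_features <- function(record) {
  s <- stsd(record)
  kp <- k_point(record, "deviation")
  tibble::tibble(stsd = s$value, stsd_lead = s$lead,
                 kpd = kp$value, k_elevation = k_elevation(record),
                 k_point_time = kp$time_ms,
                 scenario = record$scenario_tag)
}
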