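#' Compute first-arrival activation times
#'
#' Realizes the excitation-spread cellular automaton as a multi-source
#' shortest-path (first-arrival) problem on the 26-neighbour voxel graph:
#' the travel time across an edge is its euclidean length divided by the
#' harmonic mean of the two voxels' conduction velocities, and the
#' activation time of a voxel is the minimum over stimulus sites of
#' stimulus delay plus travel time. Results are rounded to the internal
#' 0.1 ms clock. Voxels not connected to any stimulus stay `Inf`.
#'
#' @param heart A `voxel_heart`.
#' @param cv_field Conduction velocity per myocardial voxel (m/s, i.e.
#'   mm/ms), all positive.
#' @param stimuli List with `index` (1-based myocardial voxel indices) and
#'   `delay` (ms); defaults to the heart's stimulus sites.
#' @return Object of class `activation_map`: numeric vector `t_act` (ms)
#'   per myocardial voxel plus metadata.
#' @export
compute_activation <- function(heart, cv_field, stimuli = heart$stimulus) {
  stopifnot(inherits(heart, "voxel_heart"))
  n <- nrow(heart$coords)
  cv_field <- rep_len(cv_field, n)
  if (any(!is.finite(cv_field)) || any(cv_field <= 0)) {
    stop("cv_field must be positive on the myocardium", call. = FALSE)
  }
  if (is.null(stimuli) || !length(stimuli$index)) {
    stop("at least one stimulus site is required", call. = FALSE)
  }
  t_act <- cpp_activation(heart$coords, cv_field, heart$voxel_size,
                          as.integer(stimuli$index) - 1L,
                          as.numeric(rep_len(stimuli$delay,
                                             length(stimuli$index))),
                          0.1)
  structure(list(t_act = t_act, stimuli = stimuli,
                 voxel_size = heart$voxel_size),
            class = "activation_map")
}

#' Assemble the transmembrane-voltage movie
#'
#' Evaluates, for every myocardial voxel, the AP template with parameters
#' interpolated at the voxel's zone factor and transmural depth, shifted
#' by its activation time, and samples the result on the saved frame grid
#' (every 2 ms over a 500 ms beat by default).
#'
#' @param act An [compute_activation()] result.
#' @param zf_field A `zone_factor_field` or a numeric ZF vector
#'   (0 for a physiological beat).
#' @param endpoints An [ischemia_endpoints()].
#' @param heart The `voxel_heart`.
#' @param duration Beat window (ms).
#' @param frame_interval Frame spacing (ms).
#' @return Object of class `tmv_movie`: matrix `tmv` (voxel x frame, mV),
#'   `times` (ms), `frame_interval`, `duration`.
#' @export
build_tmv_movie <- function(act, zf_field, endpoints, heart,
                            duration = 500, frame_interval = 2) {
  stopifnot(inherits(act, "activation_map"), inherits(heart, "voxel_heart"))
  zf <- if (inherits(zf_field, "zone_factor_field")) zf_field$zf else zf_field
  n <- nrow(heart$coords)
  zf <- rep_len(zf, n)
  if (any(!is.finite(act$t_act))) {
    stop("activation must be finite on every myocardial voxel", call. = FALSE)
  }
  pars <- params_at(zf, heart$depth, endpoints)
  if (inherits(pars, "ap_params")) pars <- tibble::as_tibble(unclass(pars))
  times <- seq(0, duration, by = frame_interval)
  tmv <- matrix(0, n, length(times))
  for (j in seq_along(times)) {
    tmv[, j] <- tmv_course(pars, act$t_act, times[j])
  }
  structure(list(tmv = tmv, times = times, frame_interval = frame_interval,
                 duration = duration),
            class = "tmv_movie")
}

# Conduction-velocity field of a (possibly ischemic) beat: layer-dependent
# healthy CV scaled down towards the ischemic endpoint by the zone factor.
cv_field_for <- function(heart, zf, endpoints) {
  pars <- params_at(rep_len(zf, nrow(heart$coords)), heart$depth, endpoints)
  if (inherits(pars, "ap_params")) pars$cv else pars$cv
}
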