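#' Action-potential template parameters
#'
#' The phenomenological transmembrane-voltage course of a voxel is fully
#' described by four electrophysiological parameters: resting membrane
#' voltage (RMV, mV), action-potential amplitude (mV), duration at 90%
#' repolarization (APD90, ms) and local conduction velocity (CV, m/s).
#'
#' @param rmv Resting membrane voltage (mV).
#' @param amplitude AP amplitude (mV), positive.
#' @param apd90 AP duration at 90% repolarization (ms), positive.
#' @param cv Conduction velocity (m/s), positive.
#' @return An object of class `ap_params`.
#' @export
ap_params <- function(rmv, amplitude, apd90, cv) {
  if (amplitude <= 0 || apd90 <= 0 || cv <= 0) {
    stop("amplitude, apd90 and cv must be positive", call. = FALSE)
  }
  structure(list(rmv = rmv, amplitude = amplitude, apd90 = apd90, cv = cv),
            class = "ap_params")
}

#' Healthy and fully ischemic AP endpoints per transmural layer
#'
#' Endpoint parameter sets between which the zone factor interpolates:
#' `healthy` (ZF = 0) and `ciz` (ZF = 1, representing hyperkalemia,
#' acidosis and hypoxia about 10 minutes after the onset of ischemia:
#' depolarized rest, reduced amplitude, shortened APD90, slowed
#' conduction). Each holds one [ap_params()] per transmural layer (endo,
#' mid, epi); the healthy defaults carry transmural APD90 heterogeneity
#' (mid-wall longest, epicardium shortest) producing concordant T waves.
#'
#' @param healthy,ciz Named lists `list(endo =, mid =, epi =)` of
#'   [ap_params()]. Defaults are representative textbook values; they are
#'   configuration, not fitted quantities.
#' @return An object of class `ischemia_endpoints`.
#' @export
ischemia_endpoints <- function(healthy = NULL, ciz = NULL) {
  if (is.null(healthy)) {
    healthy <- list(endo = ap_params(-85, 125, 320, 0.6),
                    mid = ap_params(-85, 125, 340, 0.6),
                    epi = ap_params(-85, 125, 300, 0.6))
  }
  if (is.null(ciz)) {
    ciz <- lapply(healthy, function(p) {
      ap_params(-70, 95, p$apd90 * 0.75, p$cv * 0.6)
    })
  }
  for (layer in c("endo", "mid", "epi")) {
    h <- healthy[[layer]]; c2 <- ciz[[layer]]
    if (is.null(h) || is.null(c2)) {
      stop("endpoints must define endo, mid and epi layers", call. = FALSE)
    }
    ok <- c2$rmv > h$rmv && c2$amplitude < h$amplitude &&
      c2$apd90 < h$apd90 && c2$cv < h$cv
    if (!ok) {
      stop("ischemic endpoints must depolarize rest and reduce amplitude, ",
           "APD90 and CV relative to healthy (layer ", layer, ")",
           call. = FALSE)
    }
  }
  structure(list(healthy = healthy, ciz = ciz), class = "ischemia_endpoints")
}

layer_of_depth <- function(depth) {
  ifelse(depth < 1 / 3, "endo", ifelse(depth < 2 / 3, "mid", "epi"))
}

#' Interpolate AP parameters at a given ischemia severity and wall depth
#'
#' Selects the transmural layer from the depth (endo below 1/3, mid up to
#' 2/3, epi above) and interpolates each parameter linearly in the zone
#' factor between the healthy and the fully ischemic endpoint, so ZF = 0
#' returns the healthy layer parameters exactly and ZF = 1 the ischemic
#' ones.
#'
#' @param zf Zone factor in `[0, 1]` (vectorized).
#' @param depth Transmural depth in `[0, 1]` (vectorized, recycled).
#' @param endpoints An [ischemia_endpoints()].
#' @return For scalar input an [ap_params()]; for vector input a tibble
#'   with columns `rmv`, `amplitude`, `apd90`, `cv`.
#' @export
params_at <- function(zf, depth, endpoints) {
  stopifnot(inherits(endpoints, "ischemia_endpoints"))
  if (any(!is.finite(zf)) || any(zf < 0 | zf > 1)) {
    stop("zf must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(depth)) || any(depth < 0 | depth > 1)) {
    stop("depth must lie in [0, 1]", call. = FALSE)
  }
  n <- max(length(zf), length(depth))
  zf <- rep_len(zf, n); depth <- rep_len(depth, n)
  layer <- layer_of_depth(depth)
  get <- function(side, field) {
    vapply(c(endo = "endo", mid = "mid", epi = "epi"),
           function(l) endpoints[[side]][[l]][[field]], numeric(1))[layer]
  }
  out <- tibble::tibble(
    rmv = unname((1 - zf) * get("healthy", "rmv") + zf * get("ciz", "rmv")),
    amplitude = unname((1 - zf) * get("healthy", "amplitude") +
                         zf * get("ciz", "amplitude")),
    apd90 = unname((1 - zf) * get("healthy", "apd90") + zf * get("ciz", "apd90")),
    cv = unname((1 - zf) * get("healthy", "cv") + zf * get("ciz", "cv"))
  )
  if (n == 1) return(ap_params(out$rmv, out$amplitude, out$apd90, out$cv))
  out
}

#' Transmembrane voltage template
#'
#' Piecewise AP template: resting voltage before activation, a 2 ms linear
#' upstroke to `rmv + amplitude`, a plateau, and a smooth half-cosine
#' repolarization anchored so that the voltage at `t_activation + apd90`
#' equals `rmv + 0.1 * amplitude` (the 90%-repolarization definition),
#' returning to rest afterwards.
#'
#' @param p An [ap_params()] or a data frame of parameter columns
#'   (`rmv`, `amplitude`, `apd90`) recycled against `t`.
#' @param t_activation Activation time (ms), vectorized.
#' @param t Query time (ms), vectorized.
#' @param plateau_frac Fraction of APD90 spent at full plateau before
#'   repolarization begins. The default 0.25 places the healthy ST
#'   segment in the near-isoelectric clinical regime while transmural
#'   APD90 heterogeneity still yields a nonzero, concordant T wave (a
#'   perfectly flat plateau would make the healthy heart exactly silent
#'   between QRS and T; a much earlier repolarization onset pushes the
#'   T-wave upstroke into the ST measurement window).
#' @return Transmembrane voltage (mV), vectorized.
#' @export
tmv_course <- function(p, t_activation, t, plateau_frac = 0.25) {
  if (inherits(p, "ap_params")) p <- tibble::as_tibble(unclass(p)[c("rmv", "amplitude", "apd90")])
  n <- max(length(t), length(t_activation), nrow(p))
  rmv <- rep_len(p$rmv, n); amp <- rep_len(p$amplitude, n)
  apd <- rep_len(p$apd90, n)
  tau <- rep_len(t, n) - rep_len(t_activation, n)
  # half-cosine anchored at the APD90 point: r(tau0 + x) =
  # 0.5 (1 + cos(pi x / tau_rep)), with r = 0.1 at tau = apd90
  tau0 <- plateau_frac * apd
  tau_rep <- (apd - tau0) * pi / acos(2 * 0.1 - 1)
  r <- numeric(n)
  up <- tau >= 0 & tau < 2
  r[up] <- tau[up] / 2
  plat <- tau >= 2 & tau <= tau0
  r[plat] <- 1
  rep_ph <- tau > tau0 & tau < tau0 + tau_rep
  r[rep_ph] <- 0.5 * (1 + cos(pi * (tau[rep_ph] - tau0[rep_ph]) / tau_rep[rep_ph]))
  rmv + amp * r
}
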