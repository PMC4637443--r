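#' Describe one ischemic setup
#'
#' An ischemic setup is a hemispherical region centered on the endocardial
#' surface of one AHA segment, described by the total radius (central
#' ischemic zone plus border zone) and the border-zone radius.
#'
#' @param subject Subject identifier.
#' @param segment AHA segment, integer 1-17.
#' @param total_radius Total radius (CIZ + BZ) in mm.
#' @param bz_radius Border-zone radius in mm; the study default series are
#'   2.8, 4.8 and 9.6 mm.
#' @param center_voxel Optional myocardial voxel index (1-based, into the
#'   heart's voxel list) of the hemisphere center; when `NULL` the
#'   endocardial voxel nearest the segment centroid is chosen.
#' @return An object of class `ischemia_setup`.
#' @export
ischemia_setup <- function(subject, segment, total_radius, bz_radius,
                           center_voxel = NULL) {
  segment <- as.integer(segment)
  if (is.na(segment) || segment < 1L || segment > 17L) {
    stop("segment must be an integer in 1..17", call. = FALSE)
  }
  if (!is.numeric(total_radius) || total_radius <= 0 ||
      !is.numeric(bz_radius) || bz_radius <= 0) {
    stop("radii must be positive", call. = FALSE)
  }
  if (total_radius <= bz_radius) {
    stop("total_radius must exceed bz_radius", call. = FALSE)
  }
  structure(list(subject = as.character(subject), segment = segment,
                 total_radius = total_radius, bz_radius = bz_radius,
                 center_voxel = center_voxel),
            class = "ischemia_setup")
}

#' Place a hemispherical ischemic region and compute its zone factors
#'
#' Assigns every myocardial voxel an ischemia severity (zone factor, ZF):
#' 1 inside the central ischemic zone (euclidean distance from the center
#' at most `total_radius - bz_radius`), 0 in healthy tissue (distance at
#' least `total_radius`), and a linear ramp in between (the border zone).
#' The center lies on the endocardial surface, so the sphere intersected
#' with the myocardium is effectively a hemisphere.
#'
#' @param heart A `voxel_heart` with AHA segments assigned.
#' @param setup An [ischemia_setup()].
#' @return An object of class `zone_factor_field`: `zf` (per myocardial
#'   voxel), `setup` (with the resolved `center_voxel`), and
#'   `transmural_flag` from [classify_transmurality()].
#' @export
place_ischemia <- function(heart, setup) {
  stopifnot(inherits(heart, "voxel_heart"), inherits(setup, "ischemia_setup"))
  if (all(is.na(heart$aha))) {
    stop("assign_aha_segments() must be run before placing ischemia",
         call. = FALSE)
  }
  centers <- voxel_positions(heart, "local")
  cv <- setup$center_voxel
  if (is.null(cv)) {
    in_seg <- !is.na(heart$aha) & heart$aha == setup$segment
    if (!any(in_seg)) {
      stop("AHA segment ", setup$segment, " contains no voxels", call. = FALSE)
    }
    centroid <- colMeans(centers[in_seg, , drop = FALSE])
    cand <- which(in_seg & heart$endo_surface)
    if (!length(cand)) {
      stop("AHA segment ", setup$segment, " has no endocardial surface voxel",
           call. = FALSE)
    }
    d <- sqrt(rowSums(sweep(centers[cand, , drop = FALSE], 2, centroid)^2))
    cv <- cand[which.min(d)]
  } else {
    if (cv < 1 || cv > nrow(centers) || !heart$endo_surface[cv]) {
      stop("center_voxel must index an endocardial surface voxel",
           call. = FALSE)
    }
  }
  setup$center_voxel <- cv
  d <- sqrt(rowSums(sweep(centers, 2, centers[cv, ])^2))
  r_ciz <- setup$total_radius - setup$bz_radius
  zf <- pmin(1, pmax(0, (setup$total_radius - d) / setup$bz_radius))
  zf[d <= r_ciz] <- 1
  field <- structure(list(zf = zf, setup = setup, transmural_flag = NA),
                     class = "zone_factor_field")
  field$transmural_flag <- classify_transmurality(field, heart)
  field
}

#' Classify an ischemic setup as subendocardial or transmural
#'
#' The setup is transmural as soon as the entire wall is affected by full
#' ischemia: some central-ischemic-zone voxel (ZF = 1) lies on the
#' epicardial surface or is 26-adjacent to it. Border-zone contact alone
#' does not count.
#'
#' @param field A `zone_factor_field`.
#' @param heart The matching `voxel_heart`.
#' @return `"transmural"` or `"subendocardial"`.
#' @export
classify_transmurality <- function(field, heart) {
  stopifnot(inherits(field, "zone_factor_field"), inherits(heart, "voxel_heart"))
  ciz <- field$zf >= 1
  if (!any(ciz)) return("subendocardial")
  if (any(ciz & heart$epi_surface)) return("transmural")
  epi <- heart$coords[heart$epi_surface, , drop = FALSE]
  cz <- heart$coords[ciz, , drop = FALSE]
  # 26-adjacency = Chebyshev distance 1 in voxel indices
  d <- cpp_nearest_dist(cz * 1.0, epi * 1.0)
  if (any(d <= sqrt(3) + 1e-9)) "transmural" else "subendocardial"
}

#' Fraction of the left ventricle that is ischemic
#'
#' @param field A `zone_factor_field`.
#' @param heart The matching `voxel_heart`.
#' @return Fraction of LV voxels with ZF > 0.
#' @export
ischemic_fraction <- function(field, heart) {
  lv <- heart$chamber == "LV"
  mean(field$zf[lv] > 0)
}

#' Enumerate the study grid of ischemic setups
#'
#' Cartesian product of subjects, AHA segments, border-zone radii and
#' per-subject total radii, in deterministic order (subject, segment, BZ,
#' radius). The default study — 3 subjects, 17 segments, 3 BZ radii and 5
#' total radii per subject — yields 765 setups.
#'
#' @param subjects Character vector of subject names.
#' @param segments Integer vector of AHA segments.
#' @param radii_per_subject Named list mapping each subject to its vector
#'   of total radii (mm).
#' @param bz_radii Border-zone radii (mm).
#' @return A tibble with one row per setup: `setup_id`, `subject`,
#'   `segment`, `total_radius`, `bz_radius`.
#' @examples
#' grid <- enumerate_study_grid(
#'   subjects = c("K-like", "D-like", "VM-like"),
#'   segments = 1:17,
#'   radii_per_subject = list("K-like" = c(5, 10, 15, 20, 25),
#'                            "D-like" = c(5, 10, 15, 20, 25),
#'                            "VM-like" = c(10, 15, 20, 25, 30)),
#'   bz_radii = c(2.8, 4.8, 9.6))
#' nrow(grid)  # 765
#' @export
enumerate_study_grid <- function(subjects, segments, radii_per_subject,
                                 bz_radii) {
  if (!length(subjects) || !length(segments) || !length(bz_radii)) {
    stop("subjects, segments and bz_radii must be nonempty", call. = FALSE)
  }
  rows <- purrr::map_dfr(subjects, function(su) {
    radii <- radii_per_subject[[su]]
    if (is.null(radii) || !length(radii)) {
      stop("no radii listed for subject ", su, call. = FALSE)
    }
    tidyr::expand_grid(subject = su, segment = as.integer(segments),
                       bz_radius = bz_radii, total_radius = radii)
  })
  rows <- dplyr::mutate(rows,
                        setup_id = sprintf("%s_s%02d_bz%g_r%g", .data$subject,
                                           .data$segment, .data$bz_radius,
                                           .data$total_radius),
                        .before = 1)
  rows
}
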