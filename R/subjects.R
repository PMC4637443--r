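#' Define a synthetic subject
#'
#' A subject bundles the parametric anatomy of one virtual individual: the
#' left-ventricular half-ellipsoid dimensions, wall thicknesses at base and
#' apex, a cylindrical torso, and the placement of the heart inside it.
#' Three default subjects ([default_subjects()]) span the inter-individual
#' variation (wall thickness, heart position and orientation, torso size)
#' that the study design requires.
#'
#' Coordinates are millimetres throughout. The torso is a cylinder with its
#' axis along body z (feet to head), x towards the patient's left and y
#' anterior. The heart is built in a local frame (apex towards local -z)
#' and placed in the torso by `heart_center_offset` (position of the LV
#' base center) and `heart_orientation` (unit direction the apex points to,
#' base-to-apex, in body coordinates).
#'
#' @param name Identifier, e.g. `"K-like"`.
#' @param lv_long_axis Epicardial apex-to-base length of the LV (mm).
#' @param lv_short_axis Endocardial equatorial semi-axis of the LV (mm).
#' @param wall_thickness_base,wall_thickness_apex LV wall thickness at the
#'   base (equatorial) and at the apex (mm).
#' @param rv_wall_thickness Right-ventricular free-wall thickness (mm).
#' @param torso_radius,torso_height Cylindrical torso dimensions (mm).
#' @param heart_center_offset Numeric length-3, body-frame position of the
#'   LV base center (mm).
#' @param heart_orientation Numeric length-3, base-to-apex direction of the
#'   LV long axis in body coordinates (normalized internally).
#' @param include_rv Build the right-ventricular crescent? Toy geometries
#'   for testing may switch it off.
#' @param rng_seed Integer seed controlling the (deterministic) azimuthal
#'   offset of the body-surface electrode lattice.
#' @return An object of class `subject_spec` (a named list).
#' @examples
#' spec <- subject_spec("toy", lv_long_axis = 35, lv_short_axis = 25,
#'                      wall_thickness_base = 10, wall_thickness_apex = 10,
#'                      include_rv = FALSE)
#' @export
subject_spec <- function(name,
                         lv_long_axis = 85,
                         lv_short_axis = 25,
                         wall_thickness_base = 10,
                         wall_thickness_apex = 8,
                         rv_wall_thickness = 5,
                         torso_radius = 175,
                         torso_height = 750,
                         heart_center_offset = c(25, 30, 110),
                         heart_orientation = c(0.6, 0.35, -0.72),
                         include_rv = TRUE,
                         rng_seed = 1L) {
  lens <- c(lv_long_axis = lv_long_axis, lv_short_axis = lv_short_axis,
            wall_thickness_base = wall_thickness_base,
            wall_thickness_apex = wall_thickness_apex,
            rv_wall_thickness = rv_wall_thickness,
            torso_radius = torso_radius, torso_height = torso_height)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("all subject lengths must be positive and finite", call. = FALSE)
  }
  if (wall_thickness_base >= lv_short_axis || wall_thickness_apex >= lv_short_axis) {
    stop("wall thickness must be smaller than the LV short axis", call. = FALSE)
  }
  if (wall_thickness_apex >= lv_long_axis) {
    stop("degenerate geometry: endocardium would lie outside the epicardium",
         call. = FALSE)
  }
  structure(list(
    name = as.character(name),
    lv_long_axis = lv_long_axis,
    lv_short_axis = lv_short_axis,
    wall_thickness_base = wall_thickness_base,
    wall_thickness_apex = wall_thickness_apex,
    rv_wall_thickness = rv_wall_thickness,
    torso_radius = torso_radius,
    torso_height = torso_height,
    heart_center_offset = as.numeric(heart_center_offset),
    heart_orientation = as.numeric(heart_orientation) /
      sqrt(sum(as.numeric(heart_orientation)^2)),
    include_rv = isTRUE(include_rv),
    rng_seed = as.integer(rng_seed)
  ), class = "subject_spec")
}

#' The three default synthetic subjects
#'
#' Stand-ins for a small virtual population: "VM-like" has the thickest
#' ventricular wall (and therefore supports the largest ischemia radii, up
#' to 30 mm), "K-like" is intermediate, and "D-like" has the thinnest wall
#' and smallest torso. Wall thicknesses (12/10/9 mm at the base) are
#' pairwise different so that inter-subject feature spread is nonzero.
#'
#' @return A named list of three [subject_spec()] objects.
#' @export
default_subjects <- function() {
  list(
    "VM-like" = subject_spec("VM-like",
      lv_long_axis = 90, lv_short_axis = 27,
      wall_thickness_base = 12, wall_thickness_apex = 10,
      torso_radius = 185, torso_height = 780,
      heart_center_offset = c(28, 32, 115),
      heart_orientation = c(0.60, 0.35, -0.72),
      rng_seed = 101L),
    "K-like" = subject_spec("K-like",
      lv_long_axis = 85, lv_short_axis = 25,
      wall_thickness_base = 10, wall_thickness_apex = 8,
      torso_radius = 175, torso_height = 750,
      heart_center_offset = c(25, 30, 110),
      heart_orientation = c(0.62, 0.30, -0.73),
      rng_seed = 202L),
    "D-like" = subject_spec("D-like",
      lv_long_axis = 82, lv_short_axis = 24,
      wall_thickness_base = 9, wall_thickness_apex = 7,
      torso_radius = 165, torso_height = 720,
      heart_center_offset = c(22, 28, 105),
      heart_orientation = c(0.58, 0.38, -0.72),
      rng_seed = 303L)
  )
}

#' @export
print.subject_spec <- function(x, ...) {
  cat("<subject_spec> ", x$name, "\n", sep = "")
  cat("  LV: long axis ", x$lv_long_axis, " mm, endo short axis ",
      x$lv_short_axis, " mm, wall ", x$wall_thickness_base, "/",
      x$wall_thickness_apex, " mm (base/apex)\n", sep = "")
  cat("  torso: r = ", x$torso_radius, " mm, h = ", x$torso_height,
      " mm\n", sep = "")
  invisible(x)
}

# Rotation matrix mapping heart-local axes into the body frame.
# Local +z points from apex to base; the image of local -z is the
# requested apex direction. Local +y (anterior in the heart frame) is
# aligned as closely as possible with body anterior (+y).
heart_rotation <- function(apex_dir) {
  ez <- -apex_dir / sqrt(sum(apex_dir^2))
  ref <- c(0, 1, 0)
  ey <- ref - sum(ref * ez) * ez
  ny <- sqrt(sum(ey^2))
  if (ny < 1e-8) { # apex along body y: fall back to body z as reference
    ref <- c(0, 0, 1)
    ey <- ref - sum(ref * ez) * ez
    ny <- sqrt(sum(ey^2))
  }
  ey <- ey / ny
  ex <- c(ey[2] * ez[3] - ey[3] * ez[2],
          ey[3] * ez[1] - ey[1] * ez[3],
          ey[1] * ez[2] - ey[2] * ez[1])
  cbind(ex, ey, ez, deparse.level = 0)
}
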