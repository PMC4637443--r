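#' Build the voxelized biventricular geometry
#'
#' Constructs a truncated half-ellipsoid left-ventricular shell plus a
#' thinner crescent-shaped right-ventricular shell on a regular voxel grid,
#' together with endo-/epicardial surface masks, a transmural depth
#' coordinate and endocardial stimulus sites. The transmural depth of a
#' voxel is `d_endo / (d_endo + d_epi)` where `d_endo` and `d_epi` are the
#' euclidean distances to the chamber's endocardial and epicardial surface
#' voxels, so it is 0 on the endocardium and 1 on the epicardium.
#'
#' The heart is built in a local frame (grid coordinates, mm, all
#' non-negative; voxel index = floor(coord / voxel_size), 0-based) with the
#' apex towards -z and the base plane normal to +z. The placement in the
#' torso is kept as a rigid transform in `$transform`.
#'
#' @param spec A [subject_spec()].
#' @param voxel_size Edge length of the cubic voxels (mm, at most 2).
#'   1 mm is the accuracy default; 2 mm is the fast mode used for full
#'   study sweeps.
#' @return An object of class `voxel_heart`: a list with `coords`
#'   (0-based integer voxel indices, myocardium only), `chamber`
#'   (`"LV"`/`"RV"`), `depth`, `endo_surface`, `epi_surface`, `aha`
#'   (filled by [assign_aha_segments()]), `stimulus` (voxel indices and
#'   delays in ms), grid metadata and the rigid body transform.
#' @seealso [assign_aha_segments()], [place_electrodes()]
#' @export
build_ventricles <- function(spec, voxel_size = 1) {
  stopifnot(inherits(spec, "subject_spec"))
  if (!is.numeric(voxel_size) || voxel_size <= 0 || voxel_size > 2) {
    stop("voxel_size must be in (0, 2] mm", call. = FALSE)
  }
  vs <- voxel_size
  a_endo <- spec$lv_short_axis
  a_epi <- a_endo + spec$wall_thickness_base
  c_epi <- spec$lv_long_axis
  c_endo <- c_epi - spec$wall_thickness_apex
  if (c_endo <= 0 || a_epi <= a_endo) {
    stop("degenerate geometry: epicardium does not enclose the endocardium",
         call. = FALSE)
  }

  # RV ellipsoids, relative to the LV base center (local frame, mm);
  # the crescent arises from carving the LV epicardial region out of a
  # laterally shifted, shorter shell.
  rvw <- spec$rv_wall_thickness
  rv_ctr <- c(-0.52 * a_epi, 0, 0)
  rv_a <- c(1.15 * a_epi, 0.92 * a_epi, 0.72 * c_epi)   # endocardial semi-axes
  rv_b <- rv_a + rvw                                    # epicardial semi-axes
  rv_zcut <- -0.80 * c_epi                              # RV does not reach the apex

  # local-frame bounding box (relative to base center) with 2-voxel margin
  m <- 2 * vs
  if (spec$include_rv) {
    xlim <- c(min(-a_epi, rv_ctr[1] - rv_b[1]) - m, a_epi + m)
    ylim <- c(min(-a_epi, rv_ctr[2] - rv_b[2]) - m,
              max(a_epi, rv_ctr[2] + rv_b[2]) + m)
  } else {
    xlim <- c(-a_epi - m, a_epi + m)
    ylim <- c(-a_epi - m, a_epi + m)
  }
  zlim <- c(-c_epi - m, 0 + m)
  origin <- c(xlim[1], ylim[1], zlim[1])          # local-frame position of grid corner
  dims <- as.integer(ceiling(c(diff(xlim), diff(ylim), diff(zlim)) / vs))
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  base_center <- -origin                          # base center in grid coords (mm)

  cx <- (seq_len(nx) - 0.5) * vs - base_center[1]
  cy <- (seq_len(ny) - 0.5) * vs - base_center[2]
  cz <- (seq_len(nz) - 0.5) * vs - base_center[3]
  X <- array(rep(cx, times = ny * nz), dims)
  Y <- array(rep(rep(cy, each = nx), times = nz), dims)
  Z <- array(rep(cz, each = nx * ny), dims)

  rho <- function(x, y, z, a, b, cc) (x / a)^2 + (y / b)^2 + (z / cc)^2
  below <- Z <= 0
  in_lv_endo <- rho(X, Y, Z, a_endo, a_endo, c_endo) < 1 & below
  in_lv_epi <- rho(X, Y, Z, a_epi, a_epi, c_epi) < 1 & below
  lv_myo <- in_lv_epi & !in_lv_endo
  lv_cav <- in_lv_endo

  if (spec$include_rv) {
    in_rv_endo <- rho(X - rv_ctr[1], Y - rv_ctr[2], Z - rv_ctr[3],
                      rv_a[1], rv_a[2], rv_a[3]) < 1 & below & Z >= rv_zcut
    in_rv_epi <- rho(X - rv_ctr[1], Y - rv_ctr[2], Z - rv_ctr[3],
                     rv_b[1], rv_b[2], rv_b[3]) < 1 & below & Z >= rv_zcut - rvw
    rv_myo <- in_rv_epi & !in_rv_endo & !in_lv_epi
    rv_cav <- in_rv_endo & !in_lv_epi
  } else {
    rv_myo <- rv_cav <- array(FALSE, dims)
  }

  # voxel class array: 0 exterior, 1 LV myo, 2 RV myo, 3 LV cavity,
  # 4 RV cavity, 5 above the base plane (excluded from epicardial contact
  # so that the basal cut is not labeled epicardium)
  cls <- array(0L, dims)
  cls[Z > 0] <- 5L
  cls[lv_cav] <- 3L
  cls[rv_cav] <- 4L
  cls[lv_myo] <- 1L
  cls[rv_myo] <- 2L

  # keep only the largest 26-connected component per chamber
  for (ch in c(1L, 2L)) {
    idx <- which(cls == ch)
    if (!length(idx)) next
    co <- arrayInd(idx, dims) - 1L
    lab <- cpp_components(co)
    keep <- lab == which.max(tabulate(lab))
    cls[idx[!keep]] <- 0L
  }

  nb6 <- function(arr, pad) {
    # list of 6 face-neighbor class arrays, out-of-range treated as `pad`
    out <- vector("list", 6)
    shift1 <- function(a, d, k) {
      r <- array(pad, dims)
      if (d == 1) {
        if (k == 1) r[1:(nx - 1), , ] <- a[2:nx, , ] else r[2:nx, , ] <- a[1:(nx - 1), , ]
      } else if (d == 2) {
        if (k == 1) r[, 1:(ny - 1), ] <- a[, 2:ny, ] else r[, 2:ny, ] <- a[, 1:(ny - 1), ]
      } else {
        if (k == 1) r[, , 1:(nz - 1)] <- a[, , 2:nz] else r[, , 2:nz] <- a[, , 1:(nz - 1)]
      }
      r
    }
    n <- 0
    for (d in 1:3) for (k in 1:2) { n <- n + 1; out[[n]] <- shift1(arr, d, k) }
    out
  }
  nbs <- nb6(cls, 0L)
  any_nb <- function(vals) {
    acc <- array(FALSE, dims)
    for (nb in nbs) {
      hit <- array(match(nb, vals, nomatch = 0L) > 0L, dims)
      acc <- acc | hit
    }
    acc
  }

  endo_lv <- cls == 1L & any_nb(3L)
  epi_lv <- cls == 1L & any_nb(c(0L, 2L, 4L))
  endo_rv <- cls == 2L & any_nb(4L)
  epi_rv <- cls == 2L & any_nb(0L)
  # a voxel cannot be both surfaces (can happen if the RV wall pinches to
  # one voxel at coarse resolution): treat it as interior wall
  pinch <- (endo_lv & epi_lv) | (endo_rv & epi_rv)
  endo_lv[pinch] <- epi_lv[pinch] <- endo_rv[pinch] <- epi_rv[pinch] <- FALSE

  myo_idx <- which(cls == 1L | cls == 2L)
  if (!length(myo_idx)) stop("degenerate geometry: no myocardial voxels", call. = FALSE)
  coords <- arrayInd(myo_idx, dims) - 1L
  chamber <- ifelse(cls[myo_idx] == 1L, "LV", "RV")
  centers <- (coords + 0.5) * vs            # grid coordinates, mm

  depth <- numeric(length(myo_idx))
  endo_surface <- myo_idx %in% which(endo_lv | endo_rv)
  epi_surface <- myo_idx %in% which(epi_lv | epi_rv)
  for (ch in c("LV", "RV")) {
    sel <- chamber == ch
    if (!any(sel)) next
    en <- centers[sel & endo_surface, , drop = FALSE]
    ep <- centers[sel & epi_surface, , drop = FALSE]
    if (nrow(en) == 0 || nrow(ep) == 0) {
      stop("degenerate geometry: missing ", ch, " surface", call. = FALSE)
    }
    d_en <- cpp_nearest_dist(centers[sel, , drop = FALSE], en)
    d_ep <- cpp_nearest_dist(centers[sel, , drop = FALSE], ep)
    depth[sel] <- d_en / (d_en + d_ep)
  }

  heart <- structure(list(
    voxel_size = vs,
    dims = dims,
    coords = coords,
    chamber = chamber,
    depth = depth,
    endo_surface = endo_surface,
    epi_surface = epi_surface,
    aha = rep(NA_integer_, length(myo_idx)),
    apex_base_axis = c(0, 0, 1),
    base_center = base_center,
    lv_geom = list(a_endo = a_endo, a_epi = a_epi,
                   c_endo = c_endo, c_epi = c_epi),
    cavity_z_min = if (any(lv_cav)) min(Z[lv_cav]) else -c_endo,
    transform = list(rotation = heart_rotation(spec$heart_orientation),
                     offset = spec$heart_center_offset),
    spec = spec,
    stimulus = NULL
  ), class = "voxel_heart")
  heart$stimulus <- default_stimulus_sites(heart)
  heart
}

# Voxel centers, in the heart-local grid frame or rotated+translated into
# the body frame (mm).
#' Voxel center positions of a heart
#' @param heart A [build_ventricles()] result.
#' @param frame `"local"` (grid) or `"body"` (torso) coordinates.
#' @return Numeric matrix, one row per myocardial voxel (mm).
#' @export
voxel_positions <- function(heart, frame = c("local", "body")) {
  frame <- match.arg(frame)
  p <- (heart$coords + 0.5) * heart$voxel_size
  if (frame == "local") return(p)
  rel <- sweep(p, 2, heart$base_center)
  t(heart$transform$rotation %*% t(rel)) +
    matrix(heart$transform$offset, nrow(p), 3, byrow = TRUE)
}

# ~10 early-activation sites on the LV/RV endocardium emulating the
# endocardial stimulation (Purkinje) system; delays in ms after beat start.
# Sites are the endocardial surface voxels nearest to fixed analytic
# anchors on the endocardial ellipsoids; delays span 10-30 ms so the first
# five saved frames (0-8 ms) are strictly diastolic.
default_stimulus_sites <- function(heart) {
  g <- heart$lv_geom
  anchor_lv <- function(theta_deg, s) {
    z <- -g$c_endo * (1 - s)
    r <- g$a_endo * sqrt(max(0, 1 - (z / g$c_endo)^2))
    th <- theta_deg * pi / 180
    c(r * cos(th), r * sin(th), z)
  }
  lv_anchors <- rbind(
    anchor_lv(180, 0.35), anchor_lv(180, 0.65),  # septal
    anchor_lv(90, 0.50),                         # anterior
    anchor_lv(270, 0.50),                        # inferior
    anchor_lv(0, 0.50),                          # lateral
    anchor_lv(90, 0.15), anchor_lv(270, 0.15),   # apical
    anchor_lv(0, 0.85)                           # basal lateral
  )
  lv_delays <- c(10, 12, 14, 16, 18, 14, 16, 24)
  centers <- voxel_positions(heart, "local")
  rel <- sweep(centers, 2, heart$base_center)
  pick <- function(anchors, sel) {
    vapply(seq_len(nrow(anchors)), function(i) {
      cand <- which(sel)
      d <- sqrt(rowSums(sweep(rel[cand, , drop = FALSE], 2, anchors[i, ])^2))
      cand[which.min(d)]
    }, integer(1))
  }
  lv_sel <- heart$endo_surface & heart$chamber == "LV"
  idx <- pick(lv_anchors, lv_sel)
  delays <- lv_delays
  if (any(heart$chamber == "RV")) {
    rv_sel <- heart$endo_surface & heart$chamber == "RV"
    if (any(rv_sel)) {
      rv_anchors <- rbind(c(-0.9 * g$a_epi, 8, -0.35 * g$c_epi),
                          c(-0.9 * g$a_epi, -8, -0.5 * g$c_epi))
      idx <- c(idx, pick(rv_anchors, rv_sel))
      delays <- c(delays, 20, 22)
    }
  }
  keep <- !duplicated(idx)
  list(index = idx[keep], delay = delays[keep])
}

#' Assign AHA 17-segment labels to the left ventricle
#'
#' Divides the LV along its long axis into basal, mid and apical thirds
#' plus an apex cap (the portion below the endocardial cavity), and splits
#' the basal and mid rings into 6 circumferential sectors and the apical
#' ring into 4, following the standard numbering (1 = basal anterior, ...,
#' 17 = apex). Labels are computed in the heart-local frame, so they are
#' invariant under rigid placement of the scene.
#'
#' @param heart A `voxel_heart`.
#' @return The heart with its `$aha` field filled (LV voxels only).
#' @export
assign_aha_segments <- function(heart) {
  stopifnot(inherits(heart, "voxel_heart"))
  lv <- heart$chamber == "LV"
  rel <- sweep(voxel_positions(heart, "local"), 2, heart$base_center)
  z <- rel[lv, 3]
  z_cav <- heart$cavity_z_min
  if (abs(z_cav) < 3 * heart$voxel_size) {
    stop("LV too short to form basal/mid/apical rings", call. = FALSE)
  }
  u <- (z - z_cav) / (0 - z_cav)           # 0 at cavity apex, 1 at base
  phi <- atan2(rel[lv, 2], rel[lv, 1]) * 180 / pi
  phi <- (phi + 360) %% 360                # 0 = lateral, 90 = anterior, 180 = septal
  seg <- integer(length(z))
  cap <- u < 0
  seg[cap] <- 17L
  ring6 <- function(p) 1L + as.integer(floor(((p - 60) %% 360) / 60))
  ring4 <- function(p) 13L + as.integer(floor(((p - 45) %% 360) / 90))
  api <- !cap & u < 1 / 3
  mid <- !cap & u >= 1 / 3 & u < 2 / 3
  bas <- !cap & u >= 2 / 3
  seg[api] <- ring4(phi[api])
  seg[mid] <- ring6(phi[mid]) + 6L
  seg[bas] <- ring6(phi[bas])
  heart$aha[lv] <- seg
  heart$aha[!lv] <- NA_integer_
  heart
}

#' @export
print.voxel_heart <- function(x, ...) {
  cat("<voxel_heart> ", x$spec$name, ": ", nrow(x$coords),
      " myocardial voxels @ ", x$voxel_size, " mm (LV ",
      sum(x$chamber == "LV"), ", RV ", sum(x$chamber == "RV"), ")\n", sep = "")
  if (!all(is.na(x$aha))) cat("  AHA segments assigned\n")
  cat("  stimulus sites: ", length(x$stimulus$index), ", delays ",
      min(x$stimulus$delay), "-", max(x$stimulus$delay), " ms\n", sep = "")
  invisible(x)
}
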