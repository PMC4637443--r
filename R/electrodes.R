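#' Place torso electrodes and define the clinical lead systems
#'
#' Samples the lateral torso surface quasi-uniformly with a Fibonacci
#' lattice (the body-surface-potential-map grid) and adds the standard
#' electrodes at deterministic positions: RA/LA at shoulder level, LL low
#' left, V1-V6 along the precordium and V3R-V6R mirrored across the
#' sagittal plane. Lead definitions cover the limb leads I, II, III, the
#' augmented leads aVR, aVL, aVF, the precordial leads V1-V6, the
#' right-sided leads V3R-V6R and one unipolar lead per lattice electrode,
#' all unipolars referenced against the Wilson central terminal
#' WCT = (RA + LA + LL) / 3.
#'
#' @param spec A [subject_spec()]; the torso cylinder and the lattice seed
#'   come from it.
#' @param n_bspm Number of lattice electrodes (>= 32). The default 600
#'   yields a mean inter-electrode spacing of about 4 cm on the default
#'   torso.
#' @return An object of class `electrode_set`: `positions` (body-frame mm),
#'   `names`, `standard_map` (named indices of RA, LA, LL, V1-V6,
#'   V3R-V6R), `lead_def` (tibble lead/electrode/coefficient) and
#'   `bspm_names`.
#' @export
place_electrodes <- function(spec, n_bspm = 600) {
  stopifnot(inherits(spec, "subject_spec"))
  if (n_bspm < 32) stop("n_bspm must be at least 32", call. = FALSE)
  R <- spec$torso_radius
  H <- spec$torso_height

  # position on the cylinder: alpha = 0 anterior, positive towards the
  # patient's left; z along the body axis
  cyl <- function(alpha_deg, z) {
    a <- alpha_deg * pi / 180
    c(R * sin(a), R * cos(a), z)
  }
  zs <- 0.45 * H    # shoulder level
  zl <- -0.45 * H   # lower torso
  hb <- spec$heart_center_offset[3]  # heart base height
  std <- rbind(
    RA = cyl(-95, zs), LA = cyl(95, zs), LL = cyl(30, zl),
    V1 = cyl(-10, hb + 10), V2 = cyl(10, hb + 10), V3 = cyl(25, hb - 10),
    V4 = cyl(40, hb - 25), V5 = cyl(62, hb - 25), V6 = cyl(85, hb - 25)
  )
  # right-sided Wilson electrodes: V3-V6 mirrored across the sagittal plane
  mirr <- std[c("V3", "V4", "V5", "V6"), , drop = FALSE]
  mirr[, 1] <- -mirr[, 1]
  rownames(mirr) <- c("V3R", "V4R", "V5R", "V6R")

  # Fibonacci lattice on the lateral cylinder surface; the subject seed
  # fixes a deterministic azimuthal offset
  i <- seq_len(n_bspm) - 1
  golden <- 360 * (1 - 2 / (1 + sqrt(5)))
  off <- (spec$rng_seed %% 360)
  alpha <- (i * golden + off) %% 360 - 180
  zz <- -0.48 * H + (i + 0.5) / n_bspm * 0.96 * H
  bspm <- t(vapply(seq_len(n_bspm), function(k) cyl(alpha[k], zz[k]),
                   numeric(3)))
  bspm_names <- sprintf("B%03d", seq_len(n_bspm))
  rownames(bspm) <- bspm_names

  positions <- rbind(std, mirr, bspm)
  names_all <- rownames(positions)
  standard_map <- stats::setNames(match(c(rownames(std), rownames(mirr)),
                                        names_all),
                                  c(rownames(std), rownames(mirr)))

  unipolar_row <- function(lead, el) {
    tibble::tibble(lead = lead,
                   electrode = c(el, "RA", "LA", "LL"),
                   coefficient = c(1, -1 / 3, -1 / 3, -1 / 3))
  }
  lead_def <- dplyr::bind_rows(
    tibble::tibble(lead = "I", electrode = c("LA", "RA"), coefficient = c(1, -1)),
    tibble::tibble(lead = "II", electrode = c("LL", "RA"), coefficient = c(1, -1)),
    tibble::tibble(lead = "III", electrode = c("LL", "LA"), coefficient = c(1, -1)),
    tibble::tibble(lead = "aVR", electrode = c("RA", "LA", "LL"),
                   coefficient = c(1, -0.5, -0.5)),
    tibble::tibble(lead = "aVL", electrode = c("LA", "RA", "LL"),
                   coefficient = c(1, -0.5, -0.5)),
    tibble::tibble(lead = "aVF", electrode = c("LL", "RA", "LA"),
                   coefficient = c(1, -0.5, -0.5)),
    purrr::map_dfr(c(paste0("V", 1:6), rownames(mirr), bspm_names),
                   function(e) unipolar_row(e, e))
  )

  structure(list(
    positions = positions,
    names = names_all,
    standard_map = standard_map,
    bspm_names = bspm_names,
    lead_def = lead_def,
    torso = list(radius = R, height = H),
    subject = spec$name
  ), class = "electrode_set")
}

# Dense lead matrix (lead x electrode) from the long lead-definition table.
lead_matrix <- function(electrodes) {
  ld <- electrodes$lead_def
  leads <- unique(ld$lead)
  M <- matrix(0, length(leads), length(electrodes$names),
              dimnames = list(leads, electrodes$names))
  M[cbind(match(ld$lead, leads), match(ld$electrode, electrodes$names))] <-
    ld$coefficient
  M
}

# Lead names of each acquisition scenario.
scenario_leads <- function(electrodes, scenario, extra_electrode = NULL) {
  limb <- c("I", "II", "III", "aVR", "aVL", "aVF")
  twelve <- c(limb, paste0("V", 1:6))
  switch(scenario,
    "3-channel" = limb,
    "12-lead" = twelve,
    "12+R" = c(twelve, c("V3R", "V4R", "V5R", "V6R")),
    "12+1" = {
      if (is.null(extra_electrode)) {
        stop("scenario 12+1 requires an extra electrode", call. = FALSE)
      }
      c(twelve, extra_electrode)
    },
    "BSPM" = c(twelve, c("V3R", "V4R", "V5R", "V6R"), electrodes$bspm_names),
    stop("unknown scenario: ", scenario, call. = FALSE)
  )
}

#' @export
print.electrode_set <- function(x, ...) {
  cat("<electrode_set> ", length(x$names), " electrodes (",
      length(x$bspm_names), " BSPM + standard) on torso r = ",
      x$torso$radius, " mm\n", sep = "")
  invisible(x)
}

#' Export an electrode set to CSV
#'
#' Writes two plain-text tables: electrode positions (`name, x, y, z`, mm)
#' and lead definitions (`lead, electrode, coefficient`).
#'
#' @param electrodes An `electrode_set`.
#' @param positions_path,leads_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_electrodes_csv <- function(electrodes, positions_path, leads_path) {
  pos <- tibble::tibble(name = electrodes$names,
                        x = electrodes$positions[, 1],
                        y = electrodes$positions[, 2],
                        z = electrodes$positions[, 3])
  readr::write_csv(pos, positions_path)
  readr::write_csv(electrodes$lead_def, leads_path)
  invisible(c(positions_path, leads_path))
}
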