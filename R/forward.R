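#' Lead-field (gain) matrix of the equivalent-dipole forward model
#'
#' Infinite homogeneous volume conductor: the potential at electrode `e`
#' of a current dipole `p` at voxel `v` is
#' `phi = p . (r_e - r_v) / (4 pi sigma |r_e - r_v|^3)`.
#' The gain is returned as an electrodes x (3 voxels) matrix with the
#' three dipole components of each voxel in consecutive columns, so that
#' surface potentials are a single matrix product with the dipole movie.
#'
#' @param heart A `voxel_heart` (voxel positions are taken in the body
#'   frame).
#' @param electrodes An `electrode_set`.
#' @param sigma Bulk conductivity (S/m).
#' @return Numeric matrix, `length(electrodes$names)` x `3 * n_voxels`.
#' @export
lead_field <- function(heart, electrodes, sigma = 0.2) {
  stopifnot(inherits(heart, "voxel_heart"), inherits(electrodes, "electrode_set"))
  pos_v <- voxel_positions(heart, "body")
  pos_e <- electrodes$positions
  n_e <- nrow(pos_e); n_v <- nrow(pos_v)
  G <- matrix(0, n_e, 3 * n_v)
  for (e in seq_len(n_e)) {
    d <- sweep(pos_v, 2, pos_e[e, ], "-") * -1   # r_e - r_v
    r2 <- rowSums(d^2)
    if (any(r2 < (0.1 * heart$voxel_size)^2)) {
      stop("electrode coincides with a voxel center", call. = FALSE)
    }
    w <- 1 / (4 * pi * sigma * r2^1.5)
    G[e, ] <- as.vector(t(d * w))
  }
  rownames(G) <- electrodes$names
  G
}

# Spatial gradient of a voxel-sampled scalar movie (central differences
# where both face neighbours exist, one-sided at surfaces, zero where the
# voxel is isolated along an axis), per mm.
tmv_gradient <- function(heart, tmv) {
  co <- heart$coords
  n <- nrow(co)
  dims <- heart$dims
  key <- function(m) m[, 1] + dims[1] * (m[, 2] + dims[2] * m[, 3])
  keys <- key(co)
  axis_grad <- function(ax) {
    off <- c(0L, 0L, 0L); off[ax] <- 1L
    kp <- key(sweep(co, 2, off, "+"))
    km <- key(sweep(co, 2, off, "-"))
    ip <- match(kp, keys); im <- match(km, keys)
    has_p <- !is.na(ip); has_m <- !is.na(im)
    ip[!has_p] <- seq_len(n)[!has_p]
    im[!has_m] <- seq_len(n)[!has_m]
    span <- pmax(has_p + has_m, 1L) * heart$voxel_size
    (tmv[ip, , drop = FALSE] - tmv[im, , drop = FALSE]) / span
  }
  list(x = axis_grad(1), y = axis_grad(2), z = axis_grad(3))
}

#' Compute body-surface signals from a TMV movie
#'
#' Per-voxel equivalent dipole `p_v(t) = -sigma_i * grad TMV` (central
#' differences on the voxel grid), summed through the lead field, then
#' mapped to clinical leads (bipolar/augmented limb leads and unipolar
#' leads against the Wilson central terminal), scaled to microvolts by the
#' calibration factor and baseline-corrected by subtracting the mean of
#' the first five (pre-stimulus, diastolic) frames of each lead.
#'
#' The dipole components of the heart's voxels are rotated into the body
#' frame before the gain is applied.
#'
#' @param movie A [build_tmv_movie()] result.
#' @param gain A [lead_field()] matrix.
#' @param heart The `voxel_heart`.
#' @param electrodes The `electrode_set` the gain was built with.
#' @param scale Calibration factor mapping model units to microvolts
#'   (see [calibrate_gain()]); 1 keeps raw model units.
#' @param sigma_i Intracellular conductivity (S/m).
#' @param baseline_correct Subtract the diastolic baseline?
#' @return An `ecg_record`: `signals` (lead x frame matrix, uV),
#'   `times` (ms), `lead_names`, `scenario_tag = "BSPM"` (all leads),
#'   `baseline_corrected`.
#' @export
compute_bspm <- function(movie, gain, heart, electrodes, scale = 1,
                         sigma_i = 0.1, baseline_correct = TRUE) {
  stopifnot(inherits(movie, "tmv_movie"))
  n <- nrow(heart$coords)
  if (ncol(gain) != 3 * n || nrow(movie$tmv) != n) {
    stop("gain, movie and heart shapes do not match", call. = FALSE)
  }
  g <- tmv_gradient(heart, movie$tmv)
  # rotate local-frame dipoles into the body frame
  R <- heart$transform$rotation
  P <- matrix(0, 3 * n, ncol(movie$tmv))
  P[seq(1, 3 * n, by = 3), ] <- R[1, 1] * g$x + R[1, 2] * g$y + R[1, 3] * g$z
  P[seq(2, 3 * n, by = 3), ] <- R[2, 1] * g$x + R[2, 2] * g$y + R[2, 3] * g$z
  P[seq(3, 3 * n, by = 3), ] <- R[3, 1] * g$x + R[3, 2] * g$y + R[3, 3] * g$z
  phi <- gain %*% (-sigma_i * P)           # electrode potentials
  L <- lead_matrix(electrodes)
  sig <- (L %*% phi) * scale
  if (baseline_correct) {
    nb <- min(5L, ncol(sig))
    sig <- sig - rowMeans(sig[, seq_len(nb), drop = FALSE])
  }
  structure(list(signals = sig, times = movie$times,
                 lead_names = rownames(L),
                 frame_interval = movie$frame_interval,
                 scenario_tag = "BSPM",
                 baseline_corrected = baseline_correct),
            class = "ecg_record")
}

#' Calibrate the forward-model amplitude
#'
#' Returns the global factor that scales the physiological (nonischemic)
#' simulation of a subject so that the largest absolute 12-lead QRS
#' amplitude equals `target_uv` microvolts (1.5 mV by default). The same
#' factor is then applied to every ischemic simulation of that subject,
#' making microvolt threshold grids meaningful.
#'
#' @param record_raw An uncalibrated (`scale = 1`) physiological
#'   `ecg_record` containing the 12-lead leads.
#' @param target_uv Target peak amplitude (uV).
#' @return The scalar calibration factor.
#' @export
calibrate_gain <- function(record_raw, target_uv = 1500) {
  twelve <- c("I", "II", "III", "aVR", "aVL", "aVF", paste0("V", 1:6))
  m <- max(abs(record_raw$signals[twelve, ]))
  if (m == 0) stop("cannot calibrate an all-zero record", call. = FALSE)
  target_uv / m
}

#' Extract an acquisition scenario from a full record
#'
#' @param record An `ecg_record` holding all leads.
#' @param scenario One of `"3-channel"`, `"12-lead"`, `"12+R"`, `"12+1"`,
#'   `"BSPM"`.
#' @param electrodes The `electrode_set` (defines the scenario lead sets).
#' @param extra_electrode Lattice electrode name (e.g. `"B123"`), required
#'   for `"12+1"`.
#' @return The `ecg_record` restricted to the scenario's leads, tagged.
#' @export
extract_scenario <- function(record, scenario, electrodes,
                             extra_electrode = NULL) {
  stopifnot(inherits(record, "ecg_record"))
  leads <- scenario_leads(electrodes, scenario, extra_electrode)
  missing <- setdiff(leads, record$lead_names)
  if (length(missing)) {
    stop("record lacks leads: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  record$signals <- record$signals[leads, , drop = FALSE]
  record$lead_names <- leads
  record$scenario_tag <- scenario
  record
}

#' Construct an ECG record from a signal matrix
#'
#' Mainly for tests, fixtures and imported data.
#'
#' @param signals Lead x frame matrix (uV) with row names, or a data frame
#'   of one column per lead.
#' @param times Frame times (ms); default `0, 2, 4, ...`.
#' @param scenario_tag Scenario label.
#' @param baseline_corrected Whether signals are already baseline-free.
#' @return An `ecg_record`.
#' @export
ecg_record <- function(signals, times = NULL, scenario_tag = "custom",
                       baseline_corrected = TRUE) {
  if (is.data.frame(signals)) signals <- t(as.matrix(signals))
  if (is.null(rownames(signals))) {
    rownames(signals) <- paste0("L", seq_len(nrow(signals)))
  }
  if (is.null(times)) times <- seq(0, by = 2, length.out = ncol(signals))
  if (length(times) != ncol(signals)) {
    stop("times must match the number of frames", call. = FALSE)
  }
  dt <- unique(round(diff(times), 10))
  structure(list(signals = signals, times = times,
                 lead_names = rownames(signals),
                 frame_interval = if (length(dt) == 1) dt else NA_real_,
                 scenario_tag = scenario_tag,
                 baseline_corrected = isTRUE(baseline_corrected)),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat("<ecg_record> ", length(x$lead_names), " leads x ", ncol(x$signals),
      " frames (", x$frame_interval, " ms), scenario ", x$scenario_tag,
      if (x$baseline_corrected) ", baseline-corrected" else "", "\n", sep = "")
  invisible(x)
}

#' Write / read an ECG record as CSV
#'
#' Plain-text interchange: first column `time_ms`, one column per lead
#' (microvolts).
#'
#' @param record An `ecg_record`.
#' @param path CSV path.
#' @return `write_ecg_csv()` returns the path invisibly; `read_ecg_csv()`
#'   returns an `ecg_record`.
#' @export
write_ecg_csv <- function(record, path) {
  df <- tibble::as_tibble(t(record$signals))
  df <- dplyr::bind_cols(tibble::tibble(time_ms = record$times), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_ecg_csv
#' @param scenario_tag Scenario label for the loaded record.
#' @export
read_ecg_csv <- function(path, scenario_tag = "custom") {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"time_ms" %in% names(df)) stop("CSV must have a time_ms column", call. = FALSE)
  times <- df$time_ms
  ecg_record(df[setdiff(names(df), "time_ms")], times = times,
             scenario_tag = scenario_tag)
}
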