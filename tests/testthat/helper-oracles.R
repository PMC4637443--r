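# Shared helpers: independent oracles and memoized expensive objects.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

# The reduced full-pipeline study used by several acceptance properties.
fast_study_cached <- function() {
  cached("fast_study", run_study(fast_study_config()))
}

# Shared single-subject pipeline pieces (heart, electrodes, gain,
# calibration and the physiological record) at fast settings.
k_pipeline_cached <- function() {
  cached("k_pipeline", {
    spec <- default_subjects()[["K-like"]]
    heart <- assign_aha_segments(build_ventricles(spec, voxel_size = 2))
    electrodes <- place_electrodes(spec, 200)
    gain <- lead_field(heart, electrodes)
    ep <- ischemia_endpoints()
    act <- compute_activation(heart, cv_field_for_test(heart, 0, ep))
    movie <- build_tmv_movie(act, 0, ep, heart)
    raw <- compute_bspm(movie, gain, heart, electrodes)
    scale <- calibrate_gain(raw)
    physio <- compute_bspm(movie, gain, heart, electrodes, scale = scale)
    list(spec = spec, heart = heart, electrodes = electrodes, gain = gain,
         endpoints = ep, scale = scale, physio = physio)
  })
}

# Conduction-velocity field from zone factor and depth (re-derived here
# so tests do not depend on the unexported internal helper).
cv_field_for_test <- function(heart, zf, endpoints) {
  p <- params_at(rep_len(zf, nrow(heart$coords)), heart$depth, endpoints)
  if (inherits(p, "ap_params")) rep(p$cv, nrow(heart$coords)) else p$cv
}

# Simulate one ischemic beat reusing the cached pipeline.
simulate_setup_cached <- function(segment, total_radius, bz_radius) {
  pl <- k_pipeline_cached()
  setup <- ischemia_setup("K-like", segment, total_radius, bz_radius)
  field <- place_ischemia(pl$heart, setup)
  act <- compute_activation(pl$heart,
                            cv_field_for_test(pl$heart, field$zf, pl$endpoints))
  movie <- build_tmv_movie(act, field, pl$endpoints, pl$heart)
  rec <- compute_bspm(movie, pl$gain, pl$heart, pl$electrodes,
                      scale = pl$scale)
  list(record = rec, field = field)
}

# ---- independent feature oracles (exhaustive loops) ----

oracle_stsd <- function(signals, times) {
  best <- -Inf; best_lead <- NA_character_
  idx <- which(times >= 110 & times <= 158)
  for (l in rownames(signals)) {
    s <- 0
    for (j in idx) s <- s + signals[l, j]
    v <- unname(abs(s / length(idx)))
    if (v > best) { best <- v; best_lead <- l }
  }
  list(value = best, lead = best_lead)
}

oracle_k <- function(signals, times, clip = FALSE) {
  idx <- which(times >= 40 & times <= 320)
  best <- Inf; best_t <- NA_real_
  for (j in idx) {
    env <- -Inf
    for (l in rownames(signals)) {
      v <- unname(signals[l, j])
      if (clip) v <- max(v, 0)
      env <- max(env, abs(v))
    }
    if (env < best) { best <- env; best_t <- times[j] }
  }
  list(time_ms = best_t, value = best)
}

# Random multichannel baseline-corrected record on the standard frame grid.
random_record <- function(n_leads = 5, amp = 100) {
  times <- seq(0, 500, by = 2)
  sig <- matrix(stats::runif(n_leads * length(times), -amp, amp),
                n_leads, length(times))
  rownames(sig) <- paste0("L", seq_len(n_leads))
  ecg_record(sig, times = times)
}

# ---- independent shortest-path (activation) oracle ----

# Plain-R Dijkstra over the 26-neighbour voxel graph; O(n^2), fine for
# the small random grids it is used on.
oracle_activation <- function(coords, cv, voxel_size, stim_idx, stim_delay,
                              clock = 0.1) {
  n <- nrow(coords)
  dist <- rep(Inf, n)
  dist[stim_idx] <- stim_delay
  done <- rep(FALSE, n)
  key <- coords[, 1] * 1e6 + coords[, 2] * 1e3 + coords[, 3]
  for (iter in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    dx <- coords[, 1] - coords[u, 1]
    dy <- coords[, 2] - coords[u, 2]
    dz <- coords[, 3] - coords[u, 3]
    nb <- which(!done & abs(dx) <= 1 & abs(dy) <= 1 & abs(dz) <= 1 &
                  (abs(dx) + abs(dy) + abs(dz) > 0))
    for (v in nb) {
      len <- voxel_size * sqrt(dx[v]^2 + dy[v]^2 + dz[v]^2)
      alt <- dist[u] + len * 0.5 * (1 / cv[u] + 1 / cv[v])
      if (alt < dist[v]) dist[v] <- alt
    }
  }
  ifelse(is.finite(dist), round(dist / clock) * clock, Inf)
}

# Minimal stand-in heart for propagation tests on arbitrary voxel sets.
fake_heart <- function(coords, voxel_size = 1) {
  structure(list(coords = coords, voxel_size = voxel_size,
                 dims = apply(coords, 2, max) + 1L,
                 chamber = rep("LV", nrow(coords)),
                 depth = rep(0.5, nrow(coords)),
                 stimulus = list(index = 1L, delay = 0)),
            class = "voxel_heart")
}

# Small toy heart (no RV) shared across geometry tests.
toy_heart_cached <- function() {
  cached("toy_heart", {
    spec <- subject_spec("toy-sphere", lv_long_axis = 35, lv_short_axis = 25,
                         wall_thickness_base = 10, wall_thickness_apex = 10,
                         include_rv = FALSE)
    assign_aha_segments(build_ventricles(spec, voxel_size = 1))
  })
}
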