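mk_record <- function(leads) {
  # leads: named list of functions time -> uV, evaluated on the 2 ms grid
  times <- seq(0, 500, by = 2)
  sig <- t(vapply(leads, function(f) f(times), numeric(length(times))))
  rownames(sig) <- names(leads)
  ecg_record(sig, times = times)
}

test_that("STSD matches its defining examples", {
  zero <- mk_record(list(A = function(t) 0 * t, B = function(t) 0 * t))
  expect_identical(stsd(zero)$value, 0)

  const <- mk_record(list(A = function(t) ifelse(t >= 110 & t <= 158, 100, 0),
                          B = function(t) 0 * t))
  s <- stsd(const)
  expect_equal(s$value, 100)
  expect_identical(s$lead, "A")

  # alternating +10/-10 over the 25 samples: (13*10 - 12*10)/25 = 0.4
  alt <- mk_record(list(A = function(t) {
    v <- 0 * t
    w <- t >= 110 & t <= 158
    v[w] <- 10 * rep_len(c(1, -1), sum(w))
    v
  }))
  expect_equal(stsd(alt)$value, (13 * 10 - 12 * 10) / 25)
})

test_that("K point and KPD match brute-force toys", {
  zero <- mk_record(list(A = function(t) 0 * t))
  kp <- k_point(zero)
  expect_identical(kp$time_ms, 40)   # flat envelope: earliest-frame tie break
  expect_identical(kp$value, 0)

  # leads A = [5, 2, 7], B = [-3, -4, 1] at 150/152/154 ms, large elsewhere
  toy <- mk_record(list(
    A = function(t) ifelse(t %in% c(150, 152, 154), c(5, 2, 7)[match(t, c(150, 152, 154))],
                           ifelse(t >= 40 & t <= 320, 100, 0)),
    B = function(t) ifelse(t %in% c(150, 152, 154), c(-3, -4, 1)[match(t, c(150, 152, 154))], 0)))
  kp <- k_point(toy, "deviation")
  expect_identical(kp$time_ms, 152)  # envelope [5, 4, 7]: min at middle frame
  expect_identical(kp$value, 4)
  expect_identical(kpd(toy), 4)
  ke <- k_point(toy, "elevation")    # clipped envelope [5, 2, 7]
  expect_identical(ke$value, 2)

  const <- mk_record(list(A = function(t) ifelse(t >= 40 & t <= 320, 31.7, 0)))
  expect_equal(kpd(const), 31.7)
})

test_that("features match exhaustive-loop oracles on random records", {
  set.seed(101)
  for (i in 1:25) {
    rec <- random_record(n_leads = sample(2:8, 1))
    o_s <- oracle_stsd(rec$signals, rec$times)
    s <- stsd(rec)
    expect_equal(s$value, o_s$value, tolerance = 1e-12)
    expect_identical(s$lead, o_s$lead)
    o_d <- oracle_k(rec$signals, rec$times, clip = FALSE)
    kp <- k_point(rec, "deviation")
    expect_equal(kp$value, o_d$value, tolerance = 1e-12)
    expect_identical(kp$time_ms, o_d$time_ms)
    o_e <- oracle_k(rec$signals, rec$times, clip = TRUE)
    expect_equal(k_elevation(rec), o_e$value, tolerance = 1e-12)
  }
})

test_that("stsd and kpd are monotone in the lead set and elevation <= deviation", {
  set.seed(202)
  for (i in 1:20) {
    rec <- random_record(n_leads = 6)
    sub <- rec
    keep <- sample(6, 3)
    sub$signals <- rec$signals[keep, , drop = FALSE]
    sub$lead_names <- rownames(sub$signals)
    expect_gte(stsd(rec)$value, stsd(sub)$value)
    expect_gte(kpd(rec), kpd(sub))
    expect_lte(k_elevation(rec), kpd(rec))
  }
})

test_that("KPD detects alternating ST deviation that STSD misses", {
  rec <- ischsim:::alternating_st_record()
  expect_identical(stsd(rec)$value, 0)
  expect_gte(kpd(rec), 48)
})

test_that("time-shifting the signals shifts the K point and preserves KPD", {
  set.seed(303)
  times <- seq(0, 500, by = 2)
  base <- matrix(stats::runif(3 * length(times), 20, 80), 3)
  base[, times > 320] <- 100  # keep post-window content out of the shifted window
  rownames(base) <- c("A", "B", "C")
  rec <- ecg_record(base, times = times)
  k0 <- k_point(rec)
  shift <- 5L  # frames
  shifted <- cbind(base[, (shift + 1):ncol(base)],
                   matrix(100, 3, shift))  # content moves 5 frames earlier
  rec2 <- ecg_record(shifted, times = times)
  # guard: the shifted K point stays inside the window for this fixture
  if (k0$time_ms - 2 * shift >= 40) {
    k1 <- k_point(rec2)
    expect_identical(k1$time_ms, k0$time_ms - 2 * shift)
    expect_equal(k1$value, k0$value)
  }
})

test_that("per-lead features at the shared K point reproduce the full-set KPD", {
  set.seed(404)
  rec <- random_record(n_leads = 5)
  kp <- k_point(rec)
  vals <- vapply(rec$lead_names, function(l) {
    per_lead_feature(rec, l, kp$time_ms)
  }, numeric(1))
  expect_equal(max(vals), kpd(rec))
  zero <- rec
  zero$signals["L1", ] <- 0
  expect_identical(per_lead_feature(zero, "L1", kp$time_ms), 0)
  expect_error(per_lead_feature(rec, "nope", kp$time_ms), "unknown lead")
})

test_that("feature preconditions are enforced", {
  short <- ecg_record(matrix(1, 1, 20), times = seq(0, 38, by = 2))
  expect_error(stsd(short), "window")
  uncorrected <- ischsim:::toy_ecg_record()
  uncorrected$baseline_corrected <- FALSE
  expect_error(kpd(uncorrected), "baseline")
  coarse <- ecg_record(matrix(1, 1, 101), times = seq(0, 500, by = 5))
  expect_error(stsd(coarse), "2 ms")
})
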