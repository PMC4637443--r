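mk_table <- function(values, scenario = "12-lead", feature = "kpd",
                     subject = "s", segment = 1L, radius = 10,
                     bz = 4.8, transmural = "subendocardial") {
  n <- length(values)
  tibble::tibble(
    setup_id = sprintf("s%03d", seq_len(n)), subject = subject,
    segment = rep_len(segment, n), total_radius = rep_len(radius, n),
    bz_radius = rep_len(bz, n), transmural = rep_len(transmural, n),
    ischemic_fraction = 0.1, scenario = scenario, feature = feature,
    value = values)
}

test_that("detection rate counts setups with the inclusive rule", {
  tab <- mk_table(c(10, 30, 50))
  expect_equal(detection_rate(tab, "12-lead", "kpd", 30), 2 / 3)
  expect_equal(detection_rate(tab, "12-lead", "kpd", 0), 1)
  expect_equal(detection_rate(tab, "12-lead", "kpd", 51), 0)
  expect_error(detection_rate(tab, "12-lead", "kpd", -5), "nonnegative")
  expect_error(detection_rate(tab, "BSPM", "kpd", 10), "no rows")
})

test_that("averaged rate equals brute-force enumeration of the grid", {
  tab <- mk_table(132, feature = "stsd")
  grid <- seq(24, 240, length.out = 54)
  expect_equal(averaged_rate(tab, "12-lead", "stsd", "stsd_grid"),
               sum(grid <= 132) / 54)
  expect_identical(length(threshold_grid("stsd_grid")), 54L)
  expect_identical(length(threshold_grid("kpd_grid")), 36L)
  expect_equal(range(threshold_grid("stsd_grid")), c(24, 240))
  expect_equal(range(threshold_grid("kpd_grid")), c(9, 150))
  # row order does not matter
  tab2 <- mk_table(c(200, 10, 77))
  tab3 <- tab2[c(3, 1, 2), ]
  expect_equal(averaged_rate(tab2, "12-lead", "kpd"),
               averaged_rate(tab3, "12-lead", "kpd"))
  # all values above the top of the grid: rate 1
  expect_equal(averaged_rate(mk_table(c(300, 400), feature = "stsd"),
                             "12-lead", "stsd", "stsd_grid"), 1)
  expect_error(averaged_rate(tab, "12-lead", "stsd", numeric(0)), "empty")
})

test_that("physiological thresholds expose the max and its 1.5x multiple", {
  phys <- mk_table(31.7)
  phys$setup_id <- "physio"
  one <- physiological_threshold(phys, "12-lead", "kpd", "per_subject")
  expect_equal(one$threshold, 31.7)
  expect_equal(one$threshold_1p5, 1.5 * 31.7)
  phys2 <- dplyr::bind_rows(phys, mk_table(12, subject = "t") |>
                              dplyr::mutate(setup_id = "physio"))
  pooled <- physiological_threshold(phys2, "12-lead", "kpd")
  per <- physiological_threshold(phys2, "12-lead", "kpd", "per_subject")
  expect_equal(pooled$threshold, max(per$threshold))
})

test_that("the 80% segment threshold is the lower 20th percentile value", {
  tab <- mk_table(c(10, 20, 30, 40, 50), segment = 4L)
  expect_equal(segment_threshold_80(tab, "12-lead", "kpd", 4), 20)
  expect_equal(detection_rate(tab, "12-lead", "kpd", 20), 4 / 5)
  tab2 <- mk_table(rep(33, 4), segment = 2L)
  expect_equal(segment_threshold_80(tab2, "12-lead", "kpd", 2), 33)
  tab3 <- mk_table(77, segment = 9L)
  expect_equal(segment_threshold_80(tab3, "12-lead", "kpd", 9), 77)
  # brute force over candidate thresholds for a larger draw
  set.seed(9)
  v <- round(stats::runif(23, 5, 200), 1)
  tab4 <- mk_table(v, segment = 6L)
  cand <- sort(v)
  best <- max(cand[vapply(cand, function(tau) mean(v >= tau), numeric(1)) >= 0.8])
  expect_equal(segment_threshold_80(tab4, "12-lead", "kpd", 6), best)
})

test_that("subgroup rates aggregate to the overall rate with setup weights", {
  set.seed(5)
  tab <- dplyr::bind_rows(
    mk_table(stats::runif(6, 0, 200), radius = 5),
    mk_table(stats::runif(9, 0, 200), radius = 15) |>
      dplyr::mutate(setup_id = paste0("b", setup_id)),
    mk_table(stats::runif(5, 0, 200), radius = 25) |>
      dplyr::mutate(setup_id = paste0("c", setup_id)))
  rep_r <- subgroup_report(tab, "radius", "12-lead", "kpd")
  overall <- averaged_rate(tab, "12-lead", "kpd")
  expect_equal(sum(rep_r$rate * rep_r$n_setups) / sum(rep_r$n_setups), overall)
  expect_identical(sum(rep_r$n_setups), 20L)
})

test_that("rates are nondecreasing in radius when features increase with radius", {
  tab <- dplyr::bind_rows(lapply(c(5, 10, 20), function(r) {
    mk_table(r * 4 + c(1, 2, 3), radius = r) |>
      dplyr::mutate(setup_id = paste0("r", r, "_", setup_id))
  }))
  rep_r <- subgroup_report(tab, "radius", "12-lead", "kpd")
  expect_true(all(diff(rep_r$rate[order(rep_r$level)]) >= 0))
})

test_that("the transmurality report splits all setups into two groups", {
  st <- fast_study_cached()
  rep_t <- subgroup_report(st, "transmurality", "12-lead", "kpd")
  expect_setequal(rep_t$level, c("subendocardial", "transmural"))
  expect_identical(sum(rep_t$n_setups), 34L)
})

test_that("electrode optimization picks the decisive electrode (exhaustive oracle)", {
  # construct per-electrode matrices where only one candidate lifts an
  # extra setup above the whole KPD grid
  cand <- sprintf("B%03d", 1:5)
  m <- matrix(5, 4, 5, dimnames = list(sprintf("s%03d", 1:4), cand))
  m[1, ] <- 200          # one setup detected by any electrode
  m[2, "B004"] <- 200    # only B004 adds a second setup
  study <- structure(list(
    table = mk_table(c(5, 5, 5, 5)),
    aux = list(s = list(setup_ids = rownames(m), candidates = cand,
                        plus1 = list(kpd = m, stsd = m, k_elev = m,
                                     physio = NULL),
                        segments = rep(1L, 4))),
    config = NULL), class = "ischemia_study")
  opt <- optimize_additional_electrode(study, "individual")
  expect_identical(opt$electrode, "B004")
  # exhaustive oracle over candidates
  taus <- threshold_grid("kpd_grid")
  rates <- apply(m, 2, function(col) mean(vapply(taus, function(t) mean(col >= t), numeric(1))))
  expect_identical(opt$electrode, names(which.max(rates)))
  expect_equal(opt$avg_rate, max(rates))
  # ties break to the lowest electrode index
  m2 <- m; m2[2, "B004"] <- 5; m2[, ] <- 5
  study$aux$s$plus1$kpd <- m2
  expect_identical(optimize_additional_electrode(study, "individual")$electrode,
                   "B001")
})

test_that("a one-setup study produces one ischemic row per scenario and feature", {
  cfg <- study_config(subjects = default_subjects()["D-like"],
                      segments = 7L,
                      radii_per_subject = list("D-like" = 15),
                      bz_radii = 4.8, voxel_size = 2, n_bspm = 40)
  st <- run_study(cfg)
  isch <- dplyr::filter(st$table, .data$setup_id != "physio")
  counts <- dplyr::count(isch, .data$scenario, .data$feature)
  expect_true(all(counts$n == 1))
  expect_setequal(unique(isch$scenario),
                  c("3-channel", "12-lead", "12+R", "12+1", "BSPM"))
  # physiological rows exist for every scenario
  phys <- dplyr::filter(st$table, .data$setup_id == "physio",
                        .data$feature == "kpd")
  expect_setequal(phys$scenario,
                  c("3-channel", "12-lead", "12+R", "12+1", "BSPM"))
  # exactly one row per key
  expect_false(any(duplicated(
    st$table[, c("setup_id", "scenario", "feature")])))
  g <- glance(st)
  expect_identical(g$n_setups, 1L)
  expect_s3_class(tidy(st), "tbl_df")
})

test_that("individual optimization never trails the common choice per subject", {
  st <- fast_study_cached()
  ind <- optimize_additional_electrode(st, "individual")
  com <- optimize_additional_electrode(st, "common")
  taus <- threshold_grid("kpd_grid")
  for (sname in ind$subject) {
    m <- st$aux[[sname]]$plus1$kpd
    rate_of <- function(el) mean(vapply(taus, function(t) mean(m[, el] >= t), numeric(1)))
    expect_gte(ind$avg_rate[ind$subject == sname], rate_of(com$electrode))
  }
})
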