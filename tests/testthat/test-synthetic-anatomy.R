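test_that("LV shell volume matches the analytic half-ellipsoid-shell oracle", {
  heart <- toy_heart_cached()  # spherical: endo radius 25 mm, wall 10 mm, 1 mm voxels
  v_analytic <- 0.5 * 4 / 3 * pi * (35^3 - 25^3)
  n_expected <- v_analytic / 1^3
  n_lv <- sum(heart$chamber == "LV")
  expect_lt(abs(n_lv - n_expected) / n_expected, 0.10)
})

test_that("transmural depth is 0 on the endocardium and 1 on the epicardium", {
  heart <- toy_heart_cached()
  expect_true(all(heart$depth >= 0 & heart$depth <= 1))
  expect_true(all(heart$depth[heart$endo_surface] == 0))
  expect_true(all(heart$depth[heart$epi_surface] == 1))
  expect_true(all(heart$depth[!heart$endo_surface] > 0))
  expect_true(all(heart$depth[!heart$epi_surface] < 1))
})

test_that("depth increases monotonically along radial rays through the wall", {
  heart <- toy_heart_cached()
  centers <- voxel_positions(heart, "local")
  rel <- sweep(centers, 2, heart$base_center)
  # spherical toy: depth must be non-decreasing in the radial coordinate;
  # sample rays through a set of endocardial voxels
  endo_idx <- which(heart$endo_surface)[c(1, 50, 200, 400)]
  for (i in endo_idx) {
    dir <- rel[i, ] / sqrt(sum(rel[i, ]^2))
    for (step in seq(0, 9, by = 1)) {
      a <- rel[i, ] + step * dir
      b <- rel[i, ] + (step + 1) * dir
      near <- function(p) which.min(colSums((t(rel) - p)^2))
      da <- heart$depth[near(a)]; db <- heart$depth[near(b)]
      expect_gte(db, da - 0.05)
    }
  }
})

test_that("heart construction is deterministic", {
  spec <- subject_spec("det", lv_long_axis = 40, lv_short_axis = 15,
                       wall_thickness_base = 6, wall_thickness_apex = 6,
                       include_rv = FALSE)
  h1 <- build_ventricles(spec, voxel_size = 2)
  h2 <- build_ventricles(spec, voxel_size = 2)
  expect_identical(h1$coords, h2$coords)
  expect_identical(h1$depth, h2$depth)
  expect_identical(h1$stimulus, h2$stimulus)
})

test_that("myocardium is one 26-connected component per chamber", {
  heart <- cached("k_heart_2mm", {
    assign_aha_segments(build_ventricles(default_subjects()[["K-like"]],
                                         voxel_size = 2))
  })
  for (ch in c("LV", "RV")) {
    co <- heart$coords[heart$chamber == ch, , drop = FALSE]
    lab <- ischsim:::cpp_components(co)
    expect_identical(length(unique(lab)), 1L)
  }
})

test_that("AHA labeling partitions the LV with the standard ring structure", {
  heart <- toy_heart_cached()
  lv <- heart$chamber == "LV"
  expect_true(all(!is.na(heart$aha[lv])))
  expect_true(all(is.na(heart$aha[!lv])))
  expect_setequal(sort(unique(heart$aha[lv])), 1:17)

  # apex-cap voxel (lowest along the long axis) is segment 17
  rel <- sweep(voxel_positions(heart, "local"), 2, heart$base_center)
  apex_voxel <- which(lv)[which.min(rel[lv, 3])]
  expect_identical(heart$aha[apex_voxel], 17L)

  # independent per-voxel classifier: axial thirds above the cavity apex,
  # 60 deg sectors with anterior at 90 deg (and 90 deg sectors apically)
  z <- rel[lv, 3]; u <- (z - heart$cavity_z_min) / (0 - heart$cavity_z_min)
  phi <- (atan2(rel[lv, 2], rel[lv, 1]) * 180 / pi + 360) %% 360
  expected <- ifelse(u < 0, 17L,
    ifelse(u >= 2 / 3, 1L + (floor((phi - 60) %% 360 / 60)),
      ifelse(u >= 1 / 3, 7L + (floor((phi - 60) %% 360 / 60)),
        13L + (floor((phi - 45) %% 360 / 90)))))
  expect_identical(heart$aha[lv], as.integer(expected))
})

test_that("AHA labels do not depend on the placement of the heart in the torso", {
  spec1 <- subject_spec("a", lv_long_axis = 40, lv_short_axis = 15,
                        wall_thickness_base = 6, wall_thickness_apex = 6,
                        include_rv = FALSE,
                        heart_center_offset = c(0, 0, 0))
  spec2 <- spec1; spec2$heart_center_offset <- c(40, -20, 120)
  h1 <- assign_aha_segments(build_ventricles(spec1, voxel_size = 2))
  h2 <- assign_aha_segments(build_ventricles(spec2, voxel_size = 2))
  expect_identical(h1$aha, h2$aha)
  expect_identical(h1$coords, h2$coords)
})

test_that("degenerate geometries are rejected", {
  expect_error(subject_spec("bad", lv_short_axis = 10,
                            wall_thickness_base = 12),
               "wall thickness")
  expect_error(subject_spec("bad", torso_radius = -1), "positive")
  # a spec corrupted after construction (endocardium outside the
  # epicardium along the long axis) must still be caught at build time
  spec <- subject_spec("short", lv_long_axis = 35, lv_short_axis = 25,
                       wall_thickness_base = 10, wall_thickness_apex = 10,
                       include_rv = FALSE)
  spec$wall_thickness_apex <- 40
  expect_error(build_ventricles(spec, 1), "epicardium|degenerate")
  expect_error(build_ventricles(spec, 5), "voxel_size")
})

test_that("default subjects have pairwise different wall thicknesses", {
  subs <- default_subjects()
  wt <- vapply(subs, function(s) s$wall_thickness_base, numeric(1))
  expect_identical(length(unique(wt)), 3L)
  expect_identical(unname(which.max(wt)), 1L)  # VM-like thickest
})

test_that("BSPM lattice spacing is close to 4 cm for 600 electrodes", {
  el <- place_electrodes(subject_spec("default"), n_bspm = 600)
  p <- el$positions[el$bspm_names, ]
  nn <- vapply(seq_len(nrow(p)), function(i) {
    min(sqrt(colSums((t(p[-i, , drop = FALSE]) - p[i, ])^2)))
  }, numeric(1))
  expect_lt(abs(mean(nn) - 40) / 40, 0.25)
})

test_that("electrode placement is reproducible and maps every standard electrode", {
  spec <- default_subjects()[["D-like"]]
  e1 <- place_electrodes(spec, 64)
  e2 <- place_electrodes(spec, 64)
  expect_identical(e1, e2)
  std <- c("RA", "LA", "LL", paste0("V", 1:6), "V3R", "V4R", "V5R", "V6R")
  expect_setequal(names(e1$standard_map), std)
  expect_false(any(duplicated(e1$standard_map)))
})

test_that("lead definitions satisfy bipolar/augmented zero-sum and WCT referencing", {
  el <- place_electrodes(subject_spec("default"), 64)
  M <- ischsim:::lead_matrix(el)
  for (lead in c("I", "II", "III", "aVR", "aVL", "aVF")) {
    expect_equal(sum(M[lead, ]), 0)
  }
  # unipolar rows: +1 on the electrode, -1/3 on RA/LA/LL
  expect_equal(unname(M["V2", "V2"]), 1)
  expect_equal(unname(M["V2", c("RA", "LA", "LL")]), rep(-1 / 3, 3))
  # any lead applied to identical potentials at all electrodes gives 0
  const <- rep(2.5, ncol(M))
  expect_equal(max(abs(M %*% const)), 0)
})

test_that("right-sided Wilson electrodes mirror V3-V6 across the sagittal plane", {
  el <- place_electrodes(subject_spec("default"), 64)
  for (v in c("V3", "V4", "V5", "V6")) {
    a <- el$positions[el$standard_map[[v]], ]
    b <- el$positions[el$standard_map[[paste0(v, "R")]], ]
    expect_equal(unname(b), unname(a * c(-1, 1, 1)))
  }
})
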