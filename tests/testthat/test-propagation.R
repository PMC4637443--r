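test_that("a 1-D strip activates at distance over velocity", {
  # 61 voxels of 1 mm: far end is 60 mm from the stimulus at cv 0.6 mm/ms
  coords <- cbind(0:60, 0L, 0L)
  heart <- fake_heart(coords, voxel_size = 1)
  act <- compute_activation(heart, rep(0.6, 61),
                            stimuli = list(index = 1L, delay = 0))
  expect_equal(act$t_act[61], 60 / 0.6, tolerance = 1 / 0.6 / 100)
  expect_equal(act$t_act[1], 0)
  # times are on the 0.1 ms clock
  expect_true(all(abs(act$t_act * 10 - round(act$t_act * 10)) < 1e-6))
})

test_that("activation equals an independent Dijkstra oracle on random grids", {
  set.seed(11)
  for (rep in 1:4) {
    mask <- array(stats::runif(10 * 10 * 10) < 0.7, c(10, 10, 10))
    coords <- arrayInd(which(mask), c(10, 10, 10)) - 1L
    n <- nrow(coords)
    cv <- stats::runif(n, 0.2, 1.2)
    stim <- sample(n, 2)
    delay <- c(0, 5)
    heart <- fake_heart(coords, voxel_size = 1.5)
    got <- compute_activation(heart, cv,
                              stimuli = list(index = stim, delay = delay))
    want <- oracle_activation(coords, cv, 1.5, stim, delay)
    expect_equal(got$t_act, want, tolerance = 1e-9)
  }
})

test_that("multiple stimuli give the elementwise first arrival", {
  coords <- cbind(0:30, 0L, 0L)
  heart <- fake_heart(coords)
  cv <- rep(0.5, 31)
  a1 <- compute_activation(heart, cv, stimuli = list(index = 1L, delay = 0))
  a2 <- compute_activation(heart, cv, stimuli = list(index = 31L, delay = 5))
  both <- compute_activation(heart, cv,
                             stimuli = list(index = c(1L, 31L), delay = c(0, 5)))
  expect_equal(both$t_act, pmin(a1$t_act, a2$t_act))
})

test_that("slowing conduction anywhere never speeds up activation", {
  set.seed(7)
  mask <- array(stats::runif(8^3) < 0.8, c(8, 8, 8))
  coords <- arrayInd(which(mask), c(8, 8, 8)) - 1L
  n <- nrow(coords)
  cv <- stats::runif(n, 0.3, 1)
  heart <- fake_heart(coords)
  base <- compute_activation(heart, cv, stimuli = list(index = 1L, delay = 0))
  slow <- cv
  idx <- sample(n, n %/% 3)
  slow[idx] <- slow[idx] * 0.4
  slowed <- compute_activation(heart, slow, stimuli = list(index = 1L, delay = 0))
  expect_true(all(slowed$t_act >= base$t_act - 1e-9))
})

test_that("the healthy default heart finishes activation within a QRS duration", {
  pl <- k_pipeline_cached()
  act <- compute_activation(pl$heart, cv_field_for_test(pl$heart, 0, pl$endpoints))
  expect_true(all(is.finite(act$t_act)))
  expect_lt(max(act$t_act), 120)
})

test_that("the TMV movie equals direct per-voxel template evaluation", {
  heart <- toy_heart_cached()
  ep <- ischemia_endpoints()
  field <- place_ischemia(heart, ischemia_setup("toy", 7, 12, 4.8))
  act <- compute_activation(heart, cv_field_for_test(heart, field$zf, ep))
  movie <- build_tmv_movie(act, field, ep, heart)
  expect_identical(dim(movie$tmv), c(nrow(heart$coords), 251L))
  set.seed(3)
  for (v in sample(nrow(heart$coords), 25)) {
    p <- params_at(field$zf[v], heart$depth[v], ep)
    expect_equal(movie$tmv[v, ], tmv_course(p, act$t_act[v], movie$times),
                 tolerance = 1e-12)
  }
  # before the earliest stimulus every voxel rests at its own RMV
  # (depolarized inside the ischemic region)
  pre <- which(movie$times < min(heart$stimulus$delay))
  rest <- params_at(field$zf, heart$depth, ep)$rmv
  expect_equal(movie$tmv[, pre],
               matrix(rest, nrow(heart$coords), length(pre)))
  # one frame after complete upstroke the voxel is at plateau level
  v <- 17L
  j <- which(movie$times >= act$t_act[v] + 2)[1]
  p <- params_at(field$zf[v], heart$depth[v], ep)
  expect_gte(movie$tmv[v, j], p$rmv + 0.9 * p$amplitude)
})

test_that("activation is deterministic and requires stimuli", {
  heart <- toy_heart_cached()
  cv <- rep(0.6, nrow(heart$coords))
  a1 <- compute_activation(heart, cv)
  a2 <- compute_activation(heart, cv)
  expect_identical(a1$t_act, a2$t_act)
  expect_error(compute_activation(heart, cv, stimuli = list(index = integer(0))),
               "stimulus")
  expect_error(compute_activation(heart, rep(-1, nrow(heart$coords))),
               "positive")
})
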