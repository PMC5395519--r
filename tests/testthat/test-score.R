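test_that("slope penalties follow the 1/2/4 scheme and multiply pairwise", {
  expect_equal(segment_slope_penalty(-0.1), 1)
  expect_equal(segment_slope_penalty(0), 2)
  expect_equal(segment_slope_penalty(0.1), 4)
  # tolerance band declares near-zero slopes null
  expect_equal(segment_slope_penalty(5e-10), 2)
  expect_equal(segment_slope_penalty(-5e-10), 2)
  expect_error(segment_slope_penalty(NaN), "finite")

  expect_equal(pairwise_smp(-1, -1), 1)
  expect_equal(pairwise_smp(-1, 0), 2)
  expect_equal(pairwise_smp(-1, 1), 4)
  expect_equal(pairwise_smp(0, 0), 4)
  expect_equal(pairwise_smp(0, 1), 8)
  expect_equal(pairwise_smp(1, 1), 16)
})

test_that("the hand-evaluated 3-point score comes out at 1.05", {
  y <- data.frame(iteration = 1:3, n_included_cum = c(2L, 4L, 10L),
                  accuracy_cum = c(1.0, 0.9, 0.8))
  z <- data.frame(iteration = 1:3, n_included_cum = c(2L, 4L, 10L),
                  accuracy_cum = c(0.95, 0.85, 0.75))
  sc <- ad_score(y, z, n_total_y = 10, n_total_z = 10)
  expect_equal(sc$f_added, 0.8)
  expect_equal(sc$segments$summand, c(0.21, 0.63), tolerance = 1e-12)
  expect_equal(sc$score, 1.05, tolerance = 1e-12)
  expect_equal(sc$f_total_coverage, 1)
})

test_that("two identical strictly decreasing curves score exactly 1", {
  for (s in 1:25) {
    cur <- random_decreasing_curve(seed = 900 + s)
    sc <- ad_score(cur, cur)
    expect_equal(sc$score, 1, tolerance = 1e-12)
  }
})

test_that("a constant accuracy offset adds linearly through the gap term", {
  cur <- random_decreasing_curve(seed = 1000, n_iter = 6)
  for (offset in c(0.02, 0.1)) {
    shifted <- cur
    shifted$accuracy_cum <- cur$accuracy_cum - offset
    sc <- ad_score(cur, shifted)
    base <- ad_score(cur, cur)
    # all slopes unchanged, so only the |y - z| coefficient moves the score
    expect_equal(sc$score, base$score + offset, tolerance = 1e-9)
    expect_equal(sc$segments$smp, base$segments$smp)
  }
})

test_that("the score is invariant to the absolute scale of counts", {
  cur <- random_decreasing_curve(seed = 1100, n_iter = 8)
  other <- cur
  other$accuracy_cum <- cur$accuracy_cum * 0.97
  sc1 <- ad_score(cur, other)
  doubled_y <- cur; doubled_z <- other
  doubled_y$n_included_cum <- cur$n_included_cum * 2L
  doubled_z$n_included_cum <- other$n_included_cum * 2L
  attr(doubled_y, "n_total") <- attr(cur, "n_total") * 2L
  attr(doubled_z, "n_total") <- attr(other, "n_total") * 2L
  sc2 <- ad_score(doubled_y, doubled_z)
  expect_equal(sc1$score, sc2$score, tolerance = 1e-12)
})

test_that("flipping a matched falling segment to rising raises the score 16-fold there", {
  y <- data.frame(iteration = 1:4, n_included_cum = c(2L, 5L, 8L, 12L),
                  accuracy_cum = c(0.95, 0.9, 0.85, 0.8))
  base <- ad_score(y, y, n_total_y = 15, n_total_z = 15)
  # flip segment 3 on both curves from falling to rising
  y2 <- y; y2$accuracy_cum <- c(0.95, 0.9, 0.85, 0.92)
  worse <- ad_score(y2, y2, n_total_y = 15, n_total_z = 15)
  expect_equal(worse$segments$smp[3], 16)
  expect_equal(worse$segments$wp[3], base$segments$wp[3] * 16)
  expect_gt(worse$score, base$score)
})

test_that("segments with no added instances contribute nothing", {
  y <- data.frame(iteration = 1:4, n_included_cum = c(3L, 3L, 3L, 9L),
                  accuracy_cum = c(1, 0.9, 0.8, 0.7))
  z <- y; z$accuracy_cum <- c(1, 0.95, 0.85, 0.72)
  sc <- ad_score(y, z, n_total_y = 10, n_total_z = 10)
  expect_equal(sc$segments$wp[1:2], c(0, 0))
  expect_equal(sc$segments$summand[1:2], c(0, 0))
  expect_equal(sc$f_added, (18 - 6) / 20)
})

test_that("leading empty iterations are dropped; degenerate grids error", {
  y <- data.frame(iteration = 1:4, n_included_cum = c(0L, 0L, 2L, 6L),
                  accuracy_cum = c(NA, NA, 1, 0.9))
  z <- data.frame(iteration = 1:4, n_included_cum = c(0L, 1L, 2L, 5L),
                  accuracy_cum = c(NA, 1, 1, 0.8))
  sc <- ad_score(y, z, n_total_y = 8, n_total_z = 8)
  expect_equal(sc$p, 2L)  # iterations 3 and 4 survive
  expect_equal(sc$f_added, ((6 + 5) - (2 + 2)) / 16)

  zz <- data.frame(iteration = 1:2, n_included_cum = c(0L, 0L),
                   accuracy_cum = c(NA_real_, NA_real_))
  expect_error(ad_score(zz, zz, n_total_y = 5, n_total_z = 5),
               "no iteration")
  flat <- data.frame(iteration = 1:3, n_included_cum = c(4L, 4L, 4L),
                     accuracy_cum = c(1, 1, 1))
  expect_error(ad_score(flat, flat, n_total_y = 5, n_total_z = 5),
               "no instance added")
  short_y <- data.frame(iteration = 1:2, n_included_cum = c(1L, 3L),
                        accuracy_cum = c(1, 0.9))
  short_z <- data.frame(iteration = 1:3, n_included_cum = c(1L, 2L, 3L),
                        accuracy_cum = c(1, 1, 0.9))
  expect_error(ad_score(short_y, short_z, n_total_y = 5, n_total_z = 5),
               "same iteration grid")
})

test_that("scores from profile objects carry dataset sizes automatically", {
  st <- simulate_study(seed = 5)
  p <- rdn_profile(st$train, st$weights,
                   list(e1 = st$external_1, e2 = st$external_2), k_max = 45)
  sc <- ad_score(profile_dataset(p, "e1"), profile_dataset(p, "e2"))
  expect_s3_class(sc, "ad_score")
  expect_gte(sc$score, 0)
  path <- withr::local_tempfile(fileext = ".json")
  write_ad_score(sc, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$score, sc$score, tolerance = 1e-9)
})
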