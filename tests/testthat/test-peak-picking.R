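test_that("threshold ladder spans PPmax..PPmin with the chosen spacing", {
  # geometric spacing: 100, 10, 1
  lad <- threshold_ladder(new_config(pp_max = 100, pp_min = 1, steps = 3))
  expect_equal(lad, c(100, 10, 1))

  # geometric with 7 rungs over 64..1: every ratio is 2
  lad <- threshold_ladder(new_config(pp_max = 64, pp_min = 1, steps = 7))
  expect_equal(length(lad), 7)
  expect_equal(lad[1], 64)
  expect_equal(lad[7], 1)
  expect_equal(lad[-7] / lad[-1], rep(2, 6), tolerance = 1e-12)

  # linear option
  lad <- threshold_ladder(new_config(pp_max = 100, pp_min = 20, steps = 5,
                                     spacing = "linear"))
  expect_equal(lad, c(100, 80, 60, 40, 20))

  # steps = 1 returns PPmax and warns when PPmin differs
  expect_warning(
    lad <- threshold_ladder(new_config(pp_max = 10, pp_min = 5, steps = 1)),
    "PPmax")
  expect_equal(lad, 10)

  # strictly decreasing always
  expect_true(all(diff(threshold_ladder(test_config())) < 0))
})

gauss2d <- function(direct, dq, cd, cq, sd = 0.5, sq = 0.5, amp = 100) {
  amp * outer(exp(-(dq - cq)^2 / (2 * sq^2)),
              exp(-(direct - cd)^2 / (2 * sd^2)))
}

test_that("pick_slice finds isolated and valley-separated maxima", {
  direct <- seq(50, 10, length.out = 201)   # 0.2 ppm step
  dq <- seq(120, 40, length.out = 201)      # 0.4 ppm step
  z <- gauss2d(direct, dq, 30, 80)
  sp <- new_spectrum2d(direct, dq, z)
  pk <- pick_slice(sp, 50)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$cs_direct - 30), 0.2)
  expect_lt(abs(pk$cs_dq - 80), 0.4)
  # the local maximum is a member point
  apex <- which(z == max(z), arr.ind = TRUE)
  expect_true(any(pk$points[[1]][, "row"] == apex[1] &
                  pk$points[[1]][, "col"] == apex[2]))

  # two Gaussians with a deep valley below threshold -> two regions
  z2 <- gauss2d(direct, dq, 25, 80) + gauss2d(direct, dq, 35, 80)
  pk2 <- pick_slice(new_spectrum2d(direct, dq, z2), 50)
  expect_equal(nrow(pk2), 2)

  # nothing above threshold -> empty
  expect_equal(nrow(pick_slice(sp, 1e6)), 0)
})

test_that("pick_slice region count equals the flood-fill oracle", {
  withr::local_seed(401)
  direct <- seq(60, 10, length.out = 120)
  dq <- seq(150, 40, length.out = 120)
  for (trial in 1:12) {
    z <- matrix(0, 120, 120)
    for (k in seq_len(sample(3:8, 1))) {
      z <- z + gauss2d(direct, dq, runif(1, 15, 55), runif(1, 45, 145),
                       sd = runif(1, 0.4, 1.5), sq = runif(1, 0.8, 3),
                       amp = runif(1, 40, 120))
    }
    th <- runif(1, 15, 60)
    pk <- pick_slice(new_spectrum2d(direct, dq, z), th)
    lab <- oracle_flood_fill(z >= th)
    expect_equal(nrow(pk), max(lab))
  }
})

test_that("merge grouping equals the brute-force union-find oracle", {
  withr::local_seed(402)
  for (trial in 1:10) {
    n <- sample(10:60, 1)
    cs_direct <- runif(n, 10, 40)
    cs_dq <- runif(n, 40, 100)
    ppcs <- runif(1, 0.3, 3)
    ppdq <- runif(1, 0.5, 6)
    det <- tibble::tibble(cs_direct = cs_direct, cs_dq = cs_dq,
                          intensity = runif(n, 10, 100),
                          n_points = 1L,
                          points = replicate(n, cbind(row = 1L, col = 1L),
                                             simplify = FALSE))
    merged <- merge_peaks(list(det), ppcs, ppdq)
    grp <- oracle_merge_groups(cs_direct, cs_dq, ppcs, ppdq)
    expect_equal(nrow(merged), length(unique(grp)))
    # pairwise, merged peaks violate at least one proximity condition
    if (nrow(merged) >= 2) {
      for (i in 1:(nrow(merged) - 1)) {
        for (j in (i + 1):nrow(merged)) {
          together <-
            abs(merged$cs_direct[i] - merged$cs_direct[j]) <= ppcs &&
            abs(merged$cs_dq[i] - merged$cs_dq[j]) <= ppdq
          expect_false(together)
        }
      }
    }
  }
})

test_that("merged peak keeps the highest-threshold position and max intensity", {
  sl1 <- tibble::tibble(cs_direct = 30.00, cs_dq = 80.0, intensity = 90,
                        n_points = 1L, points = list(cbind(row = 1L,
                                                           col = 1L)))
  sl2 <- tibble::tibble(cs_direct = 30.05, cs_dq = 80.1, intensity = 95,
                        n_points = 1L, points = list(cbind(row = 1L,
                                                           col = 1L)))
  sl3 <- tibble::tibble(cs_direct = c(30.1, 35.0), cs_dq = c(80.2, 80.0),
                        intensity = c(97, 60), n_points = c(1L, 1L),
                        points = list(cbind(row = 1L, col = 1L),
                                      cbind(row = 1L, col = 1L)))
  m <- merge_peaks(list(sl1, sl2, sl3), ppcs = 0.4, ppdq = 1,
                   thresholds = c(90, 50, 20))
  expect_equal(nrow(m), 2)  # same apex in 3 slices is one peak
  apex <- m[which.max(m$intensity), ]
  expect_equal(apex$cs_direct, 30.00)     # position from slice 1
  expect_equal(apex$intensity, 97)        # intensity = group max
  expect_equal(apex$slice_threshold, 90)
  expect_equal(apex$n_slices, 3L)
  # ids in descending intensity order
  expect_equal(m$id, order(-m$intensity))

  # two peaks exactly 2*ppcs apart are not merged
  a <- tibble::tibble(cs_direct = c(30, 30.8), cs_dq = c(80, 80),
                      intensity = c(50, 50), n_points = c(1L, 1L),
                      points = list(cbind(row = 1L, col = 1L),
                                    cbind(row = 1L, col = 1L)))
  expect_equal(nrow(merge_peaks(list(a), ppcs = 0.4, ppdq = 1)), 2)
})

test_that("fixture round trip: every true peak found within tolerance", {
  fx <- fixture_spec(noise_sd = 0)
  sim <- render_inadequate(fx)
  cfg <- test_config()
  peaks <- pick_peaks(sim$spectrum, cfg)
  expect_equal(nrow(peaks), nrow(sim$truth))
  for (i in seq_len(nrow(sim$truth))) {
    d <- abs(peaks$cs_direct - sim$truth$cs_direct[i])
    q <- abs(peaks$cs_dq - sim$truth$cs_dq[i])
    expect_true(any(d <= cfg$ppcs & q <= cfg$ppdq))
  }
  # per-slice counts recorded for the Summary
  sc <- attr(peaks, "slice_counts")
  expect_equal(nrow(sc), cfg$steps)
  expect_equal(sc$threshold, threshold_ladder(cfg))
})

test_that("an all-noise spectrum below PPmin yields no peaks", {
  fx <- fixture_spec(compounds = list(), intensities = numeric(0),
                     noise_sd = 1,
                     axes = list(direct = c(5, 195, 256),
                                 dq = c(10, 390, 256),
                                 jres = c(5, 195, 256)))
  sim <- render_inadequate(fx)
  peaks <- pick_peaks(sim$spectrum, test_config())
  expect_equal(nrow(peaks), 0)
})

test_that("lowering PPmin never removes a previously found peak", {
  # compounds whose peaks have no overlap saddle above the lower PPmin, so
  # the superset property of the threshold ladder is exercised cleanly
  fx <- fixture_spec(compounds = toy_library()[1:2], noise_sd = 0)
  sim <- render_inadequate(fx)
  cfg_hi <- test_config()
  cfg_lo <- new_config(pp_max = 90, pp_min = 5, steps = 6)
  hi <- pick_peaks(sim$spectrum, cfg_hi)
  lo <- pick_peaks(sim$spectrum, cfg_lo)
  expect_gte(nrow(lo), nrow(hi))
  # every high-PPmin peak has a low-PPmin peak within the merge tolerance
  for (i in seq_len(nrow(hi))) {
    d <- abs(lo$cs_direct - hi$cs_direct[i])
    q <- abs(lo$cs_dq - hi$cs_dq[i])
    expect_true(any(d <= cfg_hi$ppcs & q <= cfg_hi$ppdq))
  }
})

test_that("the threshold ladder resolves peaks a single threshold merges", {
  # two unequal Gaussians whose saddle lies between PPmin and PPmax: the
  # ladder sees them separately at high thresholds; a single PPmin
  # threshold sees one fused region
  direct <- seq(40, 20, length.out = 401)  # 0.05 ppm step
  dq <- seq(90, 70, length.out = 401)
  z <- gauss2d(direct, dq, 29.5, 80, sd = 0.45, sq = 0.45, amp = 100) +
       gauss2d(direct, dq, 31.0, 80, sd = 0.45, sq = 0.45, amp = 55)
  sp <- new_spectrum2d(direct, dq, z)
  # saddle is ~35: PPmin = 20 sits below it, PPmax = 90 above
  cfg <- new_config(pp_max = 90, pp_min = 20, steps = 6, ppcs = 0.6,
                    ppdq = 1)
  ladder_peaks <- pick_peaks(sp, cfg)
  single <- pick_slice(sp, cfg$pp_min)
  expect_equal(nrow(single), 1)
  expect_equal(nrow(ladder_peaks), 2)
})
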