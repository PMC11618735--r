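peak_tbl <- function(...) {
  d <- tibble::tibble(...)
  d$id <- seq_len(nrow(d))
  d
}

test_that("the three pairing rules admit and reject the textbook cases", {
  cfg <- new_config(dqt = 0.5, sum_xy = 0.5, sdt = 0.5)
  # exact symmetric case: sum 100 = DQ mean 100, equal distance from Y=2X
  pk <- peak_tbl(cs_direct = c(30, 70), cs_dq = c(100, 100))
  pr <- find_horizontal_pairs(pk, cfg)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$left, 1)
  expect_equal(pr$right, 2)
  expect_equal(pr$dq_value, 100)
  expect_equal(pr$sum_residual, 0)
  expect_equal(pr$symmetry_residual, 0)

  # sum rule violation: 30 + 60 = 90 vs DQ mean 100
  pk <- peak_tbl(cs_direct = c(30, 60), cs_dq = c(100, 100))
  expect_equal(nrow(find_horizontal_pairs(pk, cfg)), 0)

  # DQ misalignment beyond DQT
  pk <- peak_tbl(cs_direct = c(30, 70), cs_dq = c(100, 101))
  expect_equal(nrow(find_horizontal_pairs(pk, cfg)), 0)
})

test_that("pair search equals the exhaustive triple-predicate oracle", {
  withr::local_seed(403)
  for (trial in 1:6) {
    n <- 50
    # mixture: some true pairs + uniform clutter
    k <- sample(5:10, 1)
    a <- runif(k, 15, 90)
    b <- runif(k, 15, 90)
    jit <- function(x, s) x + rnorm(length(x), sd = s)
    pk <- peak_tbl(
      cs_direct = c(a, b, runif(n - 2 * k, 10, 100)),
      cs_dq = c(jit(a + b, 0.15), jit(a + b, 0.15),
                runif(n - 2 * k, 30, 200)))
    cfg <- new_config(dqt = runif(1, 0.2, 1), sum_xy = runif(1, 0.2, 1),
                      sdt = runif(1, 0.2, 1))
    got <- find_horizontal_pairs(pk, cfg)
    want <- oracle_pairs(pk, cfg$dqt, cfg$sum_xy, cfg$sdt)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$left, want$left)
      expect_equal(got$right, want$right)
      # left is always the smaller direct shift
      expect_true(all(got$cs_direct_left < got$cs_direct_right))
      # residuals satisfy the predicates as stated
      expect_true(all(got$sum_residual <= cfg$sum_xy))
      expect_true(all(got$symmetry_residual <= cfg$sdt))
    }
  }
})

test_that("tightening any tolerance never increases the pair count", {
  withr::local_seed(404)
  pk <- peak_tbl(cs_direct = runif(40, 10, 100),
                 cs_dq = runif(40, 30, 200))
  base <- new_config(dqt = 2, sum_xy = 2, sdt = 2)
  n0 <- nrow(find_horizontal_pairs(pk, base))
  for (f in c("dqt", "sum_xy", "sdt")) {
    args <- list(dqt = 2, sum_xy = 2, sdt = 2)
    args[[f]] <- 0.5
    n1 <- nrow(find_horizontal_pairs(pk, do.call(new_config, args)))
    expect_lte(n1, n0)
  }
})

test_that("a 3-carbon chain links into one network via the shared carbon", {
  # lactic-acid-like: shifts d1, d2, d3; bonds 1-2 and 2-3; the shared
  # carbon C2 appears in both horizontal pairs at (almost) the same direct
  # shift, so a vertical link joins them
  d <- c(183.4, 69.2, 21.0)
  pk <- peak_tbl(
    cs_direct = c(d[1], d[2], d[2] + 0.05, d[3]),
    cs_dq = c(d[1] + d[2], d[1] + d[2], d[2] + d[3], d[2] + d[3]))
  cfg <- test_config()
  pr <- find_horizontal_pairs(pk, cfg)
  expect_equal(nrow(pr), 2)
  nets <- link_networks(pr, cfg$cst, peaks = pk)
  expect_equal(nrow(nets$networks), 1)
  expect_equal(nets$networks$n_peaks, 4)
  expect_gte(nrow(nets$links), 1)

  # the same chain with the shared carbon's detections 2*CST apart stays
  # two separate 2-peak networks (a broken vertical connection)
  pk2 <- peak_tbl(
    cs_direct = c(d[1], d[2], d[2] + 2 * cfg$cst, d[3]),
    cs_dq = c(d[1] + d[2], d[1] + d[2],
              d[2] + d[3] + 2 * cfg$cst, d[2] + d[3] + 2 * cfg$cst))
  pr2 <- find_horizontal_pairs(pk2, cfg)
  expect_equal(nrow(pr2), 2)
  nets2 <- link_networks(pr2, cfg$cst, peaks = pk2)
  expect_equal(nrow(nets2$networks), 2)
  expect_equal(sort(nets2$networks$n_peaks), c(2, 2))

  # empty pair list -> empty network list
  empty <- link_networks(find_horizontal_pairs(peak_tbl(
    cs_direct = numeric(0), cs_dq = numeric(0)), cfg), cfg$cst)
  expect_equal(nrow(empty$networks), 0)
})

test_that("networks partition the paired peaks with deterministic ids", {
  fx <- fixture_spec(noise_sd = 0)
  run <- run_fixture_pipeline(fx)
  nets <- run$nets
  # no peak in two networks
  expect_equal(anyDuplicated(nets$peaks$peak_id), 0)
  # peaks = union of pair endpoints
  expect_setequal(nets$peaks$peak_id,
                  unique(c(nets$pairs$left, nets$pairs$right)))
  # every network has >= 2 peaks and ids follow ascending min direct shift
  expect_true(all(nets$networks$n_peaks >= 2))
  expect_equal(nets$networks$network_id,
               order(nets$networks$min_cs_direct))
  # emitted pairs satisfy the three predicates (re-assertable post hoc)
  cfg <- test_config()
  expect_true(all(abs(run$pairs$sum_residual) <= cfg$sum_xy))
  expect_true(all(abs(run$pairs$symmetry_residual) <= cfg$sdt))
})

test_that("network_stats summarizes sizes consistently", {
  # build 3 networks of sizes 2, 2, 4 from two 2-carbon compounds and one
  # 3-carbon chain
  pk <- peak_tbl(
    cs_direct = c(20, 30, 50, 60, 80, 90, 90.05, 110),
    cs_dq = c(50, 50, 110, 110, 170, 170, 200.05, 200.05))
  cfg <- test_config()
  nets <- link_networks(find_horizontal_pairs(pk, cfg), cfg$cst,
                        peaks = pk)
  st <- network_stats(nets)
  expect_equal(st$total, 3)
  expect_equal(st$max_size, 4)
  hist <- st$size_histogram
  expect_equal(hist$n[hist$size == 2], 2)
  expect_equal(hist$n[hist$size == 4], 1)

  st0 <- network_stats(link_networks(tibble::tibble(), cst = 0.25))
  expect_equal(st0$total, 0)
  expect_equal(st0$max_size, 0)
})

test_that("k disjoint 2-carbon compounds give k networks of size 2", {
  cmps <- lapply(1:4, function(m) {
    list(name = sprintf("pair-%d", m), entry_id = sprintf("px%04d", m),
         carbons = stats::setNames(list(20 + 10 * m, 120 + 12 * m),
                                   c("C1", "C2")),
         bonds = rbind(c("C1", "C2")))
  })
  fx <- fixture_spec(compounds = cmps, noise_sd = 0)
  run <- run_fixture_pipeline(fx)
  expect_equal(nrow(run$nets$networks), 4)
  expect_true(all(run$nets$networks$n_peaks == 2))
})
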