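test_that("recording generator validates its inputs", {
  lay <- make_layout(1, 2, 0, 5)
  expect_error(simulate_coupled_recording(lay, diag(0, 2), carrier_hz = 600,
                                          rate_hz = 1000),
               class = "gammanet_invalid_parameter")
  expect_error(simulate_coupled_recording(lay, diag(0, 3)),
               class = "gammanet_invalid_parameter")
  asym <- matrix(c(0, 1, 0.5, 0), 2)
  expect_error(simulate_coupled_recording(lay, asym),
               class = "gammanet_format_error")
})

test_that("mean dwPLI over coupled pairs is nondecreasing in coupling strength", {
  lay <- make_layout(2, 3, 2, 2)
  set.seed(3)
  base <- matrix(0, 6, 6)
  p <- gammanet:::upper_pairs(6)
  base[p] <- runif(15, 0.3, 1)
  base <- base + t(base)
  means <- vapply(c(0, 0.5, 1), function(s) {
    rec <- simulate_coupled_recording(lay, base * s, duration_s = 120,
                                      seed = 9)
    cw <- dwpli_connectome(rec)
    mean(cw[upper.tri(cw)])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("planted connectome families have their defining structure", {
  lat <- plant_connectome(16, "lattice", seed = 2)
  expect_equal(unclass(equivalent_regular(lat)), unclass(lat),
               ignore_attr = TRUE)

  rnd <- plant_connectome(16, "random", strength_scale = 2, seed = 2)
  vals <- rnd[upper.tri(rnd)]
  expect_true(all(vals >= 0 & vals <= 2))

  rc <- plant_connectome(20, "rich_club", seed = 2)
  hubs <- attr(rc, "hubs")
  expect_true(length(hubs) >= 3)
  hub_idx <- match(hubs, rownames(rc))
  hub_w <- unclass(rc)[hub_idx, hub_idx]
  expect_gt(min(hub_w[upper.tri(hub_w)]), 0.7)

  expect_error(plant_connectome(20, "star"), "arg")
  expect_error(plant_connectome(3, "random"),
               class = "gammanet_invalid_parameter")
})

test_that("generators are deterministic under a fixed seed", {
  a <- plant_connectome(12, "small_world", seed = 7)
  b <- plant_connectome(12, "small_world", seed = 7)
  expect_identical(unclass(a), unclass(b))
  d <- cohort_design(n_per_cell = c(blast_1 = 2, blast_3 = 2, sham_1 = 2,
                                    sham_3 = 2), seed = 5)
  lay <- make_layout(2, 4, 4, 4)
  c1 <- generate_cohort(d, lay)
  c2 <- generate_cohort(d, lay)
  expect_identical(c1$weight_gain, c2$weight_gain)
  expect_identical(c1$connectome[[5]], c2$connectome[[5]])
})

test_that("cost-allocation bias raises expected normalized cost", {
  lay <- make_layout(2, 4, 4, 4)
  mean_tewc <- function(b, seed) {
    set.seed(seed)
    p <- gammanet:::upper_pairs(8)
    d_vec <- lay$distances[p]
    ord <- order(d_vec, decreasing = TRUE)
    vals <- replicate(30, {
      w_raw <- sort(runif(length(d_vec), 0.05, 1), decreasing = TRUE)
      vec <- gammanet:::allocate_by_bias(w_raw, ord, b)
      m <- matrix(0, 8, 8)
      m[p] <- vec
      net <- connectome(m + t(m), node_ids = lay$ids)
      cb <- cost_bounds(net, lay)
      tewc(raw_cost(net, lay), cb$c_min, cb$c_max)
    })
    mean(vals)
  }
  ms <- vapply(c(0, 0.5, 1), mean_tewc, numeric(1), seed = 11)
  expect_true(all(diff(ms) > 0))
  expect_gt(ms[3], 0.999)   # full bias attains the maximum-cost arrangement
  expect_lt(abs(ms[1] - 0.5), 0.1)  # uniform allocation sits mid-range
})

test_that("cohort planting realizes the low-cost blast-1-month cell", {
  lay <- make_layout(2, 4, 4, 4)
  lowest <- vapply(1:10, function(s) {
    d <- cohort_design(n_per_cell = c(blast_1 = 4, blast_3 = 4, sham_1 = 4,
                                      sham_3 = 4),
                       bias = c(blast_1 = 0, blast_3 = 0.5, sham_1 = 0.5,
                                sham_3 = 0.5),
                       seed = 100 + s)
    co <- generate_cohort(d, lay)
    tw <- vapply(co$connectome, function(net) {
      cb <- cost_bounds(net, lay)
      tewc(raw_cost(net, lay), cb$c_min, cb$c_max)
    }, numeric(1))
    cellmeans <- tapply(tw, paste(co$group, co$timepoint), mean)
    names(which.min(cellmeans))
  }, character(1))
  expect_gte(sum(lowest == "blast 1"), 8)
})

test_that("weight-gain covariate tracks normalized cost with the planted sign", {
  lay <- make_layout(2, 4, 4, 4)
  rhos <- vapply(1:10, function(s) {
    d <- cohort_design(n_per_cell = c(blast_1 = 10, blast_3 = 10,
                                      sham_1 = 10, sham_3 = 10),
                       rho_weight_gain = c(blast = -0.5, sham = 0.7),
                       seed = 200 + s)
    co <- generate_cohort(d, lay)
    tw <- vapply(co$connectome, function(net) {
      cb <- cost_bounds(net, lay)
      tewc(raw_cost(net, lay), cb$c_min, cb$c_max)
    }, numeric(1))
    idx <- co$group == "blast"
    cor(tw[idx], co$weight_gain[idx], method = "spearman")
  }, numeric(1))
  expect_true(all(rhos < 0.05))          # sign respected per draw (n = 20)
  expect_lt(abs(mean(rhos) - (-0.5)), 0.2)
})

test_that("cohorts round-trip through the manifest format", {
  lay <- make_layout(2, 3, 3, 3)
  d <- cohort_design(n_per_cell = c(blast_1 = 2, blast_3 = 2, sham_1 = 2,
                                    sham_3 = 2), seed = 9)
  co <- generate_cohort(d, lay)
  dir <- withr::local_tempdir()
  mp <- write_cohort(co, dir)
  back <- read_cohort(mp)
  expect_equal(back$subject_id, co$subject_id)
  expect_equal(back$weight_gain, co$weight_gain, tolerance = 1e-6)
  expect_equal(unclass(back$connectome[[3]]), unclass(co$connectome[[3]]),
               tolerance = 1e-10, ignore_attr = TRUE)
})
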