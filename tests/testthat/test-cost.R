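test_that("raw cost is the weight-distance inner product over unordered pairs", {
  lay <- collinear_layout()
  net <- triangle_net(w12 = 3, w13 = 2, w23 = 1)
  # d = (1, 3, 2) against w = (3, 2, 1): 1*3 + 3*2 + 2*1 = 11
  expect_equal(raw_cost(net, lay), 11)
  expect_equal(raw_cost(triangle_net(0, 0, 0), lay), 0)
  expect_equal(raw_cost(connectome(2 * unclass(net)), lay), 22)
})

test_that("cost bounds follow the rearrangement inequality on the toy triangle", {
  lay <- collinear_layout()
  net <- triangle_net(w12 = 3, w13 = 2, w23 = 1)
  cb <- cost_bounds(net, lay)
  expect_equal(cb$c_min, 10)  # 3*1 + 2*2 + 1*3
  expect_equal(cb$c_max, 14)  # 1*1 + 2*2 + 3*3
  expect_equal(tewc(raw_cost(net, lay), cb$c_min, cb$c_max), 0.25)
  # exhaustive check over all 3! permutations
  oracle <- cost_extremes_bruteforce(c(3, 2, 1), c(1, 2, 3))
  expect_equal(cb$c_min, oracle$c_min)
  expect_equal(cb$c_max, oracle$c_max)
})

test_that("cost bounds equal exhaustive permutation search on random instances", {
  for (seed in 1:25) {
    inst <- random_spatial_instance(4, seed)  # 6 edges -> 720 permutations
    cb <- cost_bounds(inst$net, inst$layout)
    pv <- gammanet:::pair_vectors(inst$net, inst$layout)
    oracle <- cost_extremes_bruteforce(pv$w, pv$d)
    expect_equal(cb$c_min, oracle$c_min, tolerance = 1e-12)
    expect_equal(cb$c_max, oracle$c_max, tolerance = 1e-12)
  }
})

test_that("zero-weight pairs occupy arrangement slots", {
  lay <- collinear_layout()
  # single edge on the shortest pair: c_min places the weight on d = 1,
  # c_max on d = 3, zeros filling the remaining slots
  net <- triangle_net(w12 = 5, w13 = 0, w23 = 0)
  cb <- cost_bounds(net, lay)
  expect_equal(cb$c_min, 5)
  expect_equal(cb$c_max, 15)
})

test_that("TEWC is invariant to uniform weight scaling while raw cost is linear", {
  inst <- random_spatial_instance(12, 99)
  c0 <- raw_cost(inst$net, inst$layout)
  cb0 <- cost_bounds(inst$net, inst$layout)
  t0 <- tewc(c0, cb0$c_min, cb0$c_max)
  for (c_ in c(0.1, 10)) {
    scaled <- connectome(unclass(inst$net) * c_)
    cs <- raw_cost(scaled, inst$layout)
    cbs <- cost_bounds(scaled, inst$layout)
    expect_equal(cs, c_ * c0, tolerance = 1e-12)
    expect_lt(abs(tewc(cs, cbs$c_min, cbs$c_max) - t0), 1e-12)
  }
})

test_that("degenerate and inconsistent TEWC inputs are handled explicitly", {
  lay <- collinear_layout()
  const <- triangle_net(0.5, 0.5, 0.5)
  cb <- cost_bounds(const, lay)
  expect_equal(cb$c_min, cb$c_max)
  expect_warning(out <- tewc(raw_cost(const, lay), cb$c_min, cb$c_max),
                 "Degenerate")
  expect_true(is.na(out))
  expect_error(tewc(5, 10, 14), class = "gammanet_internal_error")
  # anti-sorted arrangement attains the minimum exactly
  anti <- triangle_net(w12 = 3, w13 = 1, w23 = 2)  # largest w on shortest d
  cba <- cost_bounds(anti, lay)
  expect_equal(tewc(raw_cost(anti, lay), cba$c_min, cba$c_max), 0)
})

test_that("tie permutations in weights or distances leave the bounds unchanged", {
  set.seed(4)
  w <- c(0.3, 0.3, 0.3, 0.8, 0.1, 0.1)
  d <- c(1, 2, 2, 3, 4, 4)
  oracle <- cost_extremes_bruteforce(w, d)
  expect_equal(sum(sort(w, decreasing = TRUE) * sort(d)), oracle$c_min)
  expect_equal(sum(sort(w) * sort(d)), oracle$c_max)
})

test_that("cost-efficiency metrics follow the joint-deviation formula", {
  expect_equal(cost_efficiency(0, 0, 0), list(sce = 1, ice = 1))
  expect_equal(cost_efficiency(1, 1, 1), list(sce = 0, ice = 0))
  ce <- cost_efficiency(0.25, 0.6, 0.8)
  expect_equal(ce$sce, 1 - sqrt((0.36 + 0.0625) / 2))
  expect_equal(ce$ice, 1 - sqrt((0.64 + 0.0625) / 2))
  expect_true(all(is.na(unlist(cost_efficiency(NA_real_, 0.5, 0.5)))))
})

test_that("network_cost assembles a consistent one-row summary", {
  inst <- random_spatial_instance(10, 7)
  res <- network_cost(inst$net, inst$layout, delta_c = 0.2, delta_l = 0.3)
  expect_s3_class(res, "cost_result")
  expect_true(res$c_min <= res$c_obs && res$c_obs <= res$c_max)
  expect_equal(res$tewc, (res$c_obs - res$c_min) / (res$c_max - res$c_min))
  expect_equal(res$sce, 1 - sqrt((0.2^2 + res$tewc^2) / 2))
  expect_error(network_cost(triangle_net(1, 1, 1, ids = c("X", "Y", "Z")),
                            make_layout(1, 2, 0, 5)),
               class = "gammanet_invalid_input")
})
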