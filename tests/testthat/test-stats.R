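# cells ordered blast_1, blast_3, sham_1, sham_3 to match `means`
make_design <- function(n_cell, means = c(0, 0, 0, 0), sd = 1, seed = 1,
                        rdist = rnorm) {
  set.seed(seed)
  cells <- data.frame(group = c("blast", "blast", "sham", "sham"),
                      timepoint = c(1, 3, 1, 3))
  dplyr::bind_rows(lapply(seq_len(4), function(i) {
    tibble::tibble(group = cells$group[i], timepoint = cells$timepoint[i],
                   value = means[i] + sd * rdist(n_cell))
  }))
}

test_that("constant data give zero F and p = 1", {
  dat <- make_design(5)
  dat$value <- 3.3
  res <- perm_anova2(dat, value, group, timepoint, n_perm = 99, seed = 1)
  expect_equal(res$table$statistic, c(0, 0, 0))
  expect_equal(res$table$p.value, c(1, 1, 1))
})

test_that("extreme separation attains the minimal permutation p-value", {
  dat <- make_design(5, sd = 0.01)
  dat$value[dat$group == "blast" & dat$timepoint == 1] <-
    dat$value[dat$group == "blast" & dat$timepoint == 1] + 100
  res <- perm_anova2(dat, value, group, timepoint, n_perm = 999, seed = 2)
  # permutations reassembling the shifted block into any one cell are the
  # only ones as extreme, so p is bounded near 1/(n_perm + 1)
  expect_lte(res$table$p.value[res$table$term == "interaction"], 0.005)
})

test_that("a pure group shift routes to the group effect", {
  dat <- make_design(8, means = c(3, 3, 0, 0), seed = 4)  # blast shifted
  res <- perm_anova2(dat, value, group, timepoint, n_perm = 999, seed = 1)
  p <- res$table$p.value
  expect_lt(p[1], 0.01)          # group
  expect_gt(p[3], 0.1)           # interaction
})

test_that("the residual permutation scheme agrees on clear effects", {
  dat <- make_design(8, means = c(3, 3, 0, 0), seed = 4)
  res <- perm_anova2(dat, value, group, timepoint, n_perm = 499, seed = 1,
                     scheme = "residual")
  expect_lt(res$table$p.value[1], 0.01)
})

test_that("design validation rejects underfilled cells", {
  dat <- make_design(5)
  dat <- dat[!(dat$group == "sham" & dat$timepoint == 3), ]
  expect_error(perm_anova2(dat, value, group, timepoint, n_perm = 9),
               class = "gammanet_invalid_design")
})

test_that("tidy and glance return the broom-shaped tables", {
  dat <- make_design(4, seed = 2)
  res <- perm_anova2(dat, value, group, timepoint, n_perm = 49, seed = 1)
  td <- tidy(res)
  expect_named(td, c("term", "statistic", "df", "df.residual", "p.value"))
  expect_equal(nrow(td), 3)
  gl <- glance(res)
  expect_equal(gl$n_perm, 49)
})

test_that("permutation Welch t test behaves at the extremes", {
  set.seed(3)
  a <- rnorm(8)
  res_same <- perm_ttest2(a, a, n_perm = 199, seed = 1)
  expect_gt(res_same$p_perm, 0.5)

  b <- rep(10, 8) + rnorm(8, sd = 1e-4)
  res_sep <- perm_ttest2(rep(0, 8) + rnorm(8, sd = 1e-4), b,
                         n_perm = 999, seed = 1)
  # only the observed split and its mirror are as extreme
  expect_lte(res_sep$p_perm, 3 / 1000)
  expect_lt(res_sep$ci95[2], 0)   # CI sign matches mean(a) - mean(b) < 0

  set.seed(9)
  aa <- rnorm(10, mean = 2)
  bb <- rnorm(10)
  res <- perm_ttest2(aa, bb, n_perm = 499, seed = 2)
  expect_gt(res$mean_diff, 0)
  expect_gt(res$ci95[1], -1e-9 + min(0, res$mean_diff))
  td <- tidy(res)
  expect_named(td, c("statistic", "df", "p.value", "estimate", "conf.low",
                     "conf.high"))
})

test_that("Welch statistic and CI match the classical computation", {
  set.seed(11)
  a <- rnorm(9, 1)
  b <- rnorm(14, 0, 2)
  res <- perm_ttest2(a, b, n_perm = 99, seed = 1)
  ref <- t.test(a, b)
  expect_equal(res$t_stat, unname(ref$statistic))
  expect_equal(res$df, unname(ref$parameter))
  expect_equal(res$ci95, as.numeric(ref$conf.int), tolerance = 1e-10)
})

test_that("Spearman correlation and bootstrap CI behave on monotone data", {
  x <- 1:12
  res <- spearman_ci(x, x^3, n_boot = 200, seed = 1)
  expect_equal(res$rho, 1)
  res_neg <- spearman_ci(x, -x, n_boot = 200, seed = 1)
  expect_equal(res_neg$rho, -1)
  expect_warning(res_c <- spearman_ci(rep(1, 10), rnorm(10), n_boot = 10),
                 "Constant")
  expect_true(is.na(res_c$rho))

  set.seed(5)
  xx <- rnorm(40)
  yy <- xx + rnorm(40)
  res2 <- spearman_ci(xx, yy, n_boot = 500, seed = 2)
  expect_true(res2$ci95[1] < res2$rho && res2$rho < res2$ci95[2])
})

test_that("multiple-testing adjustments match their definitions", {
  expect_equal(adjust_pvalues(rep(0.01, 5), "bonferroni"), rep(0.05, 5))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  set.seed(6)
  for (i in 1:10) {
    p <- runif(sample(3:20, 1))
    expect_equal(adjust_pvalues(p, "bh"), bh_oracle(p))
    expect_true(all(adjust_pvalues(p, "bonferroni") >= p))
    expect_true(all(adjust_pvalues(p, "bh") >= p))
  }
  expect_error(adjust_pvalues(c(0.5, 1.2), "bh"),
               class = "gammanet_invalid_parameter")
})

test_that("cohort_stats gates post-hoc contrasts on the interaction", {
  dat <- make_design(8, means = c(-2, 0, 0, 0), sd = 0.5, seed = 7)
  names(dat)[names(dat) == "value"] <- "tewc"
  res <- cohort_stats(dat, "tewc", n_perm = 499, seed = 1)
  expect_true(all(c("group", "time", "interaction") %in% res$effect))
  expect_true("blast1_vs_sham1" %in% res$effect)
  contr <- res[res$effect == "blast1_vs_sham1", ]
  expect_lt(contr$statistic, 0)
  expect_equal(contr$p_adj, min(1, contr$p_raw * 3))

  null_dat <- make_design(8, seed = 8)
  names(null_dat)[names(null_dat) == "value"] <- "swp"
  res0 <- cohort_stats(null_dat, "swp", n_perm = 199, seed = 1, alpha = 1e-6)
  expect_false(any(grepl("vs", res0$effect)))
})
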