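# Residual sum of squares of y (columns of Y) under the column space of Q.
rss_under <- function(Y, Q) {
  colSums(Y^2) - colSums(crossprod(Q, Y)^2)
}

#' Permutation-based two-way ANOVA
#'
#' Factorial inference for a metric over a group x time between-subjects
#' design. Observed F statistics come from the least-squares decomposition
#' (Type II sums of squares for the main effects, so unbalanced cells are
#' handled); the null distribution is built by permutation. The default
#' scheme permutes raw observations (Manly), which is exact under the
#' global null and robust to heteroscedasticity; `scheme = "residual"`
#' permutes reduced-model residuals per effect (Freedman-Lane). The p-value
#' convention includes the observed statistic:
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#'
#' @param data A data frame with one row per subject.
#' @param value,group,time Columns (tidy-eval) holding the metric and the
#'   two factors.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param scheme `"manly"` (raw-data permutation) or `"residual"`.
#' @return A `perm_anova2` object; see [tidy()] for the result table.
#' @export
perm_anova2 <- function(data, value, group, time, n_perm = 10000, seed = 1,
                        scheme = c("manly", "residual")) {
  scheme <- match.arg(scheme)
  y <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  tt <- factor(dplyr::pull(data, {{ time }}))
  if (anyNA(y)) abort_invalid("`value` contains missing values.")
  cells <- table(g, tt)
  if (any(cells < 2)) {
    abort_invalid("Every design cell needs at least 2 subjects.",
                  class = "gammanet_invalid_design")
  }
  n <- length(y)
  a <- nlevels(g)
  b <- nlevels(tt)
  q_g <- qr.Q(qr(stats::model.matrix(~g)))
  q_t <- qr.Q(qr(stats::model.matrix(~tt)))
  q_add <- qr.Q(qr(stats::model.matrix(~ g + tt)))
  q_full <- qr.Q(qr(stats::model.matrix(~ g * tt)))
  df_g <- a - 1
  df_t <- b - 1
  df_i <- df_g * df_t
  df_res <- n - a * b

  f_stats <- function(Y) {
    rss_full <- rss_under(Y, q_full)
    rss_add <- rss_under(Y, q_add)
    ms_res <- rss_full / df_res
    comp <- function(ss, df) {
      ifelse(ms_res > 1e-300, (ss / df) / ms_res, ifelse(ss <= 1e-300, 0, Inf))
    }
    list(
      group = comp(pmax(rss_under(Y, q_t) - rss_add, 0), df_g),
      time = comp(pmax(rss_under(Y, q_g) - rss_add, 0), df_t),
      interaction = comp(pmax(rss_add - rss_full, 0), df_i)
    )
  }

  obs <- f_stats(matrix(y, ncol = 1))
  set.seed(seed)
  if (scheme == "manly") {
    Yp <- vapply(seq_len(n_perm), function(i) y[sample.int(n)], numeric(n))
    perm <- f_stats(Yp)
  } else {
    perm <- list()
    reduced <- list(group = q_t, time = q_g, interaction = q_add)
    for (eff in names(reduced)) {
      Qr <- reduced[[eff]]
      fit <- Qr %*% crossprod(Qr, y)
      res <- y - fit
      Yp <- vapply(seq_len(n_perm),
                   function(i) fit + res[sample.int(n)], numeric(n))
      perm[[eff]] <- f_stats(Yp)[[eff]]
    }
  }
  pval <- function(eff) {
    (1 + sum(perm[[eff]] >= obs[[eff]][1])) / (1 + n_perm)
  }
  tab <- tibble::tibble(
    term = c("group", "time", "interaction"),
    statistic = c(obs$group[1], obs$time[1], obs$interaction[1]),
    df = c(df_g, df_t, df_i),
    df.residual = df_res,
    p.value = c(pval("group"), pval("time"), pval("interaction"))
  )
  structure(
    list(table = tab, n = n, n_perm = n_perm, seed = seed, scheme = scheme),
    class = "perm_anova2"
  )
}

#' @export
print.perm_anova2 <- function(x, ...) {
  cat(sprintf("Permutation two-way ANOVA (%s scheme, %d permutations)\n",
              x$scheme, x$n_perm))
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @rdname perm_anova2
#' @param x A `perm_anova2` object.
#' @param ... Unused.
#' @export
tidy.perm_anova2 <- function(x, ...) x$table

#' @rdname perm_anova2
#' @export
glance.perm_anova2 <- function(x, ...) {
  tibble::tibble(n = x$n, n_perm = x$n_perm, scheme = x$scheme,
                 seed = x$seed)
}

#' Permutation Welch two-sample t test
#'
#' Welch's unequal-variance t statistic, a permutation p-value from random
#' group-label reassignments, and a 95% confidence interval for the mean
#' difference from the Welch t distribution.
#'
#' @param a,b Numeric samples (each of size >= 2).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A `perm_ttest` object with fields `t_stat`, `df`, `p_perm`,
#'   `ci95`, `mean_diff`.
#' @export
perm_ttest2 <- function(a, b, n_perm = 10000, seed = 1) {
  if (length(a) < 2 || length(b) < 2) {
    abort_invalid("Each sample needs at least 2 observations.")
  }
  na <- length(a)
  nb <- length(b)
  welch <- function(xa, xb, va_, vb_) {
    se <- sqrt(va_ / na + vb_ / nb)
    ifelse(se > 0, (xa - xb) / se, 0)
  }
  ma <- mean(a); mb <- mean(b); va <- var(a); vb <- var(b)
  t_obs <- welch(ma, mb, va, vb)
  se <- sqrt(va / na + vb / nb)
  df <- if (se > 0) {
    se^4 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    na + nb - 2
  }
  ci <- if (se > 0) (ma - mb) + c(-1, 1) * qt(0.975, df) * se else c(0, 0)

  pooled <- c(a, b)
  n_tot <- na + nb
  set.seed(seed)
  t_perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n_tot, na)
    xa <- pooled[idx]; xb <- pooled[-idx]
    welch(mean(xa), mean(xb), var(xa), var(xb))
  }, numeric(1))
  p_perm <- (1 + sum(abs(t_perm) >= abs(t_obs))) / (1 + n_perm)
  structure(
    list(t_stat = t_obs, df = df, p_perm = p_perm, ci95 = ci,
         mean_diff = ma - mb, n = c(na, nb), n_perm = n_perm, seed = seed),
    class = "perm_ttest"
  )
}

#' @export
print.perm_ttest <- function(x, ...) {
  cat(sprintf(
    "Permutation Welch t test: t(%.2f) = %.3f, p_perm = %.4g, 95%% CI [%.3g, %.3g]\n",
    x$df, x$t_stat, x$p_perm, x$ci95[1], x$ci95[2]
  ))
  invisible(x)
}

#' @rdname perm_ttest2
#' @param x A `perm_ttest` object.
#' @param ... Unused.
#' @export
tidy.perm_ttest <- function(x, ...) {
  tibble::tibble(statistic = x$t_stat, df = x$df, p.value = x$p_perm,
                 estimate = x$mean_diff, conf.low = x$ci95[1],
                 conf.high = x$ci95[2])
}

#' Spearman correlation with bootstrap confidence interval
#'
#' Spearman rank correlation, a percentile bootstrap CI over paired
#' resamples (default 10000), and a p-value from the standard large-sample
#' test.
#'
#' @param x,y Paired numeric vectors (n >= 4).
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed.
#' @return A list with `rho`, `ci95`, `p`, `n`, `n_boot`.
#' @export
spearman_ci <- function(x, y, n_boot = 10000, seed = 1) {
  if (length(x) != length(y) || length(x) < 4) {
    abort_invalid("`x` and `y` must be paired with n >= 4.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warning("Constant input; Spearman correlation undefined.", call. = FALSE)
    return(list(rho = NA_real_, ci95 = c(NA_real_, NA_real_), p = NA_real_,
                n = length(x), n_boot = n_boot))
  }
  rho <- cor(x, y, method = "spearman")
  p <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)$p.value
  )
  n <- length(x)
  set.seed(seed)
  rho_b <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, replace = TRUE)
    suppressWarnings(cor(x[idx], y[idx], method = "spearman"))
  }, numeric(1))
  ci <- unname(quantile(rho_b, c(0.025, 0.975), na.rm = TRUE))
  list(rho = rho, ci95 = ci, p = p, n = n, n_boot = n_boot)
}

#' Multiple-testing adjustment
#'
#' `"bonferroni"` multiplies by the family size (capped at 1);
#' `"bh"` applies the Benjamini-Hochberg step-up false discovery rate.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort_invalid("p-values must lie in [0, 1].")
  }
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Factorial statistics over a cohort metrics table
#'
#' For each requested metric column: a permutation two-way ANOVA
#' (group x timepoint with interaction); when the interaction is significant
#' at `alpha`, the three post-hoc contrasts of interest (blast vs sham at
#' 1 month, blast vs sham at 3 months, blast 1 vs 3 months) via permutation
#' Welch t tests with Bonferroni correction over the family of three.
#'
#' @param metrics A data frame with columns `group`, `timepoint`, and the
#'   metric columns.
#' @param vars Character vector of metric column names.
#' @param n_perm Permutations per test.
#' @param seed Integer seed.
#' @param alpha Significance threshold for gating the post-hoc family.
#' @return A tidy tibble with columns `metric`, `effect`, `statistic`, `df`,
#'   `p_raw`, `p_adj`, `ci_low`, `ci_high`, `n_perm`, `seed`.
#' @export
cohort_stats <- function(metrics, vars, n_perm = 10000, seed = 1,
                         alpha = 0.05) {
  contrasts <- list(
    blast1_vs_sham1 = list(c("blast", 1), c("sham", 1)),
    blast3_vs_sham3 = list(c("blast", 3), c("sham", 3)),
    blast1_vs_blast3 = list(c("blast", 1), c("blast", 3))
  )
  cell <- function(grp, tp) {
    metrics[metrics$group == grp & metrics$timepoint == tp, , drop = FALSE]
  }
  out <- list()
  for (v in vars) {
    keep <- !is.na(metrics[[v]])
    dat <- metrics[keep, , drop = FALSE]
    an <- perm_anova2(dat, !!rlang::sym(v), group, timepoint,
                      n_perm = n_perm, seed = derive_seed(seed, match(v, vars)))
    out[[length(out) + 1L]] <- tibble::tibble(
      metric = v, effect = an$table$term, statistic = an$table$statistic,
      df = an$table$df, p_raw = an$table$p.value, p_adj = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_, n_perm = n_perm, seed = seed
    )
    p_int <- an$table$p.value[an$table$term == "interaction"]
    if (!is.na(p_int) && p_int < alpha) {
      praw <- numeric(0)
      rows <- list()
      for (cn in names(contrasts)) {
        cc <- contrasts[[cn]]
        aa <- cell(cc[[1]][1], cc[[1]][2])[[v]]
        bb <- cell(cc[[2]][1], cc[[2]][2])[[v]]
        tt <- perm_ttest2(aa, bb, n_perm = n_perm,
                          seed = derive_seed(seed, 100 + match(cn, names(contrasts))))
        praw <- c(praw, tt$p_perm)
        rows[[cn]] <- tibble::tibble(
          metric = v, effect = cn, statistic = tt$t_stat, df = tt$df,
          p_raw = tt$p_perm, p_adj = NA_real_, ci_low = tt$ci95[1],
          ci_high = tt$ci95[2], n_perm = n_perm, seed = seed
        )
      }
      padj <- adjust_pvalues(praw, "bonferroni")
      for (i in seq_along(rows)) rows[[i]]$p_adj <- padj[i]
      out <- c(out, rows)
    }
  }
  dplyr::bind_rows(out)
}
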