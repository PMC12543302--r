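#' Configure an end-to-end pipeline run
#'
#' Collects every stage's parameters plus a master seed. Every random stage
#' receives a seed derived from the master seed and logged, so reruns with
#' the same configuration reproduce identical outputs. The `"desk"` preset
#' (smaller cohort, fewer nulls, scaled-down theta-model sweep) is sized to
#' run interactively on one CPU; `"full"` uses the published settings.
#'
#' @param out_dir Output directory.
#' @param design A [cohort_design()]; the desk preset defaults to 6
#'   subjects per cell.
#' @param layout An `electrode_layout`; defaults to the 32-channel grid
#'   (desk preset: a 4 x 4 grid).
#' @param scale `"desk"` or `"full"`.
#' @param n_nulls Null-ensemble size for topology (desk 20, full 100).
#' @param theta A [theta_params()] object (defaults follow `scale`).
#' @param n_perm Permutations for the statistics stage (desk 2000,
#'   full 10000).
#' @param rich_club_threshold Proportional edge threshold for the rich-club
#'   sweep (dense dwPLI-like networks need one for degree variation).
#' @param run_ictogenicity Compute per-subject BNI (default `TRUE`).
#' @param compute_ni Also run node-removal NI sweeps per subject (slow;
#'   default `FALSE`).
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, design = NULL, layout = NULL,
                            scale = c("desk", "full"), n_nulls = NULL,
                            theta = NULL, n_perm = NULL,
                            rich_club_threshold = 0.5,
                            run_ictogenicity = TRUE, compute_ni = FALSE,
                            seed = 42) {
  scale <- match.arg(scale)
  desk <- scale == "desk"
  design <- design %||% if (desk) {
    cohort_design(n_per_cell = c(blast_1 = 6, blast_3 = 6, sham_1 = 6,
                                 sham_3 = 6), seed = seed)
  } else {
    cohort_design(seed = seed)
  }
  layout <- layout %||% if (desk) make_layout(4, 4) else make_layout(4, 8)
  structure(
    list(out_dir = out_dir, design = design, layout = layout, scale = scale,
         n_nulls = n_nulls %||% if (desk) 20L else 100L,
         theta = theta %||% theta_params(scale = if (desk) "desk" else "full",
                                         seed = derive_seed(seed, 5L)),
         n_perm = n_perm %||% if (desk) 2000L else 10000L,
         rich_club_threshold = rich_club_threshold,
         run_ictogenicity = run_ictogenicity, compute_ni = compute_ni,
         seed = seed),
    class = "pipeline_config"
  )
}

log_line <- function(con, ...) {
  cat(sprintf(...), "\n", sep = "", file = con, append = TRUE)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Generates the cohort, then per subject computes topology (small-world
#' propensity and its deviations, centralities), cost (raw cost, TEWC,
#' cost-efficiency), the rich-club curve, and optionally the theta-model
#' ictogenicity sweep, and finally runs the factorial statistics over all
#' metrics plus the cost/weight-gain correlations per group. All tables are
#' written as tab-delimited text with a provenance log (configuration hash
#' and derived seeds). Reruns with the same configuration are byte-identical
#' for every metric table.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `metrics`, `stats`, `rich_club`,
#'   `correlations` and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$layout)) {
    abort_invalid("A layout is required before any compute.",
                  class = "gammanet_config_error")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  cat("", file = log_path)
  cfg_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  log_line(log_path, "config_hash\t%s", cfg_hash)
  log_line(log_path, "master_seed\t%d", config$seed)
  log_line(log_path, "scale\t%s", config$scale)

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      log_line(log_path, "stage\t%s\tFAILED\t%s", name, conditionMessage(e))
      rlang::abort(sprintf("Stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   class = "gammanet_stage_error", parent = e)
    })
    log_line(log_path, "stage\t%s\tok\t%.1fs", name,
             proc.time()[["elapsed"]] - t0)
    out
  }

  write_layout(config$layout, file.path(config$out_dir, "layout.tsv"))
  cohort <- stage("synthetic_data", {
    co <- generate_cohort(config$design, config$layout)
    write_cohort(co, file.path(config$out_dir, "connectomes"))
    co
  })

  topo_rows <- cost_rows <- icto_rows <- list()
  rc_rows <- list()
  stage("topology_cost", {
    for (i in seq_len(nrow(cohort))) {
      net <- cohort$connectome[[i]]
      sid <- cohort$subject_id[i]
      sseed <- derive_seed(config$seed, 1000L + i)
      topo <- suppressWarnings(
        network_topology(net, n_nulls = config$n_nulls, seed = sseed)
      )
      topo_rows[[i]] <- topo
      cost_rows[[i]] <- network_cost(net, config$layout,
                                      delta_c = topo$delta_c,
                                      delta_l = topo$delta_l)
      rc <- suppressWarnings(
        rich_club(net, n_nulls = config$n_nulls, seed = sseed,
                  prop_threshold = config$rich_club_threshold)
      )
      rc_rows[[i]] <- dplyr::mutate(tibble::as_tibble(rc),
                                     subject_id = sid, .before = 1)
    }
  })
  metrics <- dplyr::bind_cols(
    dplyr::select(as.data.frame(cohort), -dplyr::any_of("connectome")),
    dplyr::bind_rows(topo_rows),
    dplyr::bind_rows(cost_rows)
  )
  rc_long <- dplyr::bind_rows(rc_rows)
  rc_long <- rc_long[, c("subject_id", "k", "phi_obs", "phi_norm")]

  if (config$run_ictogenicity) {
    stage("ictogenicity", {
      for (i in seq_len(nrow(cohort))) {
        net <- cohort$connectome[[i]]
        params <- config$theta
        params$seed <- derive_seed(config$seed, 2000L + i)
        if (config$compute_ni) {
          res <- node_ictogenicity(net, params)
          icto_rows[[i]] <- tibble::tibble(bni = res$bni_pre,
                                            ni_mean = res$ni_mean,
                                            ni_sd = res$ni_sd)
        } else {
          icto_rows[[i]] <- tibble::tibble(bni = bni(psz_curve(net, params)),
                                            ni_mean = NA_real_,
                                            ni_sd = NA_real_)
        }
      }
    })
    metrics <- dplyr::bind_cols(metrics, dplyr::bind_rows(icto_rows))
  }

  metric_vars <- intersect(
    c("swp", "delta_c", "delta_l", "betweenness_global",
      "eigenvector_global", "c_obs", "tewc", "sce", "ice", "bni",
      "ni_mean", "ni_sd"),
    names(metrics)
  )
  metric_vars <- metric_vars[vapply(metric_vars, function(v) {
    sum(!is.na(metrics[[v]])) == nrow(metrics)
  }, logical(1))]
  stats_tab <- stage("stats", {
    cohort_stats(metrics, metric_vars, n_perm = config$n_perm,
                 seed = derive_seed(config$seed, 3000L))
  })
  correlations <- stage("correlations", {
    purrr::map_dfr(c("blast", "sham"), function(grp) {
      idx <- metrics$group == grp
      sc <- spearman_ci(metrics$tewc[idx], metrics$weight_gain[idx],
                        n_boot = config$n_perm,
                        seed = derive_seed(config$seed, 4000L))
      tibble::tibble(group = grp, rho = sc$rho, ci_low = sc$ci95[1],
                     ci_high = sc$ci95[2], p = sc$p, n = sc$n)
    })
  })

  paths <- list(
    metrics = file.path(config$out_dir, "metrics.tsv"),
    stats = file.path(config$out_dir, "stats.tsv"),
    rich_club = file.path(config$out_dir, "rich_club.tsv"),
    correlations = file.path(config$out_dir, "correlations.tsv")
  )
  fmt <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) formatC(x, digits = 12,
                                                   format = "g"))
    df
  }
  write.table(fmt(metrics), paths$metrics, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(fmt(stats_tab), paths$stats, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(fmt(rc_long), paths$rich_club, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(fmt(correlations), paths$correlations, sep = "\t",
              quote = FALSE, row.names = FALSE)
  log_line(log_path, "done\t%s", cfg_hash)
  invisible(list(metrics = tibble::as_tibble(metrics), stats = stats_tab,
                 rich_club = rc_long, correlations = correlations,
                 paths = paths))
}
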