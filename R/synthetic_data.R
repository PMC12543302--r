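# Ring-lattice slot order: pair indices filled along subdiagonal offsets
# 1, 2, ... in ring order, stable within an offset. Used both to build
# lattice fixtures and to construct the equivalent regular null.
ring_lattice_slots <- function(n) {
  out <- matrix(0L, nrow = n * (n - 1) / 2, ncol = 2)
  row <- 1L
  for (d in seq_len(floor(n / 2))) {
    top <- if (2 * d == n) n / 2 else n  # opposite offset has n/2 unique pairs
    for (i in seq_len(top)) {
      j <- (i + d - 1L) %% n + 1L
      out[row, ] <- sort(c(i, j))
      row <- row + 1L
    }
  }
  out
}

#' Simulate a phase-coupled multichannel recording
#'
#' Channels are stochastic phase oscillators about a common carrier
#' frequency. Coupled pairs are pulled toward a fixed, non-zero target phase
#' lag, so their phase-lag consistency — and hence downstream dwPLI —
#' increases monotonically with the planted coupling strength. Target lags
#' are drawn uniformly from 30-150 degrees, away from the 0/180-degree blind
#' spots of phase-lag estimators.
#'
#' @param layout An `electrode_layout`; channel count follows it.
#' @param coupling Symmetric matrix of planted coupling strengths in
#'   \[0, 1\], zero diagonal.
#' @param carrier_hz Carrier frequency (Hz), strictly below Nyquist.
#' @param duration_s Recording duration (s).
#' @param rate_hz Sampling rate (Hz).
#' @param noise_sd Additive measurement noise SD (uV).
#' @param seed Integer seed; identical seeds give bit-identical samples.
#' @param lag_deg Optional fixed target lag in degrees for all coupled pairs
#'   (otherwise drawn per pair).
#' @param phase_noise_sd Wiener phase-noise intensity (rad/sqrt(s)).
#' @param pull Phase-pulling rate per unit coupling (rad/s).
#' @param amp Oscillation amplitude (uV).
#' @return A `synthetic_recording`: list with `samples` (channels x time,
#'   uV), `rate` (Hz), `ground_truth_coupling`, `node_ids`, `carrier_hz`,
#'   `seed`.
#' @export
simulate_coupled_recording <- function(layout, coupling, carrier_hz = 40,
                                       duration_s = 60, rate_hz = 1000,
                                       noise_sd = 5, seed = 1,
                                       lag_deg = NULL, phase_noise_sd = 12,
                                       pull = 25, amp = 20) {
  stopifnot(inherits(layout, "electrode_layout"))
  check_weight_matrix(coupling, "coupling")
  n <- length(layout$ids)
  if (nrow(coupling) != n) {
    abort_invalid("`coupling` dimension must equal the layout size.")
  }
  check_scalar_number(carrier_hz, "carrier_hz", lower = 0, strict_lower = TRUE)
  if (carrier_hz >= rate_hz / 2) {
    abort_invalid("`carrier_hz` must lie strictly below the Nyquist frequency.")
  }
  check_scalar_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  n_samples <- round(duration_s * rate_hz)

  set.seed(seed)
  lag <- matrix(0, n, n)
  pairs <- upper_pairs(n)
  lag_vals <- if (is.null(lag_deg)) {
    runif(nrow(pairs), 30, 150) * pi / 180
  } else {
    rep(lag_deg * pi / 180, nrow(pairs))
  }
  lag[pairs] <- lag_vals
  lag <- lag - t(lag)   # antisymmetric: target phi_i - phi_j for i < j

  samples <- phase_recording_cpp(coupling, lag, carrier_hz, rate_hz,
                                 n_samples, pull, phase_noise_sd, noise_sd,
                                 amp)
  rownames(samples) <- layout$ids
  structure(
    list(samples = samples, rate = rate_hz,
         ground_truth_coupling = coupling, node_ids = layout$ids,
         carrier_hz = carrier_hz, seed = seed),
    class = "synthetic_recording"
  )
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf(
    "<synthetic_recording> %d channels x %d samples @ %g Hz (carrier %g Hz)\n",
    nrow(x$samples), ncol(x$samples), x$rate, x$carrier_hz
  ))
  invisible(x)
}

#' Drop channels from a recording
#'
#' @param recording A `synthetic_recording`.
#' @param drop Channel ids to remove.
#' @return The recording restricted to the remaining channels.
#' @export
drop_channels <- function(recording, drop) {
  keep <- setdiff(recording$node_ids, drop)
  if (length(keep) < 2) abort_invalid("At least two channels must remain.")
  idx <- match(keep, recording$node_ids)
  recording$samples <- recording$samples[idx, , drop = FALSE]
  recording$ground_truth_coupling <-
    recording$ground_truth_coupling[idx, idx, drop = FALSE]
  recording$node_ids <- keep
  recording
}

#' Generate a connectome with a planted topology family
#'
#' Families: `random` places i.i.d. uniform weights on all pairs; `lattice`
#' sorts weights in descending order along ring-lattice subdiagonals (so it
#' is its own equivalent regular null); `small_world` starts from the
#' lattice and randomly relocates a small fraction of weights; `rich_club`
#' concentrates the largest weights among a designated hub set (about a
#' quarter of the nodes) on a sparse background, so hubs carry both high
#' degree and the strongest mutual edges.
#'
#' @param n_nodes Number of nodes (>= 4).
#' @param family One of `"random"`, `"lattice"`, `"small_world"`,
#'   `"rich_club"`.
#' @param strength_scale Upper bound of the weight range.
#' @param seed Integer seed.
#' @param rewire_prob Fraction of weight slots relocated for
#'   `family = "small_world"`.
#' @param density Background edge density for `family = "rich_club"`.
#' @return A `connectome` with weights in \[0, `strength_scale`\]. For
#'   `rich_club`, the hub labels are stored in attribute `hubs`.
#' @export
plant_connectome <- function(n_nodes, family = c("random", "lattice",
                                                 "small_world", "rich_club"),
                             strength_scale = 1, seed = 1,
                             rewire_prob = 0.1, density = 0.4) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 4L)
  family <- match.arg(family)
  check_scalar_number(strength_scale, "strength_scale", lower = 0,
                      strict_lower = TRUE)
  set.seed(seed)
  n_pairs <- n_nodes * (n_nodes - 1) / 2
  w <- matrix(0, n_nodes, n_nodes)
  pairs <- upper_pairs(n_nodes)
  hubs <- NULL

  if (family == "random") {
    w[pairs] <- runif(n_pairs, 0, strength_scale)
  } else if (family %in% c("lattice", "small_world")) {
    vals <- sort(runif(n_pairs, 0, strength_scale), decreasing = TRUE)
    slots <- ring_lattice_slots(n_nodes)
    w[slots] <- vals
    if (family == "small_world") {
      vec <- w[pairs]
      move <- which(runif(n_pairs) < rewire_prob)
      if (length(move) >= 2) vec[move] <- vec[sample(move)]
      w[pairs] <- vec
    }
  } else { # rich_club
    n_hubs <- max(3L, ceiling(n_nodes / 4))
    hub_idx <- sample.int(n_nodes, n_hubs)
    is_hub_pair <- pairs[, 1] %in% hub_idx & pairs[, 2] %in% hub_idx
    vals <- numeric(n_pairs)
    vals[is_hub_pair] <- runif(sum(is_hub_pair), 0.75, 1) * strength_scale
    other <- which(!is_hub_pair)
    present <- other[runif(length(other)) < density]
    vals[present] <- runif(length(present), 0.05, 0.5) * strength_scale
    w[pairs] <- vals
    hubs <- sprintf("E%02d", sort(hub_idx))
  }
  w <- w + t(w)
  out <- connectome(w)
  attr(out, "hubs") <- hubs
  out
}

#' Describe a 2 x 2 synthetic cohort design
#'
#' Encodes the between-subjects factorial design (injury group x timepoint)
#' with plantable effects: per-group connectivity strength scaling, a
#' per-cell cost-allocation bias in \[0, 1\] controlling how strongly large
#' weights are routed to distant electrode pairs (expected normalized wiring
#' cost increases with the bias), and a per-group target Spearman
#' correlation between normalized cost and the weight-gain covariate.
#'
#' Default sample sizes follow the study cohort (blast 13/20, sham 8/9 at
#' 1/3 months); the default bias pattern plants a low normalized cost for
#' blast at 1 month with recovery by 3 months, and the default correlation
#' targets are -0.52 (blast) and 0.71 (sham).
#'
#' @param n_per_cell Named integer vector with entries `blast_1`, `blast_3`,
#'   `sham_1`, `sham_3`, each >= 2.
#' @param strength_scale Named vector `c(blast = , sham = )` of global
#'   connectivity scalings.
#' @param bias Named vector of cost-allocation biases per cell, in \[0, 1\].
#' @param rho_weight_gain Named vector `c(blast = , sham = )` of target
#'   Spearman correlations between normalized cost and weight gain.
#' @param seed Master seed; every subject-level draw derives from it.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_per_cell = c(blast_1 = 13, blast_3 = 20,
                                         sham_1 = 8, sham_3 = 9),
                          strength_scale = c(blast = 1.15, sham = 1),
                          bias = c(blast_1 = 0.15, blast_3 = 0.5,
                                   sham_1 = 0.5, sham_3 = 0.5),
                          rho_weight_gain = c(blast = -0.52, sham = 0.71),
                          seed = 42) {
  cells <- c("blast_1", "blast_3", "sham_1", "sham_3")
  if (!all(cells %in% names(n_per_cell))) {
    abort_invalid("`n_per_cell` must name all four design cells.")
  }
  if (any(n_per_cell[cells] < 2)) {
    abort_invalid("Each design cell needs at least 2 subjects.")
  }
  if (!all(cells %in% names(bias)) || any(bias[cells] < 0 | bias[cells] > 1)) {
    abort_invalid("`bias` must name all four cells with values in [0, 1].")
  }
  if (!all(c("blast", "sham") %in% names(strength_scale))) {
    abort_invalid("`strength_scale` must name groups blast and sham.")
  }
  if (!all(c("blast", "sham") %in% names(rho_weight_gain)) ||
      any(abs(rho_weight_gain) >= 1)) {
    abort_invalid("`rho_weight_gain` must name both groups, values in (-1, 1).")
  }
  structure(
    list(n_per_cell = n_per_cell[cells],
         strength_scale = strength_scale[c("blast", "sham")],
         bias = bias[cells],
         rho_weight_gain = rho_weight_gain[c("blast", "sham")],
         seed = seed),
    class = "cohort_design"
  )
}

# Allocate sorted weights to distance-ranked pair slots. With probability b
# the next-largest weight goes to the farthest remaining pair, otherwise to
# a uniformly chosen remaining pair; b = 1 attains the maximum-cost
# arrangement, b = 0 a uniform one.
allocate_by_bias <- function(w_sorted_desc, dist_order_desc, b) {
  n <- length(w_sorted_desc)
  avail <- dist_order_desc          # slot ids, farthest first
  out <- numeric(n)
  take_sorted <- runif(n) < b
  for (k in seq_len(n)) {
    pick <- if (take_sorted[k]) 1L else sample.int(length(avail), 1L)
    out[avail[pick]] <- w_sorted_desc[k]
    avail <- avail[-pick]
  }
  out
}

#' Generate a synthetic cohort of connectomes with planted effects
#'
#' One connectome and one weight-gain value per subject. Edge weights are
#' drawn per subject, scaled by the group connectivity factor, and allocated
#' to electrode pairs according to the cell's cost-allocation bias, so the
#' expected normalized wiring cost increases with the bias. The weight-gain
#' covariate is built by rank-matching Gaussian noise to the realized
#' normalized cost with the per-group target correlation.
#'
#' @param design A `cohort_design`.
#' @param layout An `electrode_layout` shared by all subjects.
#' @return A tibble (`cohort_table`) with columns `subject_id`, `group`,
#'   `timepoint`, `weight_gain` and a list-column `connectome`.
#' @export
generate_cohort <- function(design, layout) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(layout, "electrode_layout"))
  n <- length(layout$ids)
  pairs <- upper_pairs(n)
  d_vec <- layout$distances[pairs]
  dist_order_desc <- order(d_vec, decreasing = TRUE)

  rows <- list()
  sid <- 0L
  for (cell in names(design$n_per_cell)) {
    grp <- sub("_(1|3)$", "", cell)
    tp <- as.integer(sub("^(blast|sham)_", "", cell))
    b <- design$bias[[cell]]
    scl <- design$strength_scale[[grp]]
    for (k in seq_len(design$n_per_cell[[cell]])) {
      sid <- sid + 1L
      set.seed(derive_seed(design$seed, sid))
      w_raw <- runif(nrow(pairs), 0.05, 1) * scl
      vec <- allocate_by_bias(sort(w_raw, decreasing = TRUE),
                              dist_order_desc, b)
      w <- matrix(0, n, n)
      w[pairs] <- vec
      w <- w + t(w)
      net <- connectome(w, node_ids = layout$ids)
      rows[[sid]] <- tibble::tibble(
        subject_id = sprintf("S%03d", sid),
        group = grp, timepoint = tp,
        connectome = list(net)
      )
    }
  }
  tab <- dplyr::bind_rows(rows)
  tab$group <- factor(tab$group, levels = c("blast", "sham"))
  tab$timepoint <- factor(tab$timepoint, levels = c(1, 3))

  # weight-gain covariate: Gaussian copula on realized normalized-cost ranks
  tewc_vals <- purrr::map_dbl(tab$connectome, function(net) {
    cb <- cost_bounds(net, layout)
    tewc(raw_cost(net, layout), cb$c_min, cb$c_max)
  })
  gain <- numeric(nrow(tab))
  set.seed(derive_seed(design$seed, 777777L))
  for (grp in c("blast", "sham")) {
    idx <- which(tab$group == grp)
    rho_s <- design$rho_weight_gain[[grp]]
    rho_p <- 2 * sin(pi * rho_s / 6)   # Spearman -> Pearson on the copula
    u <- qnorm(rank(tewc_vals[idx], ties.method = "average") /
                 (length(idx) + 1))
    u <- u / sd(u)   # normal scores of a small sample under-disperse
    z <- rnorm(length(idx))
    latent <- rho_p * u + sqrt(1 - rho_p^2) * z
    gain[idx] <- 100 + 15 * latent     # grams, arbitrary positive scale
  }
  tab$weight_gain <- gain
  tab <- tab[, c("subject_id", "group", "timepoint", "weight_gain",
                 "connectome")]
  class(tab) <- c("cohort_table", class(tab))
  attr(tab, "design") <- design
  tab
}

#' Write a cohort manifest and its connectomes to a directory
#'
#' Writes each subject's connectome as a delimited matrix and a tab-delimited
#' manifest `manifest.tsv` with columns `subject_id`, `group`, `timepoint`,
#' `weight_gain`, `connectome_path`.
#'
#' @param cohort A `cohort_table`.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::map_chr(seq_len(nrow(cohort)), function(i) {
    p <- file.path(dir, paste0(cohort$subject_id[i], "_connectome.tsv"))
    write_connectome(cohort$connectome[[i]], p)
    basename(p)
  })
  manifest <- dplyr::mutate(
    dplyr::select(as.data.frame(cohort), -dplyr::any_of("connectome")),
    connectome_path = paths
  )
  mp <- file.path(dir, "manifest.tsv")
  write.table(manifest, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mp)
}

#' Read a cohort manifest written by [write_cohort()]
#'
#' @param path Path to `manifest.tsv`.
#' @return A `cohort_table` tibble with connectomes loaded.
#' @export
read_cohort <- function(path) {
  manifest <- read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  dir <- dirname(path)
  nets <- purrr::map(manifest$connectome_path,
                     function(p) read_connectome(file.path(dir, p)))
  tab <- tibble::as_tibble(manifest[, setdiff(names(manifest),
                                              "connectome_path")])
  tab$group <- factor(tab$group, levels = c("blast", "sham"))
  tab$timepoint <- factor(tab$timepoint, levels = c(1, 3))
  tab$connectome <- nets
  class(tab) <- c("cohort_table", class(tab))
  tab
}
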