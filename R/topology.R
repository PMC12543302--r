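as_igraph <- function(net, inverse_weights = FALSE) {
  w <- unclass(net)
  attr(w, "band") <- NULL
  attr(w, "hubs") <- NULL
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (inverse_weights && igraph::ecount(g) > 0) {
    igraph::E(g)$weight <- 1 / igraph::E(g)$weight
  }
  g
}

#' Onnela weighted clustering coefficient
#'
#' `C_i = (1 / (k_i (k_i - 1))) * sum_{j,k} (w'_ij w'_jk w'_ik)^(1/3)` with
#' weights normalized by the network maximum; nodes with degree below 2 get
#' `C_i = 0`. An all-zero network yields all zeros.
#'
#' @param net A `connectome` (non-negative symmetric weights).
#' @return A list with `per_node` (named vector) and `mean`.
#' @export
onnela_clustering <- function(net) {
  net <- as_connectome(net)
  w <- unclass(net)
  n <- nrow(w)
  mx <- max(w)
  k <- rowSums(w > 0)
  if (mx == 0) {
    per <- stats::setNames(numeric(n), rownames(w))
    return(list(per_node = per, mean = 0))
  }
  w3 <- (w / mx)^(1 / 3)
  num <- diag(w3 %*% w3 %*% w3)
  per <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  names(per) <- rownames(w)
  list(per_node = per, mean = mean(per))
}

#' Characteristic path length under inverse-weight distances
#'
#' Edge length is the inverse weight (strong coupling = short distance);
#' shortest paths by Dijkstra; `L` is the mean geodesic over all ordered
#' node pairs. Disconnected pairs make `L` infinite (flagged by a warning).
#'
#' @param net A `connectome`.
#' @return The scalar `L` (possibly `Inf`).
#' @export
path_length <- function(net) {
  net <- as_connectome(net)
  g <- as_igraph(net, inverse_weights = TRUE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  offd <- d[row(d) != col(d)]
  if (any(is.infinite(offd))) {
    warning("Network is disconnected; path length is infinite.",
            call. = FALSE)
    return(Inf)
  }
  mean(offd)
}

#' Equivalent regular (ring-lattice) null network
#'
#' Sorts the observed weights in descending order and lays them along the
#' ring-lattice subdiagonal offsets 1, 2, ... , preserving the weight
#' multiset; ties keep their original relative order. A lattice network is
#' its own equivalent regular null.
#'
#' @param net A `connectome`.
#' @return A `connectome` with identical weight multiset.
#' @export
equivalent_regular <- function(net) {
  net <- as_connectome(net)
  n <- nrow(net)
  pairs <- upper_pairs(n)
  vals <- sort(unclass(net)[pairs], decreasing = TRUE)
  w <- matrix(0, n, n)
  w[ring_lattice_slots(n)] <- vals
  w <- w + t(w)
  connectome(w, node_ids = rownames(net), band = attr(net, "band"))
}

#' Equivalent random null ensemble
#'
#' Each null reassigns the observed weight multiset uniformly at random over
#' node pairs. Per-null clustering and path length are returned alongside
#' the null networks.
#'
#' @param net A `connectome`.
#' @param n_nulls Ensemble size (default 100).
#' @param seed Integer seed.
#' @return A `null_ensemble`: list with `kind`, `nets`, `stats` (tibble with
#'   per-null `clustering` and `path_length`), `seed`.
#' @export
equivalent_random <- function(net, n_nulls = 100, seed = 1) {
  net <- as_connectome(net)
  n <- nrow(net)
  pairs <- upper_pairs(n)
  vals <- unclass(net)[pairs]
  set.seed(seed)
  nets <- vector("list", n_nulls)
  cl <- pl <- numeric(n_nulls)
  for (b in seq_len(n_nulls)) {
    w <- matrix(0, n, n)
    w[pairs] <- sample(vals)
    w <- w + t(w)
    nb <- connectome(w, node_ids = rownames(net))
    nets[[b]] <- nb
    cl[b] <- onnela_clustering(nb)$mean
    pl[b] <- suppressWarnings(path_length(nb))
  }
  structure(
    list(kind = "random", nets = nets,
         stats = tibble::tibble(null = seq_len(n_nulls), clustering = cl,
                                path_length = pl),
         seed = seed),
    class = "null_ensemble"
  )
}

#' Small-world propensity
#'
#' Locates a weighted network on the regular-to-random continuum via the
#' clustering deviation from the equivalent regular network,
#' `delta_c = (C_reg - C_obs) / (C_reg - C_rand)`, and the path-length
#' deviation from the equivalent random ensemble,
#' `delta_l = (L_obs - L_rand) / (L_reg - L_rand)`. Both deviations are
#' clamped to \[0, 1\] before combining, so
#' `swp = 1 - sqrt((delta_c^2 + delta_l^2) / 2)` always lies in \[0, 1\].
#' Degenerate null brackets (regular equals random) set the corresponding
#' deviation to 0 with a warning.
#'
#' @param net A `connectome`.
#' @param n_nulls Random-null ensemble size.
#' @param seed Integer seed for the random nulls.
#' @param regular Optional precomputed equivalent regular network.
#' @param nulls Optional precomputed random `null_ensemble`.
#' @return A list with `swp`, `delta_c`, `delta_l`, `clustering_mean`,
#'   `path_length` and the null summaries `c_reg`, `c_rand`, `l_reg`,
#'   `l_rand`.
#' @export
swp <- function(net, n_nulls = 100, seed = 1, regular = NULL, nulls = NULL) {
  net <- as_connectome(net)
  regular <- regular %||% equivalent_regular(net)
  nulls <- nulls %||% equivalent_random(net, n_nulls = n_nulls, seed = seed)
  c_obs <- onnela_clustering(net)$mean
  l_obs <- suppressWarnings(path_length(net))
  c_reg <- onnela_clustering(regular)$mean
  l_reg <- suppressWarnings(path_length(regular))
  c_rand <- mean(nulls$stats$clustering)
  l_rand <- mean(nulls$stats$path_length)

  safe_ratio <- function(num, den, label) {
    if (!is.finite(den) || den == 0) {
      warning(sprintf("Degenerate null bracket for %s; deviation set to 0.",
                      label), call. = FALSE)
      return(0)
    }
    num / den
  }
  delta_c <- safe_ratio(c_reg - c_obs, c_reg - c_rand, "clustering")
  delta_l <- safe_ratio(l_obs - l_rand, l_reg - l_rand, "path length")
  delta_c <- min(max(delta_c, 0), 1)
  delta_l <- min(max(delta_l, 0), 1)
  list(
    swp = 1 - sqrt((delta_c^2 + delta_l^2) / 2),
    delta_c = delta_c, delta_l = delta_l,
    clustering_mean = c_obs, path_length = l_obs,
    c_reg = c_reg, c_rand = c_rand, l_reg = l_reg, l_rand = l_rand
  )
}

#' Betweenness centrality with random-null normalization
#'
#' Node betweenness on inverse-weight edge lengths (Brandes algorithm,
#' fractional credit over tied shortest paths). The global value is the mean
#' over nodes; the normalized value divides it by the mean global
#' betweenness of `n_nulls` equivalent random networks.
#'
#' @param net A `connectome`.
#' @param n_nulls Random-null count for normalization (0 skips it).
#' @param seed Integer seed.
#' @return A list with `per_node`, `global` and `normalized` (NA when
#'   `n_nulls = 0`).
#' @export
betweenness_centrality <- function(net, n_nulls = 100, seed = 1) {
  net <- as_connectome(net)
  g <- as_igraph(net, inverse_weights = TRUE)
  btw <- igraph::betweenness(g, directed = FALSE)
  global <- mean(btw)
  normalized <- NA_real_
  if (n_nulls > 0) {
    nulls <- equivalent_random(net, n_nulls = n_nulls, seed = seed)
    null_glob <- purrr::map_dbl(nulls$nets, function(nb) {
      mean(igraph::betweenness(as_igraph(nb, inverse_weights = TRUE),
                               directed = FALSE))
    })
    normalized <- global / mean(null_glob)
  }
  list(per_node = btw, global = global, normalized = normalized)
}

#' Eigenvector centrality
#'
#' Principal eigenvector of the weight matrix, non-negative and scaled to
#' unit Euclidean norm. On a disconnected network the leading component is
#' used and remaining nodes get centrality 0 (with a warning).
#'
#' @param net A `connectome`.
#' @return A list with `per_node` and `global` (mean over all nodes).
#' @export
eigenvector_centrality <- function(net) {
  net <- as_connectome(net)
  w <- unclass(net)
  n <- nrow(w)
  g <- as_igraph(net)
  comp <- igraph::components(g)
  v <- numeric(n)
  if (comp$no > 1) {
    warning("Network is disconnected; centrality computed on the largest component.",
            call. = FALSE)
    keep <- which(comp$membership == which.max(comp$csize))
  } else {
    keep <- seq_len(n)
  }
  sub <- w[keep, keep, drop = FALSE]
  ev <- eigen(sub, symmetric = TRUE)
  vec <- ev$vectors[, 1]
  if (sum(vec) < 0) vec <- -vec
  vec[vec < 0] <- 0                       # numerical negatives
  v[keep] <- vec / sqrt(sum(vec^2))
  names(v) <- rownames(w)
  list(per_node = v, global = mean(v))
}

# Degree- and connectedness-preserving weighted rewiring (edge swaps:
# (a,b),(c,d) -> (a,d),(c,b), weights travelling with their edges). If the
# result is disconnected the rewiring is redrawn.
rewire_weighted <- function(net, n_attempts = NULL, max_redraws = 10) {
  w0 <- unclass(as_connectome(net))
  n <- nrow(w0)
  el0 <- which(upper.tri(w0) & w0 > 0, arr.ind = TRUE)
  n_edges <- nrow(el0)
  if (n_edges < 2) return(net)
  n_attempts <- n_attempts %||% (5L * n_edges)
  for (redraw in seq_len(max_redraws)) {
    w <- w0
    ei <- el0[, 1]
    ej <- el0[, 2]
    for (t in seq_len(n_attempts)) {
      e <- sample.int(n_edges, 2L)
      a <- ei[e[1]]; b <- ej[e[1]]
      c_ <- ei[e[2]]; d <- ej[e[2]]
      if (runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
      if (length(unique(c(a, b, c_, d))) < 4L) next
      if (w[a, d] > 0 || w[c_, b] > 0) next
      w1 <- w[a, b]; w2 <- w[c_, d]
      w[a, b] <- 0; w[b, a] <- 0; w[c_, d] <- 0; w[d, c_] <- 0
      w[a, d] <- w1; w[d, a] <- w1; w[c_, b] <- w2; w[b, c_] <- w2
      ei[e[1]] <- min(a, d); ej[e[1]] <- max(a, d)
      ei[e[2]] <- min(c_, b); ej[e[2]] <- max(c_, b)
    }
    g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected",
                                             diag = FALSE)
    if (igraph::is_connected(g)) {
      return(connectome(w, node_ids = rownames(net)))
    }
  }
  warning("Rewired null remained disconnected after redraws; returning last draw.",
          call. = FALSE)
  connectome(w, node_ids = rownames(net))
}

phi_weighted <- function(w, degrees, k, ranked_weights) {
  surv <- which(degrees > k)
  if (length(surv) < 2) return(NA_real_)
  sub <- w[surv, surv, drop = FALSE]
  ww <- sub[upper.tri(sub)]
  ww <- ww[ww > 0]
  n_e <- length(ww)
  if (n_e == 0) return(NA_real_)
  sum(ww) / sum(ranked_weights[seq_len(n_e)])
}

#' Weighted rich-club curve with rewired-null normalization
#'
#' For each richness level `k` (node degree, `1 ... N-1`), nodes with degree
#' `<= k` are removed and the weighted rich-club coefficient is the total
#' weight among survivors divided by the sum of the equally many strongest
#' weights anywhere in the network. Nulls are degree- and
#' connectedness-preserving weighted rewirings; the normalized coefficient
#' is the ratio of the observed to the mean null coefficient. Levels leaving
#' fewer than two survivors, or with no valid null value, are reported as
#' missing.
#'
#' Dense dwPLI networks are near-complete, which leaves no degree variation
#' for the richness sweep; `prop_threshold` optionally keeps only the
#' strongest proportion of edges first, as a sensitivity device.
#'
#' @param net A `connectome`.
#' @param n_nulls Number of rewired nulls (default 100).
#' @param seed Integer seed.
#' @param prop_threshold Optional proportion of strongest edges to retain
#'   before the sweep (in (0, 1\]).
#' @return A tibble of class `rich_club_curve` with columns `k`, `phi_obs`,
#'   `phi_null_mean`, `phi_norm`.
#' @export
rich_club <- function(net, n_nulls = 100, seed = 1, prop_threshold = NULL) {
  net <- as_connectome(net)
  if (!is.null(prop_threshold)) {
    net <- threshold_proportional(net, prop_threshold)
  }
  w <- unclass(net)
  n <- nrow(w)
  degrees <- rowSums(w > 0)
  ranked <- sort(w[upper.tri(w) & w > 0], decreasing = TRUE)
  ks <- seq_len(n - 1)
  phi_obs <- purrr::map_dbl(ks, function(k) {
    phi_weighted(w, degrees, k, ranked)
  })
  set.seed(seed)
  null_phi <- matrix(NA_real_, nrow = n_nulls, ncol = length(ks))
  for (b in seq_len(n_nulls)) {
    nb <- suppressWarnings(rewire_weighted(net))
    wb <- unclass(nb)
    db <- rowSums(wb > 0)
    rb <- sort(wb[upper.tri(wb) & wb > 0], decreasing = TRUE)
    null_phi[b, ] <- purrr::map_dbl(ks, function(k) {
      phi_weighted(wb, db, k, rb)
    })
  }
  phi_null_mean <- colMeans(null_phi, na.rm = TRUE)
  phi_null_mean[is.nan(phi_null_mean)] <- NA_real_
  phi_norm <- ifelse(!is.na(phi_obs) & !is.na(phi_null_mean) &
                       phi_null_mean > 0,
                     phi_obs / phi_null_mean, NA_real_)
  out <- tibble::tibble(k = ks, phi_obs = phi_obs,
                        phi_null_mean = phi_null_mean, phi_norm = phi_norm)
  class(out) <- c("rich_club_curve", class(out))
  out
}

#' Keep only the strongest proportion of edges
#'
#' Sets all but the top `prop` fraction of edge weights to zero (stable
#' ranking; ties resolved by original order).
#'
#' @param net A `connectome`.
#' @param prop Proportion of edges to retain, in (0, 1\].
#' @return A thresholded `connectome`.
#' @export
threshold_proportional <- function(net, prop) {
  check_scalar_number(prop, "prop", lower = 0, upper = 1, strict_lower = TRUE)
  net <- as_connectome(net)
  n <- nrow(net)
  pairs <- upper_pairs(n)
  vals <- unclass(net)[pairs]
  keep_n <- ceiling(prop * length(vals))
  keep <- order(vals, decreasing = TRUE)[seq_len(keep_n)]
  w <- matrix(0, n, n)
  w[pairs[keep, , drop = FALSE]] <- vals[keep]
  w <- w + t(w)
  connectome(w, node_ids = rownames(net), band = attr(net, "band"))
}

#' Full topology summary for one connectome
#'
#' Computes clustering, path length, small-world propensity with its
#' deviations, betweenness (raw and null-normalized) and eigenvector
#' centrality in one pass, sharing one random-null ensemble.
#'
#' @param net A `connectome`.
#' @param n_nulls Null-ensemble size (default 100).
#' @param seed Integer seed.
#' @return A one-row tibble of class `topology_result`.
#' @export
network_topology <- function(net, n_nulls = 100, seed = 1) {
  net <- as_connectome(net)
  nulls <- equivalent_random(net, n_nulls = n_nulls, seed = seed)
  reg <- equivalent_regular(net)
  s <- swp(net, regular = reg, nulls = nulls)
  g <- as_igraph(net, inverse_weights = TRUE)
  btw <- igraph::betweenness(g, directed = FALSE)
  null_btw <- purrr::map_dbl(nulls$nets, function(nb) {
    mean(igraph::betweenness(as_igraph(nb, inverse_weights = TRUE),
                             directed = FALSE))
  })
  eig <- eigenvector_centrality(net)
  out <- tibble::tibble(
    clustering_mean = s$clustering_mean,
    path_length = s$path_length,
    delta_c = s$delta_c, delta_l = s$delta_l, swp = s$swp,
    betweenness_global = mean(btw),
    betweenness_norm = if (mean(null_btw) > 0) mean(btw) / mean(null_btw)
                       else NA_real_,
    eigenvector_global = eig$global
  )
  class(out) <- c("topology_result", class(out))
  out
}
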