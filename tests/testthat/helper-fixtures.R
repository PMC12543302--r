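# Shared fixtures and independent oracles, all built in code.

# Layout of three collinear points with pairwise distances 1, 2, 3
# (pairs (1,2), (2,3), (1,3)).
collinear_layout <- function() {
  coords <- tibble::tibble(id = c("A", "B", "C"), x_mm = c(0, 1, 3),
                           y_mm = 0)
  gammanet:::new_layout(coords)
}

# Triangle connectome with named edge weights w12, w13, w23.
triangle_net <- function(w12, w13, w23, ids = c("A", "B", "C")) {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- w12
  m[1, 3] <- m[3, 1] <- w13
  m[2, 3] <- m[3, 2] <- w23
  connectome(m, node_ids = ids)
}

# Random spatial instance: layout with uniform planar coordinates plus a
# complete random connectome over the same nodes.
random_spatial_instance <- function(n_nodes, seed) {
  set.seed(seed)
  coords <- tibble::tibble(
    id = sprintf("E%02d", seq_len(n_nodes)),
    x_mm = runif(n_nodes, 0, 10), y_mm = runif(n_nodes, 0, 10)
  )
  layout <- gammanet:::new_layout(coords)
  m <- matrix(0, n_nodes, n_nodes)
  p <- gammanet:::upper_pairs(n_nodes)
  m[p] <- runif(nrow(p))
  list(layout = layout, net = connectome(m + t(m), node_ids = coords$id))
}

# All permutations of 1..n (iterative heap-free construction), n small.
perms_all <- function(n) {
  out <- matrix(1L, 1, 1)
  for (k in 2:n) {
    prev <- out
    out <- matrix(0L, nrow(prev) * k, k)
    r <- 0L
    for (i in seq_len(nrow(prev))) {
      for (pos in seq_len(k)) {
        r <- r + 1L
        out[r, ] <- append(prev[i, ], k, after = pos - 1L)
      }
    }
  }
  out
}

# Brute-force exhaustive cost extremes: all permutations of w against d.
cost_extremes_bruteforce <- function(w, d) {
  pm <- perms_all(length(w))
  costs <- as.vector(matrix(w[pm], nrow = nrow(pm)) %*% d)
  list(c_min = min(costs), c_max = max(costs))
}

# Brute-force betweenness oracle: enumerate all simple paths between every
# ordered pair on inverse-weight lengths, split credit over tied shortest
# paths (Brandes convention), small n only.
betweenness_bruteforce <- function(net) {
  w <- unclass(net)
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  score <- numeric(n)
  all_paths <- function(from, to) {
    paths <- list()
    walk <- function(path, total) {
      last <- path[length(path)]
      if (last == to) {
        paths[[length(paths) + 1]] <<- list(path = path, len = total)
        return()
      }
      for (nxt in seq_len(n)) {
        if (nxt %in% path || !is.finite(len[last, nxt])) next
        walk(c(path, nxt), total + len[last, nxt])
      }
    }
    walk(from, 0)
    paths
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      ps <- all_paths(s, t)
      if (length(ps) == 0) next
      lens <- vapply(ps, `[[`, numeric(1), "len")
      best <- min(lens)
      shortest <- ps[abs(lens - best) < 1e-12]
      for (sp in shortest) {
        inner <- setdiff(sp$path, c(s, t))
        score[inner] <- score[inner] + 1 / length(shortest)
      }
    }
  }
  stats::setNames(score, rownames(w))
}

# Step-up false-discovery-rate oracle via explicit rank recursion.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# Build an evoked_waveform object directly from a time grid and matrix.
make_evoked <- function(times, amplitude) {
  amplitude <- as.matrix(amplitude)
  structure(
    list(times = times, amplitude = amplitude,
         n_trials = 1L, n_trials_retained = 1L,
         channel_ids = colnames(amplitude) %||%
           sprintf("E%02d", seq_len(ncol(amplitude))),
         rate = 1000 / diff(times[1:2])),
    class = "evoked_waveform"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
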