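# Align a connectome to a layout: returns the pairwise weight and distance
# vectors over all unordered pairs of the network's nodes. Zero-weight pairs
# are kept so the weight multiset matches the connectome exactly.
pair_vectors <- function(net, layout) {
  net <- as_connectome(net)
  stopifnot(inherits(layout, "electrode_layout"))
  ids <- rownames(net)
  if (!all(ids %in% layout$ids)) {
    abort_invalid("Connectome nodes are not all present in the layout.",
                  class = "gammanet_invalid_input")
  }
  sub <- if (identical(ids, layout$ids)) layout else subset_layout(layout, ids)
  pairs <- upper_pairs(nrow(net))
  list(w = unclass(net)[pairs], d = sub$distances[pairs])
}

#' Raw spatial wiring cost
#'
#' `C = sum_{i<j} d_ij w_ij`: the inner product of edge weights with the
#' Euclidean distances between their electrodes, each unordered pair counted
#' once. Strong or long-range coupling contributes more cost.
#'
#' @param net A `connectome` whose nodes appear in `layout`.
#' @param layout An `electrode_layout` (distances in mm).
#' @return The scalar cost (mm x weight units).
#' @export
raw_cost <- function(net, layout) {
  pv <- pair_vectors(net, layout)
  sum(pv$d * pv$w)
}

#' Extreme-cost equivalent networks via the rearrangement inequality
#'
#' Holding the distance multiset and the weight multiset fixed, the minimum
#' attainable cost pairs the largest weights with the shortest distances
#' (weights sorted descending against distances sorted ascending) and the
#' maximum cost pairs them sorted the same way — a direct consequence of the
#' rearrangement inequality, so both bounds need only one sorting operation.
#' All node pairs, including zero-weight ones, occupy arrangement slots.
#'
#' @inheritParams raw_cost
#' @return A list with `c_min` and `c_max`.
#' @export
cost_bounds <- function(net, layout) {
  pv <- pair_vectors(net, layout)
  d_sorted <- sort(pv$d)
  list(
    c_min = sum(sort(pv$w, decreasing = TRUE) * d_sorted),
    c_max = sum(sort(pv$w) * d_sorted)
  )
}

#' Total effective wiring cost (TEWC)
#'
#' The fractional deviation of the observed cost from the minimum attainable
#' cost, relative to the attainable range:
#' `TEWC = (C_obs - C_min) / (C_max - C_min)`, bounded in \[0, 1\]. Because
#' both bounds share the observed weight multiset, uniform rescaling of
#' connectivity strength cancels, which is the point of the normalization.
#' When the range is degenerate (e.g. constant weights) every arrangement
#' costs the same and the value is returned as missing with a warning.
#'
#' @param c_obs Observed cost from [raw_cost()].
#' @param c_min,c_max Bounds from [cost_bounds()].
#' @param tol Tolerance for the ordering sanity check.
#' @return TEWC in \[0, 1\], or `NA` in the degenerate case.
#' @export
tewc <- function(c_obs, c_min, c_max, tol = 1e-9) {
  rng <- c_max - c_min
  if (c_obs < c_min - tol * max(1, abs(c_min)) ||
      c_obs > c_max + tol * max(1, abs(c_max))) {
    rlang::abort("`c_obs` falls outside [c_min, c_max]; inconsistent inputs.",
                 class = "gammanet_internal_error")
  }
  if (rng <= tol * max(1, abs(c_max))) {
    warning("Degenerate cost range (c_max = c_min); TEWC undefined.",
            call. = FALSE)
    return(NA_real_)
  }
  min(max((c_obs - c_min) / rng, 0), 1)
}

#' Segregative and integrative cost-efficiency
#'
#' Joint deviation of cost and topological efficiency from their optimal
#' corner, in the same functional form as small-world propensity:
#' `SCE = 1 - sqrt((delta_c^2 + TEWC^2) / 2)` and
#' `ICE = 1 - sqrt((delta_l^2 + TEWC^2) / 2)`. High values mean low wiring
#' cost alongside small deviation from the corresponding null benchmark.
#'
#' @param tewc_value TEWC in \[0, 1\] (missing propagates).
#' @param delta_c,delta_l Clamped SWP deviations in \[0, 1\].
#' @return A list with `sce` and `ice`.
#' @export
cost_efficiency <- function(tewc_value, delta_c, delta_l) {
  if (is.na(tewc_value)) return(list(sce = NA_real_, ice = NA_real_))
  for (v in list(tewc_value, delta_c, delta_l)) {
    check_scalar_number(v, "cost_efficiency inputs", lower = 0, upper = 1)
  }
  list(
    sce = 1 - sqrt((delta_c^2 + tewc_value^2) / 2),
    ice = 1 - sqrt((delta_l^2 + tewc_value^2) / 2)
  )
}

#' Full cost decomposition for one connectome
#'
#' @param net A `connectome`.
#' @param layout An `electrode_layout`.
#' @param delta_c,delta_l Optional SWP deviations; when supplied, the
#'   cost-efficiency metrics are included.
#' @return A one-row tibble of class `cost_result` with columns `c_obs`,
#'   `c_min`, `c_max`, `tewc`, `sce`, `ice`.
#' @export
network_cost <- function(net, layout, delta_c = NULL, delta_l = NULL) {
  c_obs <- raw_cost(net, layout)
  cb <- cost_bounds(net, layout)
  tw <- tewc(c_obs, cb$c_min, cb$c_max)
  ce <- if (!is.null(delta_c) && !is.null(delta_l)) {
    cost_efficiency(tw, delta_c, delta_l)
  } else {
    list(sce = NA_real_, ice = NA_real_)
  }
  out <- tibble::tibble(c_obs = c_obs, c_min = cb$c_min, c_max = cb$c_max,
                        tewc = tw, sce = ce$sce, ice = ce$ice)
  class(out) <- c("cost_result", class(out))
  out
}
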