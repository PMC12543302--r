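#' Parameters of the theta-neuron ictogenicity model
#'
#' Defaults follow the published simulation study: excitability swept over
#' \[-1.7, -0.5\] in 40 steps, global coupling scale `K = 10`, noise level
#' `sigma = 6`, time step `dt = 0.01` and 4e6 integration steps repeated 5
#' times. The `"desk"` preset keeps the same dynamical regime at a size that
#' runs interactively (20 sweep points, 2e5 steps, 2 repetitions).
#'
#' A node is classified ictal at a sample when its phase has escaped the
#' resting fixed point: `1 - cos(theta - theta_s) > h` (default `h = 1`,
#' i.e. more than 90 degrees away).
#'
#' @param i0_range Excitability sweep interval.
#' @param n_i0 Number of sweep values.
#' @param K Global coupling scale.
#' @param sigma Noise level.
#' @param n_steps Integration steps per simulation.
#' @param dt Time step.
#' @param n_reps Repetitions per sweep value.
#' @param h Ictal phase-escape threshold.
#' @param burn_in Initial samples excluded from classification (default 0:
#'   trajectories start at the resting phase).
#' @param seed Integer seed.
#' @param scale `"full"` or `"desk"` preset; explicit arguments override it.
#' @return A `theta_params` list.
#' @export
theta_params <- function(i0_range = c(-1.7, -0.5), n_i0 = NULL, K = 10,
                         sigma = 6, n_steps = NULL, dt = 1e-2, n_reps = NULL,
                         h = 1, burn_in = 0, seed = 1,
                         scale = c("full", "desk")) {
  scale <- match.arg(scale)
  n_i0 <- n_i0 %||% if (scale == "full") 40L else 20L
  n_steps <- n_steps %||% if (scale == "full") 4e6 else 2e5
  n_reps <- n_reps %||% if (scale == "full") 5L else 2L
  if (length(i0_range) != 2 || i0_range[2] <= i0_range[1]) {
    abort_invalid("`i0_range` must be an increasing interval.")
  }
  check_scalar_number(dt, "dt", lower = 0, strict_lower = TRUE)
  check_count(n_steps, "n_steps")
  check_count(n_i0, "n_i0", min = 2L)
  check_count(n_reps, "n_reps")
  structure(
    list(i0_range = i0_range, n_i0 = as.integer(n_i0), K = K, sigma = sigma,
         n_steps = n_steps, dt = dt, n_reps = as.integer(n_reps), h = h,
         burn_in = burn_in, seed = seed),
    class = "theta_params"
  )
}

#' Scale a connectome to the unit coupling range
#'
#' Divides all weights by the network maximum, statically: the divisor is
#' computed once from the full network and reused unchanged across node
#' removals, so node-removal analyses are not confounded by renormalization.
#'
#' @param net A `connectome` with at least one positive weight.
#' @return A coupling matrix in \[0, 1\] with maximum entry 1.
#' @export
scale_connectome <- function(net) {
  net <- as_connectome(net)
  mx <- max(net)
  if (mx <= 0) {
    abort_invalid("Cannot scale an all-zero network.",
                  class = "gammanet_invalid_input")
  }
  unclass(net) / mx
}

#' Simulate the coupled theta-neuron network at one excitability
#'
#' Euler-Maruyama integration of
#' `dtheta_j = [1 - cos(theta_j) + (1 + cos(theta_j)) I_j] dt` with input
#' `I_j = i0 + sigma xi_j + (K/N) sum_i a_ij (1 - cos(theta_i - theta_s))`,
#' all phases initialized at the resting phase
#' `theta_s = -Re(acos((1 + i0)/(1 - i0)))`. Noise increments are Gaussian
#' with standard deviation `sigma * sqrt(dt)`, entering through the same
#' `(1 + cos theta)` gain as the deterministic input.
#'
#' @param A Coupling matrix in \[0, 1\] (see [scale_connectome()]).
#' @param params A [theta_params()] object.
#' @param i0 Excitability value. For `i0 >= 1` the resting phase is complex
#'   and the real-part convention applies (flagged with a warning).
#' @param seed Integer seed (defaults to `params$seed`).
#' @param return_trajectory If `TRUE`, return the full phase matrix
#'   (steps + 1 x nodes) instead of ictal fractions.
#' @return Per-node ictal fractions in \[0, 1\], or the trajectory matrix.
#' @export
simulate_theta <- function(A, params = theta_params(scale = "desk"), i0,
                           seed = NULL, return_trajectory = FALSE) {
  if (is_connectome(A)) A <- unclass(A)
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (i0 >= 1) {
    warning("`i0` >= 1: resting phase taken as the real part of a complex acos.",
            call. = FALSE)
  }
  set.seed(seed %||% params$seed)
  if (return_trajectory) {
    theta_trajectory_cpp(A, i0, params$K, params$sigma, params$n_steps,
                         params$dt)
  } else {
    theta_ictal_fraction_cpp(A, i0, params$K, params$sigma, params$n_steps,
                             params$dt, params$h, params$burn_in)
  }
}

#' Seizure probability across the excitability sweep
#'
#' For every sweep value `i0`, the seizure probability
#' `P_sz(i0) = (1/N) sum_i t_sz_i / T` is the per-node ictal time fraction
#' averaged over nodes, then over repetitions.
#'
#' @param net A `connectome` (scaled internally), or a pre-scaled coupling
#'   matrix.
#' @param params A [theta_params()] object.
#' @param seed_offset Internal offset so node-removal sweeps can share
#'   repetition seed streams.
#' @return An `ictogenicity_sweep`: tibble with columns `i0`, `rep`, `psz`
#'   plus attribute `psz_curve` (per-`i0` repetition means).
#' @export
psz_curve <- function(net, params = theta_params(scale = "desk"),
                      seed_offset = 0L) {
  A <- if (is_connectome(net)) scale_connectome(net) else as.matrix(net)
  i0_grid <- seq(params$i0_range[1], params$i0_range[2],
                 length.out = params$n_i0)
  rows <- list()
  r <- 0L
  for (rep in seq_len(params$n_reps)) {
    # one seed stream per repetition, shared across node removals
    set.seed(derive_seed(params$seed, rep + seed_offset))
    for (i0 in i0_grid) {
      fr <- theta_ictal_fraction_cpp(A, i0, params$K, params$sigma,
                                     params$n_steps, params$dt, params$h,
                                     params$burn_in)
      r <- r + 1L
      rows[[r]] <- tibble::tibble(i0 = i0, rep = rep, psz = mean(fr))
    }
  }
  out <- dplyr::bind_rows(rows)
  curve <- dplyr::summarise(dplyr::group_by(out, .data$i0),
                            psz = mean(.data$psz), .groups = "drop")
  attr(out, "psz_curve") <- curve
  class(out) <- c("ictogenicity_sweep", class(out))
  out
}

#' Brain network ictogenicity
#'
#' Normalized integral of the seizure probability over the excitability
#' sweep: the trapezoidal integral of `P_sz(i0)` divided by the sweep range,
#' so the value is bounded in \[0, 1\] and comparable across sweep
#' configurations.
#'
#' @param x An `ictogenicity_sweep` from [psz_curve()], or a data frame with
#'   columns `i0` and `psz` on a strictly increasing grid.
#' @return The scalar BNI.
#' @export
bni <- function(x) {
  curve <- if (inherits(x, "ictogenicity_sweep")) attr(x, "psz_curve") else x
  i0 <- curve$i0
  p <- curve$psz
  if (length(i0) < 2 || any(diff(i0) <= 0)) {
    abort_invalid("BNI needs a strictly increasing i0 grid of length >= 2.",
                  class = "gammanet_invalid_input")
  }
  integral <- sum(diff(i0) * (head(p, -1) + p[-1]) / 2)
  integral / (i0[length(i0)] - i0[1])
}

#' Node ictogenicity from node-removal sweeps
#'
#' Reruns the full excitability sweep with each node removed (network size
#' decremented; the static coupling divisor from the intact network is kept)
#' and reports `NI_i = (BNI_pre - BNI_post_i) / BNI_pre`: the fractional
#' drop in network ictogenicity attributable to node `i`. Repetition seed
#' streams are shared across removals to reduce comparison variance.
#'
#' @param net A `connectome`.
#' @param params A [theta_params()] object.
#' @return An `ictogenicity_result`: list with `bni_pre`, a tibble `ni`
#'   (columns `node`, `ni`), `ni_mean`, `ni_sd` and the intact-network
#'   sweep. When `bni_pre` is 0 the NI vector is missing, with a warning.
#' @export
node_ictogenicity <- function(net, params = theta_params(scale = "desk")) {
  net <- as_connectome(net)
  A <- scale_connectome(net)
  n <- nrow(A)
  sweep_pre <- psz_curve(A, params)
  bni_pre <- bni(sweep_pre)
  nodes <- rownames(net)
  if (bni_pre <= 0) {
    warning("BNI of the intact network is 0; node ictogenicity is undefined.",
            call. = FALSE)
    ni <- tibble::tibble(node = nodes, ni = NA_real_)
    return(structure(list(bni_pre = bni_pre, ni = ni, ni_mean = NA_real_,
                          ni_sd = NA_real_, sweep = sweep_pre),
                     class = "ictogenicity_result"))
  }
  ni_vals <- purrr::map_dbl(seq_len(n), function(i) {
    A_post <- A[-i, -i, drop = FALSE]
    (bni_pre - bni(psz_curve(A_post, params))) / bni_pre
  })
  ni <- tibble::tibble(node = nodes, ni = ni_vals)
  structure(
    list(bni_pre = bni_pre, ni = ni, ni_mean = mean(ni_vals),
         ni_sd = sd(ni_vals), sweep = sweep_pre),
    class = "ictogenicity_result"
  )
}

#' @export
print.ictogenicity_result <- function(x, ...) {
  cat(sprintf(
    "<ictogenicity_result> BNI = %.3f, mean NI = %.3f (SD %.3f) over %d nodes\n",
    x$bni_pre, x$ni_mean, x$ni_sd, nrow(x$ni)
  ))
  invisible(x)
}
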