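# Internal validators shared across modules.

abort_invalid <- function(msg, class = "gammanet_invalid_parameter") {
  rlang::abort(msg, class = class)
}

abort_insufficient <- function(msg) {
  rlang::abort(msg, class = "gammanet_insufficient_data")
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_invalid(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (strict_lower && x <= lower) {
    abort_invalid(sprintf("`%s` must be > %s.", name, format(lower)))
  }
  if (!strict_lower && x < lower) {
    abort_invalid(sprintf("`%s` must be >= %s.", name, format(lower)))
  }
  if (x > upper) {
    abort_invalid(sprintf("`%s` must be <= %s.", name, format(upper)))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    abort_invalid(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  as.integer(x)
}

# Symmetric, zero-diagonal, non-negative weight matrix check.
check_weight_matrix <- function(w, name = "weights", tol = 1e-9) {
  if (!is.matrix(w) || !is.numeric(w) || nrow(w) != ncol(w)) {
    abort_invalid(sprintf("`%s` must be a square numeric matrix.", name))
  }
  if (anyNA(w)) abort_invalid(sprintf("`%s` contains missing values.", name))
  asym <- max(abs(w - t(w)))
  if (asym > tol) {
    idx <- which(abs(w - t(w)) == asym, arr.ind = TRUE)[1, ]
    abort_invalid(sprintf(
      "`%s` is asymmetric beyond tolerance %g at pair (%d, %d).",
      name, tol, idx[1], idx[2]
    ), class = "gammanet_format_error")
  }
  if (any(diag(w) != 0)) {
    abort_invalid(sprintf("`%s` must have a zero diagonal.", name))
  }
  if (any(w < 0)) {
    abort_invalid(sprintf("`%s` must be non-negative.", name))
  }
  invisible(w)
}

# Index pairs i < j for an n-node network, column-major stable order.
upper_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

# Derive a child seed from a master seed; keeps results < 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 9973) %% 2147483629)
}
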