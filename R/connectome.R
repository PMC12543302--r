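#' Create a connectome object
#'
#' A connectome is the package's central currency: a symmetric, non-negative
#' weighted adjacency matrix over named electrodes, usually holding dwPLI
#' values in \[0, 1\] for a frequency band.
#'
#' @param weights Square numeric matrix; symmetric, zero diagonal,
#'   non-negative.
#' @param node_ids Node labels; defaults to existing dimnames or `E01`,
#'   `E02`, ...
#' @param band Optional length-2 frequency interval (Hz) the weights refer to.
#' @return A matrix of class `connectome` with node ids as dimnames and a
#'   `band` attribute.
#' @export
connectome <- function(weights, node_ids = NULL, band = NULL) {
  check_weight_matrix(weights)
  n <- nrow(weights)
  if (is.null(node_ids)) {
    node_ids <- rownames(weights) %||% sprintf("E%02d", seq_len(n))
  }
  if (length(node_ids) != n) {
    abort_invalid("`node_ids` length must match the matrix dimension.")
  }
  weights <- (weights + t(weights)) / 2   # remove sub-tolerance asymmetry
  dimnames(weights) <- list(node_ids, node_ids)
  structure(weights, band = band, class = c("connectome", "matrix", "array"))
}

is_connectome <- function(x) inherits(x, "connectome")

as_connectome <- function(x, ...) {
  if (is_connectome(x)) x else connectome(as.matrix(x), ...)
}

#' @export
print.connectome <- function(x, ...) {
  offd <- x[upper.tri(x)]
  band <- attr(x, "band")
  cat(sprintf(
    "<connectome> %d nodes, %d nonzero edges, weights in [%.3g, %.3g]%s\n",
    nrow(x), sum(offd > 0), min(offd), max(offd),
    if (is.null(band)) "" else sprintf(", band %g-%g Hz", band[1], band[2])
  ))
  invisible(x)
}

#' Node strengths and degrees of a connectome
#'
#' Degree counts nonzero-weight edges; strength sums edge weights.
#'
#' @param net A `connectome`.
#' @return A tibble with columns `node`, `degree`, `strength`.
#' @export
node_summary <- function(net) {
  net <- as_connectome(net)
  tibble::tibble(
    node = rownames(net),
    degree = as.integer(rowSums(net > 0)),
    strength = rowSums(net)
  )
}

#' Read and write connectomes as delimited square matrices
#'
#' The format is a tab-delimited square matrix with node ids as both header
#' row and first column. On read, the matrix must be square with matching
#' header labels and symmetric to within `tol`; violations raise a format
#' error naming the offending pair.
#'
#' @param path File path.
#' @param net A `connectome` (for writing).
#' @param tol Maximum tolerated asymmetry on read.
#' @return `read_connectome()` returns a `connectome`; `write_connectome()`
#'   returns `path` invisibly.
#' @export
read_connectome <- function(path, tol = 1e-9) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    row.names = 1)
  m <- as.matrix(tab)
  if (nrow(m) != ncol(m)) {
    abort_invalid(sprintf("Connectome file is not square: %d x %d.",
                          nrow(m), ncol(m)),
                  class = "gammanet_format_error")
  }
  if (!identical(rownames(m), colnames(m))) {
    abort_invalid("Row and column labels disagree.",
                  class = "gammanet_format_error")
  }
  check_weight_matrix(m, name = basename(path), tol = tol)
  connectome(m, node_ids = rownames(m))
}

#' @rdname read_connectome
#' @export
write_connectome <- function(net, path) {
  net <- as_connectome(net)
  tab <- cbind(id = rownames(net), as.data.frame(unclass(net)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
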