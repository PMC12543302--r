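#' Construct a planar electrode grid layout
#'
#' Builds a regular grid of electrodes spanning a rectangular skull-surface
#' footprint and computes all pairwise Euclidean distances. The default
#' geometry emulates a 32-channel rodent EEG array spanning 11.7 mm on the
#' rostrocaudal axis and 9.6 mm on the left-to-right axis, which yields a
#' minimum inter-electrode spacing above 1.2 mm.
#'
#' Rows are laid out along the rostrocaudal (x) axis and columns along the
#' left-to-right (y) axis. A span of zero is permitted only for a degenerate
#' axis with a single row or column.
#'
#' @param n_rows Number of grid rows (along the rostrocaudal axis).
#' @param n_cols Number of grid columns (along the left-to-right axis).
#' @param span_rc Rostrocaudal extent of the array in mm.
#' @param span_lr Left-to-right extent of the array in mm.
#' @return An object of class `electrode_layout`: a list with elements
#'   `ids` (electrode labels), `coords` (a tibble with columns `id`, `x_mm`,
#'   `y_mm`) and `distances` (a symmetric matrix of pairwise distances, mm).
#' @examples
#' lay <- make_layout(4, 8)
#' min(lay$distances[upper.tri(lay$distances)])
#' @export
make_layout <- function(n_rows, n_cols, span_rc = 11.7, span_lr = 9.6) {
  n_rows <- check_count(n_rows, "n_rows")
  n_cols <- check_count(n_cols, "n_cols")
  if (n_rows * n_cols < 2L) {
    abort_invalid("A layout needs at least two electrodes.")
  }
  if (span_rc < 0 || span_lr < 0) abort_invalid("Spans must be non-negative.")
  if (n_rows > 1L && span_rc <= 0) {
    abort_invalid("`span_rc` must be positive when `n_rows` > 1.")
  }
  if (n_cols > 1L && span_lr <= 0) {
    abort_invalid("`span_lr` must be positive when `n_cols` > 1.")
  }
  xs <- if (n_rows == 1L) 0 else seq(0, span_rc, length.out = n_rows)
  ys <- if (n_cols == 1L) 0 else seq(0, span_lr, length.out = n_cols)
  grid <- expand.grid(y_mm = ys, x_mm = xs)[, c("x_mm", "y_mm")]
  ids <- sprintf("E%02d", seq_len(nrow(grid)))
  coords <- tibble::tibble(id = ids, x_mm = grid$x_mm, y_mm = grid$y_mm)
  new_layout(coords)
}

new_layout <- function(coords) {
  d <- as.matrix(stats::dist(coords[, c("x_mm", "y_mm")]))
  dimnames(d) <- list(coords$id, coords$id)
  structure(
    list(ids = coords$id, coords = coords, distances = d),
    class = "electrode_layout"
  )
}

#' @export
print.electrode_layout <- function(x, ...) {
  offd <- x$distances[upper.tri(x$distances)]
  cat(sprintf(
    "<electrode_layout> %d electrodes, span %.1f x %.1f mm, min spacing %.2f mm\n",
    length(x$ids), diff(range(x$coords$x_mm)), diff(range(x$coords$y_mm)),
    min(offd)
  ))
  invisible(x)
}

#' Restrict a layout to a subset of electrodes
#'
#' Distances are recomputed on the retained subset; nothing is imputed, so a
#' layout stays valid when electrodes were dropped during recording cleanup.
#'
#' @param layout An `electrode_layout`.
#' @param ids Electrode labels to keep.
#' @return An `electrode_layout` over `ids`, in the requested order.
#' @export
subset_layout <- function(layout, ids) {
  stopifnot(inherits(layout, "electrode_layout"))
  missing_ids <- setdiff(ids, layout$ids)
  if (length(missing_ids) > 0) {
    abort_invalid(paste0(
      "Unknown electrode id(s): ", paste(missing_ids, collapse = ", ")
    ))
  }
  coords <- layout$coords[match(ids, layout$coords$id), ]
  new_layout(coords)
}

#' Read and write electrode layouts as delimited text
#'
#' The on-disk format is a tab-delimited table with columns `id`, `x_mm`,
#' `y_mm`; the distance matrix is derived on read.
#'
#' @param path File path.
#' @param layout An `electrode_layout` (for writing).
#' @return `read_layout()` returns an `electrode_layout`; `write_layout()`
#'   returns `path` invisibly.
#' @export
read_layout <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  needed <- c("id", "x_mm", "y_mm")
  if (!all(needed %in% names(tab))) {
    abort_invalid("Layout file must have columns id, x_mm, y_mm.",
                  class = "gammanet_format_error")
  }
  new_layout(tibble::as_tibble(tab[, needed]))
}

#' @rdname read_layout
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "electrode_layout"))
  write.table(layout$coords, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
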