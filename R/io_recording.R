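#' Read and write recordings as delimited matrices with a metadata sidecar
#'
#' A recording is stored as a tab-delimited channels x samples matrix with
#' channel ids as row names and a YAML sidecar (`<path>.meta.yaml`) holding
#' the sampling rate, units and seed, so the pair round-trips without loss
#' of analysis-relevant metadata.
#'
#' @param recording A recording object (list with `samples`, `rate`,
#'   `node_ids`).
#' @param path Matrix file path; the sidecar is `<path>.meta.yaml`.
#' @return `read_recording()` returns a recording list; `write_recording()`
#'   returns `path` invisibly.
#' @export
write_recording <- function(recording, path) {
  rec <- resolve_recording(recording)
  m <- rec$samples
  rownames(m) <- rec$node_ids
  write.table(m, path, sep = "\t", quote = FALSE, col.names = FALSE)
  meta <- list(rate_hz = rec$rate, units = "uV",
               n_channels = nrow(m), n_samples = ncol(m))
  if (!is.null(recording$seed)) meta$seed <- recording$seed
  if (!is.null(recording$carrier_hz)) meta$carrier_hz <- recording$carrier_hz
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta_path <- paste0(path, ".meta.yaml")
  if (!file.exists(meta_path)) {
    abort_invalid("Missing metadata sidecar for recording.",
                  class = "gammanet_format_error")
  }
  meta <- yaml::read_yaml(meta_path)
  tab <- read.table(path, header = FALSE, sep = "\t", row.names = 1)
  m <- as.matrix(tab)
  colnames(m) <- NULL
  list(samples = m, rate = meta$rate_hz, node_ids = rownames(m))
}
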