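# File formats: LFPs as little-endian float64 raw binary with a JSON
# sidecar; tables as TSV with a header row; models and ground truth as JSON.

#' Construct an LFP record
#'
#' @param samples numeric matrix, channels x time (a vector is treated as
#'   one channel), arbitrary voltage units.
#' @param fs sampling rate, Hz.
#' @param channel_depths electrode depths in micrometers, ordered
#'   superficial to deep; must be strictly monotonic for laminar probes.
#' @param t0 time of the first sample, seconds.
#' @return an object of class `lfp_record`.
#' @export
lfp_record <- function(samples, fs, channel_depths = NULL, t0 = 0) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  stopifnot(is.matrix(samples), fs > 0, all(is.finite(samples)))
  if (is.null(channel_depths)) channel_depths <- seq_len(nrow(samples)) * 50 - 50
  stopifnot(length(channel_depths) == nrow(samples))
  if (nrow(samples) > 1L && !(all(diff(channel_depths) > 0) ||
                              all(diff(channel_depths) < 0)))
    stop("channel_depths must be strictly monotonic")
  structure(list(samples = samples, fs = fs,
                 channel_depths = as.numeric(channel_depths), t0 = t0),
            class = "lfp_record")
}

#' @export
print.lfp_record <- function(x, ...) {
  cat(sprintf("<lfp_record> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  invisible(x)
}

#' Write / read an LFP record (raw float64 binary + JSON sidecar)
#'
#' Samples are stored little-endian, channel-major (channel 1 first), with
#' a sidecar `<path>.json` carrying `fs`, `n_channels`, `n_samples`,
#' `depths` and `t0`.
#'
#' @param lfp an [lfp_record()].
#' @param path path of the binary file.
#' @export
write_lfp <- function(lfp, path) {
  stopifnot(inherits(lfp, "lfp_record"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(lfp$samples)), con, size = 8L, endian = "little")
  jsonlite::write_json(
    list(fs = lfp$fs, n_channels = nrow(lfp$samples),
         n_samples = ncol(lfp$samples), depths = lfp$channel_depths,
         t0 = lfp$t0),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lfp
#' @export
read_lfp <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = meta$n_channels * meta$n_samples,
               size = 8L, endian = "little")
  lfp_record(matrix(x, nrow = meta$n_channels, byrow = TRUE),
             fs = meta$fs, channel_depths = meta$depths, t0 = meta$t0)
}

#' Write / read a table as TSV with header
#' @param df data frame.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) read.delim(path, sep = "\t", check.names = FALSE)
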