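# Container I/O. Recordings are stored in a single-file binary container:
# an ASCII first line "MEAR1 <header_bytes>\n", a UTF-8 JSON header, then the
# signal payload as little-endian float32, channel-contiguous. The float32
# payload round-trips losslessly; unknown header keys are preserved.

.MEAR_MAGIC <- "MEAR1"

#' Quantize to float32 precision
#'
#' Recordings store float32 payloads; quantizing up front makes write/read
#' round trips bit-identical.
#'
#' @param x numeric vector or matrix.
#' @return x with every value rounded to the nearest representable float32.
#' @export
float32 <- function(x) {
  d <- dim(x)
  out <- readBin(writeBin(as.vector(as.numeric(x)), raw(), size = 4,
                          endian = "little"),
                 numeric(), n = length(x), size = 4, endian = "little")
  dim(out) <- d
  out
}

#' Write a recording container
#'
#' @param recording `mea_recording` (see [assemble_recording]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "mea_recording"))
  sig <- recording$signals
  header <- list(
    magic = .MEAR_MAGIC,
    n_channels = nrow(sig),
    n_samples = ncol(sig),
    fs_hz = recording$fs_hz,
    t0_s = recording$t0_s,
    channel_meta = recording$channel_meta,
    poration_events = recording$poration_events,
    protocol = if (is.null(recording$protocol)) NULL else unclass(recording$protocol)
  )
  header <- c(header, recording$extra)
  hjson <- charToRaw(jsonlite::toJSON(header, dataframe = "columns",
                                      auto_unbox = TRUE, null = "null",
                                      digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("%s %d\n", .MEAR_MAGIC, length(hjson)), con, eos = NULL)
  writeBin(hjson, con)
  # channel-contiguous payload
  writeBin(as.vector(t(sig)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a recording container
#'
#' Validates structure: mandatory keys (`signals` payload, `fs_hz`,
#' `n_channels`, `n_samples`), channel-metadata consistency, payload size.
#' Missing poration events read back as an empty event table.
#'
#' @param path file written by [write_recording].
#' @return `mea_recording`.
#' @export
read_recording <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- character(0)
  repeat {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (length(ch) == 0) stop("read_recording: truncated file (no header line)")
    if (ch == "\n") break
    first <- c(first, ch)
  }
  parts <- strsplit(paste(first, collapse = ""), " ")[[1]]
  if (length(parts) != 2 || parts[1] != .MEAR_MAGIC)
    stop("read_recording: not a MEAR1 container")
  hlen <- as.integer(parts[2])
  header <- jsonlite::fromJSON(rawToChar(readBin(con, raw(), n = hlen)))
  for (key in c("fs_hz", "n_channels", "n_samples"))
    if (is.null(header[[key]]))
      stop(sprintf("read_recording: format error, missing key '%s'", key))
  if (header$fs_hz <= 0) stop("read_recording: fs_hz must be > 0")
  n_ch <- header$n_channels
  n_samp <- header$n_samples
  payload <- readBin(con, numeric(), n = n_ch * n_samp + 1L, size = 4,
                     endian = "little")
  if (length(payload) != n_ch * n_samp)
    stop("read_recording: format error, missing or truncated key 'signals'")
  meta <- as.data.frame(header$channel_meta %||%
                          data.frame(electrode_id = seq_len(n_ch) - 1L))
  if (nrow(meta) != n_ch)
    stop(sprintf("read_recording: validation error, channel_meta has %d rows but payload has %d channels",
                 nrow(meta), n_ch))
  ev <- header$poration_events
  ev <- if (is.null(ev) || length(ev) == 0) .empty_events() else as.data.frame(ev)
  known <- c("magic", "n_channels", "n_samples", "fs_hz", "t0_s",
             "channel_meta", "poration_events", "protocol")
  extra <- header[setdiff(names(header), known)]
  if (any(!is.finite(payload))) stop("read_recording: non-finite samples")
  protocol <- header$protocol
  if (!is.null(protocol)) class(protocol) <- "poration_protocol"
  structure(list(signals = matrix(payload, n_ch, n_samp, byrow = TRUE),
                 fs_hz = header$fs_hz, t0_s = header$t0_s %||% 0,
                 channel_meta = meta, poration_events = ev,
                 protocol = protocol, extra = extra),
            class = "mea_recording")
}

.feature_cols <- c("electrode_id", "repeat_idx", "phase", "label",
                   "ap_amplitude_mv", "apd90_ms", "tdep_ms",
                   "fp_amplitude_uv", "n_beats_averaged", "t_measure_s")

#' Write a feature table as CSV with stable column order
#'
#' @param table feature data.frame (schema columns are ordered first; extra
#'   columns follow alphabetically).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  cols <- c(intersect(.feature_cols, names(table)),
            sort(setdiff(names(table), .feature_cols)))
  utils::write.csv(table[, cols, drop = FALSE], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature table CSV
#'
#' @param path CSV written by [write_feature_table].
#' @return data.frame.
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                  encoding = "UTF-8")
}

#' Build a run manifest
#'
#' @param run_id short run label.
#' @param seed master seed of the run.
#' @param config configuration list (hashed order-insensitively).
#' @param inputs,outputs character vectors of file paths.
#' @return list with `run_id`, `created_utc`, `seed`, `config_hash`,
#'   `inputs`, `outputs`.
#' @export
run_manifest <- function(run_id, seed, config, inputs = character(0),
                         outputs = character(0)) {
  list(run_id = run_id,
       created_utc = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
       seed = seed,
       config_hash = config_hash(config),
       inputs = inputs, outputs = outputs)
}

#' Write a run manifest as JSON
#'
#' @param manifest [run_manifest] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
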