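# File-format plumbing: record containers (plain-text array + EDF), token
# CSV files, and JSON serialization of bin boundaries.
#
# The array container is the package's native record format: a CSV matrix
# of samples (one column per channel) plus a JSON sidecar carrying sampling
# rate, record id and blank ground truth. EDF support is a minimal
# self-contained reader/writer for the standard 16-bit EDF layout (ASCII
# header, one data record per second), sufficient for exchanging 4-channel
# 250 Hz records with standard EEG tooling.

blanks_to_df <- function(blanks) {
  if (length(blanks) == 0) {
    return(data.frame(onset = integer(0), blank_duration = integer(0),
                      recovery_spike_amplitude = numeric(0),
                      recovery_decay_tau = numeric(0)))
  }
  do.call(rbind, lapply(blanks, function(b) {
    data.frame(onset = b$onset, blank_duration = b$blank_duration,
               recovery_spike_amplitude = b$recovery_spike_amplitude,
               recovery_decay_tau = b$recovery_decay_tau)
  }))
}

df_to_blanks <- function(df) {
  if (is.null(df) || length(df) == 0 ||
      (is.data.frame(df) && nrow(df) == 0)) {
    return(list())
  }
  lapply(seq_len(nrow(df)), function(i) {
    blank_spec(df$onset[i], df$blank_duration[i],
               recovery_spike_amplitude = df$recovery_spike_amplitude[i],
               recovery_decay_tau = df$recovery_decay_tau[i])
  })
}

#' Write / read a record in the array container format
#'
#' `write_record` writes `<path>` as a CSV of samples (one column per
#' channel) and `<path>.json` as a sidecar with sampling rate, record id
#' and injected-blank ground truth. `read_record` reads either this format
#' (`format = "array"`) or EDF (`format = "edf"`, see [read_edf()]),
#' inferring the format from the file extension when not given.
#'
#' @param record a `ts_record`.
#' @param path file path (`.csv` recommended for the array container).
#' @return `write_record` returns `path` invisibly; `read_record` returns a
#'   `ts_record`.
#' @export
write_record <- function(record, path) {
  if (!inherits(record, "ts_record")) {
    stop("`record` must be a ts_record", call. = FALSE)
  }
  utils::write.csv(as.data.frame(record$samples), path, row.names = FALSE)
  sidecar <- list(
    record_id = record$record_id,
    sampling_rate = record$sampling_rate,
    n_channels = ncol(record$samples),
    n_samples = nrow(record$samples),
    injected_blanks = blanks_to_df(record$injected_blanks)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_record
#' @param format `"array"`, `"edf"`, or `NULL` to infer from the extension.
#' @export
read_record <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     "edf" = "edf",
                     "csv" = "array",
                     stop(sprintf("unsupported record file extension '%s'",
                                  ext), call. = FALSE))
  }
  format <- match.arg(format, c("array", "edf"))
  if (format == "edf") return(read_edf(path))
  if (!file.exists(path)) stop("record file not found", call. = FALSE)
  samples <- as.matrix(utils::read.csv(path))
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop("array container sidecar (.json) missing", call. = FALSE)
  }
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(side$sampling_rate)) {
    stop("sidecar missing sampling_rate", call. = FALSE)
  }
  new_ts_record(samples, side$sampling_rate, side$record_id,
                df_to_blanks(side$injected_blanks))
}

pad_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

#' Write / read a record as EDF
#'
#' Minimal implementation of the 16-bit EDF layout: ASCII header (256 bytes
#' plus 256 per signal), little-endian int16 samples, one data record per
#' second. Samples are linearly scaled into the 16-bit range per channel,
#' so a write/read round trip is exact only up to that quantization. Blank
#' ground truth is not representable in EDF; `read_edf` returns an empty
#' blank list.
#'
#' @param record a `ts_record`; its duration must be a whole number of
#'   seconds.
#' @param path output file path.
#' @return `write_edf` returns `path` invisibly; `read_edf` a `ts_record`.
#' @export
write_edf <- function(record, path) {
  if (!inherits(record, "ts_record")) {
    stop("`record` must be a ts_record", call. = FALSE)
  }
  fs <- record$sampling_rate
  x <- record$samples
  ns <- ncol(x)
  if (nrow(x) %% fs != 0) {
    stop("EDF export requires a whole number of 1-s data records",
         call. = FALSE)
  }
  n_rec <- nrow(x) %/% fs
  phys_min <- apply(x, 2, min)
  phys_max <- apply(x, 2, max)
  flat <- phys_max - phys_min <= 0
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- -32768
  dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(record$record_id, 80),
    pad_field("synthetic iEEG", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 + ns * 256, 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field(1, 8),
    pad_field(ns, 4)
  )
  per_sig <- function(vals, width) {
    paste0(vapply(vals, pad_field, character(1), width = width),
           collapse = "")
  }
  labels <- colnames(x)
  if (is.null(labels)) labels <- paste0("ch", seq_len(ns))
  hdr <- paste0(
    hdr,
    per_sig(labels, 16),
    per_sig(rep("", ns), 80),
    per_sig(rep("uV", ns), 8),
    per_sig(sprintf("%.6g", phys_min), 8),
    per_sig(sprintf("%.6g", phys_max), 8),
    per_sig(rep(dig_min, ns), 8),
    per_sig(rep(dig_max, ns), 8),
    per_sig(rep("", ns), 80),
    per_sig(rep(fs, ns), 8),
    per_sig(rep("", ns), 32)
  )
  writeChar(hdr, con, eos = NULL)
  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((x[idx, ch] - phys_min[ch]) * scale[ch]) + dig_min
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf_field <- function(con, width) {
  trimws(readChar(con, width, useBytes = TRUE))
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file not found", call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 8, useBytes = TRUE) # version
  record_id <- read_edf_field(con, 80)
  read_edf_field(con, 80) # recording id
  read_edf_field(con, 8); read_edf_field(con, 8) # date, time
  header_bytes <- as.integer(read_edf_field(con, 8))
  read_edf_field(con, 44)
  n_rec <- as.integer(read_edf_field(con, 8))
  rec_dur <- as.numeric(read_edf_field(con, 8))
  ns <- as.integer(read_edf_field(con, 4))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || is.na(rec_dur)) {
    stop("corrupt EDF header", call. = FALSE)
  }
  read_sig <- function(width) {
    vapply(seq_len(ns), function(i) read_edf_field(con, width),
           character(1))
  }
  labels <- read_sig(16)
  read_sig(80); read_sig(8)
  phys_min <- as.numeric(read_sig(8))
  phys_max <- as.numeric(read_sig(8))
  dig_min <- as.numeric(read_sig(8))
  dig_max <- as.numeric(read_sig(8))
  read_sig(80)
  spr <- as.integer(read_sig(8)) # samples per data record
  read_sig(32)
  seek(con, header_bytes)
  if (length(unique(spr)) != 1) {
    stop("mixed per-signal sampling rates are not supported", call. = FALSE)
  }
  fs <- spr[1] / rec_dur
  out <- matrix(NA_real_, nrow = n_rec * spr[1], ncol = ns)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2,
                     endian = "little", signed = TRUE)
      if (length(dig) < spr[ch]) stop("truncated EDF data", call. = FALSE)
      idx <- ((r - 1) * spr[ch] + 1):(r * spr[ch])
      out[idx, ch] <- phys_min[ch] + (dig - dig_min[ch]) * scale[ch]
    }
  }
  colnames(out) <- labels
  new_ts_record(out, fs, record_id)
}

#' Write / read token sequences as CSV
#'
#' One row per channel: `record_id`, `channel_id`, `signal_length`,
#' `band_count`, then the 90 token columns `t1..t90`.
#'
#' @param token_list list of `token_sequence` objects.
#' @param path CSV file path.
#' @return `write_tokens` returns `path` invisibly; `read_tokens` returns a
#'   list of `token_sequence`.
#' @export
write_tokens <- function(token_list, path) {
  rows <- lapply(token_list, function(ts) {
    stopifnot(inherits(ts, "token_sequence"))
    cbind(
      data.frame(record_id = ts$record_id, channel_id = ts$channel_id,
                 signal_length = ts$signal_length,
                 band_count = ts$band_count),
      as.data.frame(matrix(ts$tokens, nrow = 1,
                           dimnames = list(NULL,
                                           paste0("t", seq_along(ts$tokens)))))
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tokens
#' @export
read_tokens <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tok_cols <- grep("^t[0-9]+$", names(df))
  lapply(seq_len(nrow(df)), function(i) {
    new_token_sequence(as.integer(df[i, tok_cols]),
                       df$signal_length[i], df$band_count[i],
                       record_id = df$record_id[i],
                       channel_id = df$channel_id[i])
  })
}

#' Serialize bin boundaries to / from JSON
#'
#' @param boundaries a `bin_boundaries` object.
#' @param path JSON file path.
#' @return `write_boundaries` returns `path` invisibly; `read_boundaries`
#'   returns a `bin_boundaries`.
#' @export
write_boundaries <- function(boundaries, path) {
  if (!inherits(boundaries, "bin_boundaries")) {
    stop("`boundaries` must be a bin_boundaries object", call. = FALSE)
  }
  jsonlite::write_json(unclass(boundaries), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_boundaries
#' @export
read_boundaries <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(
    list(boundaries = lapply(obj$boundaries,
                             function(v) as.numeric(unlist(v))),
         band_count = as.integer(obj$band_count[[1]]),
         n_calibration = vapply(obj$n_calibration,
                                function(x) as.integer(x[[1]]), integer(1)),
         scheme_name = as.character(obj$scheme_name[[1]])),
    class = "bin_boundaries"
  )
}
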