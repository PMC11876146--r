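# Spectral band-power tokenization.
#
# One second of one channel becomes one integer token: band power is
# computed per non-overlapping 250-sample window (Hann-tapered
# periodogram, summed over the frequency bins of each band, in dB), each
# band's dB value is quantized into deciles of a calibration distribution,
# and the per-band digits are concatenated positionally (lowest-frequency
# band = most significant digit). The 3-band scheme yields tokens 000-999,
# the 4-band scheme 0000-9999.

#' Frequency-band schemes
#'
#' `"3band"`: 0-13 Hz (delta/theta/alpha), 13-35 Hz (beta), 35-125 Hz
#' (gamma). `"4band"` splits the low range into 0-8 Hz (delta/theta) and
#' 8-13 Hz (alpha) for finer low-frequency resolution given the 1/f shape
#' of neural spectra. Band intervals are left-closed; the final band
#' includes the Nyquist frequency.
#'
#' @param name `"3band"` or `"4band"`.
#' @return an object of class `band_scheme` with fields `name`, `bands`
#'   (matrix of `f_lo`, `f_hi` rows) and `band_count`.
#' @export
band_scheme <- function(name = c("3band", "4band")) {
  name <- match.arg(name)
  bands <- switch(name,
    "3band" = rbind(c(0, 13), c(13, 35), c(35, 125)),
    "4band" = rbind(c(0, 8), c(8, 13), c(13, 35), c(35, 125))
  )
  colnames(bands) <- c("f_lo", "f_hi")
  structure(
    list(name = name, bands = bands, band_count = nrow(bands)),
    class = "band_scheme"
  )
}

# Periodic Hann taper.
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

#' Per-second band-power matrix of a signal
#'
#' The signal is cut into non-overlapping windows of `window_size` samples
#' (a trailing partial window is discarded). Each window is Hann-tapered,
#' its one-sided periodogram computed, power summed over the frequency bins
#' falling in each band of the scheme, and converted to dB (10 log10).
#'
#' @param signal numeric vector, length >= `window_size`.
#' @param scheme a [band_scheme()].
#' @param sampling_rate sampling rate in Hz.
#' @param window_size window length in samples (default 250, i.e. 1 s at
#'   250 Hz).
#' @return a windows x bands numeric matrix of dB values, with attribute
#'   `window_size`.
#' @export
band_power_matrix <- function(signal, scheme, sampling_rate = 250,
                              window_size = 250) {
  if (!inherits(scheme, "band_scheme")) {
    stop("`scheme` must be a band_scheme", call. = FALSE)
  }
  n <- length(signal)
  n_win <- n %/% window_size
  if (n_win < 1) {
    stop("signal shorter than one analysis window", call. = FALSE)
  }
  x <- matrix(signal[seq_len(n_win * window_size)], nrow = window_size)
  w <- hann_window(window_size)
  X <- stats::mvfft(x * w)
  n_freq <- window_size %/% 2 + 1
  freqs <- (seq_len(n_freq) - 1) * sampling_rate / window_size
  scale <- 1 / (sampling_rate * sum(w^2))
  psd <- (Mod(X[seq_len(n_freq), , drop = FALSE])^2) * scale
  # one-sided: double all bins except DC (and Nyquist when present)
  dbl <- rep(2, n_freq)
  dbl[1] <- 1
  if (window_size %% 2 == 0) dbl[n_freq] <- 1
  psd <- psd * dbl
  f_max <- max(scheme$bands[, "f_hi"])
  out <- matrix(NA_real_, nrow = n_win, ncol = scheme$band_count)
  for (b in seq_len(scheme$band_count)) {
    lo <- scheme$bands[b, "f_lo"]
    hi <- scheme$bands[b, "f_hi"]
    sel <- freqs >= lo & (if (hi >= f_max) freqs <= hi else freqs < hi)
    p <- colSums(psd[sel, , drop = FALSE])
    out[, b] <- 10 * log10(pmax(p, .Machine$double.xmin))
  }
  colnames(out) <- paste0("band", seq_len(scheme$band_count))
  attr(out, "window_size") <- window_size
  out
}

#' Calibrate quantile bin boundaries
#'
#' Computes, per band, the 10th..90th percentiles (linear-interpolation
#' estimator) of a calibration sample of dB band powers. These nine
#' interior boundaries define ten bins of (asymptotically) equal occupancy,
#' which is what makes the per-band digit distribution uniform regardless
#' of the long-tailed shape of raw spectral power.
#'
#' @param power_samples either a windows x bands matrix (e.g. row-bound
#'   [band_power_matrix()] outputs) or a list of per-band numeric vectors.
#' @param scheme optional [band_scheme()] recorded as metadata.
#' @return an object of class `bin_boundaries`: `boundaries` (list of
#'   9-vectors per band), `band_count`, `n_calibration`, `scheme_name`.
#' @export
calibrate_bins <- function(power_samples, scheme = NULL) {
  if (is.matrix(power_samples)) {
    power_samples <- lapply(seq_len(ncol(power_samples)),
                            function(b) power_samples[, b])
  }
  if (!is.list(power_samples) || length(power_samples) < 1) {
    stop("power_samples must be a matrix or list of per-band vectors",
         call. = FALSE)
  }
  probs <- seq(0.1, 0.9, by = 0.1)
  boundaries <- lapply(seq_along(power_samples), function(b) {
    v <- power_samples[[b]]
    v <- v[is.finite(v)]
    if (length(unique(v)) < 10) {
      stop(sprintf("band %d: fewer than 10 distinct calibration values", b),
           call. = FALSE)
    }
    q <- unname(stats::quantile(v, probs = probs, type = 7))
    if (any(diff(q) <= 0)) {
      stop(sprintf("band %d: non-increasing quantile boundaries", b),
           call. = FALSE)
    }
    q
  })
  structure(
    list(
      boundaries = boundaries,
      band_count = length(power_samples),
      n_calibration = vapply(power_samples, length, integer(1)),
      scheme_name = if (!is.null(scheme)) scheme$name else NA_character_
    ),
    class = "bin_boundaries"
  )
}

#' Quantize dB values into decile digits 0-9
#'
#' Left-closed binning: a value equal to a boundary falls in the upper bin;
#' values below the first boundary map to 0 and above the last to 9.
#'
#' @param values numeric vector of dB values.
#' @param boundaries strictly increasing numeric vector of 9 interior
#'   boundaries (one band's entry of a `bin_boundaries` object).
#' @return integer vector of digits in 0..9.
#' @export
quantize_power <- function(values, boundaries) {
  if (is.unsorted(boundaries, strictly = TRUE)) {
    stop("boundaries must be strictly increasing", call. = FALSE)
  }
  findInterval(values, boundaries)
}

#' Encode per-band digits as an integer token
#'
#' The lowest-frequency band is the most significant digit, so e.g. digits
#' (4, 5, 6) for a 3-band scheme encode to token 456.
#'
#' @param digits integer vector of length `band_count`, or an
#'   n x `band_count` matrix of digits, each in 0..9.
#' @param band_count number of bands B.
#' @return integer token(s) in `[0, 10^B)`.
#' @export
encode_token <- function(digits, band_count) {
  if (!is.matrix(digits)) digits <- matrix(digits, nrow = 1)
  if (ncol(digits) != band_count) {
    stop("digits must have band_count columns", call. = FALSE)
  }
  if (any(digits < 0 | digits > 9 | digits != floor(digits))) {
    stop("digits must be integers in 0..9", call. = FALSE)
  }
  weights <- 10^((band_count - 1):0)
  as.integer(drop(digits %*% weights))
}

#' Decode an integer token into per-band digits
#'
#' Exact inverse of [encode_token()]. The mask token (10^B) is outside the
#' real vocabulary and is rejected.
#'
#' @param tokens integer vector of tokens in `[0, 10^B)`.
#' @param band_count number of bands B.
#' @return an n x B integer matrix of digits (most significant first).
#' @export
decode_token <- function(tokens, band_count) {
  v <- 10^band_count
  if (any(tokens < 0 | tokens >= v | tokens != floor(tokens))) {
    stop(sprintf("tokens must be integers in [0, %d)", v), call. = FALSE)
  }
  out <- matrix(0L, nrow = length(tokens), ncol = band_count)
  rest <- as.integer(tokens)
  for (b in band_count:1) {
    out[, b] <- rest %% 10L
    rest <- rest %/% 10L
  }
  out
}

MAX_TOKENS <- 90L
PAD_TOKEN <- 0L

new_token_sequence <- function(tokens, signal_length, band_count,
                               record_id = NA_character_,
                               channel_id = NA_character_) {
  structure(
    list(tokens = as.integer(tokens),
         signal_length = as.integer(signal_length),
         band_count = as.integer(band_count),
         record_id = record_id,
         channel_id = channel_id),
    class = "token_sequence"
  )
}

#' @export
print.token_sequence <- function(x, ...) {
  cat(sprintf("<token_sequence %s/%s: %d real of %d tokens, %d bands>\n",
              x$record_id, x$channel_id, x$signal_length, length(x$tokens),
              x$band_count))
  invisible(x)
}

#' Tokenize one cleaned channel
#'
#' Band powers are computed per window, quantized against calibrated
#' boundaries, and encoded. Sequences shorter than 90 tokens are padded
#' with token 0 (the padding convention; `signal_length` records how many
#' tokens are real), longer ones truncated to the first 90.
#'
#' @param signal numeric vector (a cleaned, normalized channel) or a
#'   `clean_channel` object.
#' @param scheme a [band_scheme()].
#' @param boundaries a `bin_boundaries` calibrated for the scheme.
#' @param sampling_rate sampling rate in Hz.
#' @param max_tokens sequence length (default 90).
#' @param record_id,channel_id identifiers carried in the result.
#' @return a `token_sequence`.
#' @export
tokenize_channel <- function(signal, scheme, boundaries,
                             sampling_rate = 250, max_tokens = MAX_TOKENS,
                             record_id = NA_character_,
                             channel_id = NA_character_) {
  if (inherits(signal, "clean_channel")) signal <- signal$samples
  if (!inherits(boundaries, "bin_boundaries")) {
    stop("`boundaries` must be a bin_boundaries object", call. = FALSE)
  }
  if (boundaries$band_count != scheme$band_count) {
    stop("boundaries/scheme band count mismatch", call. = FALSE)
  }
  bpm <- band_power_matrix(signal, scheme, sampling_rate = sampling_rate)
  digits <- vapply(seq_len(scheme$band_count), function(b) {
    quantize_power(bpm[, b], boundaries$boundaries[[b]])
  }, integer(nrow(bpm)))
  if (!is.matrix(digits)) digits <- matrix(digits, nrow = 1)
  toks <- encode_token(digits, scheme$band_count)
  n_real <- min(length(toks), max_tokens)
  out <- rep(PAD_TOKEN, max_tokens)
  out[seq_len(n_real)] <- toks[seq_len(n_real)]
  new_token_sequence(out, n_real, scheme$band_count,
                     record_id = record_id, channel_id = channel_id)
}

#' Tokenize every channel of a preprocessed record
#'
#' @param clean a `clean_record` from [preprocess_record()].
#' @param scheme,boundaries,max_tokens as in [tokenize_channel()].
#' @return a list of `token_sequence`, one per surviving channel.
#' @export
tokenize_record <- function(clean, scheme, boundaries,
                            max_tokens = MAX_TOKENS) {
  if (!inherits(clean, "clean_record")) {
    stop("`clean` must be a clean_record", call. = FALSE)
  }
  out <- vector("list", length(clean$channels))
  for (i in seq_along(clean$channels)) {
    out[[i]] <- tokenize_channel(
      clean$channels[[i]], scheme, boundaries,
      sampling_rate = clean$sampling_rate, max_tokens = max_tokens,
      record_id = clean$record_id, channel_id = names(clean$channels)[i]
    )
  }
  names(out) <- names(clean$channels)
  out
}
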