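# Shared fixtures, built lazily and cached for the session so expensive
# synthetic corpora are generated once across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# A clean (blank-free) corpus of 125 records x 4 channels = 500 channels,
# preprocessed, with calibrated 3- and 4-band tokenizers. Used by the
# random-baseline and calibration checks.
clean_tokenized_corpus <- function() {
  fixture("clean_tok", function() {
    cfg <- synthetic_config(seed = 2024L)
    corpus <- generate_corpus(cfg, n_records = 125, blank_rate = 0)
    cleaned <- lapply(corpus, preprocess_record)
    out <- list(cleaned = cleaned)
    for (nm in c("3band", "4band")) {
      sch <- band_scheme(nm)
      power <- do.call(rbind, unlist(lapply(cleaned, function(cr) {
        lapply(cr$channels, function(ch) band_power_matrix(ch$samples, sch))
      }), recursive = FALSE))
      bnd <- calibrate_bins(power, sch)
      toks <- unlist(lapply(cleaned, function(cr) {
        tokenize_record(cr, sch, bnd)
      }), recursive = FALSE)
      out[[nm]] <- list(scheme = sch, boundaries = bnd, tokens = toks)
    }
    out
  })
}

# Small calibrated 3-band tokenizer from a handful of records, for cheap
# unit tests that need plausible boundaries.
small_boundaries_3band <- function() {
  fixture("small_bnd3", function() {
    cfg <- synthetic_config(duration = 200, n_channels = 1, seed = 99L)
    rec <- generate_record(cfg)
    sch <- band_scheme("3band")
    bp <- band_power_matrix(rec$samples[, 1], sch)
    calibrate_bins(bp, sch)
  })
}

# Brute-force ±1-digit tolerance check, kept deliberately naive (explicit
# per-digit loop on decimal strings) as an independent oracle.
tolerance_oracle <- function(true_token, predicted_token, band_count) {
  td <- as.integer(strsplit(formatC(true_token, width = band_count,
                                    flag = "0"), "")[[1]])
  pd <- as.integer(strsplit(formatC(predicted_token, width = band_count,
                                    flag = "0"), "")[[1]])
  all(abs(td - pd) <= 1)
}
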