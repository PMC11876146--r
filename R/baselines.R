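# Reconstruction baselines: token interpolation and uniform random tokens,
# plus the closed-form expected accuracy of the random baseline under the
# ±1-digit tolerance rule.

#' Interpolate masked tokens from neighbouring tokens
#'
#' For each masked position, up to `context` nearest unmasked, non-padding
#' tokens are collected on each side (skipping other masked positions;
#' one-sided at sequence edges or when a side has no usable token). By
#' default each collected token is decoded into its per-band digits, digits
#' are averaged per band and rounded half-up, and the digit vector is
#' re-encoded — averaging raw token integers would mix independent band
#' digits through carry effects. Raw-integer averaging is available for
#' comparison via `average = "integer"`.
#'
#' @param tokens integer vector of length 90 containing mask tokens at
#'   `plan$positions`.
#' @param plan a `mask_plan`.
#' @param band_count number of bands B.
#' @param context tokens of context per side (1-5 in the benchmark sweep).
#' @param signal_length number of real tokens; positions beyond it are
#'   padding and never used as context.
#' @param average `"digit"` (default) or `"integer"`.
#' @return integer vector of predictions, one per masked position (sorted
#'   position order).
#' @export
interpolate_predict <- function(tokens, plan, band_count, context = 1,
                                signal_length = length(tokens),
                                average = c("digit", "integer")) {
  average <- match.arg(average)
  if (context < 1) stop("context must be >= 1", call. = FALSE)
  mask_set <- plan$positions
  usable <- setdiff(seq_len(signal_length), mask_set)
  if (length(usable) == 0) {
    stop("sequence entirely masked: no context available", call. = FALSE)
  }
  vapply(mask_set, function(p) {
    left <- usable[usable < p]
    right <- usable[usable > p]
    left <- utils::tail(left, context)
    right <- utils::head(right, context)
    ctx <- tokens[c(left, right)]
    if (average == "integer") {
      as.integer(floor(mean(ctx) + 0.5))
    } else {
      digs <- decode_token(ctx, band_count)
      avg <- floor(colMeans(digs) + 0.5)
      encode_token(avg, band_count)
    }
  }, integer(1))
}

#' Uniform random-token predictions
#'
#' Each masked position receives an independent uniform draw from the real
#' vocabulary `[0, 10^B)`.
#'
#' @param plan a `mask_plan`.
#' @param band_count number of bands B.
#' @param seed integer seed.
#' @return integer vector of predictions, one per masked position.
#' @export
random_predict <- function(plan, band_count, seed) {
  k <- length(plan$positions)
  with_seed(seed, sample.int(10^band_count, k, replace = TRUE) - 1L)
}

#' Expected accuracy of the random baseline
#'
#' Under quantile binning each band digit is uniform on 0-9, and a uniform
#' random prediction matches a uniform true digit within ±1 with
#' probability 28/100 (the 8 interior digits each accept 3 of 10
#' predictions, the 2 edge digits accept 2). Bands are independent, so the
#' token-level expected accuracy is \eqn{100 \cdot 0.28^B} percent:
#' 2.1952% for 3 bands, 0.6147% for 4.
#'
#' @param band_count number of bands B (>= 1).
#' @return expected accuracy in percent.
#' @export
expected_random_accuracy <- function(band_count) {
  if (band_count < 1) stop("band_count must be >= 1", call. = FALSE)
  100 * 0.28^band_count
}
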