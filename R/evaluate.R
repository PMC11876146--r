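# Tolerance-metric evaluation and the 1-10-token benchmark harness.

#' ±1-digit tolerance comparison of two tokens
#'
#' A prediction counts as correct when every per-band digit is within one
#' bin of the true digit (no wraparound: 0 and 9 are not adjacent). E.g.
#' with 3 bands, truth 456 accepts 345 but rejects 256.
#'
#' @param true_token,predicted_token integer vectors (recycled) of real
#'   tokens in `[0, 10^B)`; the mask token is rejected.
#' @param band_count number of bands B.
#' @return logical vector.
#' @export
within_tolerance <- function(true_token, predicted_token, band_count) {
  n <- max(length(true_token), length(predicted_token))
  t_dig <- decode_token(rep_len(true_token, n), band_count)
  p_dig <- decode_token(rep_len(predicted_token, n), band_count)
  rowSums(abs(t_dig - p_dig) > 1L) == 0L
}

#' Per-channel reconstruction accuracy
#'
#' Percentage of masked positions whose prediction is within the ±1-digit
#' tolerance of the true token.
#'
#' @param true_tokens the channel's full true token vector (or a
#'   `token_sequence`).
#' @param predicted_tokens predictions, one per masked position, in sorted
#'   position order.
#' @param plan the `mask_plan` used.
#' @param band_count number of bands B.
#' @return accuracy in percent.
#' @export
channel_accuracy <- function(true_tokens, predicted_tokens, plan,
                             band_count) {
  if (inherits(true_tokens, "token_sequence")) {
    true_tokens <- true_tokens$tokens
  }
  k <- length(plan$positions)
  if (k == 0) stop("empty mask plan", call. = FALSE)
  if (length(predicted_tokens) != k) {
    stop("one prediction per masked position is required", call. = FALSE)
  }
  truth <- true_tokens[plan$positions]
  100 * mean(within_tolerance(truth, predicted_tokens, band_count))
}

#' Aggregate per-channel accuracies
#'
#' @param per_channel numeric vector of per-channel accuracies (percent).
#' @return a list with `mean` and `sem` (sample SD over sqrt(n)).
#' @export
aggregate_accuracy <- function(per_channel) {
  n <- length(per_channel)
  if (n < 2) stop("SEM undefined for fewer than 2 channels", call. = FALSE)
  list(mean = mean(per_channel), sem = stats::sd(per_channel) / sqrt(n))
}

#' Benchmark reconstruction methods over 1-10 masked tokens
#'
#' For every combination of method, masking mode and mask count `k`, each
#' test channel is masked with [make_eval_mask()] (never touching padding),
#' predictions are obtained, per-channel accuracy is scored with the
#' ±1-digit tolerance rule, and mean and SEM over channels are reported.
#' Channels whose signal length is below `k` (below `k + 1` when
#' interpolation is among the methods, which needs at least one unmasked
#' real token as context) are skipped with a warning.
#'
#' @param test_tokens list of `token_sequence` objects.
#' @param model an `mlm_model`, required when `"stimbert"` is among the
#'   methods.
#' @param methods subset of `c("stimbert", "interpolation", "random")`.
#' @param k_range mask counts to sweep (default 1:10).
#' @param modes masking modes (default both).
#' @param context interpolation context per side.
#' @param seed integer seed for mask placement and random draws.
#' @param detail if `TRUE`, attach per-channel accuracies as attribute
#'   `"per_channel"` (data.frame with method, mode, k, channel, accuracy).
#' @return a data.frame with one row per method x mode x k: columns
#'   `method`, `mode`, `k`, `mean`, `sem`, `n_channels`, `band_count`.
#' @export
run_benchmark <- function(test_tokens, model = NULL,
                          methods = c("stimbert", "interpolation", "random"),
                          k_range = 1:10,
                          modes = c("individual", "consecutive"),
                          context = 1, seed = 1L, detail = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  modes <- match.arg(modes, c("individual", "consecutive"),
                     several.ok = TRUE)
  if ("stimbert" %in% methods && is.null(model)) {
    stop("a trained model is required for the 'stimbert' method",
         call. = FALSE)
  }
  band_count <- test_tokens[[1]]$band_count
  if (!is.null(model) && model$config$band_count != band_count) {
    stop("model band count does not match the token sequences",
         call. = FALSE)
  }
  mask_token <- as.integer(10^band_count)
  sig_len <- vapply(test_tokens, `[[`, integer(1), "signal_length")
  rows <- list()
  per_channel <- list()

  for (mode_i in seq_along(modes)) {
    mode <- modes[mode_i]
    for (k in k_range) {
      # interpolation needs at least one unmasked real token for context,
      # so channels whose whole signal would be masked are skipped too
      min_len <- if ("interpolation" %in% methods) k + 1L else k
      eligible <- which(sig_len >= min_len)
      if (length(eligible) < length(test_tokens)) {
        warning(sprintf(
          "%d channel(s) with signal_length < %d skipped (%s masking)",
          length(test_tokens) - length(eligible), k, mode
        ), call. = FALSE)
      }
      if (length(eligible) < 2) next
      plans <- lapply(eligible, function(ch) {
        make_eval_mask(sig_len[ch], k, mode,
                       seed = derive_seed(seed, mode_i, k, ch))
      })
      truths <- lapply(seq_along(eligible), function(j) {
        test_tokens[[eligible[j]]]$tokens[plans[[j]]$positions]
      })
      preds_by_method <- list()
      if ("stimbert" %in% methods) {
        masked_mat <- tokens_to_matrix(test_tokens[eligible],
                                       length(test_tokens[[1]]$tokens))
        for (j in seq_along(eligible)) {
          masked_mat[j, plans[[j]]$positions] <- mask_token
        }
        preds_by_method$stimbert <-
          predict_masked_batch(model, masked_mat,
                               lapply(plans, `[[`, "positions"))
      }
      if ("interpolation" %in% methods) {
        preds_by_method$interpolation <- lapply(seq_along(eligible), function(j) {
          ch <- eligible[j]
          toks <- test_tokens[[ch]]$tokens
          toks[plans[[j]]$positions] <- mask_token
          interpolate_predict(toks, plans[[j]], band_count,
                              context = context,
                              signal_length = sig_len[ch])
        })
      }
      if ("random" %in% methods) {
        preds_by_method$random <- lapply(seq_along(eligible), function(j) {
          random_predict(plans[[j]], band_count,
                         seed = derive_seed(seed, mode_i, k, eligible[j], 17))
        })
      }
      for (method in methods) {
        acc <- vapply(seq_along(eligible), function(j) {
          100 * mean(within_tolerance(truths[[j]],
                                      preds_by_method[[method]][[j]],
                                      band_count))
        }, numeric(1))
        agg <- aggregate_accuracy(acc)
        rows[[length(rows) + 1]] <- data.frame(
          method = method, mode = mode, k = k,
          mean = agg$mean, sem = agg$sem,
          n_channels = length(eligible), band_count = band_count
        )
        if (detail) {
          per_channel[[length(per_channel) + 1]] <- data.frame(
            method = method, mode = mode, k = k,
            channel = eligible, accuracy = acc
          )
        }
      }
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (detail) {
    attr(report, "per_channel") <- do.call(rbind, per_channel)
  }
  report
}

#' Benchmark interpolation context sizes
#'
#' Sweeps the interpolation context from 1 to 5 tokens per side at a fixed
#' mask count and mode (default: 7 consecutive tokens), alongside the model
#' and random baselines whose predictions do not depend on context.
#'
#' @param test_tokens,model,seed as in [run_benchmark()].
#' @param contexts context sizes to sweep.
#' @param k mask count (fixed).
#' @param mode masking mode.
#' @param methods methods to include.
#' @return a data.frame with one row per context x method.
#' @export
run_context_benchmark <- function(test_tokens, model = NULL,
                                  contexts = 1:5, k = 7,
                                  mode = "consecutive",
                                  methods = c("stimbert", "interpolation",
                                              "random"),
                                  seed = 1L) {
  rows <- list()
  for (ctx in contexts) {
    rep_ctx <- run_benchmark(test_tokens, model = model, methods = methods,
                             k_range = k, modes = mode, context = ctx,
                             seed = seed)
    rep_ctx$context <- ctx
    rows[[length(rows) + 1]] <- rep_ctx
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  report
}

#' Two-sample t-test between per-channel accuracy vectors
#'
#' Convenience wrapper for comparing two methods' per-channel accuracies
#' (e.g. extracted from the `"per_channel"` attribute of a detailed
#' [run_benchmark()] report).
#'
#' @param acc_a,acc_b numeric vectors of per-channel accuracies.
#' @return the `htest` object from [stats::t.test()].
#' @export
compare_methods <- function(acc_a, acc_b) {
  stats::t.test(acc_a, acc_b)
}
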