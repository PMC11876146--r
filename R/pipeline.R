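# End-to-end pipeline: simulate -> preprocess -> split -> calibrate ->
# tokenize -> train -> evaluate, with artifacts written to an output
# directory and every stage seeded from one master seed.

#' Grouped train/validation/test split
#'
#' Splits units into train/validation/test with no group straddling two
#' sets. For synthetic corpora the grouping key is the record id (all
#' channels of a record stay together); for real data a patient key can be
#' supplied instead.
#'
#' @param ids character vector of unit ids (e.g. record ids).
#' @param proportions length-3 numeric vector (train, validation, test),
#'   summing to 1.
#' @param seed integer seed.
#' @param group optional grouping key, parallel to `ids`; defaults to the
#'   ids themselves.
#' @return a list with character vectors `train`, `validation`, `test`;
#'   pairwise disjoint, union = `ids`.
#' @export
split_corpus <- function(ids, proportions = c(0.8, 0.1, 0.1), seed = 1L,
                         group = NULL) {
  if (length(proportions) != 3 || abs(sum(proportions) - 1) > 1e-8) {
    stop("proportions must be 3 values summing to 1", call. = FALSE)
  }
  if (is.null(group)) group <- ids
  if (length(group) != length(ids)) {
    stop("group must be parallel to ids", call. = FALSE)
  }
  groups <- unique(group)
  shuffled <- with_seed(seed, sample(groups))
  n <- length(shuffled)
  n_train <- max(1, round(proportions[1] * n))
  n_val <- max(1, round(proportions[2] * n))
  n_train <- min(n_train, n - 2)
  n_val <- min(n_val, n - n_train - 1)
  g_train <- shuffled[seq_len(n_train)]
  g_val <- shuffled[n_train + seq_len(n_val)]
  g_test <- shuffled[(n_train + n_val + 1):n]
  list(
    train = ids[group %in% g_train],
    validation = ids[group %in% g_val],
    test = ids[group %in% g_test]
  )
}

#' Pipeline configuration
#'
#' Bundles the per-stage parameters of [run_pipeline()] into one
#' JSON-serializable object. All stage seeds are derived from `seed`.
#'
#' @param out_dir output directory for stage artifacts.
#' @param scheme `"3band"` or `"4band"`.
#' @param n_records number of synthetic records to simulate.
#' @param blank_rate fraction of records receiving stimulation blanks.
#' @param duration,sampling_rate,n_channels,band_state_half_life passed to
#'   [synthetic_config()].
#' @param calibration_records number of training records pooled for
#'   quantile calibration (capped at the training-set size).
#' @param split train/validation/test proportions (by record id).
#' @param model named list of [model_config()] overrides (e.g.
#'   `list(model_dimension = 64, max_epochs = 10)`).
#' @param k_range,modes,context evaluation protocol, as in
#'   [run_benchmark()].
#' @param seed master seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            scheme = "3band",
                            n_records = 50,
                            blank_rate = 0.35,
                            duration = 90,
                            sampling_rate = 250,
                            n_channels = 4,
                            band_state_half_life = 5,
                            calibration_records = 250,
                            split = c(0.8, 0.1, 0.1),
                            model = list(),
                            k_range = 1:10,
                            modes = c("individual", "consecutive"),
                            context = 1,
                            seed = 1L) {
  structure(
    list(out_dir = out_dir, scheme = scheme, n_records = n_records,
         blank_rate = blank_rate, duration = duration,
         sampling_rate = sampling_rate, n_channels = n_channels,
         band_state_half_life = band_state_half_life,
         calibration_records = calibration_records, split = split,
         model = model, k_range = k_range, modes = modes,
         context = context, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full pipeline
#'
#' Simulates a corpus, preprocesses every channel, splits record ids into
#' train/validation/test (grouped, no leakage), calibrates quantile bin
#' boundaries on training records only, tokenizes everything, trains the
#' masked-token model, and benchmarks it against the interpolation and
#' random baselines on the test set. Artifacts (resolved config, split,
#' boundaries, tokens, model checkpoint, reports) are written to
#' `config$out_dir`; existing artifacts are reused unless `force = TRUE`.
#'
#' @param config a [pipeline_config()].
#' @param force recompute stages whose outputs already exist.
#' @param train run the model-training stage (skipped when `FALSE`, in
#'   which case only the baselines are benchmarked).
#' @param verbose print stage progress.
#' @return named list of artifact paths, invisibly; the benchmark report is
#'   also returned in the `report` element.
#' @export
run_pipeline <- function(config, force = FALSE, train = TRUE,
                         verbose = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    stop("`config` must be a pipeline_config", call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    config = file.path(config$out_dir, "config.json"),
    split = file.path(config$out_dir, "split.json"),
    boundaries = file.path(config$out_dir, "boundaries.json"),
    tokens = file.path(config$out_dir, "tokens.csv"),
    model = file.path(config$out_dir, "model.rds"),
    report = file.path(config$out_dir, "report.csv"),
    context_report = file.path(config$out_dir, "context_report.csv")
  )
  say <- function(...) if (verbose) message(sprintf(...))
  cfg_json <- unclass(config)
  cfg_json$package_version <- as.character(utils::packageVersion("stimfill"))
  jsonlite::write_json(cfg_json, paths$config, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  scheme <- band_scheme(config$scheme)

  done <- file.exists(paths$tokens) && file.exists(paths$boundaries) &&
    file.exists(paths$split) && !force
  if (!done) {
    say("simulating %d records", config$n_records)
    syn_cfg <- synthetic_config(
      sampling_rate = config$sampling_rate, duration = config$duration,
      n_channels = config$n_channels,
      band_state_half_life = config$band_state_half_life,
      seed = derive_seed(config$seed, 1)
    )
    corpus <- generate_corpus(syn_cfg, config$n_records,
                              blank_rate = config$blank_rate)

    say("preprocessing")
    cleaned <- lapply(corpus, preprocess_record)

    ids <- names(cleaned)
    split <- split_corpus(ids, proportions = config$split,
                          seed = derive_seed(config$seed, 2))
    jsonlite::write_json(split, paths$split, digits = NA)

    say("calibrating %s boundaries", config$scheme)
    calib_ids <- utils::head(split$train,
                             min(config$calibration_records,
                                 length(split$train)))
    calib_power <- do.call(rbind, unlist(lapply(cleaned[calib_ids], function(cr) {
      lapply(cr$channels, function(ch) {
        band_power_matrix(ch$samples, scheme,
                          sampling_rate = config$sampling_rate)
      })
    }), recursive = FALSE))
    boundaries <- calibrate_bins(calib_power, scheme)
    write_boundaries(boundaries, paths$boundaries)

    say("tokenizing")
    token_list <- unlist(lapply(cleaned, function(cr) {
      tokenize_record(cr, scheme, boundaries)
    }), recursive = FALSE)
    write_tokens(token_list, paths$tokens)
  } else {
    say("reusing existing tokens/boundaries/split")
    token_list <- read_tokens(paths$tokens)
    split <- jsonlite::read_json(paths$split, simplifyVector = TRUE)
  }

  rec_of <- vapply(token_list, `[[`, character(1), "record_id")
  sets <- list(
    train = token_list[rec_of %in% split$train],
    validation = token_list[rec_of %in% split$validation],
    test = token_list[rec_of %in% split$test]
  )

  model <- NULL
  if (train) {
    if (file.exists(paths$model) && !force) {
      say("reusing existing model checkpoint")
      model <- load_model(paths$model)
    } else {
      say("training on %d channels (validating on %d)",
          length(sets$train), length(sets$validation))
      margs <- utils::modifyList(
        list(band_count = scheme$band_count,
             seed = derive_seed(config$seed, 3)),
        config$model
      )
      mcfg <- do.call(model_config, margs)
      model <- train_mlm(sets$train, sets$validation, mcfg,
                         verbose = verbose)
      save_model(model, paths$model)
    }
  }

  methods <- if (train) c("stimbert", "interpolation", "random") else
    c("interpolation", "random")
  say("benchmarking %d test channels", length(sets$test))
  report <- run_benchmark(sets$test, model = model, methods = methods,
                          k_range = config$k_range, modes = config$modes,
                          context = config$context,
                          seed = derive_seed(config$seed, 4), detail = TRUE)
  utils::write.csv(report, paths$report, row.names = FALSE)
  ctx_report <- run_context_benchmark(sets$test, model = model,
                                      methods = methods,
                                      seed = derive_seed(config$seed, 5))
  utils::write.csv(ctx_report, paths$context_report, row.names = FALSE)

  out <- paths
  out$report_df <- report
  out$context_report_df <- ctx_report
  out$model_obj <- model
  out$sets <- lapply(sets, length)
  invisible(out)
}
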