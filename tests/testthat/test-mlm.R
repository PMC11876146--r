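test_that("training masks hit exactly 16 of 90 positions, reproducibly", {
  cfg <- model_config(band_count = 3)
  toks <- sample(0:999, 90, replace = TRUE)
  am <- apply_training_mask(toks, cfg, seed = 4)
  expect_length(am$plan$positions, 16)
  expect_equal(sum(am$masked_tokens == cfg$mask_token), 16L)
  expect_equal(am$masked_tokens[-am$plan$positions],
               as.integer(toks[-am$plan$positions]))
  am2 <- apply_training_mask(toks, cfg, seed = 4)
  expect_identical(am$plan, am2$plan)
  expect_error(apply_training_mask(toks[1:80], cfg, seed = 1), "max_len")
})

test_that("training-mask positions are uniform over all 90 slots", {
  cfg <- model_config(band_count = 3)
  toks <- rep(0L, 90)
  n_draws <- 3000
  counts <- integer(90)
  for (s in seq_len(n_draws)) {
    p <- apply_training_mask(toks, cfg, seed = s)$plan$positions
    counts[p] <- counts[p] + 1L
  }
  # each slot is chosen with probability 16/90; Bonferroni-adjusted
  # binomial 99.9% band across the 90 slots
  bounds <- qbinom(c(0.0005 / 90, 1 - 0.0005 / 90), n_draws, 16 / 90)
  expect_true(all(counts >= bounds[1] & counts <= bounds[2]))
})

test_that("evaluation masks stay inside the real signal", {
  p1 <- make_eval_mask(80, 10, "individual", seed = 2)
  expect_true(all(p1$positions <= 80))
  expect_length(unique(p1$positions), 10)
  p2 <- make_eval_mask(80, 10, "consecutive", seed = 2)
  expect_true(all(p2$positions <= 80))
  expect_equal(p2$positions, p2$positions[1] + 0:9)
  # k = 1: both modes coincide
  expect_identical(make_eval_mask(50, 1, "individual", seed = 3)$positions,
                   make_eval_mask(50, 1, "consecutive", seed = 3)$positions)
  expect_error(make_eval_mask(5, 6, "individual", seed = 1), "exceeds")
})

test_that("analytic gradients match numerical differentiation", {
  ns <- asNamespace("stimfill")
  cfg <- model_config(band_count = 1, model_dimension = 8,
                      num_hidden_layers = 2, num_attention_heads = 2,
                      ffn_multiplier = 2, max_len = 12, seed = 5)
  set.seed(42)
  tok <- matrix(sample(0:9, 3 * 12, replace = TRUE), 3, 12)
  mrows <- c(2L, 5L, 13L, 20L, 30L)
  labels <- sample(0:9, 5, replace = TRUE)
  for (r in mrows) {
    i <- (r - 1) %/% 12 + 1
    tok[i, (r - 1) %% 12 + 1] <- cfg$mask_token
  }
  p <- ns$init_transformer_params(cfg)
  fw <- ns$mlm_forward(p, cfg, tok, mrows, labels = labels,
                       want_grad = TRUE)
  eps <- 1e-6
  for (nm in names(fw$grads)) {
    g <- fw$grads[[nm]]
    for (j in sample(length(g), min(3, length(g)))) {
      p2 <- p
      p2[[nm]][j] <- p2[[nm]][j] + eps
      l1 <- ns$mlm_forward(p2, cfg, tok, mrows, labels = labels)$loss
      p2[[nm]][j] <- p2[[nm]][j] - 2 * eps
      l2 <- ns$mlm_forward(p2, cfg, tok, mrows, labels = labels)$loss
      num <- (l1 - l2) / (2 * eps)
      # absolute floor absorbs finite-difference noise on near-zero grads
      expect_lt(abs(num - g[j]), 1e-4 * max(1e-2, abs(num) + abs(g[j])))
    }
  }
})

test_that("a constant-pattern corpus is learned to near-perfect accuracy", {
  cfg <- model_config(band_count = 3, model_dimension = 32,
                      num_hidden_layers = 1, num_attention_heads = 2,
                      max_epochs = 10, batch_size = 16, seed = 2)
  seqs <- lapply(1:32, function(i) rep(456L, 90))
  model <- train_mlm(seqs, seqs[1:8], cfg)
  expect_lt(model$history$train_loss[nrow(model$history)],
            model$history$train_loss[1])
  correct <- 0L
  total <- 0L
  for (s in 1:5) {
    am <- apply_training_mask(seqs[[1]], cfg, seed = 100 + s)
    pred <- predict_masked(model, am$masked_tokens, am$plan)
    correct <- correct + sum(pred == 456L)
    total <- total + length(pred)
  }
  expect_gte(100 * correct / total, 99)
})

test_that("training is reproducible and predictions deterministic", {
  cfg <- model_config(band_count = 1, model_dimension = 16,
                      num_hidden_layers = 1, num_attention_heads = 2,
                      max_epochs = 2, batch_size = 8, seed = 77)
  set.seed(5)
  seqs <- lapply(1:16, function(i) sample(0:9, 90, replace = TRUE))
  m1 <- train_mlm(seqs, seqs[1:4], cfg)
  m2 <- train_mlm(seqs, seqs[1:4], cfg)
  expect_equal(m1$history$val_loss, m2$history$val_loss, tolerance = 1e-12)
  plan <- make_eval_mask(90, 3, "individual", seed = 9)
  masked <- seqs[[1]]
  masked[plan$positions] <- cfg$mask_token
  expect_identical(predict_masked(m1, masked, plan),
                   predict_masked(m2, masked, plan))
})

test_that("predictions exclude the mask token and respect the plan", {
  cfg <- model_config(band_count = 1, model_dimension = 16,
                      num_hidden_layers = 1, num_attention_heads = 2,
                      max_epochs = 1, batch_size = 8, seed = 1)
  set.seed(6)
  seqs <- lapply(1:8, function(i) sample(0:9, 90, replace = TRUE))
  model <- train_mlm(seqs, seqs[1:2], cfg)
  plan <- make_eval_mask(90, 5, "individual", seed = 3)
  masked <- seqs[[1]]
  masked[plan$positions] <- cfg$mask_token
  pred <- predict_masked(model, masked, plan)
  expect_length(pred, 5)
  expect_true(all(pred >= 0 & pred < 10))
  # empty plan -> empty prediction set
  empty <- structure(list(positions = integer(0), mode = "individual",
                          seed = 1L), class = "mask_plan")
  expect_length(predict_masked(model, seqs[[1]], empty), 0)
  # inconsistent mask placement is rejected
  expect_error(predict_masked(model, seqs[[1]], plan), "placement")
})

test_that("checkpoints round trip to identical predictions", {
  cfg <- model_config(band_count = 1, model_dimension = 16,
                      num_hidden_layers = 1, num_attention_heads = 2,
                      max_epochs = 1, batch_size = 8, seed = 12)
  set.seed(13)
  seqs <- lapply(1:8, function(i) sample(0:9, 90, replace = TRUE))
  model <- train_mlm(seqs, seqs[1:2], cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  expect_true(file.exists(paste0(path, ".json")))
  reloaded <- load_model(path)
  plan <- make_eval_mask(90, 4, "consecutive", seed = 21)
  masked <- seqs[[3]]
  masked[plan$positions] <- cfg$mask_token
  expect_identical(predict_masked(model, masked, plan),
                   predict_masked(reloaded, masked, plan))
})

test_that("config invariants are enforced", {
  expect_error(model_config(model_dimension = 30, num_attention_heads = 4),
               "divisible")
  cfg <- model_config(band_count = 4)
  expect_equal(cfg$vocab_size, 10001L)
  expect_equal(cfg$mask_token, 10000L)
  # out-of-vocabulary corpus is rejected
  cfg3 <- model_config(band_count = 3, max_epochs = 1)
  bad <- lapply(1:4, function(i) rep(1000L, 90))
  expect_error(train_mlm(bad, bad, cfg3), "vocabulary")
})
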