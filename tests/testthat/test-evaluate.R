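eval_plan <- function(positions, mode = "individual", seed = 1L) {
  structure(list(positions = sort(as.integer(positions)), mode = mode,
                 seed = as.integer(seed)), class = "mask_plan")
}

test_that("±1-digit tolerance matches the documented examples", {
  expect_true(within_tolerance(456L, 345L, 3))
  expect_false(within_tolerance(456L, 256L, 3))
  toks <- sample(0:999, 50)
  expect_true(all(within_tolerance(toks, toks, 3)))
  # no wraparound between digits 0 and 9
  expect_false(within_tolerance(900L, 0L, 3))
  expect_false(within_tolerance(9L, 0L, 1))
  expect_error(within_tolerance(1000L, 5L, 3), "\\[0, 1000\\)")
})

test_that("fast tolerance metric agrees with the brute-force oracle", {
  set.seed(19)
  truth <- sample(0:999, 400, replace = TRUE)
  pred <- sample(0:999, 400, replace = TRUE)
  # bias some pairs toward near-misses so both outcomes are exercised
  pred[1:100] <- pmin(999, truth[1:100] + sample(0:2, 100, replace = TRUE))
  fast <- within_tolerance(truth, pred, 3)
  slow <- mapply(tolerance_oracle, truth, pred,
                 MoreArgs = list(band_count = 3))
  expect_identical(fast, unname(slow))
  expect_gt(sum(fast), 0)
  expect_gt(sum(!fast), 0)
})

test_that("channel accuracy is the percentage of tolerated predictions", {
  truth <- rep(456L, 90)
  plan <- eval_plan(1:16)
  pred <- c(rep(456L, 8), rep(111L, 8))
  expect_equal(channel_accuracy(truth, pred, plan, 3), 50)
  expect_equal(channel_accuracy(truth, rep(455L, 16), plan, 3), 100)
  plan3 <- eval_plan(1:3)
  expect_equal(channel_accuracy(truth, c(456L, 0L, 0L), plan3, 3),
               100 / 3)
  expect_error(channel_accuracy(truth, pred, eval_plan(integer(0)), 3),
               "empty")
  expect_error(channel_accuracy(truth, pred[1:3], plan, 3),
               "per masked position")
})

test_that("aggregation reports mean and SEM with n-1 convention", {
  a <- aggregate_accuracy(c(50, 60))
  expect_equal(a$mean, 55)
  expect_equal(a$sem, 5)
  expect_equal(aggregate_accuracy(c(70, 70, 70))$sem, 0)
  b <- aggregate_accuracy(c(0, 100))
  expect_equal(b$mean, 50)
  expect_equal(b$sem, 50)
  expect_error(aggregate_accuracy(42), "fewer than 2")
})

test_that("benchmark bookkeeping: rows, determinism, perfect oracle", {
  set.seed(33)
  toks <- lapply(1:20, function(i) {
    ns <- asNamespace("stimfill")
    ns$new_token_sequence(sample(0:999, 90, replace = TRUE), 90L, 3L,
                          record_id = paste0("r", i), channel_id = "ch1")
  })
  rep1 <- run_benchmark(toks, methods = c("interpolation", "random"),
                        k_range = 1:4, modes = c("individual", "consecutive"),
                        seed = 6)
  expect_equal(nrow(rep1), 2 * 2 * 4)
  expect_true(all(rep1$mean >= 0 & rep1$mean <= 100))
  expect_equal(unique(rep1$n_channels), 20L)
  rep2 <- run_benchmark(toks, methods = c("interpolation", "random"),
                        k_range = 1:4, modes = c("individual", "consecutive"),
                        seed = 6)
  expect_identical(rep1, rep2)
})

test_that("short channels are skipped when k exceeds their signal length", {
  ns <- asNamespace("stimfill")
  toks <- c(
    lapply(1:6, function(i)
      ns$new_token_sequence(sample(0:999, 90, replace = TRUE), 90L, 3L)),
    list(ns$new_token_sequence(c(sample(0:999, 3), rep(0L, 87)), 3L, 3L))
  )
  expect_warning(
    rep1 <- run_benchmark(toks, methods = "random", k_range = 5,
                          modes = "individual", seed = 2),
    "skipped"
  )
  expect_equal(rep1$n_channels, 6L)
})

test_that("a method that echoes the truth scores exactly 100", {
  truth <- sample(0:999, 90, replace = TRUE)
  plan <- eval_plan(c(4, 9, 40))
  expect_equal(channel_accuracy(truth, truth[plan$positions], plan, 3), 100)
})

test_that("the context sweep emits one row per context and method", {
  set.seed(44)
  ns <- asNamespace("stimfill")
  toks <- lapply(1:12, function(i)
    ns$new_token_sequence(sample(0:999, 90, replace = TRUE), 90L, 3L))
  ctx <- run_context_benchmark(toks, contexts = 1:3, k = 7,
                               methods = c("interpolation", "random"),
                               seed = 5)
  expect_equal(nrow(ctx), 3 * 2)
  expect_equal(sort(unique(ctx$context)), 1:3)
  # the random baseline does not depend on context
  rnd <- ctx[ctx$method == "random", ]
  expect_equal(length(unique(rnd$mean)), 1L)
})
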