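test_that("band power matrix has one row per whole window", {
  sig <- rnorm(22500)
  bp <- band_power_matrix(sig, band_scheme("3band"))
  expect_equal(dim(bp), c(90L, 3L))
  bp4 <- band_power_matrix(sig, band_scheme("4band"))
  expect_equal(dim(bp4), c(90L, 4L))
  # trailing partial window dropped
  expect_equal(nrow(band_power_matrix(rnorm(22400), band_scheme("3band"))),
               89L)
  expect_error(band_power_matrix(rnorm(100), band_scheme("3band")),
               "shorter")
  expect_true(all(is.finite(bp)))
})

test_that("a pure 20 Hz sinusoid concentrates in the beta band", {
  t <- (0:22499) / 250
  sig <- sin(2 * pi * 20 * t)
  bp <- band_power_matrix(sig, band_scheme("3band"))
  expect_true(all(apply(bp, 1, which.max) == 2L))
  bp4 <- band_power_matrix(sig, band_scheme("4band"))
  expect_true(all(apply(bp4, 1, which.max) == 3L))
})

test_that("quantile calibration on 1..100 gives textbook decile boundaries", {
  v <- as.numeric(1:100)
  bnd <- calibrate_bins(list(v))
  expect_equal(bnd$boundaries[[1]],
               unname(quantile(v, seq(0.1, 0.9, 0.1), type = 7)))
  expect_equal(bnd$boundaries[[1]][1], 10.9)
  expect_equal(bnd$boundaries[[1]][9], 90.1)
  digs <- quantize_power(v, bnd$boundaries[[1]])
  expect_equal(as.vector(table(digs)), rep(10L, 10))
})

test_that("calibration equalizes occupancy even for heavy-tailed samples", {
  set.seed(31)
  v <- rlnorm(20000, sdlog = 2) # strongly skewed
  bnd <- calibrate_bins(list(v))
  occ <- table(quantize_power(v, bnd$boundaries[[1]])) / length(v)
  expect_length(occ, 10)
  expect_true(all(abs(occ - 0.1) < 0.01))
})

test_that("degenerate calibration samples are rejected", {
  expect_error(calibrate_bins(list(rep(5, 1000))), "distinct")
  expect_error(calibrate_bins(list(c(rep(1, 500), rep(2, 500)))), "distinct")
})

test_that("quantization clips at the ends and sends ties to the upper bin", {
  b <- as.numeric(1:9)
  expect_equal(quantize_power(0.5, b), 0L)
  expect_equal(quantize_power(9.5, b), 9L)
  expect_equal(quantize_power(100, b), 9L)
  # value exactly on the 3rd boundary -> upper bin (digit 3)
  expect_equal(quantize_power(3, b), 3L)
  expect_equal(quantize_power(c(1, 5, 9), b), c(1L, 5L, 9L))
  expect_error(quantize_power(1, c(3, 2, 1)), "increasing")
})

test_that("token codec is exact and positional", {
  expect_equal(encode_token(c(0, 0, 0), 3), 0L)
  expect_equal(encode_token(c(9, 9, 9), 3), 999L)
  expect_equal(encode_token(c(4, 5, 6), 3), 456L)
  expect_equal(decode_token(456L, 3), matrix(c(4L, 5L, 6L), 1))
  expect_equal(decode_token(0L, 4), matrix(rep(0L, 4), 1))
  expect_equal(decode_token(9999L, 4), matrix(rep(9L, 4), 1))
  expect_error(encode_token(c(10, 0, 0), 3), "0..9")
  expect_error(decode_token(1000L, 3), "\\[0, 1000\\)")
  expect_error(decode_token(-1L, 3), "\\[0, 1000\\)")
})

test_that("codec round trip is exact for sampled 4-band tokens", {
  set.seed(8)
  toks <- sample(0:9999, 500)
  expect_equal(encode_token(decode_token(toks, 4), 4), toks)
})

test_that("raising power in one band never lowers that band's digit", {
  bnd <- small_boundaries_3band()
  for (b in 1:3) {
    v <- sort(runif(50, min(bnd$boundaries[[b]]) - 5,
                    max(bnd$boundaries[[b]]) + 5))
    d <- quantize_power(v, bnd$boundaries[[b]])
    expect_true(all(diff(d) >= 0))
  }
})

test_that("tokenization pads short records and truncates long ones", {
  bnd <- small_boundaries_3band()
  sch <- band_scheme("3band")
  sig80 <- rnorm(80 * 250)
  ts80 <- tokenize_channel(sig80, sch, bnd)
  expect_equal(ts80$signal_length, 80L)
  expect_true(all(ts80$tokens[81:90] == 0L))
  expect_length(ts80$tokens, 90)

  ts100 <- tokenize_channel(rnorm(100 * 250), sch, bnd)
  expect_equal(ts100$signal_length, 90L)
  expect_length(ts100$tokens, 90)

  ts90 <- tokenize_channel(rnorm(90 * 250), sch, bnd)
  expect_equal(ts90$signal_length, 90L)
  expect_true(all(ts90$tokens >= 0 & ts90$tokens <= 999))
})
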