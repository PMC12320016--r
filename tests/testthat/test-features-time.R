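test_that("mean curve length matches hand and analytic values", {
  expect_equal(mean_curve_length(c(5, 5, 5, 5)), 0)
  expect_equal(mean_curve_length(c(1, -1, 1, -1, 1)), 2)
  # unit 10 Hz sine at fs 256: mean |diff| ~ (2/pi) * 2 sin(pi f / fs)
  mcl <- mean_curve_length(sine_epoch(10))
  expect_lt(abs(mcl - (2 / pi) * 2 * sin(pi * 10 / 256)), 0.002)
  expect_error(mean_curve_length(3), "2 samples")
})

test_that("Hjorth parameters match closed forms for noise and sinusoids", {
  set.seed(3)
  hw <- hjorth_params(stats::rnorm(1e4))
  expect_lt(abs(hw["mobility"] - sqrt(2)) / sqrt(2), 0.05)
  hs <- hjorth_params(sine_epoch(10))
  expect_lt(abs(hs["mobility"] - 2 * sin(pi * 10 / 256)), 0.002)
  expect_lt(abs(hs["complexity"] - 1), 0.01)
  expect_true(all(is.nan(hjorth_params(rep(2, 100)))))
})

test_that("zero crossings count sign changes of the mean-removed signal", {
  expect_equal(zero_crossings(cos(2 * pi * 10 * (0:255) / 256)), 20)
  expect_equal(zero_crossings(rep(4, 10)), 0)
  expect_equal(zero_crossings(c(1, -1)), 1)
})

test_that("distribution statistics use the documented conventions", {
  ds <- distribution_stats(c(1, 2, 3, 4, 5))
  expect_equal(unname(ds["mean"]), 3)
  expect_equal(unname(ds["median"]), 3)
  expect_equal(unname(ds["sd"]), sqrt(2.5), tolerance = 1e-12)
  expect_lt(abs(distribution_stats(sine_epoch(8))["skewness"]), 1e-10)
  set.seed(4)
  k <- distribution_stats(stats::rnorm(1e5))["kurtosis"]
  expect_lt(abs(k - 3), 0.1)  # non-excess convention
})

test_that("Hurst exponent separates white noise from random walks", {
  set.seed(5)
  h_white <- mean(vapply(1:20, function(i)
    hurst_exponent(stats::rnorm(8192)), numeric(1)))
  expect_lt(abs(h_white - 0.5), 0.1)
  h_walk <- mean(vapply(1:10, function(i)
    hurst_exponent(cumsum(stats::rnorm(8192))), numeric(1)))
  expect_gt(h_walk, 0.8)
  expect_true(is.nan(hurst_exponent(stats::rnorm(32))))
  x <- stats::rnorm(256)
  expect_identical(hurst_exponent(x), hurst_exponent(x))
})

test_that("permutation entropy matches the brute-force ordinal-pattern oracle", {
  # brute-force oracle: enumerate ordinal patterns of consecutive triples
  oracle <- function(x) {
    n <- length(x)
    pats <- vapply(1:(n - 2), function(i)
      paste(order(x[i:(i + 2)]), collapse = ""), character(1))
    p <- table(pats) / length(pats)
    -sum(p * log(p)) / log(6)
  }
  saw4 <- rep(c(1, 2, 3, 4), 32)
  expect_equal(permutation_entropy(saw4), oracle(saw4), tolerance = 1e-12)
  # long-period sawtooth: pattern distribution concentrates, entropy is low
  saw32 <- rep(seq_len(32), 8)
  expect_equal(permutation_entropy(saw32), oracle(saw32), tolerance = 1e-12)
  expect_lt(permutation_entropy(saw32), 0.2)
  set.seed(6)
  expect_gt(permutation_entropy(stats::rnorm(4096)), 0.99)
})

test_that("entropy features handle degenerate input per the NaN policy", {
  expect_true(is.nan(sample_entropy(rep(1, 100))))
  expect_true(is.nan(approximate_entropy(rep(1, 100))))
  ef <- entropy_features(rep(1, 100), 256)
  expect_length(ef, 7)
  expect_false(any(is.infinite(ef)))
})

test_that("spectral entropy is maximal for white noise and low for a tone", {
  set.seed(7)
  se_noise <- mean(vapply(1:10, function(i)
    spectral_entropy(stats::rnorm(1024), 256), numeric(1)))
  expect_gt(se_noise, 0.85)
  expect_lt(spectral_entropy(sine_epoch(10), 256), 0.2)
})

test_that("the TimeFeats registry and per-epoch output have exactly 41 entries", {
  reg <- timefeats_registry()
  expect_length(reg, 41)
  expect_equal(anyDuplicated(reg), 0)
  e <- synthesize_state_epoch(default_state_presets()$EC, 256, 256, seed = 1)
  tf <- compute_timefeats(e, 256)
  expect_length(tf, 41)
  expect_identical(names(tf), reg)
})

test_that("constant epochs give NaN only at degenerate features", {
  tf <- compute_timefeats(rep(3, 256), 256)
  expect_length(tf, 41)
  # location/trivial features stay finite
  finite_expected <- c("mean", "median", "sd", "zero_crossings",
                       "mean_curve_length", "permutation_entropy",
                       "weighted_permutation_entropy",
                       "lempel_ziv_complexity")
  expect_true(all(is.finite(tf[finite_expected])))
  expect_equal(unname(tf["sd"]), 0)
  # scale-dependent moments and tolerance-based entropies degenerate to NaN
  expect_true(all(is.nan(tf[c("skewness", "kurtosis", "hjorth_mobility",
                              "sample_entropy", "approximate_entropy")])))
})

test_that("features scale as documented when the signal is amplified", {
  e <- synthesize_state_epoch(default_state_presets()$EC, 256, 256, seed = 2)
  tf1 <- compute_timefeats(e, 256)
  tf2 <- compute_timefeats(2 * e, 256)
  invariant <- c("zero_crossings", "permutation_entropy", "hjorth_mobility",
                 "hjorth_complexity", "spectral_entropy", "higuchi_fd",
                 statefeats:::catch22_names)
  expect_equal(tf1[invariant], tf2[invariant], tolerance = 1e-8)
  expect_equal(unname(tf2["sd"]), 2 * unname(tf1["sd"]), tolerance = 1e-12)
  expect_equal(unname(tf2["mean_curve_length"]),
               2 * unname(tf1["mean_curve_length"]), tolerance = 1e-12)
})

test_that("banded TimeFeats reflect the band-limited signal", {
  x <- sine_epoch(10, dur = 1) + sine_epoch(70, dur = 1)
  alpha <- band_definition("alpha", 8, 13)
  tf_band <- compute_timefeats_banded(x, 256, alpha)
  expect_length(tf_band, 41)
  # zero crossings approximately those of the 10 Hz component alone
  zc_pure <- zero_crossings(sine_epoch(10))
  expect_lte(abs(tf_band["zero_crossings"] - zc_pure), 2)
  # filtering removes power
  set.seed(8)
  noise <- stats::rnorm(256)
  tf_n <- compute_timefeats_banded(noise, 256, alpha)
  expect_lt(unname(tf_n["sd"]), stats::sd(noise))
})

test_that("all TimeFeats are deterministic functions of the input", {
  e <- synthesize_state_epoch(default_state_presets()$VS, 256, 256, seed = 9)
  expect_identical(compute_timefeats(e, 256), compute_timefeats(e, 256))
})
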