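test_that("power-law noise has the requested spectral exponent", {
  # white noise: flat spectrum
  x <- make_powerlaw_noise(0, 4096, 256, seed = 1)
  sp <- power_spectrum(x, 256, taper = "none")
  sel <- sp$freqs >= 1 & sp$freqs <= 100
  sl0 <- unname(stats::coef(stats::lm(log10(sp$power[sel]) ~
                                        log10(sp$freqs[sel])))[2])
  expect_lt(abs(sl0), 0.1)

  # exponent 2: average periodogram over 50 seeds, then one fit
  avg <- Reduce(`+`, lapply(1:50, function(s) {
    power_spectrum(make_powerlaw_noise(2, 4096, 256, seed = s), 256,
                   taper = "none")$power
  })) / 50
  sl2 <- unname(stats::coef(stats::lm(log10(avg[sel]) ~
                                        log10(sp$freqs[sel])))[2])
  expect_lt(abs(sl2 - (-2)), 0.15)
})

test_that("power-law noise is deterministic, zero-mean, and validated", {
  a <- make_powerlaw_noise(1.5, 512, 256, seed = 11)
  b <- make_powerlaw_noise(1.5, 512, 256, seed = 11)
  expect_identical(a, b)
  expect_lt(abs(mean(a)), 1e-12)
  expect_error(make_powerlaw_noise(NaN, 512, 256, 1), "exponent")
  expect_error(make_powerlaw_noise(1, 4, 256, 1), "n_samples")
})

test_that("a pure sinusoidal epoch has variance amplitude^2 / 2", {
  p <- state_params("EC", aperiodic_exponent = 0, aperiodic_scale = 1e-12,
                    oscillations = list(list(center_freq = 10, amplitude = 1,
                                             burst_fraction = 1)))
  e <- synthesize_state_epoch(p, 256, 256, seed = 3)
  expect_lt(abs(mean((e - mean(e))^2) - 0.5), 1e-3)
})

test_that("epoch synthesis reduces to the power-law background when all else is off", {
  p <- state_params("EC", aperiodic_exponent = 1.5, aperiodic_scale = 2,
                    oscillations = list(list(center_freq = 10, amplitude = 5,
                                             burst_fraction = 0)),
                    drift_amplitude = 0, noise_sd = 0)
  e <- synthesize_state_epoch(p, 256, 256, seed = 5)
  bg <- 2 * make_powerlaw_noise(1.5, 256, 256,
                                seed = statefeats:::derive_seed(5, 1))
  expect_equal(e, bg, tolerance = 1e-12)
})

test_that("oscillations above Nyquist are rejected", {
  p <- state_params("VS", 1, 1,
                    oscillations = list(list(center_freq = 200, amplitude = 1,
                                             burst_fraction = 1)))
  expect_error(synthesize_state_epoch(p, 256, 256, seed = 1), "Nyquist")
})

test_that("EC has more alpha power than EO on average", {
  presets <- default_state_presets()
  alpha <- band_definition("alpha", 8, 13)
  mean_alpha <- function(pars) {
    mean(vapply(1:100, function(s) {
      e <- synthesize_state_epoch(pars, 256, 256, seed = s)
      band_power_features(power_spectrum(e, 256), alpha)
    }, numeric(1)))
  }
  expect_gt(mean_alpha(presets$EC), mean_alpha(presets$EO))
})

test_that("default presets encode the canonical state contrasts", {
  presets <- default_state_presets()
  osc_amp <- function(p, f) {
    amps <- vapply(p$oscillations, function(o)
      if (abs(o$center_freq - f) < 5) o$amplitude else 0, numeric(1))
    max(amps, 0)
  }
  expect_gt(osc_amp(presets$EC, 10), osc_amp(presets$EO, 10))
  expect_gt(osc_amp(presets$VS, 65), osc_amp(presets$BSL, 65))
  for (p in presets) {
    for (o in p$oscillations) expect_lt(o$center_freq, 128)
  }
})

test_that("cohort generation has correct shape, labels and determinism", {
  cohort <- small_cohort(n_subjects = 3, n_epochs_per_state = 10, seed = 99)
  expect_length(cohort, 3)
  for (rec in cohort) {
    expect_s3_class(rec, "epoched_recording")
    expect_equal(dim(rec$epochs)[1], 40)
    expect_equal(as.integer(table(rec$state_labels)), rep(10L, 4))
    expect_false(anyNA(rec$epochs))
  }
  cohort2 <- small_cohort(n_subjects = 3, n_epochs_per_state = 10, seed = 99)
  expect_identical(cohort, cohort2)
  expect_error(
    generate_cohort(cohort_config(master_seed = 1),
                    presets = default_state_presets()[c("EC", "EO")]),
    "missing state preset")
})

test_that("zero subject_sd gives subjects identical expected spectra", {
  cohort <- generate_cohort(cohort_config(n_subjects = 2,
                                          n_epochs_per_state = 30,
                                          n_spatial_units = 1,
                                          subject_sd = 0,
                                          master_seed = 5))
  mean_spec <- function(rec) {
    idx <- which(rec$state_labels == "EC")
    Reduce(`+`, lapply(idx, function(e)
      power_spectrum(rec$epochs[e, 1, ], 256)$power)) / length(idx)
  }
  s1 <- mean_spec(cohort[[1]])
  s2 <- mean_spec(cohort[[2]])
  # same generative parameters: mean spectra agree up to sampling noise
  expect_gt(stats::cor(log10(s1), log10(s2)), 0.97)
})

test_that("doubling the EC/EO alpha gap does not decrease EC/EO separability", {
  presets_with_gap <- function(ec_alpha) {
    p <- default_state_presets()
    p$EC$oscillations[[1]]$amplitude <- ec_alpha
    p
  }
  ec_eo_accuracy <- function(presets, seed) {
    cohort <- generate_cohort(cohort_config(n_subjects = 3,
                                            n_epochs_per_state = 10,
                                            n_spatial_units = 1,
                                            master_seed = seed),
                              presets = presets)
    tab <- assemble_feature_table(cohort, "freqbands")
    rows <- which(tab$y %in% c("EC", "EO"))
    sub <- structure(list(X = tab$X[rows, , drop = FALSE], y = tab$y[rows],
                          subject = tab$subject[rows],
                          epoch_order = tab$epoch_order[rows],
                          column_meta = tab$column_meta,
                          feature_set = "freqbands"),
                     class = "feature_table")
    plan <- build_folds(sub, "across", n_folds = 5, seed = seed)
    run_classification(sub, plan, seed = seed)$mean_accuracy
  }
  # default gap: EC 1.0 vs EO 0.35; doubled gap: EC 1.65
  base <- mean(vapply(1:5, function(s)
    ec_eo_accuracy(presets_with_gap(1.0), 200 + s), numeric(1)))
  doubled <- mean(vapply(1:5, function(s)
    ec_eo_accuracy(presets_with_gap(1.65), 200 + s), numeric(1)))
  expect_gte(doubled, base)
})

test_that("generated epochs show spectral peaks at configured oscillation frequencies", {
  presets <- default_state_presets()
  for (st in c("EC", "VS")) {
    pars <- presets[[st]]
    avg <- Reduce(`+`, lapply(1:60, function(s) {
      power_spectrum(synthesize_state_epoch(pars, 256, 256, seed = s),
                     256)$power
    })) / 60
    freqs <- power_spectrum(sine_epoch(10), 256)$freqs
    for (o in pars$oscillations) {
      near <- which(abs(freqs - o$center_freq) <= 3)
      peak_f <- freqs[near][which.max(avg[near])]
      expect_lte(abs(peak_f - o$center_freq), 1)
    }
  }
})
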