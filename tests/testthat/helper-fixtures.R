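# Shared fixtures, all generated in code.

sine_epoch <- function(freq, fs = 256, dur = 1, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (0:(fs * dur - 1)) / fs + phase)
}

# Small cohort for fold/bookkeeping tests (fast to extract).
small_cohort <- function(n_subjects = 3, n_epochs_per_state = 10,
                         n_units = 4, seed = 7, subject_sd = 0.2) {
  generate_cohort(cohort_config(n_subjects = n_subjects,
                                n_epochs_per_state = n_epochs_per_state,
                                n_spatial_units = n_units,
                                subject_sd = subject_sd,
                                master_seed = seed))
}

# A feature table of pure noise with four balanced classes and two
# subjects; used for permutation-null and fold-logic tests.
noise_feature_table <- function(n_per_class = 30, n_feat = 6, seed = 9) {
  n <- n_per_class * 4
  set.seed(seed)
  X <- matrix(stats::rnorm(n * n_feat), n, n_feat)
  colnames(X) <- paste0("f", seq_len(n_feat), "|u1")
  structure(list(
    X = X,
    y = rep(c("EC", "EO", "BSL", "VS"), n_per_class),
    subject = rep(c("s1", "s2"), each = n / 2),
    epoch_order = rep(seq_len(n / 2), 2),
    column_meta = data.frame(feature = paste0("f", seq_len(n_feat)),
                             spatial_unit = "u1",
                             stringsAsFactors = FALSE),
    feature_set = "freqbands"), class = "feature_table")
}

# The default study cohort (5 subjects x 40 epochs x 4 units) and its
# TimeFeats table are expensive; memoize them across test files.
.fixture_cache <- new.env(parent = emptyenv())

default_cohort_fixture <- function() {
  if (is.null(.fixture_cache$cohort)) {
    .fixture_cache$cohort <-
      generate_cohort(cohort_config(master_seed = 20260101))
  }
  .fixture_cache$cohort
}

default_timefeats_fixture <- function() {
  if (is.null(.fixture_cache$timefeats)) {
    .fixture_cache$timefeats <-
      assemble_feature_table(default_cohort_fixture(), "timefeats")
  }
  .fixture_cache$timefeats
}
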