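test_that("feature tables have the documented shape and ordering", {
  cohort <- small_cohort(n_subjects = 3, n_epochs_per_state = 10,
                         n_units = 4, seed = 21)
  tab <- assemble_feature_table(cohort, "freqbands")
  expect_equal(dim(tab$X), c(120, 24))
  expect_equal(nrow(tab$column_meta), 24)
  # feature-major, unit-minor ordering
  expect_equal(tab$column_meta$feature[1:4], rep("delta", 4))
  expect_equal(length(tab$y), 120)
  expect_equal(length(unique(tab$subject)), 3)

  ff <- assemble_feature_table(cohort[1], "fullfft")
  expect_equal(ncol(ff$X), 400)  # 100 features x 4 units
})

test_that("mismatched spatial units are rejected", {
  cohort <- small_cohort(n_subjects = 2, n_epochs_per_state = 5,
                         n_units = 2, seed = 3)
  cohort[[2]]$unit_names <- c("a", "b")
  expect_error(assemble_feature_table(cohort, "freqbands"),
               "share fs and spatial units")
})

test_that("within-scheme folds are contiguous per subject and state", {
  tab <- assemble_feature_table(small_cohort(2, 10, 1, seed = 4),
                                "freqbands")
  plan <- build_folds(tab, "within", n_folds = 5)
  expect_equal(plan$n_folds, 10)  # 2 subjects x 5 folds
  for (fold in plan$folds) {
    expect_equal(length(unique(tab$subject[c(fold$train, fold$test)])), 1)
    # 2 contiguous epochs per state in each test fold
    for (st in unique(tab$y[fold$test])) {
      rows <- fold$test[tab$y[fold$test] == st]
      expect_equal(length(rows), 2)
      expect_equal(diff(tab$epoch_order[rows]), 1)
    }
    expect_length(intersect(fold$train, fold$test), 0)
  }
})

test_that("between-scheme folds hold out whole subjects", {
  tab <- assemble_feature_table(small_cohort(5, 4, 1, seed = 5),
                                "freqbands")
  plan <- build_folds(tab, "between")
  expect_equal(plan$n_folds, 5)  # leave-one-subject-out
  for (fold in plan$folds) {
    test_subj <- unique(tab$subject[fold$test])
    expect_length(test_subj, 1)
    expect_false(test_subj %in% tab$subject[fold$train])
  }
  # grouped k-fold variant: subjects never split
  plan2 <- build_folds(tab, "between", n_folds = 2, seed = 1)
  expect_equal(plan2$n_folds, 2)
  for (fold in plan2$folds) {
    expect_length(intersect(unique(tab$subject[fold$train]),
                            unique(tab$subject[fold$test])), 0)
  }
  all_test <- sort(unlist(lapply(plan2$folds, `[[`, "test")))
  expect_equal(all_test, seq_len(nrow(tab$X)))
})

test_that("across-scheme folds draw test rows from every subject", {
  tab <- assemble_feature_table(small_cohort(3, 10, 1, seed = 6),
                                "freqbands")
  plan <- build_folds(tab, "across", n_folds = 10)
  for (fold in plan$folds) {
    expect_setequal(unique(tab$subject[fold$test]), unique(tab$subject))
    expect_setequal(unique(tab$subject[fold$train]), unique(tab$subject))
    frac <- length(fold$test) / nrow(tab$X)
    expect_lt(abs(frac - 0.1), 0.05)
  }
  # single-split 85/15 mode
  plan85 <- build_folds(tab, "across", n_folds = 1,
                        holdout_fraction = 0.15, seed = 2)
  expect_equal(plan85$n_folds, 1)
  frac <- length(plan85$folds[[1]]$test) / nrow(tab$X)
  expect_lt(abs(frac - 0.15), 0.07)
})

test_that("preprocessing is leakage-free and bounded", {
  set.seed(11)
  X <- matrix(stats::rnorm(200), 20, 10)
  X[3, 4] <- NaN
  X[, 7] <- 5  # constant column
  params <- fit_preprocessor(X, pca_mode = "none")
  P <- apply_preprocessor(params, X)
  expect_true(all(P > -1 & P < 1))
  expect_false(anyNA(P))
  # constant column: IQR guarded to 1, output all zeros
  expect_true(all(P[, 7] == 0))
  # frozen parameters: transforming twice is identical
  expect_identical(apply_preprocessor(params, X), P)
  # test-row perturbation cannot change training-fitted parameters
  params2 <- fit_preprocessor(X[1:15, , drop = FALSE], pca_mode = "none")
  X_pert <- X
  X_pert[16:20, ] <- X_pert[16:20, ] + 100
  params3 <- fit_preprocessor(X_pert[1:15, , drop = FALSE],
                              pca_mode = "none")
  expect_identical(params2, params3)
})

test_that("PCA retains the smallest component count reaching 90% variance", {
  set.seed(12)
  # rank-1 matrix -> a single component
  u <- stats::rnorm(50)
  X1 <- outer(u, stats::rnorm(6))
  p1 <- fit_preprocessor(X1, pca_mode = "global")
  expect_equal(p1$pca$k, 1L)
  # isotropic 10-d Gaussian: equal eigenvalues -> 9 of 10 components
  X2 <- matrix(stats::rnorm(10000 * 10), 10000, 10)
  # bypass tanh squashing effects by feeding small-scale data
  p2 <- fit_preprocessor(X2 * 0.1, pca_mode = "global")
  expect_equal(p2$pca$k, 9L)
})

test_that("per-feature PCA keeps one block per feature", {
  tab <- assemble_feature_table(small_cohort(2, 5, 3, seed = 13),
                                "freqbands")
  red <- reduce_dimensions_per_feature(tab)
  expect_setequal(unique(red$column_meta$feature),
                  unique(tab$column_meta$feature))
  expect_true(all(table(red$column_meta$feature) >= 1))
  # identical unit columns collapse to one component
  tab$X[, tab$column_meta$feature == "alpha"] <-
    tab$X[, which(tab$column_meta$feature == "alpha")[1]]
  red2 <- reduce_dimensions_per_feature(tab)
  expect_equal(sum(red2$column_meta$feature == "alpha"), 1)
})

test_that("balanced accuracy equals the mean per-class recall", {
  expect_equal(balanced_accuracy(c("A", "B"), c("A", "B")), 1)
  expect_equal(balanced_accuracy(c("A", "A", "B", "B"),
                                 c("A", "A", "A", "A")), 0.5)
  expect_equal(balanced_accuracy(c("A", "A", "A", "B"),
                                 c("A", "A", "B", "B")), 5 / 6)
})

test_that("separable classes are classified perfectly", {
  set.seed(14)
  n <- 40
  X <- rbind(matrix(stats::rnorm(n * 2, 0, 0.1), n, 2),
             matrix(stats::rnorm(n * 2, 5, 0.1), n, 2))
  colnames(X) <- c("f1|u1", "f2|u1")
  tab <- structure(list(
    X = X, y = rep(c("EC", "EO"), each = n),
    subject = rep(c("s1", "s2"), times = n),
    epoch_order = c(seq_len(n), seq_len(n)),
    column_meta = data.frame(feature = c("f1", "f2"), spatial_unit = "u1"),
    feature_set = "freqbands"), class = "feature_table")
  plan <- build_folds(tab, "between")
  res <- run_classification(tab, plan)
  expect_equal(res$mean_accuracy, 1)
  expect_true(all(res$fold_accuracy >= 0 & res$fold_accuracy <= 1))
})

test_that("classification results are bit-identical under fixed seeds", {
  tab <- assemble_feature_table(small_cohort(3, 6, 2, seed = 15),
                                "freqbands")
  plan <- build_folds(tab, "across", n_folds = 5, seed = 3)
  r1 <- run_classification(tab, plan, seed = 2)
  r2 <- run_classification(tab, plan, seed = 2)
  expect_identical(r1, r2)
})

test_that("single-class training folds are skipped with a warning", {
  tab <- noise_feature_table(n_per_class = 5)
  plan <- structure(list(scheme = "within",
                         folds = list(list(train = which(tab$y == "EC"),
                                           test = which(tab$y == "EO")[1:3]))),
                    class = "fold_plan")
  expect_warning(res <- run_classification(tab, plan), "single class")
  expect_equal(res$n_folds_run, 0)
})
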