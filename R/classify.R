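#' Assemble a feature table from a cohort
#'
#' Computes one of the three feature sets for every epoch and spatial
#' unit of every recording and stacks the results into an
#' observations-by-columns matrix (one row per epoch; columns ordered
#' feature-major, spatial-unit-minor). For `TimeFeats`, oscillatory
#' peaks are first detected once per subject and spatial unit on the
#' spectrum averaged over that unit's epochs, and their frequency
#' ranges are excluded from every epoch's aperiodic fit. NaN feature
#' values are preserved for the downstream imputation stage.
#'
#' @param cohort list of [epoched_recording()] objects sharing `fs` and
#'   spatial units.
#' @param feature_set `"timefeats"`, `"freqbands"` or `"fullfft"`.
#' @param band optional one-row band definition: for `"timefeats"`,
#'   compute the banded variant ([compute_timefeats_banded()]).
#' @param bands band bank for `"freqbands"` (default [default_bands()]).
#' @param peak_cfg [peak_detect_config()] for the aperiodic stage.
#' @return A `feature_table` object with fields `X`, `y`, `subject`,
#'   `epoch_order` and `column_meta`.
#' @export
assemble_feature_table <- function(cohort,
                                   feature_set = c("timefeats", "freqbands",
                                                   "fullfft"),
                                   band = NULL, bands = default_bands(),
                                   peak_cfg = peak_detect_config()) {
  feature_set <- match.arg(feature_set)
  stopifnot(length(cohort) >= 1)
  fs <- cohort[[1]]$fs
  unit_names <- cohort[[1]]$unit_names
  for (rec in cohort) {
    if (!identical(rec$fs, fs) || !identical(rec$unit_names, unit_names)) {
      stop("all recordings must share fs and spatial units", call. = FALSE)
    }
  }
  n_units <- length(unit_names)
  feat_names <- switch(feature_set,
    timefeats = timefeats_registry(),
    freqbands = bands$name,
    fullfft = paste0("f", 1:100))
  n_feat <- length(feat_names)

  blocks <- lapply(cohort, function(rec) {
    n_ep <- dim(rec$epochs)[1]
    vals <- array(NA_real_, dim = c(n_ep, n_feat, n_units))
    for (u in seq_len(n_units)) {
      if (feature_set == "timefeats") {
        specs <- lapply(seq_len(n_ep), function(e)
          power_spectrum(rec$epochs[e, u, ], fs, taper = "hann"))
        avg <- as_power_spectrum(specs[[1]]$freqs,
                                 Reduce(`+`, lapply(specs, `[[`, "power")) /
                                   n_ep,
                                 taper = "hann")
        peaks <- detect_spectral_peaks(avg, peak_cfg)
        for (e in seq_len(n_ep)) {
          vals[e, , u] <- if (is.null(band)) {
            compute_timefeats(rec$epochs[e, u, ], fs, avg_peaks = peaks)
          } else {
            compute_timefeats_banded(rec$epochs[e, u, ], fs, band,
                                     avg_peaks = peaks)
          }
        }
      } else {
        for (e in seq_len(n_ep)) {
          sp <- power_spectrum(rec$epochs[e, u, ], fs, taper = "hann")
          vals[e, , u] <- if (feature_set == "freqbands") {
            band_power_features(sp, bands)
          } else {
            fullfft_features(sp)
          }
        }
      }
    }
    vals
  })

  n_rows <- sum(vapply(blocks, function(b) dim(b)[1], integer(1)))
  X <- matrix(NA_real_, nrow = n_rows, ncol = n_feat * n_units)
  col_feature <- rep(feat_names, each = n_units)
  col_unit <- rep(unit_names, times = n_feat)
  colnames(X) <- paste(col_feature, col_unit, sep = "|")
  y <- character(n_rows)
  subject <- character(n_rows)
  epoch_order <- integer(n_rows)
  row0 <- 0L
  for (i in seq_along(cohort)) {
    b <- blocks[[i]]
    n_ep <- dim(b)[1]
    rows <- row0 + seq_len(n_ep)
    for (f in seq_len(n_feat)) {
      for (u in seq_len(n_units)) {
        X[rows, (f - 1L) * n_units + u] <- b[, f, u]
      }
    }
    y[rows] <- cohort[[i]]$state_labels
    subject[rows] <- cohort[[i]]$subject_id
    epoch_order[rows] <- seq_len(n_ep)
    row0 <- row0 + n_ep
  }
  structure(list(X = X, y = y, subject = subject,
                 epoch_order = epoch_order,
                 column_meta = data.frame(feature = col_feature,
                                          spatial_unit = col_unit,
                                          stringsAsFactors = FALSE),
                 feature_set = feature_set),
            class = "feature_table")
}

# contiguous chunk boundaries: splits 1..n into k runs of near-equal size
chunk_indices <- function(n, k) {
  bounds <- round(seq(0, n, length.out = k + 1))
  lapply(seq_len(k), function(i) {
    if (bounds[i + 1] > bounds[i]) (bounds[i] + 1):bounds[i + 1] else integer(0)
  })
}

#' Build cross-validation folds under a partition scheme
#'
#' Three schemes relate folds to subjects:
#' \describe{
#'   \item{within}{one classifier per subject: folds are contiguous
#'     blocks of each subject's epochs (contiguity is enforced inside
#'     each state block, so every training fold sees all states), and
#'     train/test rows both come from that subject only.}
#'   \item{between}{whole subjects are held out: leave-one-subject-out
#'     by default, or a grouped k-fold (subjects never split across
#'     train and test) when `n_folds < n_subjects`.}
#'   \item{across}{every subject contributes to both sides: fold k
#'     holds out the k-th contiguous chunk (about `1/n_folds` of each
#'     state block) of every subject. With `n_folds = 1` and a
#'     `holdout_fraction`, a single split is made with a uniformly
#'     placed contiguous test chunk per subject and state block.}
#' }
#' Contiguous test blocks minimize leakage between filtered short
#' epochs that are adjacent in time.
#'
#' @param table a `feature_table`.
#' @param scheme `"within"`, `"between"` or `"across"`.
#' @param n_folds number of folds (default 10; for `"between"`, values
#'   below the subject count select the grouped k-fold variant).
#' @param holdout_fraction optional test fraction for the single-split
#'   across mode (e.g. 0.15 for an 85/15 split).
#' @param seed integer seed (used for grouped-fold subject shuffling
#'   and random holdout placement).
#' @return A `fold_plan` with a list of `(train, test)` row-index pairs.
#' @export
build_folds <- function(table, scheme = c("within", "between", "across"),
                        n_folds = 10, holdout_fraction = NULL, seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(table, "feature_table"))
  subjects <- unique(table$subject)
  if (scheme %in% c("between", "across") && length(subjects) < 2) {
    stop("between/across schemes require at least 2 subjects", call. = FALSE)
  }
  folds <- list()
  if (scheme == "within") {
    for (s in subjects) {
      rows_s <- which(table$subject == s)
      per_state <- split(rows_s, table$y[rows_s])
      test_chunks <- lapply(per_state, function(rows) {
        chunk_indices(length(rows), n_folds)
      })
      for (k in seq_len(n_folds)) {
        test <- unlist(lapply(names(per_state), function(st) {
          per_state[[st]][test_chunks[[st]][[k]]]
        }), use.names = FALSE)
        train <- setdiff(rows_s, test)
        if (length(test) == 0 || length(train) == 0) {
          stop("fold with empty train or test set; reduce n_folds",
               call. = FALSE)
        }
        folds[[length(folds) + 1L]] <-
          list(train = sort(train), test = sort(test), subject = s, fold = k)
      }
    }
  } else if (scheme == "between") {
    groups <- if (n_folds >= length(subjects)) {
      as.list(subjects)  # leave-one-subject-out
    } else {
      shuffled <- with_seed(seed, sample(subjects))
      split(shuffled, rep_len(seq_len(n_folds), length(shuffled)))
    }
    for (k in seq_along(groups)) {
      test <- which(table$subject %in% groups[[k]])
      train <- which(!(table$subject %in% groups[[k]]))
      folds[[length(folds) + 1L]] <-
        list(train = train, test = sort(test), fold = k)
    }
  } else {  # across
    single <- !is.null(holdout_fraction)
    if (single && n_folds != 1) {
      stop("holdout_fraction implies a single fold (n_folds = 1)",
           call. = FALSE)
    }
    starts_seed <- derive_seed(seed, 17)
    for (k in seq_len(n_folds)) {
      test <- integer(0)
      for (s in subjects) {
        rows_s <- which(table$subject == s)
        per_state <- split(rows_s, table$y[rows_s])
        for (st in names(per_state)) {
          rows <- per_state[[st]]
          if (single) {
            len <- max(1L, round(holdout_fraction * length(rows)))
            if (len >= length(rows)) {
              stop("holdout_fraction leaves an empty training set",
                   call. = FALSE)
            }
            start <- with_seed(derive_seed(starts_seed,
                                           match(s, subjects) * 100 +
                                             match(st, names(per_state))),
                               sample.int(length(rows) - len + 1L, 1L))
            test <- c(test, rows[start:(start + len - 1L)])
          } else {
            test <- c(test, rows[chunk_indices(length(rows), n_folds)[[k]]])
          }
        }
      }
      train <- setdiff(seq_len(nrow(table$X)), test)
      if (length(test) == 0 || length(train) == 0) {
        stop("fold with empty train or test set", call. = FALSE)
      }
      folds[[length(folds) + 1L]] <- list(train = train, test = sort(test),
                                          fold = k)
    }
  }
  structure(list(scheme = scheme, folds = folds, n_folds = length(folds)),
            class = "fold_plan")
}

#' Fit the leakage-free preprocessing pipeline on training rows
#'
#' The pipeline, fitted exclusively on the training matrix and then
#' frozen, is: (1) all-NaN columns dropped; (2) remaining NaNs replaced
#' by the training column mean; (3) robust scaling — subtract the
#' training column median, divide by the training column interquartile
#' range (IQR of 0 replaced by 1); (4) elementwise `tanh`, squeezing
#' values into (-1, 1) to curb outliers; (5) PCA retaining the smallest
#' number of components whose cumulative explained-variance ratio
#' reaches `variance_target`. PCA can be fitted globally over all
#' columns or separately per feature block across its spatial-unit
#' columns (`pca_mode = "per_feature"`, used by the across-subjects
#' feature-set analysis), or skipped.
#'
#' @param train_X numeric training matrix (>= 2 rows).
#' @param variance_target cumulative explained-variance ratio for PCA
#'   (default 0.90).
#' @param pca_mode `"global"`, `"per_feature"` or `"none"`.
#' @param column_meta column metadata (required for `"per_feature"`).
#' @return A `preprocess_params` object for [apply_preprocessor()].
#' @export
fit_preprocessor <- function(train_X, variance_target = 0.9,
                             pca_mode = c("global", "per_feature", "none"),
                             column_meta = NULL) {
  pca_mode <- match.arg(pca_mode)
  stopifnot(is.matrix(train_X), nrow(train_X) >= 2)
  all_nan <- apply(train_X, 2, function(col) all(is.na(col)))
  if (any(all_nan)) {
    warning(sum(all_nan), " all-NaN column(s) dropped in preprocessing")
  }
  keep <- which(!all_nan)
  Xt <- train_X[, keep, drop = FALSE]
  if (!is.null(column_meta)) column_meta <- column_meta[keep, , drop = FALSE]
  col_mean <- colMeans(Xt, na.rm = TRUE)
  for (j in seq_len(ncol(Xt))) {
    nas <- is.na(Xt[, j])
    if (any(nas)) Xt[nas, j] <- col_mean[j]
  }
  col_median <- apply(Xt, 2, stats::median)
  col_iqr <- apply(Xt, 2, stats::IQR)
  col_iqr[col_iqr == 0] <- 1
  Xs <- tanh(sweep(sweep(Xt, 2, col_median), 2, col_iqr, "/"))

  fit_pca <- function(M) {
    pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
    v <- pc$sdev^2
    k <- if (sum(v) <= 0) 1L else which(cumsum(v) / sum(v) >=
                                          variance_target)[1]
    list(rotation = pc$rotation[, seq_len(k), drop = FALSE],
         center = pc$center, k = k)
  }
  pca <- NULL
  if (pca_mode == "global") {
    pca <- fit_pca(Xs)
  } else if (pca_mode == "per_feature") {
    if (is.null(column_meta)) {
      stop("per-feature PCA requires `column_meta`", call. = FALSE)
    }
    feats <- unique(column_meta$feature)
    pca <- lapply(feats, function(f) {
      cols <- which(column_meta$feature == f)
      c(fit_pca(Xs[, cols, drop = FALSE]), list(cols = cols))
    })
    names(pca) <- feats
  }
  structure(list(keep = keep, col_mean = col_mean,
                 col_median = col_median, col_iqr = col_iqr,
                 pca_mode = pca_mode, pca = pca,
                 variance_target = variance_target),
            class = "preprocess_params")
}

#' Apply frozen preprocessing parameters to a matrix
#'
#' @param params a `preprocess_params` from [fit_preprocessor()].
#' @param X matrix with the same columns as the training matrix.
#' @return Preprocessed (and possibly PCA-reduced) matrix.
#' @export
apply_preprocessor <- function(params, X) {
  stopifnot(inherits(params, "preprocess_params"), is.matrix(X))
  Xt <- X[, params$keep, drop = FALSE]
  for (j in seq_len(ncol(Xt))) {
    nas <- is.na(Xt[, j])
    if (any(nas)) Xt[nas, j] <- params$col_mean[j]
  }
  Xs <- tanh(sweep(sweep(Xt, 2, params$col_median), 2, params$col_iqr, "/"))
  if (params$pca_mode == "none") return(Xs)
  if (params$pca_mode == "global") {
    return(sweep(Xs, 2, params$pca$center) %*% params$pca$rotation)
  }
  blocks <- lapply(params$pca, function(p) {
    sweep(Xs[, p$cols, drop = FALSE], 2, p$center) %*% p$rotation
  })
  out <- do.call(cbind, blocks)
  colnames(out) <- unlist(lapply(names(params$pca), function(f)
    paste0(f, "|PC", seq_len(params$pca[[f]]$k))), use.names = FALSE)
  out
}

#' Per-feature dimensionality reduction over spatial units
#'
#' For each feature name, a PCA across that feature's spatial-unit
#' columns is fitted on the training rows only and applied to all rows,
#' retaining the smallest component count reaching `variance_target`
#' cumulative explained variance; the per-feature blocks are then
#' concatenated. Every feature block keeps at least one component.
#'
#' @param table a `feature_table` (NaNs are imputed with training
#'   column means first).
#' @param train_rows row indices used to fit the reduction (default:
#'   all rows).
#' @param variance_target explained-variance target (default 0.90).
#' @return A `feature_table` whose columns are per-feature components.
#' @export
reduce_dimensions_per_feature <- function(table, train_rows = NULL,
                                          variance_target = 0.9) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(train_rows)) train_rows <- seq_len(nrow(table$X))
  params <- fit_preprocessor(table$X[train_rows, , drop = FALSE],
                             variance_target = variance_target,
                             pca_mode = "per_feature",
                             column_meta = table$column_meta)
  Xr <- apply_preprocessor(params, table$X)
  meta <- data.frame(
    feature = sub("\\|PC[0-9]+$", "", colnames(Xr)),
    spatial_unit = sub("^.*\\|", "", colnames(Xr)),
    stringsAsFactors = FALSE)
  structure(list(X = Xr, y = table$y, subject = table$subject,
                 epoch_order = table$epoch_order, column_meta = meta,
                 feature_set = table$feature_set),
            class = "feature_table")
}

#' Balanced accuracy
#'
#' Unweighted mean of per-class recall over the classes present in
#' `y_true`; robust to class imbalance.
#'
#' @param y_true true labels (non-empty).
#' @param y_pred predicted labels, same length.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
#' @examples
#' balanced_accuracy(c("A", "A", "A", "B"), c("A", "A", "B", "B"))  # 5/6
balanced_accuracy <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0)
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  classes <- unique(y_true)
  recalls <- vapply(classes, function(cl) {
    sel <- y_true == cl
    mean(y_pred[sel] == cl)
  }, numeric(1))
  mean(recalls)
}

#' Classifier configuration
#'
#' Soft-margin SVM settings: Gaussian (RBF) kernel with `C = 10` by
#' default, kernel width `gamma = 1 / (n_columns * mean column
#' variance)`, multiclass handled by one-vs-one voting.
#'
#' @param kernel `"rbf"` (alias `"radial"`) or `"linear"`.
#' @param C regularization constant (> 0, default 10).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(kernel = c("rbf", "radial", "linear"), C = 10) {
  kernel <- match.arg(kernel)
  if (kernel == "rbf") kernel <- "radial"
  stopifnot(C > 0)
  structure(list(kernel = kernel, C = C), class = "classifier_config")
}

#' Run cross-validated SVM classification of brain states
#'
#' For every fold of the plan the preprocessing pipeline is fitted on
#' the training rows only ([fit_preprocessor()]) and applied to both
#' sides; an SVM (one-vs-one for more than two classes) is trained and
#' the fold's balanced accuracy recorded. The PCA flavor follows the
#' scheme, as appropriate for feature-set analyses: a single global PCA
#' for `within`/`between`, a per-feature PCA over spatial units for
#' `across` (overridable via `pca_mode`). Folds whose training rows
#' contain a single class are skipped with a warning.
#'
#' @param table a `feature_table`.
#' @param plan a `fold_plan` built from the same table.
#' @param cfg a [classifier_config()].
#' @param variance_target PCA explained-variance target (default 0.90).
#' @param pca_mode optional override of the scheme's PCA flavor.
#' @param seed integer seed (recorded in the result; the fitting itself
#'   is deterministic).
#' @return A `classification_result` with per-fold balanced accuracies
#'   (`fold_accuracy`), their mean (`mean_accuracy`), and the balanced
#'   accuracy of all test predictions pooled (`pooled_accuracy`).
#' @export
run_classification <- function(table, plan, cfg = classifier_config(),
                               variance_target = 0.9, pca_mode = NULL,
                               seed = 1) {
  stopifnot(inherits(table, "feature_table"), inherits(plan, "fold_plan"),
            inherits(cfg, "classifier_config"))
  if (is.null(pca_mode)) {
    pca_mode <- if (plan$scheme == "across") "per_feature" else "global"
  }
  fold_acc <- numeric(0)
  pooled_true <- character(0)
  pooled_pred <- character(0)
  for (fold in plan$folds) {
    y_tr <- table$y[fold$train]
    if (length(unique(y_tr)) < 2) {
      warning("fold skipped: training rows contain a single class")
      next
    }
    params <- fit_preprocessor(table$X[fold$train, , drop = FALSE],
                               variance_target = variance_target,
                               pca_mode = pca_mode,
                               column_meta = table$column_meta)
    P_tr <- apply_preprocessor(params, table$X[fold$train, , drop = FALSE])
    P_te <- apply_preprocessor(params, table$X[fold$test, , drop = FALSE])
    mean_var <- mean(apply(P_tr, 2, stats::var))
    gamma <- if (is.finite(mean_var) && mean_var > 0) {
      1 / (ncol(P_tr) * mean_var)
    } else {
      1 / ncol(P_tr)
    }
    model <- with_seed(seed, e1071::svm(
      x = P_tr, y = factor(y_tr), kernel = cfg$kernel, cost = cfg$C,
      gamma = gamma, scale = FALSE))
    pred <- as.character(stats::predict(model, P_te))
    truth <- table$y[fold$test]
    fold_acc <- c(fold_acc, balanced_accuracy(truth, pred))
    pooled_true <- c(pooled_true, truth)
    pooled_pred <- c(pooled_pred, pred)
  }
  structure(list(scheme = plan$scheme, fold_accuracy = fold_acc,
                 mean_accuracy = mean(fold_acc),
                 pooled_accuracy = if (length(pooled_true) > 0) {
                   balanced_accuracy(pooled_true, pooled_pred)
                 } else {
                   NaN
                 },
                 config = cfg, pca_mode = pca_mode, seed = seed,
                 n_folds_run = length(fold_acc)),
            class = "classification_result")
}
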