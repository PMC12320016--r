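#' Correlation distance between features
#'
#' For each feature, the values over all observations and spatial units
#' are concatenated into one vector (spatial units stacked across
#' subjects as observations); the distance between two features is
#' `1 - |r|` with `r` the Pearson correlation of those vectors, so that
#' both strongly correlated and strongly anti-correlated features are
#' close. NaNs must be imputed beforehand (see
#' [fit_preprocessor()]); zero-variance features yield NaN rows, which
#' are flagged in the result.
#'
#' @param table a `feature_table`.
#' @return A `distance_matrix` object: labels (feature names), the
#'   symmetric matrix `D` of `1 - |r|` values, and `nan_features`.
#' @export
feature_distance_matrix <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  feats <- unique(table$column_meta$feature)
  if (length(feats) < 2) stop("need at least 2 features", call. = FALSE)
  vecs <- sapply(feats, function(f) {
    cols <- which(table$column_meta$feature == f)
    as.numeric(table$X[, cols, drop = FALSE])
  })
  if (nrow(vecs) < 3) stop("need at least 3 observations per feature",
                           call. = FALSE)
  # impute any remaining NaN by the feature's mean so r is defined
  for (j in seq_len(ncol(vecs))) {
    nas <- !is.finite(vecs[, j])
    if (any(nas)) vecs[nas, j] <- mean(vecs[!nas, j])
  }
  sds <- apply(vecs, 2, stats::sd)
  r <- suppressWarnings(stats::cor(vecs))
  D <- 1 - abs(r)
  diag(D) <- 0
  nan_feats <- feats[sds == 0 | !is.finite(sds)]
  D[!is.finite(D)] <- NA_real_
  structure(list(labels = feats, D = D, nan_features = nan_feats),
            class = "distance_matrix")
}

#' Complete-linkage hierarchical clustering of features
#'
#' Agglomerative clustering where the distance between clusters is the
#' maximum pairwise member distance (complete linkage), applied to a
#' `1 - |r|` feature distance matrix.
#'
#' @param dm a `distance_matrix` from [feature_distance_matrix()].
#' @return An object of class `hclust` (merge sequence, heights,
#'   labels), ready for dendrogram plotting or [stats::cutree()].
#' @export
hierarchical_clustering <- function(dm) {
  stopifnot(inherits(dm, "distance_matrix"))
  if (anyNA(dm$D)) {
    bad <- dm$labels[apply(dm$D, 1, anyNA)]
    stop("distance matrix contains NaN rows for feature(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  d <- stats::as.dist(dm$D)
  attr(d, "Labels") <- dm$labels
  stats::hclust(d, method = "complete")
}

#' Cophenetic distance between two features in a linkage tree
#'
#' Height at which the two features are first merged into one cluster —
#' a convenient scalar for asserting which features group early.
#'
#' @param hc an `hclust` object.
#' @param a,b feature labels.
#' @return Merge height.
#' @export
merge_height <- function(hc, a, b) {
  cd <- as.matrix(stats::cophenetic(hc))
  cd[a, b]
}
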