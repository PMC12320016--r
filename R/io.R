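#' Write a cohort of epoched recordings to a directory
#'
#' One CSV per subject (long format: epoch, unit, sample columns are
#' collapsed as one row per epoch x unit, samples across columns) plus
#' a YAML sidecar holding the sampling rate, unit names and state
#' labels. The format round-trips exactly through [read_epochs()].
#'
#' @param cohort list of [epoched_recording()] objects.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_epochs <- function(cohort, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort) {
    n_ep <- dim(rec$epochs)[1]
    n_units <- dim(rec$epochs)[2]
    n_samp <- dim(rec$epochs)[3]
    flat <- matrix(NA_real_, nrow = n_ep * n_units, ncol = n_samp)
    epoch_col <- integer(n_ep * n_units)
    unit_col <- character(n_ep * n_units)
    i <- 0L
    for (e in seq_len(n_ep)) {
      for (u in seq_len(n_units)) {
        i <- i + 1L
        flat[i, ] <- rec$epochs[e, u, ]
        epoch_col[i] <- e
        unit_col[i] <- rec$unit_names[u]
      }
    }
    df <- data.frame(epoch = epoch_col, unit = unit_col, flat)
    names(df)[-(1:2)] <- paste0("s", seq_len(n_samp))
    utils::write.csv(df, file.path(path,
                                   paste0(rec$subject_id, "_epochs.csv")),
                     row.names = FALSE)
    meta <- list(subject_id = rec$subject_id, fs = rec$fs,
                 unit_names = as.list(rec$unit_names),
                 state_labels = as.list(rec$state_labels))
    yaml::write_yaml(meta, file.path(path,
                                     paste0(rec$subject_id, "_meta.yaml")))
  }
  invisible(path)
}

#' Read a cohort of epoched recordings from a directory
#'
#' Reads the per-subject CSV + YAML layout written by [write_epochs()],
#' validating state labels, shapes and sampling rates. A channel/parcel
#' subset can be selected by name.
#'
#' @param path directory written by [write_epochs()].
#' @param units optional character vector of spatial-unit names to
#'   keep (in the given order).
#' @return List of `epoched_recording` objects.
#' @export
read_epochs <- function(path, units = NULL) {
  metas <- sort(list.files(path, pattern = "_meta\\.yaml$",
                           full.names = TRUE))
  if (length(metas) == 0) {
    stop("no recordings found under ", path, call. = FALSE)
  }
  lapply(metas, function(mf) {
    meta <- yaml::read_yaml(mf)
    labels <- unlist(meta$state_labels)
    bad <- setdiff(unique(labels), STATE_LEVELS)
    if (length(bad) > 0) {
      stop("file ", mf, ": unknown state label(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    df <- utils::read.csv(sub("_meta\\.yaml$", "_epochs.csv", mf),
                          stringsAsFactors = FALSE)
    unit_names <- unlist(meta$unit_names)
    n_ep <- length(labels)
    n_units <- length(unit_names)
    n_samp <- ncol(df) - 2L
    if (nrow(df) != n_ep * n_units) {
      stop("file ", mf, ": expected ", n_ep * n_units,
           " rows, found ", nrow(df), call. = FALSE)
    }
    epochs <- array(NA_real_, dim = c(n_ep, n_units, n_samp))
    m <- as.matrix(df[, -(1:2), drop = FALSE])
    for (i in seq_len(nrow(df))) {
      u <- match(df$unit[i], unit_names)
      epochs[df$epoch[i], u, ] <- m[i, ]
    }
    if (!is.null(units)) {
      missing_u <- setdiff(units, unit_names)
      if (length(missing_u) > 0) {
        stop("unknown unit(s): ", paste(missing_u, collapse = ", "),
             call. = FALSE)
      }
      epochs <- epochs[, match(units, unit_names), , drop = FALSE]
      unit_names <- units
    }
    epoched_recording(meta$subject_id, epochs, labels, meta$fs, unit_names)
  })
}

#' Export a feature table in long format
#'
#' Writes columns subject, epoch, spatial_unit, feature, state, value.
#'
#' @param table a `feature_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  n <- nrow(table$X)
  out <- do.call(rbind, lapply(seq_len(ncol(table$X)), function(j) {
    data.frame(subject = table$subject, epoch = table$epoch_order,
               spatial_unit = table$column_meta$spatial_unit[j],
               feature = table$column_meta$feature[j],
               state = table$y, value = table$X[, j],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
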