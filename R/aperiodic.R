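#' Configuration for spectral peak detection
#'
#' Settings for the iterative Gaussian peak extraction performed on
#' average log-power spectra before aperiodic fitting.
#'
#' @param fit_range frequency interval (Hz) over which peaks are sought
#'   and the aperiodic component is fitted; default 1-100 Hz.
#' @param max_n_peaks maximum number of peaks to extract (default 6).
#' @param min_peak_height minimum height, in log10-power units above the
#'   aperiodic line, for a residual maximum to qualify as a peak
#'   (default 0.1).
#' @param peak_width_limits admissible full-width-at-half-maximum range
#'   in Hz (default 1-12).
#' @return A `peak_detect_config` list.
#' @export
peak_detect_config <- function(fit_range = c(1, 100), max_n_peaks = 6,
                               min_peak_height = 0.1,
                               peak_width_limits = c(1, 12)) {
  stopifnot(length(fit_range) == 2L, fit_range[1] > 0,
            fit_range[2] > fit_range[1],
            length(peak_width_limits) == 2L, peak_width_limits[1] > 0,
            peak_width_limits[2] > peak_width_limits[1],
            max_n_peaks >= 0, min_peak_height > 0)
  structure(list(fit_range = as.numeric(fit_range),
                 max_n_peaks = as.integer(max_n_peaks),
                 min_peak_height = min_peak_height,
                 peak_width_limits = as.numeric(peak_width_limits)),
            class = "peak_detect_config")
}

# Robust log-log line through the aperiodic component of a spectrum:
# an initial OLS fit, then a refit restricted to the bins lying closest
# to (or below) the initial line, which discounts oscillatory peaks.
robust_aperiodic_line <- function(log_f, log_p) {
  fit <- stats::lm.fit(cbind(1, log_f), log_p)
  flat <- log_p - (fit$coefficients[1] + fit$coefficients[2] * log_f)
  flat[flat < 0] <- 0
  thresh <- stats::quantile(flat, 0.025, names = FALSE)
  keep <- flat <= thresh
  if (sum(keep) >= 3) {
    fit <- stats::lm.fit(cbind(1, log_f[keep]), log_p[keep])
  }
  c(offset = unname(fit$coefficients[1]), slope = unname(fit$coefficients[2]))
}

gaussian_bump <- function(f, center, height, sd) {
  height * exp(-(f - center)^2 / (2 * sd^2))
}

#' Detect oscillatory peaks on an average power spectrum
#'
#' Iterative Gaussian peak extraction in log10-power space: a robust
#' log-log line is removed from the spectrum, then the largest residual
#' maximum at least `min_peak_height` above the line is fitted with a
#' Gaussian (center, height, width), subtracted, and the search repeats
#' up to `max_n_peaks` times. Intended to run on the spectrum averaged
#' over all repetitions (epochs) of one spatial unit, where oscillatory
#' peaks stand out most clearly from the 1/f background.
#'
#' @param avg_spec a `power_spectrum` object (average over epochs).
#' @param cfg a [peak_detect_config()].
#' @return A data frame with columns `center_freq`, `height` (log10-power
#'   units) and `bandwidth` (Hz, two Gaussian standard deviations);
#'   zero rows when no peak exceeds the threshold.
#' @export
detect_spectral_peaks <- function(avg_spec, cfg = peak_detect_config()) {
  stopifnot(inherits(avg_spec, "power_spectrum"),
            inherits(cfg, "peak_detect_config"))
  sel <- avg_spec$freqs >= cfg$fit_range[1] &
    avg_spec$freqs <= cfg$fit_range[2]
  if (!any(sel)) {
    stop("fit_range lies outside the spectrum's support", call. = FALSE)
  }
  f <- avg_spec$freqs[sel]
  p <- avg_spec$power[sel]
  ok <- p > 0
  f <- f[ok]
  p <- p[ok]
  if (length(f) < 5) {
    return(data.frame(center_freq = numeric(0), height = numeric(0),
                      bandwidth = numeric(0)))
  }
  log_f <- log10(f)
  log_p <- log10(p)
  line <- robust_aperiodic_line(log_f, log_p)
  flat <- log_p - (line["offset"] + line["slope"] * log_f)

  sd_lims <- cfg$peak_width_limits / (2 * sqrt(2 * log(2)))  # FWHM -> sd
  peaks <- list()
  for (k in seq_len(cfg$max_n_peaks)) {
    i_max <- which.max(flat)
    h0 <- flat[i_max]
    if (!is.finite(h0) || h0 < cfg$min_peak_height) break
    c0 <- f[i_max]
    # half-height width guess
    half <- h0 / 2
    i_lo <- i_max
    while (i_lo > 1 && flat[i_lo] > half) i_lo <- i_lo - 1
    i_hi <- i_max
    while (i_hi < length(f) && flat[i_hi] > half) i_hi <- i_hi + 1
    fwhm0 <- max(f[i_hi] - f[i_lo], min(diff(f)))
    sd0 <- min(max(fwhm0 / (2 * sqrt(2 * log(2))), sd_lims[1]), sd_lims[2])
    obj <- function(par) {
      sum((flat - gaussian_bump(f, par[1], par[2], par[3]))^2)
    }
    fit <- stats::optim(c(c0, h0, sd0), obj, method = "L-BFGS-B",
                        lower = c(max(c0 - 2 * sd0, f[1]),
                                  0.5 * cfg$min_peak_height, sd_lims[1]),
                        upper = c(min(c0 + 2 * sd0, f[length(f)]),
                                  2 * h0 + 1, sd_lims[2]))
    par <- fit$par
    flat <- flat - gaussian_bump(f, par[1], par[2], par[3])
    peaks[[length(peaks) + 1L]] <-
      data.frame(center_freq = par[1], height = par[2],
                 bandwidth = 2 * par[3])
  }
  if (length(peaks) == 0) {
    return(data.frame(center_freq = numeric(0), height = numeric(0),
                      bandwidth = numeric(0)))
  }
  out <- do.call(rbind, peaks)
  out[out$height >= cfg$min_peak_height, , drop = FALSE]
}

#' Build the peak-exclusion mask for aperiodic fitting
#'
#' Marks as excluded every frequency bin within one bandwidth of a
#' detected peak center, i.e. the interval
#' `[center - bandwidth, center + bandwidth]` for each peak; all other
#' bins are retained. Overlapping peaks simply union their exclusions.
#'
#' @param freqs frequency vector (Hz) of the spectra to be fitted.
#' @param peaks data frame as returned by [detect_spectral_peaks()].
#' @return Logical vector, `TRUE` for retained bins.
#' @export
build_aperiodic_mask <- function(freqs, peaks) {
  keep <- rep(TRUE, length(freqs))
  if (is.null(peaks) || nrow(peaks) == 0) return(keep)
  for (i in seq_len(nrow(peaks))) {
    lo <- peaks$center_freq[i] - peaks$bandwidth[i]
    hi <- peaks$center_freq[i] + peaks$bandwidth[i]
    keep[freqs >= lo & freqs <= hi] <- FALSE
  }
  keep
}

#' Fit the aperiodic (1/f) component of a single-epoch spectrum
#'
#' Ordinary least squares of log10(power) on log10(frequency) over the
#' retained (unmasked) bins inside `fit_range`. The slope is the
#' negative of the 1/f exponent for power-law spectra; the offset is the
#' fitted log10-power at log10(f) = 0. Bins with zero power are dropped
#' with a warning before taking logs; fewer than 3 usable bins yield an
#' all-NaN fit (which downstream imputation handles).
#'
#' @param spec a `power_spectrum` object (one epoch's spectrum).
#' @param mask logical retain-mask aligned with `spec$freqs` (default:
#'   retain everything).
#' @param fit_range frequency interval for the regression (default 1-100 Hz).
#' @return A list of class `aperiodic_fit` with elements `slope`,
#'   `offset` and `n_bins_used`.
#' @export
#' @examples
#' sp <- as_power_spectrum(1:100, (1:100)^-2)
#' fit_aperiodic(sp)  # slope -2, offset 0
fit_aperiodic <- function(spec, mask = NULL, fit_range = c(1, 100)) {
  stopifnot(inherits(spec, "power_spectrum"))
  if (is.null(mask)) mask <- rep(TRUE, length(spec$freqs))
  stopifnot(length(mask) == length(spec$freqs))
  sel <- mask & spec$freqs >= fit_range[1] & spec$freqs <= fit_range[2]
  f <- spec$freqs[sel]
  p <- spec$power[sel]
  bad <- p <= 0
  if (any(bad)) {
    warning(sum(bad), " zero-power bin(s) dropped before log transform")
    f <- f[!bad]
    p <- p[!bad]
  }
  if (length(f) < 3) {
    return(structure(list(slope = NaN, offset = NaN,
                          n_bins_used = length(f)),
                     class = "aperiodic_fit"))
  }
  fit <- stats::lm.fit(cbind(1, log10(f)), log10(p))
  structure(list(slope = unname(fit$coefficients[2]),
                 offset = unname(fit$coefficients[1]),
                 n_bins_used = length(f)),
            class = "aperiodic_fit")
}
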