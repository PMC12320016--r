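#' Mean curve length
#'
#' Mean absolute value of the first difference of the signal — a
#' time-domain summary of overall signal variability, and in practice
#' one of the most informative single descriptors for separating brain
#' states. Raw differences are used, with no sampling-rate scaling.
#'
#' @param x numeric signal vector, length >= 2.
#' @return Mean of `|x[n+1] - x[n]|`.
#' @export
#' @examples
#' mean_curve_length(c(1, -1, 1, -1, 1))  # 2
mean_curve_length <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)
  if (!all(is.finite(x))) stop("x must be finite", call. = FALSE)
  mean(abs(diff(x)))
}

#' Hjorth mobility and complexity
#'
#' Classic EEG descriptors: mobility is `sqrt(var(diff(x))/var(x))`;
#' complexity is the mobility of the differenced signal divided by the
#' mobility of the signal. A zero-variance input returns an NaN pair
#' (handled by downstream imputation) rather than raising.
#'
#' @param x numeric signal vector, length >= 3.
#' @return Named numeric vector `c(mobility, complexity)`.
#' @export
hjorth_params <- function(x) {
  if (length(x) < 3) stop("need at least 3 samples", call. = FALSE)
  v0 <- stats::var(x)
  d1 <- diff(x)
  v1 <- stats::var(d1)
  if (!is.finite(v0) || v0 == 0) {
    return(c(mobility = NaN, complexity = NaN))
  }
  mob <- sqrt(v1 / v0)
  v2 <- stats::var(diff(d1))
  comp <- if (v1 == 0) NaN else sqrt(v2 / v1) / mob
  c(mobility = mob, complexity = comp)
}

#' Zero crossings of the mean-removed signal
#'
#' Number of sign changes between consecutive samples after removing
#' the mean (which removes drift-induced bias). Exact zeros are
#' assigned positive sign.
#'
#' @param x numeric signal vector, length >= 2.
#' @return Integer count of sign changes.
#' @export
zero_crossings <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)
  y <- x - mean(x)
  s <- ifelse(y >= 0, 1L, -1L)
  sum(diff(s) != 0L)
}

#' Distribution statistics of a signal
#'
#' Sample mean, median, standard deviation (denominator N-1), and
#' skewness / kurtosis as standardized third / fourth central moments
#' (moment denominators N). Kurtosis is reported non-excess, so a
#' Gaussian signal scores approximately 3.
#'
#' @param x numeric signal vector, length >= 4.
#' @return Named vector `c(mean, median, sd, skewness, kurtosis)`.
#' @export
distribution_stats <- function(x) {
  if (length(x) < 4) stop("need at least 4 samples", call. = FALSE)
  n <- length(x)
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  skew <- if (m2 == 0) NaN else mean(d^3) / m2^1.5
  kurt <- if (m2 == 0) NaN else mean(d^4) / m2^2
  c(mean = mu, median = stats::median(x), sd = stats::sd(x),
    skewness = skew, kurtosis = kurt)
}

#' Hurst exponent via rescaled-range analysis
#'
#' Classical R/S estimate: the signal is split into non-overlapping
#' windows at dyadic sizes from 8 up to N/2; in each window the range
#' of the cumulative mean-removed sum is divided by the window standard
#' deviation, and the Hurst exponent is the slope of log(mean R/S)
#' against log(window size). White noise scores about 0.5, persistent
#' (random-walk-like) signals approach 1.
#'
#' @param x numeric signal vector; fewer than 64 samples yield NaN.
#' @return Hurst exponent estimate (or NaN).
#' @export
hurst_exponent <- function(x) {
  n <- length(x)
  if (n < 64) return(NaN)
  sizes <- 2^(3:floor(log2(n / 2)))
  rs <- vapply(sizes, function(w) {
    n_seg <- floor(n / w)
    vals <- vapply(seq_len(n_seg), function(i) {
      seg <- x[((i - 1) * w + 1):(i * w)]
      s <- stats::sd(seg)
      if (!is.finite(s) || s == 0) return(NA_real_)
      cs <- cumsum(seg - mean(seg))
      (max(cs) - min(cs)) / s
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 2) return(NaN)
  fit <- stats::lm.fit(cbind(1, log(sizes[ok])), log(rs[ok]))
  unname(fit$coefficients[2])
}

# Chebyshev-distance template match counts for sample/approximate
# entropy, embedding dimension m, tolerance r.
embed_match_counts <- function(x, m, r) {
  n <- length(x)
  n_vec <- n - m + 1L
  D <- abs(outer(x, x, "-"))
  C <- D[1:n_vec, 1:n_vec]
  if (m > 1) {
    for (k in 1:(m - 1L)) {
      C <- pmax(C, D[(1 + k):(n_vec + k), (1 + k):(n_vec + k)])
    }
  }
  C <= r
}

#' Sample entropy
#'
#' Negative log of the conditional probability that template matches of
#' length `m` (Chebyshev distance within `r`) remain matches at length
#' `m + 1`; self-matches excluded.
#'
#' @param x numeric signal vector, length >= 32.
#' @param m embedding dimension (default 2).
#' @param r tolerance; default `0.2 * sd(x)`. Zero tolerance gives NaN.
#' @return Sample entropy (NaN when degenerate or no matches).
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  if (length(x) < 32) stop("need at least 32 samples", call. = FALSE)
  if (!is.finite(r) || r <= 0) return(NaN)
  n <- length(x)
  n_t <- n - m  # templates for which the m+1 extension exists
  Bm <- embed_match_counts(x, m, r)
  Am <- embed_match_counts(x, m + 1L, r)
  B <- sum(Bm[1:n_t, 1:n_t]) - n_t  # exclude self-matches
  A <- sum(Am) - n_t
  if (A == 0 || B == 0) return(NaN)
  -log(A / B)
}

#' Approximate entropy
#'
#' Difference of the average log template-match frequencies at
#' embedding dimensions `m` and `m + 1` (self-matches included).
#'
#' @inheritParams sample_entropy
#' @return Approximate entropy (NaN when degenerate).
#' @export
approximate_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  if (length(x) < 32) stop("need at least 32 samples", call. = FALSE)
  if (!is.finite(r) || r <= 0) return(NaN)
  phi <- function(mm) {
    M <- embed_match_counts(x, mm, r)
    mean(log(rowMeans(M)))
  }
  phi(m) - phi(m + 1L)
}

perm_pattern_codes <- function(x, order, delay) {
  n <- length(x)
  n_pat <- n - (order - 1L) * delay
  emb <- sapply(0:(order - 1L), function(k) x[(1 + k * delay):(n_pat + k * delay)])
  codes <- integer(n_pat)
  # rank pattern encoded in factorial base; ties broken by position
  for (i in seq_len(n_pat)) {
    codes[i] <- sum(order(emb[i, ]) * order^(0:(order - 1L)))
  }
  list(codes = codes, emb = emb)
}

#' Permutation entropy (normalized)
#'
#' Shannon entropy of the ordinal-pattern distribution of embedded
#' vectors (order 3, delay 1 by default), normalized by `log(order!)`
#' to `[0, 1]`. The weighted variant weights each pattern occurrence by
#' the variance of its embedded vector.
#'
#' @param x numeric signal vector, length >= 32.
#' @param order ordinal pattern order (default 3).
#' @param delay embedding delay (default 1).
#' @param weighted logical; variance-weighted pattern probabilities.
#' @return Normalized permutation entropy in `[0, 1]`.
#' @export
permutation_entropy <- function(x, order = 3L, delay = 1L,
                                weighted = FALSE) {
  if (length(x) < 32) stop("need at least 32 samples", call. = FALSE)
  pp <- perm_pattern_codes(x, order, delay)
  if (weighted) {
    w <- apply(pp$emb, 1, function(v) mean((v - mean(v))^2))
    if (sum(w) == 0) return(0)
    p <- tapply(w, pp$codes, sum) / sum(w)
  } else {
    p <- table(pp$codes) / length(pp$codes)
  }
  p <- as.numeric(p[p > 0])
  -sum(p * log(p)) / log(factorial(order))
}

#' Spectral entropy (normalized)
#'
#' Shannon entropy of the normalized (untapered) periodogram,
#' divided by `log(#bins)`.
#'
#' @param x numeric signal vector, length >= 32.
#' @param fs sampling rate in Hz.
#' @return Normalized spectral entropy in `[0, 1]` (NaN for an
#'   all-zero spectrum).
#' @export
spectral_entropy <- function(x, fs) {
  if (length(x) < 32) stop("need at least 32 samples", call. = FALSE)
  sp <- power_spectrum(x, fs, taper = "none")
  tot <- sum(sp$power)
  if (tot <= 0) return(NaN)
  p <- sp$power / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(sp$power))
}

#' Lempel-Ziv complexity (normalized)
#'
#' LZ76 phrase count of the median-binarized signal, normalized by
#' `N / log2(N)` so that values are comparable across lengths.
#'
#' @param x numeric signal vector, length >= 32.
#' @return Normalized complexity.
#' @export
lempel_ziv_complexity <- function(x) {
  if (length(x) < 32) stop("need at least 32 samples", call. = FALSE)
  b <- as.integer(x > stats::median(x))
  n <- length(b)
  # LZ76 parsing, classic two-pointer formulation
  c_count <- 1L
  l <- 1L
  i <- 0L
  k <- 1L
  k_max <- 1L
  repeat {
    if (b[i + k] == b[l + k]) {
      k <- k + 1L
      if (l + k > n) {
        c_count <- c_count + 1L
        break
      }
    } else {
      if (k > k_max) k_max <- k
      i <- i + 1L
      if (i == l) {
        c_count <- c_count + 1L
        l <- l + k_max
        if (l + 1L > n) break
        i <- 0L
        k <- 1L
        k_max <- 1L
      } else {
        k <- 1L
      }
    }
  }
  c_count * log2(n) / n
}

#' Higuchi fractal dimension
#'
#' Curve-length based fractal dimension with scale parameter
#' `k_max = 10` by default: mean normalized curve lengths `L(k)` are
#' regressed on `log(1/k)`.
#'
#' @param x numeric signal vector, length >= 32.
#' @param k_max maximum scale (default 10).
#' @return Fractal dimension estimate in `[1, 2]` for typical signals
#'   (NaN for constant input).
#' @export
higuchi_fd <- function(x, k_max = 10L) {
  if (length(x) < 32) stop("need at least 32 samples", call. = FALSE)
  n <- length(x)
  lk <- vapply(seq_len(k_max), function(k) {
    lm_k <- vapply(seq_len(k), function(m) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2) return(NA_real_)
      norm <- (n - 1) / (floor((n - m) / k) * k)
      sum(abs(diff(x[idx]))) * norm / k
    }, numeric(1))
    mean(lm_k, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(lk) & lk > 0
  if (sum(ok) < 2) return(NaN)
  k <- seq_len(k_max)[ok]
  fit <- stats::lm.fit(cbind(1, log(1 / k)), log(lk[ok]))
  unname(fit$coefficients[2])
}

#' The seven entropy/complexity features
#'
#' Sample entropy and approximate entropy (m = 2, r = 0.2 sd),
#' permutation and weighted permutation entropy (order 3, delay 1,
#' normalized), spectral entropy, Lempel-Ziv complexity, and Higuchi
#' fractal dimension (k_max = 10).
#'
#' @param x numeric signal vector, length >= 32.
#' @param fs sampling rate in Hz (for spectral entropy).
#' @return Named numeric vector of length 7.
#' @export
entropy_features <- function(x, fs) {
  c(sample_entropy = sample_entropy(x),
    approximate_entropy = approximate_entropy(x),
    permutation_entropy = permutation_entropy(x),
    weighted_permutation_entropy = permutation_entropy(x, weighted = TRUE),
    spectral_entropy = spectral_entropy(x, fs),
    lempel_ziv_complexity = lempel_ziv_complexity(x),
    higuchi_fd = higuchi_fd(x))
}

#' The TimeFeats feature registry
#'
#' Ordered names of the default 41-feature TimeFeats set: the 22
#' canonical catch22 descriptors, the peak-excluded aperiodic slope and
#' offset, five distribution statistics, the two Hjorth parameters,
#' the Hurst exponent, zero crossings, mean curve length, and seven
#' entropy/complexity measures.
#'
#' @return Character vector of length 41; order is stable across runs.
#' @export
timefeats_registry <- function() {
  c(catch22_names,
    "aperiodic_slope", "aperiodic_offset",
    "mean", "median", "sd", "skewness", "kurtosis",
    "hjorth_mobility", "hjorth_complexity",
    "hurst_exponent", "zero_crossings", "mean_curve_length",
    "sample_entropy", "approximate_entropy", "permutation_entropy",
    "weighted_permutation_entropy", "spectral_entropy",
    "lempel_ziv_complexity", "higuchi_fd")
}

#' Compute the TimeFeats set on one epoch
#'
#' Produces the 41 TimeFeats values in registry order. The aperiodic
#' slope and offset are computed from the epoch's own spectrum after
#' masking the frequency ranges of `avg_peaks` — the oscillatory peaks
#' detected once per spatial unit on the spectrum averaged over all of
#' that unit's epochs (see [detect_spectral_peaks()]).
#'
#' @param epoch numeric signal vector (one epoch, one spatial unit).
#' @param fs sampling rate in Hz.
#' @param avg_peaks peak data frame for this spatial unit (may have
#'   zero rows; `NULL` means no exclusion).
#' @param fit_range frequency range (Hz) for the aperiodic fit
#'   (default 1-100).
#' @param taper taper for the aperiodic-fit spectrum (default Hann).
#' @return Named numeric vector of length 41 (NaN at degenerate
#'   features, never an error).
#' @export
compute_timefeats <- function(epoch, fs, avg_peaks = NULL,
                              fit_range = c(1, 100), taper = "hann") {
  ds <- distribution_stats(epoch)
  hj <- hjorth_params(epoch)
  sp <- power_spectrum(epoch, fs, taper = taper)
  mask <- build_aperiodic_mask(sp$freqs, avg_peaks)
  fit <- suppressWarnings(fit_aperiodic(sp, mask, fit_range = fit_range))
  vals <- c(catch22_features(epoch),
            aperiodic_slope = fit$slope,
            aperiodic_offset = fit$offset,
            ds,
            hjorth_mobility = unname(hj["mobility"]),
            hjorth_complexity = unname(hj["complexity"]),
            hurst_exponent = hurst_exponent(epoch),
            zero_crossings = zero_crossings(epoch),
            mean_curve_length = mean_curve_length(epoch),
            entropy_features(epoch, fs))
  vals[timefeats_registry()]
}

#' Compute TimeFeats on a band-passed epoch
#'
#' Band-pass filters the epoch (zero-phase Butterworth, see
#' [bandpass_filter()]), then computes the full TimeFeats set; the
#' aperiodic slope and offset are fitted over the band's frequency
#' range only.
#'
#' @param epoch numeric signal vector.
#' @param fs sampling rate in Hz.
#' @param band one-row band definition.
#' @param avg_peaks optional peak data frame (as in
#'   [compute_timefeats()]).
#' @return Named numeric vector of length 41.
#' @export
compute_timefeats_banded <- function(epoch, fs, band, avg_peaks = NULL) {
  validate_bands(band, fs = fs)
  filtered <- bandpass_filter(epoch, fs, band)
  compute_timefeats(filtered, fs, avg_peaks = avg_peaks,
                    fit_range = c(band$f_lo, band$f_hi))
}
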