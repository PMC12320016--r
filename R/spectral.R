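#' Canonical frequency-band bank
#'
#' The six canonical M/EEG bands used by the `FreqBands` feature set:
#' delta 1-4, theta 4-8, alpha 8-13, beta 13-30, low gamma 30-45 and
#' high gamma 55-100 Hz. Bands are closed intervals; integer-Hz bins
#' falling on a shared edge (e.g. 4 Hz) belong to both neighbours. The
#' 45-55 Hz gap skips the mains-line region and is intentional.
#'
#' @return A data frame with columns `name`, `f_lo`, `f_hi`.
#' @export
#' @examples
#' default_bands()
default_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma_low", "gamma_high"),
    f_lo = c(1, 4, 8, 13, 30, 55),
    f_hi = c(4, 8, 13, 30, 45, 100),
    stringsAsFactors = FALSE
  )
}

#' Define a frequency band
#'
#' @param name band label.
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi`.
#' @return A one-row band definition data frame.
#' @export
band_definition <- function(name, f_lo, f_hi) {
  stopifnot_scalar_number(f_lo, "f_lo", lower = 0)
  stopifnot_scalar_number(f_hi, "f_hi", lower = 0)
  if (f_lo <= 0 || f_hi <= f_lo) {
    stop("band must satisfy 0 < f_lo < f_hi", call. = FALSE)
  }
  data.frame(name = as.character(name), f_lo = f_lo, f_hi = f_hi,
             stringsAsFactors = FALSE)
}

validate_bands <- function(bands, fs = NULL) {
  stopifnot(is.data.frame(bands),
            all(c("name", "f_lo", "f_hi") %in% names(bands)))
  if (any(bands$f_lo <= 0) || any(bands$f_hi <= bands$f_lo)) {
    stop("invalid band bank: need 0 < f_lo < f_hi for every band",
         call. = FALSE)
  }
  if (!is.null(fs) && any(bands$f_hi >= fs / 2)) {
    stop("band edges must lie strictly below the Nyquist frequency",
         call. = FALSE)
  }
  invisible(bands)
}

#' Construct a power spectrum object from precomputed values
#'
#' Mainly useful for feeding analytically constructed spectra to the
#' aperiodic fitting routines.
#'
#' @param freqs strictly increasing frequency vector (Hz).
#' @param power non-negative power values, same length as `freqs`.
#' @param taper character tag recording the taper used.
#' @return An object of class `power_spectrum`.
#' @export
as_power_spectrum <- function(freqs, power, taper = "none") {
  stopifnot(length(freqs) == length(power))
  if (is.unsorted(freqs, strictly = TRUE)) {
    stop("`freqs` must be strictly increasing", call. = FALSE)
  }
  if (any(power < 0)) stop("`power` must be non-negative", call. = FALSE)
  structure(list(freqs = as.numeric(freqs), power = as.numeric(power),
                 taper = taper),
            class = "power_spectrum")
}

#' Single-taper periodogram of one epoch
#'
#' Computes a one-sided periodogram with an optional Hann taper.
#' The normalization is chosen so that, with `taper = "none"`, the sum of
#' power over all non-DC bins equals the epoch's population variance
#' (mean squared deviation, denominator `N`) — the discrete Parseval
#' identity relating signal variance to total spectral power. With the
#' Hann taper the window's power loss is compensated by `1/mean(w^2)` so
#' that broadband power estimates remain comparable.
#'
#' @param epoch numeric signal vector (one epoch, one spatial unit).
#' @param fs sampling rate in Hz.
#' @param taper `"hann"` (default) or `"none"`.
#' @return A `power_spectrum` object with frequencies from `fs/N` up to
#'   the Nyquist frequency at resolution `fs/N` Hz.
#' @export
#' @examples
#' x <- sin(2 * pi * 10 * (0:255) / 256)
#' sp <- power_spectrum(x, fs = 256, taper = "none")
#' sp$freqs[which.max(sp$power)]  # 10 Hz
power_spectrum <- function(epoch, fs, taper = c("hann", "none")) {
  taper <- match.arg(taper)
  n <- length(epoch)
  if (n < 8) stop("epoch too short for a periodogram (need N >= 8)",
                  call. = FALSE)
  if (!all(is.finite(epoch))) stop("epoch contains non-finite values",
                                   call. = FALSE)
  if (taper == "hann") {
    w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / n))  # periodic Hann
    xw <- epoch * w
    scale <- 1 / mean(w^2)
  } else {
    xw <- epoch
    scale <- 1
  }
  X <- stats::fft(xw)
  n_half <- n %/% 2
  # one-sided power; factor 2 for bins with a conjugate partner
  p <- Mod(X[seq_len(n_half + 1)])^2 / n^2
  two_sided <- rep(2, n_half + 1)
  two_sided[1] <- 1
  if (n %% 2 == 0) two_sided[n_half + 1] <- 1
  p <- p * two_sided * scale
  freqs <- (0:n_half) * fs / n
  # drop DC: the analysis range starts at the first positive frequency
  as_power_spectrum(freqs[-1], p[-1], taper = taper)
}

#' Mean band power in a band bank
#'
#' Arithmetic mean of spectral power over the bins falling inside each
#' band (closed intervals; edge bins shared by adjacent bands count in
#' both). With the default bank this is the six-value `FreqBands` set.
#'
#' @param spec a `power_spectrum` object.
#' @param bands band bank data frame (default [default_bands()]).
#' @return Named numeric vector, one value per band in bank order.
#' @export
band_power_features <- function(spec, bands = default_bands()) {
  stopifnot(inherits(spec, "power_spectrum"))
  validate_bands(bands)
  out <- vapply(seq_len(nrow(bands)), function(i) {
    sel <- spec$freqs >= bands$f_lo[i] & spec$freqs <= bands$f_hi[i]
    if (!any(sel)) {
      stop(sprintf("band '%s' (%g-%g Hz) contains no spectral bins",
                   bands$name[i], bands$f_lo[i], bands$f_hi[i]),
           call. = FALSE)
    }
    mean(spec$power[sel])
  }, numeric(1))
  names(out) <- bands$name
  out
}

#' Full-spectrum power features at 1 Hz resolution
#'
#' Power at every integer frequency from 1 to 100 Hz — the `fullFFT`
#' benchmark set (one hundred values per spatial unit).
#'
#' @param spec a `power_spectrum` object whose bins cover 1-100 Hz at a
#'   resolution of 1 Hz or finer.
#' @param f_max upper frequency (default 100 Hz).
#' @return Named numeric vector `f1 ... f100`.
#' @export
fullfft_features <- function(spec, f_max = 100) {
  stopifnot(inherits(spec, "power_spectrum"))
  df <- min(diff(spec$freqs))
  if (df > 1 + 1e-9) {
    stop("spectrum resolution is coarser than 1 Hz; cannot extract ",
         "integer-frequency features", call. = FALSE)
  }
  targets <- seq_len(f_max)
  if (max(spec$freqs) < f_max - 1e-9 || min(spec$freqs) > 1 + 1e-9) {
    stop("spectrum must cover 1-", f_max, " Hz", call. = FALSE)
  }
  idx <- vapply(targets, function(f) which.min(abs(spec$freqs - f)),
                integer(1))
  out <- spec$power[idx]
  names(out) <- paste0("f", targets)
  out
}

#' Zero-phase Butterworth band-pass filter
#'
#' Fourth-order Butterworth band-pass applied forward and reverse
#' (`filtfilt`), giving zero phase distortion and output of the same
#' length as the input.
#'
#' @param epoch numeric signal vector.
#' @param fs sampling rate in Hz.
#' @param band one-row band definition (see [band_definition()]).
#' @return Filtered signal, same length as `epoch`.
#' @export
bandpass_filter <- function(epoch, fs, band) {
  validate_bands(band, fs = fs)
  if (nrow(band) != 1L) stop("`band` must be a single band", call. = FALSE)
  ny <- fs / 2
  bf <- signal::butter(4, c(band$f_lo, band$f_hi) / ny, type = "pass")
  as.numeric(signal::filtfilt(bf, epoch))
}
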