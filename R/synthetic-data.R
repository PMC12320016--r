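#' The four-state vocabulary
#'
#' EC = eyes-closed rest, EO = eyes-open rest, BSL = pre-stimulus
#' baseline, VS = visual stimulation.
#' @export
STATE_LEVELS <- c("EC", "EO", "BSL", "VS")

#' Parameters of one brain state's generative model
#'
#' Each state is modelled as an additive mixture of a 1/f^chi power-law
#' background, narrow-band oscillations (optionally bursty), a slow
#' baseline drift and white sensor noise.
#'
#' @param state_label one of `"EC"`, `"EO"`, `"BSL"`, `"VS"`.
#' @param aperiodic_exponent power-law exponent chi >= 0 of the
#'   background spectrum P(f) ~ f^-chi.
#' @param aperiodic_scale amplitude multiplier (> 0) of the background.
#' @param oscillations list of oscillations, each a list with
#'   `center_freq` (Hz), `amplitude` (signal units) and `burst_fraction`
#'   in `[0, 1]` (1 = sustained sinusoid).
#' @param drift_amplitude magnitude (signal units) of the slow baseline
#'   drift offset.
#' @param noise_sd standard deviation of additive white noise.
#' @return A `state_params` list.
#' @export
state_params <- function(state_label, aperiodic_exponent, aperiodic_scale = 1,
                         oscillations = list(), drift_amplitude = 0,
                         noise_sd = 0) {
  state_label <- match.arg(state_label, STATE_LEVELS)
  stopifnot_scalar_number(aperiodic_exponent, "aperiodic_exponent", lower = 0)
  stopifnot_scalar_number(aperiodic_scale, "aperiodic_scale")
  stopifnot_scalar_number(drift_amplitude, "drift_amplitude", lower = 0)
  stopifnot_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (aperiodic_scale <= 0) stop("`aperiodic_scale` must be > 0",
                                 call. = FALSE)
  for (osc in oscillations) {
    stopifnot(is.list(osc),
              all(c("center_freq", "amplitude", "burst_fraction") %in%
                    names(osc)))
    if (osc$burst_fraction < 0 || osc$burst_fraction > 1) {
      stop("`burst_fraction` must lie in [0, 1]", call. = FALSE)
    }
    if (osc$center_freq <= 0) stop("`center_freq` must be > 0",
                                   call. = FALSE)
  }
  structure(list(state_label = state_label,
                 aperiodic_exponent = aperiodic_exponent,
                 aperiodic_scale = aperiodic_scale,
                 oscillations = oscillations,
                 drift_amplitude = drift_amplitude,
                 noise_sd = noise_sd),
            class = "state_params")
}

#' Default generative presets for the four brain states
#'
#' Encodes the canonical state contrasts the analysis is designed to
#' detect: alpha (10 Hz) much stronger with eyes closed than open,
#' broadband/narrow-band gamma stronger under visual stimulation than in
#' baseline, a steeper aperiodic exponent at rest than during
#' stimulation, and state-specific slow-drift magnitudes so that
#' location features (mean, median) also carry state information.
#'
#' @return Named list of [state_params()] objects for EC, EO, BSL, VS.
#' @export
default_state_presets <- function() {
  list(
    EC = state_params("EC", aperiodic_exponent = 1.6, aperiodic_scale = 1,
                      oscillations = list(
                        list(center_freq = 10, amplitude = 1.0,
                             burst_fraction = 0.8)),
                      drift_amplitude = 0.5, noise_sd = 0.3),
    EO = state_params("EO", aperiodic_exponent = 1.4, aperiodic_scale = 1,
                      oscillations = list(
                        list(center_freq = 10, amplitude = 0.35,
                             burst_fraction = 0.8)),
                      drift_amplitude = 0.2, noise_sd = 0.3),
    BSL = state_params("BSL", aperiodic_exponent = 1.5, aperiodic_scale = 1,
                       oscillations = list(
                         list(center_freq = 10, amplitude = 0.6,
                              burst_fraction = 0.8),
                         list(center_freq = 65, amplitude = 0.1,
                              burst_fraction = 0.6)),
                       drift_amplitude = 0.3, noise_sd = 0.3),
    VS = state_params("VS", aperiodic_exponent = 1.2, aperiodic_scale = 1,
                      oscillations = list(
                        list(center_freq = 10, amplitude = 0.4,
                             burst_fraction = 0.8),
                        list(center_freq = 65, amplitude = 0.45,
                             burst_fraction = 0.7)),
                      drift_amplitude = 0.3, noise_sd = 0.3)
  )
}

#' Cohort-level configuration of the synthetic generator
#'
#' @param n_subjects number of subjects.
#' @param n_epochs_per_state epochs generated per state per subject.
#' @param epoch_len_s epoch length in seconds (default 1).
#' @param fs sampling rate in Hz (default 256).
#' @param n_spatial_units number of parcels/channels per subject.
#' @param subject_sd fractional between-subject jitter: every positive
#'   state parameter is multiplied per subject by
#'   `exp(rnorm(1, 0, subject_sd))`.
#' @param master_seed integer master seed; mandatory, all randomness in
#'   the cohort derives from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 5, n_epochs_per_state = 10,
                          epoch_len_s = 1, fs = 256, n_spatial_units = 4,
                          subject_sd = 0.2, master_seed) {
  if (missing(master_seed)) stop("`master_seed` is mandatory", call. = FALSE)
  stopifnot_scalar_number(master_seed, "master_seed")
  n_samples <- epoch_len_s * fs
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    stop("epoch_len_s * fs must be an integer number of samples",
         call. = FALSE)
  }
  stopifnot(n_subjects >= 1, n_epochs_per_state >= 1, n_spatial_units >= 1,
            subject_sd >= 0, fs > 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_epochs_per_state = as.integer(n_epochs_per_state),
                 epoch_len_s = epoch_len_s, fs = fs,
                 n_spatial_units = as.integer(n_spatial_units),
                 subject_sd = subject_sd,
                 master_seed = as.integer(master_seed)),
            class = "cohort_config")
}

#' Generate zero-mean 1/f^chi power-law noise
#'
#' White Gaussian noise is transformed to the frequency domain, its
#' spectral amplitudes are shaped by `f^(-exponent/2)` (DC set to zero),
#' and the result is inverse-transformed and standardized to unit
#' variance. The expected power spectrum follows `P(f) ~ f^-exponent`.
#'
#' @param exponent power-law exponent chi >= 0 (0 gives white noise).
#' @param n_samples number of samples (>= 8).
#' @param fs sampling rate in Hz (sets the frequency axis only).
#' @param seed integer seed; identical arguments give identical output.
#' @return Numeric vector of length `n_samples`, zero mean, unit variance.
#' @export
make_powerlaw_noise <- function(exponent, n_samples, fs, seed) {
  stopifnot_scalar_number(exponent, "exponent", lower = 0)
  stopifnot_scalar_number(n_samples, "n_samples", lower = 8)
  n <- as.integer(n_samples)
  w <- with_seed(seed, stats::rnorm(n))
  X <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n  # two-sided frequency magnitude
  shape <- numeric(n)
  pos <- f > 0
  shape[pos] <- f[pos]^(-exponent / 2)
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x <- x / s
  x
}

#' Synthesize one epoch of a given brain state
#'
#' Sums the state's power-law background, its oscillations (sustained
#' sinusoids with random phase, or rectangular bursts covering
#' `burst_fraction` of the epoch at a uniformly placed onset), a
#' constant baseline-drift offset of magnitude `drift_amplitude`, and
#' white noise.
#'
#' @param params a [state_params()] object.
#' @param fs sampling rate in Hz.
#' @param n_samples samples per epoch.
#' @param seed integer seed.
#' @param drift_value optional standardized drift value (the generator
#'   supplies values from a slow random walk across the epoch sequence);
#'   drawn `N(0, 1)` from `seed` when `NULL`. The epoch's additive
#'   offset is `drift_amplitude * drift_value`.
#' @return Numeric signal vector of length `n_samples`.
#' @export
synthesize_state_epoch <- function(params, fs, n_samples, seed,
                                   drift_value = NULL) {
  stopifnot(inherits(params, "state_params"))
  for (osc in params$oscillations) {
    if (osc$center_freq >= fs / 2) {
      stop("oscillation center_freq must lie below the Nyquist frequency",
           call. = FALSE)
    }
  }
  n <- as.integer(n_samples)
  t <- (0:(n - 1)) / fs
  x <- params$aperiodic_scale *
    make_powerlaw_noise(params$aperiodic_exponent, n, fs,
                        seed = derive_seed(seed, 1))
  x <- x + with_seed(derive_seed(seed, 2), {
    osc_sum <- numeric(n)
    for (osc in params$oscillations) {
      phase <- stats::runif(1, 0, 2 * pi)
      s <- osc$amplitude * sin(2 * pi * osc$center_freq * t + phase)
      if (osc$burst_fraction < 1) {
        len <- round(osc$burst_fraction * n)
        env <- numeric(n)
        if (len > 0) {
          onset <- sample.int(n - len + 1L, 1L)
          env[onset:(onset + len - 1L)] <- 1
        }
        s <- s * env
      }
      osc_sum <- osc_sum + s
    }
    osc_sum
  })
  if (is.null(drift_value)) {
    drift_value <- with_seed(derive_seed(seed, 3), stats::rnorm(1))
  }
  x <- x + params$drift_amplitude * drift_value
  if (params$noise_sd > 0) {
    x <- x + with_seed(derive_seed(seed, 4),
                       stats::rnorm(n, 0, params$noise_sd))
  }
  x
}

#' One subject's epoched recording
#'
#' @param subject_id subject identifier string.
#' @param epochs numeric array `[n_epochs, n_spatial_units, n_samples]`.
#' @param state_labels character/factor vector, one state per epoch.
#' @param fs sampling rate in Hz.
#' @param unit_names names of the spatial units (parcels/channels).
#' @return An `epoched_recording` object.
#' @export
epoched_recording <- function(subject_id, epochs, state_labels, fs,
                              unit_names = NULL) {
  stopifnot(is.array(epochs), length(dim(epochs)) == 3L)
  n_epochs <- dim(epochs)[1]
  n_units <- dim(epochs)[2]
  state_labels <- as.character(state_labels)
  if (length(state_labels) != n_epochs) {
    stop("state_labels length must equal the number of epochs",
         call. = FALSE)
  }
  bad <- setdiff(unique(state_labels), STATE_LEVELS)
  if (length(bad) > 0) {
    stop("unknown state label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(epochs) || !all(is.finite(epochs))) {
    stop("epochs must contain only finite values at construction",
         call. = FALSE)
  }
  if (is.null(unit_names)) unit_names <- sprintf("unit%02d", seq_len(n_units))
  stopifnot(length(unit_names) == n_units)
  structure(list(subject_id = as.character(subject_id), epochs = epochs,
                 state_labels = state_labels, fs = fs,
                 unit_names = as.character(unit_names)),
            class = "epoched_recording")
}

jitter_params <- function(params, subject_sd) {
  if (subject_sd == 0) return(params)
  jit <- function(v) v * exp(stats::rnorm(1, 0, subject_sd))
  params$aperiodic_exponent <- jit(params$aperiodic_exponent)
  params$aperiodic_scale <- jit(params$aperiodic_scale)
  params$drift_amplitude <- jit(params$drift_amplitude)
  params$noise_sd <- jit(params$noise_sd)
  params$oscillations <- lapply(params$oscillations, function(osc) {
    osc$amplitude <- jit(osc$amplitude)
    osc
  })
  params
}

#' Generate a synthetic multi-subject cohort
#'
#' One [epoched_recording()] per subject. Each subject's state presets
#' are jittered multiplicatively by `subject_sd` using a
#' subject-specific random stream derived from `master_seed`. Within a
#' subject, epochs are laid out in contiguous state blocks (EC, EO,
#' BSL, VS), in temporal order inside each block, so that
#' contiguous-fold cross-validation logic is meaningful. Baseline-drift
#' offsets follow an independent slow random walk across each state
#' block per spatial unit.
#'
#' @param config a [cohort_config()].
#' @param presets named list of [state_params()], one per state
#'   (default [default_state_presets()]).
#' @return List of `epoched_recording`, length `config$n_subjects`.
#' @export
generate_cohort <- function(config, presets = default_state_presets()) {
  stopifnot(inherits(config, "cohort_config"))
  missing_states <- setdiff(STATE_LEVELS, names(presets))
  if (length(missing_states) > 0) {
    stop("missing state preset(s): ", paste(missing_states, collapse = ", "),
         call. = FALSE)
  }
  n_samples <- as.integer(round(config$epoch_len_s * config$fs))
  n_ep_state <- config$n_epochs_per_state
  n_epochs <- n_ep_state * length(STATE_LEVELS)
  lapply(seq_len(config$n_subjects), function(s) {
    sub_seed <- derive_seed(config$master_seed, s)
    sub_presets <- with_seed(derive_seed(sub_seed, 0),
                             lapply(presets[STATE_LEVELS], jitter_params,
                                    subject_sd = config$subject_sd))
    epochs <- array(0, dim = c(n_epochs, config$n_spatial_units, n_samples))
    labels <- rep(STATE_LEVELS, each = n_ep_state)
    for (u in seq_len(config$n_spatial_units)) {
      for (st_i in seq_along(STATE_LEVELS)) {
        st <- STATE_LEVELS[st_i]
        pars <- sub_presets[[st]]
        # slow random walk of standardized drift values over the block
        walk_seed <- derive_seed(sub_seed, 1000L + u * 10L + st_i)
        drift <- with_seed(walk_seed,
                           cumsum(stats::rnorm(n_ep_state,
                                               sd = 1 / sqrt(n_ep_state))))
        for (e in seq_len(n_ep_state)) {
          row <- (st_i - 1L) * n_ep_state + e
          ep_seed <- derive_seed(sub_seed,
                                 2000L + ((u - 1L) * n_epochs + row))
          epochs[row, u, ] <- synthesize_state_epoch(
            pars, config$fs, n_samples, seed = ep_seed,
            drift_value = drift[e])
        }
      }
    }
    epoched_recording(sprintf("sub%02d", s), epochs, labels, config$fs)
  })
}
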