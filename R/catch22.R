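# The 22 canonical time-series descriptors ("catch22"): a published
# selection from the hctsa library covering distribution shape,
# autocorrelation structure, symbolic motifs, fluctuation scaling,
# simple forecasting and spectral summaries. Each descriptor is
# computed on the z-scored signal, following the set's convention.

catch22_names <- c(
  "DN_HistogramMode_5",
  "DN_HistogramMode_10",
  "CO_f1ecac",
  "CO_FirstMin_ac",
  "CO_HistogramAMI_even_2_5",
  "CO_trev_1_num",
  "MD_hrv_classic_pnn40",
  "SB_BinaryStats_mean_longstretch1",
  "SB_TransitionMatrix_3ac_sumdiagcov",
  "PD_PeriodicityWang_th0_01",
  "CO_Embed2_Dist_tau_d_expfit_meandiff",
  "IN_AutoMutualInfoStats_40_gaussian_fmmi",
  "FC_LocalSimple_mean1_tauresrat",
  "DN_OutlierInclude_p_001_mdrmd",
  "DN_OutlierInclude_n_001_mdrmd",
  "SP_Summaries_welch_rect_area_5_1",
  "SB_BinaryStats_diff_longstretch0",
  "SB_MotifThree_quantile_hh",
  "SC_FluctAnal_2_rsrangefit_50_1_logi_prop_r1",
  "SC_FluctAnal_2_dfa_50_1_2_logi_prop_r1",
  "SP_Summaries_welch_rect_centroid",
  "FC_LocalSimple_mean3_stderr"
)

# autocorrelation values at lags 0..max_lag (biased estimator, as is
# conventional for these descriptors)
acf_vals <- function(x, max_lag) {
  max_lag <- min(max_lag, length(x) - 1L)
  as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                        demean = TRUE)$acf)
}

# first lag at which the autocorrelation crosses zero
first_zero_ac <- function(x, max_lag = length(x) - 1L) {
  a <- acf_vals(x, max_lag)
  idx <- which(a[-1] < 0)
  if (length(idx) == 0) max_lag else idx[1]
}

longest_run <- function(b) {
  if (length(b) == 0 || !any(b)) return(0)
  r <- rle(b)
  max(r$lengths[r$values])
}

histogram_mode <- function(x, n_bins) {
  br <- seq(min(x), max(x), length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, br, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  centers <- (br[-1] + br[-length(br)]) / 2
  mean(centers[counts == max(counts)])
}

co_f1ecac <- function(x) {
  a <- acf_vals(x, length(x) - 1L)
  thresh <- exp(-1)
  for (i in seq_along(a)[-1]) {
    if (a[i] < thresh) {
      # linear interpolation between lags i-2 and i-1 (0-based lags)
      return((i - 2) + (a[i - 1] - thresh) / (a[i - 1] - a[i]))
    }
  }
  length(x)
}

co_first_min_ac <- function(x) {
  a <- acf_vals(x, length(x) - 1L)
  for (i in 2:(length(a) - 1L)) {
    if (a[i] < a[i - 1] && a[i] < a[i + 1]) return(i - 1)
  }
  length(a) - 1L
}

co_histogram_ami <- function(x, tau = 2L, n_bins = 5L) {
  n <- length(x)
  br <- seq(min(x), max(x), length.out = n_bins + 1L)
  b1 <- findInterval(x[1:(n - tau)], br, rightmost.closed = TRUE,
                     all.inside = TRUE)
  b2 <- findInterval(x[(tau + 1):n], br, rightmost.closed = TRUE,
                     all.inside = TRUE)
  joint <- table(factor(b1, levels = 1:n_bins),
                 factor(b2, levels = 1:n_bins))
  p <- joint / sum(joint)
  px <- rowSums(p)
  py <- colSums(p)
  mi <- 0
  for (i in 1:n_bins) {
    for (j in 1:n_bins) {
      if (p[i, j] > 0) {
        mi <- mi + p[i, j] * log(p[i, j] / (px[i] * py[j]))
      }
    }
  }
  as.numeric(mi)
}

tertile_symbols <- function(x) {
  q <- stats::quantile(x, c(1 / 3, 2 / 3), names = FALSE, type = 7)
  findInterval(x, q) + 1L  # 1, 2, 3
}

sb_motif_three_hh <- function(x) {
  s <- tertile_symbols(x)
  n <- length(s)
  pair <- (s[1:(n - 1)] - 1L) * 3L + s[2:n]
  p <- tabulate(pair, nbins = 9L) / (n - 1L)
  p <- p[p > 0]
  -sum(p * log(p))
}

sb_transition_matrix_3ac <- function(x) {
  tau <- first_zero_ac(x)
  y <- x[seq(1, length(x), by = max(tau, 1L))]
  if (length(y) < 4) return(NaN)
  s <- tertile_symbols(y)
  n <- length(s)
  trans <- matrix(0, 3, 3)
  for (i in 1:(n - 1L)) {
    trans[s[i], s[i + 1L]] <- trans[s[i], s[i + 1L]] + 1
  }
  trans <- trans / (n - 1L)
  sum(diag(stats::cov(trans)))
}

pd_periodicity_wang <- function(x, threshold = 0.01) {
  n <- length(x)
  tt <- seq_len(n)
  # cubic-polynomial detrend stands in for the original spline detrend
  detr <- stats::lm.fit(cbind(1, tt, tt^2, tt^3), x)$residuals
  max_lag <- max(3L, floor(n / 3))
  a <- acf_vals(detr, max_lag)
  a <- a[-1]  # lags 1..max_lag
  n_a <- length(a)
  trough <- 0L
  for (i in 2:(n_a - 1L)) {
    if (a[i] < a[i - 1] && a[i] < a[i + 1]) { trough <- i; break }
  }
  if (trough == 0L) return(0)
  for (i in (trough + 1L):(n_a - 1L)) {
    if (a[i] > a[i - 1] && a[i] > a[i + 1] && a[i] > threshold) {
      return(i)
    }
  }
  0
}

co_embed2_dist_expfit <- function(x) {
  n <- length(x)
  tau <- min(first_zero_ac(x), floor(n / 10))
  tau <- max(tau, 1L)
  m <- n - tau
  if (m < 3) return(NaN)
  e1 <- x[1:m]
  e2 <- x[(tau + 1):n]
  d <- sqrt(diff(e1)^2 + diff(e2)^2)
  l <- mean(d)
  if (!is.finite(l) || l <= 0) return(NaN)
  n_bins <- max(ceiling(sqrt(length(d))), 2L)
  br <- seq(min(d), max(d), length.out = n_bins + 1L)
  if (br[1] == br[length(br)]) return(NaN)
  counts <- tabulate(findInterval(d, br, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  bw <- br[2] - br[1]
  emp <- counts / (sum(counts) * bw)
  centers <- (br[-1] + br[-length(br)]) / 2
  fit <- stats::dexp(centers, rate = 1 / l)
  mean(abs(emp - fit))
}

in_ami_gaussian_fmmi <- function(x) {
  max_lag <- min(40L, floor(length(x) / 2))
  a <- acf_vals(x, max_lag)[-1]
  a2 <- pmin(a^2, 1 - 1e-12)
  ami <- -0.5 * log(1 - a2)
  if (length(ami) < 3) return(length(ami))
  for (i in 2:(length(ami) - 1L)) {
    if (ami[i] < ami[i - 1] && ami[i] < ami[i + 1]) return(i)
  }
  length(ami)
}

fc_local_simple_mean <- function(x, train_len) {
  n <- length(x)
  if (n <= train_len) return(rep(NaN, 2))
  idx <- (train_len + 1L):n
  pred <- vapply(idx, function(t) mean(x[(t - train_len):(t - 1L)]),
                 numeric(1))
  x[idx] - pred
}

dn_outlier_include_mdrmd <- function(x, sign_dir = 1) {
  y <- sign_dir * x
  n <- length(y)
  if (max(y) < 0.01) return(0)
  thresholds <- seq(0, max(y), by = 0.01)
  med_rel <- numeric(0)
  pct <- numeric(0)
  for (th in thresholds) {
    r <- which(y >= th)
    if (length(r) < 2) break
    med_rel <- c(med_rel, stats::median(r) / (n / 2) - 1)
    pct <- c(pct, 100 * length(r) / n)
  }
  keep <- pct > 2
  if (!any(keep)) return(0)
  # use the contiguous leading stretch with more than 2% of points
  last <- which(!keep)[1]
  if (!is.na(last)) keep[last:length(keep)] <- FALSE
  stats::median(med_rel[keep])
}

# density-normalized one-sided rectangular-window spectrum of a
# z-scored signal; total area equals the signal variance (= 1)
welch_rect_spectrum <- function(x) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  n_half <- n %/% 2
  p <- Mod(X[2:(n_half + 1)])^2 / n^2
  two <- rep(2, n_half)
  if (n %% 2 == 0) two[n_half] <- 1
  p <- p * two
  w <- 2 * pi * seq_len(n_half) / n  # rad/sample
  list(w = w, power = p)
}

sp_welch_area_5_1 <- function(x) {
  sp <- welch_rect_spectrum(x)
  tot <- sum(sp$power)
  if (tot <= 0) return(NaN)
  n5 <- max(floor(length(sp$power) / 5), 1L)
  sum(sp$power[1:n5]) / tot
}

sp_welch_centroid <- function(x) {
  sp <- welch_rect_spectrum(x)
  tot <- sum(sp$power)
  if (tot <= 0) return(NaN)
  cs <- cumsum(sp$power)
  sp$w[which(cs >= tot / 2)[1]]
}

sc_fluct_anal_prop_r1 <- function(x, lag, how = c("dfa", "rsrangefit")) {
  how <- match.arg(how)
  y <- x[seq(1, length(x), by = lag)]
  cs <- cumsum(y - mean(y))
  n <- length(cs)
  if (n < 10) return(NaN)
  taus <- unique(round(exp(seq(log(5), log(floor(n / 2)),
                               length.out = 50))))
  taus <- taus[taus >= 5 & taus <= floor(n / 2)]
  if (length(taus) < 8) return(NaN)
  F_tau <- vapply(taus, function(tau) {
    n_buf <- floor(n / tau)
    vals <- vapply(seq_len(n_buf), function(b) {
      seg <- cs[((b - 1) * tau + 1):(b * tau)]
      tt <- seq_len(tau)
      res <- stats::lm.fit(cbind(1, tt), seg)$residuals
      if (how == "dfa") mean(res^2) else (max(res) - min(res))^2
    }, numeric(1))
    sqrt(mean(vals))
  }, numeric(1))
  ok <- is.finite(F_tau) & F_tau > 0
  taus <- taus[ok]
  F_tau <- F_tau[ok]
  ntt <- length(taus)
  if (ntt < 8) return(NaN)
  lt <- log(taus)
  lf <- log(F_tau)
  min_pts <- 3L
  sse <- rep(Inf, ntt)
  for (i in min_pts:(ntt - min_pts)) {
    r1 <- stats::lm.fit(cbind(1, lt[1:i]), lf[1:i])$residuals
    r2 <- stats::lm.fit(cbind(1, lt[(i + 1):ntt]),
                        lf[(i + 1):ntt])$residuals
    sse[i] <- sum(r1^2) + sum(r2^2)
  }
  which.min(sse) / ntt
}

#' The 22 canonical catch22 descriptors
#'
#' Computes the published catch22 set on the z-scored signal. The
#' output order is fixed (see `names()` of the result) and matches the
#' canonical ordering of the reference implementations. A zero-variance
#' input yields a named all-NaN vector.
#'
#' @param x numeric signal vector, length >= 32.
#' @return Named numeric vector of length 22.
#' @export
catch22_features <- function(x) {
  if (length(x) < 32) stop("catch22 requires at least 32 samples",
                           call. = FALSE)
  out <- stats::setNames(rep(NaN, 22L), catch22_names)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(out)
  z <- (x - mean(x)) / s
  out["DN_HistogramMode_5"] <- histogram_mode(z, 5L)
  out["DN_HistogramMode_10"] <- histogram_mode(z, 10L)
  out["CO_f1ecac"] <- co_f1ecac(z)
  out["CO_FirstMin_ac"] <- co_first_min_ac(z)
  out["CO_HistogramAMI_even_2_5"] <- co_histogram_ami(z)
  out["CO_trev_1_num"] <- mean(diff(z)^3)
  out["MD_hrv_classic_pnn40"] <- mean(abs(diff(z)) > 0.04)
  out["SB_BinaryStats_mean_longstretch1"] <- longest_run(z > mean(z))
  out["SB_TransitionMatrix_3ac_sumdiagcov"] <- sb_transition_matrix_3ac(z)
  out["PD_PeriodicityWang_th0_01"] <- pd_periodicity_wang(z)
  out["CO_Embed2_Dist_tau_d_expfit_meandiff"] <- co_embed2_dist_expfit(z)
  out["IN_AutoMutualInfoStats_40_gaussian_fmmi"] <- in_ami_gaussian_fmmi(z)
  tau_x <- first_zero_ac(z)
  res1 <- fc_local_simple_mean(z, 1L)
  out["FC_LocalSimple_mean1_tauresrat"] <-
    if (anyNA(res1)) NaN else first_zero_ac(res1) / tau_x
  out["DN_OutlierInclude_p_001_mdrmd"] <- dn_outlier_include_mdrmd(z, 1)
  out["DN_OutlierInclude_n_001_mdrmd"] <- dn_outlier_include_mdrmd(z, -1)
  out["SP_Summaries_welch_rect_area_5_1"] <- sp_welch_area_5_1(z)
  out["SB_BinaryStats_diff_longstretch0"] <- longest_run(diff(z) < 0)
  out["SB_MotifThree_quantile_hh"] <- sb_motif_three_hh(z)
  out["SC_FluctAnal_2_rsrangefit_50_1_logi_prop_r1"] <-
    sc_fluct_anal_prop_r1(z, 1L, "rsrangefit")
  out["SC_FluctAnal_2_dfa_50_1_2_logi_prop_r1"] <-
    sc_fluct_anal_prop_r1(z, 2L, "dfa")
  out["SP_Summaries_welch_rect_centroid"] <- sp_welch_centroid(z)
  res3 <- fc_local_simple_mean(z, 3L)
  out["FC_LocalSimple_mean3_stderr"] <-
    if (anyNA(res3)) NaN else stats::sd(res3)
  out
}
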