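#' Amplitude and frequency features of an sEMG repetition
#'
#' RMS (root mean square, signal units) and median frequency: the smallest
#' frequency at which the cumulative power of the one-sided FFT spectrum
#' (magnitude squared) reaches half the total power.
#'
#' @param x signal vector.
#' @param fs sampling frequency (Hz).
#' @return list with `rms` and `mf` (Hz; `NA` with a warning for an all-zero
#'   signal, whose spectrum carries no power to halve).
#' @export
compute_features <- function(x, fs) {
  if (length(x) == 0L) stop("empty signal")
  rms <- sqrt(mean(x^2))
  sp <- spectrum_onesided(x, fs)
  pw <- sp$mag^2
  tot <- sum(pw)
  if (tot == 0) {
    warning("all-zero signal: median frequency undefined")
    return(list(rms = rms, mf = NA_real_))
  }
  mf <- sp$freq[which(cumsum(pw) >= tot / 2)[1]]
  list(rms = rms, mf = mf)
}

# one-sided FFT magnitude spectrum of the whole repetition (no averaging)
spectrum_onesided <- function(x, fs) {
  n <- length(x)
  half <- floor(n / 2) + 1L
  mag <- Mod(stats::fft(x))[seq_len(half)]
  list(freq = (seq_len(half) - 1L) * fs / n, mag = mag, df = fs / n)
}

# centered moving average with edge truncation (partial windows at edges)
moving_average <- function(x, w) {
  w <- max(as.integer(w), 1L)
  if (w == 1L) return(x)
  n <- length(x)
  hl <- (w - 1L) %/% 2L; hr <- w - 1L - hl
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - hl, 1L)
  hi <- pmin(seq_len(n) + hr, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Temporal and spectral envelopes of an sEMG repetition
#'
#' The temporal envelope is the rectified signal smoothed by a moving
#' average of `t_window` seconds; the spectral envelope is the one-sided
#' FFT magnitude spectrum smoothed by a moving average of `f_window` Hz.
#' Both are non-negative by construction.
#'
#' @param x signal vector, longer than the temporal window.
#' @param fs sampling frequency (Hz).
#' @param t_window temporal smoothing window (s).
#' @param f_window spectral smoothing window (Hz).
#' @return list of two `envelope` objects (`domain`, `values`, `step`).
#' @export
compute_envelopes <- function(x, fs, t_window = 0.5, f_window = 10) {
  wt <- round(t_window * fs)
  if (length(x) < wt) stop("signal shorter than the temporal window")
  temporal <- moving_average(abs(x), wt)
  sp <- spectrum_onesided(x, fs)
  wf <- max(round(f_window / sp$df), 1L)
  spectral <- moving_average(sp$mag, wf)
  list(temporal = structure(list(domain = "time", values = temporal,
                                 step = 1 / fs), class = "envelope"),
       spectral = structure(list(domain = "frequency", values = spectral,
                                 step = sp$df), class = "envelope"))
}

# |avg1 - avg2| / (avg1 + avg2) style dissimilarity; NA when the
# denominator vanishes (undefined rather than guessed)
half_rel_diff <- function(a, b) {
  if (a + b == 0) return(NA_real_)
  abs(a - b) / (a + b)
}

#' Feature similarity between a real and a simulated distribution
#'
#' `FeatSimi = 1 - (avgSimi + stdSimi) / 2`, where avgSimi (stdSimi) is the
#' absolute difference of the means (standard deviations) over their sum.
#' Bounded in [0, 1]; 1 means identical mean and spread. Symmetric in its
#' arguments.
#'
#' @param f_real,f_sim numeric feature distributions (one value per
#'   repetition).
#' @return scalar similarity, NA if a denominator vanishes.
#' @export
feat_simi <- function(f_real, f_sim) {
  avg_s <- half_rel_diff(mean(f_real), mean(f_sim))
  sd_r <- if (length(f_real) > 1L) stats::sd(f_real) else 0
  sd_s <- if (length(f_sim) > 1L) stats::sd(f_sim) else 0
  std_s <- if (sd_r + sd_s == 0) 0 else abs(sd_r - sd_s) / (sd_r + sd_s)
  1 - (avg_s + std_s) / 2
}

# Pearson correlation of two envelopes, linearly resampled to the shorter
# length, clamped below at 0
envelope_cc <- function(e1, e2) {
  v1 <- e1$values; v2 <- e2$values
  n <- min(length(v1), length(v2))
  if (length(v1) != n) v1 <- stats::approx(seq_along(v1), v1, n = n)$y
  if (length(v2) != n) v2 <- stats::approx(seq_along(v2), v2, n = n)$y
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) return(NA_real_)
  max(stats::cor(v1, v2), 0)
}

#' Similarity indices and the General Similarity Index
#'
#' Combines the four comparison metrics between a real and a simulated
#' signal set: RMS and median-frequency feature similarities (means and
#' spreads over repetitions), and the temporal- and spectral-envelope
#' Pearson correlations (negative correlations clamp to 0, indicating no
#' correlation). The General Similarity Index is their mean; all outputs
#' lie in [0, 1], with 1 for perfect similarity.
#'
#' @param real_feats,sim_feats lists with numeric vectors `rms` and `mf`
#'   (one entry per repetition).
#' @param real_envs,sim_envs envelope pairs from [compute_envelopes()].
#' @return named list: `rms_simi`, `mf_simi`, `time_cc`, `freq_cc`, `gsi`.
#' @export
similarity_indices <- function(real_feats, sim_feats, real_envs, sim_envs) {
  out <- list(
    rms_simi = feat_simi(real_feats$rms, sim_feats$rms),
    mf_simi = feat_simi(real_feats$mf, sim_feats$mf),
    time_cc = envelope_cc(real_envs$temporal, sim_envs$temporal),
    freq_cc = envelope_cc(real_envs$spectral, sim_envs$spectral))
  out$gsi <- mean(unlist(out))
  out
}

#' Full similarity report between two signal sets
#'
#' Convenience wrapper: computes per-repetition features, whole-set
#' envelopes (repetitions concatenated) and the similarity indices for a
#' group of repetitions of the same task/intensity.
#'
#' @param real_reps,sim_reps lists of signal vectors (one per repetition).
#' @param fs sampling frequency (Hz).
#' @return a [similarity_indices()] list.
#' @export
gsi_report <- function(real_reps, sim_reps, fs) {
  feats <- function(reps) {
    f <- lapply(reps, compute_features, fs = fs)
    list(rms = vapply(f, `[[`, numeric(1), "rms"),
         mf = vapply(f, `[[`, numeric(1), "mf"))
  }
  similarity_indices(feats(real_reps), feats(sim_reps),
                     compute_envelopes(unlist(real_reps), fs),
                     compute_envelopes(unlist(sim_reps), fs))
}
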