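# Time/frequency feature bank. Per channel: 17 time-domain descriptors in
# the vibration-analysis convention and 4 frequency-domain descriptors on
# the one-sided amplitude spectrum (DC excluded). 22 channels x 21 features
# = 462 per trial, channel-major.

.degenerate <- function(what, degenerate) {
  if (degenerate == "error") {
    stop(structure(class = c("gaitfuse_degenerate", "error", "condition"),
                   list(message = paste0("degenerate signal: ", what),
                        call = NULL)))
  }
  NA_real_
}

#' Time-domain features of one signal
#'
#' Computes the 17 classical time-domain descriptors, in this fixed order:
#' maximum; minimum; peak = max |x|; peak-to-peak; mean; average amplitude
#' = mean |x|; root amplitude = (mean sqrt |x|)^2; variance (population,
#' divisor T); standard deviation; RMS; kurtosis = m4 / sd^4 (not excess);
#' skewness = m3 / sd^3; shape factor = RMS / average amplitude; peak
#' factor = peak / RMS; pulse factor = peak / average amplitude; margin
#' factor = peak / root amplitude; clearance factor = peak / (average
#' amplitude)^2.
#'
#' Moments use the population convention (divisor T). The margin and
#' clearance factors are often used interchangeably in the literature; here
#' margin divides the peak by the root amplitude and clearance by the
#' squared mean absolute value, keeping the 17 features distinct.
#'
#' @param x Numeric vector, length >= 2, all finite.
#' @param degenerate What to do when a ratio feature is undefined (all-zero
#'   signal for the factor features, zero variance for kurtosis/skewness):
#'   `"error"` raises a structured condition of class `gaitfuse_degenerate`,
#'   `"na"` substitutes `NA` so batch extraction can continue.
#' @return Named numeric vector of length 17 (names from
#'   `feature_labels("time")`).
#' @export
#' @examples
#' time_features(sin(seq(0, 2 * pi, length.out = 100)))
time_features <- function(x, degenerate = c("error", "na")) {
  degenerate <- match.arg(degenerate)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("signal must have at least 2 samples", call. = FALSE)
  if (!all(is.finite(x))) stop("signal contains non-finite values",
                               call. = FALSE)
  ax <- abs(x)
  mx <- max(x); mn <- min(x)
  peak <- max(ax)
  mu <- mean(x)
  avg_amp <- mean(ax)
  root_amp <- mean(sqrt(ax))^2
  v <- mean((x - mu)^2)           # population variance
  s <- sqrt(v)
  rms <- sqrt(mean(x^2))
  kur <- if (s == 0) .degenerate("sd = 0, kurtosis undefined", degenerate)
         else mean((x - mu)^4) / s^4
  ske <- if (s == 0) .degenerate("sd = 0, skewness undefined", degenerate)
         else mean((x - mu)^3) / s^3
  ratio <- function(num, den, what) {
    if (den == 0) .degenerate(what, degenerate) else num / den
  }
  out <- c(mx, mn, peak, mx - mn, mu, avg_amp, root_amp, v, s, rms, kur, ske,
           ratio(rms, avg_amp, "zero signal, shape factor undefined"),
           ratio(peak, rms, "zero signal, peak factor undefined"),
           ratio(peak, avg_amp, "zero signal, pulse factor undefined"),
           ratio(peak, root_amp, "zero signal, margin factor undefined"),
           ratio(peak, avg_amp^2, "zero signal, clearance factor undefined"))
  stats::setNames(out, feature_labels("time"))
}

# One-sided amplitude spectrum, DC bin excluded: |DFT(x)|_k for
# k = 1 .. floor(T/2), at frequencies k * fs / T. No window, no padding.
amplitude_spectrum <- function(x, fs) {
  n <- length(x)
  k <- seq_len(n %/% 2)
  list(freq = k * fs / n, amp = Mod(stats::fft(x))[k + 1L])
}

#' Frequency-domain features of one signal
#'
#' On the one-sided amplitude spectrum `s_k` at frequencies `f_k` (DC
#' excluded): mean frequency `MF = mean(s_k)` (an amplitude-scale quantity,
#' the spectrum's average level); gravity frequency (spectral centroid)
#' `FC = sum(f_k s_k) / sum(s_k)`; RMS frequency
#' `RMSF = sqrt(sum(f_k^2 s_k) / sum(s_k))`; root variance of frequency
#' `RVF = sqrt(sum((f_k - FC)^2 s_k) / sum(s_k))`. The definitions satisfy
#' `RVF^2 + FC^2 = RMSF^2` identically.
#'
#' @param x Numeric vector, length >= 8, all finite.
#' @param fs Sampling frequency in Hz.
#' @param degenerate As in [time_features()]: behaviour when the spectrum is
#'   all-zero (FC/RMSF/RVF undefined).
#' @return Named numeric vector of length 4 (names from
#'   `feature_labels("freq")`).
#' @export
freq_features <- function(x, fs, degenerate = c("error", "na")) {
  degenerate <- match.arg(degenerate)
  x <- as.numeric(x)
  if (length(x) < 8L) stop("signal must have at least 8 samples",
                           call. = FALSE)
  if (!all(is.finite(x))) stop("signal contains non-finite values",
                               call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be positive", call. = FALSE)
  sp <- amplitude_spectrum(x, fs)
  s <- sp$amp; f <- sp$freq
  tot <- sum(s)
  mf <- mean(s)
  if (tot == 0) {
    nd <- .degenerate("all-zero spectrum, spectral moments undefined",
                      degenerate)
    return(stats::setNames(c(mf, nd, nd, nd), feature_labels("freq")))
  }
  fc <- sum(f * s) / tot
  rmsf <- sqrt(sum(f^2 * s) / tot)
  rvf <- sqrt(sum((f - fc)^2 * s) / tot)
  stats::setNames(c(mf, fc, rmsf, rvf), feature_labels("freq"))
}

#' Extract the 462-dimension feature vector of one trial
#'
#' Concatenates the 17 time-domain and 4 frequency-domain features of each
#' of the 22 channels, channel-major (all 21 features of channel 1 first).
#'
#' @param trial A `trial_recording` (or any list with a 22-row `channels`
#'   matrix and a `sample_rate`).
#' @param degenerate Degenerate-signal handling, see [time_features()].
#' @return Named numeric vector of length 462; names match
#'   [feature_names()].
#' @export
extract_features <- function(trial, degenerate = c("error", "na")) {
  degenerate <- match.arg(degenerate)
  n_ch <- nrow(kinematic_channels())
  if (!is.matrix(trial$channels) || nrow(trial$channels) != n_ch) {
    stop("trial must have exactly ", n_ch, " channels", call. = FALSE)
  }
  abbrs <- kinematic_channels()$abbr
  out <- numeric(0)
  for (ch in seq_len(n_ch)) {
    x <- trial$channels[ch, ]
    feats <- tryCatch(
      c(time_features(x, degenerate),
        freq_features(x, trial$sample_rate, degenerate)),
      gaitfuse_degenerate = function(e) {
        stop(structure(class = c("gaitfuse_degenerate", "error", "condition"),
          list(message = sprintf("channel %s: %s", abbrs[ch],
                                 conditionMessage(e)), call = NULL)))
      })
    out <- c(out, feats)
  }
  stats::setNames(out, feature_names())
}

#' Build the trial-by-feature matrix of a dataset
#'
#' @param dataset A `gait_dataset` (or a plain list of `trial_recording`s,
#'   in which case labels are taken from each trial).
#' @param degenerate Degenerate-signal handling, see [time_features()].
#' @return A data.frame with 462 named feature columns and a final integer
#'   `label` column, one row per trial.
#' @export
feature_matrix <- function(dataset, degenerate = c("error", "na")) {
  degenerate <- match.arg(degenerate)
  trials <- if (inherits(dataset, "gait_dataset")) dataset$trials else dataset
  labels <- if (inherits(dataset, "gait_dataset")) dataset$labels
            else vapply(trials, function(tr) as.integer(tr$label), 1L)
  X <- t(vapply(trials, extract_features, numeric(462),
                degenerate = degenerate))
  out <- as.data.frame(X)
  names(out) <- feature_names()
  out$label <- labels
  out
}
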