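# Seeded synthetic gait-transition trials: class- and channel-specific
# band-limited waveforms (<= 7 Hz, matching low-pass-filtered motion-capture
# kinematics) plus additive band-limited Gaussian noise. A smooth burst
# envelope keeps each trial's spectral energy inside the band (a transition
# stride starts and ends near rest), and the noise is synthesised from
# random-phase Fourier components on exact DFT bins below 7 Hz, so the
# band limit holds by construction rather than by filtering.

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for the synthetic gait-transition generator
#'
#' Defaults mirror the benchmark dataset the generator emulates: 8 transition
#' classes with 42-45 trials each (350 total), sampled at 100 Hz and
#' band-limited below 7 Hz.
#'
#' @param n_per_class Trials per class: a single integer (recycled to all 8
#'   classes) or a length-8 integer vector. Must be at least 2.
#' @param duration_s Nominal trial duration in seconds; actual trial lengths
#'   are jittered by +/-10% to emulate variable transition durations.
#' @param sample_rate Sampling frequency in Hz.
#' @param noise_sd Per-sample standard deviation of the additive
#'   band-limited Gaussian noise, in signal units (class templates have
#'   amplitudes of order 1).
#' @param class_separation Scale of the between-class differences in template
#'   amplitude, phase and frequency; larger values make classes easier to
#'   separate.
#' @param seed Integer master seed; all template and noise draws derive
#'   deterministically from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_per_class = reference_class_counts(),
                         duration_s = 2,
                         sample_rate = 100,
                         noise_sd = 0.15,
                         class_separation = 1,
                         seed = 1L) {
  n_class <- nrow(gait_classes())
  n_per_class <- as.integer(n_per_class)
  if (length(n_per_class) == 1L) n_per_class <- rep(n_per_class, n_class)
  if (length(n_per_class) != n_class || anyNA(n_per_class)) {
    stop("`n_per_class` must be a single integer or one per class (",
         n_class, ")", call. = FALSE)
  }
  if (any(n_per_class < 2L)) {
    stop("`n_per_class` must be >= 2 (cross-validation impossible otherwise)",
         call. = FALSE)
  }
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("`sample_rate` must be positive", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!is.numeric(class_separation) || class_separation <= 0)
    stop("`class_separation` must be > 0", call. = FALSE)
  # shortest jittered trial must still give T >= 32 samples
  if (floor(0.9 * duration_s * sample_rate) < 32) {
    stop("`duration_s` too short: trials must have at least 32 samples ",
         "after -10% length jitter", call. = FALSE)
  }
  structure(list(
    n_per_class = n_per_class,
    duration_s = duration_s,
    sample_rate = sample_rate,
    noise_sd = noise_sd,
    class_separation = class_separation,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic gait-transition configuration\n")
  cat("  trials per class:", paste(x$n_per_class, collapse = ", "),
      sprintf("(total %d)\n", sum(x$n_per_class)))
  cat(sprintf("  duration %.2f s @ %g Hz (+/-10%% length jitter)\n",
              x$duration_s, x$sample_rate))
  cat(sprintf("  noise sd %.3f, class separation %.2f, seed %d\n",
              x$noise_sd, x$class_separation, x$seed))
  invisible(x)
}

# Per-class, per-channel waveform parameters, drawn once from the master seed
# and frozen so classes are stable across trials. Each channel is a mixture of
# up to 3 sinusoids; every frequency stays strictly below 7 Hz.
class_templates <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    n_class <- nrow(gait_classes())
    channels <- kinematic_channels()
    n_ch <- nrow(channels)
    sep <- cfg$class_separation
    templ <- vector("list", n_class)
    n_harm <- sample(1:3, n_ch, replace = TRUE)
    base_freq <- lapply(n_harm, function(h) stats::runif(h, 0.5, 6.5))
    for (c_id in seq_len(n_class)) {
      per_ch <- vector("list", n_ch)
      for (ch in seq_len(n_ch)) {
        h <- n_harm[ch]
        freq <- pmin(6.99, pmax(0.2,
          base_freq[[ch]] + sep * stats::runif(h, -0.3, 0.3)))
        per_ch[[ch]] <- list(
          freq = freq,
          amp = 1 + sep * stats::runif(h, -0.6, 0.6),
          phase = stats::runif(h, 0, 2 * pi))
      }
      templ[[c_id]] <- per_ch
    }
    templ
  })
}

#' Generate one synthetic gait-transition trial
#'
#' Each of the 22 channels is a class- and channel-specific smooth template
#' (a mixture of at most three sinusoids below 7 Hz under a smooth burst
#' envelope) plus band-limited Gaussian noise. The trial length is the
#' configured duration jittered by +/-10%.
#'
#' @param class_id Gait class id in 1..8.
#' @param cfg A [synth_config()].
#' @param templates Frozen class templates, as returned by the internal
#'   template generator; recomputed from `cfg$seed` when `NULL`.
#' @param seed Optional integer seed for this trial's noise and length
#'   jitter; when `NULL` the current RNG stream is used (the usual case
#'   inside [generate_dataset()]).
#' @return A `trial_recording`: list with `channels` (22 x T matrix, rows
#'   named by channel abbreviation), `sample_rate` and `label`.
#' @export
generate_trial <- function(class_id, cfg, templates = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  class_id <- as.integer(class_id)
  if (length(class_id) != 1L || is.na(class_id) ||
      !(class_id %in% gait_classes()$id)) {
    stop("unknown gait class id: ", class_id, call. = FALSE)
  }
  if (is.null(templates)) templates <- class_templates(cfg)
  body <- function() {
    t0 <- round(cfg$duration_s * cfg$sample_rate)
    len <- max(32L, as.integer(round(t0 * stats::runif(1, 0.9, 1.1))))
    tt <- (seq_len(len) - 1L) / cfg$sample_rate
    # smooth burst envelope: the stride starts and ends near rest, and the
    # taper confines spectral leakage of off-bin template frequencies
    env <- 0.5 * (1 - cos(2 * pi * (seq_len(len) - 1L) / (len - 1L)))
    per_ch <- templates[[class_id]]
    n_ch <- length(per_ch)
    m <- matrix(0, nrow = n_ch, ncol = len)
    for (ch in seq_len(n_ch)) {
      p <- per_ch[[ch]]
      sig <- 0
      for (h in seq_along(p$freq)) {
        sig <- sig + p$amp[h] * sin(2 * pi * p$freq[h] * tt + p$phase[h])
      }
      m[ch, ] <- sig * env
    }
    if (cfg$noise_sd > 0) {
      # band-limited Gaussian noise on exact DFT bins below 7 Hz; each
      # sample is marginally N(0, noise_sd^2), correlated in time exactly
      # as low-pass-filtered white noise would be
      k_max <- floor(7 * len / cfg$sample_rate)
      if (k_max >= 1L) {
        fk <- (1:k_max) * cfg$sample_rate / len
        basis <- rbind(cos(2 * pi * outer(fk, tt)),
                       sin(2 * pi * outer(fk, tt)))
        coef <- matrix(stats::rnorm(n_ch * 2L * k_max,
                                    sd = cfg$noise_sd / sqrt(k_max)),
                       nrow = n_ch)
        m <- m + coef %*% basis
      } else {
        m <- m + matrix(stats::rnorm(length(m), sd = cfg$noise_sd),
                        nrow = n_ch)
      }
    }
    rownames(m) <- kinematic_channels()$abbr
    structure(list(channels = m, sample_rate = cfg$sample_rate,
                   label = class_id),
              class = "trial_recording")
  }
  if (is.null(seed)) body() else with_seed(seed, body())
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("Gait trial: class %d (%s), %d channels x %d samples @ %g Hz\n",
              x$label, gait_classes()$abbr[x$label], nrow(x$channels),
              ncol(x$channels), x$sample_rate))
  invisible(x)
}

#' Generate a full synthetic gait-transition dataset
#'
#' Draws frozen per-class templates from the master seed, then generates
#' `n_per_class` trials for each of the 8 classes. Identical configurations
#' (including seed) yield bit-identical datasets.
#'
#' @param cfg A [synth_config()].
#' @return A `gait_dataset`: list with `trials` (list of `trial_recording`),
#'   `labels` (integer vector aligned with `trials`) and `config`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  templates <- class_templates(cfg)
  with_seed(cfg$seed + 1L, {
    n_class <- nrow(gait_classes())
    trials <- vector("list", sum(cfg$n_per_class))
    labels <- integer(sum(cfg$n_per_class))
    i <- 0L
    for (c_id in seq_len(n_class)) {
      for (j in seq_len(cfg$n_per_class[c_id])) {
        i <- i + 1L
        trials[[i]] <- generate_trial(c_id, cfg, templates = templates)
        labels[i] <- c_id
      }
    }
    structure(list(trials = trials, labels = labels, config = cfg),
              class = "gait_dataset")
  })
}

#' @export
print.gait_dataset <- function(x, ...) {
  cat(sprintf("Synthetic gait-transition dataset: %d trials, %d classes\n",
              length(x$trials), length(unique(x$labels))))
  print(table(factor(x$labels, levels = gait_classes()$id,
                     labels = gait_classes()$abbr)))
  invisible(x)
}
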