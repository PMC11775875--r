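#' Neural response specification for the simulator
#'
#' Ground truth for the steady-state responses the analysis measures.
#' The periodic stimulation is modeled directly through its steady-state
#' outcome: pure sinusoids at the tagged frequencies. Base harmonics sit
#' at multiples of the base rate; oddball harmonics at multiples of the
#' oddball rate, except that multiples coinciding with base harmonics
#' (e.g., the 5th at 6 Hz) are never injected as oddball energy,
#' mirroring the exclusion rule used at analysis time.
#'
#' @param base_harmonic_amps named-by-harmonic-index numeric vector of
#'   peak amplitudes in microvolts, e.g. `c("1" = 1, "2" = 0.6, "3" = 0.2)`.
#' @param oddball_harmonic_amps amplitudes at 100% expression intensity.
#' @param intensity_gain `"linear"` (gain = intensity / 100, the default,
#'   matching a linear intensity trend) or `"sigmoid"`
#'   (logistic in intensity, rescaled so gain(100) = 1), or a function.
#' @param sigmoid_mid,sigmoid_slope parameters of the sigmoid gain.
#' @param base_topo,oddball_topo channel gain in `[0, 1]`: a named numeric
#'   vector, or NULL for the defaults (Gaussian falloff around a medial
#'   occipital peak for the base response, around a right
#'   occipito-temporal peak for the oddball response; see [topo_gaussian()]).
#' @param base_phase,oddball_phase radians.
#' @return object of class `neural_spec`.
#' @export
neural_spec <- function(base_harmonic_amps = c("1" = 1.0, "2" = 0.6, "3" = 0.2),
                        oddball_harmonic_amps = c("1" = 0.25, "2" = 0.15,
                                                  "3" = 0.1, "4" = 0.1,
                                                  "6" = 0.05),
                        intensity_gain = c("linear", "sigmoid"),
                        sigmoid_mid = 50, sigmoid_slope = 0.1,
                        base_topo = NULL, oddball_topo = NULL,
                        base_phase = 0, oddball_phase = 0) {
  stopifnot(all(base_harmonic_amps >= 0), all(oddball_harmonic_amps >= 0))
  if (is.function(intensity_gain)) {
    gain_fun <- intensity_gain
  } else {
    intensity_gain <- match.arg(intensity_gain)
    gain_fun <- if (intensity_gain == "linear") {
      function(i) i / 100
    } else {
      function(i) stats::plogis(sigmoid_slope * (i - sigmoid_mid)) /
        stats::plogis(sigmoid_slope * (100 - sigmoid_mid))
    }
  }
  if (abs(gain_fun(100) - 1) > 1e-9)
    stop("intensity_gain(100) must equal 1")
  structure(list(
    base_harmonic_amps = base_harmonic_amps,
    oddball_harmonic_amps = oddball_harmonic_amps,
    gain_fun = gain_fun,
    base_topo = base_topo, oddball_topo = oddball_topo,
    base_phase = base_phase, oddball_phase = oddball_phase
  ), class = "neural_spec")
}

#' Gaussian scalp topography around a peak electrode
#'
#' Channel gain `exp(-d^2 / (2 sigma^2))` where `d` is the great-circle
#' distance (radians) from the peak electrode on the unit sphere.
#'
#' @param peak electrode label at which gain is 1.
#' @param sigma falloff in radians (default 0.7, about 40 degrees).
#' @param montage from [standard_montage()].
#' @return named numeric vector of gains in `[0, 1]`, EOG channels 0.
#' @export
topo_gaussian <- function(peak, sigma = 0.7, montage = standard_montage()) {
  p <- montage[montage$label == peak, c("x", "y", "z")]
  if (nrow(p) != 1L) stop("peak electrode not in montage: ", peak)
  d <- acos(pmin(1, pmax(-1, as.matrix(montage[, c("x", "y", "z")]) %*%
                           t(as.matrix(p)))))
  g <- exp(-d^2 / (2 * sigma^2))
  g[montage$kind == "eog"] <- 0
  stats::setNames(as.numeric(g), montage$label)
}

#' Background noise and artifact specification
#'
#' @param pink_exponent alpha of the 1/f^alpha amplitude background
#'   (default 1, canonical EEG-like spectrum).
#' @param noise_rms per-channel RMS of the background noise, microvolts.
#' @param blink_rate blinks per minute (Poisson).
#' @param blink_amp blink peak amplitude on the vertical EOG, microvolts.
#' @param seed integer RNG seed; identical specs and seed give identical
#'   recordings.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(pink_exponent = 1, noise_rms = 2,
                       blink_rate = 8, blink_amp = 120, seed = 1L) {
  stopifnot(noise_rms >= 0, blink_rate >= 0, pink_exponent >= 0)
  structure(list(pink_exponent = pink_exponent, noise_rms = noise_rms,
                 blink_rate = blink_rate, blink_amp = blink_amp,
                 seed = as.integer(seed)), class = "noise_spec")
}

# n samples of 1/f^alpha noise, unit RMS, via spectral shaping
pink_noise <- function(n, alpha, fs) {
  freqs <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  half <- seq(2, floor(n / 2) + 1)
  spec <- complex(real = numeric(n), imaginary = numeric(n))
  mag <- freqs[half]^(-alpha / 2)
  z <- complex(real = stats::rnorm(length(half)),
               imaginary = stats::rnorm(length(half))) * mag
  spec[half] <- z
  # enforce conjugate symmetry for a real signal
  mirror <- n - half + 2
  keep <- mirror > floor(n / 2) + 1 & mirror <= n
  spec[mirror[keep]] <- Conj(z[keep])
  if (n %% 2 == 0) spec[n / 2 + 1] <- complex(real = Re(spec[n / 2 + 1]))
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# stereotyped biphasic blink waveform, 400 ms, peak amplitude 1
blink_waveform <- function(fs, dur = 0.4) {
  t <- seq(0, dur, by = 1 / fs)
  w <- sin(2 * pi * t / dur) * sin(pi * t / dur)^2
  w / max(abs(w))
}

# blink propagation gain per channel: strong frontally, zero occipitally
blink_topo <- function(montage) {
  g <- pmax(0, montage$y)^2
  g[montage$kind == "eog"] <- ifelse(
    grepl("^V", montage$label[montage$kind == "eog"]), 1, 0.6)
  stats::setNames(as.numeric(g), montage$label)
}

#' Simulate an FPVS EEG recording with known ground truth
#'
#' Builds the stimulus schedule for `design`, then synthesizes, for each
#' stimulation segment, base-harmonic sinusoids plus intensity-scaled
#' oddball-harmonic sinusoids (excluding oddball multiples that coincide
#' with base harmonics), spatially weighted by the response topographies;
#' adds 1/f background noise and, if requested, Poisson-timed biphasic
#' blinks on frontal/EOG channels. All randomness derives from
#' `noise$seed`.
#'
#' @param design an [fpvs_design()].
#' @param neural a [neural_spec()].
#' @param noise a [noise_spec()].
#' @param montage channel table from [standard_montage()]; must contain
#'   the ROI electrodes and at least one EOG channel.
#' @return list with elements `recording` (an `fpvs_recording` whose
#'   events table is the schedule) and `manifest` (ground truth: the
#'   schedule, per-segment injected amplitudes at 1x topography gain,
#'   topographies, blink times, seed).
#' @export
simulate_recording <- function(design, neural = neural_spec(),
                               noise = noise_spec(),
                               montage = standard_montage()) {
  stopifnot(inherits(design, "fpvs_design"), inherits(neural, "neural_spec"),
            inherits(noise, "noise_spec"))
  if (!any(montage$kind == "eog"))
    stop("montage must include at least one EOG channel")
  set.seed(noise$seed)
  sched <- build_schedule(design, seed = noise$seed)
  fs <- design$sampling_rate
  total_s <- max(sched$onset_s) + 1 / design$base_freq + design$gap_dur
  n <- ceiling(total_s * fs)
  nch <- nrow(montage)
  labels <- montage$label
  base_topo <- neural$base_topo %||% topo_gaussian("Oz", montage = montage)
  odd_topo <- neural$oddball_topo %||% topo_gaussian("PO8", montage = montage)
  base_topo <- base_topo[labels]
  odd_topo <- odd_topo[labels]
  if (any(is.na(base_topo)) || any(is.na(odd_topo)))
    stop("topography must cover every montage channel")
  dat <- matrix(0, nch, n, dimnames = list(labels, NULL))

  f_base <- design$base_freq
  f_odd <- design$oddball_freq
  seg_key <- paste(sched$sequence, sched$segment)
  seg_rows <- !duplicated(seg_key)
  segs <- sched[seg_rows, c("sequence", "segment", "emotion", "identity",
                            "intensity")]
  segs$start_s <- sched$onset_s[seg_rows]
  segs$end_s <- segs$start_s + design$sequence_dur
  odd_idx <- as.integer(names(neural$oddball_harmonic_amps))
  base_idx <- as.integer(names(neural$base_harmonic_amps))
  # oddball multiples coinciding with base harmonics are base-only
  coincide <- (odd_idx %% design$oddball_every) == 0L
  odd_idx_use <- odd_idx[!coincide]
  odd_amp_use <- neural$oddball_harmonic_amps[!coincide]
  inj <- vector("list", nrow(segs))
  for (s in seq_len(nrow(segs))) {
    i0 <- as.integer(round(segs$start_s[s] * fs)) + 1L
    i1 <- min(n, as.integer(round(segs$end_s[s] * fs)))
    t <- (seq(i0, i1) - i0) / fs
    gain <- neural$gain_fun(segs$intensity[s])
    wave_b <- rep(0, length(t)); wave_o <- rep(0, length(t))
    for (k in seq_along(base_idx))
      wave_b <- wave_b + neural$base_harmonic_amps[k] *
        sin(2 * pi * base_idx[k] * f_base * t + neural$base_phase)
    for (k in seq_along(odd_idx_use))
      wave_o <- wave_o + gain * odd_amp_use[k] *
        sin(2 * pi * odd_idx_use[k] * f_odd * t + neural$oddball_phase)
    dat[, i0:i1] <- dat[, i0:i1] + outer(base_topo, wave_b) +
      outer(odd_topo, wave_o)
    inj[[s]] <- list(
      base_amps = neural$base_harmonic_amps,
      base_freqs = base_idx * f_base,
      oddball_amps = gain * odd_amp_use,
      oddball_freqs = odd_idx_use * f_odd,
      intensity = segs$intensity[s], emotion = segs$emotion[s])
  }

  if (noise$noise_rms > 0)
    for (i in seq_len(nch))
      dat[i, ] <- dat[i, ] + noise$noise_rms *
        pink_noise(n, noise$pink_exponent, fs)

  blink_times <- numeric(0)
  if (noise$blink_rate > 0 && noise$blink_amp > 0) {
    n_blinks <- stats::rpois(1, noise$blink_rate * total_s / 60)
    if (n_blinks > 0) {
      blink_times <- sort(stats::runif(n_blinks, 0, total_s - 0.5))
      w <- blink_waveform(fs)
      bt <- blink_topo(montage)[labels]
      for (b in blink_times) {
        i0 <- as.integer(round(b * fs)) + 1L
        idx <- i0:(i0 + length(w) - 1L)
        idx <- idx[idx <= n]
        dat[, idx] <- dat[, idx] +
          noise$blink_amp * outer(bt, w[seq_along(idx)])
      }
    }
  }

  rec <- recording(dat, fs, labels, montage$kind, events = sched,
                   reference = "Cz", montage = montage)
  manifest <- list(
    design = design, schedule = sched, segments = segs, injected = inj,
    base_topography = base_topo, oddball_topography = odd_topo,
    blink_times = blink_times, seed = noise$seed)
  list(recording = rec, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate an explicit emotion-recognition task block
#'
#' One block per emotion: `trials_per_intensity` expressive trials per
#' intensity step plus `neutral_trials` neutral trials, in shuffled
#' order. Expressive-trial accuracy follows the design's psychometric
#' function ([ert_psychometric()]); neutral-trial accuracy is
#' `p_correct_neutral`. Reaction times are Gaussian around a linearly
#' intensity-dependent mean, truncated below at 150 ms; draws exceeding
#' `max_rt` are timeouts (no response, incorrect).
#'
#' @param design an [ert_design()].
#' @param emotions emotions to run blocks for.
#' @param seed integer seed.
#' @return data.frame: `emotion`, `trial`, `trial_type`
#'   (`"neutral"`/`"expressive"`), `intensity` (percent, 0 for neutral),
#'   `response` (`"neutral"`/`"expressive"`/`"none"`), `correct`
#'   (logical), `rt_s` (NA on timeout), `timeout`.
#' @export
simulate_ert <- function(design = ert_design(),
                         emotions = c("happy", "angry"), seed = 1L) {
  stopifnot(inherits(design, "ert_design"))
  set.seed(seed)
  blocks <- lapply(emotions, function(em) {
    intens <- c(rep(design$intensities, each = design$trials_per_intensity),
                rep(0, design$neutral_trials))
    type <- ifelse(intens > 0, "expressive", "neutral")
    ord <- sample.int(length(intens))
    intens <- intens[ord]; type <- type[ord]
    p_corr <- ifelse(type == "expressive",
                     ert_psychometric(design, intens),
                     design$p_correct_neutral)
    correct <- stats::runif(length(intens)) < p_corr
    response <- ifelse(xor(correct, type == "neutral"),
                       "expressive", "neutral")
    rt <- design$rt_base - design$rt_slope * intens / 100 +
      stats::rnorm(length(intens), 0, design$rt_sd)
    rt <- pmax(rt, 0.15)
    timeout <- rt > design$max_rt
    correct[timeout] <- FALSE
    response[timeout] <- "none"
    rt[timeout] <- NA_real_
    data.frame(emotion = em, trial = seq_along(intens), trial_type = type,
               intensity = intens, response = response, correct = correct,
               rt_s = rt, timeout = timeout, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
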