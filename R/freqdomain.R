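#' Crop a recording to a cycle-locked epoch at the first oddball
#'
#' The analysis epoch starts exactly at the onset sample of the first
#' expressive (oddball) stimulus and must contain an integer number of
#' oddball cycles so that all tag frequencies fall on exact FFT bins.
#'
#' @param rec an `fpvs_recording` whose events contain `"oddball"` rows.
#' @param duration_s epoch length in seconds; `duration_s * oddball_freq`
#'   must be an integer and `duration_s * sampling_rate` a whole number
#'   of samples.
#' @param oddball_freq oddball rate in Hz (for the cycle-lock check).
#' @param sequence,segment optionally restrict the event search to one
#'   stimulation sequence / intensity segment.
#' @return an `fpvs_recording` of exactly `duration_s * fs` samples; its
#'   `n_cycles` attribute records the number of oddball cycles.
#' @export
crop_to_cycles <- function(rec, duration_s, oddball_freq = 1.2,
                           sequence = NULL, segment = NULL) {
  stopifnot(inherits(rec, "fpvs_recording"))
  ev <- rec$events
  sel <- ev$label == "oddball"
  if (!is.null(sequence) && "sequence" %in% names(ev))
    sel <- sel & ev$sequence == sequence
  if (!is.null(segment) && "segment" %in% names(ev))
    sel <- sel & ev$segment == segment
  if (!any(sel)) stop("no oddball event found")
  onset <- min(ev$onset_s[sel])
  n_cyc <- duration_s * oddball_freq
  if (abs(n_cyc - round(n_cyc)) > 1e-9)
    stop("epoch is not cycle-locked: ", duration_s, " s x ", oddball_freq,
         " Hz = ", n_cyc, " cycles")
  fs <- rec$sampling_rate
  n_want <- duration_s * fs
  if (abs(n_want - round(n_want)) > 1e-6)
    stop("duration does not correspond to a whole number of samples")
  n_want <- as.integer(round(n_want))
  i0 <- sample_at(rec, onset)
  if (i0 + n_want - 1L > n_samples(rec))
    stop("insufficient samples after first oddball onset: need ", n_want,
         ", have ", n_samples(rec) - i0 + 1L)
  out <- rec
  out$data <- rec$data[, i0:(i0 + n_want - 1L), drop = FALSE]
  keep <- ev$onset_s >= onset & ev$onset_s < onset + duration_s
  out$events <- ev[keep, , drop = FALSE]
  out$events$onset_s <- out$events$onset_s - onset
  attr(out, "n_cycles") <- as.integer(round(n_cyc))
  attr(out, "epoch_onset_s") <- onset
  out
}

#' Single-sided amplitude spectrum of an epoch
#'
#' FFT with rectangular window and no zero padding (legitimate because
#' epochs are cycle-locked, so all tag frequencies fall on exact bins).
#' Normalization is such that a sinusoid of peak amplitude A at an exact
#' bin yields amplitude A.
#'
#' @param epoch an `fpvs_recording` (typically from [crop_to_cycles()])
#'   or a channels x samples matrix with a `sampling_rate` argument.
#' @param sampling_rate required if `epoch` is a bare matrix.
#' @return object of class `fpvs_spectrum`: `freqs` (Hz, 0..Nyquist),
#'   `amps` (channels x bins, microvolts), `resolution` (Hz),
#'   `duration` (s), `channel_labels`.
#' @export
amplitude_spectrum <- function(epoch, sampling_rate = NULL) {
  if (inherits(epoch, "fpvs_recording")) {
    dat <- epoch$data
    fs <- epoch$sampling_rate
    labels <- epoch$channel_labels
  } else {
    dat <- as.matrix(epoch)
    fs <- sampling_rate
    if (is.null(fs)) stop("sampling_rate required for matrix input")
    labels <- rownames(dat) %||% paste0("ch", seq_len(nrow(dat)))
  }
  n <- ncol(dat)
  if (n < 2L) stop("epoch must have at least 2 samples")
  X <- stats::mvfft(t(dat))                 # bins x channels
  nb <- floor(n / 2) + 1L
  amp <- Mod(X[seq_len(nb), , drop = FALSE]) / n
  amp[2:nb, ] <- 2 * amp[2:nb, , drop = FALSE]
  if (n %% 2 == 0) amp[nb, ] <- amp[nb, ] / 2   # Nyquist bin is unique
  structure(list(
    freqs = (seq_len(nb) - 1) * fs / n,
    amps = t(amp),
    resolution = fs / n,
    duration = n / fs,
    channel_labels = labels
  ), class = "fpvs_spectrum")
}

#' @export
print.fpvs_spectrum <- function(x, ...) {
  cat(sprintf("<fpvs_spectrum> %d channels x %d bins, resolution %g Hz\n",
              nrow(x$amps), ncol(x$amps), x$resolution))
  invisible(x)
}

# index of the bin at freq; errors if freq is not an exact bin
bin_index <- function(spectrum, freq, tol = 1e-6) {
  i <- round(freq / spectrum$resolution) + 1
  if (abs(spectrum$freqs[i] - freq) > tol)
    stop("frequency ", freq, " Hz is not on an exact bin (resolution ",
         spectrum$resolution, " Hz)")
  as.integer(i)
}

#' Harmonic frequency sets for base and oddball responses
#'
#' The oddball set is the first `n` multiples of the oddball rate that
#' are not multiples of the base rate (so for 1.2/6 Hz and n = 5:
#' 1.2, 2.4, 3.6, 4.8, 7.2 Hz, skipping 6 Hz); the base set is the first
#' `n` multiples of the base rate (6, 12, 18 Hz for n = 3).
#'
#' @param kind `"base"` or `"oddball"`.
#' @param n number of harmonics in the set.
#' @param base_f,oddball_f rates in Hz; `base_f` must be an integer
#'   multiple of `oddball_f`.
#' @return numeric vector of frequencies in Hz.
#' @export
harmonic_set <- function(kind = c("base", "oddball"), n = if (kind == "base") 3L else 5L,
                         base_f = 6, oddball_f = 1.2) {
  kind <- match.arg(kind)
  ratio <- base_f / oddball_f
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("base_f must be a multiple of oddball_f")
  if (kind == "base") return(base_f * seq_len(n))
  k <- seq_len(ceiling(n * ratio / (ratio - 1)) + round(ratio))
  f <- oddball_f * k[k %% round(ratio) != 0]
  f[seq_len(n)]
}

#' Noise-window bookkeeping parameters
#'
#' The noise at a target bin is estimated from the surrounding bins:
#' `n_side` bins on each side after skipping `skip_adjacent` immediately
#' neighboring bins per side; among those candidates the
#' `drop_extremes` most extreme amplitudes (split between the largest
#' and smallest) are excluded before taking mean and SD (SD with the
#' n - 1 denominator). Defaults follow the FPVS convention: 10 bins per
#' side for long (40 s) sequences, 5 per side (`n_side = 5`) for short
#' ones.
#'
#' @param n_side candidate bins on each side.
#' @param skip_adjacent bins skipped immediately next to the target.
#' @param drop_extremes total number of extreme values excluded.
#' @return list of class `noise_params`.
#' @export
noise_params <- function(n_side = 10L, skip_adjacent = 1L, drop_extremes = 2L) {
  stopifnot(n_side >= 1, skip_adjacent >= 0, drop_extremes >= 0,
            drop_extremes < 2 * n_side)
  structure(list(n_side = as.integer(n_side),
                 skip_adjacent = as.integer(skip_adjacent),
                 drop_extremes = as.integer(drop_extremes)),
            class = "noise_params")
}

# offsets of candidate noise bins relative to the target bin
noise_offsets <- function(params) {
  o <- (params$skip_adjacent + 1L):(params$skip_adjacent + params$n_side)
  c(-rev(o), o)
}

# mean/sd of candidate amplitudes after dropping extremes
noise_stats <- function(cand) {
  n_hi <- ceiling(attr(cand, "drop") / 2)
  n_lo <- attr(cand, "drop") - n_hi
  ord <- order(cand)
  keep <- ord
  if (n_lo > 0) keep <- setdiff(keep, ord[seq_len(n_lo)])
  if (n_hi > 0) keep <- setdiff(keep, rev(ord)[seq_len(n_hi)])
  used <- cand[sort(keep)]
  list(mean = mean(used), sd = stats::sd(used), used = used,
       kept_index = sort(keep))
}

#' Estimate the noise distribution around a target frequency bin
#'
#' @param spectrum an `fpvs_spectrum`.
#' @param target_freq target frequency (must be an exact bin).
#' @param params a [noise_params()].
#' @param channel channel label, or `"mean"` for the cross-channel mean
#'   spectrum; defaults to the only channel if there is just one.
#' @return list: `mean`, `sd` (microvolts), `used_bins` (bin indices
#'   used), `offsets` (candidate offsets), `amps` (used amplitudes).
#' @export
estimate_noise <- function(spectrum, target_freq, params = noise_params(),
                           channel = NULL) {
  a <- channel_amps(spectrum, channel)
  i <- bin_index(spectrum, target_freq)
  off <- noise_offsets(params)
  idx <- i + off
  if (any(idx < 1L) || any(idx > length(a)))
    stop("target bin too close to the spectrum edge for the noise window")
  cand <- a[idx]
  attr(cand, "drop") <- params$drop_extremes
  st <- noise_stats(cand)
  list(mean = st$mean, sd = st$sd,
       used_bins = idx[st$kept_index], offsets = off, amps = st$used)
}

channel_amps <- function(spectrum, channel = NULL) {
  if (is.null(channel)) {
    if (nrow(spectrum$amps) != 1L)
      stop("specify a channel (or \"mean\") for a multichannel spectrum")
    return(spectrum$amps[1, ])
  }
  if (identical(channel, "mean")) return(colMeans(spectrum$amps))
  match_ch <- function(ch) {
    j <- match(ch, spectrum$channel_labels)
    j[is.na(j)] <- match(normalize_channel_labels(ch[is.na(j)]),
                         spectrum$channel_labels)
    if (anyNA(j)) stop("no such channel: ",
                       paste(ch[is.na(j)], collapse = ", "))
    j
  }
  if (length(channel) > 1L)
    return(colMeans(spectrum$amps[match_ch(channel), , drop = FALSE]))
  spectrum$amps[match_ch(channel), ]
}

#' Score a target frequency bin: Z, BCA and SNR
#'
#' With `x` the amplitude at the target bin and the noise mean/SD taken
#' from the surrounding-bin window: `z = (x - mean) / sd`,
#' `bca = x - mean`, `snr = x / mean`. A zero noise SD (z) or zero noise
#' mean (snr) yields `NA` with a `flag`.
#'
#' @param spectrum an `fpvs_spectrum`.
#' @param target_freq frequency on an exact bin.
#' @param params a [noise_params()].
#' @param channel channel label / `"mean"` / vector of labels (averaged).
#' @return one-row data.frame: `freq`, `amp`, `noise_mean`, `noise_sd`,
#'   `z`, `bca`, `snr`, `flag`.
#' @export
score_bin <- function(spectrum, target_freq, params = noise_params(),
                      channel = NULL) {
  a <- channel_amps(spectrum, channel)
  i <- bin_index(spectrum, target_freq)
  nw <- estimate_noise(spectrum, target_freq, params, channel)
  x <- a[i]
  flag <- ""
  z <- if (nw$sd > 0) (x - nw$mean) / nw$sd else { flag <- "sd0"; NA_real_ }
  snr <- if (nw$mean > 0) x / nw$mean else { flag <- paste0(flag, "mean0"); NA_real_ }
  data.frame(freq = target_freq, amp = x, noise_mean = nw$mean,
             noise_sd = nw$sd, z = z, bca = x - nw$mean, snr = snr,
             flag = flag, stringsAsFactors = FALSE)
}

#' Summed response over a harmonic set
#'
#' `summed_bca` is the sum of the per-harmonic baseline-corrected
#' amplitudes. The significance of the summed response (`summed_z`) is
#' computed on the aggregate itself: for every candidate noise offset,
#' amplitudes at that offset from each harmonic are summed position-wise,
#' the extreme sums are dropped with the same rule as for single bins,
#' and the summed target amplitude is z-scored against the mean/SD of
#' the remaining summed noise values. The mean per-harmonic z is also
#' reported.
#'
#' @param spectrum an `fpvs_spectrum`.
#' @param harmonic_freqs frequencies (exact bins), e.g. [harmonic_set()].
#' @param params a [noise_params()].
#' @param channel channel label / `"mean"` / vector of labels (averaged).
#' @return list of class `fpvs_summed`: `summed_bca`, `summed_z`,
#'   `summed_snr`, `mean_harmonic_z`, `per_harmonic` (data.frame from
#'   [score_bin()]), `harmonic_freqs`.
#' @export
summed_response <- function(spectrum, harmonic_freqs,
                            params = noise_params(), channel = NULL) {
  a <- channel_amps(spectrum, channel)
  idx <- vapply(harmonic_freqs, function(f) bin_index(spectrum, f),
                integer(1))
  off <- noise_offsets(params)
  if (length(idx) > 1L && min(diff(sort(idx))) <= 2L * max(off))
    warning("noise windows of neighboring harmonics overlap")
  per <- do.call(rbind, lapply(harmonic_freqs, function(f)
    score_bin(spectrum, f, params, channel)))
  sums <- vapply(off, function(o) sum(a[idx + o]), numeric(1))
  attr(sums, "drop") <- params$drop_extremes
  st <- noise_stats(sums)
  target_sum <- sum(a[idx])
  structure(list(
    summed_bca = sum(per$bca),
    summed_z = if (st$sd > 0) (target_sum - st$mean) / st$sd else NA_real_,
    summed_snr = if (st$mean > 0) target_sum / st$mean else NA_real_,
    mean_harmonic_z = mean(per$z),
    per_harmonic = per,
    harmonic_freqs = harmonic_freqs,
    target_sum = target_sum,
    noise_sum_mean = st$mean, noise_sum_sd = st$sd
  ), class = "fpvs_summed")
}

#' Grand-average amplitude spectrum
#'
#' Averages amplitude spectra (same binning) across epochs, conditions
#' and participants, per channel, in the order given.
#'
#' @param spectra list of `fpvs_spectrum` with identical freqs/channels.
#' @return an `fpvs_spectrum`.
#' @export
grand_average_spectrum <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  f0 <- spectra[[1]]$freqs
  for (s in spectra[-1])
    if (length(s$freqs) != length(f0) || max(abs(s$freqs - f0)) > 1e-9)
      stop("spectra have mismatched frequency bins")
  out <- spectra[[1]]
  out$amps <- Reduce(`+`, lapply(spectra, `[[`, "amps")) / length(spectra)
  out
}

#' Determine the harmonics to analyze from group-level data
#'
#' Walks consecutive harmonics of the requested kind on a grand-average
#' spectrum and keeps them while their z-score exceeds `z_crit`
#' (one-sided 5% criterion, 1.64), stopping at the first non-significant
#' harmonic. For the gradual-intensity task the z criterion is bypassed
#' (`mode = "reuse"`): the response is expected to be near-absent at low
#' intensity, so the harmonic sets from the maximal-intensity task are
#' reused verbatim.
#'
#' @param ga an `fpvs_spectrum` grand average.
#' @param kind `"base"` or `"oddball"`.
#' @param z_crit significance criterion.
#' @param params a [noise_params()].
#' @param channel channel / `"mean"` / labels (averaged).
#' @param base_f,oddball_f stimulation rates.
#' @param max_harmonics upper bound on harmonics examined.
#' @param mode `"zscore"` (default) or `"reuse"` (return the stock
#'   max-int sets: first 5 non-base oddball multiples / first 3 base
#'   multiples).
#' @param reuse_n set sizes used when `mode = "reuse"`.
#' @return numeric vector of harmonic frequencies (possibly empty).
#' @export
group_significant_harmonics <- function(ga, kind = c("base", "oddball"),
                                        z_crit = 1.64,
                                        params = noise_params(),
                                        channel = "mean",
                                        base_f = 6, oddball_f = 1.2,
                                        max_harmonics = 12L,
                                        mode = c("zscore", "reuse"),
                                        reuse_n = c(base = 3L, oddball = 5L)) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  if (mode == "reuse")
    return(harmonic_set(kind, n = reuse_n[[kind]], base_f = base_f,
                        oddball_f = oddball_f))
  cands <- harmonic_set(kind, n = max_harmonics, base_f = base_f,
                        oddball_f = oddball_f)
  cands <- cands[cands <= max(ga$freqs) -
                   (params$n_side + params$skip_adjacent) * ga$resolution]
  keep <- numeric(0)
  for (f in cands) {
    z <- score_bin(ga, f, params, channel)$z
    if (is.na(z) || z <= z_crit) break
    keep <- c(keep, f)
  }
  keep
}

#' Individual intensity threshold from per-intensity summed responses
#'
#' Given one participant's summed-response z-scores per intensity step
#' (optionally per emotion and per channel), averages z across emotions,
#' takes at every intensity the channel with the largest z, and returns
#' the lowest intensity whose z exceeds the criterion (NA if none does).
#'
#' @param df data.frame with columns `intensity`, `z`, optionally
#'   `emotion` (averaged out) and `channel`.
#' @param z_crit significance criterion (one-sided 5%: 1.64).
#' @param intensities the expected intensity steps; all must be present.
#' @return list of class `fpvs_threshold`: `threshold` (percent or NA),
#'   `profile` (data.frame intensity, z, channel).
#' @export
individual_threshold <- function(df, z_crit = 1.64,
                                 intensities = c(20, 40, 60, 80, 100)) {
  stopifnot(all(c("intensity", "z") %in% names(df)))
  missing <- setdiff(intensities, unique(df$intensity))
  if (length(missing))
    stop("missing intensity steps: ", paste(missing, collapse = ", "))
  if (!"channel" %in% names(df)) df$channel <- NA_character_
  if ("emotion" %in% names(df)) {
    agg <- stats::aggregate(z ~ intensity + channel, data = df, FUN = mean)
  } else {
    agg <- df[, c("intensity", "channel", "z")]
  }
  prof <- do.call(rbind, lapply(intensities, function(i) {
    sub <- agg[agg$intensity == i, , drop = FALSE]
    best <- which.max(sub$z)
    data.frame(intensity = i, z = sub$z[best], channel = sub$channel[best],
               stringsAsFactors = FALSE)
  }))
  sig <- prof$intensity[prof$z > z_crit]
  structure(list(threshold = if (length(sig)) min(sig) else NA_real_,
                 profile = prof, z_crit = z_crit),
            class = "fpvs_threshold")
}

#' Cycle-locked spectra for every stimulation segment of a recording
#'
#' For each (sequence, intensity-step) segment: crops at the onset of the
#' segment's first expressive face, keeps the largest number of complete
#' oddball cycles that both fit inside the segment and correspond to a
#' whole number of samples (so all tag frequencies are exact bins), and
#' computes the amplitude spectrum. With a 500 Hz sampling rate and a
#' 1.2 Hz oddball this means cycle counts in multiples of 3.
#'
#' @param rec an `fpvs_recording` whose events carry `sequence`,
#'   `segment`, `intensity`, `emotion` columns (as from
#'   [simulate_recording()]).
#' @param design the matching [fpvs_design()].
#' @return data.frame-ish list: one element per segment with `spectrum`,
#'   `emotion`, `intensity`, `sequence`, `segment`, `n_cycles`,
#'   `duration`.
#' @export
segment_spectra <- function(rec, design) {
  ev <- rec$events
  key <- paste(ev$sequence, ev$segment)
  segs <- unique(key)
  f_odd <- design$oddball_freq
  fs <- rec$sampling_rate
  out <- vector("list", length(segs))
  for (s in seq_along(segs)) {
    rows <- ev[key == segs[s], , drop = FALSE]
    onset1 <- min(rows$onset_s[rows$label == "oddball"])
    seg_start <- min(rows$onset_s)
    avail <- design$sequence_dur - (onset1 - seg_start)
    n_cyc <- floor(avail * f_odd + 1e-9)
    # shrink until the epoch is a whole number of samples
    while (n_cyc > 0 &&
           abs(n_cyc / f_odd * fs - round(n_cyc / f_odd * fs)) > 1e-6)
      n_cyc <- n_cyc - 1L
    if (n_cyc < 1) stop("segment too short for one oddball cycle")
    dur <- n_cyc / f_odd
    ep <- crop_to_cycles(rec, dur, f_odd,
                         sequence = rows$sequence[1],
                         segment = rows$segment[1])
    out[[s]] <- list(spectrum = amplitude_spectrum(ep),
                     emotion = rows$emotion[1],
                     intensity = rows$intensity[1],
                     sequence = rows$sequence[1],
                     segment = rows$segment[1],
                     n_cycles = n_cyc, duration = dur)
  }
  out
}

#' Summed-response results table for a recording
#'
#' Convenience wrapper: computes segment spectra, then per segment and
#' ROI the summed oddball and base responses, returning a long-format
#' table of `summed_bca` / `summed_z` / `summed_snr` values.
#'
#' @param rec,design as in [segment_spectra()].
#' @param params a [noise_params()]; by default 10 bins per side for
#'   long (> 30 s) sequences and 5 per side for short ones, following
#'   the convention for short stimulation sequences.
#' @param rois a [roi_set()] (set `NULL` to score single channels of
#'   `channels`).
#' @param channels channel labels scored individually when `rois` is
#'   NULL.
#' @param participant id attached to rows.
#' @return data.frame: participant, task, emotion, intensity, roi,
#'   kind, measure, value.
#' @export
quantify_recording <- function(rec, design, params = NULL,
                               rois = roi_set(), channels = NULL,
                               participant = "p1") {
  if (is.null(params))
    params <- noise_params(if (design$sequence_dur > 30) 10L else 5L)
  specs <- segment_spectra(rec, design)
  locs <- if (!is.null(rois)) {
    stats::setNames(lapply(names(rois), function(n) rois[[n]]), names(rois))
  } else {
    stats::setNames(as.list(channels), channels)
  }
  rows <- list()
  for (sp in specs) {
    for (loc in names(locs)) {
      for (kind in c("base", "oddball")) {
        hs <- harmonic_set(kind, base_f = design$base_freq,
                           oddball_f = design$oddball_freq)
        sr <- summed_response(sp$spectrum, hs, params, locs[[loc]])
        rows[[length(rows) + 1]] <- data.frame(
          participant = participant, task = design$task,
          emotion = sp$emotion, intensity = sp$intensity,
          sequence = sp$sequence, roi = loc, kind = kind,
          summed_bca = sr$summed_bca, summed_z = sr$summed_z,
          summed_snr = sr$summed_snr, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
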