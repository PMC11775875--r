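#' FFT notch filter at the base frequency and its harmonics
#'
#' Removes the general visual response so that the time-domain signal
#' reflects only expression-change-specific activity: the whole-recording
#' spectrum is computed per channel, bins within `bw_bins` of each base
#' harmonic (6, 12, ..., up to `up_to_hz`) are zeroed (both spectral
#' halves), and the signal is inverse-transformed. Exact at the tag
#' frequencies because the notch acts directly on FFT bins.
#'
#' @param rec an `fpvs_recording`.
#' @param base_f base rate in Hz.
#' @param up_to_hz notch harmonics up to this frequency.
#' @param bw_bins bins zeroed on each side of every harmonic bin.
#' @return notch-filtered recording.
#' @export
notch_base <- function(rec, base_f = 6, up_to_hz = 30, bw_bins = 1L) {
  stopifnot(inherits(rec, "fpvs_recording"))
  n <- n_samples(rec)
  fs <- rec$sampling_rate
  if (n < fs / base_f) stop("recording shorter than one base cycle")
  harm <- seq(base_f, up_to_hz, by = base_f)
  X <- stats::mvfft(t(rec$data))
  res <- fs / n
  for (f in harm) {
    i <- round(f / res)             # 0-based bin of the positive frequency
    idx <- (i - bw_bins):(i + bw_bins)
    idx <- idx[idx >= 1 & idx <= n - 1]
    X[idx + 1L, ] <- 0
    X[n - idx + 1L, ] <- 0          # conjugate half
  }
  rec$data <- t(Re(stats::mvfft(X, inverse = TRUE))) / n
  rec_log(rec, sprintf("FFT notch at %s Hz (+/-%d bins)",
                       paste(harm, collapse = ","), bw_bins))
}

#' ERP component definitions for the oddball response
#'
#' The triphasic expression-change response: C1 (positive, 120-200 ms),
#' C2 (negative, 220-300 ms), C3 (positive, 350-450 ms) after expression
#' change onset. Peaks are quantified as the mean amplitude in a window
#' of `2 * peak_halfwidth` around the component peak.
#'
#' @param peak_halfwidth half-width of the mean-amplitude window, ms.
#' @return data.frame `name`, `t_min`, `t_max` (ms), `polarity`,
#'   `peak_halfwidth`.
#' @export
component_specs <- function(peak_halfwidth = 10) {
  data.frame(
    name = c("C1", "C2", "C3"),
    t_min = c(120, 220, 350), t_max = c(200, 300, 450),
    polarity = c("positive", "negative", "positive"),
    peak_halfwidth = peak_halfwidth,
    stringsAsFactors = FALSE)
}

#' Epoch a recording around oddball events
#'
#' Segments `[-167, +667]` ms around every oddball onset (one base cycle
#' of pre-stimulus baseline) and subtracts the per-channel mean of the
#' baseline window. At 500 Hz the window is realized as 84 samples
#' before the onset sample, the onset sample, and 332 samples after it
#' (417 samples in total); generally `round(0.167 * fs)` pre and
#' `round(0.667 * fs) - 1` post plus the onset sample.
#'
#' @param rec an `fpvs_recording` with `"oddball"` events.
#' @param t_pre,t_post window bounds in seconds (positive numbers).
#' @param events optional replacement event table.
#' @return list of class `fpvs_epochs`: `data` (epochs x channels x
#'   samples array), `times` (s, 0 = onset), `channel_labels`,
#'   `channel_kinds`, `meta` (per-epoch event rows), `rejected` (logical),
#'   `reject_reason`, `n_dropped_bounds`.
#' @export
epoch_oddballs <- function(rec, t_pre = 0.167, t_post = 0.667,
                           events = NULL) {
  stopifnot(inherits(rec, "fpvs_recording"))
  ev <- events %||% rec$events
  ev <- ev[ev$label == "oddball", , drop = FALSE]
  if (nrow(ev) == 0L) stop("no oddball events to epoch")
  fs <- rec$sampling_rate
  n_pre <- as.integer(round(t_pre * fs))
  # half-sample windows round down so that 667 ms at 500 Hz gives 332
  # samples after the onset sample (417-sample epochs)
  n_post <- as.integer(ceiling(t_post * fs - 0.5)) - 1L
  times <- seq(-n_pre, n_post) / fs
  n_len <- length(times)
  keep <- logical(nrow(ev))
  epochs <- list()
  for (e in seq_len(nrow(ev))) {
    i0 <- sample_at(rec, ev$onset_s[e])
    lo <- i0 - n_pre; hi <- i0 + n_post
    if (lo < 1L || hi > n_samples(rec)) next
    keep[e] <- TRUE
    seg <- rec$data[, lo:hi, drop = FALSE]
    bl <- rowMeans(seg[, times < 0, drop = FALSE])
    epochs[[length(epochs) + 1]] <- sweep(seg, 1, bl)
  }
  if (!length(epochs)) stop("all epochs fell outside the recording")
  arr <- array(0, c(length(epochs), nrow(rec$data), n_len))
  for (e in seq_along(epochs)) arr[e, , ] <- epochs[[e]]
  structure(list(
    data = arr, times = times,
    channel_labels = rec$channel_labels,
    channel_kinds = rec$channel_kinds,
    meta = ev[keep, , drop = FALSE],
    rejected = rep(FALSE, length(epochs)),
    reject_reason = rep("", length(epochs)),
    n_dropped_bounds = sum(!keep)
  ), class = "fpvs_epochs")
}

#' @export
print.fpvs_epochs <- function(x, ...) {
  cat(sprintf("<fpvs_epochs> %d epochs (%d rejected) x %d channels x %d samples\n",
              dim(x$data)[1], sum(x$rejected), dim(x$data)[2],
              dim(x$data)[3]))
  invisible(x)
}

#' Reject epochs exceeding an absolute voltage threshold
#'
#' An epoch is rejected iff any sample on any analysis channel exceeds
#' the threshold in absolute value (strictly greater; an epoch peaking
#' exactly at the threshold is retained). Deterministic.
#'
#' @param epochs an `fpvs_epochs`.
#' @param threshold microvolts (default 100).
#' @param channels labels inspected; default all EEG channels.
#' @return `epochs` with updated `rejected` flags and reasons.
#' @export
reject_epochs <- function(epochs, threshold = 100, channels = NULL) {
  stopifnot(inherits(epochs, "fpvs_epochs"))
  idx <- if (is.null(channels)) which(epochs$channel_kinds == "eeg")
         else match(normalize_channel_labels(channels), epochs$channel_labels)
  if (anyNA(idx)) stop("unknown analysis channels")
  for (e in seq_len(dim(epochs$data)[1])) {
    mx <- max(abs(epochs$data[e, idx, ]))
    if (mx > threshold) {
      epochs$rejected[e] <- TRUE
      epochs$reject_reason[e] <- sprintf("amplitude %.1f uV > %g", mx,
                                         threshold)
    }
  }
  if (all(epochs$rejected))
    stop("all epochs rejected at +/-", threshold,
         " uV; max amplitudes range ",
         paste(range(apply(abs(epochs$data[, idx, , drop = FALSE]),
                           1, max)), collapse = "-"))
  epochs
}

#' Average retained epochs into an ERP
#'
#' @param epochs an `fpvs_epochs`.
#' @param channels channels averaged over (e.g. an ROI); default all EEG.
#' @param which optional logical/integer subset of epochs (on top of
#'   rejection flags).
#' @return numeric vector (microvolts) over `epochs$times`.
#' @export
average_erp <- function(epochs, channels = NULL, which = NULL) {
  keep <- !epochs$rejected
  if (!is.null(which)) {
    w <- rep(FALSE, length(keep)); w[which] <- TRUE
    keep <- keep & w
  }
  if (!any(keep)) stop("no retained epochs to average")
  idx <- if (is.null(channels)) which(epochs$channel_kinds == "eeg")
         else match(normalize_channel_labels(channels), epochs$channel_labels)
  m <- apply(epochs$data[keep, idx, , drop = FALSE], 3,
             function(s) mean(s))
  as.numeric(m)
}

#' Quantify ERP component amplitudes from an averaged waveform
#'
#' For each component: find the extremum of the specified polarity
#' inside the component's window (earliest sample on exact ties); the
#' amplitude is the mean over peak +/- `peak_halfwidth`. If the window
#' contains no extremum of the required polarity (the waveform does not
#' cross zero in the right direction), the window extremum is used and
#' the component is flagged.
#'
#' @param erp numeric waveform (from [average_erp()]).
#' @param times time vector in seconds, aligned with `erp`.
#' @param specs component table from [component_specs()].
#' @return data.frame: `component`, `peak_latency_ms`, `mean_amp`,
#'   `flag`.
#' @export
component_amplitudes <- function(erp, times, specs = component_specs()) {
  stopifnot(length(erp) == length(times))
  out <- lapply(seq_len(nrow(specs)), function(i) {
    w <- which(times * 1000 >= specs$t_min[i] & times * 1000 <= specs$t_max[i])
    if (!length(w)) stop("component window outside the epoch: ",
                         specs$name[i])
    seg <- erp[w]
    pos <- specs$polarity[i] == "positive"
    flag <- ""
    if ((pos && max(seg) <= 0) || (!pos && min(seg) >= 0)) {
      flag <- "no-peak"
    }
    pk <- if (pos) w[which.max(seg)] else w[which.min(seg)]
    hw <- specs$peak_halfwidth[i] / 1000
    win <- which(times >= times[pk] - hw & times <= times[pk] + hw)
    data.frame(component = specs$name[i],
               peak_latency_ms = times[pk] * 1000,
               mean_amp = mean(erp[win]), flag = flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Time-domain analysis pipeline for one recording
#'
#' Notch the base rate and its harmonics, low-pass at 30 Hz, epoch
#' around oddballs, reject epochs over +/-100 microvolts, average per
#' condition and ROI, and quantify C1-C3.
#'
#' @param rec a preprocessed `fpvs_recording`.
#' @param rois a [roi_set()]; the medial cluster can be dropped via
#'   `use_rois`.
#' @param use_rois names of clusters analyzed (gradual-intensity
#'   analyses conventionally use only left and right).
#' @param by event columns defining conditions (e.g.
#'   `c("emotion", "intensity")`).
#' @param specs component table.
#' @param threshold rejection threshold, microvolts.
#' @return data.frame: condition columns, `roi`, `component`,
#'   `peak_latency_ms`, `mean_amp`, `n_epochs`, `flag`.
#' @export
timedomain_components <- function(rec, rois = roi_set(),
                                  use_rois = names(rois),
                                  by = "emotion",
                                  specs = component_specs(),
                                  threshold = 100) {
  rec <- notch_base(rec)
  rec <- lowpass_30(rec)
  ep <- epoch_oddballs(rec)
  ep <- reject_epochs(ep, threshold,
                      channels = unlist(rois[use_rois], use.names = FALSE))
  conds <- unique(ep$meta[, by, drop = FALSE])
  rows <- list()
  for (ci in seq_len(nrow(conds))) {
    sel <- rep(TRUE, nrow(ep$meta))
    for (b in by) sel <- sel & ep$meta[[b]] == conds[ci, b]
    for (r in use_rois) {
      erp <- average_erp(ep, channels = rois[[r]], which = which(sel))
      ca <- component_amplitudes(erp, ep$times, specs)
      ca$roi <- r
      ca$n_epochs <- sum(sel & !ep$rejected)
      for (b in by) ca[[b]] <- conds[ci, b]
      rows[[length(rows) + 1]] <- ca
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
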