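#' Interpolate bad channels from spherical neighbors
#'
#' Replaces each bad channel by an inverse great-circle-distance weighted
#' average of its `k` nearest good EEG channels on the unit sphere
#' (weights normalized to sum to 1). This is a simplified stand-in for
#' spherical-spline interpolation; the simplification is recorded in the
#' recording log.
#'
#' @param rec an `fpvs_recording` with a montage.
#' @param bad character vector of bad channel labels.
#' @param k number of good neighbors to combine.
#' @return recording with bad channels replaced; good channels unchanged.
#' @export
interpolate_channels <- function(rec, bad, k = 4L) {
  stopifnot(inherits(rec, "fpvs_recording"))
  if (length(bad) == 0L) return(rec)
  bad <- normalize_channel_labels(bad)
  if (is.null(rec$montage)) stop("recording has no montage")
  unknown <- setdiff(bad, rec$channel_labels)
  if (length(unknown))
    stop("bad channels not in recording: ", paste(unknown, collapse = ", "))
  eeg <- rec$channel_labels[rec$channel_kinds == "eeg"]
  good <- setdiff(eeg, bad)
  if (length(good) < 3L)
    stop("need at least 3 good EEG channels to interpolate")
  pos <- rec$montage
  xyz <- as.matrix(pos[match(rec$channel_labels, pos$label), c("x", "y", "z")])
  rownames(xyz) <- rec$channel_labels
  for (ch in bad) {
    d <- acos(pmin(1, pmax(-1, xyz[good, , drop = FALSE] %*% xyz[ch, ])))
    nb <- good[order(d)][seq_len(min(k, length(good)))]
    w <- 1 / pmax(as.numeric(d[order(d)][seq_along(nb)]), 1e-6)
    w <- w / sum(w)
    rec$data[ch, ] <- as.numeric(w %*% rec$data[nb, , drop = FALSE])
  }
  rec_log(rec, sprintf(
    "interpolated %s (inverse great-circle distance, %d neighbors; simplified spherical)",
    paste(bad, collapse = ","), k))
}

#' Remove ocular activity by EOG regression
#'
#' Subtracts from every EEG channel its least-squares projection onto the
#' EOG channels (with intercept). A deterministic substitute for
#' ICA-based blink removal; EOG channels are kept unmodified so the
#' correction is reproducible.
#'
#' @param rec an `fpvs_recording`.
#' @param eog_channels labels to regress out; default all channels of
#'   kind `"eog"`.
#' @return corrected recording.
#' @export
regress_eog <- function(rec, eog_channels = NULL) {
  stopifnot(inherits(rec, "fpvs_recording"))
  if (is.null(eog_channels))
    eog_channels <- rec$channel_labels[rec$channel_kinds == "eog"]
  if (length(eog_channels) == 0L) stop("no EOG channels available")
  eog_channels <- normalize_channel_labels(eog_channels)
  E <- t(rec$data[eog_channels, , drop = FALSE])
  if (any(apply(E, 2, stats::sd) == 0))
    stop("constant EOG channel: regression is rank deficient")
  X <- cbind(1, E)
  XtX <- crossprod(X)
  eeg <- which(rec$channel_kinds == "eeg")
  Y <- t(rec$data[eeg, , drop = FALSE])
  beta <- solve(XtX, crossprod(X, Y))
  rec$data[eeg, ] <- t(Y - X %*% beta)
  rec_log(rec, sprintf("EOG regression using %s",
                       paste(eog_channels, collapse = ",")))
}

#' Re-reference EEG channels to the common average
#'
#' Subtracts, at every sample, the mean over EEG channels (EOG channels
#' are excluded from the mean and left unmodified). Idempotent.
#'
#' @param rec an `fpvs_recording` with at least 2 EEG channels.
#' @return re-referenced recording with `reference = "average"`.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "fpvs_recording"))
  eeg <- which(rec$channel_kinds == "eeg")
  if (length(eeg) < 2L) stop("need at least 2 EEG channels")
  avg <- colMeans(rec$data[eeg, , drop = FALSE])
  rec$data[eeg, ] <- sweep(rec$data[eeg, , drop = FALSE], 2, avg)
  rec$reference <- "average"
  rec_log(rec, "re-referenced to average (EEG channels)")
}

#' Full offline preprocessing pipeline
#'
#' Fixed order: band-pass filter, interpolate bad channels, EOG
#' regression, average re-reference. Each step is appended to the
#' recording log.
#'
#' @param rec an `fpvs_recording`.
#' @param spec a [filter_spec()].
#' @param bad bad channel labels to interpolate.
#' @param eog_regression apply [regress_eog()] (default TRUE).
#' @return preprocessed recording.
#' @export
preprocess <- function(rec, spec = filter_spec(), bad = character(0),
                       eog_regression = TRUE) {
  rec <- bandpass(rec, spec)
  rec <- interpolate_channels(rec, bad)
  if (eog_regression && any(rec$channel_kinds == "eog"))
    rec <- regress_eog(rec)
  rereference_average(rec)
}

#' Quality-control report for a recording
#'
#' Flags channels whose variance is an outlier (beyond `z_thresh` robust
#' z-scores of the log-variance across EEG channels) and counts samples
#' exceeding an absolute amplitude bound. Advisory only: nothing is
#' excluded automatically.
#'
#' @param rec an `fpvs_recording`.
#' @param amp_bound microvolt bound for the extreme-sample count.
#' @param z_thresh robust z threshold on log channel variance.
#' @return list: `flagged_channels`, `channel_variance`,
#'   `n_samples_extreme`, `log`.
#' @export
qc_report <- function(rec, amp_bound = 100, z_thresh = 3) {
  eeg <- which(rec$channel_kinds == "eeg")
  v <- apply(rec$data[eeg, , drop = FALSE], 1, stats::var)
  lv <- log(v + 1e-12)
  rz <- (lv - stats::median(lv)) / (stats::mad(lv) + 1e-12)
  list(
    flagged_channels = rec$channel_labels[eeg][abs(rz) > z_thresh],
    channel_variance = stats::setNames(v, rec$channel_labels[eeg]),
    n_samples_extreme = sum(abs(rec$data[eeg, , drop = FALSE]) > amp_bound),
    log = rec$log)
}
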