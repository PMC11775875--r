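#' Multichannel EEG recording container
#'
#' The unit every pipeline stage consumes and produces: a channels x
#' samples matrix in microvolts, a sampling rate, channel metadata, and an
#' event table. Time is 0-based seconds from the start of the data;
#' sample indices are 1-based in R convention with `onset_s = (i - 1) / fs`.
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_labels character vector, one unique label per row.
#' @param channel_kinds `"eeg"`/`"eog"` per channel; default guesses EOG
#'   from the label.
#' @param events data.frame with at least `onset_s` and `label`; any other
#'   columns are carried as metadata. May be empty.
#' @param reference reference label or `"average"`.
#' @param montage optional data.frame as returned by [standard_montage()].
#' @return object of class `fpvs_recording`.
#' @export
recording <- function(data, sampling_rate, channel_labels,
                      channel_kinds = NULL, events = NULL,
                      reference = "Cz", montage = NULL) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), sampling_rate > 0,
            length(channel_labels) == nrow(data))
  channel_labels <- normalize_channel_labels(channel_labels)
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  if (is.null(channel_kinds))
    channel_kinds <- ifelse(grepl("EOG", channel_labels, ignore.case = TRUE),
                            "eog", "eeg")
  if (is.null(events))
    events <- data.frame(onset_s = numeric(0), label = character(0),
                         stringsAsFactors = FALSE)
  stopifnot(all(c("onset_s", "label") %in% names(events)) ||
              nrow(events) == 0L)
  n <- ncol(data)
  if (nrow(events) > 0) {
    smp <- round(events$onset_s * sampling_rate)
    if (any(smp < 0) || any(smp >= n))
      stop("event onsets fall outside the recording [0, ",
           n / sampling_rate, ") s")
  }
  rownames(data) <- channel_labels
  structure(list(
    data = data,
    sampling_rate = sampling_rate,
    channel_labels = channel_labels,
    channel_kinds = channel_kinds,
    events = events,
    reference = reference,
    montage = montage,
    log = character(0)
  ), class = "fpvs_recording")
}

#' @export
print.fpvs_recording <- function(x, ...) {
  cat(sprintf(
    "<fpvs_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events, ref=%s\n",
    nrow(x$data), ncol(x$data), x$sampling_rate,
    ncol(x$data) / x$sampling_rate, nrow(x$events), x$reference))
  invisible(x)
}

#' Number of samples / duration helpers
#' @param x an `fpvs_recording`.
#' @return `n_samples`: integer; `duration`: seconds.
#' @export
n_samples <- function(x) ncol(x$data)

#' @rdname n_samples
#' @export
duration <- function(x) ncol(x$data) / x$sampling_rate

# index (1-based) of the sample at a given onset time
sample_at <- function(x, onset_s) as.integer(round(onset_s * x$sampling_rate)) + 1L

rec_log <- function(x, msg) {
  x$log <- c(x$log, msg)
  x
}

eeg_idx <- function(x) which(x$channel_kinds == "eeg")
eog_idx <- function(x) which(x$channel_kinds == "eog")

#' Select or aggregate a region-of-interest
#'
#' For a recording, returns the recording restricted to the ROI member
#' channels (or, with `aggregate = TRUE`, a single averaged channel named
#' after the ROI). For a matrix with channel rownames, returns the
#' arithmetic channel mean.
#'
#' @param x an `fpvs_recording` or a channels x n matrix with rownames.
#' @param roi ROI name in [roi_set()] (`"left"`, `"right"`, `"medial"`)
#'   or a character vector of channel labels.
#' @param rois a `roi_set` (defaults to [roi_set()]).
#' @param aggregate average over member channels (default TRUE for
#'   matrices, FALSE for recordings).
#' @return subset recording, or numeric vector/matrix of the ROI mean.
#' @export
select_roi <- function(x, roi, rois = roi_set(), aggregate = NULL) {
  members <- if (is.character(roi) && length(roi) == 1L && roi %in% names(rois))
    rois[[roi]] else as.character(roi)
  if (inherits(x, "fpvs_recording")) {
    missing <- setdiff(members, x$channel_labels)
    if (length(missing))
      stop("ROI channels missing from recording: ",
           paste(missing, collapse = ", "))
    idx <- match(members, x$channel_labels)
    if (isTRUE(aggregate)) {
      out <- x
      out$data <- matrix(colMeans(x$data[idx, , drop = FALSE]), nrow = 1,
                         dimnames = list(if (is.character(roi)) roi[1] else "roi"))
      out$channel_labels <- rownames(out$data)
      out$channel_kinds <- "eeg"
      return(out)
    }
    out <- x
    out$data <- x$data[idx, , drop = FALSE]
    out$channel_labels <- members
    out$channel_kinds <- x$channel_kinds[idx]
    return(out)
  }
  m <- as.matrix(x)
  missing <- setdiff(members, rownames(m))
  if (length(missing))
    stop("ROI channels missing: ", paste(missing, collapse = ", "))
  if (is.null(aggregate)) aggregate <- TRUE
  sub <- m[members, , drop = FALSE]
  if (aggregate) colMeans(sub) else sub
}
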