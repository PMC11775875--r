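#' Write a recording to EDF with a TSV events sidecar
#'
#' European Data Format: 16-bit integers with per-channel physical
#' scaling. Physical range is fixed at +/-3276.7 microvolts so one
#' digital step is exactly 0.1 microvolt. The whole recording is stored
#' as a single data record whose duration equals the recording length,
#' which keeps the round trip exact up to quantization for any number of
#' samples. Events go to `<path>.events.tsv` (UTF-8, tab-separated, dot
#' decimal) because EDF+ annotations are dialect-prone.
#'
#' @param rec an `fpvs_recording`.
#' @param path output file path (`.edf`).
#' @param events_path events sidecar path; default `<path>.events.tsv`.
#' @return invisibly, the paths written.
#' @export
write_recording <- function(rec, path,
                            events_path = paste0(path, ".events.tsv")) {
  stopifnot(inherits(rec, "fpvs_recording"))
  if (!all(is.finite(rec$data)))
    stop("recording contains non-finite sample values")
  phys_max <- 3276.7
  if (max(abs(rec$data)) > phys_max)
    warning("samples exceed +/-3276.7 uV and will clip in EDF")
  nch <- nrow(rec$data)
  nsamp <- ncol(rec$data)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  pad <- function(s, w) {
    s <- as.character(s)
    if (nchar(s) > w) s <- substr(s, 1, w)
    formatC(s, width = -w)  # left-justified, space padded
  }
  wr <- function(s, w) writeChar(pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8)
  wr("X", 80)
  wr(sprintf("fpvs fs=%g", rec$sampling_rate), 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 * (1 + nch), 8)
  wr("", 44)
  wr(1, 8)                                   # one data record
  wr(format(nsamp / rec$sampling_rate, digits = 7), 8)
  wr(nch, 4)
  for (l in rec$channel_labels) wr(l, 16)
  for (i in seq_len(nch)) wr(rec$channel_kinds[i], 80)
  for (i in seq_len(nch)) wr("uV", 8)
  for (i in seq_len(nch)) wr(-phys_max, 8)
  for (i in seq_len(nch)) wr(phys_max, 8)
  for (i in seq_len(nch)) wr(-32767, 8)
  for (i in seq_len(nch)) wr(32767, 8)
  for (i in seq_len(nch)) wr("", 80)
  for (i in seq_len(nch)) wr(nsamp, 8)
  for (i in seq_len(nch)) wr("", 32)
  for (i in seq_len(nch)) {
    dig <- as.integer(pmax(-32767, pmin(32767, round(rec$data[i, ] / 0.1))))
    writeBin(dig, con, size = 2L, endian = "little")
  }
  write_events_tsv(rec$events, events_path)
  invisible(c(edf = path, events = events_path))
}

write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

read_events_tsv <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (nrow(ev) > 0 && !"onset_s" %in% names(ev))
    stop("events sidecar lacks an onset_s column")
  ev
}

#' Read an EDF recording and its events sidecar
#'
#' @param path `.edf` file written by [write_recording()] (or any EDF
#'   whose channels share one sampling rate).
#' @param events_path TSV sidecar; default `<path>.events.tsv`, skipped
#'   if absent.
#' @param require_channels optional labels that must be present.
#' @return an `fpvs_recording` (microvolts).
#' @export
read_recording <- function(path, events_path = paste0(path, ".events.tsv"),
                           require_channels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80)
  rid <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(i) rd(16), character(1))
  kinds <- vapply(seq_len(nch), function(i) rd(80), character(1))
  units <- vapply(seq_len(nch), function(i) rd(8), character(1))
  if (!all(tolower(units) %in% c("uv", "µv", "")))
    stop("unit mismatch: expected uV, got ", paste(unique(units), collapse = ","))
  pmin_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), character(1)))
  dmin_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), character(1)))
  dmax_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), character(1)))
  for (i in seq_len(nch)) rd(80)
  spr <- as.integer(vapply(seq_len(nch), function(i) rd(8), character(1)))
  for (i in seq_len(nch)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("channels with differing sampling rates are not supported")
  fs <- spr[1] / rec_dur
  dat <- matrix(0, nch, spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(nch)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      scale <- (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
      dat[i, (r - 1L) * spr[i] + seq_len(spr[i])] <-
        pmin_[i] + (dig - dmin_[i]) * scale
    }
  }
  kinds <- ifelse(kinds %in% c("eeg", "eog"), kinds,
                  ifelse(grepl("EOG", labels, ignore.case = TRUE),
                         "eog", "eeg"))
  ev <- if (file.exists(events_path)) read_events_tsv(events_path) else NULL
  labels <- normalize_channel_labels(labels)
  if (!is.null(require_channels)) {
    missing <- setdiff(normalize_channel_labels(require_channels), labels)
    if (length(missing))
      stop("missing channels: ", paste(missing, collapse = ", "))
  }
  recording(dat, fs, labels, kinds, events = ev)
}
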