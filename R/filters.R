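#' Band-pass filter specification
#'
#' Fourth-order Butterworth, applied zero-phase (forward-backward) as a
#' high-pass / low-pass cascade. Defaults match wide-band EEG
#' preprocessing: 0.01--100 Hz.
#'
#' @param highpass high-pass cutoff in Hz.
#' @param lowpass low-pass cutoff in Hz.
#' @param order filter order per edge.
#' @param zero_phase apply forward-backward (TRUE, default).
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(highpass = 0.01, lowpass = 100, order = 4L,
                        zero_phase = TRUE) {
  stopifnot(highpass > 0, lowpass > highpass, order >= 2, order %% 2 == 0)
  structure(list(highpass = highpass, lowpass = lowpass,
                 order = as.integer(order), zero_phase = zero_phase),
            class = "filter_spec")
}

# Butterworth design as second-order sections via bilinear transform.
# Returns a list of sections, each list(b = c(b0,b1,b2), a = c(1,a1,a2)).
butter_sos <- function(order, cutoff, fs, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(order %% 2 == 0, cutoff > 0)
  if (cutoff >= fs / 2)
    stop("cutoff at or above Nyquist (", fs / 2, " Hz)")
  n <- order
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))   # analog prototype poles
  wc <- 2 * fs * tan(pi * cutoff / fs)            # pre-warped cutoff
  s_poles <- if (type == "low") wc * p else wc / p
  zp <- (2 * fs + s_poles) / (2 * fs - s_poles)   # bilinear transform
  z0 <- if (type == "low") -1 else 1              # digital zeros
  # pair conjugate poles into biquads; normalize gain at DC (low) or
  # Nyquist (high) so the cascade has unit pass-band gain
  ord <- order(Im(zp))
  zp <- zp[ord]
  used <- rep(FALSE, n)
  sections <- list()
  for (i in seq_len(n)) {
    if (used[i]) next
    j <- which(!used & abs(zp - Conj(zp[i])) < 1e-8 & seq_len(n) != i)[1]
    if (is.na(j)) j <- which(!used & seq_len(n) != i)[1]
    used[c(i, j)] <- TRUE
    pr <- c(zp[i], zp[j])
    a <- c(1, -Re(pr[1] + pr[2]), Re(pr[1] * pr[2]))
    b <- c(1, -2 * z0, z0^2)
    at <- if (type == "low") sum(a) else a[1] - a[2] + a[3]
    bt <- if (type == "low") sum(b) else b[1] - b[2] + b[3]
    sections[[length(sections) + 1]] <- list(b = b * at / bt, a = a)
  }
  sections
}

# single forward pass of one biquad over a vector (zero initial state)
biquad_filter <- function(x, b, a) {
  v <- stats::filter(x, b, method = "convolution", sides = 1)
  v[1] <- b[1] * x[1]
  if (length(x) > 1) v[2] <- b[1] * x[2] + b[2] * x[1]
  as.numeric(stats::filter(as.numeric(v), -a[2:3], method = "recursive"))
}

sos_filter <- function(x, sos) {
  for (s in sos) x <- biquad_filter(x, s$b, s$a)
  x
}

# zero-phase (forward-backward) filtering with odd-reflection padding
sos_filtfilt <- function(x, sos, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- min(n - 1L, 1500L)
  xp <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  y <- sos_filter(xp, sos)
  y <- rev(sos_filter(rev(y), sos))
  y[(padlen + 1):(padlen + n)]
}

# closed-form Butterworth magnitude response (single pass)
butter_magnitude <- function(f, cutoff, order, type = c("low", "high")) {
  type <- match.arg(type)
  r <- if (type == "low") f / cutoff else cutoff / f
  1 / sqrt(1 + r^(2 * order))
}

apply_filter_rows <- function(mat, sos, zero_phase = TRUE) {
  out <- mat
  for (i in seq_len(nrow(mat)))
    out[i, ] <- if (zero_phase) sos_filtfilt(mat[i, ], sos)
                else sos_filter(mat[i, ], sos)
  out
}

#' Band-pass filter a recording
#'
#' High-pass then low-pass Butterworth cascade on every channel; events
#' and metadata are untouched.
#'
#' @param rec an `fpvs_recording`.
#' @param spec a [filter_spec()].
#' @return filtered `fpvs_recording`.
#' @export
bandpass <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "fpvs_recording"), inherits(spec, "filter_spec"))
  fs <- rec$sampling_rate
  if (spec$lowpass >= fs / 2)
    stop("low-pass cutoff ", spec$lowpass, " Hz at or above Nyquist (",
         fs / 2, " Hz)")
  hp <- butter_sos(spec$order, spec$highpass, fs, "high")
  lp <- butter_sos(spec$order, spec$lowpass, fs, "low")
  rec$data <- apply_filter_rows(rec$data, c(hp, lp), spec$zero_phase)
  rec_log(rec, sprintf("bandpass %g-%g Hz butterworth order %d zero_phase=%s",
                       spec$highpass, spec$lowpass, spec$order,
                       spec$zero_phase))
}

#' Low-pass filter a recording at 30 Hz
#'
#' Zero-phase 4th-order Butterworth low-pass, used before time-domain
#' component analysis.
#'
#' @param rec an `fpvs_recording`.
#' @param cutoff cutoff in Hz.
#' @return filtered `fpvs_recording`.
#' @export
lowpass_30 <- function(rec, cutoff = 30) {
  stopifnot(inherits(rec, "fpvs_recording"))
  sos <- butter_sos(4L, cutoff, rec$sampling_rate, "low")
  rec$data <- apply_filter_rows(rec$data, sos, TRUE)
  rec_log(rec, sprintf("lowpass %g Hz butterworth order 4 zero-phase", cutoff))
}
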