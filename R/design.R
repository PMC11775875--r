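#' FPVS stimulation design
#'
#' Describes a fast periodic visual stimulation task: a stream of neutral
#' faces presented at `base_freq` with an expressive face at every
#' `oddball_every`-th position, giving an oddball rate of
#' `base_freq / oddball_every` (6 / 5 = 1.2 Hz by default). Two stock
#' layouts are provided: `"max-int"` (full-intensity expressions, 4
#' sequences of 40 s) and `"grad-int"` (intensity ramps 20--100% in 20%
#' steps, 20 s per step, 2 emotions x 2 identities).
#'
#' @param task `"max-int"` or `"grad-int"`; fills in the stock per-task
#'   defaults below, all of which can be overridden.
#' @param base_freq base stimulation rate in Hz.
#' @param oddball_every oddball appears at every this-many-th stimulus.
#' @param sequence_dur duration of one stimulation sequence in seconds
#'   (per intensity step for grad-int).
#' @param emotions character vector of expressive conditions.
#' @param identities character vector of face identities; each sequence
#'   uses a single identity.
#' @param intensities expression intensity steps in percent, strictly
#'   increasing in (0, 100]. Max-int uses a single 100% step.
#' @param n_sequences_per_condition sequences per emotion condition.
#' @param size_jitter integer percent range for random stimulus size,
#'   drawn uniformly in 1% steps.
#' @param sampling_rate EEG sampling rate in Hz.
#' @param gap_dur inter-sequence gap in seconds (fixation cross).
#' @return An object of class `fpvs_design`.
#' @examples
#' d <- fpvs_design("max-int")
#' d$oddball_freq  # 1.2
#' @export
fpvs_design <- function(task = c("max-int", "grad-int"),
                        base_freq = 6,
                        oddball_every = 5L,
                        sequence_dur = NULL,
                        emotions = c("happy", "angry"),
                        identities = c("m1", "m2", "f1", "f2"),
                        intensities = NULL,
                        n_sequences_per_condition = NULL,
                        size_jitter = c(90L, 110L),
                        sampling_rate = 500,
                        gap_dur = 1) {
  task <- match.arg(task)
  if (task == "max-int") {
    if (is.null(sequence_dur)) sequence_dur <- 40
    if (is.null(intensities)) intensities <- 100
    # each emotion shown twice, once male once female identity
    if (is.null(n_sequences_per_condition)) n_sequences_per_condition <- 2L
  } else {
    if (is.null(sequence_dur)) sequence_dur <- 20
    if (is.null(intensities)) intensities <- c(20, 40, 60, 80, 100)
    if (is.null(n_sequences_per_condition)) n_sequences_per_condition <- 2L
  }
  oddball_freq <- base_freq / oddball_every
  stopifnot(base_freq > 0, oddball_every >= 2, sequence_dur > 0,
            sampling_rate > 0, length(size_jitter) == 2L,
            size_jitter[1] <= size_jitter[2])
  if (any(diff(intensities) <= 0) || any(intensities <= 0) ||
      any(intensities > 100)) {
    stop("intensities must be strictly increasing in (0, 100]")
  }
  n_cyc <- sequence_dur * oddball_freq
  if (abs(n_cyc - round(n_cyc)) > 1e-9) {
    stop("design not cycle-locked: sequence_dur * oddball_freq = ",
         n_cyc, " is not an integer")
  }
  structure(list(
    task = task,
    base_freq = base_freq,
    oddball_every = as.integer(oddball_every),
    oddball_freq = oddball_freq,
    sequence_dur = sequence_dur,
    emotions = emotions,
    identities = identities,
    intensities = intensities,
    n_sequences_per_condition = as.integer(n_sequences_per_condition),
    size_jitter = as.integer(size_jitter),
    sampling_rate = sampling_rate,
    gap_dur = gap_dur
  ), class = "fpvs_design")
}

#' @export
print.fpvs_design <- function(x, ...) {
  cat(sprintf("<fpvs_design> task=%s base=%g Hz oddball=%g Hz (every %d)\n",
              x$task, x$base_freq, x$oddball_freq, x$oddball_every))
  cat(sprintf("  %d emotions x %d seq/cond, %g s per sequence, intensities: %s\n",
              length(x$emotions), x$n_sequences_per_condition,
              x$sequence_dur, paste(x$intensities, collapse = ",")))
  invisible(x)
}

#' Build the stimulus event schedule for an FPVS design
#'
#' Expands a design into a per-stimulus table. Stimuli are presented at the
#' base rate; every `oddball_every`-th stimulus (positions 5, 10, 15, ...)
#' is the expressive oddball. For grad-int designs each sequence is a ramp
#' of the intensity steps in ascending order, `sequence_dur` seconds each;
#' for max-int a sequence is a single `sequence_dur` block at 100%.
#' Stimulus size is jittered uniformly over the design's percent range.
#'
#' @param design an [fpvs_design()].
#' @param seed integer seed for the size jitter (and nothing else).
#' @return data.frame with one row per stimulus: `sequence` (index),
#'   `segment` (intensity-step index within sequence), `onset_s` (from
#'   recording start), `label` (`"neutral"`/`"oddball"`), `emotion`,
#'   `identity`, `intensity` (percent, for oddball stimuli; neutral rows
#'   carry the segment's nominal intensity for bookkeeping), `size_pct`.
#' @examples
#' sch <- build_schedule(fpvs_design("max-int"), seed = 1)
#' sum(sch$label == "oddball")  # 4 sequences x 48 oddballs
#' @export
build_schedule <- function(design, seed = 1L) {
  stopifnot(inherits(design, "fpvs_design"))
  rng <- local({ set.seed(seed); NULL })
  isi <- 1 / design$base_freq
  n_per_seg <- round(design$sequence_dur * design$base_freq)
  n_seq <- length(design$emotions) * design$n_sequences_per_condition
  n_steps <- length(design$intensities)
  # identities cycle within emotion so that each emotion gets distinct faces
  rows <- vector("list", n_seq)
  t0 <- design$gap_dur
  seq_i <- 0L
  for (em in design$emotions) {
    for (rep_i in seq_len(design$n_sequences_per_condition)) {
      seq_i <- seq_i + 1L
      id <- design$identities[((rep_i - 1L) %% length(design$identities)) + 1L]
      seg_list <- vector("list", n_steps)
      for (s in seq_len(n_steps)) {
        pos <- seq_len(n_per_seg)
        onset <- t0 + (s - 1L) * design$sequence_dur + (pos - 1L) * isi
        lab <- ifelse(pos %% design$oddball_every == 0L, "oddball", "neutral")
        seg_list[[s]] <- data.frame(
          sequence = seq_i, segment = s, onset_s = onset, label = lab,
          emotion = em, identity = id, intensity = design$intensities[s],
          stringsAsFactors = FALSE)
      }
      rows[[seq_i]] <- do.call(rbind, seg_list)
      t0 <- t0 + n_steps * design$sequence_dur + design$gap_dur
    }
  }
  out <- do.call(rbind, rows)
  jit <- design$size_jitter
  out$size_pct <- sample(seq(jit[1], jit[2], by = 1L), nrow(out),
                         replace = TRUE)
  rownames(out) <- NULL
  attr(out, "total_stim_s") <- n_seq * n_steps * design$sequence_dur
  attr(out, "design") <- design
  out
}

#' Explicit emotion-recognition task (ERT) design
#'
#' One block per emotion: 10 expressive trials at each of the five
#' intensity steps plus 10 neutral trials, 60 trials total, responded to
#' as neutral vs. expressive within `max_rt` seconds. Accuracy on
#' expressive trials follows a lapse-limited logistic psychometric
#' function of intensity; reaction times follow a linear intensity model
#' with Gaussian noise.
#'
#' @param trials_per_intensity expressive trials per intensity step.
#' @param neutral_trials neutral trials per block.
#' @param intensities intensity steps in percent.
#' @param max_rt response deadline in seconds.
#' @param threshold,slope,lapse,guess psychometric parameters: probability
#'   of a correct "expressive" response at intensity I is
#'   `guess + (1 - guess - lapse) * plogis(slope * (I - threshold))`.
#' @param p_correct_neutral probability of a correct "neutral" response on
#'   neutral trials.
#' @param rt_base,rt_slope,rt_sd reaction-time model: mean RT at intensity
#'   I is `rt_base - rt_slope * I / 100`, Gaussian noise `rt_sd`.
#' @return An object of class `ert_design`.
#' @export
ert_design <- function(trials_per_intensity = 10L,
                       neutral_trials = 10L,
                       intensities = c(20, 40, 60, 80, 100),
                       max_rt = 3,
                       threshold = 50, slope = 0.08, lapse = 0.02,
                       guess = 0.5,
                       p_correct_neutral = 0.9,
                       rt_base = 1.6, rt_slope = 0.5, rt_sd = 0.35) {
  stopifnot(trials_per_intensity >= 1, neutral_trials >= 0, max_rt > 0,
            lapse >= 0, lapse < 1, guess >= 0, guess < 1, slope > 0)
  structure(list(
    trials_per_intensity = as.integer(trials_per_intensity),
    neutral_trials = as.integer(neutral_trials),
    intensities = intensities,
    max_rt = max_rt,
    threshold = threshold, slope = slope, lapse = lapse, guess = guess,
    p_correct_neutral = p_correct_neutral,
    rt_base = rt_base, rt_slope = rt_slope, rt_sd = rt_sd
  ), class = "ert_design")
}

#' Psychometric accuracy function of an ERT design
#'
#' @param design an [ert_design()].
#' @param intensity intensity in percent (vectorized).
#' @return Probability of a correct response on an expressive trial.
#' @export
ert_psychometric <- function(design, intensity) {
  design$guess + (1 - design$guess - design$lapse) *
    stats::plogis(design$slope * (intensity - design$threshold))
}
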