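# Shared fixtures: small montages and designs keep simulations fast while
# preserving the geometry the pipeline needs (both ROIs, medial cluster,
# an EOG channel).

small_montage <- function(extra = character(0)) {
  standard_montage(unique(c(
    "P7", "PO7", "PO3", "PO9", "P8", "PO8", "PO4", "PO10",
    "O1", "Oz", "O2", "Pz", "Cz", "Fp1", "VEOG", extra)))
}

# uniform unit topography over EEG channels of a montage
flat_topo <- function(montage) {
  stats::setNames(as.numeric(montage$kind == "eeg"), montage$label)
}

# one-emotion, one-sequence max-int-style design (22 s of data)
tiny_design <- function(sequence_dur = 20, ...) {
  fpvs_design("max-int", n_sequences_per_condition = 1L,
              emotions = "happy", sequence_dur = sequence_dur, ...)
}

# noiseless single-sequence simulation with flat topographies
noiseless_sim <- function(base_amps = c("1" = 1.0),
                          oddball_amps = c("1" = 0.5),
                          montage = small_montage(),
                          design = tiny_design(), seed = 1L, ...) {
  simulate_recording(
    design,
    neural_spec(base_harmonic_amps = base_amps,
                oddball_harmonic_amps = oddball_amps,
                base_topo = flat_topo(montage),
                oddball_topo = flat_topo(montage), ...),
    noise_spec(noise_rms = 0, blink_rate = 0, seed = seed),
    montage)
}

# amplitude spectrum carrying a prescribed amplitude vector (for window
# bookkeeping tests): one channel "ch1", resolution `res`
spectrum_from_amps <- function(amps, res = 0.05) {
  structure(list(
    freqs = (seq_along(amps) - 1) * res,
    amps = matrix(amps, 1, dimnames = list("ch1", NULL)),
    resolution = res, duration = 1 / res, channel_labels = "ch1"),
    class = "fpvs_spectrum")
}
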