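test_that("the FFT notch removes base harmonics and spares the oddball band", {
  fs <- 500
  t <- (0:9999) / fs
  rec6 <- recording(matrix(sin(2 * pi * 6 * t), 1), fs, "O1")
  out6 <- notch_base(rec6)
  expect_lt(sqrt(mean(out6$data^2)) / sqrt(mean(rec6$data^2)), 0.01)
  rec12 <- recording(matrix(sin(2 * pi * 1.2 * t), 1), fs, "O1")
  out12 <- notch_base(rec12)
  expect_lt(sqrt(mean((out12$data - rec12$data)^2)) /
              sqrt(mean(rec12$data^2)), 0.05)
  # linearity: the mixture reduces to its oddball part
  mix <- recording(matrix(sin(2 * pi * 6 * t) + sin(2 * pi * 1.2 * t), 1),
                   fs, "O1")
  outm <- notch_base(mix)
  expect_lt(sqrt(mean((outm$data - rec12$data)^2)) /
              sqrt(mean(rec12$data^2)), 0.05)
})

test_that("post-notch base summed response is non-significant", {
  mont <- small_montage()
  sim <- simulate_recording(
    tiny_design(),
    neural_spec(base_harmonic_amps = c("1" = 1, "2" = 0.5, "3" = 0.2)),
    noise_spec(noise_rms = 1, blink_rate = 0, seed = 12), mont)
  rec <- notch_base(sim$recording)
  sp <- segment_spectra(rec, tiny_design())[[1]]$spectrum
  sr <- summed_response(sp, harmonic_set("base"), noise_params(5),
                        roi_set()$medial)
  expect_lt(sr$summed_z, 1.64)
})

test_that("30 Hz low-pass matches the analytic Butterworth magnitude", {
  fs <- 500
  t <- (0:19999) / fs
  mid <- 5000:15000
  g_meas <- function(f) {
    rec <- recording(matrix(sin(2 * pi * f * t), 1), fs, "O1")
    out <- lowpass_30(rec)
    stats::sd(out$data[1, mid]) / stats::sd(rec$data[1, mid])
  }
  # zero-phase application squares the single-pass magnitude
  expect_equal(g_meas(45), butter_magnitude(45, 30, 4)^2, tolerance = 0.05)
  expect_lt(abs(g_meas(1.2) - 1), 0.01)
  # DC preserved
  recdc <- recording(matrix(rep(2, 5000), 1), fs, "O1")
  expect_equal(mean(lowpass_30(recdc)$data[1, 1000:4000]), 2,
               tolerance = 1e-6)
})

test_that("oddball epochs span -167..667 ms with baseline correction", {
  mont <- small_montage()
  sim <- noiseless_sim()
  ep <- epoch_oddballs(sim$recording)
  expect_equal(dim(ep$data)[3], 417)           # 84 + 1 + 332 samples
  expect_equal(min(ep$times), -84 / 500)
  expect_equal(max(ep$times), 332 / 500)
  # constant recording: zero after baseline subtraction
  recc <- recording(matrix(7, 2, 5000), 500, c("O1", "O2"),
                    events = data.frame(onset_s = c(2, 4),
                                        label = "oddball"))
  epc <- epoch_oddballs(recc)
  expect_equal(max(abs(epc$data)), 0)
  # early event is dropped and counted
  rec_early <- recording(matrix(0, 1, 5000), 500, "O1",
                         events = data.frame(onset_s = c(0.1, 2),
                                             label = "oddball"))
  ep2 <- epoch_oddballs(rec_early)
  expect_equal(dim(ep2$data)[1], 1)
  expect_equal(ep2$n_dropped_bounds, 1)
})

test_that("epoch rejection applies the +/-100 uV rule strictly", {
  dat <- array(0, c(3, 2, 417))
  dat[1, 1, 100] <- 150
  dat[2, 1, 100] <- 99.9
  ep <- structure(list(data = dat, times = seq(-84, 332) / 500,
                       channel_labels = c("PO8", "P8"),
                       channel_kinds = c("eeg", "eeg"),
                       meta = data.frame(onset_s = 1:3, label = "oddball"),
                       rejected = rep(FALSE, 3),
                       reject_reason = rep("", 3), n_dropped_bounds = 0),
                  class = "fpvs_epochs")
  out <- reject_epochs(ep, 100)
  expect_equal(out$rejected, c(TRUE, FALSE, FALSE))
  dat[, , ] <- 500
  ep$data <- dat
  expect_error(reject_epochs(ep, 100), "all epochs rejected")
})

test_that("component quantification matches a closed-form bump", {
  fs <- 1000
  times <- seq(-0.167, 0.667, by = 1 / fs)
  erp <- -2 * exp(-((times - 0.256)^2) / (2 * 0.02^2))
  ca <- component_amplitudes(erp, times)
  c2 <- ca[ca$component == "C2", ]
  expect_equal(c2$peak_latency_ms, 256)
  # analytic mean of the Gaussian over [246, 266] ms
  f <- function(t) -2 * exp(-((t - 0.256)^2) / (2 * 0.02^2))
  analytic <- stats::integrate(f, 0.246, 0.266)$value / 0.02
  expect_equal(c2$mean_amp, analytic, tolerance = 0.01)
  # flat waveform: all zero, flagged
  ca0 <- component_amplitudes(rep(0, length(times)), times)
  expect_true(all(ca0$mean_amp == 0))
  expect_true(all(ca0$flag == "no-peak"))
  # positive bump at 176 ms is C1, not C2/C3
  erp1 <- 1.5 * exp(-((times - 0.176)^2) / (2 * 0.015^2))
  ca1 <- component_amplitudes(erp1, times)
  expect_gt(ca1$mean_amp[ca1$component == "C1"], 1.3)
  expect_lt(max(abs(ca1$mean_amp[ca1$component != "C1"])), 0.3)
})

test_that("averaging epochs recovers the injected oddball waveform", {
  # two 20 s sequences give 48 oddball epochs; with noise RMS equal to
  # the waveform RMS (SNR 1) averaging must restore the shape
  mont <- standard_montage(c("PO8", "P8", "VEOG"))
  des <- fpvs_design("max-int", n_sequences_per_condition = 2L,
                     emotions = "happy", sequence_dur = 20)
  amps_o <- c("1" = 0.3, "2" = 0.2, "3" = 0.1)
  wave_rms <- sqrt(sum(amps_o^2) / 2)
  neur <- neural_spec(base_harmonic_amps = c("1" = 1),
                      oddball_harmonic_amps = amps_o,
                      base_topo = flat_topo(mont),
                      oddball_topo = flat_topo(mont))
  sim <- simulate_recording(des, neur,
                            noise_spec(noise_rms = wave_rms, blink_rate = 0,
                                       seed = 13), mont)
  rec <- lowpass_30(notch_base(sim$recording))
  ep <- epoch_oddballs(rec)
  ep <- reject_epochs(ep, 100, c("PO8", "P8"))
  erp <- average_erp(ep, c("PO8", "P8"))
  # reference: the injected oddball sinusoids, phase-locked to oddball
  # onset (oddballs sit 4 stimulus periods into each segment), with the
  # same baseline correction as the epochs
  offs <- 4 / 6
  ref <- rowSums(sapply(seq_along(amps_o), function(k) {
    j <- as.integer(names(amps_o))[k]
    amps_o[k] * sin(2 * pi * j * 1.2 * (ep$times + offs))
  }))
  ref <- ref - mean(ref[ep$times < 0])
  expect_gt(stats::cor(erp, ref), 0.95)
})
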