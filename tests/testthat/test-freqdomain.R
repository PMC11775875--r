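test_that("cycle-locked cropping starts at the first oddball", {
  sim <- noiseless_sim()
  ep <- crop_to_cycles(sim$recording, 20, 1.2, sequence = 1, segment = 1)
  expect_equal(ncol(ep$data), 10000)           # 20 s x 500 Hz
  expect_equal(attr(ep, "n_cycles"), 24L)      # 20 s at 1.2 Hz
  # the epoch begins exactly at the first oddball onset
  first_odd <- min(sim$recording$events$onset_s[
    sim$recording$events$label == "oddball"])
  expect_equal(attr(ep, "epoch_onset_s"), first_odd)
  expect_error(crop_to_cycles(sim$recording, 20.2, 1.2), "cycle-locked")
  expect_error(crop_to_cycles(sim$recording, 25, 1.2), "insufficient")
})

test_that("spectral resolution is the reciprocal epoch duration", {
  x40 <- matrix(rnorm(40 * 500), 1)
  expect_equal(amplitude_spectrum(x40, 500)$resolution, 1 / 40)
  x20 <- matrix(rnorm(20 * 500), 1)
  expect_equal(amplitude_spectrum(x20, 500)$resolution, 0.05)
  # exact-bin sinusoid normalization: peak amplitude recovered exactly
  t <- (0:9999) / 500
  sp <- amplitude_spectrum(matrix(0.7 * sin(2 * pi * 1.2 * t + 1), 1), 500)
  i <- round(1.2 / sp$resolution) + 1
  expect_lt(abs(sp$amps[1, i] - 0.7), 1e-9)
  expect_lt(max(sp$amps[1, -i]), 1e-9)
})

test_that("harmonic sets follow the exclusion rule", {
  expect_equal(harmonic_set("oddball", 5), c(1.2, 2.4, 3.6, 4.8, 7.2))
  expect_equal(harmonic_set("base", 3), c(6, 12, 18))
  expect_equal(harmonic_set("oddball", 1), 1.2)
  # no oddball harmonic is ever a base multiple
  for (n in c(1, 5, 10, 20)) {
    h <- harmonic_set("oddball", n)
    expect_length(h, n)
    expect_true(all(abs(h / 6 - round(h / 6)) > 1e-9))
  }
  expect_error(harmonic_set("base", base_f = 6, oddball_f = 1.3),
               "multiple")
})

test_that("noise window bookkeeping drops extremes and uses n-1 SD", {
  # constant candidates: mean c, sd 0
  amps <- rep(0.5, 400)
  sp <- spectrum_from_amps(amps)
  nw <- estimate_noise(sp, 100 * 0.05, noise_params(), "ch1")
  expect_equal(nw$mean, 0.5)
  expect_equal(nw$sd, 0)
  expect_length(nw$amps, 18)                   # 2 x 10 - 2
  # candidates 1..20 in bin order: drop 1 and 20, mean 10.5, sd(2:19)
  amps2 <- rep(0.5, 400)
  amps2[101 + c(-(11:2), 2:11)] <- 1:20
  sp2 <- spectrum_from_amps(amps2)
  nw2 <- estimate_noise(sp2, 100 * 0.05, noise_params(), "ch1")
  expect_equal(nw2$mean, 10.5)
  expect_equal(nw2$sd, sd(2:19))               # 5.3385 (n-1 denominator)
  # grad-int window: 5 per side, 8 used bins
  nw3 <- estimate_noise(sp, 100 * 0.05, noise_params(5), "ch1")
  expect_length(nw3$amps, 8)
  # immediately adjacent bins are never candidates
  expect_false(any(abs(nw2$used_bins - 101) <= 1))
  expect_error(estimate_noise(sp, 5 * 0.05, noise_params(), "ch1"), "edge")
})

test_that("bin scores follow the Z / BCA / SNR definitions", {
  amps <- rep(2, 400)
  amps[101 + c(-(11:2), 2:11)] <- rep(c(1, 3), 10)   # mean 2, sd > 0
  sp <- spectrum_from_amps(amps)
  s <- score_bin(sp, 100 * 0.05, noise_params(), "ch1")
  expect_equal(s$z, 0)                # amp equals the noise mean
  expect_equal(s$bca, 0)
  expect_equal(s$snr, 1)
  # criterion boundary: amp = mean + 1.64 sd gives z = 1.64
  nw <- estimate_noise(sp, 100 * 0.05, noise_params(), "ch1")
  amps[101] <- nw$mean + 1.64 * nw$sd
  s2 <- score_bin(spectrum_from_amps(amps), 100 * 0.05, noise_params(), "ch1")
  expect_equal(s2$z, 1.64)
  # homogeneity: scaling the spectrum leaves z and snr unchanged,
  # scales bca
  s3 <- score_bin(spectrum_from_amps(3 * amps), 100 * 0.05, noise_params(),
                  "ch1")
  expect_equal(s3$z, s2$z)
  expect_equal(s3$snr, s2$snr)
  expect_equal(s3$bca, 3 * s2$bca)
  # degenerate windows are flagged
  s4 <- score_bin(spectrum_from_amps(rep(1, 400)), 100 * 0.05,
                  noise_params(), "ch1")
  expect_true(is.na(s4$z))
  expect_equal(s4$flag, "sd0")
})

test_that("summed responses add BCAs and z-score the aggregate", {
  set.seed(9)
  amps <- abs(rnorm(2000, 1, 0.1))
  i1 <- 201; i2 <- 401
  amps[i1] <- 1.3; amps[i2] <- 1.2
  sp <- spectrum_from_amps(amps)
  f1 <- (i1 - 1) * 0.05; f2 <- (i2 - 1) * 0.05
  s1 <- score_bin(sp, f1, noise_params(), "ch1")
  s2 <- score_bin(sp, f2, noise_params(), "ch1")
  # single harmonic: summed equals the single-bin quantities
  one <- summed_response(sp, f1, noise_params(), "ch1")
  expect_equal(one$summed_bca, s1$bca)
  expect_equal(one$summed_z, s1$z)
  # two harmonics: BCA adds
  both <- summed_response(sp, c(f1, f2), noise_params(), "ch1")
  expect_equal(both$summed_bca, s1$bca + s2$bca)
  expect_true(is.finite(both$summed_z))
  # overlapping windows warn rather than fail
  expect_warning(summed_response(sp, c(f1, f1 + 5 * 0.05), noise_params(),
                                 "ch1"), "overlap")
})

test_that("scale equivariance holds through the full quantification", {
  sim <- noiseless_sim(c("1" = 0.8), c("1" = 0.4, "2" = 0.2))
  des <- tiny_design()
  sp <- segment_spectra(sim$recording, des)[[1]]$spectrum
  rec3 <- sim$recording; rec3$data <- 3 * rec3$data
  sp3 <- segment_spectra(rec3, des)[[1]]$spectrum
  np <- noise_params(5)
  a <- summed_response(sp, harmonic_set("oddball"), np, "PO8")
  b <- summed_response(sp3, harmonic_set("oddball"), np, "PO8")
  expect_equal(b$summed_bca, 3 * a$summed_bca, tolerance = 1e-9)
})

test_that("injected amplitudes are recovered on pink noise at high SNR", {
  # low-noise regime: the BCA small-sample bias (about the per-bin noise
  # floor) is held below the assertion tolerance by design
  amps <- c("1" = 0.2, "2" = 0.1, "3" = 0.05, "4" = 0.05, "6" = 0.02)
  mont <- standard_montage(c("PO8", "P8", "VEOG"))
  des <- tiny_design()
  vals <- vapply(1:30, function(s) {
    sim <- simulate_recording(
      des, neural_spec(base_harmonic_amps = c("1" = 0.5),
                       oddball_harmonic_amps = amps,
                       base_topo = flat_topo(mont),
                       oddball_topo = flat_topo(mont)),
      noise_spec(noise_rms = 0.02, blink_rate = 0, seed = s), mont)
    sp <- segment_spectra(sim$recording, des)[[1]]$spectrum
    summed_response(sp, harmonic_set("oddball"), noise_params(5),
                    "PO8")$summed_bca
  }, numeric(1))
  expect_lt(abs(mean(vals) - 0.42) / 0.42, 0.03)
})

test_that("group harmonic selection finds the injected support", {
  amps_o <- c("1" = 0.5, "2" = 0.4, "3" = 0.3, "4" = 0.3, "6" = 0.2)
  mont <- standard_montage(c("PO8", "P8", "VEOG"))
  specs <- lapply(1:6, function(s) {
    sim <- simulate_recording(
      tiny_design(),
      neural_spec(base_harmonic_amps = c("1" = 1, "2" = 0.5),
                  oddball_harmonic_amps = amps_o,
                  base_topo = flat_topo(mont), oddball_topo = flat_topo(mont)),
      noise_spec(noise_rms = 0.3, blink_rate = 0, seed = s), mont)
    segment_spectra(sim$recording, tiny_design())[[1]]$spectrum
  })
  ga <- grand_average_spectrum(specs)
  got <- group_significant_harmonics(ga, "oddball", params = noise_params(5),
                                     channel = "PO8")
  expect_equal(got, c(1.2, 2.4, 3.6, 4.8, 7.2))
  gb <- group_significant_harmonics(ga, "base", params = noise_params(5),
                                    channel = "PO8")
  expect_equal(gb, c(6, 12))
  # grad-int mode bypasses the criterion and reuses the stock sets
  expect_equal(group_significant_harmonics(ga, "oddball", mode = "reuse"),
               c(1.2, 2.4, 3.6, 4.8, 7.2))
  expect_equal(group_significant_harmonics(ga, "base", mode = "reuse"),
               c(6, 12, 18))
})

test_that("individual thresholds are the first criterion crossing", {
  prof <- data.frame(intensity = c(20, 40, 60, 80, 100),
                     z = c(0.5, 1.0, 2.0, 2.5, 3.0))
  th <- individual_threshold(prof)
  expect_equal(th$threshold, 60)
  prof$z <- rep(1.0, 5)
  expect_true(is.na(individual_threshold(prof)$threshold))
  expect_error(individual_threshold(prof[-1, ]), "missing intensity")
  # emotions averaged, best channel recorded
  df <- expand.grid(intensity = c(20, 40, 60, 80, 100),
                    emotion = c("happy", "angry"),
                    channel = c("PO8", "P8"))
  df$z <- ifelse(df$channel == "PO8", df$intensity / 25, 0.1)
  th2 <- individual_threshold(df)
  expect_equal(th2$threshold, 60)    # 60 / 25 = 2.4 > 1.64, 40 / 25 < 1.64
  expect_true(all(th2$profile$channel == "PO8"))
})

test_that("grand averaging rejects mismatched binning", {
  a <- spectrum_from_amps(rep(1, 100))
  b <- spectrum_from_amps(rep(1, 101))
  expect_error(grand_average_spectrum(list(a, b)), "mismatched")
})
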