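# Waveforms, patch projection and calibrated sensor noise.

test_that("the default sinusoid has 180 samples and six cycles", {
  x <- sinusoid_waveform(20, 300, 600)
  expect_length(x, 180)
  expect_identical(x[1], 0)
  # zero-upcrossing cycle count
  expect_equal(sum(x[-length(x)] <= 0 & x[-1] > 0), 6)
  # the 30-samples-per-cycle grid never lands on the continuous peak;
  # the sampled maximum is sin(2*pi*7/30)
  expect_equal(max(abs(x)), sin(2 * pi * 7 / 30), tolerance = 1e-12)
  expect_error(sinusoid_waveform(400, 300, 600), "alias")
})

test_that("band-limited noise is seeded, unit-rms and spectrally confined", {
  w <- bandlimited_noise_waveform(1, 80, 300, 600, rng_seed = 5)
  expect_identical(w, bandlimited_noise_waveform(1, 80, 300, 600, rng_seed = 5))
  expect_false(identical(w, bandlimited_noise_waveform(1, 80, 300, 600, 6)))
  expect_equal(sqrt(mean(w^2)), 1, tolerance = 1e-9)
  # periodogram audit: out-of-band power < 1% of total
  n <- length(w)
  pw <- Mod(fft(w))^2
  fr <- (seq_len(n) - 1) * 600 / n
  fr <- pmin(fr, 600 - fr)
  out_band <- sum(pw[fr < 1 | fr > 80]) / sum(pw)
  expect_lt(out_band, 0.01)
  expect_error(bandlimited_noise_waveform(80, 1, 300, 600, 1), "band")
})

test_that("patch sources conserve the total moment and are linear", {
  anat <- small_anatomy()
  sp <- anat$space_combined; L <- anat$L_combined
  wv <- sinusoid_waveform()
  sv <- hippocampal_index(sp, 30)
  sim <- simulate_patch_source(sp, L, sv, wv)
  expect_equal(sum(sim$truth$moments), 20)
  expect_identical(sim$truth$structure, "hippocampal")
  # a vanishing patch degenerates to a single gain column
  sim1 <- simulate_patch_source(sp, L, sv, wv, fwhm_mm = 1e-3)
  expect_equal(sim1$data, (L$gain[, sv] * 20) %o% wv, tolerance = 1e-12)
  # linearity: doubling the total moment doubles the sensor data, and a
  # two-patch mixture is the exact sum of its single-patch simulations
  sim2x <- simulate_patch_source(sp, L, sv, wv, total_moment_nAm = 40)
  expect_equal(sim2x$data, 2 * sim$data, tolerance = 1e-12)
  expect_error(simulate_patch_source(anat$space_cortical, L, 5, wv), "match")
})

test_that("sensor noise hits the requested SNR exactly, per seed", {
  anat <- small_anatomy()
  wv <- sinusoid_waveform()
  sim <- simulate_patch_source(anat$space_combined, anat$L_combined,
                               hippocampal_index(anat$space_combined, 50), wv)
  for (snr in c(0, -5, -20)) {
    ds <- add_sensor_noise(sim$data, snr_db = snr, rng_seed = 9, truth = sim$truth)
    expect_equal(realized_snr_db(ds), snr, tolerance = 1e-9)
    noise <- ds$data - ds$noiseless
    expect_equal(mean(noise^2), mean(sim$data^2) / 10^(snr / 10),
                 tolerance = 1e-9)
  }
  # absolute-rms mode
  da <- add_sensor_noise(sim$data, absolute_rms = 10, rng_seed = 9)
  expect_equal(sqrt(mean((da$data - da$noiseless)^2)), 10, tolerance = 1e-9)
  expect_identical(add_sensor_noise(sim$data, snr_db = -5, rng_seed = 3)$data,
                   add_sensor_noise(sim$data, snr_db = -5, rng_seed = 3)$data)
  expect_error(add_sensor_noise(matrix(0, 4, 5), snr_db = 0), "zero-signal")
})

test_that("simulation batches draw valid, distinct seeds per structure", {
  anat <- small_anatomy()
  sp <- anat$space_combined; L <- anat$L_combined
  hb <- make_simulation_batch(sp, L, n = 30, structure = "hippocampal",
                              snr_db = -5, rng_seed = 4)
  seeds <- vapply(hb, function(d) d$truth$seed_vertex, integer(1))
  expect_length(unique(seeds), 30)
  expect_true(all(source_structures(sp)[seeds] == "hippocampal"))
  # neighbour-pairs seeds are exactly the nearest cortical vertices
  loc <- c(3L, 40L, 77L)
  nb <- make_simulation_batch(sp, L, n = 3, structure = "neighbour-pairs",
                              snr_db = -5, rng_seed = 4,
                              hippocampal_seeds = loc)
  want <- nearest_cortical_neighbours(sp, loc)$cortical_index
  got <- vapply(nb, function(d) d$truth$seed_vertex, integer(1))
  expect_identical(got, want)
  # 4H mixture: four hippocampal dipoles at 200 nAm each
  mx <- make_simulation_batch(sp, L, n = 2, structure = "mixture",
                              n_hippocampal = 4, rng_seed = 4)
  for (d in mx) {
    expect_length(d$truth_all, 4)
    for (tr in d$truth_all) {
      expect_identical(tr$structure, "hippocampal")
      expect_equal(tr$total_moment_nAm, 200)
    }
  }
  expect_error(make_simulation_batch(sp, L, n = 1e5, structure = "hippocampal",
                                     snr_db = 0, rng_seed = 1), "exceeds")
  # bit-exact reproducibility
  hb2 <- make_simulation_batch(sp, L, n = 30, structure = "hippocampal",
                               snr_db = -5, rng_seed = 4)
  expect_identical(hb, hb2)
})
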