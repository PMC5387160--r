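# Temporal reduction, covariance priors and ReML free-energy optimization.

test_that("temporal-mode reduction matches the SVD oracle", {
  anat <- small_anatomy()
  wv <- sinusoid_waveform()
  sim <- simulate_patch_source(anat$space_combined, anat$L_combined,
                               hippocampal_index(anat$space_combined, 25), wv)
  md1 <- reduce_temporal_modes(sim$data, 1)
  expect_equal(md1$retained_variance_fraction, 1, tolerance = 1e-9)
  ds <- add_sensor_noise(sim$data, snr_db = 0, rng_seed = 2)
  md <- reduce_temporal_modes(ds$data, 16)
  expect_equal(crossprod(md$mode_vectors), diag(16), tolerance = 1e-9)
  expect_equal(md$reduced_data, ds$data %*% md$mode_vectors)
  # reconstruction from k modes equals the best rank-k approximation
  sv <- svd(ds$data)
  best <- sv$u[, 1:16] %*% (sv$d[1:16] * t(sv$v[, 1:16]))
  recon <- md$reduced_data %*% t(md$mode_vectors)
  expect_equal(sum((ds$data - recon)^2), sum((ds$data - best)^2),
               tolerance = 1e-9)
  expect_error(reduce_temporal_modes(ds$data, 0), "n_modes")
})

test_that("MNE and EBB priors have the stated structure", {
  anat <- small_anatomy()
  pm <- build_prior_mne(anat$space_combined)
  expect_equal(pm$scheme, "MNE")
  expect_length(pm$components, 1)
  expect_equal(pm$components[[1]]$n, n_sources(anat$space_combined))

  sv <- hippocampal_index(anat$space_combined, 60)
  sim <- simulate_patch_source(anat$space_combined, anat$L_combined, sv,
                               sinusoid_waveform(), fwhm_mm = 1e-3)
  md <- reduce_temporal_modes(sim$data, 1)
  pe <- build_prior_ebb(anat$L_combined, md)
  q <- pe$components[[1]]$q
  expect_true(all(q > 0))
  expect_equal(max(q), 1)
  # strongest beamformer variance at the simulated vertex
  expect_equal(which.max(q), sv)
  # scale invariance of the normalized variance map
  md10 <- md; md10$reduced_data <- 10 * md$reduced_data
  expect_equal(build_prior_ebb(anat$L_combined, md10)$components[[1]]$q, q,
               tolerance = 1e-9)
})

test_that("MSP prior sets have one confined rank-1 component per seed", {
  anat <- small_anatomy()
  sp <- anat$space_combined
  seeds <- c(seq(5, 450, by = 5)[1:90], hippocampal_index(sp, 1:10))
  pr <- build_prior_msp(sp, seeds)
  expect_length(pr$components, 100)
  expect_error(build_prior_msp(sp, c(5, 5)), "duplicate")
  for (k in c(1, 50, 95)) {
    cmp <- pr$components[[k]]
    expect_identical(cmp$kind, "rank1")
    sup <- which(cmp$q > 0)
    # support confined to the truncated patch around the seed
    offs <- sp$vertex_offset
    mi <- if (seeds[k] >= offs[2]) 2L else 1L
    loc <- seeds[k] - offs[mi] + 1L
    pw <- patch_weights(sp$meshes[[mi]], loc, 6)
    expect_setequal(sup, which(pw$weights > 0) + offs[mi] - 1L)
    expect_equal(max(cmp$q), 1)
  }
})

test_that("ReML recovers known hyperparameter ratios on synthetic data", {
  # small dedicated forward model so the test isolates the optimizer
  set.seed(31)
  p <- 16L; ns <- 40L; N <- 3000L
  L <- matrix(rnorm(p * ns), p, ns)
  lf <- structure(list(gain = L, conductor_center = c(0, 0, 0),
                       source_space_ref = "cortical/40",
                       channel_names = sprintf("S%02d", 1:p)),
                  class = "lead_field")
  G <- tcrossprod(L) * (p / sum(diag(tcrossprod(L))))
  sig2 <- 4; noise2 <- 1
  Sg <- noise2 * diag(p) + sig2 * G
  Y <- t(chol(Sg)) %*% matrix(rnorm(p * N), p, N)
  md <- structure(list(reduced_data = Y, mode_vectors = diag(N)[, 1:N],
                       n_modes = N, retained_variance_fraction = 1),
                  class = "temporal_modes")
  pr <- list(scheme = "MNE", components = list(list(kind = "identity", n = ns)),
             component_labels = "mne")
  class(pr) <- "prior_component_set"
  r <- reml_optimize(md, lf, pr)
  ratio <- exp(r$hyperparameters[2] - r$hyperparameters[1])
  expect_equal(as.numeric(ratio), sig2 / noise2, tolerance = 0.1)
  expect_true(r$converged)
})

test_that("free energy is self-consistent and penalizes duplicate components", {
  anat <- small_anatomy()
  sp <- anat$space_combined; L <- anat$L_combined
  sv <- hippocampal_index(sp, 45)
  sim <- simulate_patch_source(sp, L, sv, sinusoid_waveform())
  ds <- add_sensor_noise(sim$data, snr_db = -5, rng_seed = 21, truth = sim$truth)
  md <- reduce_temporal_modes(ds$data, 1)
  pr <- build_prior_ebb(L, md)
  r <- reml_optimize(md, L, pr)
  expect_equal(r$free_energy, r$accuracy - r$complexity)
  expect_gte(r$complexity, 0)
  # independent objective evaluation at the returned hyperparameters
  fe <- evaluate_free_energy(md, L, pr, r)
  expect_equal(fe$F, r$free_energy, tolerance = 1e-6 * abs(r$free_energy))
  expect_equal(fe$accuracy, r$accuracy, tolerance = 1e-6 * abs(r$accuracy))
  # duplicating a component cannot raise the evidence bound
  pr2 <- pr
  pr2$components <- c(pr$components, pr$components)
  pr2$component_labels <- c("a", "b")
  r2 <- reml_optimize(md, L, pr2)
  expect_lte(r2$free_energy, r$free_energy + 0.5)
  # determinism: repeated runs are bit-identical
  expect_identical(reml_optimize(md, L, pr)$free_energy, r$free_energy)
})

test_that("variance explained behaves at its extremes", {
  anat <- small_anatomy()
  sp <- anat$space_combined; L <- anat$L_combined
  sim <- simulate_patch_source(sp, L, hippocampal_index(sp, 12),
                               sinusoid_waveform())
  md <- reduce_temporal_modes(sim$data, 1)
  r <- reml_optimize(md, L, build_prior_mne(sp))
  expect_gte(variance_explained(r, md), 99.9)   # noiseless, correct model
  expect_true(r$variance_explained_pct >= 0 && r$variance_explained_pct <= 100)
  r0 <- r
  r0$fitted <- r$fitted * 0
  expect_equal(variance_explained(r0, md), 0)
  md0 <- md
  md0$reduced_data <- md$reduced_data * 0
  expect_error(variance_explained(r, md0), "zero-data")
})
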