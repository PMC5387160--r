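# Ground-truth sensor-data simulation: source waveforms, Gaussian patch
# sources projected through the true lead field, and calibrated sensor
# noise (dB SNR or absolute rms). A noiseless copy is stored with every
# dataset so the realized SNR can be audited exactly.

#' Sinusoidal source waveform
#'
#' Unit-amplitude sine with zero phase at t = 0; the default parameters
#' (20 Hz for 300 ms at 600 Hz) give six full cycles in 180 samples.
#'
#' @param freq_hz oscillation frequency (must be below Nyquist).
#' @param duration_ms waveform duration.
#' @param fs_hz sampling rate.
#' @return numeric vector of `round(duration * fs)` samples.
#' @export
sinusoid_waveform <- function(freq_hz = 20, duration_ms = 300, fs_hz = 600) {
  if (freq_hz >= fs_hz / 2)
    stop("freq_hz at or above the Nyquist frequency: aliasing")
  n <- round(duration_ms / 1000 * fs_hz)
  sin(2 * pi * freq_hz * (seq_len(n) - 1) / fs_hz)
}

#' Band-limited Gaussian noise waveform
#'
#' White Gaussian noise brick-wall filtered in the frequency domain to
#' `[low_hz, high_hz]` and normalized to unit rms; deterministic per seed.
#'
#' @param low_hz,high_hz passband edges (Hz), `0 < low < high < fs/2`.
#' @param duration_ms duration.
#' @param fs_hz sampling rate.
#' @param rng_seed integer seed.
#' @return numeric vector with rms exactly 1.
#' @export
bandlimited_noise_waveform <- function(low_hz = 1, high_hz = 80,
                                       duration_ms = 300, fs_hz = 600,
                                       rng_seed = 1L) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs_hz / 2))
    stop("infeasible band: need 0 < low < high < fs/2")
  n <- round(duration_ms / 1000 * fs_hz)
  x <- with_seed(rng_seed, rnorm(n))
  freqs <- (seq_len(n) - 1) * fs_hz / n
  freqs <- pmin(freqs, fs_hz - freqs)          # two-sided frequency axis
  X <- fft(x)
  X[freqs < low_hz | freqs > high_hz] <- 0
  y <- Re(fft(X, inverse = TRUE)) / n
  y / sqrt(mean(y^2))
}

#' Project a Gaussian patch source through a lead field
#'
#' Distributes `total_moment_nAm` over a geodesic Gaussian patch centred
#' at `seed_vertex` (weights from [patch_weights()], normalized so the
#' per-vertex moments sum exactly to the total), and projects the
#' moment-weighted waveform through the gain matrix.
#'
#' @param space the generating `source_space`.
#' @param leadfield the matching `lead_field`.
#' @param seed_vertex index into the concatenated source list.
#' @param waveform numeric vector (source time course).
#' @param total_moment_nAm total effective dipole moment (default 20 nAm).
#' @param fwhm_mm patch full-width half-maximum (default 6 mm).
#' @return list with `data` (noiseless channels x samples, fT) and `truth`
#'   (seed vertex, structure, per-vertex moments, waveform, parameters).
#' @export
simulate_patch_source <- function(space, leadfield, seed_vertex, waveform,
                                  total_moment_nAm = 20, fwhm_mm = 6) {
  stopifnot(inherits(space, "source_space"), inherits(leadfield, "lead_field"))
  ns <- n_sources(space)
  if (ncol(leadfield$gain) != ns)
    stop("lead field does not match the source space (column count differs)")
  if (seed_vertex < 1 || seed_vertex > ns) stop("seed_vertex out of range")
  # locate the mesh owning the seed and compute patch weights on it
  offs <- c(space$vertex_offset, ns + 1L)
  mi <- findInterval(seed_vertex, offs[-length(offs)])
  local_seed <- seed_vertex - space$vertex_offset[mi] + 1L
  pw <- patch_weights(space$meshes[[mi]], local_seed, fwhm_mm)
  w <- numeric(ns)
  w[space$vertex_offset[mi] - 1L + seq_along(pw$weights)] <- pw$weights
  moments <- total_moment_nAm * w / sum(w)
  active <- which(moments > 0)
  topo <- leadfield$gain[, active, drop = FALSE] %*% moments[active]
  list(data = as.vector(topo) %o% waveform,
       truth = list(seed_vertex = as.integer(seed_vertex),
                    structure = source_structures(space)[seed_vertex],
                    moments = moments, waveform = waveform,
                    total_moment_nAm = total_moment_nAm, fwhm_mm = fwhm_mm))
}

#' Add calibrated Gaussian sensor noise
#'
#' Adds i.i.d. Gaussian white noise across channels and samples, scaled so
#' the realized SNR (10 log10 of mean signal power over mean noise power,
#' pooled over all channels and samples) equals `snr_db` exactly, or so
#' the noise rms equals `absolute_rms` exactly. The drawn noise matrix is
#' rescaled to its empirical power, so the requested level is met by
#' construction and can be audited from the stored noiseless copy.
#'
#' @param noiseless channels x samples matrix (fT).
#' @param snr_db target SNR in dB (power ratio convention), or NULL.
#' @param absolute_rms target noise rms in fT (used when `snr_db` is NULL).
#' @param rng_seed integer seed.
#' @param fs_hz sampling rate stored with the dataset.
#' @param truth ground-truth record (from [simulate_patch_source()]).
#' @return object of class `simulated_dataset`: `data`, `noiseless`, `fs`,
#'   `truth`, `snr_db` or `noise_rms`, `rng_seed`.
#' @export
add_sensor_noise <- function(noiseless, snr_db = NULL, absolute_rms = NULL,
                             rng_seed = 1L, fs_hz = 600, truth = NULL) {
  noiseless <- as.matrix(noiseless)
  sig_p <- mean(noiseless^2)
  if (!is.null(snr_db)) {
    if (sig_p == 0) stop("zero-signal input: SNR in dB is undefined")
    noise_p <- sig_p / 10^(snr_db / 10)
  } else {
    if (is.null(absolute_rms)) stop("give either snr_db or absolute_rms")
    noise_p <- absolute_rms^2
  }
  noise <- with_seed(rng_seed,
                     matrix(rnorm(length(noiseless)), nrow(noiseless)))
  noise <- noise * sqrt(noise_p / mean(noise^2))
  structure(list(data = noiseless + noise, noiseless = noiseless,
                 fs = fs_hz, truth = truth, snr_db = snr_db,
                 noise_rms = if (is.null(snr_db)) absolute_rms else NULL,
                 rng_seed = as.integer(rng_seed)),
            class = "simulated_dataset")
}

#' Realized SNR of a simulated dataset
#' @param dataset a `simulated_dataset`.
#' @return realized SNR in dB, from the stored noiseless copy.
#' @export
realized_snr_db <- function(dataset) {
  noise <- dataset$data - dataset$noiseless
  10 * log10(mean(dataset$noiseless^2) / mean(noise^2))
}

#' Simulate a batch of ground-truth datasets
#'
#' Draws seed vertices without replacement from the requested structure
#' and simulates one dataset per seed: single 20 nAm, 6 mm FWHM patches
#' with a 20 Hz / 300 ms sinusoid at the requested SNR (the core
#' condition), or four simultaneous band-limited dipoles for the mixture
#' condition.
#'
#' @param space the generating (combined) `source_space`.
#' @param leadfield the matching `lead_field`.
#' @param n number of datasets (default 30).
#' @param structure `"hippocampal"`, `"cortical"`, `"neighbour-pairs"`
#'   (cortical seeds nearest to a hippocampal draw) or `"mixture"`.
#' @param snr_db sensor-level SNR in dB (ignored for `"mixture"`).
#' @param rng_seed master seed for the batch.
#' @param n_hippocampal for `"mixture"`: how many of the 4 dipoles are
#'   hippocampal (0-4).
#' @param total_moment_nAm,fwhm_mm patch parameters for single-source modes.
#' @param absolute_rms sensor noise rms for `"mixture"` (default 10).
#' @param hippocampal_seeds optional fixed hippocampal-mesh vertex draws
#'   (local indices), e.g. to pair batches across conditions.
#' @return list of `simulated_dataset` objects.
#' @export
make_simulation_batch <- function(space, leadfield, n = 30,
                                  structure = c("hippocampal", "cortical",
                                                "neighbour-pairs", "mixture"),
                                  snr_db = -5, rng_seed = 1L,
                                  n_hippocampal = 4,
                                  total_moment_nAm = 20, fwhm_mm = 6,
                                  absolute_rms = 10,
                                  hippocampal_seeds = NULL) {
  structure_ <- match.arg(structure)
  stopifnot(inherits(space, "source_space"))
  labs <- source_structures(space)
  if (structure_ %in% c("hippocampal", "neighbour-pairs", "mixture") &&
      space$anatomy_kind != "combined")
    stop("this batch structure requires a combined source space")

  if (structure_ == "mixture") {
    nh <- as.integer(n_hippocampal)
    stopifnot(nh >= 0, nh <= 4)
    hip_pool <- which(labs == "hippocampal")
    cor_pool <- which(labs == "cortical")
    out <- vector("list", n)
    for (i in seq_len(n)) {
      si <- derive_seed(rng_seed, 900 + nh, i)
      picks <- with_seed(si, c(
        if (nh > 0) sample(hip_pool, nh) else integer(0),
        if (nh < 4) sample(cor_pool, 4 - nh) else integer(0)))
      noiseless <- 0
      truth_list <- list()
      for (k in seq_along(picks)) {
        wv <- bandlimited_noise_waveform(1, 80, 300, 600,
                                         rng_seed = derive_seed(si, 30 + k))
        mom <- if (labs[picks[k]] == "hippocampal") 200 else 100
        sim <- simulate_patch_source(space, leadfield, picks[k], wv,
                                     total_moment_nAm = mom, fwhm_mm = fwhm_mm)
        noiseless <- noiseless + sim$data
        truth_list[[k]] <- sim$truth
      }
      ds <- add_sensor_noise(noiseless, snr_db = NULL,
                             absolute_rms = absolute_rms,
                             rng_seed = derive_seed(si, 77),
                             truth = truth_list[[1]])
      ds$truth_all <- truth_list
      out[[i]] <- ds
    }
    return(out)
  }

  # single-source batches: draw seeds without replacement
  if (structure_ == "hippocampal") {
    pool_local <- seq_len(nrow(space$meshes[[2]]$vertices))
    if (n > length(pool_local)) stop("n exceeds available hippocampal vertices")
    loc <- hippocampal_seeds %||%
      with_seed(derive_seed(rng_seed, 101), sample(pool_local, n))
    seeds <- hippocampal_index(space, loc)
  } else if (structure_ == "neighbour-pairs") {
    pool_local <- seq_len(nrow(space$meshes[[2]]$vertices))
    if (n > length(pool_local)) stop("n exceeds available hippocampal vertices")
    loc <- hippocampal_seeds %||%
      with_seed(derive_seed(rng_seed, 101), sample(pool_local, n))
    nb <- nearest_cortical_neighbours(space, loc)
    seeds <- nb$cortical_index   # cortical mesh is first: global == local
  } else {
    pool <- which(labs == "cortical")
    if (n > length(pool)) stop("n exceeds available cortical vertices")
    seeds <- with_seed(derive_seed(rng_seed, 202), sample(pool, n))
  }
  wv <- sinusoid_waveform(20, 300, 600)
  lapply(seq_len(n), function(i) {
    sim <- simulate_patch_source(space, leadfield, seeds[i], wv,
                                 total_moment_nAm = total_moment_nAm,
                                 fwhm_mm = fwhm_mm)
    add_sensor_noise(sim$data, snr_db = snr_db,
                     rng_seed = derive_seed(rng_seed, 303, i),
                     truth = sim$truth)
  })
}
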