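# Experiment runner: anatomy presets, the SNR x co-registration grid, the
# nearest-cortical-neighbour control, the shifted-hippocampus battery and
# the multi-dipole mixture experiment. Every run is reproducible from
# (config, master seed): per-dataset seeds are derived by stable hashing
# of the cell coordinates and dataset index.

#' Anatomy / sensor presets
#'
#' `"desk"`: ~2000-vertex cortex + 162-vertex hippocampus, tractable on a
#' laptop. `"paper"`: 10595 + 162 vertices (the full-scale geometry).
#' Both use a 274-channel helmet.
#'
#' @param name `"desk"` or `"paper"`.
#' @return named list of preset parameters.
#' @export
hm_preset <- function(name = c("desk", "paper")) {
  name <- match.arg(name)
  switch(name,
         desk = list(name = "desk", n_cortex = 2000L, spacing_cortex = 3.7,
                     n_hippo = 162L, spacing_hippo = 3.69,
                     n_channels = 274L, helmet_standoff_mm = 18),
         paper = list(name = "paper", n_cortex = 10595L, spacing_cortex = 3.73,
                      n_hippo = 162L, spacing_hippo = 3.69,
                      n_channels = 274L, helmet_standoff_mm = 18))
}

#' Build the full study anatomy for a preset
#'
#' Generates the cortical and hippocampal meshes, the cortical and
#' combined source spaces, the sensor helmet, the fiducials, and the true
#' (zero co-registration-error) lead fields of both anatomical models.
#' The combined lead field's cortical block is bit-identical to the
#' cortical lead field.
#'
#' @param preset preset name or the list from [hm_preset()].
#' @param anatomy_seed seed for the mesh generators.
#' @param leadfields compute lead fields (default TRUE).
#' @return named list: `cortex`, `hippocampus`, `space_cortical`,
#'   `space_combined`, `sensors`, `fiducials`, `L_cortical`, `L_combined`,
#'   `preset`.
#' @export
build_study_anatomy <- function(preset = "desk", anatomy_seed = 1L,
                                leadfields = TRUE) {
  if (is.character(preset)) preset <- hm_preset(preset)
  cx <- generate_cortex_mesh(preset$n_cortex, preset$spacing_cortex,
                             seed = anatomy_seed)
  hp <- generate_hippocampus_mesh(preset$n_hippo, preset$spacing_hippo,
                                  seed = anatomy_seed, cortex_mesh = cx)
  spc <- build_source_space(cx)
  spb <- build_source_space(cx, hp)
  R <- cx$meta$sphere_radius
  sens <- meg_helmet_array(preset$n_channels,
                           helmet_radius_mm = R + preset$helmet_standoff_mm)
  fids <- fiducial_set(c(0, 0.95 * R, 0), c(-0.95 * R, 0, 0), c(0.95 * R, 0, 0))
  out <- list(cortex = cx, hippocampus = hp,
              space_cortical = spc, space_combined = spb,
              sensors = sens, fiducials = fids, preset = preset)
  if (leadfields) {
    out$L_combined <- assemble_leadfield(spb, sens)
    out$L_cortical <- structure(
      list(gain = out$L_combined$gain[, seq_len(preset$n_cortex), drop = FALSE],
           conductor_center = out$L_combined$conductor_center,
           source_space_ref = sprintf("cortical/%d", preset$n_cortex),
           channel_names = sens$channel_names),
      class = "lead_field")
  }
  out
}

#' Experiment configuration
#'
#' @param preset anatomy preset name (`"desk"` or `"paper"`).
#' @param snr_levels sensor-level SNR levels in dB.
#' @param coreg_std_levels fiducial-error standard deviations in mm.
#' @param schemes inversion schemes, subset of `c("MNE","EBB","MSP")`.
#' @param n_sims simulations per cell (default 30).
#' @param master_seed master seed; every per-dataset seed derives from it.
#' @param structure simulated-source structure for [run_grid()].
#' @param anatomy_seed seed for the mesh generators.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(preset = "desk",
                              snr_levels = -5,
                              coreg_std_levels = 0,
                              schemes = "EBB",
                              n_sims = 30L,
                              master_seed = 1L,
                              structure = "hippocampal",
                              anatomy_seed = 1L) {
  stopifnot(all(schemes %in% c("MNE", "EBB", "MSP")),
            all(coreg_std_levels >= 0), n_sims >= 1)
  structure(list(preset = preset, snr_levels = snr_levels,
                 coreg_std_levels = coreg_std_levels, schemes = schemes,
                 n_sims = as.integer(n_sims),
                 master_seed = as.integer(master_seed),
                 structure = structure,
                 anatomy_seed = as.integer(anatomy_seed)),
            class = "experiment_config")
}

# MSP seed plan for a run: 90 shared cortical patches (drawn once from the
# master seed), 10 extra cortical patches for the cortex-only model, and
# consecutive sets of 10 hippocampal patches covering the simulated seeds
# (each dataset's set contains its own simulated location).
msp_plan <- function(anat, master_seed) {
  ncx <- nrow(anat$cortex$vertices)
  shared <- with_seed(derive_seed(master_seed, 9001), sample(ncx, 90))
  extra_c <- with_seed(derive_seed(master_seed, 9002),
                       sample(setdiff(seq_len(ncx), shared), 10))
  list(shared = shared, extra_cortical = extra_c)
}

# hippocampal prior set of 10 for dataset i: its simulated (local) seed
# plus 9 companions drawn deterministically from the remaining vertices
msp_hip_set <- function(sim_local, n_hippo, master_seed, set_id) {
  comp <- with_seed(derive_seed(master_seed, 9100, set_id),
                    sample(setdiff(seq_len(n_hippo), sim_local), 9))
  c(sim_local, comp)
}

# invert one dataset under one scheme and both anatomical models,
# optionally under a co-registration transform of the inversion geometry.
# Returns the two inversion results plus localisation metrics.
invert_pair <- function(ds, anat, scheme, coreg_tf = NULL, n_modes = 1,
                        master_seed = 1L, dataset_id = 1L) {
  md <- reduce_temporal_modes(ds$data, n_modes)
  if (is.null(coreg_tf)) {
    spb <- anat$space_combined; spc <- anat$space_cortical
    Lb <- anat$L_combined; Lc <- anat$L_cortical
  } else {
    spb <- transform_source_space(anat$space_combined, coreg_tf)
    spc <- build_source_space(spb$meshes[[1]])
    Lb <- assemble_leadfield(spb, anat$sensors)
    ncx <- nrow(anat$cortex$vertices)
    Lc <- structure(list(gain = Lb$gain[, seq_len(ncx), drop = FALSE],
                         conductor_center = Lb$conductor_center,
                         source_space_ref = sprintf("cortical/%d", ncx),
                         channel_names = Lb$channel_names),
                    class = "lead_field")
  }
  if (scheme == "MNE") {
    rb <- reml_optimize(md, Lb, build_prior_mne(spb), model_label = "combined")
    rc <- reml_optimize(md, Lc, build_prior_mne(spc), model_label = "cortical")
  } else if (scheme == "EBB") {
    rb <- reml_optimize(md, Lb, build_prior_ebb(Lb, md), model_label = "combined")
    rc <- reml_optimize(md, Lc, build_prior_ebb(Lc, md), model_label = "cortical")
  } else {                              # MSP: constant source space,
    plan <- msp_plan(anat, master_seed) # priors define the model
    nhip <- nrow(anat$hippocampus$vertices)
    truth_global <- ds$truth$seed_vertex
    if (ds$truth$structure == "hippocampal") {
      loc <- truth_global - nrow(anat$cortex$vertices)
      hipset <- msp_hip_set(loc, nhip, master_seed, (dataset_id - 1L) %/% 10L)
      shared <- plan$shared
    } else {
      # cortical simulation: the 90 shared priors include the simulated patch
      shared <- unique(c(truth_global, plan$shared))[1:90]
      hipset <- msp_hip_set(1L, nhip, master_seed, 0L)
    }
    seeds_comb <- c(shared, hippocampal_index(spb, hipset))
    seeds_cort <- c(shared, setdiff(plan$extra_cortical, shared)[1:10])
    rb <- reml_optimize(md, Lb, build_prior_msp(spb, seeds_comb),
                        model_label = "combined")
    rc <- reml_optimize(md, Lb, build_prior_msp(spb, seeds_cort),
                        model_label = "cortical")
  }
  # localisation on the combined-model solution: truth position from the
  # true anatomy, argmax position from the (possibly transformed) space
  amp <- rb$posterior_source_amplitude
  amax <- which.max(amp)
  truth_pos <- space_vertices(anat$space_combined)$vertices[ds$truth$seed_vertex, ]
  est_pos <- space_vertices(spb)$vertices[amax, ]
  list(combined = rb, cortical = rc,
       dle_mm = vnorm(truth_pos - est_pos),
       winning_structure = source_structures(spb)[amax])
}

row_for <- function(ds_id, scheme, res, cell = list()) {
  base <- data.frame(dataset = ds_id, scheme = scheme,
                     anatomy = c("combined", "cortical"),
                     F = c(res$combined$free_energy, res$cortical$free_energy),
                     delta_F = res$combined$free_energy - res$cortical$free_energy,
                     variance_explained_pct = c(res$combined$variance_explained_pct,
                                                res$cortical$variance_explained_pct),
                     dle_mm = res$dle_mm,
                     winning_structure = res$winning_structure,
                     converged = c(res$combined$converged, res$cortical$converged),
                     stringsAsFactors = FALSE)
  for (nm in names(cell)) base[[nm]] <- cell[[nm]]
  base
}

#' Run the SNR x co-registration x scheme grid
#'
#' For every cell: simulate `n_sims` datasets on the true anatomy, draw a
#' per-dataset co-registration transform at the cell's fiducial-error
#' level (applied to the inversion geometry only), invert under both
#' anatomical models with the cell's scheme, and record free energies and
#' localisation metrics. One output row per (dataset, scheme, anatomy).
#'
#' @param config an [experiment_config()].
#' @param anat optional pre-built [build_study_anatomy()] output.
#' @return a `data.frame` results table.
#' @export
run_grid <- function(config, anat = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  anat <- anat %||% build_study_anatomy(config$preset, config$anatomy_seed)
  out <- list()
  for (snr in config$snr_levels) for (cstd in config$coreg_std_levels) {
    cell_seed <- derive_seed(config$master_seed, round(snr * 10), round(cstd * 10))
    batch <- make_simulation_batch(anat$space_combined, anat$L_combined,
                                   n = config$n_sims,
                                   structure = config$structure,
                                   snr_db = snr, rng_seed = cell_seed)
    for (scheme in config$schemes) {
      for (i in seq_along(batch)) {
        tf <- if (cstd > 0)
          coregistration_error_transform(anat$fiducials, cstd,
                                         derive_seed(cell_seed, 501, i))
        else NULL
        res <- tryCatch(
          invert_pair(batch[[i]], anat, scheme, coreg_tf = tf,
                      master_seed = config$master_seed, dataset_id = i),
          error = function(e) e)
        if (inherits(res, "error")) {
          warning(sprintf("inversion failed (dataset %d, %s): %s",
                          i, scheme, conditionMessage(res)))
          next
        }
        out[[length(out) + 1L]] <-
          row_for(i, scheme, res,
                  list(snr_db = snr, coreg_std_mm = cstd,
                       truth_structure = batch[[i]]$truth$structure,
                       truth_vertex = batch[[i]]$truth$seed_vertex,
                       seed = batch[[i]]$rng_seed))
      }
    }
  }
  do.call(rbind, out)
}

#' Nearest-cortical-neighbour control experiment
#'
#' Pairs each simulated hippocampal source with a simulation on its
#' euclidean-nearest cortical vertex (same waveform, moment, SNR) and
#' computes the anatomical free-energy difference for both arms with EBB
#' at SNR -5 dB and zero co-registration error.
#'
#' @param config an [experiment_config()] (`n_sims` pairs).
#' @param anat optional pre-built anatomy.
#' @param snr_db SNR for both arms (default -5).
#' @return `data.frame` with one row per (pair, arm, anatomy).
#' @export
run_neighbour_control <- function(config, anat = NULL, snr_db = -5) {
  stopifnot(inherits(config, "experiment_config"))
  anat <- anat %||% build_study_anatomy(config$preset, config$anatomy_seed)
  n <- config$n_sims
  nhip <- nrow(anat$hippocampus$vertices)
  loc <- with_seed(derive_seed(config$master_seed, 601), sample(nhip, n))
  hb <- make_simulation_batch(anat$space_combined, anat$L_combined, n = n,
                              structure = "hippocampal", snr_db = snr_db,
                              rng_seed = derive_seed(config$master_seed, 602),
                              hippocampal_seeds = loc)
  nb <- make_simulation_batch(anat$space_combined, anat$L_combined, n = n,
                              structure = "neighbour-pairs", snr_db = snr_db,
                              rng_seed = derive_seed(config$master_seed, 602),
                              hippocampal_seeds = loc)
  pairs <- nearest_cortical_neighbours(anat$space_combined, loc)
  out <- list()
  for (i in seq_len(n)) {
    for (arm in c("hippocampal", "neighbour")) {
      ds <- if (arm == "hippocampal") hb[[i]] else nb[[i]]
      res <- invert_pair(ds, anat, "EBB", master_seed = config$master_seed,
                         dataset_id = i)
      out[[length(out) + 1L]] <-
        row_for(i, "EBB", res,
                list(arm = arm, snr_db = snr_db, coreg_std_mm = 0,
                     truth_structure = ds$truth$structure,
                     truth_vertex = ds$truth$seed_vertex,
                     pair_distance_mm = pairs$distance_mm[i]))
    }
  }
  do.call(rbind, out)
}

#' Shifted-hippocampus model battery
#'
#' Inverts the same hippocampal datasets (EBB) under the cortical model,
#' the standard combined model, and the 24 shifted-hippocampus combined
#' models ({5, 10, 15, 20} mm x {x, y, z} x {+, -}): 26 models per
#' dataset. A mis-placed hippocampus should not beat the correctly placed
#' one.
#'
#' @param config an [experiment_config()].
#' @param anat optional pre-built anatomy.
#' @param snr_db SNR (default -5).
#' @param magnitudes_mm shift magnitudes (default `c(5, 10, 15, 20)`).
#' @return `data.frame` with one row per (dataset, model); `model` is
#'   `"cortical"`, `"combined"`, or the shift code (e.g. `"x+10"`).
#' @export
run_shift_battery <- function(config, anat = NULL, snr_db = -5,
                              magnitudes_mm = c(5, 10, 15, 20)) {
  stopifnot(inherits(config, "experiment_config"))
  anat <- anat %||% build_study_anatomy(config$preset, config$anatomy_seed)
  n <- config$n_sims
  batch <- make_simulation_batch(anat$space_combined, anat$L_combined, n = n,
                                 structure = "hippocampal", snr_db = snr_db,
                                 rng_seed = derive_seed(config$master_seed, 701))
  shifted <- shifted_hippocampus_models(anat$space_combined, magnitudes_mm)
  L_shift <- lapply(shifted, assemble_leadfield, sensors = anat$sensors)
  out <- list()
  for (i in seq_len(n)) {
    md <- reduce_temporal_modes(batch[[i]]$data, 1)
    Fc <- reml_optimize(md, anat$L_cortical,
                        build_prior_ebb(anat$L_cortical, md),
                        model_label = "cortical")$free_energy
    Fb <- reml_optimize(md, anat$L_combined,
                        build_prior_ebb(anat$L_combined, md),
                        model_label = "combined")$free_energy
    rows <- data.frame(dataset = i, model = c("cortical", "combined"),
                       F = c(Fc, Fb), stringsAsFactors = FALSE)
    for (nm in names(shifted)) {
      Fs <- reml_optimize(md, L_shift[[nm]],
                          build_prior_ebb(L_shift[[nm]], md),
                          model_label = "combined")$free_energy
      rows <- rbind(rows, data.frame(dataset = i, model = nm, F = Fs))
    }
    rows$F_cortical <- Fc
    rows$F_standard <- Fb
    rows$truth_vertex <- batch[[i]]$truth$seed_vertex
    rows$snr_db <- snr_db
    out[[length(out) + 1L]] <- rows
  }
  do.call(rbind, out)
}

#' Four-dipole mixture experiment
#'
#' Simulates four simultaneous band-limited (1-80 Hz) dipole patches at
#' cortex:hippocampus ratios 4:0 ... 0:4 (moments 100 nAm cortical /
#' 200 nAm hippocampal, absolute sensor noise 10 fT rms), inverts with
#' EBB and 16 temporal modes under both anatomical models, and records
#' the anatomical free-energy difference per dataset.
#'
#' @param config an [experiment_config()].
#' @param anat optional pre-built anatomy.
#' @param ratios hippocampal dipole counts to run (default 0:4).
#' @param n_modes temporal modes (default 16).
#' @param absolute_rms sensor noise rms (default 10 fT).
#' @return `data.frame` with one row per (ratio, dataset, anatomy).
#' @export
run_mixture_experiment <- function(config, anat = NULL, ratios = 0:4,
                                   n_modes = 16, absolute_rms = 10) {
  stopifnot(inherits(config, "experiment_config"))
  anat <- anat %||% build_study_anatomy(config$preset, config$anatomy_seed)
  out <- list()
  for (nh in ratios) {
    batch <- make_simulation_batch(anat$space_combined, anat$L_combined,
                                   n = config$n_sims, structure = "mixture",
                                   rng_seed = derive_seed(config$master_seed, 801, nh),
                                   n_hippocampal = nh,
                                   absolute_rms = absolute_rms)
    for (i in seq_along(batch)) {
      res <- invert_pair(batch[[i]], anat, "EBB", n_modes = n_modes,
                         master_seed = config$master_seed, dataset_id = i)
      out[[length(out) + 1L]] <-
        row_for(i, "EBB", res,
                list(n_hippocampal = nh, n_cortical = 4L - nh,
                     snr_db = NA_real_, coreg_std_mm = 0,
                     truth_structure = if (nh == 4) "hippocampal" else "cortical",
                     truth_vertex = batch[[i]]$truth$seed_vertex))
    }
  }
  do.call(rbind, out)
}

#' Group-level summary of a results table
#'
#' For each grid cell, runs random-effects BMS over the per-dataset
#' (F_cortical, F_combined) pairs and reports the mean free-energy
#' difference, the probability that the combined model wins, and the
#' Bayes omnibus risk.
#'
#' @param results a results table from [run_grid()].
#' @return `data.frame` with one row per (snr_db, coreg_std_mm, scheme).
#' @export
summarize_bms <- function(results) {
  stopifnot(all(c("F", "delta_F", "anatomy", "scheme") %in% names(results)))
  cells <- unique(results[, c("snr_db", "coreg_std_mm", "scheme")])
  out <- list()
  for (r in seq_len(nrow(cells))) {
    sub <- merge(results, cells[r, , drop = FALSE])
    wb <- sub[sub$anatomy == "combined", ]
    wc <- sub[sub$anatomy == "cortical", ]
    wb <- wb[order(wb$dataset), ]; wc <- wc[order(wc$dataset), ]
    bms <- rfx_bms(cbind(cortical = wc$F, combined = wb$F))
    out[[r]] <- cbind(cells[r, , drop = FALSE],
                      data.frame(n = nrow(wb),
                                 mean_delta_F = mean(wb$F - wc$F),
                                 prob_combined_wins = bms$prob_combined_wins,
                                 bor = bms$bor))
  }
  do.call(rbind, out)
}
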