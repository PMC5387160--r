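# Headline desk-scale runs shared by several acceptance checks: 30
# hippocampal and 30 cortical single-patch simulations at SNR -5 dB, no
# co-registration error, inverted under both anatomical models. Computed
# once per test run.

ACCEPT_SEED <- 20260926L %% 100000L

headline_runs <- function() {
  if (!is.null(.fixtures$headline)) return(.fixtures$headline)
  anat <- desk_anatomy()
  sp <- anat$space_combined
  hb <- make_simulation_batch(sp, anat$L_combined, n = 30,
                              structure = "hippocampal", snr_db = -5,
                              rng_seed = derive_seed(ACCEPT_SEED, 1))
  cb <- make_simulation_batch(sp, anat$L_combined, n = 30,
                              structure = "cortical", snr_db = -5,
                              rng_seed = derive_seed(ACCEPT_SEED, 2))
  n <- 30
  hip <- data.frame(dF_ebb = numeric(n), ve_mne = numeric(n),
                    ve_ebb = numeric(n), ve_msp = numeric(n),
                    dle_ebb = numeric(n))
  cort <- data.frame(dF_ebb = numeric(n), win = character(n),
                     stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    res <- hippomeg:::invert_pair(hb[[i]], anat, "EBB",
                                  master_seed = ACCEPT_SEED, dataset_id = i)
    md <- reduce_temporal_modes(hb[[i]]$data, 1)
    rM <- reml_optimize(md, anat$L_combined, build_prior_mne(sp),
                        model_label = "combined")
    rS <- hippomeg:::invert_pair(hb[[i]], anat, "MSP",
                                 master_seed = ACCEPT_SEED, dataset_id = i)
    hip$dF_ebb[i] <- res$combined$free_energy - res$cortical$free_energy
    hip$ve_mne[i] <- rM$variance_explained_pct
    hip$ve_ebb[i] <- res$combined$variance_explained_pct
    hip$ve_msp[i] <- rS$combined$variance_explained_pct
    hip$dle_ebb[i] <- res$dle_mm

    resc <- hippomeg:::invert_pair(cb[[i]], anat, "EBB",
                                   master_seed = ACCEPT_SEED, dataset_id = i)
    cort$dF_ebb[i] <- resc$combined$free_energy - resc$cortical$free_energy
    cort$win[i] <- resc$winning_structure
  }
  .fixtures$headline <- list(hippocampal = hip, cortical = cort)
  .fixtures$headline
}
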