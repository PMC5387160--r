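# hippomeg

Simulation framework for a deceptively hard question in MEG neuroimaging:
**can magnetoencephalography tell whether the hippocampus is active?** The
hippocampus is a small, deep, curved structure (~5 cm long, ~8–9 cm from
the nearest sensor), and source reconstruction is conventionally
constrained to the neocortical surface, so hippocampal currents — if
picked up at all — get mis-attributed to nearby cortex. `hippomeg`
implements the model-comparison approach to this problem: treat the
source-space anatomy itself as part of the generative model, invert the
same sensor data under a **cortex-only** model and a **cortex +
hippocampus** model, and ask which anatomy provides the better Bayesian
account of the data.

The package is aimed at MEG methodologists who want a fully synthetic,
fully reproducible sandbox for this inference: every mesh, sensor, source
and noise sample is generated by code from a seed, so every figure-style
result can be recomputed exactly.

## The model

Sensor data reduced to its dominant temporal mode(s) `Y` (channels ×
modes) are modelled as zero-mean Gaussian:

    Y ~ N(0, Σ),   Σ = exp(λ₀) I + Σᵢ exp(λᵢ) L Qᵢ Lᵀ

where `L` is the lead field of the candidate anatomy (spherical-conductor
forward model, dipoles oriented along the surface normals) and the source
covariance components `Qᵢ` encode one of three functional priors:

* **MNE** — a single identity component (equal prior variance everywhere);
* **EBB** — a single diagonal component with unit-gain beamformer
  variances estimated from the data;
* **MSP** — 100 rank-1 components, each a locally coherent geodesic patch
  (Gaussian profile, FWHM 6 mm).

Log-hyperparameters λ are optimized by ReML / Fisher scoring under broad
Gaussian hyperpriors, yielding the variational free energy

    F = accuracy − complexity  ≤  log p(Y | anatomy, scheme),

and anatomical models are compared by `ΔF = F_combined − F_cortical`;
`ΔF = 3` corresponds to ~20:1 posterior odds. Across a batch of
simulations, `rfx_bms()` runs random-effects Bayesian model selection
(variational Dirichlet) and reports the probability that the combined
model is the more frequent, plus the Bayes omnibus risk (BOR < 0.05
rejects "all models equally frequent").

The simulation side places 20 nAm, 6 mm-FWHM patch sources (20 Hz
sinusoid, 300 ms, 600 Hz sampling) on either mesh, adds calibrated
Gaussian sensor noise (0 to −20 dB SNR, or absolute fT rms), and can
corrupt the inversion anatomy with fiducial-based co-registration error
(0–3 mm) — the data themselves are never altered.

## Worked example

Five hippocampal patch sources at −5 dB SNR, inverted with the empirical
Bayes beamformer under both anatomies:

```r
library(hippomeg)
anat <- build_study_anatomy("desk")   # 2000 + 162 vertices, 274 sensors
cfg  <- experiment_config(n_sims = 5, master_seed = 1, schemes = "EBB")
tab  <- run_grid(cfg, anat)
aggregate(cbind(delta_F, variance_explained_pct, dle_mm) ~ anatomy, tab, mean)
#>    anatomy  delta_F variance_explained_pct   dle_mm
#> 1 combined 33.09348               99.08213 0.628082
#> 2 cortical 33.09348               99.04022 0.628082
summarize_bms(tab)
#>   snr_db coreg_std_mm scheme n mean_delta_F prob_combined_wins       bor
#> 1     -5            0    EBB 5     33.09348           0.984375 0.1578947
```

The mean `ΔF` of +33 nats says the combined anatomy is decisively the
better account of these hippocampal simulations (threshold 3 ≈ 20:1
odds); variance explained is ~99%, and the reconstruction maximum lands
essentially on the simulated vertex (mean localisation error 0.6 mm).
Repeating with `structure = "cortical"` sources gives `ΔF` near zero:
adding the hippocampal mesh is only rewarded when hippocampal activity is
actually present.

A command-line front end wraps the batteries
(`exec/hippomeg fixtures|grid|neighbours|shifts|mixture|bms`); meshes are
written as OBJ, sensors as a whitespace table, results as CSV.

## Layout

* `R/` — anatomy generators, forward model, simulation, inversion,
  comparison statistics, experiment runner
* `tests/testthat/` — unit, property and end-to-end acceptance tests
* `vignettes/hippocampal-model-comparison.Rmd` — methods notes: model,
  parameter choices, what the synthetic anatomy does and does not emulate
* `exec/hippomeg` — CLI entry point
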