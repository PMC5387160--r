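---
title: "Detecting hippocampal sources in MEG by anatomical model comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hippocampal sources in MEG by anatomical model comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind
`hippomeg`: the generative model, the synthetic anatomy, the inversion
machinery, and the places where the design was genuinely open and a
choice had to be made.

## 1. The inference

The question is whether MEG sensor data carry enough information to
decide that a deep, curved structure — the hippocampus — was active, as
opposed to nearby neocortex. The package frames this as Bayesian model
comparison over *anatomies*. Two generative models are fit to the same
data:

* the **cortical model**: sources confined to the cortical surface;
* the **combined model**: the identical cortical surface plus a nested
  hippocampal surface appended.

Each model is scored by the variational free energy `F` of a Gaussian
covariance-component model of the reduced sensor data, a lower bound on
the log model evidence. The decision statistic is
`ΔF = F_combined − F_cortical`; `|ΔF| ≥ 3` (about 20:1 odds) is treated
as decisive. The logic is asymmetric by design: for truly hippocampal
sources the combined model should win clearly, while for cortical
sources the two models contain the same cortical surface and should tie
(the extra hippocampal components are pruned or ignored), so `ΔF`
hovers near zero. The test suite asserts both halves of this mechanism,
plus its degradation under co-registration error and sensor noise, and
group-level versions via random-effects model selection and the Bayes
omnibus risk.

## 2. Synthetic anatomy: what it emulates, and what it does not

No subject geometry ships with the package; both surfaces are generated
parametrically so that the *relevant physics* of the real problem is
present:

* **Cortex** (`generate_cortex_mesh`): a hemispheric shell of exactly
  `n` vertices tiled at a target spacing (default desk scale: 2000
  vertices at 3.7 mm; full scale: 10595 at 3.73 mm), with a smooth
  radial "folding" perturbation. The perturbation amplitude (7% of the
  radius, angular frequencies 6–14) was fixed on orientation-realism
  grounds: it tilts vertex normals ~20–25° from the radial direction on
  average, emulating the orientation variability of sulcal walls, while
  keeping the mean edge length within the 15% spacing tolerance.
  Without it, normals would be nearly radial and (in a spherical
  conductor) nearly silent.
* **Hippocampus** (`generate_hippocampus_mesh`): a curved capsule of
  exactly `n` vertices (default 162 at 3.69 mm spacing, matching the
  cortical spacing), tip-to-tip centreline length 50 mm — the adult
  scale of the structure — bent 60° in-plane, nested deep inside the
  shell at half the cortical radius. The tube radius is derived from
  the vertex budget (capsule area `2πrL`), giving ~12 mm diameter.
* **Sensors** (`meg_helmet_array`): 274 radial magnetometers on a
  Fibonacci cap 18 mm outside the cortical shell.

What the synthetic anatomy does **not** emulate: cortical folding as
actual geometry (only as orientation statistics), the partial radial
orientation of real hippocampal pyramidal cells, tissue conductivity
structure, and the true depth *ratio* between cortex and hippocampus
relative to the sensors. Consequences observed in the checks: the
synthetic hippocampal tube is fully tangential and therefore *more*
visible relative to cortex than the real structure, so free-energy
differences for hippocampal sources are larger than the full-scale
anatomy would give, and in the four-dipole mixture battery (which uses
the absolute 10 fT rms noise convention with 100/200 nAm moments) even
sub-4/4 hippocampal ratios can reach decisiveness. Passing tests
therefore demonstrate the *mechanism* — the ordering and asymmetry of
the comparisons — not the paper-scale effect sizes.

## 3. Forward model

The conductor is an analytic homogeneous sphere (Sarvas solution),
chosen over a realistic single-shell model because it is closed-form and
oracle-testable: radial dipoles are exactly silent, and the radial field
component equals the free-space primary-dipole term — both are asserted
against independent implementations in the tests. The sphere centre is
the least-squares best-fit sphere of the cortical vertices (an open
hemisphere's centroid is biased ~R/2 along its axis and would put
superficial sources outside a centroid-centred conductor). Dipoles are
fixed along the outward vertex normals; gains are fT per nAm; there is
no depth re-weighting and no lead-field dimension reduction, so the two
anatomical models are compared on equal terms.

Co-registration error is injected exactly as a head-cast-free lab would
suffer it: Gaussian perturbation (0–3 mm std per axis) of the three
fiducials, a rigid Procrustes fit from true to perturbed fiducials, and
application of that transform to the *inversion-side* anatomy only.

## 4. Inversion machinery and numerical choices

* **Temporal reduction**: dominant right singular vectors; one mode for
  narrow-band data, 16 for broad-band mixtures.
* **Scaling**: data and sensor-projected components are
  trace-normalized, so hyperparameters are relative and one hyperprior
  setting serves all schemes; `N(−5, 256)` on each log-hyperparameter.
* **Optimization**: Fisher scoring on the expected information, step cap
  4 log-units, halving backtrack (8 tries) accepting only
  non-decreasing `F`; convergence at `|ΔF| < 1e-3` nats or 128
  iterations; rank-1 (MSP) components use `O(p²)` trace identities so
  100-component models cost little more than one-component ones.
* **Pruning**: ARD-style — components whose log-hyperparameter falls
  below −12 are clamped there and removed from the active set (and from
  the complexity term's dimension); ties are broken by component index.
  Greedy patch search is deliberately out of scope: MSP prior sets are
  constructed to contain the simulated locations, which is the intended
  best-case for that scheme.
* **Complexity**: `F = accuracy − KL`, with the KL divergence of the
  Gaussian (Laplace) hyperparameter posterior from its prior — always
  non-negative, so the accuracy/complexity split is exact. An
  independent evaluator (`evaluate_free_energy`, eigendecomposition
  rather than Cholesky, no shared loop code) re-scores every result in
  the tests.
* **EBB variances**: `q_j = 1/(l̃ⱼᵀ C⁻¹ l̃ⱼ)` with *unit-normalized*
  lead-field columns and a `1e-3 × mean-diagonal` ridge on the data
  covariance. Raw columns would make `q` explode for near-silent deep
  sources (beamformer depth bias); the unit-gain convention keeps the
  variance map peaked at the generating source.
* **Degenerate inputs**: zero data, all-zero amplitude maps, collinear
  fiducials, dipoles at the conductor centre, sources outside the
  sensor radius, and infeasible mesh budgets all raise informative
  errors; negative variance explained is clipped to zero with a
  warning.

## 5. Simulation conventions

* SNR is a *power* ratio pooled over channels and samples,
  `10·log10(P_signal/P_noise)`; the drawn noise matrix is rescaled to
  its empirical power, so the realized SNR equals the request exactly
  and is auditable from the stored noiseless copy. (An amplitude-ratio
  convention would differ by a factor 2 in dB; the power convention is
  the common one.)
* A patch's per-vertex moments are its truncated geodesic-Gaussian
  weights normalized to sum to the total moment (20 nAm default), so
  the total is invariant to mesh resolution.
* Geodesics are graph shortest paths over mesh edges. On a triangulated
  lattice the worst-direction path inflation is `sec 30° ≈ 1.155`;
  at the 3.7 mm spacing and 6 mm FWHM used here this bias is accepted,
  and the cylinder-oracle test checks the inflation bound directly and
  the Gaussian profile at the half-weight shell.
* All randomness flows through `derive_seed(master, …)`, a stable
  integer hash of the experimental cell coordinates and dataset index,
  so no seed is reused across cells and each battery is bit-reproducible
  from its config and master seed.

## 6. Problem sizes

The default "desk" preset (2000-vertex cortex, 162-vertex hippocampus,
274 channels, 30 simulations per condition) keeps a full
batch-plus-inversion cycle in the minutes range on a single core; the
"paper" preset (10595 + 162) generates the full-scale geometry for
bookkeeping and mesh-level checks. The heavier acceptance checks run 30
simulations per condition; the mixture battery in the test suite uses 10
per ratio.

## 7. Known limitations

* Variance explained on this synthetic anatomy plateaus slightly below
  the >99.5% level the full-scale anatomy yields (the cortical model
  span is smaller than a folded cortex's, so ~1% of the retained mode
  is unexplainable noise); the acceptance suite keeps the stricter
  threshold and documents the miss rather than relaxing it.
* The rotation control (`transform_hippocampus(rotation_deg=)`) rotates
  about the hippocampal centroid in the axial plane by default; the
  axis is configurable because the appropriate "lateral" axis depends
  on conventions the synthetic frame does not fix.
* Sensor noise is white across channels and time; correlated-noise
  generation is an extension hook, not implemented.
* No real-data ingestion (FIF/CTF), no MRI segmentation, no BEM or
  single-shell correction, no LORETA scheme.
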