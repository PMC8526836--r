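---
title: "From synaptic coupling to BOLD connectivity: methods behind dmfconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From synaptic coupling to BOLD connectivity: methods behind dmfconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmfconn)
```

## What the package models

`dmfconn` implements a complete in-silico pipeline linking a microscale
hypothesis — stronger excitatory synaptic coupling between brain regions —
to the macroscale observable it is meant to explain: elevated resting-state
fMRI functional connectivity. The pipeline has five stages, each exposed as
ordinary functions and each exercisable on synthetic data with known ground
truth:

1. a **dynamic mean-field (DMF) neural mass model** with feedback inhibition
   control (FIC);
2. a **Balloon–Windkessel hemodynamic forward model** producing BOLD signal;
3. a **global-coupling fit**: grid search of the scalar G that best matches
   a subject's empirical functional connectivity, plus a permutation group
   test on the fitted values;
4. **rsfMRI connectivity statistics** (weighted-degree "global
   connectivity" maps and their long-range variant, seed maps, Cohen's d,
   pooled-variance t maps with permutation cluster correction, occurrence
   maps, Dice overlap, motion censoring, covariate residualisation);
5. **imaging transcriptomics and subtyping**: decoding genes whose spatial
   expression tracks an imaging map, odds-ratio/hypergeometric enrichment
   against an interactome-derived gene set, and agglomerative subject
   subtyping with index majority voting.

## The neural model

Each region i is a coupled pair of excitatory (E) and inhibitory (I) pools
with input currents

$$I^{(E)}_i = W_E I_0 + w_+ J_{NMDA} S^{(E)}_i
  + G\, J_{NMDA} \textstyle\sum_j C_{ij} S^{(E)}_j - J_i S^{(I)}_i,$$
$$I^{(I)}_i = W_I I_0 + J_{NMDA} S^{(E)}_i - S^{(I)}_i,$$

firing rates through the sigmoidal transfer function
$H(I) = (aI-b)/(1-e^{-d(aI-b)})$ with pool-specific constants, and gating
dynamics

$$\dot S^{(E)} = -S^{(E)}/\tau_{NMDA} + (1-S^{(E)})\,\gamma\, r^{(E)} + \sigma v(t),
\qquad
\dot S^{(I)} = -S^{(I)}/\tau_{GABA} + r^{(I)} + \sigma v(t).$$

All constants take their conventional printed values (`dmf_parameters()`);
integration is Euler–Maruyama at dt = 1.2 ms with noise $\sigma\sqrt{dt}$
per step — the discretisation is a package choice, as the continuous-time
notation $\sigma v(t)$ does not prescribe one. We treat 1.2 ms as the
neural integration step (the output sampling grid is set separately by the
scanner TR); the step is a configurable argument throughout. Gating is
clamped to [0, 1] after every step, and an internal check aborts with a
simulation-failure error if a pre-clamp value leaves [-0.1, 1.1].

### Feedback inhibition control

FIC tunes the inhibitory weight $J_i$ so each region's mean excitatory rate
sits near 3 Hz despite the excitatory input it receives through the
connectome. Two implementation facts shaped the algorithm:

* **The balanced state must be solved, not just nudged.** A naive damped
  iteration $J_i \mathrel{+}= \eta\,(\bar r_i - 3)$ with small fixed η
  either crawls (hundreds of iterations) or overshoots into the model's
  *other* attractor: the coupled system is bistable, with a high-firing
  state that the trajectory falls into whenever inhibition is transiently
  too weak. `calibrate_fic` therefore starts from the closed-form
  balanced-state solution (`fic_fixed_point`): assume every region at the
  target rate, solve the inhibitory pool's scalar fixed point, and read
  $J_i$ off the current-balance equation. Each refinement trial then
  restarts the state from a common low-activity initial condition — the
  measured rate must be a function of J, not of which attractor the
  previous trial ended in — and applies a damped Newton step in current
  units, $\Delta J_i = \lambda (\bar r_i - r^*) / (H'(\bar I_i)\bar S^I_i)$,
  with per-region trust regions that halve when the deviation changes sign.
* **Convergence is declared on rates**, max deviation ≤ 0.15 Hz by default;
  exhausting `max_iter` returns `converged = FALSE` rather than an error,
  because supercritical G values legitimately have no balanced solution and
  the fitting stage must be able to scan past them.

### Stability and connectome normalisation

The balanced 3 Hz state loses stability when the collective excitatory loop
gain exceeds one. Empirically (scratch experiments reproduced in the tests)
the deterministic critical coupling obeys $G_c \cdot \rho(C) \approx 2.0$
for the standard parameters, where $\rho(C)$ is the spectral radius of the
structural matrix. The scale of C is therefore not a free detail: it decides
which G values are simulable. `make_connectome` fixes edge-level scale (mean
nonzero weight 1, log-normal weights, symmetric, zero diagonal) and
`normalize_connectome` fixes network-level scale, rescaling to spectral
radius 2.4 by default so that $G_c \approx 0.83$ — just above the
conventional search grid [0, 0.75], which then spans the subcritical branch
the way empirical whole-brain studies arrange their structural matrices.
Under the production noise level, stochastic escapes into the high-firing
attractor begin around G ≈ 0.55–0.6; the fitting grid may extend beyond
that (fitness values there are far from any subcritical empirical summary,
so the argmin is unaffected), but planted couplings for recovery studies
are kept at or below 0.5.

## Hemodynamics

The literature on this model family fixes the Balloon–Windkessel form but
not its constants; we adopt the canonical set (κ = 0.65 s⁻¹, γ = 0.41 s⁻¹,
τ = 0.98 s, α = 0.32, ρ = 0.34, V₀ = 0.02, k₁ = 7ρ, k₂ = 2, k₃ = 2ρ − 0.2).
The balloon input is the excitatory gating $S^{(E)}$ by default; whether
gating, rates, or currents drive the transform is genuinely underdetermined
in this literature, so `simulate_bold(drive = "rate")` exposes the main
alternative rather than hard-coding a guess. The balloon ODEs share the
neural dt; BOLD is sampled at the nearest integration step to each TR tick.

Two numerical choices matter in practice:

* **Burn-in.** The neural transient settles within ~2 s, but the balloon
  states approach their baseline over ~10 s, and that transient is *common
  to all regions*: with a short burn-in it dominates the variance and drives
  all interareal correlations toward 1. `simulate_bold` therefore discards
  20 s by default.
* The resting state (0, 1, 1, 1) is an exact fixed point, so zero drive
  yields identically zero BOLD — a property the tests assert to machine
  precision.

## Fitting the global coupling

`fit_G` mirrors the published procedure: for each grid value, calibrate
FIC, simulate repeated BOLD runs, average the mean upper-triangular Pearson
FC over repeats, and minimise the absolute difference to the subject's
empirical summary (ties toward smaller G). The summary is compared on the
r scale by default (a z-scale switch exists), and an optional Frobenius
mode was deliberately left out of the default path: the published fitness
is the scalar mean difference. Fitting is per subject; group comparisons
run a permutation t test on the per-subject optima with
$p = (1 + \#\{|t_\pi| \ge |t_{obs}|\})/(n_\pi + 1)$.

One design choice departs from naive replication: the simulation seeds are
**common random numbers across grid values** (each repeat reuses one noise
stream at every G). The fitness curve then varies smoothly in G and the
argmin reflects the mean structure rather than independent per-point noise —
a standard variance-reduction device in simulation-based calibration that
substantially tightens parameter recovery at fixed compute.

### Problem sizes used in the tests

Parameter recovery is verified on a 20-region synthetic connectome with
subjects planted at G = 0.3 and 0.5. The FC-vs-G slope is steep near
criticality and shallow deep in the subcritical range, so the two cases
need different data volumes for the same ±2-grid-step precision: the
G = 0.3 runs use 8000 s subject scans and 8 × 1000 s simulation repeats per
grid value, the G = 0.5 runs 2000 s and 5 × 400 s. These sizes follow from
the measured noise-to-slope ratios (FC standard deviation ≈ 0.02 at 300
samples against slopes of ≈ 1.4 and ≈ 4 per unit G respectively) and are
the package's chosen study conditions, stated here so the power of the
recovery checks is interpretable.

## Connectivity statistics

All estimators follow the field's standard definitions: Pearson FC with
Fisher's r-to-z (correlations clipped at 1 − 10⁻⁷ before atanh so maps stay
finite); global connectivity as the per-voxel mean z against all other
in-mask voxels, with the long-range variant excluding neighbours within a
strict physical radius (600 µm in the rodent application); Cohen's d with
df-pooled SD; Student (pooled-variance) t rather than Welch, matching the
procedure being reproduced; occurrence maps counting sites with d above
0.2. Cluster-level inference is a permutation max-statistic test: group
labels are permuted, the maximal suprathreshold-cluster extent (or mass)
forms the null, and observed clusters above its (1 − α) quantile are
retained. This replaces the Gaussian-random-field correction used by
external neuroimaging suites — a deliberate substitution, since the
permutation null is assumption-light and self-contained; adjacency defaults
to 6-connectivity on the voxel grid. Site and covariate adjustment is
fixed-effect OLS residualisation on an intercept, site indicators, and
covariates (the mixed-effects harmonisation used in large multi-site
mega-analyses is approximated by this fixed-effect form). Motion censoring
drops frames with framewise displacement above 0.2 mm and signals subject
exclusion through a typed condition when too few frames survive.

## Gene decoding and enrichment

Decoding regresses expression on the mean-centred imaging map per donor and
gene (expression as response, map as predictor; a per-donor z-scoring knob
exists because upstream decoding services do not document their
normalisation), then tests the donor-wise slopes against zero with a
two-sided one-sample t and retains genes with positive t surviving
Benjamini–Hochberg q < 0.05. Enrichment uses the 2 × 2 universe table:
odds ratio with Haldane–Anscombe correction only when a zero cell occurs,
and the inclusive upper hypergeometric tail P(X ≥ k) — the standard
over-representation convention. `fdr_bh` and `hypergeom_p` delegate to
`p.adjust` and `phyper`; the tests verify the tail against exhaustive
enumeration of all draws for universes up to 12.

## Subtyping

Subjects are clustered by complete-linkage agglomeration on Euclidean
distances between vectorised connectivity maps. Complete linkage is the
default because the heatmap tooling conventionally used for such analyses
defaults to it on a precomputed distance matrix; Ward and average linkage
are options, and the true linkage behind the published analysis is not
stated. The number of clusters is chosen by majority vote among six
internal indices (silhouette, Calinski–Harabasz, Davies–Bouldin, Dunn,
C-index, gap statistic) — a reimplementation in spirit of the 16-index
screens used in applied work, not a reproduction of any one package; ties
break toward smaller k. Per-cluster contrasts reuse the pooled-variance t
map against controls, and per-cluster enrichment repeats the decoding
pipeline on each contrast map with BH correction across clusters.

## What the synthetic data do and do not show

Every generator is a pure function of its arguments including the seed
(one master seed is split counter-style into substreams, so adding subjects
does not perturb earlier draws). The generators emulate the *statistical
skeleton* of each data type: connectomes are heavy-tailed symmetric
matrices, not anatomy; voxel data are region-latent signals plus i.i.d.
noise on a regular grid, with group hyperconnectivity planted as a common
latent loading — no scanner noise spectrum, no spatial autocorrelation
beyond region blocks, no motion artifacts; expression atlases plant exact
linear map-coupling in a known gene subset; subject maps plant exact
simplex-vertex prototypes. Passing tests therefore demonstrate that the
estimators recover planted truth under clean, correctly-specified
conditions — they do not certify behaviour under registration error,
physiological confounds, site batch structure beyond additive offsets, or
non-Gaussian noise.

## Known limitations

* No regional heterogeneity in neural or hemodynamic parameters; no
  plasticity; only G is fitted.
* The high-firing attractor is a real feature of the model: above the
  stochastic stability boundary FIC reports non-convergence and simulated
  FC saturates. Analyses that scan G should treat that regime as
  out-of-calibration rather than as data.
* The permutation cluster test controls family-wise error under
  exchangeability of subjects; it is not a spatial-specificity guarantee
  for individual voxels.
* Enrichment p values assume the decoded list and the target set were
  derived independently, as in the intended design.
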