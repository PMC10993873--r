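---
title: "Methods: tissue fate and perfusion analysis after experimental stroke"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue fate and perfusion analysis after experimental stroke}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokefate)
```

# Scope and model

`strokefate` quantifies post-recanalization cerebral hemodynamics in the rat
transient middle-cerebral-artery-occlusion (tMCAO) model from
multiparametric MRI. The pipeline takes co-registered native-space volumes —
two-point diffusion-weighted images (b = 0 and 1454 s/mm²), multi-echo
T2-weighted images (TE = 30/50/80/190 ms) and a dynamic susceptibility
contrast (DSC) time series (TR/TE = 164/13 ms, bolus at the 180th image) —
and derives, per subject and timepoint:

1. **Parametric maps.** A mean ADC map from monoexponential two-point fits
   along three gradient directions, and a T2 map from (optionally
   S²-weighted) log-linear least squares across the echoes.
2. **Perfusion maps.** CBF by oscillation-index-regularized block-circulant
   SVD deconvolution of tissue concentration curves against an arterial
   reference from the contralateral hemisphere; CBV by trapezoidal
   integration of the concentration curve truncated at the 400th image; MTT
   as CBV/CBF by the central volume theorem. All perfusion values are in
   relative units — the analysis only ever uses contralateral-referenced
   ratios, so the unknown arterial proportionality cancels.
3. **Lesion masks and tissue fates.** Acute ischemic tissue is segmented as
   ADC < x̄ − 2·sd and the subacute infarct as T2 > x̄ + 2·sd, where x̄ and
   sd are taken over the contralateral MCA territory (S1FL, S2, CPu) after
   CSF exclusion; thresholds are strict on both sides. Fates follow from
   set algebra: core = acute ∩ subacute, salvageable = acute \ subacute,
   delayed injury = subacute \ acute. Contralateral homologues are exact
   midline reflections.
4. **Perfusion profiles.** Relative regional indices
   (rrCBF/rrCBV/rrMTT = 100 × ROI mean / homologue mean) and voxel-class
   fractions after repercentaging each map to the contralateral median:
   hyperperfused above 115%, hypoperfused below 85%, boundaries and the
   interior band normoperfused, with the hypo/hyper convention reversed for
   MTT. The fraction triple of each ROI sums to one exactly.
5. **Outcome models.** Kenward-Roger linear mixed models of the rr indices
   over timepoint, occlusion duration (45/90 min) and sex; beta-family
   GLMMs (log link) of the voxel-class fractions over hemisphere, ROI and
   time; and AICc-ranked multi-model inference of lesion volume change
   (100 × (V_T2 − V_ADC)/V_ADC) and the sensorimotor deficit score
   (SDS, 0–22, Poisson/log), across the perfusion configurations
   {rrCBF & rrCBV}, {rrMTT}, {rrCBV}, {rrCBF}, a base model without
   perfusion terms, and the intercept-only NULL model. rrMTT is never
   combined with rrCBF or rrCBV because it is their quotient.

Subjects whose acute lesion is smaller than 30 µL are flagged excluded.

# Synthetic data: what it emulates and what it does not

Because every stage must be verifiable without animal data, the package
generates its own ground truth at two levels.

**Phantoms** (`make_phantom()`) are two-hemisphere ellipsoidal "brains" on a
grid whose first axis has even length, so the midline is a grid plane and
mirroring is an exact voxel permutation. Labels (cortex, S1FL, S2, CPu,
striatum, thalamus, ventricular CSF, arterial voxels) are defined on the
mirrored lateral coordinate and are therefore exactly symmetric. Tissue
values are conventional rodent magnitudes at high field (cortical ADC
0.75×10⁻³ mm²/s, T2 ≈ 48 ms, MTT 1.6–1.8 s); CBV is stored as CBF × MTT and
MTT re-derived as CBV/CBF so the central-volume identity holds bit-exactly.
An acute and a subacute ellipsoid with configurable volume change and
offset plant all three fates with known masks; lesion ADC is reduced
≥ 30% and subacute T2 elevated ≥ 30%, several reference SDs away from
contralateral tissue.

**Acquisitions** follow the forward models the fitters invert:
S(b) = S0·e^(−b·ADC), S(TE) = S0·e^(−TE/T2), and for DSC
C(t) = CBF·(AIF ⊛ R)(t)·Δt with a gamma-variate AIF
A·(t−t0)^α·e^(−(t−t0)/β) (α = 3, β = 1.5 s, bolus pinned to frame 180) and
exponential (or boxcar) residue with R(0) = 1, so the flow-scaled residue
peaks exactly at CBF and the trapezoidal residue integral equals MTT to
O(Δt²). The AIF amplitude default (0.09) was set so that healthy-tissue
peak signal drops are physiological (≈ 40% at TE = 13 ms); arterial voxels
carry the input function directly (scaled so their signal drop is deep),
as arterial signal reflects arterial concentration rather than a convolved
tissue curve. Noise is additive Gaussian by default (Rician optional); at
the SNRs studied the difference is negligible and Gaussian keeps the
oracles simple. The simulator does **not** model realistic anatomy,
partial-volume effects, motion, registration error, bias fields or
contrast recirculation — passing tests certify the algorithms under the
stated forward models, not robustness to those artifacts.

**Cohorts** exist at two levels. `make_cohort()` draws per-subject metric
tables directly, with cell means emulating the reported effect structure:
volume-change means averaging to about −31% (female) vs −8% (male) with
between-subject SD near 30, hyperacute rrCBF coupling positively
(standardized +15.5) and rrCBV negatively (−16.8) to volume change, rrMTT
carrying no independent effect, perfusion collapsing to ~35% of
contralateral during occlusion and overshooting by day 4 (more in males),
delayed-injury tissue relatively hypoperfused at 0.5 h (ipsilateral hypo
fraction 0.20 vs 0.05 contralaterally, beta precision 20), and SDS linked
to lesion evolution on the log scale. `simulate_subject()` plants the same
structure at the image level and runs it through raw acquisitions.

# Numerical choices in the deconvolution

The deconvolution is the one stage where numerical policy materially
affects the result, so the choices are spelled out.

* **Discretization.** Curves of length L (the window from 15 frames before
  the bolus to the end of the series) are zero-padded to 2L; the
  block-circulant matrix of the AIF (frame interval folded in) is
  decomposed once per AIF by SVD.
* **Matched smoothing.** Tissue curves and the AIF are both smoothed with
  the same 5-frame moving average before deconvolution. Because
  convolution commutes, filtering both sides leaves the underlying residue
  mathematically unchanged while suppressing frame-to-frame noise at this
  short TR (164 ms); setting `smooth_width = 1` disables it.
* **Adaptive truncation.** For each voxel the retained number of singular
  components is chosen over a 64-point log-spaced grid, scanned from
  strong regularization toward the full spectrum. A candidate is
  admissible when (a) the oscillation index of the reconstructed residue,
  OI = Σ|r(k) − 2r(k+1) + r(k+2)| / (L·max r), stays at or below 0.17, and
  (b) the residue's negative excursion stays within 30% of its peak. The
  least-regularized admissible candidate is selected; if none is
  admissible the strongest regularization on the grid is used. The
  oscillation index targets high-frequency noise ringing but is
  structurally blind to the smooth, spike-like blow-up that truncated
  circular deconvolution develops when curves have not fully decayed
  within the acquisition; residue functions are nonnegative up to
  filtering ripple, so the negative-lobe bound is the physiological guard
  against exactly that failure mode. The OI formula is pluggable
  (`oi_fun`) for variant normalizations.
* **Operating accuracy.** Under these defaults, 1000 voxels with CBF
  uniform in 20–100 (arbitrary units) and MTT uniform in 2–10 s, simulated
  through the full signal chain, are recovered noiselessly with a median
  absolute CBF error near 3% and mean bias near −3% (worst voxels ≈ 7%, at
  the short-MTT end, the classic SVD underestimation); at baseline
  SNR 50 the median absolute CBF error is ≈ 13%. These figures are
  recomputed by `scripts/acceptance.R` and the test suite rather than
  asserted here.
* **CBV.** Negative concentration values are retained in the deconvolution
  (preserving the linear-systems assumptions) but clipped to zero for the
  truncated CBV integral. With noise this clipping biases CBV upward and
  the CBF truncation biases flow downward, so absolute noisy MTT estimates
  are biased long; both biases cancel to first order in the
  contralateral-relative indices the analysis actually reports, which is
  the same reason the study design normalizes everything to the
  contralateral hemisphere.
* **AIF selection.** The automated arterial reference ranks contralateral
  voxels by peak height, arrival frame and curve first moment (rank sums,
  voxel index as the deterministic tiebreak), computed on smoothed curves
  restricted to the post-bolus window so baseline noise cannot fake an
  early arrival; the top 10 curves are averaged. A manual AIF can be
  supplied (`aif_override`).

# Statistical layer

Kenward-Roger F-tests are computed as nested-model comparisons
(`pbkrtest::KRmodcomp`, full model against the model with the term
dropped), which is the same statistic as the per-term KR ANOVA but an order
of magnitude faster across simulations; Satterthwaite is available as a
fallback. A singular random-intercept fit downgrades to a fixed-effects
model with a warning. Beta-family GLMMs use glmmTMB with a log link;
boundary fractions are compressed by (y·(n−1) + 0.5)/n before fitting
because the beta likelihood excludes exact 0 and 1, and the log-link
intercept is started at log(mean y) because the default start sits on the
boundary of the valid mean space. AICc counts all estimated parameters,
including the intercept and the gaussian residual variance. The F-test
column of the model ranking is a nested-model test against the base
(no-perfusion) model — for the Poisson outcome a likelihood-ratio
chi-square — and Nagelkerke R² is reported for the Poisson branch. The SDS
model has no offset: the score is a bounded sum, not a rate.

One genuine design tension deserves record. The central volume theorem
ties rrMTT to rrCBV/rrCBF; in our own image-level pipeline the decoupling
between rrMTT and 100·rrCBV/rrCBF (mean-of-ratios vs ratio-of-means plus
estimation noise) has an SD of only ~2 points. Under that physiological
tie, and with near-equal-and-opposite planted couplings on rrCBF and
rrCBV, the single-parameter rrMTT configuration is a near-perfect proxy
for the two-parameter generating configuration and wins the AICc ranking
in roughly a third of simulated cohorts — an exact analogue of the
published ranking, where those two configurations sit ~2 AICc apart.
Recovering the generating configuration is therefore only a well-posed
check when rrMTT varies independently, which is what
`cohort_effect_spec(mtt_model = "independent")` provides; the default
(`"ratio"`) keeps the physiological tie.

# Defaults, units and degenerate inputs

| Parameter | Default | Units | Note |
|---|---|---|---|
| lesion threshold | 2 | contralateral SD | strict `<`/`>` |
| binning band | 85–115 | % of contralateral median | boundaries normo; reversed for MTT |
| oscillation index | 0.17 | – | per-voxel admissibility bound |
| negative-lobe bound | 0.30 | fraction of residue peak | deconvolution guard |
| smoothing width | 5 | frames (0.82 s) | applied to tissue and AIF alike |
| CBV truncation | 400 | frame ordinal (1-based) | frames beyond are ignored bit-exactly |
| baseline window | 20–170 | frame ordinals | before the bolus at frame 180 |
| CSF cutoffs | ADC > 1.2×10⁻³ mm²/s, T2 > 90 ms | – | plus atlas CSF labels |
| cleanup | 8 voxels, closing radius 1 | – | deterministic surrogate for manual correction |
| inclusion | 30 | µL acute lesion | subjects below are flagged excluded |

Frame ordinals from the acquisition protocol ("180th image", "400th
image") are 1-based throughout the user interface. Degenerate inputs are
contracts, not surprises: a zero tissue curve yields CBF = 0; zero flow
masks MTT rather than dividing; a constant reference region, an empty
baseline window, an all-zero AIF, an empty ROI, a zero homologue mean and
a non-positive acute volume all raise errors; non-positive signals are
dropped from fits rather than clipped.

# Problem sizes used by the tests

The shipped test-suite and acceptance script run on deliberately compact
problems chosen to exercise every code path: 24³-scale phantoms
(≈ 0.5 µL voxels, ≈ 500 µL hemispheres, ≈ 100 µL lesions), 1000-voxel
deconvolution experiments, 500–1000 simulated null cohorts for test
calibration, 200-replicate recovery checks, and a 40-subject image-level
cohort for the end-to-end run. Larger volumes change nothing structurally:
all stages are linear or near-linear in voxel count except the
deconvolution, whose cost is one SVD per AIF plus two matrix products per
subject-timepoint.

# Known limitations

* The T2 fitter is a magnitude-domain log-linear fit; complex-data fitting
  is not implemented. With the last echo near the noise floor the
  unweighted fit is unstable — the pipeline uses S² weights by default.
* Absolute CBF/CBV are relative units by design; only
  contralateral-referenced quantities are interpretable.
* The deconvolution underestimates flow at MTT below ~2 sampling
  intervals, as truncated-SVD methods do.
* Automated mask cleanup replaces manual noise correction; its parameters
  are logged, but it is not a model of expert editing.
* The synthetic cohort encodes effect directions and magnitudes, not the
  full covariance structure of real cohorts; statistical-power statements
  transfer only to the extent those magnitudes are realistic.
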