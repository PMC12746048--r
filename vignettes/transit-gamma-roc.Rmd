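---
title: "Gamma criteria for transit dosimetry: models, simulator and ROC analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gamma criteria for transit dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transitgamma)
```

## The problem

EPID transit dosimetry verifies a radiotherapy delivery *in vivo*: the
flat-panel imager behind the patient records the treatment beam after it has
traversed the anatomy, and the resulting transit dose image is compared with
a prediction. Any event that changes either the fluence leaving the linac
(wrong MLC aperture, wrong monitor units) or the attenuation along the beam
path (wrong breathing phase, wrong patient, wrong planning CT, missing
bolus) shows up as a discrepancy between the two images.

The comparison is almost universally a 2D gamma analysis, and the clinical
question is which gamma criterion — dose-difference tolerance, distance to
agreement (DTA), global or local normalization — and which passing-rate
tolerance make the test *sensitive* to deviations that matter (say, a PTV
mean-dose change above 10%) while remaining *specific* (not flagging
harmless deliveries). `transitgamma` treats this as a classification
problem: simulate failure modes of known dosimetric magnitude, score each
with every candidate gamma metric, and read the operating characteristics
off ROC curves.

## The gamma index engine

For a reference image $D_r$ and an evaluated image $D_e$, the gamma value at
a reference point $\mathbf{r}$ is

$$\gamma(\mathbf{r}) \;=\; \min_{\mathbf{r}'}
\sqrt{\frac{\lVert \mathbf{r}' - \mathbf{r} \rVert^2}{\delta^2}
      + \frac{\bigl(D_e(\mathbf{r}') - D_r(\mathbf{r})\bigr)^2}{\Delta^2}},$$

where $\delta$ is the DTA tolerance in mm and $\Delta$ the absolute dose
tolerance. With **global** normalization $\Delta$ is a fixed percentage of
the normalization dose; with **local** normalization it is the same
percentage of $D_r(\mathbf{r})$, which tightens the test wherever the local
dose is below the maximum — hence local passing rates can never exceed
global ones at the same percentage. A point passes when $\gamma \le 1$, and
the passing rate is the percentage of analysed points that pass.

Conventions the engine fixes (each was a genuinely open choice):

* **Normalization dose = maximum of the reference image.** Commercial
  systems differ (plan maximum, evaluated maximum, prescription); the
  reference maximum is self-contained and is reported in every
  `gamma_result` so downstream consumers know what the percentages mean.
* **Pass rule $\gamma \le 1$**, not $\gamma < 1$. Ties are measure-zero on
  measured data but decide the uniform-field edge case (a 3% offset under a
  3% tolerance); the inclusive convention matches common clinical software.
  `pass_limit` is a parameter, so the strict rule is one argument away.
* **Low-dose threshold** (default 20% of the normalization dose) excludes
  reference points only; it is relative, which makes the whole analysis
  invariant under joint rescaling of both images.

### Numerical search

The evaluated image is interpolated bilinearly and minimized over a disc
around each reference point. The search has three accuracy controls:

* coarse step `min(pixel spacing, DTA/10)`;
* search radius `gamma_cap * DTA` (default cap 2): beyond it the distance
  term alone exceeds the cap, and values above the cap are reported as the
  cap;
* a pattern-search refinement around the best coarse offset (3×3 stencil,
  step halved seven times), because the coarse lattice alone leaves errors
  of order 0.1 near sharp minima.

Reference points whose search disc pokes out of the evaluated extent are
minimized over the available region; points with no evaluated coverage at
all are excluded and flagged `NA`. The comparison is deliberately
asymmetric — swapping reference and evaluated changes the answer — and no
test in the package assumes otherwise.

`brute_force_gamma()` is the package's independent oracle: a plain-R
exhaustive scan over the evaluated image upsampled bilinearly by a chosen
factor, restricted (provably without loss, given the cap) to the same disc.
On 16×16 smooth random field pairs with an upsample factor of 32 the two
engines agree within 0.02 per point and 0.5 percentage points of passing
rate; those sizes were chosen so the whole 51-pair comparison runs in well
under a minute.

## The synthetic failure-mode suite

No public dataset pairs predicted transit images with deliberately injected
errors, so the package generates its own with a transparent forward model:

$$D(x,y) = k \cdot \mathrm{MU} \cdot
\bigl[A \ast G_\sigma\bigr](x,y)\cdot e^{-\mu\, t_{\mathrm{eff}}(x,y)},$$

an open-air fluence (MLC-and-jaw aperture mask $A$, rasterized with
sub-pixel weighting and blurred by a Gaussian penumbra $G_\sigma$)
attenuated through the patient's density-weighted water-equivalent
thickness $t_{\mathrm{eff}}$. Defaults, chosen once as desk-scale stand-ins
for a 6 MV beam at the imager plane: 256×256 grid at 1 mm, $\mu = 0.005$
per mm water-equivalent, $\sigma = 3$ mm, and $k$ calibrated per base plan
so the base transit maximum is 100 dose units. The model captures exactly
the physics transit dosimetry reacts to — fluence and attenuation changes —
and nothing else (no scatter, no beam hardening, no detector response).

The default suite reproduces the study composition of 22 erroneous
deliveries:

1. **Linac hardware/output (11).** A head-and-neck-like patient with a
   modulated multi-segment beam (eight control-point apertures whose
   pseudo-random per-leaf insets block part of the target per segment, as a
   modulated arc does). Errors: MLC aperture ±1.0 / ±1.5 mm (each bank
   moves half the magnitude, so the gap changes by the full magnitude),
   +2 / +5 mm restricted to the central leaves (defined as the middle third
   of the open leaf pairs — a configurable convention), collimator ±1°,
   MU ±2%, and a retracted-MLC incident in which every leaf is parked
   behind the jaws at unchanged MU: because the base fluence is modulated,
   the open jaw field delivers far more dose than the plan.
2. **Breathing management (6).** A lung-SBRT thorax whose diaphragm, tumor
   and lung density ride a sinusoidal phase displacement (amplitude 25 mm;
   lung density 0.15 at full inspiration to 0.45 at full expiration —
   deliberately wide, so that the inspiration↔expiration mismatch produces
   a mean-dose change above 10%, as severe phase errors do). Plans built on
   the inspiration and expiration CTs are each "delivered" on the alternate
   phase, on a 30–60% expiration-averaged CT and on an all-phase average CT
   (averaged CTs are implemented as weighted means of the per-phase
   effective thickness maps). Delivering in expiration what was planned in
   inspiration puts soft tissue where lung was expected, so the transit
   dose drops; the converse delivery raises it.
3. **Patient identification (2).** Two breast patients that differ
   structurally (laterality, mound size, chest-wall thickness) with small
   seeded jitter on top; each patient's plan is delivered on the other.
   The structural difference guarantees both a geometric target miss and a
   large attenuation change for every seed.
4. **Wrong CT / wrong adapted plan (2).** A palliative lung patient whose
   pleural-fluid region either holds fluid (density 1) or aerated lung
   (density 0.25); each CT's plan is delivered on the other anatomy.
5. **Bolus (1).** A breast plan with a 10 mm bolus slab, delivered without
   it.

### The surrogate label

Each scenario carries a scalar stand-in for the planning-system PTV mean
dose: the mean over the *planned* PTV mask of the fluence attenuated to
mid-depth, $k\,\mathrm{MU}\,[A\ast G_\sigma]\,e^{-\mu t_{\mathrm{eff}}/2}$.
It is exactly linear in MU (a +2% MU error labels exactly +2.0%) and
monotone in any attenuation change over the target — all the ROC stage
needs from a label. It is *not* a dose calculation: buildup and scatter
effects are absent, which is most visible for the bolus scenario, whose
label is $e^{\mu b/2}-1 \approx +2.5\%$ for a 10 mm bolus even though a
treatment planning system would report a much larger coverage change from
the loss of buildup. The bolus scenario therefore sits in the small-label
band while still perturbing the transit image by ~5% under the footprint.

Determinism: the suite is a pure function of (config, seed); per-scenario
randomness is sub-seeded by a stable hash of the scenario id, so inserting
or removing scenarios does not reshuffle the others.

## ROC analysis

Passing rates score each delivery; a delivery is *positive* when its
absolute surrogate mean-dose change exceeds the studied magnitude (5, 10 or
20%). At decision threshold $\tau$ a delivery is called positive when its
passing rate is **strictly below** $\tau$ — a rate equal to the threshold
is a negative. Candidate thresholds are the observed rates plus sentinels
beyond both extremes; the AUC is the trapezoidal area, which equals the
Mann–Whitney probability with half credit for ties (the package asserts
this equivalence to 1e-12 against a direct pair-counting oracle, and
cross-checks against pROC). The optimal cutoff maximizes Youden's
$J = \text{sensitivity} + \text{specificity} - 1$; exact ties in $J$ are
broken toward higher specificity and then toward the lower threshold,
because in routine clinical use false positives burn physicist time. The
reported cutoff is the observed candidate threshold itself, not an
interpolated midpoint — with 22 observations an interpolated value would
suggest precision the data do not have.

## A worked run

```{r, eval = FALSE}
study <- run_study(study_config(seed = 1))
study$manifest[, c("scenario_id", "delta_dmean_pct")]
report_tables(study$roc)$global
```

On the default suite the severe scenarios (retracted MLC, both patient
swaps, both wrong-CT deliveries, inspiration↔expiration mismatches)
collapse below a 95% tolerance under every one of the 14 metrics, while
sub-2% linac errors pass almost everywhere; the global 10%/1 mm criterion
separates deviations above 10% essentially perfectly (AUC ≈ 1.0 at
`seed = 1`). Absolute AUC values are higher than one observes on measured
transit images — the simulator has no noise floor and its 22 labels are
cleanly banded — so the suite supports *ordering* conclusions (which
criteria discriminate, in which dose band) rather than absolute ones.

## Known limitations

* The forward model is 2D and static: VMAT delivery is approximated by a
  segment-averaged fluence, so intra-arc effects (interplay, per-angle
  anatomy) are out of reach.
* The broad 3 mm penumbra makes the simulator *understate* the local
  criteria's sensitivity to millimetre MLC errors relative to measured
  data; small aperture errors here mostly pass even the local 10%/1 mm
  metric, whereas sharper measured penumbras fail it.
* The surrogate label measures attenuation only (see the bolus discussion
  above).
* DICOM support is intentionally minimal: single-plane RT Dose and the RT
  Plan attributes needed for error injection, explicit VR little endian
  only. It round-trips its own files bit-faithfully and is cross-checked
  against an independent reader, but it is not a general DICOM toolkit.
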