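---
title: "Quantitative SPECT/CT SUV analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative SPECT/CT SUV analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectsuv)
```

## Scope and model

`spectsuv` implements absolute quantification for reconstructed SPECT/CT
volumes of somatostatin-receptor radiotracers (⁹⁹ᵐTc-labelled somatostatin
analogues imaged in metastatic neuroendocrine tumours), and the
longitudinal response assessment built on it. The package consumes
*already reconstructed* activity-concentration volumes: projection
physics, OSEM reconstruction, attenuation/scatter correction and
collimator modelling are deliberately out of scope, as is any
operator-in-the-loop lesion segmentation — volumes of interest are
explicit spheres (or sphere lists read from CSV/JSON) supplied by the
caller.

The quantitative core is the voxelwise conversion

$$\mathrm{SUV_{lbm}} = \frac{C\ \mathrm{[Bq/mL]} \times \mathrm{LBM\ [kg]}
\times 1000}{A_{actual}\ \mathrm{[Bq]}} \quad \mathrm{[g/mL]},$$

with lean body mass from the James formulas (males
$1.10w - 120(w/h)^2$, females $1.07w - 148(w/h)^2$; $w$ in kg, $h$ in cm)
and the administered activity decay-corrected through the full syringe
cascade: the residual syringe activity is back-corrected from its
post-injection measurement time to the pre-injection measurement time
(`decay2` ≥ 1), subtracted from the measured activity, and the net dose is
decayed to the administration time (`decay1` ≤ 1) and on to the scan time
(`decay_scan` ≤ 1), all with $\lambda = 0.693 / t_{1/2}$. The three
exponentials are kept as separate factors, signs exactly as the clinical
formula sheet writes them, so that each can be unit-tested against the
composition identity $e^{\lambda a} e^{\lambda b} = e^{\lambda(a+b)}$ and
the all-timestamps-equal case reduces to
$A_{measured} - A_{residual}$.

SUV is normalized to lean body mass, not body weight, because body fat
takes up little tracer and would bias uptake values in heavier patients;
no body-weight or body-surface-area SUV and no SUVmean are offered.

## VOI statistics

*SUVmax* is the maximum voxel value among voxels whose **centers** fall
inside the VOI sphere. Voxel membership is by center inclusion with no
partial-volume weighting: it is reproducible, easy to reason about, and
lets a brute-force oracle verify every statistic exhaustively.

*SUVpeak* is the maximum, over spherical kernels of 1 cm³ (radius
$(3/4\pi)^{1/3}$ cm ≈ 6.204 mm) centered on each voxel center inside the
VOI, of the mean SUV over voxel centers inside the kernel. Two readings of
the "1-cm³ volume inside a larger VOI" definition are possible; we
restrict kernel *centers* to the VOI but let kernel *membership* extend
beyond its boundary, which keeps the search space well defined while
still measuring the locally averaged peak of the lesion. Kernel
placements whose bounding span would leave the voxel grid are excluded
(a kernel larger than the whole grid is an error). A consequence worth
knowing: for a lesion *colder* than its surroundings the kernel mean can
exceed the hottest lesion voxel, so the invariant that holds universally
is SUVpeak ≤ max over the kernels' reachable support, not SUVpeak ≤
SUVmax of the VOI alone; for ordinary hot lesions the familiar
SUVpeak ≤ SUVmax holds and is tested.

*Reference uptake* is the SUVmax of a 10-mm-radius sphere placed in
imagistically normal tissue (healthy liver for hepatic lesions, spleen
for nodal lesions, normal vertebra for bone lesions). The *TL/N ratio* is
computed **per lesion** (lesion SUVmax over that patient's reference
SUVmax) and then averaged across lesions; this is not the same number as
the ratio of the two population means, and the package deliberately
reports the former. An absent reference (e.g. spleen after splenectomy)
is passed as `NA` and propagates to an `NA` ratio rather than a division
error.

## Scanner calibration

Hot-sphere accuracy is $(1 - |A_{true} - a_{meas}|/A_{true}) \times 100$
percent — symmetric in the sign of the error, strictly decreasing in its
magnitude, and negative when the error exceeds the truth (reported
as-is). A scanner qualifies when every sphere exceeds the 90% vendor
threshold and the planar/SPECT sensitivity conversion factors deviate by
at most 5%. The deviation denominator is not standardized anywhere we
know of; we use the SPECT factor as reference, since quantification runs
on the SPECT data. Reconstruction settings are outside the package, so
accuracy is computed on supplied true/measured pairs; the bundled
six-sphere layout (10–37 mm diameters on a 114.4 mm ring, 8:1 sphere-to-
background) is the conventional phantom geometry, used as a plausible
default without claiming fidelity to any particular physical phantom.

## Response classification

Treatment response adapts PERCIST 1.0 to SPECT. Target lesions are the
(up to) five with highest SUVmax; ties break lexicographically by lesion
id, making selection a pure function. Between two scans the summed
SUVmax of the targets gives $\Delta\% = 100(\Sigma_f - \Sigma_b)/
\Sigma_b$ and:

* **CR** — every baseline target's follow-up SUVmax at or below a
  caller-supplied background reference (e.g. healthy-liver SUVmax) and no
  new lesions. No numeric "no uptake" threshold is standard, so the
  reference is an explicit argument; passing `NA` disables the CR check
  and complete disappearance grades as PR on the delta.
* **PD** — new tumoral foci (this overrides everything except CR, which
  is impossible with new foci), or $\Delta > +30\%$.
* **PR** — $\Delta < -30\%$.
* **SD** — otherwise. PR and PD are defined by *strict* inequalities, so
  a change of exactly ±30% falls to SD by convention.

A baseline with zero summed uptake followed by measurable uptake is
classified PD (re-appearance counts as a new focus) and flagged in the
assessment note. Lesion matching across scans is by stable lesion id;
spatial matching is out of scope. Multi-scan series are evaluated either
against the original baseline (`vs_baseline`, the default, PERCIST-style)
or against the preceding scan (`vs_previous`); published narratives are
ambiguous on this point for multi-follow-up patients, so both modes exist
and neither is asserted as "the" clinical rule. Only the last follow-up's
category counts as the patient's final category. The classifier applies
the per-organ cap of at most two target lesions nowhere: the SPECT
adaptation tracks a plain top-five, and a per-organ cap is left to the
caller's pre-filtering.

## The synthetic generator

No public image data accompany this class of study, so the generator is a
first-class module: every pipeline stage is validated by recovering
parameters the generator planted.

**Geometry.** Default 4 mm isotropic voxels on a 64³ grid (a desk-scale
stand-in for clinical 128×128 acquisitions) so the 1-cm³ kernel spans
±1 voxel per axis (19 voxels). Lesions are uniform-uptake spheres; with a
target SUVpeak they become two-compartment: a single hottest voxel at the
lesion center carries SUVmax and the rim carries
$(K p - s)/(K - 1)$ (with $K = 19$ kernel voxels, $s$ = SUVmax, $p$ =
SUVpeak), so the kernel centered on the hot voxel averages to $p$
*exactly* — SUVmax and SUVpeak are both analytically known. The
attainable band $p \in [s/K,\ s]$ is enforced.

**Uptake distributions.** Site-stratified lesion SUVmax, SUVpeak,
reference-tissue uptake and TL/N parameters
(`reference_uptake_table()`) encode typical values reported for
somatostatin-receptor SPECT in metastatic NETs: liver metastases
12.44 ± 7.76 g/mL over healthy liver 3.34 ± 0.93 (TL/N 4.20 ± 2.67),
nodal 11.98 ± 10.45 over spleen 8.01 ± 5.31 (1.84 ± 1.53), bone
5.90 ± 3.68 over vertebra 0.66 ± 0.37 (9.37 ± 2.91), with
SUVmax–SUVpeak correlations 0.982 / 0.980 / 0.920. Several of these have
large $\sigma/\mu$, so naive normal draws truncated at zero would not
have the stated mean; the generator samples a normal truncated below at
zero whose **location** parameter is recalibrated numerically (uniroot on
the closed-form truncated-normal mean, spread kept nominal) so the
post-truncation mean equals the table mean. SUVpeak is drawn
conditionally on SUVmax with the site's correlation, then clipped into
the attainable two-compartment band; clipping touches only extreme draws
and shifts cohort means by well under the recovery tolerance.

**Noise.** Multiplicative Gaussian voxel noise, mean 1, sd `noise_cv`
(default 0 in the constructor; the recovery studies use 0.02), clipped at
zero. This emulates the voxel-level variability of a reconstructed SPECT
volume at desk scale. It does **not** emulate spatially correlated
reconstruction noise, partial-volume blur, respiratory motion or
segmentation variability — so passing recovery tests demonstrates the
*pipeline arithmetic* is right, not that clinical images would yield
these exact numbers.

**Cohorts.** `generate_cohort()` emits per-scan lesion tables whose
summed SUVmax follows each patient's trajectory multipliers exactly
(follow-up lesions are scaled copies of baseline lesions, so the change
is reproduced to floating-point precision; a flagged new focus alters the
sum but the new-lesion rule dominates classification anyway). Patient
lesion counts are drawn from 2–8 — per-patient counts per scan are not
published, so this is an arbitrary plausible range. Lesion sites follow
the pooled frequencies 52% liver / 20.3% nodal / 5.7% bone / 22% other;
"other"-site lesions reuse the liver distribution since no separate one
is published. ki67 (7 ± 6.25, truncated below at 1) is drawn
independently of every SUV, so the cohort-level ki67–SUV correlation is
null by construction — recovering $|r| \approx 0$ checks the statistics
layer, and mirrors the null association reported clinically.
`cohort14_plan()` encodes a 14-patient reference cohort: 35 scans, four
multi-follow-up patients (continuous PD; SD–SD–PR; PD–PR–SD; PD–SD), one
PD driven by new lesions despite decreasing uptake, and final categories
9 SD / 3 PR / 2 PD. Physiology is sampled from plausible adult ranges
(weight ~N(75, 12²) kg clipped to 45–120, height ~N(170, 9²) cm clipped
to 150–195, 64.3% male). Marker flags reproduce reference positivity
rates either exactly (`marker_mode = "exact"`, `round(rate × n)`
positives assigned at random) or by independent Bernoulli draws.

**Phantom.** `generate_phantom()` perturbs each sphere's true
concentration by a fractional error drawn uniformly from $[-d, d]$; with
$d = 0.05$ every accuracy is ≥ 95% by construction, which is the analytic
link between the deviation band and the accuracy floor that the
calibration tests exploit.

## Numerical choices and degenerate inputs

* Sphere membership uses a $10^{-9}$ slack on the squared-distance
  comparison so lesions placed exactly on voxel-center shells are stable
  against floating-point rounding.
* `truncnorm_location()` solves on a bracket of ±(6 sd, 1 sd) around the
  target with the hazard computed from log-scale `dnorm`/`pnorm`, which
  is stable far into the tail.
* Timestamps may be `POSIXct` or plain numerics (hours); differences are
  taken in hours. Record construction rejects orderings that violate
  measured ≤ administered ≤ scan or measured ≤ postinjection, and
  `actual_activity()` rejects a back-decayed residual exceeding the
  measured activity.
* Physiology outside 20–300 kg / 100–250 cm requires an explicit
  override; an LBM that evaluates negative (extreme weight/height ratio)
  is an error naming the inputs rather than a silent negative SUV scale.
* Zero-variance inputs are rejected by the paired t-test (except the
  all-identical case, reported as $t = 0, p = 1$) and by the Pearson
  correlation.
* Percentages in cohort distributions and positivity rates are rounded
  for display (2 and 1 decimals); underlying counts are exact. p-values
  format to three decimals, so values below 0.0005 display as "0.000".

## Validation problem sizes

The recovery studies use 500 lesions per site mean (packed ~500 to a 64³
volume on a 30-mm lattice), 500 lesion/reference pairs for TL/N, 64
lesions for the correlation study, and a six-sphere phantom — sizes at
which three standard errors of the mean are a few percent of the target,
tight enough to catch conversion or kernel bugs while running in seconds
on a laptop. Acceptance of a recovered mean is always "within three
standard errors of the generator target", never a hand-picked absolute
band.

## Known limitations

* No reconstruction physics: resolution recovery, partial-volume effects
  and correlated noise are absent, so recovered accuracy on synthetic
  data is an upper bound on clinical accuracy.
* Sphere VOIs only; irregular masks can be emulated only as unions of
  spheres supplied by the caller.
* SUVmax of a noisy uniform region is an extreme-value statistic and is
  biased upward by a few percent at the default noise level; the TL/N
  ratio largely cancels this bias because numerator and denominator are
  both maxima over similar voxel counts.
* Lesion matching across scans relies on caller-stable lesion ids.
* The truncated-normal uptake model is a calibration device, not a claim
  about the true population shape of lesion uptake.
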