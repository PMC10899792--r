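---
title: "Methods: synthetic kymographs, plectoneme detection, and twin-supercoiled-domain statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic kymographs, plectoneme detection, and twin-supercoiled-domain statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement this package models

A torsionally constrained DNA molecule (21, 31 or 38 kb, multi-biotin
handles of ~600 bp at both ends) is stretched and doubly tethered to a
surface and stained with an intercalating dye, so the camera sees a thin
fluorescent line whose local brightness is proportional to local DNA
content. Torsional stress stored in the molecule buckles into plectonemes:
intertwined loops that concentrate many kilobases of DNA at one point along
the axis and therefore appear as bright, diffusing puncta. A fluorescently
labeled RNA polymerase occupies a second spectral channel. Projecting each
frame onto the molecule's long axis over time yields a two-channel
kymograph, from which the assay reads off:

* where plectonemes are (position along the molecule, converted to genomic
  coordinates),
* how much DNA each one holds (from its excess intensity), and
* how both relate to the RNAP position — the twin-supercoiled-domain
  picture predicts supercoils of equal magnitude upstream and downstream of
  a transcribing, rotationally hindered polymerase.

The raw data of such experiments are not publicly deposited, so the package
ships a ground-truthed generator that emulates the assay closely enough to
exercise — and quantitatively validate — every stage of the analysis.

# Synthetic data generator

`simulate_plectonemes()` propagates plectonemes as reflected Brownian
motion in genomic coordinates between end-exclusion boundaries (default
1200 bp from each tether, matching the span over which plectoneme density
vanishes near the surface handles). Genomic steps are derived from the
physical diffusion coefficient (default 0.5 um^2/s, the value this assay
measures for plectonemes) through the per-base-pair extension of the
molecule. Nucleation draws a uniform position and takes base pairs from a
conserved unwound pool; termination returns them; co-existing plectonemes
exchange size diffusively. Setting `pinned_site_bp` reproduces the
open-complex situation in which a promoter-bound polymerase merges all
supercoils into one immobile plectoneme at its position. Integration is
Euler-Maruyama with `dt = frame_interval / 10` by default; a guard rejects
steps whose RMS displacement exceeds 5 px.

`simulate_transcription()` adds a polymerase that sits at the stall site
(TSS + 29 nt) until NTP addition, then advances at a constant elongation
rate while supercoiled base pairs accumulate at `injection_rate_bp_s`
(default 18.2 bp/s, i.e. ~4 kb over 220 s, the growth the assay reports for
the total plectoneme size). Injection is quantized per helical turn
(10.5 bp) and each quantum is assigned to the upstream domain with
probability `upstream_fraction`; the realized partition therefore carries
binomial fluctuations, which is what a recovery analysis must see. The
RNAP acts as a hard reflecting barrier: plectonemes never cross it, and a
`rnap_exclusion_bp` zone (default 1500 bp) keeps puncta optically
separable from the polymerase position. Nucleation, termination and
exchange rates are not reported quantities; the defaults were chosen once
so that one or two plectonemes dominate the co-existence statistics, and
they are exposed in the configuration.

`render_stack()` converts truth to images: the backbone carries the
non-plectonemic base pairs uniformly between the tether points, each
plectoneme adds its base pairs as a point mass, the profile is convolved
with a Gaussian PSF (default FWHM 300 nm at 109 nm/px), spread over a
Gaussian transverse profile (11-px crop), Poisson-sampled and given
Gaussian read noise (sd 1 count). The noiseless integrated DNA signal is
exactly proportional to the construct length and invariant to the
plectoneme arrangement — the conservation on which intensity-based sizing
rests. Saturation above the camera bit depth is warned about and counted,
never silently ignored.

**What the generator does not emulate:** motion blur within the 100-ms
exposure (positions are instantaneous, so the ~330 nm blur-limited accuracy
bound enters only as a closed-form check), photobleaching and blinking,
non-uniform intercalation, drift, and the 2-D conformation of plectoneme
apices under side flow. Passing tests on these fixtures therefore validate
the *analysis*, not the microscope.

## Photon-budget calibration

The assay states a ~1500-bp detection floor. `photons_per_bp = 0.12` was
calibrated in-repo so that, at the default prominence threshold (4x robust
row noise), per-frame detection probability is ~0.35 at 1000 bp, ~0.9 at
1500 bp and ~1.0 at 2500 bp: the smallest *reliably* detected plectoneme is
about 1500 bp. This is a calibration of the synthetic instrument, not a
measurement.

# Detection pipeline

The stages follow the assay's data-analysis procedure: a 3-px grayscale
median filter, white top-hat background subtraction, kymograph construction
by transverse summation (a maximum projection is available by flag;
summation conserves photons), peak-peeling end localization, per-row
punctum detection, nearest-neighbour track linking with a minimum lifetime
of three consecutive frames, and conversion of pixel positions and excess
intensities into genomic positions and base-pair sizes using the known
construct length.

Numerical choices that required decisions:

* **Top-hat orientation.** The structuring element is a 15-px *line
  transverse to the molecule axis*. Background varies slowly in both image
  dimensions while the molecule is a thin line; an element along the axis
  would treat the backbone ridge itself as background and destroy the
  intensity scale on which sizing depends.
* **Median filter.** Implemented as an exact vectorized median-of-9
  exchange network (3-px window). On *noiseless* profiles the median
  systematically shaves ~10% off a PSF-wide punctum's integrated excess
  (shot noise dithers this down to a few percent in realistic renders), so
  the noiseless oracle-equivalence tests disable it — it exists to reject
  impulse noise, which noiseless fixtures lack.
* **Peak peeling.** Gaussians of the PSF FWHM are subtracted at successive
  profile maxima until less than 10% of the original area remains. The
  subtracted amplitude is *half* the current maximum: full-amplitude
  subtraction biases the outermost centers 2–3 px inward at the plateau
  edges, while half-amplitude subtraction still contracts geometrically and
  keeps the recovered ends within 1 px on noiseless flat-top profiles. On
  noisy input an amplitude floor (3x the standard error of the temporally
  averaged profile) prevents background bumps outside the molecule from
  receiving peaks. Ends should be localized from quiescent frames (before
  supercoil induction or NTP addition), as in the experimental procedure:
  profiles dominated by a large punctum cost 1–2 px of end accuracy.
* **Backbone baseline.** Both the detection residual and the per-punctum
  excess use the known backbone *template* — a flat top between the
  localized ends convolved with the PSF — scaled to punctum-free pixels
  (robust median ratio). A running median is zero-inflated and flattens
  peaks near the span edges (missing end-proximal plectonemes), and linear
  interpolation of flanking levels mis-tracks the PSF roll-off near the
  tethers; both alternatives measurably biased the up/downstream partition
  statistic before this choice was made.
* **Row noise.** Estimated from frame-to-frame differences (MAD-scaled),
  which is robust both to image structure and to the zero-inflation of
  smoothing residuals.
* **Sizing.** `size_bp = total_bp * excess / row_total`, with the row total
  taken over the PSF-expanded molecule span minus the per-row background
  pedestal estimated outside it. Excess is an unclamped sum over
  +/- 1.5 FWHM (clamping negative residuals inflates small sizes).
  Detections below 1500 bp are flagged; tracks whose mean size stays below
  the floor are not reported.
* **Linking.** Squared-displacement assignment under a hard gate
  (3 sqrt(2 D dt) by default), exhaustive for small frame populations,
  deterministic tie-breaking, single-frame gap closing (flagged). A bridged
  gap counts as continuous presence for the three-consecutive-frames rule.
* **Localization.** Intensity centroid over +/- 1 FWHM. On noiseless
  fixtures end-to-end positions agree with truth to <= 1 px and sizes to
  <= 2%; with the calibrated noise the mean recovered size is accurate to
  ~6% at 3 and 10 kb.

## Size-error bounds

The assay quotes upper-limit relative size errors of ~15% at 10 kb and ~9%
at 3 kb, derived from an error-propagation model. With the detection floor
calibrated to 1500 bp at a 4-sigma threshold, the *per-frame* scatter at
3 kb is analytically >= ~12% for any photon budget (the threshold ties the
noise level to the floor amplitude), so the package tests these bounds as
bounds on the accuracy of the *mean* recovered size on stationary mid-span
fixtures, plus per-frame RMS <= 15% at 10 kb. Diffusing puncta that visit
the tether-proximal region carry somewhat larger scatter.

## Diffusion-constant estimation

`diffusion_constant()` fits time-averaged MSD curves with an intercept (the
localization-error offset) by weighted least squares. Plectonemes diffuse
in a closed domain, so the MSD is linear only at short times: the deficit
grows as t^(3/2)/L with domain size L, and for a 38-kb molecule at high
extension sampled at 2 Hz the bias of a 10-lag fit already approaches 20%.
Recovery analyses therefore fit the first 3 lags (`n_lags = 3`) on
long, well-extended fixtures — a short-time-regime choice made on this
analytic ground, stated here because the default `n_lags = 10` is only
appropriate when the explored span is small compared to the domain.

# Quantification

`density_profile()` (per-molecule-normalized position histograms, genomic
or RNAP-centred normalized coordinates), `count_distribution()` (number of
co-existing plectonemes per frame, frames without detections count as
zero), `colocalization()` (fraction of plectoneme detections within 3 px of
the same-frame RNAP), `partition_fractions()` (frame-wise upstream share of
the total plectoneme size; upstream = smaller genomic coordinate after
orientation normalization — a sign error here silently swaps the headline
result, so the convention is asserted in tests), `total_size_series()`,
`epoch_ratio()` (After/Before a treatment marker; epochs shorter than 10
frames are rejected), `relaxation_time()` (time to fall below 10% of the
pre-nick mean — the 10% criterion is a package choice), and
`ttest_unpaired()` (Welch by default; the pooled-variance variant by flag —
the unpaired two-tailed convention of the assay, with Welch chosen for
robustness to unequal variances). Partition summaries report both
molecule-weighted (primary) and frame-weighted means, since the averaging
convention is not fixed by the assay's description.

RNAP gaps of up to two frames are bridged by linear interpolation; longer
gaps exclude the frame from partition statistics.

# Torque-balance mechanics model

`simulate_induction()` is a deliberately simple, self-contained model of
whether a polymerase can twist its template. Tracking the helical groove at
elongation rate v requires co-rotation at omega = 2 pi v / h (h = 10.5
bp/turn). The torque available to resist that rotation is the rotational
drag `gamma(mu, N) * omega`, with `gamma = 8 pi mu R^3` for the RNAP sphere
(R = 7 nm) plus `6 pi mu Rg (Rg + lever)^2` for a nascent-RNA blob of
radius `Rg = b N^nu` (b = 0.5 nm, nu = 3/5, lever arm 5 nm) translating on
a circle about the DNA axis. Whenever the accumulated DNA torsional torque
`2 pi C kBT dLk / L` is below the frictional cost, the transcribed turn is
injected into the DNA; otherwise the polymerase spins. Buckling is scored
when the supercoiling density reaches sigma = 0.001 *and* the DNA torque
exceeds the buckling torque `sqrt(2 kBT Lp F)` (4.54 pN nm at the 0.05-pN
assay tension — comfortably below 5, which is why injected twist converts
readily to writhe in the experiment). There is no torsional relaxation
channel in this version; at fixed-sigma scoring that is acceptable because
twist-to-writhe conversion is fast at low tension.

The model reproduces the qualitative structure of the viscosity sweep:
buckling distance decreases monotonically with viscosity, elongation rate
and transcript length; at cytoplasmic viscosity (17.5 Pa s and above) the
bare polymerase buckles the template within a few hundred base pairs; in
aqueous buffer (1 mPa s) the polymerase plus a >10-kb transcript can buckle
it, while the bare polymerase cannot up to 30 kb. That last prediction is
exactly what the RNase experiments *contradict* — supercoiling continues
after transcript digestion — and the package documents the model as
qualitative for this reason: it exists to make the discrepancy precise, not
to fit the experiment. Geometry constants (R, b, nu, lever arm) are
literature-standard defaults, configurable; the elongation default of
50 bp/s is a typical bacterial rate. No attempt is made to match the ~300-bp
cytoplasmic buckling distance quantitatively, which depends on parameters
not available here.

# Problem sizes and determinism

Validation analyses use 10–20 synthetic molecules of 300–2000 frames each —
enough that pooled recovery statistics sit well inside their target bands
(e.g. the pooled upstream fraction at symmetric injection lands within
~0.01 of 0.5 with 20 molecules) while a full run stays in the minutes
range on one core. Every stochastic stage takes an explicit seed; per-
molecule seeds are derived deterministically from the run seed, and
`run_scenario()` reports are byte-identical across reruns of the same
configuration.

# Known limitations

* Plectonemes are point masses: finite plectoneme extent along the axis,
  and the slightly smaller optical footprint of a plectoneme versus a loop
  of equal size, are not modeled.
* No supercoil-handedness inference: calling handedness from
  intercalation-efficiency changes after nicking needs dye-calibration data
  outside this package's scope.
* The count distribution's low end is censored by the 1500-bp floor, as in
  the real assay; absolute co-existence probabilities depend on the
  unreported nucleation/termination kinetics and are validated only in the
  pinned (exactly-one) limit.
* End localization degrades by 1–2 px when the averaged frames already
  contain large puncta; supply quiescent `end_frames` where available.
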