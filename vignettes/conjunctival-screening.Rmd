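---
title: "Conjunctival microvascular haemodynamics and ocular-biomarker screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conjunctival microvascular haemodynamics and ocular-biomarker screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocuflow)
```

## The problem

The bulbar conjunctiva is the one place in the body where a microvascular
bed can be filmed directly, non-invasively, with nothing more exotic than a
slit lamp and a phone camera. Microvascular dysfunction — slowed flow,
dilated vessels, reduced wall shear — accompanies atherosclerotic disease,
and blood biomarkers such as NT-proBNP and adiponectin shift with cardiac
stress and lipid/inflammatory state. `ocuflow` implements the full analysis
chain that turns (a) short conjunctival video clips and (b) a blood
biomarker panel into a logistic screening score for coronary artery
disease, together with a ground-truthed simulator so that every stage can
be verified quantitatively without any clinical data.

The chain is:

1. **Registration** — pick the sharpest frame, rigidly align the rest.
2. **Vessel geometry** — segment dark vessels, extract centerlines,
   estimate per-point diameter $D$ from the Euclidean distance transform.
3. **Velocimetry** — sample a spatio-temporal image (STI, a kymograph)
   along each centerline; estimate the axial velocity $V_a$ from the
   streak slope by a one-dimension-plus-time continuous wavelet transform;
   derive the cross-sectional velocity $V_s = V_a / k$, the volumetric
   flow $Q = V_s \pi D^2 / 4$ (pl/s) and the wall shear rate
   $\mathrm{WSR} = 8 V_s / D$ (s$^{-1}$).
4. **Biomarker preparation** — impute sub-LOD assay results as 90% of the
   limit of detection, log$_{10}$-transform right-skewed markers, pool
   per-segment ocular measurements into per-patient means.
5. **Screening statistics** — Shapiro–Wilk-gated group comparisons,
   2×2 chi-squares, stepwise Wald logistic regression, Nagelkerke $R^2$,
   Hosmer–Lemeshow calibration, and ROC analysis with sensitivity,
   specificity, PPV and NPV at a classification cut.

## What the simulator emulates — and what it does not

`render_vessel_video()` draws a single anti-aliased dark tube (diameter
15–30 µm) along a spline on a bright scleral background, with a periodic
train of dark Gaussian "plugs" — cell aggregates — advected along the
centerline at a constant speed. Advection is arc-length parameterised, so
the ground-truth velocity is well defined on curved vessels. Per frame the
scene is rigidly translated by integer-rounded Gaussian jitter (micro-
saccades), optionally defocus-blurred, and corrupted with Gaussian sensor
noise. The exact mask, centerline, shifts, diameter and velocity are
returned, so registration, segmentation, diameter and velocimetry are all
scored against known truth.

Defaults mirror the acquisition the analysis targets: 60 frames/s, pixel
pitch 1.5 µm, vessel contrast 0.55, jitter SD 1 px, noise SD 0.015 on a
0.85 background. We render 80-frame clips rather than full 10 s (600
frame) acquisitions: recovery accuracy is already stable at that length
and the whole five-video verification sweep runs in seconds.

The simulator deliberately omits: pulse-cycle velocity waveforms (the
estimator reports a single speed per segment), photorealistic sclera
texture, specular reflections, eyelash occlusion, blinks, and vessel
branching networks (one vessel per clip). Passing the recovery tests
therefore demonstrates correctness of the estimators under controlled
conditions, not robustness to every artefact of real clinical video.

`simulate_cohort()` draws a two-group (control vs post-MI) cohort from a
Gaussian copula: each variable's marginal is either Gaussian or — for
right-skewed markers whose SD rivals the mean (NT-proBNP, CRP, H-FABP,
IL-6) — lognormal, parameterised so the *arithmetic* mean and SD match the
group summaries the defaults encode. Adiponectin is also lognormal, purely
to guarantee positivity under the log$_{10}$ transform. Binary traits use
a latent-threshold Bernoulli. The defaults encode the study conditions the
package is calibrated for: 66 subjects per group and the group means/SDs
of the ocular and biomarker panel. No between-variable correlation
structure is asserted (the default latent correlation is 0) because none
is reported for this population; the parameter is exposed for sensitivity
analysis.

## Design choices that were genuinely open

**Registration.** The transform family and similarity measure are not
prescribed by the source methodology, which simply "registers" frames.
We use translation only (slit-lamp micro-saccade motion is predominantly
translational) with zero-padded FFT cross-correlation and parabolic
sub-pixel refinement. One non-obvious choice: frames are **binarised at
their Otsu level before correlating**. The only strong features in these
scenes are the dark vessels, and the moving aggregates inside them drag a
raw-intensity correlation peak along the vessel by up to a pixel; the
binary vessel footprint is invariant to aggregate position (aggregates
only darken pixels already inside the footprint), which is what makes
integer jitter exactly recoverable on noiseless input. Focus scoring for
reference-frame selection is variance-of-Laplacian, monotone in Gaussian
defocus.

**Segmentation.** No algorithm is prescribed. We estimate the background
by grey-scale morphological closing with a disc wider than any vessel
(box or Gaussian smoothing dips into the vessel and biases the edge
inward by close to a pixel), take the response `background − frame`,
locate the vessel core by Otsu, and place the lumen edge at half the core
response level — for a blurred flat-topped tube profile the half-maximum
falls on the true edge. In the pipeline the segmented frame is the
*temporal mean* of the registered stack: aggregates average into a nearly
uniform tube and noise shrinks by $\sqrt{T}$.

**Diameter.** $D = 2\,\mathrm{EDT}\times$µm/px at each centerline point,
exactly the nearest-background-pixel definition; an exhaustive brute-force
oracle confirms equality on random masks. Skeletons come from Zhang–Suen
thinning with 10 px spur pruning; segments shorter than 50 µm or with
quality below 0.5 are excluded from patient means.

**Velocimetry.** The exact wavelet formulation behind the original
semi-automated software is not published. We fix a defensible variant:
per STI row, a Mexican-hat (second-derivative-of-Gaussian) wavelet bank
spanning 0.5–2× the expected aggregate length (9–36 µm); the ridge is the
scale/position of maximal modulus with parabolic sub-sample refinement;
ridges are tracked across rows by nearest-candidate association (strong
local maxima only), displacements beyond 3× the running median are
rejected as plug-identity switches, and the speed is the median surviving
displacement over the frame interval. The estimate is validated not
against the original code but against an independent brute-force oracle
(`axial_velocity_oracle()`, exhaustive integer-lag normalised
cross-correlation of consecutive rows) — the two must agree within 10%
on simulated vessels, and do within ~7%.

A velocity is reported as a magnitude (the reporting convention for this
analysis is speed only). An estimate is declared **indeterminate** — a
distinct outcome from zero — when the ridge track is incoherent: the
streak SNR, defined as the working wavelet scale over the robust SD of
ridge displacements, falls below 4. A noise-dominated STI scores near 1
on this ratio regardless of length; a true streak scores far above; a
perfectly stationary pattern scores infinity and is reported as 0 mm/s.

**Axial-to-cross-sectional conversion.** The conversion factor is not
stated in the source methodology; the paired group means it prints
(0.54/0.38 and 0.50/0.35 mm/s) imply a constant ratio of ≈1.42, which we
adopt as the default `k_axial_to_cross` (a blunted, non-parabolic
microvascular profile; a true parabola would give 2). Only the
constant-factor form is implemented; `k` is exposed in
`velocimetry_config()`.

**Patient pooling.** "Overall mean per patient" is ambiguous between
video-weighted and segment-weighted pooling; we pool **segment-weighted**
(every included segment counts once across all videos of both eyes),
declared and deterministic.

**Stepwise entry.** Forward selection uses the Rao score test; removal
uses Wald $p > 0.10$. The entry comparison applies a Bonferroni
adjustment for the number of candidates scanned at that step. This is the
package's family-wise entry rule: a screen over many null biomarkers
retains the intercept-only model with probability at least
$1 - p_{\text{enter}}$, whereas per-candidate entry at $\alpha = 0.05$
over six candidates would admit a false biomarker about a quarter of the
time. Wald statistics are $(\beta/\mathrm{SE})^2$ against $\chi^2_1$;
standard errors come from the observed information (equal to expected for
the logit link).

**Classification cut.** Sensitivity/specificity/PPV/NPV are reported at
fitted probability 0.5 by default, with the Youden-optimal point also
returned, because the operating rule behind published operating points of
this kind is typically unstated.

**Chi-square.** 2×2 tests are Pearson **without** continuity correction —
the convention is pinned by the worked example the package reproduces
(χ²(1) = 1.91 for the 45/66 vs 52/66 gender table; the Yates-corrected
value would be 1.40).

**Hosmer–Lemeshow.** Deciles of fitted risk with ties kept together
(g = 10, df = 8); groups with zero expected events are merged with a
neighbour and the merge recorded.

## Numerical choices

* Logistic IRLS converges on a log-likelihood change below $10^{-8}$
  (max 50 iterations); separation is flagged, never silently reported,
  when coefficients diverge and fitted probabilities collapse.
* Lognormal moments: for arithmetic mean $m$, SD $s$,
  $\sigma^2 = \log(1 + s^2/m^2)$, $\mu = \log m - \sigma^2/2$.
* Registration correlation ties break toward the smaller shift magnitude;
  parabolic refinement is clamped to ±0.5 px and skipped at non-maxima.
* The STI is sampled by bilinear interpolation at one pixel-pitch
  arc-length steps (finer on request), each row mean-detrended, making
  the velocity estimate exactly invariant to affine intensity rescaling.
* Degenerate inputs have defined outcomes: constant frames give empty
  masks; empty masks give empty centerline tables; a constant sample is
  rejected by the normality gate; a zero table margin is rejected by the
  chi-square; an absent class is rejected by the ROC.

## Problem sizes used in verification

The shipped tests and the acceptance script run, per invocation: five
80-frame 120×160 px recovery videos (diameters 16–30 µm, velocities
0.3–0.7 mm/s); 100 random masks for the EDT equivalence sweep; 2000
null replicates at $n = 66/66$ for the comparison type-I error; 100
stepwise replicates at $n = 2000$ with six candidates for each of the
power and null selection rates; 500 replicates at $n = 2000$ for
Hosmer–Lemeshow calibration; and one full synthetic screening run at
$n = 66/66$. These sizes were chosen so the whole verification cycle
completes in about a minute while leaving every rate well inside its
binomial noise band.

## Known limitations

* Velocities are cardiac-cycle averages; pulse-resolved waveforms are out
  of scope, and the simulator does not generate them.
* Vessels are not classified as arterioles/venules/capillaries; pooled
  means mix vessel types exactly as the underlying imaging protocol does.
* The axial-to-cross-sectional factor is a constant; any true
  diameter-dependence of the velocity profile is absorbed into it.
* The screening stage is in-sample: no cross-validation or external
  validation is implemented, matching the analysis it reproduces — the
  reported AUROCs are optimistic in the usual in-sample sense.
* On real clinical video, segmentation quality — not the estimators
  downstream — is expected to be the binding constraint; the quality
  score and inclusion thresholds exist to make that culling explicit.

## A worked miniature

```{r mini, eval = FALSE}
sim <- render_vessel_video(video_sim_config(seed = 3))
ext <- extract_haemodynamics(sim$stack)
ext$haemodynamics          # one row per included segment: D, Va, Vs, Q, WSR

cohort <- simulate_cohort(cohort_sim_config(seed = 3)) |>
  impute_below_lod() |>
  apply_log10(c("nt_probnp", "adiponectin", "hfabp", "wsr_per_s"))
cohort$case <- as.numeric(cohort$group == "post_mi")
sw <- stepwise_wald(cohort, "case",
                    c("vs_mm_s", "nt_probnp", "adiponectin", "hfabp", "age"))
tidy(sw$model)
roc <- roc_curve(sw$model$fitted, sw$model$y)
glance(roc)
autoplot(roc)
```
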