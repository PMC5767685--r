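---
title: "Part-based whole-person patterns: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Part-based whole-person patterns: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(personmvpa)
```

## The question and the two generative scenarios

When a person views a whole person, are the evoked multi-voxel response
patterns in face- and body-selective cortex simply a mixture of the
patterns evoked by the isolated face and the isolated body (a *part-based*
representation), or do they carry an additional component from
whole-person-specific neural populations (an *integrated* representation)?

`personmvpa` operationalises both hypotheses as generative models over
voxel patterns. For each subject, ROI and emotion $e$, a face template
$f_e$ and body template $b_e$ are drawn as standard normal voxel vectors.
The whole-person template is

$$ p_e = \gamma\,\bigl(\alpha_e f_e + (1-\alpha_e)\, b_e\bigr)
       + (1-\gamma)\, u_e , $$

where $\alpha_e \in [0,1]$ is the face weight (body weight
$\beta_e = 1-\alpha_e$; the total part weight is constrained to 1),
$u_e$ is an independent standard normal person-only component, and
$\gamma \in [0,1]$ is the fraction of the person template explained by the
part combination. The part-based scenario is $\gamma = 1$; any
$\gamma < 1$ injects integrated structure. The study leaves the magnitude
of the person-only signal under the integrated hypothesis unspecified, so
$\gamma$ is exposed as a free parameter rather than fixed; the bundled
integrated configuration uses $\gamma = 0.5$, which puts the template-level
correlation between $p_e$ and its part combination at $1/\sqrt{3} \approx
0.58$ — clearly separated from 1 but far from independence.

Each run-level pattern is its template plus i.i.d. Gaussian noise of SD
$\sigma$ (`sigma_noise`). Between-emotion template correlation
$\rho$ (`rho_emotion`, default 0.2) is induced by mixing a shared and an
idiosyncratic component,
$f_e = \sqrt{\rho}\, f_{\text{shared}} + \sqrt{1-\rho}\, \epsilon_e$, the
simplest construction consistent with distributed, partially overlapping
emotion codes. The person-only components $u_e$ are drawn independently
per emotion because the integrated hypothesis posits genuinely
whole-person-specific populations.

### Calibration of the default noise level

`sigma_noise = 0.4` was fixed analytically, before any simulation, so that
the part-based scenario at $\alpha = 0.5$ yields a cross-run
person–synthetic Pearson correlation near 0.8 — the regime the weight
recovery analysis assumes. With unit-variance templates, face and body
independent, the synthetic mean $s = (f+b)/2$ has variance $1/2$, the
cross-run covariance between a person pattern and a synthetic pattern is
$1/2$, and

$$ r \;=\; \frac{1/2}{\sqrt{(1/2+\sigma^2)\,(1/2+\sigma^2/2)}} , $$

which equals $0.8$ at $\sigma \approx 0.41$.

## The experiment's design arithmetic

A run has 18 blocks. Each block consists of a 10 s inter-block fixation
interval, 8 trials of a 2 s video plus 0.5 s ISI (20 s of stimulation),
and a 2 s response window: 32 s per block, 576 s per run, 288 volumes at
TR = 2 s. The first 5 volumes (10 s) are discarded for signal
equilibration, leaving 283.

Two bookkeeping decisions here were genuinely open:

* **Fixation placement.** The block's fixation interval is placed at the
  *head* of the block. The experiment describes an inter-block fixation
  ending with a 1 s attention cross, which reads most naturally as leading
  into the next block; more importantly, it is the only placement under
  which the discarded 10 s remove fixation only, so all 18 stimulus blocks
  keep their full complement of volumes.
* **Hemodynamic shift.** Condition volumes are extracted from the window
  `[stimulus onset + shift, stimulus end + shift)`. The default is one TR
  (`shift_s = 2`). Because 18 × 32 s tiles the 288 acquired volumes
  exactly, any shift larger than the 2 s response window pushes the last
  block's window past the end of acquisition and costs that condition a
  volume; 2 s is the largest physiologically sensible shift that preserves
  exactly 20 volumes per condition per run (two 20 s blocks × 10 volumes).
  Shifts that push any block past the run end raise an error rather than
  silently dropping volumes. Response-window volumes are never labeled
  with a condition, since they would mix in motor activity.

Runs 1–3 present all nine conditions (3 body types × 3 emotions, two
blocks each); run 4 presents only the three whole-person conditions, so
classifier test data stay independent of all training data.

## Time-series forward model and GLM

Each voxel's time course is the sum over conditions of the condition's
pattern amplitude times a stimulus boxcar convolved with a canonical
double-gamma HRF (gamma-density difference, response peak near 5 s,
undershoot near 15 s, peak-to-undershoot ratio 6, unit peak), plus eight
nuisance series (six slow random walks standing in for head-motion
parameters, two low-frequency drifts standing in for mean white-matter and
CSF signals) and Gaussian noise, optionally AR(1). The HRF is implemented
directly from its closed form.

The GLM design matrix holds one convolved boxcar per condition, the
nuisance regressors, their temporal derivatives (first differences), and
an intercept — 26 columns for a nine-condition run. Estimation is
voxelwise OLS via a QR decomposition; rank deficiency is reported with the
offending columns rather than silently pivoted away. Prewhitening is
deliberately omitted: at the simulated scale the OLS estimator is exact
under white noise, and the AR(1) switch exists to let users study the
sensitivity themselves.

The default time-series noise `noise_sd = 8` was chosen relative to the
convolved-boxcar plateau (≈ 4.7 for the unit-peak HRF): it puts the
correlation between a single stimulus volume's spatial pattern and its
generating template near 0.5, a moderate single-volume SNR typical of
block designs, so classification accuracies sit in the informative
mid-range rather than at ceiling.

## Pattern similarity

The synthetic mean is the elementwise face/body average, computed
*within run* before any cross-run correlation so that run noise stays
independent across the correlated pair. For categories $A \neq B$ all six
directed run-pair combinations of runs 1–3 are correlated and the Fisher-z
values averaged (symmetric and lower-variance than a single direction);
for $A = B$ the three unordered pairs are used, which also furnishes the
RSM diagonal as a cross-run reliability rather than a forced maximum.
Correlations are clipped to $\pm(1-10^{-7})$ before `atanh` so perfect
correlations stay finite.

The Category × Emotion comparisons are balanced two-way fully
within-subject ANOVAs (`aov` with `Error(subject/(category*emotion))`),
reported without sphericity correction, matching the uncorrected
F/p reporting style of the underlying analyses.

## Weight analysis

For each subject, ROI and emotion, the face, body and person patterns are
averaged over runs 1–3; the face weight $\alpha$ is swept over the closed
grid $0.00, 0.01, \ldots, 1.00$ (101 points, the stated resolution — no
continuous refinement); and the Pearson correlation of
$\alpha f + (1-\alpha) b$ with the person average is Fisher-z transformed
at each point. The optimum is the *smallest* grid $\alpha$ attaining the
maximum, with the number of tied points reported. Ties are detected within
an absolute tolerance of $10^{-12}$ on z so that analytically constant
curves (e.g. $f = b$) register as full 101-point ties despite
floating-point rounding. Since `atanh` is strictly increasing, maximising
z and maximising r give the same argmax. Grid points where the weighted
pattern has zero variance (possible only when $f \propto -b$) are flagged
and excluded from the argmax.

Group statistics run on body weights $\hat\beta = 1-\hat\alpha$. The
follow-up paired comparisons are exported both pooled (emotion comparisons
pool subject × ROI cells; ROI comparisons pool subject × emotion cells,
matching the degrees of freedom the pooled framing implies) and per level,
because the pooling scheme behind the reported group tests is not
otherwise recoverable.

## Classification

Condition volumes are z-scored per voxel per run (population SD; constant
voxels are zeroed with a warning). Feature selection is a voxelwise
one-way ANOVA across all nine condition labels of runs 1–3 at $p < 0.05$,
computed from training runs only — tests assert that altering run-4
content cannot change the mask. Four training sets are built from runs
1–3: face volumes, body volumes, their volume-wise average ("mean"), and
the volume-wise combination at the subject's optimal $\hat\alpha$
("weighted mean"); the k-th face and k-th body volume of the same run and
emotion are paired in acquisition order. The classifier is a linear SVM
(libsvm via `e1071`, one-vs-one, cost 1, no internal rescaling), tested on
the run-4 whole-person volumes; accuracies are compared against the
analytic chance level of 1/3 with one-sample t-tests and
Benjamini–Hochberg FDR correction across all ROI × training-type cells
(28 in the full seven-ROI design). Whether test exemplars should be
single volumes or block averages is not determined by the source analyses;
volume-wise is the default, with `aggregate = "block"` available.

## Stimulus statistics

Movement per clip: absolute inter-frame luminance difference per pixel,
averaged over pixels whose difference exceeds 10 (on the 0–255 scale),
then averaged over frame pairs. The threshold is read as applying to the
*difference* image (the movement estimate itself), not to raw luminance;
the alternative reading would make a bright static clip score nonzero
movement. Frame pairs with no supra-threshold pixel contribute 0 rather
than being skipped — an explicit assumption, flagged here. RMS contrast is
the per-frame population SD of luminance averaged over frames (population
rather than sample SD is a documented convention choice); mean luminance
is the grand mean. Group comparisons are paired t-tests (clips matched by
within-group order) plus a one-way ANOVA per statistic.

## What the generator does and does not emulate

The synthetic data reproduce the *statistical structure* the analyses
assume: per-condition templates with controlled part-composition,
run-level noise, block-design timing, nuisance structure, and the
train/test split. They do not emulate spatial autocorrelation between
voxels, scanner drift beyond the modeled nuisance series, motion
artifacts, slice timing, susceptibility dropout, or realistic face/body
videos. Passing tests therefore demonstrate that the *pipeline* is
correct and well-calibrated — that it recovers known weights, separates
the two scenarios, and controls error rates under its own assumptions —
not that real cortex is part-based.

## Problem sizes and numerical choices

Simulated analyses use 20 subjects, the full 4-run design, and 600 voxels
per ROI (comparable to the larger localised regions) for pattern-level
analyses; time-series and classification stages run at 60–150 voxels and
1–7 ROIs, since the estimators are voxelwise and the extra columns only
scale runtime. Tests freeze their seeds; every generator is deterministic
given its configuration. Degenerate inputs (zero-variance patterns,
rank-deficient designs, empty feature masks, single-class training sets,
unbalanced ANOVA tables) raise explicit errors or flagged results rather
than being imputed around.

## Known limitations

* ROIs are opaque labels: no spatial geometry, no localizer, no
  anatomical variability across subjects.
* OLS without prewhitening slightly misstates GLM standard errors under
  AR(1) noise (betas remain unbiased; only betas are consumed downstream).
* The weight grid bounds $\hat\alpha$ to [0, 1]; truly negative part
  weights would pile up at the boundary.
* The integrated scenario's person-only magnitude is a modeling choice
  ($\gamma$), not an estimate; conclusions about scenario separation are
  conditional on it.
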