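---
title: "Methods: vowel centering, speaking-induced suppression, and lesion profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vowel centering, speaking-induced suppression, and lesion profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(censis)
```

`censis` implements the analysis layer of a speech detection–correction
study: how the brain detects that a self-produced vowel is drifting away
from its target (indexed by speaking-induced suppression, SIS, of the M100
auditory evoked response) and how the speech motor system corrects it
(indexed by vowel centering in F1–F2 formant space). This vignette explains
the models and procedures, the tunable parameters, the synthetic cohort
generator that stands in for raw MEG/audio data, and the numerical and
design choices a maintainer should know about.

## Vowel centering

Each trial of a monosyllabic word is summarized in two windows of its
F1/F2 formant trajectory, both converted to the mel scale
(`mel = 2595 log10(1 + f/700)`):

* the **initial window**, 0–50 ms from voicing onset, reflecting the
  feedforward motor command before auditory feedback can act;
* the **mid-utterance window**, the middle 50% of the voiced trajectory,
  by which time feedback-based corrections are expressed.

For each speaker, vowel, and window, the component-wise **median** F1/F2
point defines the center of that vowel's distribution; each window's
distances are measured against *its own* median, so a systematic formant
drift between windows does not masquerade as centering. **Variability** is
the mean Euclidean distance (mels) to the median; per-trial distances are
pooled across vowels within speaker after per-vowel median referencing.

**Peripheral trials** are those with the largest initial distances —
either a fixed-size subset (e.g. 125 of 600, sampled equally across vowels
with any remainder assigned in lexicographic vowel order) or a per-vowel
median split. **Centering** of the peripheral subset is its initial minus
its mid-utterance variability; positive values mean off-target productions
moved toward the vowel median during the syllable. The **time-reversed
control** re-selects "peripheral" trials by mid-window distance and
measures their apparent movement backwards in time; if forward centering
merely reflected regression to the mean, forward and reversed movement
would be statistically equivalent.

Error-marked speak trials (omissions, misselections, severe distortions,
other words) and artifact-marked listen trials remove *both* members of
the speak/listen pair, keeping the two conditions acoustically matched.

## The synthetic speaker model

No raw audio or MEG accompanies the study, so every stage is exercised on
a generator with known ground truth. Per trial, a latent feedforward
deviation $\varepsilon \sim N(0, \sigma_{\text{init}}^2 I)$ in the mel
F1–F2 plane persists through the syllable unless corrected, and each
analysis window adds independent noise:

$$\text{init} = \mu_v + \varepsilon + \nu_1, \qquad
  \text{mid} = \mu_v + (1 - g)\,\varepsilon + \nu_2,
  \qquad \nu_i \sim N(0, \sigma_{\text{mid}}^2 I).$$

The **centering gain** $g \in [0,1]$ is the fraction of the planned
deviation removed by mid-utterance. Two properties motivated this
parameterization over the simpler "mid = (1−g)·init + noise" form:

* at $g = 0$ the two windows are *exchangeable* (equal variance, symmetric
  dependence through the shared $\varepsilon$), so the forward-vs-reversed
  comparison is an exact null — any apparent centering is pure regression
  to the median. Under the simpler form the mid window would have strictly
  larger variance at $g = 0$, and the regression-to-the-mean control could
  never be calibrated;
* expected centering increases strictly with $g$, and $g = 1$ with
  $\sigma_{\text{mid}} = 0$ collapses every mid-window point onto the
  median.

**Default calibration.** The defaults were chosen once, by Monte Carlo, so
that a default cohort (15 speakers per group, 3 words × 200 trials × 2
conditions, 125-trial peripheral subsets) reproduces the study-scale group
means: peripheral trials start ≈ 62 mels from the median and end
≈ 42 mels away, i.e. ≈ 20 mels of centering (a ≈ 32% reduction). This
gives $\sigma_{\text{init}} = 25.2$ mels, $\sigma_{\text{mid}} = 12$ mels,
and $g = 0.22$. A note on the gain: once the peripheral initial distance
is pinned at 62 mels, no gain above ≈ 0.45 can leave a 42-mel mid distance
in this model, so the default gain is modest; $g = 0.5$ remains the
canonical value in the power and parameter-recovery simulations. Listen
trials replay the recorded audio and therefore mirror the speak trials'
acoustics exactly. Materialized formant tracks are piecewise linear
(initial value over the first 50 ms, a transition, then the mid value),
which makes the windowed summaries recover the generated points exactly —
real trajectories are smoother, but the analysis only consumes the two
window means.

What the generator does *not* emulate: consonant transitions, f0/formant
interaction, trial-to-trial duration variation, perceptual error
adjudication, or any systematic group difference in acoustics (both
groups share the same generative parameters by default; only the error
rate differs, 0.5% for controls vs 10% for the aphasia group). Passing
tests therefore demonstrate correctness of the *analysis*, not realism of
aphasic speech.

## Evoked responses and SIS

Epochs run from −700 to 400 ms around sound onset at `sfreq` Hz, with a
−700 to −400 ms baseline (kept clear of preparatory movement). The evoked
pipeline is:

1. **Functional ROI**: at the latency of the listen-condition M100, the
   highest-amplitude vertex (optionally restricted to a lateral-surface
   mask) seeds a region grown to exactly 10 connected vertices, restricted
   to vertices with at least 33% of the map maximum; if 10 cannot be
   captured the threshold drops one percentage point at a time (floor 1%,
   then an explicit error). Growth is greedy by amplitude with ties broken
   toward the lowest vertex id — the published procedure fixes the size
   and threshold but not the growth order, and a deterministic rule is
   required for reproducibility.
2. **Waveform**: average over trials per vertex, RMS across the 10
   vertices per sample, then z-score against the waveform's own baseline
   mean and SD. A zero-SD baseline is an explicit error.
3. **M100 peak**: maximum z in a 70–180 ms search window (earliest sample
   on ties; a flat window returns a no-peak flag). Peak identification is
   automated — the published procedure confirmed peaks by eye, which a
   pipeline cannot do — and peaks below `low_snr_z = 3.5` are flagged
   low-SNR; that threshold was calibrated on noise-only simulations so
   that pure-noise waveforms are usually flagged.
4. **SIS** = listen peak − speak peak (z units); negative values are
   speaking-induced *enhancement*. **SIS fall-off** = SIS in the center
   half of trials minus SIS in the peripheral half (median split within
   vowel; listen halves are the paired trials of each speak half).
5. **Laterality indices** = (right − left)/(right + left) for latency,
   amplitude, and SIS; for SIS, negative values are clamped to 0 first and
   a zero denominator excludes the participant (a distinguished sentinel,
   not a number).

The synthetic evoked generator drives a canonical M50/M100/M200 Gaussian
morphology (50/100/200 ms latencies, 12/18/30 ms widths, 0.4/1/0.5
relative amplitudes) on a smooth spatial bump over an abstract vertex
lattice, plus i.i.d. Gaussian noise. Listen trials carry the full M100;
each speak trial's M100 is scaled by
$\mathrm{clip}(1 - \rho + \kappa \tilde d, 0, 1)$, where $\tilde d$ is the
trial's within-vowel rank-normalized initial distance — so the most
typical productions are suppressed the most, and $\kappa > 0$ produces
SIS fall-off downstream.

**A measurement subtlety worth knowing.** Because each waveform is
z-scored by its *own* baseline SD, every z-scored peak carries a
multiplicative error equal to the relative error of that SD estimate
(about $1/\sqrt{2(n_b - 1)}$ for $n_b$ baseline samples — 8% at 250 Hz,
4% at 1 kHz). Two consequences for the simulations: the scale-invariant
SIS/listen ratio used for parameter recovery is measured on the raw RMS
peaks (its low-noise limit is exactly the generative $\rho$, whereas the
z-path error does not vanish at low noise), and the per-replicate sign of
simulated SIS fall-off is only reliable when the baseline is long enough —
the fall-off recovery simulations therefore sample at 1 kHz.

## Lesion profiling

Lesion and atlas ROI masks are binary volumes on a shared grid.
`percent spared` = 100 · |ROI ∖ lesion| / |ROI| by exact voxel counts (no
partial-volume weighting, matching nearest-neighbor–normalized binary
maps); total lesion volume = lesion voxel count × voxel volume in mm³.
Whether to count voxels or mm³ only matters for anisotropic voxels; voxel
counts are used, equivalent for the uniform grids produced upstream.
Segmentation, normalization, and ventricle exclusion are upstream
responsibilities — masks arrive final. The synthetic geometry (ellipsoid
lesion over box ROIs) is deliberately simple so overlaps are exactly
enumerable.

## Statistics

* **Mixed type-III ANOVA** with subject nested in group: the classical
  univariate repeated-measures decomposition. Each within-subject effect
  is extracted per subject by orthonormal contrasts over its cells;
  between-subject effects are tested against the Subject(Group) mean
  square and within effects (and their Group interactions) against the
  corresponding Within×Subject(Group) mean square. Sums of squares are
  type III (unweighted means under sum-to-zero contrasts), so unequal
  group sizes — e.g. after excluding non-suppressors — are handled;
  subjects with incomplete within-cells can be dropped explicitly. On
  balanced designs the table reproduces `aov`'s error-strata output
  exactly, and a two-condition design's F equals the paired t².
  The published Hemisphere × Subject F tests imply error terms a standard
  mixed design does not produce; conventional error terms are used and no
  attempt is made to match those degrees of freedom.
* **Correlations**: Pearson; Spearman as Pearson on mid-ranks; partial
  Spearman as rank-transform followed by residualization on the covariates
  (the quantity is standard, the algorithm was unspecified; the
  first-order recursion formula serves as the independent test oracle).
  Rank-based methods are the caller's choice for bounded variables such as
  percent spared.
* **t tests** default to the pooled equal-variance form — the study's
  reported df (28 for 15 + 15) identifies that choice — with Welch behind
  a flag; zero-variance data yield t = 0 when means agree and an explicit
  error otherwise.
* **Pure-tone average**: mean of the 500/1000/2000 Hz thresholds per ear.
* No multiple-comparisons correction anywhere; all p values are reported
  uncorrected. The significance level is 0.05 throughout.

## Numerical choices

* Windows are half-open `[start, end)`; comparisons use a 1-ns tolerance
  so floating-point representation of window bounds (e.g. `0.75 * 0.2`)
  cannot pull an exact-boundary sample into the wrong window. Sample
  spacings are ≥ ms scale, so the tolerance is inert otherwise.
* Distance ties at subset boundaries are broken by trial id order; vowel
  quotas use ⌈n/#vowels⌉ with the remainder assigned lexicographically;
  median splits give the extra trial of an odd vowel count to the center
  half.
* The ROI threshold decrements in exact percentage points from 33% with a
  1% floor; seed ties go to the lowest vertex id.
* Per-speaker seeds are derived from the master seed (kept below 2³¹), so
  cohorts, epochs, masks, and pipeline summaries are bit-identical across
  runs with the same configuration.

## Problem sizes

The default cohort mirrors the study design (15 + 15 speakers, 3 × 200
× 2 trials). The evoked simulations run on reduced sizes chosen as the
package's own defaults — tens of vertices on an abstract lattice (real
source spaces have ~15,000; the non-goal list excludes realistic meshes),
250 Hz sampling for pipeline runs, 1 kHz where baseline-SD precision
matters, and 60–400 trials per condition. The test suite's calibration
check uses 200 replicates of 30 speakers × 150 peripheral trials; power
and recovery checks use 30–60 replicates.

## Known limitations

* The generator shares acoustic parameters across groups, so group
  contrasts on synthetic data are null by construction (only error rates
  differ); it cannot validate analyses of real group differences.
* Automated peak picking can lock onto noise in very low-SNR waveforms;
  the low-SNR flag marks, but does not adjudicate, such cases.
* The ANOVA layer supports one between-subject factor and fully crossed
  within-subject factors with one observation per cell — the designs the
  study uses — not general unbalanced mixed models.
* Laterality indices assume both hemispheres were measured; there is no
  imputation for missing hemispheres.
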