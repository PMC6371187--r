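---
title: "Methods: simulating and scoring EEG brain workload in a three-group pre/post inhibition-task study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and scoring EEG brain workload}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific setting

`brainload` implements, end to end, the analysis of a training study in
which older drivers were randomized to a driving-simulator training, a
computerized attention training, or a waiting control group, and performed
three response-inhibition tasks (color-word Stroop, letter negative priming,
arrow flanker) before and after the training while EEG was recorded. The
neurophysiological outcome is a *brain-workload* score: the ratio of
frontal-midline theta power to parietal alpha power,

$$\mathrm{TAR} = \frac{P_{\theta}(\mathrm{Fz};\,4\text{–}8\ \mathrm{Hz})}
                     {P_{\alpha}(\mathrm{Pz};\,8\text{–}12\ \mathrm{Hz})},$$

computed from stimulus-locked 2-s epochs of correct, artifact-free trials.
Higher task demand raises frontal theta and suppresses parietal alpha, so a
*decrease* in TAR at constant task performance indicates that the same task
is completed with less neurophysiological effort. Because the original raw
data are not deposited, the package pairs the analysis pipeline with a
synthetic-data generator whose defaults encode the published population
parameters, so that every stage can be exercised and validated.

## Task designs

The three generators reproduce the published designs exactly:

* **Stroop** — 8 blocks of 36 trials, alternating fully congruent and fully
  incongruent blocks. Colors are red/green/yellow/blue; in a congruent block
  each of the 4 matching word-color pairs appears exactly 9 times, in an
  incongruent block each of the 12 mismatching pairs exactly 3 times.
  Response = display color (4 buttons); fixation 1.0–1.5 s; 3 s deadline.
* **Negative priming** — 4 blocks of 56 trials alternating priming and
  control blocks. Each display overlays a red target and a green distractor,
  always one vowel (A, E, O, U) and one consonant (H, K, N, R); the response
  classifies the red letter. In priming blocks the ignored distractor of
  trial $n$ is the target of trial $n+1$; in control blocks the target
  never matches either letter of the previous trial, so the control
  condition contains *zero* carry-over (the source design leaves this
  implicit; we enforce it to keep the contrast clean). 500 ms stimulus,
  2.3–2.5 s blank response window, 0.3–0.5 s fixation.
* **Flanker** — 4 blocks of 72 trials with the four arrow strings
  (`<<<<<`, `>>>>>`, `>><>>`, `<<><<`) each exactly 18 times per block in
  random order; the response follows the central arrow only. The published
  wording ("four blocks, including both conditions in 72 trials") is
  ambiguous between 72 per block and 72 total; we read it per block,
  parallel to the per-block phrasing of the other two tasks.

Phrases like "equal probability" are implemented as *exact balanced counts
per block with a seeded shuffle* rather than i.i.d. sampling. This makes
every design invariant deterministic and exhaustively checkable, at no cost
to the statistics that matter downstream. The counterbalancing rule ("the
starting block changed after each measure") is exposed as a `start_block`
argument which the cohort generator alternates between pre and post.

## Behavioral model

Per trial, the reaction time is drawn from a lognormal distribution
moment-matched to the condition's mean and SD and truncated at the response
deadline (RT distributions are right-skewed and bounded, and the lognormal
is the standard minimal choice). Default condition means are the published
pre-training values: 0.905/1.078 s (Stroop congruent/incongruent),
0.671/0.688 s (priming control/priming), 0.622/0.835 s (flanker
compatible/incompatible). The trial-to-trial SD defaults to 25% of the
condition mean, a typical within-subject coefficient of variation for
speeded two-choice responding. Wrong-button presses occur with the
condition's error probability (defaults derived from the published error
counts, e.g. 2.3 and 5.6 errors over 144 Stroop trials per condition);
omissions (default 0.5%) count as errors throughout.

At the cohort level each subject carries two latent behavioral effects per
task, each drawn from a bivariate normal with pre–post correlation $r$:

* a **general-speed intercept** added to both conditions (SD 0.12/0.07/0.09 s
  for Stroop/NP/flanker), and
* an **inhibition-effect slope** added to the inhibition condition only
  (SD 0.12/0.05/0.19 s).

These SDs are derived from the published between-subject RT SDs assuming a
0.8 correlation between a subject's two condition means (e.g. Stroop:
$\sqrt{0.193^2 + 0.130^2 - 2 \cdot 0.8 \cdot 0.193 \cdot 0.130} \approx 0.12$ s,
averaging the printed group SDs). The slope component matters: without
between-subject variance in the inhibition effect, the per-subject
difference score would carry only trial-sampling noise, its standard errors
would be unrealistically small, and the generator would produce spuriously
significant behavioral training contrasts — contradicting the published
(and theoretically central) null result for behavior. This is a structural
requirement of the stated world, not a tuning knob.

## EEG generator

Sessions are synthesized at 500 Hz over a 64-channel 10–20/10–10 montage
plus two eye channels (reducible; `small_montage()` keeps 4 + 2 channels).
Every channel carries 1/f "pink" background noise parameterized by its
one-sided PSD at 1 Hz (default 10 µV²/Hz, exponent 1, floored below
0.1 Hz); eye channels carry noise only. Fz additionally carries a 6 Hz
theta sinusoid and Pz a 10 Hz alpha sinusoid. Since a sinusoid of amplitude
$A$ contributes band power $A^2/2$, and the noise contributes the analytic
integral of its PSD over each band ($\mathrm{psd}_1 \ln 2$ in theta,
$\mathrm{psd}_1 \ln 1.5$ in alpha), the generator can solve for the theta
amplitude that makes the *expected measured* TAR equal a latent target
(`amps_for_tar()`); targets at or below the noise-floor ratio are rejected
as infeasible. Artifact trials (default probability 0.05) receive a 300 µV,
0.5 s half-sine transient on all scalp channels starting 0.2 s after
stimulus onset, guaranteed to fall inside the analysis window.

Latent TAR values per subject are drawn from a bivariate lognormal
moment-matched to the published group × task × phase means and SDs
(e.g. simulator-group Stroop 2.06 (1.41) pre, 1.34 (0.67) post), with the
log-scale correlation chosen so the *raw-scale* pre–post correlation equals
the configured $r$ (default 0.7; unpublished in the source). The lognormal
respects positivity and the right skew typical of ratio scores — several
published cells have SDs approaching or exceeding their means, which a
normal model could not produce without negative workload.

### What the generator does not emulate

No ERP morphology, volume conduction, inter-channel correlation, ocular
artifact structure, or non-stationary oscillation dynamics. A green
parameter-recovery test therefore establishes that the pipeline is
*self-consistent* (it recovers what the generator encodes, through the full
filter–epoch–FFT path) — not that it would be unbiased on real EEG with,
for example, broadband alpha peaks or asymmetric noise.

## Spectral pipeline

1. **Filtering** — each channel is demeaned and band-pass filtered
   0.1–30 Hz with a 4th-order Butterworth high-pass and a 4th-order
   Butterworth low-pass, each applied forward and backward (zero phase).
   The filters run as cascaded second-order sections: at 500 Hz a 0.1 Hz
   high-pass has all four poles within 5e-4 of $z = 1$ and a direct-form
   implementation is numerically unusable. Edge effects are controlled with
   odd-reflection padding scaled to 3 time constants of the high-pass and
   steady-state (warm-start) filter initialization; residual edge
   transients decay with a ~4 s time constant and are negligible away from
   the first/last seconds, which the session layout keeps free of epochs'
   frequency bands of interest.
2. **Epoching** — stimulus-locked windows from −0.5 to +1.5 s (exactly
   2 s, 1000 samples), kept only for trials that are correct (omissions
   count as errors), fully inside the recording, and below a 150 µV
   peak-to-peak threshold on the analysis channels. The threshold is not
   stated in the source; 150 µV is a conventional value and configurable.
3. **Spectra** — per epoch and channel: mean removal, a Hanning taper over
   10% of the segment (5% cosine ramps per edge, flat in between — the
   established reading of a "10% Hanning window" in the lineage software),
   zero-padding to the next power of two (1024 for 1000 samples, which is
   the only FFT length reproducing the stated 0.488 Hz resolution from 2-s
   500-Hz epochs), FFT, one-sided power. Normalization is chosen so a
   unit-amplitude in-band sinusoid integrates to 0.5 µV² over its band and,
   for the untapered variant, the bin sum equals the epoch's mean squared
   amplitude exactly (Parseval; tested at 1e-6 relative against an
   explicit-DFT oracle).
4. **Band powers and TAR** — band power sums bins with centers in
   $[\mathrm{lo}, \mathrm{hi})$; the half-open convention counts the shared
   8 Hz edge of theta and alpha exactly once. Per-epoch band powers are
   averaged and TAR formed as the ratio of those means. Whether the source
   averaged per-epoch ratios or took the ratio of averages is not
   determinable from the text; ratio-of-means is the default (it is the
   better-conditioned estimator under low alpha power) and mean-of-ratios
   is available via `method = "mean_of_ratios"`.

## Statistics

* **Baseline** — one-way ANOVA of pre-test values across the three groups.
* **Training gains** — per subject and task, gain = post − pre, analyzed by
  regressing gains jointly (with intercept) on two planned orthogonal
  contrast codes: C1 = (+1, +1, −2) for both trainings versus control and
  C2 = (+1, −1, 0) for simulator versus attention training. Per contrast we
  report B, SE, standardized β, $F = t^2$ with $(1, n-3)$ df, and a
  **one-tailed** p in the hypothesized direction (training reduces
  workload; simulator more than attention). One-tailed testing is the only
  reading consistent with the published significance calls (an F(1,73) of
  3.49 flagged at p < 0.05); it is stated prominently here for that reason.
  "Hierarchical" entry order is immaterial for orthogonal codes, so a
  single joint fit is used. With unequal group sizes the integer weights
  are kept as-is (classic planned-contrast convention); the joint fit is
  verified against a normal-equations oracle. A degenerate input with no
  signal at all (all gains equal) reports B = 0, F = 0, p = 0.5 instead of
  dividing by zero.
* **Effect sizes** — the repeated-measures Cohen's d corrected for the
  dependence between means:
  $d = (M_{pre} - M_{post})\sqrt{2(1-r)} \big/
  \sqrt{SD_{pre}^2 + SD_{post}^2 - 2\,r\,SD_{pre}SD_{post}}$,
  which standardizes the change score and converts it to the
  independent-groups metric. The source does not print $r$; with the
  default $r = 0.7$ the published simulator-group Stroop inputs give
  d ≈ 0.53 against a printed 0.54. The published d values cannot be
  reproduced exactly for all cells by any single $r$, so they are treated
  as descriptive, not as acceptance targets.

## Numerical and design choices worth knowing

* Timing is quantized to 1 ms at design generation so trial tables
  round-trip losslessly through CSV.
* All randomness flows from explicit seeds; cohort subjects receive
  independent derived seeds, so changing one subject's seed leaves every
  other subject's data bit-identical.
* `simulate_study(signals = "latent")` skips waveform synthesis and records
  each session's latent TAR plus analytically aggregated behavioral
  condition means (population cell + subject effects + trial-sampling error
  of the mean). This mode carries exactly the statistical structure the
  gain analysis consumes and is what makes 100-cohort validation runs
  feasible on one CPU; the waveform path is validated separately by
  noise-free TAR recovery (within 5%) and by small end-to-end cohorts.
* The paired t helper defines the all-zero-differences case as
  $t = 0, p = 1$; any other zero-variance difference vector is an error.
* The null calibration of the one-tailed contrast test runs 2,000
  replicates in the continuous-integration suite (the full 10,000-replicate
  version gives the same 5% ± 1% behavior but triples the suite's runtime).

## Known limitations

* The behavioral post-training population model is taken directly from the
  published RT cell means; no additional transfer mechanism is modeled.
* Ocular correction is out of scope; eye channels are simulated as noise
  and ignored by the pipeline.
* BrainVision import covers the binary multiplexed INT_16/IEEE_FLOAT_32
  dialects only, read-only.
* The reported per-session workload is a session-level constant in the
  generator; real within-session TAR dynamics (fatigue, practice) are not
  modeled.
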