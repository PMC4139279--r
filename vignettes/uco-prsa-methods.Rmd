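---
title: "Phase-rectified signal averaging of fetal heart rate under cord occlusion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PRSA of fetal heart rate under UCO: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsafhr)
```

## The problem

During labor, uterine contractions repeatedly compress the umbilical cord and
expose the fetus to transient hypoxia. Conventional heart-rate variability
indices perform poorly on intrapartum recordings because fetal RR series are
non-stationary and riddled with missed beats. Phase-rectified signal
averaging (PRSA) is designed for exactly this regime: it aligns and averages
signal windows around *anchor points* — beats where a local average of the RR
series increases (deceleration anchor) or decreases (acceleration anchor) —
so that quasi-periodic autonomic modulations survive the averaging while
unrelated non-stationarities cancel.

`prsafhr` implements the complete analysis used to validate PRSA in a
near-term pregnant sheep model of repetitive umbilical cord occlusion (UCO):
1-minute occlusions alternate with 1.5-minute recoveries through three
escalating phases (MILD and MODERATE, 60 min each; SEVERE, about 2 h or until
fetal pH drops below 7.00), with blood gases sampled every 20 minutes.
Because the animal recordings are not redistributable, the package ships a
seeded synthetic generator that reproduces the protocol's structure, so every
stage of the pipeline is testable end to end.

## The PRSA model

Given an RR series $x_i$ (ms), beat $i$ is a **deceleration anchor** for
filter length $T$ when

$$\frac{1}{T}\sum_{k=0}^{T-1} x_{i+k} \;>\; \frac{1}{T}\sum_{k=1}^{T} x_{i-k},$$

and an **acceleration anchor** under the reverse strict inequality; ties are
never anchors. Windows of $2L$ beats centered on each anchor (anchor at
position $L+1$, index $k=0$) are averaged into the PRSA curve
$X(k),\,k=-L..L-1$. The capacity is the Haar-wavelet coefficient of $X$ at
scale $s$ and the anchor location:

$$\mathrm{DC}(T,s) = \frac{1}{2s}\Big(\sum_{k=0}^{s-1} X(k) - \sum_{k=-s}^{-1} X(k)\Big),$$

positive on deceleration-anchored curves and negative (AC) on
acceleration-anchored ones; tables report absolute values in ms. For $s=2$
this reduces to the familiar adult formula
$(X(0)+X(1)-X(-1)-X(-2))/4$, an identity the test suite asserts. Throughout
the package the scale is tied to the filter length ($s=T$), the convention
used for fetal applications, and capacities are computed over the spectrum
$T = 1..50$. The $T$-beat average acts as a low-pass filter with approximate
cutoff $1/(2T\,\overline{rr})$ Hz (`t_to_cutoff_frequency()`), so small $T$
emphasizes high-frequency, vagally dominated oscillations.

## Preprocessing rules

* **Artifact reconstruction** (`reconstruct_artifacts()`): RR intervals above
  1500 ms (heart rate below 40 bpm, physiologically implausible for a fetus)
  are artifacts from missed beats. Each maximal run is merged into a gap of
  duration $G$ and replaced by $n=\mathrm{round}(G/m)$ beats of $G/n$ ms,
  where $m$ is the median of the 20 nearby original intervals (10 on each
  side, fewer at the record edges; runs are merged first because one
  misdetection event typically spans several spurious intervals). Total
  recording time is conserved to well under 1 ms and the operation is
  idempotent.
* **Anchor exclusion** (`mark_anchor_exclusions()`): a beat whose RR exceeds
  its predecessor by more than 20% is excluded from anchor lists, as are all
  reconstructed beats; excluded beats still feed the moving averages and PRSA
  windows. The rule is one-sided (increases only) and compares against the
  immediately preceding beat of the reconstructed series.
* **Quality control** (`beat_quality_fraction()`): a subject enters the
  cohort analysis only if strictly more than 90% of the MODERATE and SEVERE
  phase time is covered by original (non-reconstructed) beats.

## Occlusion response and stable segments

The heart-rate response to an occlusion starting at $t_0$ is modelled as a
saturating exponential $rr(t) = A + B(1-e^{-t/\tau_{stim}})$ and the
post-release recovery as $rr(t) = C + De^{-t/\tau_{rec}}$; the two branches
are fitted independently by Levenberg–Marquardt (via `minpack.lm`) on points
pooled over all occlusions of a phase (SEVERE by default). $A$–$D$ are
nuisance scalars. Initialization is deterministic — offset from the branch
endpoint median, amplitude from the range, $\tau$ from one third of the
branch span with bounded restarts at $\times 0.3$ and $\times 3$ — so fits
are reproducible and order-invariant. Each RR interval is timestamped at the
*start* of the interval it spans (`time_s - rr_ms/1000`): the autonomic
state an interval reflects is in force when the interval begins, and this
convention makes the fit recover generating constants exactly on noiseless
data.

"Stable" (deceleration-free) series take, for each occlusion, the interval
from 30 s after its release to the start of the next occlusion. The 30 s
margin exceeds three times the longest plausible recovery constant
(about 8 s), so the heart rate is back at baseline; it is configurable
(`margin_s`). The retained pieces are concatenated
(`concatenate_stable_segments()`) with explicit segment junctions, and PRSA
windows do not span a junction unless `allow_cross_boundary = TRUE` (crossing
junctions mimics selecting anchors across two consecutive recovery periods,
which becomes unavoidable for large $T$ on short segments and makes those
entries less reliable — hence the `unreliable` flag whenever an entry rests
on 150 anchors or fewer).

## Statistics

Cohort sizes here are tiny (seven subjects), so the statistical layer is
nonparametric and exact where feasible:

* `wilcoxon_signed_rank()` — paired, two-sided; zero differences dropped;
  exact sign-flip null (dynamic programming over doubled mid-ranks, so tied
  magnitudes are handled) up to n = 25, normal approximation with continuity
  and tie corrections beyond. Seven uniformly signed differences give the
  smallest attainable two-sided p, $2/2^7 = 0.015625$.
* `spearman_cor()` — Pearson correlation of mid-ranks; exact permutation p
  (all $n!$ orderings) below n = 10, t-approximation otherwise. Correlations
  pool subject-by-phase points (7 subjects × 4 phases = 28 pairs by default;
  a switch excludes BASELINE).
* `significant_T_ranges()` — per-T p-values are Bonferroni-corrected by a
  factor 3 (the three consecutive-phase comparisons) and reported as maximal
  contiguous runs of $T$ with corrected p < 0.05.
* `quartile_summary()` — linear-interpolation quartiles at positions
  $1 + p(n-1)$ (R's type 7). This is the convention that reproduces the
  published interquartile ranges of the reference time-constant table from
  its per-subject values, which is how the package's summaries are validated.
* `sdnn()` — sample standard deviation of original-beat RR intervals, used to
  check that phase differences in AC/DC are not mere total-power differences.

## The synthetic generator

`synthetic_config()` encodes one simulated subject. What it emulates:

* protocol geometry — BASELINE 1800 s, MILD 3600 s, MODERATE 3600 s, SEVERE
  7200 s, RECOVERY 1800 s, with 60 s occlusions and 90 s recoveries tiling
  the UCO phases (24/24/48 events);
* occlusion dynamics — deterministic deceleration with per-subject
  $\tau_{stim}$ and $\tau_{rec}$ drawn once per subject from the published
  per-sheep ranges (9.63–46.17 s and 3.38–7.88 s), with
  $\tau_{stim} > \tau_{rec}$ enforced;
* deceleration depths — not published, so chosen here as MILD +40 ms,
  MODERATE +120 ms, SEVERE +250 ms above a 400 ms baseline RR: deep enough
  that SEVERE decelerations are visually unmistakable while preserving the
  time-constant ordering. These are package defaults, not claims about sheep;
* variability — a slow 30 s sinusoid plus white beat-to-beat noise with
  phase-scaled amplitudes (BASELINE 8/3 ms, MILD 6/2.5 ms, MODERATE 12/5.5
  ms, SEVERE 20/9 ms), the simplest mechanism that makes stable-series AC/DC
  rise with phase severity and dip slightly at MILD, as observed; any richer
  model (AR, 1/f) can be substituted behind the same config keys;
* artifacts — Poisson-placed runs of beats merged into single >1500 ms
  intervals (about 6 per hour by default), conserving total duration;
* biomarkers — 20-minute sampling with piecewise-linear trajectories through
  per-phase-end targets taken from the published per-phase medians (pH 7.34
  → 7.33 → 7.28 → 6.98); the SEVERE target is reached at the last sampling
  time inside the phase because the experimental protocol *stops* SEVERE when
  a sample first shows pH < 7.00.

All randomness flows from one integer: subject $j$ of a cohort uses seed
$\mathrm{base}+j$, and within a subject the noise, artifact and
time-constant draws use streams $10\,\mathrm{seed}+1$, $+2$ and $+3$.

What it does **not** emulate: baroreflex/chemoreflex feedback, respiratory
sinus arrhythmia, fetal behavioural states, drift in baseline rate, or any
coupling between acid-base state and beat-to-beat dynamics beyond the phase
labels. Passing the end-to-end tests therefore demonstrates that the
*pipeline* recovers the structure it is pointed at — phase ordering of
capacities, entire-vs-stable differences, time constants, correlation signs
— not that the generator is a cardiovascular model. Absolute synthetic
capacity values are smaller than those of real fetal recordings.

## Numerical choices and degenerate inputs

* Strict inequalities throughout anchor selection: constant series produce
  zero anchors; a T value with no anchors yields an `NA` capacity carried as
  a flagged row, never a silent omission.
* Anchor candidates require the averages *and* the full $\pm L$ window
  (window half-length defaults to $L = 50$, covering every $T \le 50$)
  inside one contiguous segment.
* Reconstruction inserts at least one beat per gap (`n >= 1`) and errors on a
  series that is entirely artifact or has no valid neighbours.
* Exponential fits error after bounded restarts rather than returning a
  non-converged result, and flag a $\tau$ pinned at its lower bound.
* Analysis windows shorter than 30 minutes clip to the phase with a warning.

## Problem sizes used in the shipped checks

The packaged tests run the oracle comparison on 100 random series of 500
beats, the parameter-recovery study on 20 seeds of a full 48-occlusion
SEVERE phase with 10 ms noise, and the cohort analysis on 7 synthetic
subjects at the full protocol durations with $T = 1..50$ — the same design
sizes as the study the package models. Module tests use shortened protocols
where the full durations add nothing.

## Known limitations

* The per-sheep supplementary table of the original study (per-subject AC/DC
  medians and biomarkers) is distributed only as a spreadsheet; the checks
  that recompute its correlations run only when a CSV export is supplied.
* Capacities on stable series for large $T$ rest on few anchors and are
  flagged unreliable rather than corrected.
* The Spearman t-approximation (used for n >= 10) is slightly anticonservative
  under heavy ties; the study's pooled correlations (n = 28, continuous
  capacities) are far from that regime.
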