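---
title: "Temporal coherence mapping: model, conventions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal coherence mapping: model, conventions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcmap)
```

## The model

Temporal coherence mapping (TCM) asks how strongly a one-dimensional
signal's present resembles — or mirrors — its distant past. A series
$x = [x_1, \dots, x_N]$ is expanded into temporal-embedding vectors
$u_i = [x_{(i-1)g+1}, \dots, x_{(i-1)g+w}]$: windows of $w$ consecutive
samples whose start points advance in steps of the gap $g$. Each window
is one *transit state* of the reconstructed phase space, and the
$n_v \times n_v$ matrix of pairwise correlations between windows
($n_v = \lfloor (N-w+1)/g \rfloor$) — the TCM matrix — encodes when the
system revisits (positive correlation) or mirrors (negative correlation)
an earlier state. Because window $i$ and window $i+d$ are separated by a
fixed delay $d \cdot g$ samples, each diagonal of the matrix collects
all state pairs at one delay.

Six scalar metrics condense the matrix:

* **TC**, temporal coherence: the mean positive correlation,
  $\sum_i cc_i H(cc_i) / D$ with $H$ the Heaviside step ($H(0)=0$).
* **TAC**, temporal anti-coherence: the mean magnitude of negative
  correlation, $\sum_i (-cc_i) H(-cc_i) / D$.
* **CAB1** $= \mathrm{TC} - \mathrm{TAC}$: the coherence/anti-coherence
  balance.
* **MLP** / **MLN**: the matrix is binarized at $cc > r$ (positive) and
  $cc < -r$ (negative, both strict); maximal runs of 1s along each
  diagonal with length $\ge 2$ are diagonal *line segments* — states the
  system stays locked to (or locked against) for several steps. Isolated
  single points are transient flukes and are dropped. MLP and MLN are
  the summed segment lengths divided by $D$.
* **CAB2** $= \mathrm{MLP} - \mathrm{MLN}$.

Both balance measures are differences, not ratios: a ratio of two small
noisy quantities amplifies noise.

## The normalization convention

Two conventions exist for the denominator $D$ and the included pairs,
and they do not coincide. The textbook-style definition averages over
*all* off-diagonal elements, $M = (N-w+1)(N-w)$. The operational
algorithm — the one this package treats as canonical because it is what
produces the reference results — restricts the sums to the upper
triangle and to diagonals $d$ with
$\mathrm{dia}_s \le d < n_v - \mathrm{dia}_e$, but normalizes by

$$\mathrm{Totnum_{cc}} = \frac{n_v(n_v-1)}{2} -
  \frac{\mathrm{dia}_e(\mathrm{dia}_e+1)}{2},$$

which subtracts the trailing exclusion but *not* the near-diagonal one.
TC is therefore not exactly a mean over evaluated pairs: a fully
coherent ramp signal under default exclusions gives
$\mathrm{TC} = n_\text{evaluated}/\mathrm{Totnum_{cc}} \approx 0.89$,
not 1. The package follows the operational convention everywhere,
reports the evaluated pair count (`n_pairs`) next to `totnum_cc`, and
exposes the all-off-diagonal variant for TC/TAC behind
`tcm_config(convention = "text")` for comparability.

The near-diagonal exclusion `dia_s` (default $\lfloor w/3 \rfloor$,
empirically supported between $w/4$ and $w/2$) removes delays shorter
than a window, where overlapping windows correlate trivially — in fMRI
the hemodynamic response makes these diagonals near-solid lines that
would swamp MLP. The trailing exclusion `dia_e` (default $w$) removes
the longest delays, whose diagonals are too short to carry stable
segment statistics. The main diagonal (self-correlations) is never
included, under either convention.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `w` | 30 | samples | window/transit-state length; larger w admits more within-window variance and lowers all correlations |
| `r` | 0.3 | — | binarization threshold for MLP/MLN (TC/TAC/CAB1 are independent of it) |
| `g` | 1 | samples | stride between windows and between evaluated delays |
| `dia_s` | ⌊w/3⌋ | diagonals | near-main-diagonal exclusion |
| `dia_e` | w | diagonals | trailing-diagonal exclusion |
| `corr_kind` | pearson | — | `spearman` rank-correlates windows, robust to slow monotone drift when no temporal filtering was applied upstream |

The defaults are the configuration the reference results use for
1200-timepoint resting-state fMRI. The gap default of 1 is the
least-assuming choice (the reference leaves it unstated); sampling
interval only matters for physiological rates, so series are treated as
unit-spaced.

## Streaming implementation

Materializing the $n_v \times n_v$ matrix needs $O(n_v^2)$ memory
(~11 MB per voxel at $N=1200$, ruinous across a brain volume). Since
every metric decomposes over diagonals, `tcm_metrics()` streams: for
each delay it slides both windows in lock-step, maintaining the five
Pearson sufficient statistics ($\sum a$, $\sum a^2$, $\sum b$,
$\sum b^2$, $\sum ab$) by rolling updates, so a diagonal of $m$ pairs
costs $O(m \cdot g)$ instead of $O(m \cdot w)$. Numerical safeguards:

* the series is centered by its global mean once up front — Pearson is
  per-window shift-invariant, and centering prevents cancellation in
  $w\sum ab - \sum a \sum b$ for signals with large offsets;
* rolling accumulators use extended (long double) precision, and the
  metric sums use Kahan-compensated accumulation (~$7 \times 10^5$
  terms per series at $N = 1200$);
* computed correlations are clamped to $[-1, 1]$;
* a window variance below $10^{-12}$ of its raw second moment marks the
  correlation *undefined*: it contributes 0 to every sum, breaks any
  run, stays in the denominator, and is counted and warned about once
  per series. A fully constant series thus yields all-zero metrics with
  a warning rather than an error, so flat or masked-edge voxels cannot
  abort a volume run.

The full-matrix path (`tcm_matrix_full()` +
`tcm_metrics_from_matrix()`) is retained as an in-package reference and
for inspection; the test suite additionally checks both paths against a
definition-level brute force (one `cor()` call per pair, explicit run
scan) and requires agreement to $10^{-10}$. Spearman windows are ranked
once into an $n_v \times w$ matrix (ranks cannot roll), which keeps
memory linear in the input while avoiding re-ranking per pair.

Voxelwise mapping flattens the 4D volume, processes in-mask voxels in
flat column-major order, and is embarrassingly parallel; results are
bit-identical for any worker count because voxels share no state. Maps
hold `NaN` outside the mask (never 0, so background cannot leak into
statistics), compute in float64, and store as float32 NIfTI-1 with a
JSON sidecar echoing the configuration.

## Synthetic benchmarks: what they do and do not show

Three signal classes exercise the method:

* **sinusoids** — periodic and exactly balanced between positive and
  negative excursions; the balance metrics should be near 0;
* **1/f (pink) noise** — the canonical long-range-correlated signal,
  generated by spectral shaping (scale white-noise Fourier amplitudes
  by $f^{-\beta/2}$, zero DC, invert, standardize to mean 0, variance
  1). Shaping was chosen over autoregressive or wavelet synthesis for
  exact spectral control and determinism; amplitude is standardized
  because no reference scale is stated and the metrics are
  scale-invariant anyway;
* **white Gaussian noise** — the memoryless null.

Synthetic 4D volumes tile these generators over labeled voxels, with
each voxel's seed derived from a stable integer hash of (master seed,
flat voxel index), so volumes are reproducible independently of
evaluation order and worker count. These benchmarks validate the
estimator's algebra and orderings (pink > white in TC; sinusoid at or
above pink), but deliberately do not emulate hemodynamic convolution,
motion, or physiological structure of real fMRI — passing them shows
the machinery is right, not that any neurobiological claim transfers.

Two measured behaviors of the estimator itself are worth knowing.
First, the sinusoid TC/TAC plateau in $w$ is approximate: once
$w \ge$ period, per-pair correlations are exactly $\cos(2\pi l/p)$ for
whole-period windows, but the included lag set, the pair weights and
$\mathrm{Totnum_{cc}}$ all move with $w$, leaving ~0.3% variation
across $w \in \{p, p+10, 2p\}$ — a plateau relative to the sharp rise
below the period, not a constant to machine precision. Second, at
$g = 1$ the overlapping-window delays ($\mathrm{dia}_s \le d < w$)
carry a small negative expected correlation for white noise, so white
Gaussian CAB1 sits near $-4 \times 10^{-4}$ rather than exactly 0; with
20 replicates at $N = 1200$ this tiny bias is statistically detectable
even though it is practically negligible against, e.g., the 1/f
anti-coherence dominance it is compared to.

## Test-retest and physiological covariates

Repeated-session agreement uses the single-measure intraclass
correlation from the two-way ANOVA decomposition. The default is the
consistency-type ICC(3,1), the natural variant when the two sessions
are fixed repetitions of the same measurement; the absolute-agreement
ICC(2,1) is selectable. Two sampling frames are provided: across
in-mask voxels for a single pair of maps (the desk-scale frame), and
per voxel across subjects when lists of per-subject maps are supplied
(the population reliability-map frame). Degenerate voxels return `NaN`
with a warning.

Respiration and heart rate come from 400 Hz recordings: zero-phase
(forward–backward, so peak times are unbiased) 4th-order Butterworth
low-pass at 5 Hz (respiration) or 10 Hz (cardiac); strict local maxima
with prominence at least 10% of the filtered range (suppressing ripple
peaks); first differences of peak times; removal of intervals beyond
median ± 3 scaled MAD (with zero MAD, any off-median interval is an
outlier, matching the conventional default of this rule); the mean
surviving interval is the cycle. Recordings are excluded — not errored —
when the mean respiration cycle exceeds 10 s or the cardiac cycle 4 s
(strictly: a cycle exactly at the boundary is kept) or when fewer than
3 peaks survive.

## Problem sizes

The test suite runs the full synthetic grids at the study scale
($N = 1200$; periods 10–100 by 10 against $w$ = 10–120 by 10; 20
replicates per noise class over $w$ = 30–90 and $r$ = 0.2–0.6) in
under a minute of compute, thanks to the streaming core; volume-level
tests use small grids (tens of voxels, 100–300 timepoints) since
voxelwise mapping is exactly the single-series computation replicated.

## Limitations

* Only diagonal-line recurrence structure is quantified; laminarity,
  trapping time and other recurrence statistics are out of scope.
* Maps are computed from preprocessed inputs; no smoothing, filtering,
  nuisance regression or mask construction is performed here.
* The GPU backend of the original implementation is not reproduced;
  the determinism contract (bit-identical results for any worker
  count) is designed so one could be added without changing results.
* Group-level voxelwise regression of maps on covariates is standard
  GLM tooling and intentionally not duplicated in this package.
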