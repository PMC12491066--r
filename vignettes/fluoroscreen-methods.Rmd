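---
title: "Methods: melt-curve scoring and spectral discrimination for fluoroprobe screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: melt-curve scoring and spectral discrimination for fluoroprobe screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluoroscreen)
```

# Scope and rationale

Amyloid fibrils of one protein can adopt distinct molecular conformations
(polymorphs), and dyes that fluoresce selectively on a subset of polymorphs
are valuable probes for dissecting them. `fluoroscreen` implements the
computational side of a screening campaign for such dyes: scoring
differential-scanning-fluorimetry (paDSF) melt curves, triaging hits
against controls, quantifying polymorph discrimination from multispectral
confocal stacks, normalizing aggregation kinetics, and summarizing the
chemical diversity of hit sets. A seeded synthetic-data module emulates the
statistical structure of each input so every stage is testable end to end
without instrument data.

# The paDSF stage

## Assay model

Each well holds one dye and one sample (a fibril preparation, or one of
three controls: dye alone, dye + polyanion inducer, dye + monomeric
protein) heated from 25 to 95 °C at 1 °C per read, with fluorescence
recorded in six optical channels (FAM through Cy5.5). A fibril-binding dye
shows high initial fluorescence that decays as heating disrupts the binding
site; unbound dye stays near baseline.

## Curve summary and rule table

Four statistics feed the scoring rules: the raw curve's maximum (`f_max`),
minimum (`f_min`) and temperature-of-maximum (`T_at_max`), and the
amplitude `Δf` of the control-subtracted curve. Design choices here,
made once and kept:

* **`Δf` is the max − min amplitude of the subtracted series.** The
  alternative reading — the maximum of the subtracted series — is a
  one-argument switch in `summarize_curve(delta_mode = "max")`; amplitude
  is the standard DSF reading of a "Δfluorescence".
* **`f_max`, `f_min`, `T_at_max` come from the raw curve**, since the rule
  table mentions subtraction only for `Δf`.
* **Ties in the maximum resolve to the lowest temperature**, so a flat
  bright curve reports its onset, not an arbitrary late read.
* **Control pairing:** fibril wells subtract the polyanion-only control for
  the same dye and inducer (the inducer itself can fluoresce with dye);
  monomer wells subtract the no-protein control.

The rule table assigns 10/8/5/3/1/0 in descending order, first match wins
(see `?score_summary` for the exact inequalities). Two boundary
conventions make the bands tile without dead zones: an amplitude of
exactly 2500 RFU belongs to the 8 band (the 10 rule requires
strictly > 2500), and a maximum at exactly 70 °C belongs to the 55–70 °C
band (the late band requires strictly > 70). The 8/5 boundary at 1500 RFU
is half-open, owned by the higher band.

## Wells, replicates, triage

A well's score is the **maximum over its six channels** — different
chemotypes report in different channels — and the winning channel is
recorded. Scores from two biological replicates are summed into the
cumulative 0–20 score; a dye qualifies when it reaches 20 (a perfect 10 in
both replicates) against at least one sample. Qualified dyes whose monomer
control scored ≥ 5 in either replicate are excluded with an explicit
`monomer_flag`; they bind the unaggregated protein and are useless as
fibril reporters. Manual curation — rescuing dyes that just miss the bar —
is represented only as an explicit `curated_additions` argument, never
inferred, and curated dyes pass the same monomer filter.

Bright dyes are the dominant false-positive mode: small pipetting
differences at high intrinsic fluorescence masquerade as binding. Wells
whose no-protein control already exceeds 1000 RFU at the ramp start are
therefore *flagged* (`attr(score_table, "bright_dyes")`) but not removed;
removal is an analyst's decision.

Hit rates are reported as percentages rounded half-up to one decimal
(`hit_rate(30, 306)` → 9.8). For intensity-based screens read at a single
emission maximum (no ramp), `sd_activity_call()` implements the inclusive
"at least k standard deviations above the monomer mean" rule with k = 3 by
default; zero monomer variance is an error demanding an explicit
tolerance rather than a silent division.

Heatmap ordering (`cluster_order`) uses average-linkage agglomerative
clustering on Euclidean distances, rows and columns independently,
pre-sorted by identifier so the output is a deterministic function of the
table.

# The spectral discrimination stage

## Scan grid

The acquisition protocol sweeps excitation 470–670 nm in 20 nm steps; for
each excitation, contiguous 20 nm emission windows start 10 nm above the
excitation line and tile up to 780 nm (110 channels), plus an 18-window
emission sweep at 405 nm — 128 spectral channels in total.
`build_scan_grid()` enumerates this deterministically
(excitation-major) and refuses protocols whose windows do not divide the
emission span.

## Segmentation

Particles are segmented on the maximum-intensity projection across
channels (max preserves particles bright in only a few channels). The
threshold is Bradley-style adaptive: a pixel is foreground when it exceeds
the local mean over a square window (side = 1/8 of the image side,
computed exactly with an integral image) scaled by `1 + sensitivity`.
`sensitivity = 0` suits noise-free images; around 0.5 is appropriate at
the ~5 % noise levels the generator defaults to. A guard epsilon of
`1e-8 ×` the dynamic range absorbs integral-image round-off on flat
backgrounds; because it scales with intensity, segmentation is invariant
to global intensity rescaling. Foreground pixels form 8-connected
components; components under `min_area = 10` pixels are dropped. An
all-constant image yields zero particles, not an error.

## Profiles, PCA, QDA

Each particle's profile is the mean intensity over its mask in each of the
128 channels, normalized to unit sum (total-intensity normalization keeps
profiles on a simplex; unit-Euclidean normalization would weight bright
channels more — the choice is isolated in `normalize_profiles`). Profiles
from both fibril classes are concatenated and embedded with mean-centered
PCA. Component signs are fixed by making each component's
largest-magnitude loading positive, so embeddings reproduce across runs;
when two loadings tie in magnitude to machine precision the first index
wins.

Discrimination is quantified by a quadratic discriminant (per-class means
and covariances, **empirical** class priors — particle counts per
condition are unbalanced) on the first two principal components, matching
the 2-D decision boundaries used for visualization. The reported score is
the **resubstitution** accuracy; a seeded k-fold cross-validation mode
(`cv_folds`) is available for sensitivity analysis but is not the headline
number. Each class needs at least `n_components + 2` particles for an
estimable covariance; singular covariances raise with a suggestion rather
than silently regularizing. Per-inducer accuracies average arithmetically
into the overall discrimination score.

# Kinetics

Real-time aggregation traces are min–max normalized,
`(x − min)/(max − min)` — the only reading of "fraction of total signal"
that lands exactly on [0, 1]. Constant traces raise rather than return
0/0. The timing statistic is the half-time t50: the first upward crossing
of 0.5, linearly interpolated between bracketing reads (accurate to one
sampling interval by construction). Early/concurrent/late calls against a
reference use an explicit tolerance (default 2 h); tangent-based lag-time
fitting was deliberately avoided because the downstream comparisons are
qualitative and t50 is robust to plateau drift. A moving-median pre-filter
(window 3) is available but off by default. Curves that never reach 0.5
raise — a dye that inhibits aggregation has no half-time, and flagging
that is more honest than extrapolating one.

# Chemical diversity

The Tanimoto coefficient |A∩B| / |A∪B| is computed on precomputed bit
sets; fingerprint generation from structures (type, radius, bit length)
belongs to an external cheminformatics toolkit and is out of this
package's contract. Similarity histograms default to width-0.1 bins on
[0, 1] with the last bin right-closed so identity pairs are counted
exactly once; without a reference the histogram covers the n(n−1)/2
distinct pairs, with a reference the n comparisons against it.

# The synthetic-data generators

`gen_screen()` emulates the screen's statistical structure: 306 dyes × 26
fibril samples (WT and P301S × 13 polyanion inducers) in two biological
replicates with the three control types, by default. Dyes are assigned
archetypes — pan-binder, WT-selective, P301S-selective, monomer-binder,
inert, bright-artefact — whose RFU parameters are placed around the rule
thresholds so the noise-free archetypes map onto known scores: binders
(baseline 200, amplitude 3000, logistic melt decay with midpoint 45 °C,
width 3 °C, active in the FAM channel) earn exactly 10 on their targets;
monomer binders (amplitude 1200) earn exactly 5 on the monomer control and
are therefore excluded by the default triage cutoff; inert dyes are flat
at baseline; bright artefacts are flat at 5000 RFU everywhere, scoring 0
(zero amplitude) but tripping the bright-dye flag. Every curve's noise
comes from a substream seeded by (master seed, well key), so enlarging a
design never perturbs existing wells, and the same seed reproduces output
byte for byte.

`gen_ember()` renders Gaussian particles (σ = 1.8 px, peak ≈ 1000 above a
200-unit detector background) on a jittered cell grid that guarantees
non-overlap; each class's channel intensities follow a bivariate Gaussian
response (σ = 60 nm) over (excitation, emission midpoint), with class B's
peak shifted by `shift_nm` in both coordinates (clamped to the grid with a
warning). `gen_kinetics()` produces logistic
`baseline + plateau / (1 + exp(−(t − t50)/rate))` curves over 0–48 h.
All generators record their planted truth (archetypes, intended scores,
particle centres, curve midpoints) so recovery can be checked without
reading generator internals.

What the generators do **not** emulate — and hence what passing tests do
not establish about real data: instrument-specific baseline drift and
optical crosstalk between channels; heteroscedastic, intensity-dependent
photon noise; dyes that shift wavelength without intensity change;
aggregation inhibition by the dye itself; spatially correlated image
background; and real chemical-series structure in fingerprints. Tests on
synthetic data validate the *pipeline logic and its statistical
behaviour*, not assay performance on any particular instrument.

# Problem sizes and determinism

The shipped test suite runs desk-scale versions of each study: screens of
6–30 dyes against 2–8 conditions, spectral stacks of 96 × 96 px with 30–40
particles per class over the full 128-channel grid, 10-seed repetitions
for the stochastic properties (triage degradation under noise,
discrimination at 0 vs 60 nm shift). The chance band asserted for
zero-shift discrimination ([0.45, 0.70] for the 10-seed mean) was frozen
from an independent null simulation of resubstitution QDA at the same
sample size. All randomness flows through explicit seeds; re-running any
generator or the acceptance script with the same seed reproduces its
output exactly.

# Known limitations

* The scoring rule table is a fixed-threshold heuristic; wells near
  several thresholds at realistic noise levels flip scores, which is why
  triage demands a perfect 20 across replicates rather than a softer sum.
* Resubstitution QDA is optimistically biased (the chance band above sits
  near 0.59, not 0.50); it is used because it is the field's convention
  for this discrimination score, and the cross-validated mode exists for
  honest generalization estimates.
* Segmentation assumes particles brighter than their local background;
  dim particles inside a bright neighbour's window can be missed.
* Tanimoto values depend entirely on the upstream fingerprint definition,
  which this package intentionally does not control.
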