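---
title: "Methods: from oscillations to multilayer integration and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from oscillations to multilayer integration and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megmultiplex)
```

This vignette records the model, the defaults, and the design choices made
where the underlying methodology leaves room — the things a maintainer
would otherwise have to reverse-engineer from the code.

## The pipeline model

A recording is a real matrix of region-level source signals (time ×
regions) with a sampling frequency, nominally 78 cortical regions at
1250 Hz. The analysis chain is:

**Epoching.** The first `max_epochs` (default 60) consecutive,
non-overlapping epochs of `epoch_length` (default 4096) samples. Partial
trailing data is discarded; fewer samples than one epoch is an error, not
a silent truncation.

**Band filtering.** Per epoch and channel, the signal is mean-centered
and its DFT is masked to the band, then inverse-transformed. Bands are
half-open `[f_lo, f_hi)`: a bin exactly on a shared edge (8 Hz between
theta and lower alpha) belongs to the *higher* band, so adjacent bands
never double-count a bin. Mean-centering removes the DC bin
deterministically. No samples are trimmed after filtering; tests that
need analytic precision evaluate mid-epoch samples where Gibbs effects
are negligible. The inverse transform's imaginary residue is asserted
below `1e-9` of the signal norm (relative to the *input* norm, so a
signal with no in-band energy passes with an output of zeros), then
discarded.

**Phase and PLI.** The phase is the argument of the FFT-computed analytic
(Hilbert) signal of each band-filtered channel, per epoch, without
padding — the standard estimator in the PLI literature; the value at the
branch point is mapped so all phases lie in `(-pi, pi]`. For a region
pair,

$$\mathrm{PLI} = \left| \frac{1}{T}\sum_t \mathrm{sign}\,
\sin(\varphi_a(t) - \varphi_b(t)) \right| \in [0, 1],$$

with `sign(0) = 0`: an exactly zero phase difference *dilutes* the mean
rather than counting as a lag, which is what makes the index blind to
zero-lag (volume-conduction-like) coupling and gives identical signals a
PLI of exactly 0. PLI is invariant to amplitude scaling by construction
(only phases enter). Per-epoch matrices are averaged; averaging k copies
of the same epoch reproduces the single-epoch matrix exactly.

**Backbone.** Each weighted layer is binarized to a spanning tree with
Kruskal's algorithm. "Minimum spanning tree" in the MEG literature means
the *strongest-connection* backbone — the tree maximizing total PLI
(equivalently the minimum tree on the distance `1 - PLI`); a literal
minimum over PLI weights would keep the weakest links and is not what the
cited methodology computes. Ties between equal weights are broken
lexicographically on `(min node index, max node index)` so the result is
deterministic; exact PLI ties are measure-zero in practice but occur in
constructed tests. A disconnected weight graph (possible only with exact
zeros) is an error listing the components.

**Multiplex.** The L tree layers are stacked into an `(L·N) × (L·N)`
supra-adjacency matrix with identity interlayer blocks scaled by the
interlayer weight (default 1, giving a fully binary multilayer network).
The link counts follow closed forms: `L(N−1)` intralayer and
`N·L(L−1)/2` interlayer undirected links — 462 and 1170 for six layers
of 78 nodes.

**Multilayer eigenvector centrality.** The leading eigenvector of the
supra matrix, computed by a deterministic symmetric eigendecomposition
(LAPACK) rather than power iteration — same limit, no iteration-count or
tolerance knobs to document, and deterministic up to sign, which is fixed
by requiring a nonnegative vector (Perron–Frobenius guarantees one on a
connected supra graph; connectivity is checked and a disconnected supra
matrix is an error). Each node's L replica entries are then **averaged**
(sum is equivalent up to the final rescaling and selectable), and the
aggregated vector is rescaled to maximum 1. When all layers are
identical to adjacency A the supra matrix is
$I_L \otimes A + (J_L - I_L) \otimes I_N$, whose leading eigenvector is
$\mathbf{1}_L \otimes v_A$; the aggregated result therefore reduces to
single-layer eigenvector centrality of A, independent of the interlayer
weight — both facts are regression tests. The absolute scale of the
reported centrality is a convention (max = 1, recorded in output
metadata); group means from other normalizations are not comparable.

**Frontoparietal average.** Nodal centralities are averaged over a node
set, yielding one integration value per subject per timepoint. The
canonical frontoparietal membership table is not reproducible here, so
`default_fpn_nodes()` ships a clearly-labeled *synthetic stand-in*
(a deterministic subset of the generator's `R1..RN` labels); any real
analysis must supply its atlas-matched node-set file.

## Cohort statistics

* **Impairment**: Z < −1.5, strict; −1.5 itself is unimpaired; missing
  propagates as missing.
* **Change scores**: T2 − T1 per subject, per-measure omission of missing
  components with logged counts.
* **Paired tests**: Shapiro–Wilk on the differences at α = 0.05 decides
  paired t versus Wilcoxon signed-rank (two-sided; exact Wilcoxon p for
  n ≤ 25, normal approximation with continuity correction above). The
  underlying methodology says only "t-test (or nonparametric Wilcoxon)";
  the explicit normality gate is this package's rule, and the same gate
  governs parametric-vs-rank choices in covariate screening (Pearson vs
  Spearman for continuous candidates, t vs Mann–Whitney for binary,
  ANOVA vs Kruskal–Wallis for categorical — resolving an ambiguity the
  source leaves open).
* **Backward elimination**: all entered predictors (including the
  literature-motivated covariates — nothing is forced to stay), removal
  of the largest-p predictor while p ≥ 0.10. The 0.10 criterion is the
  default of the statistical software the methodology implies but never
  states; it is configurable. Categorical predictors enter as
  reference-coded indicators (configurable references) and are removed
  indicator-by-indicator. Standardized betas are `b · sd(x)/sd(y)` on
  the complete-case analysis set; the achieved n is reported because
  missingness varies by regression. Candidate covariates correlating at
  |r| > 0.8 are pre-pruned keeping the first-listed.
* **Bonferroni**: α/m, 0.05/3 = 0.0167 at the 4-decimal report
  precision.

## The synthetic world

`simulate_sources()` builds each channel as a sum over bands of
band-limited Gaussian noise (FFT-masked white noise, unit SD) plus
broadband white noise (`noise_sd = 1`). A coupling edge replaces the band
component of a region pair with a shared carrier mixed against the
independent component: strength *s* gives `s·c + sqrt(1−s²)·indep`, and
the second region receives the carrier rotated by the lag as a constant
phase shift across the band. This produces stationary signals whose
expected PLI is monotone in *s* without committing to a neural model.

Two honest limitations of this world, measured with the package's own
pipeline and frozen into the tests:

1. **The per-epoch |PLI| floor.** For two *independent* band-limited
   signals the phase difference decorrelates at the band's inverse
   bandwidth, so one 3.28 s epoch of a 2 Hz band holds only ~6.5
   effective samples; |mean sign sin| of a zero-mean estimate then has
   expectation ≈ `sqrt(2/(π·B·T))` ≈ 0.27 — and because the absolute
   value is taken per epoch, averaging more epochs does **not** shrink
   it. Narrow bands therefore floor near 0.2–0.27 and wide bands near
   0.1. Claims that uncoupled pairs fall below 0.1–0.2 are unattainable
   in this model; the tests assert the floor at its analytic value
   (×1.5 slack) instead.
2. **Strength does not saturate PLI.** At s = 0.9 each channel keeps
   `sqrt(1−0.81)` ≈ 0.44 of independent amplitude, i.e. ~0.45 rad of
   phase jitter, so the coupled-pair PLI plateaus near 0.7, not above
   0.8. Tests assert the coupled pair exceeds 0.55 and beats every
   uncoupled pair by ≥ 0.25, and that the coupled-vs-uncoupled *ordering*
   survives the full pipeline in ≥ 95% of seeds — the property the
   pipeline actually needs.

What a green spectral test therefore establishes: the pipeline preserves
planted coupling topology and lag structure. What it does not establish:
behavior under nonstationarity, 1/f spectra, field spread, or realistic
source mixing — none of which the generator emulates.

`simulate_cohort()` draws T1 centrality as `Normal(0.41, 0.10)` — the
scale typical of max-normalized FPN averages in cohorts like the one this
pipeline targets, chosen purely as a realistic scale, not a reproduction
target — with T2 = T1 + `Normal(0, 0.05)` drift. The target EF Z-score is
`beta_ec · std(EC) + Σ beta_k · std(covariate) + noise`, with the residual
SD defaulting to `sqrt(1 − Σβ²)` so the score is approximately standard
normal; the T2 score adds `ec_change_coupling · std(ΔEC)` plus fresh
noise. Covariate distributions (epilepsy ~0.89, three molecular subtypes
16:14:6, four treatment arms, ~12-month intervals, age 41.7 ± 12.3)
mirror a realistic glioma cohort. Every generator is a pure function of
`(spec, seed)`; one global seed fans out to per-component substreams via
a counter scheme (multiplicative hash mod 2³¹−1) so adding a component
never perturbs another's draws.

## Numerical choices and degenerate inputs

* Symmetric eigendecomposition tolerance is LAPACK's; the residual
  `‖Sv − λv‖/‖v‖ < 1e-8` is asserted in tests.
* Matrix TSV round-trips are validated at `1e-9`; asymmetry below `1e-9`
  is averaged away, above it is an error naming the worst cell.
* Constant (zero-variance) channels are an error naming the channel —
  phase is undefined there.
* All-zero paired differences return statistic 0, p = 1 without touching
  Shapiro–Wilk (which is undefined on constants); constant *nonzero*
  differences route to the Wilcoxon branch.
* Exact collinearity in the design is an error naming the dependent
  columns; near-collinearity is the screener's |r| > 0.8 rule.
* Supra/eigen artifacts are written at 12 significant digits (6 for
  connectivity matrices) so downstream reads reproduce within `1e-9`.

## Known limitations

* The CLI `run` subcommand drives the synthetic study generator; real
  recordings enter through `run_pipeline()` with files read via
  `read_timeseries_tsv()`.
* Runtime at full scale (78 regions × 60 epochs × 6 bands) is dominated
  by the `O(N²·T)` pairwise PLI loop — minutes per recording, not
  seconds; tests and examples use scaled-down worlds and say so.
* Only the multiplex coupling (node-to-replica, uniform weight) is
  implemented; weighted multilayer variants, other centralities and
  layer-weight optimization are out of scope.
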