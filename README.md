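# megmultiplex

Multilayer network analysis of MEG frequency-band connectivity, with the
cohort statistics used to relate frontoparietal network integration to
executive functioning.

## The problem

Resting-state MEG studies describe brain networks one frequency band at a
time, yet executive functioning draws on oscillations across bands. The
multiplex approach synthesizes them: each band is a network layer over the
same cortical regions, layers are coupled node-to-node, and a region's
importance is read off the joint structure. `megmultiplex` implements that
pipeline end to end for region-level time series:

1. **Epoching** — the first 60 non-overlapping epochs of 4096 samples
   (3.28 s at 1250 Hz).
2. **Band filtering** — FFT masking into six bands: delta (0.5–4 Hz),
   theta (4–8 Hz), lower alpha (8–10 Hz), upper alpha (10–13 Hz), beta
   (13–30 Hz), gamma (30–48 Hz); bands are half-open `[f_lo, f_hi)`.
3. **Connectivity** — the phase lag index per region pair,
   `PLI = |⟨sign sin(Δφ(t))⟩|`, computed on the analytic-signal phase of
   each epoch and averaged over epochs: one weighted `N × N` network per
   band (insensitive to amplitude and to zero-lag coupling).
4. **Backbone** — each layer binarized to its spanning tree by Kruskal's
   algorithm, keeping the strongest connections: `N − 1` links (77 for
   the standard 78-region cortical parcellation), connected, acyclic.
5. **Multiplex** — an `(L·N) × (L·N)` supra-adjacency matrix: tree layers
   on the diagonal blocks, identity interlayer coupling (weight 1)
   off-diagonal.
6. **Centrality** — multilayer eigenvector centrality: the leading
   eigenvector of the supra matrix, node replicas averaged across layers
   and rescaled to max 1; averaged over a frontoparietal (FPN) node set
   this yields one integration value per subject per timepoint.
7. **Statistics** — impairment classification (Z < −1.5), paired
   t / Wilcoxon change tests with a Shapiro–Wilk gate, univariate
   covariate screening at p < 0.05, backward-elimination regression
   (removal at p ≥ 0.10, standardized betas), Bonferroni correction
   (0.05 / 3 = 0.0167).

A synthetic-data module generates multichannel oscillators with planted
band-specific phase coupling of known topology, and two-timepoint cohorts
with a known standardized centrality → EF effect, so every stage is
testable without patient data.

## Worked example

```r
library(megmultiplex)

# 6 regions, 20 epochs; regions 1-2 share a lower-alpha oscillator with a
# constant pi/4 lag at strength 0.9
spec <- coupling_spec(
  n_regions = 6, fs = 1250, n_samples = 4096 * 20,
  coupling = list(alpha1 = data.frame(i = 1L, j = 2L, strength = 0.9,
                                      lag = pi / 4)),
  seed = 42)
ts <- simulate_sources(spec)
epochs <- segment_epochs(ts, epoch_length = 4096, max_epochs = 20)
conn <- pli_matrix(epochs, default_bands()$alpha1, fs = 1250)
round(conn$weights[1:3, 1:3], 3)
#>       R1    R2    R3
#> R1 0.000 0.748 0.316
#> R2 0.748 0.000 0.237
#> R3 0.316 0.237 0.000
```

The planted pair (R1, R2) stands out at 0.748; uncoupled pairs sit near
0.2–0.3, the sampling floor of per-epoch |PLI| for a 2 Hz-wide band (see
the methods vignette). Continuing through the network stage:

```r
backbones <- lapply(default_bands(), function(b)
  spanning_backbone(pli_matrix(epochs, b, 1250)))
mp <- build_multiplex(backbones, interlayer_weight = 1)
mp
#> <multiplex_network> L = 6 layers x N = 6 nodes (supra 36 x 36), interlayer weight 1
ec <- multilayer_eigenvector_centrality(mp)
subnetwork_mean(ec, c("R1", "R2", "R4"))   # FPN-style node-set average
#> [1] 0.8579
```

and the cohort statistics on a synthetic 300-subject cohort with a
planted standardized centrality effect of 0.4:

```r
co <- simulate_cohort(cohort_spec(n_subjects = 300, beta_ec = 0.4, seed = 7))
t1 <- co[co$timepoint == "T1", ]
backward_regression(
  t1$ef_set_shifting,
  t1[, c("ec_fpn", "epilepsy", "subtype", "treatment",
         "interval_resection_npa", "age")],
  reference_levels = list(epilepsy = "no",
                          subtype = "IDH-mutant-codeleted",
                          treatment = "none"))
#> <regression_result> n = 300, adj R^2 = 0.322, F(5, 294) = 29.4, model p = 3.648e-24
#>   retained:
#>     ec_fpn                       beta* = +0.382  p = 0.0000
#>     epilepsy:yes                 beta* = -0.336  p = 0.0000
#>     ...
```

The standardized coefficient on centrality (0.382) recovers the planted
0.4 within sampling error; the planted epilepsy effect (−0.3) is likewise
retained, and null covariates are eliminated. Significance after
Bonferroni correction means `p < bonferroni_threshold(0.05, 3)` = 0.0167.

`run_pipeline()` drives all stages for a set of recordings and writes
per-band PLI matrices, backbones, the supra matrix with a JSON sidecar,
centrality vectors, the cohort table, statistics JSON and a run manifest;
`mlx_cli()` exposes `simulate`, `connect`, `backbone`, `multiplex`,
`centrality`, `cohort-stats` and `run` subcommands.

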