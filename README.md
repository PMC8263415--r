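# striasig

Computational comparison of striated tool marks from 3D surface topography.

When a blade strikes a softer material — bone, cartilage, wax, metal — the
microscopic irregularities of its cutting edge (burrs, dents, wear scratches)
carve a pattern of parallel grooves and ridges, the *striae*. Because those
irregularities are individual to one tool, two marks made by the same blade
carry near-identical striae patterns, and a questioned mark can be compared
against test marks made with a candidate weapon. `striasig` implements the
computational half of that examination for forensic examiners and
methods researchers: it turns scanned height maps of striated marks into 1D
*signatures*, scores their similarity by normalized cross-correlation, counts
consecutive matching striae (CMS), and renders a verdict against
known-match / known-non-match (KM/KNM) reference distributions.

## The statistic

A signature is a profile S[i], i = 1..N, of surface heights taken
perpendicular to the striae after detrending and noise filtering. Two
signatures are compared at every integer lag k by

```
             Σ_i S1[i] · S2[i+k]
xcorr{k} = ───────────────────────────────
           √( Σ_i S1[i]² · Σ_i S2[i+k]² )
```

with all sums over the overlapping sample range at that lag, so
|xcorr{k}| ≤ 1 by Cauchy–Schwarz. The similarity score of two marks is the
maximum of this curve over lags (and, optionally, over reversal of one
signature, since casts of opposite blade sides mirror the profile). Scores
from pairs of marks known to share a blade (KM) and known not to (KNM) form
reference distributions; a questioned score is classified by membership in
their 95% intervals: inside the KM interval only → supports identification,
inside the KNM interval only → supports exclusion, anything else →
inconclusive.

Because raw case scans are rarely shareable, the package includes a
fully-seeded simulator of striated mark surfaces (blade edge profile
replicated along the cut direction, plus tilt, low-frequency form,
measurement noise, spikes, and dropouts) with complete ground truth, so the
whole pipeline is testable end to end.

## Worked example

Two marks struck with the same simulated blade, compared end to end:

```r
library(striasig)

blade <- generate_blade(seed = 1, length_um = 2500, blade_id = "blade-A")
mark1 <- imprint_mark(blade, mark_sim_config(rng_seed = 101), mark_id = "mark-1")
mark2 <- imprint_mark(blade, mark_sim_config(rng_seed = 102), mark_id = "mark-2")

validate_grid(mark1)
#> # A tibble: 1 × 8
#>   n_rows n_cols pitch_x pitch_y invalid_fraction height_min height_max flagged
#>    <int>  <int>   <dbl>   <dbl>            <dbl>      <dbl>      <dbl> <lgl>
#> 1    128    512       3       3          0.00989      -19.8       34.2 FALSE

sig1 <- preprocess_mark(mark1)   # outlier removal, orientation, extraction,
sig2 <- preprocess_mark(mark2)   # detrend + low-pass of 5 signatures
sig1
#> <signature_set> mark 'mark-1': 5 signatures (filtered), rows 2, 12, 22, 115, 125

res <- compare_marks(sig1, sig2)
res
#> <correlation_result> score 0.9881 at lag 0 (510-sample overlap)

count_cms(res$avg_a, res$avg_b, aligned_lag = res$best_lag)
#> <cms_result> 62 vs 61 striae, 60 matched, max consecutive run 27 (tol 6 um)
```

The two marks share 1% dropouts, sub-degree orientation jitter, tilt, bow and
noise, yet correlate at 0.988 at zero lag with a run of 27 consecutive
matching striae — same-blade behaviour. The full reference experiment (4
blades × 2 marks → 4 KM + 24 KNM pairs, plus two held-out queries) runs as
one call:

```r
print(run_pipeline(out_dir = NULL, seed = 1))
#> <km_knm_experiment> 28 comparisons (4 KM, 24 KNM, 0 failed)
#> <ref_distributions> (t scores-interval, 95%)
#>   KM : n = 4, mean 0.9802, sd 0.0154, CI [0.9255, 1.0348]
#>   KNM: n = 24, mean 0.3101, sd 0.0256, CI [0.2560, 0.3643]
#> verdicts:
#>              query target     score                   label
#> 1 query_same_blade b01m01 0.9598955 supports_identification
#> 2  query_new_blade b01m01 0.3047922      supports_exclusion
```

KM and KNM scores separate by ~0.67 with disjoint intervals; the held-out
same-blade query is identified and the unseen-blade query excluded.
`autoplot()` methods are available for grids, signature sets, correlation
curves, and reference distributions; `tidy()`/`glance()` return tibbles.

A thin command-line wrapper (`inst/scripts/striasig`) exposes the same
functions as subcommands: `simulate`, `convert`, `extract`, `compare`,
`reference`, `classify`, `run`.

## Package layout

- `R/` — surface I/O and validation, mark simulator, orientation estimation,
  outlier handling, signature extraction and filtering, cross-correlation and
  CMS, reference distributions and classification, pipeline and CLI.
- `vignettes/striated-mark-comparison.Rmd` — the methods vignette: model,
  parameters, simulator scope, numerical choices, limitations.
- `tests/testthat/` — unit, property and end-to-end acceptance tests with
  independent brute-force oracles.
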