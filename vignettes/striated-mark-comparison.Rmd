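---
title: "Comparing striated tool marks by signature cross-correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing striated tool marks by signature cross-correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striasig)
```

## The measurement model

A striated tool mark is the negative of a blade edge's micro-topography,
replicated along the direction of the cut: to first order the surface height
at position $(x, y)$ is

$$ h(x, y) \;=\; e\!\left(u\right) \;+\; t_x x + t_y y \;+\; f(x, y)
   \;+\; \varepsilon(x, y), \qquad u = x\cos\alpha + y\sin\alpha, $$

where $e(\cdot)$ is the edge profile (the individual characteristics of one
tool), $\alpha$ the striation angle, $t_x, t_y$ the specimen tilt against the
scanner's reference plane, $f$ a smooth low-frequency form (bow), and
$\varepsilon$ measurement noise, possibly contaminated by spike artefacts and
dropouts. Everything the package does follows from this decomposition:

1. **Pre-processing** removes what is not $e$: spikes and dropouts
   (`remove_outliers()`), orientation (`estimate_striation_orientation()` +
   resampling), tilt and form (`detrend_signature()`), and noise
   (`lowpass_signature()` / `bandpass_signature()`).
2. **Extraction** (`extract_signatures()`) reads $n$ cross-sections
   perpendicular to the striae from the least-disturbed regions; alignment
   and averaging (`align_and_average()`) suppress residual disturbances by
   $\sqrt{n}$ while preserving the shared profile.
3. **Scoring** (`normalized_xcorr()`, `compare_marks()`) quantifies how well
   two cleaned profiles agree, maximally over relative shift (and optionally
   reversal). The normalization makes the score invariant to overall scale,
   so only the *shape* of the striae pattern matters.
4. **Decision** (`build_reference()`, `classify_score()`) situates a
   questioned score between the empirical behaviour of known matches and
   known non-matches.

The correlation statistic is evaluated, at every lag, strictly over the
overlapping sample range, with the second profile's energy taken over the
same shifted window as the numerator. Lags whose overlap falls below
`min_overlap` (default 0.5) of the shorter profile are excluded: tiny
overlaps produce spuriously extreme correlations. No mean is subtracted
inside the statistic — profiles are already mean-free after detrending — but
a `pearson_window` option re-centres each overlap window for users who prefer
a windowed Pearson correlation.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| pixel pitch | 3 | µm/px | typical photometric-stereo scan resolution |
| detrend window | 301 | samples (≈0.9 mm) | separates mm-scale form from striae of tens of µm |
| low-pass cutoff | 1/15 | cycles/µm | keeps striae ≥15 µm wavelength, cuts pixel noise |
| signatures per mark | 5 | — | practical count for marks a few mm long |
| line spacing | 10 | rows (30 µm) | avoids near-duplicate extraction lines |
| `min_overlap` | 0.5 | fraction | guards against tiny-overlap correlation spikes |
| reversal search | on | — | casts of opposite blade sides mirror the profile |
| CMS prominence | 0.5·sd | µm | a stria must stand out of the local texture |
| CMS tolerance | 2 | samples (6 µm) | positional slack for matched striae |
| CI level | 95 | % | conventional |

The band-pass variants (`gaussian`: FFT filter with erf-shaped transition
edges; `chebyshev2`: type-2 IIR, flat passband, 40 dB equiripple stopband,
applied forward–backward) replace detrend + low-pass in one step. All
filters are zero-phase by construction — a filter that shifted striae
laterally would corrupt the lag and the CMS count.

## The synthetic-mark generator

Real case scans are rarely shareable, so the simulator is a first-class part
of the package: every downstream stage is tested against its ground truth.

* **Edge profile** (`generate_blade()`): band-limited Gaussian noise, band
  1/200–1/10 cycles/µm at SD 1 µm. At 3 µm sampling this produces striae
  roughly 10–60 µm wide — the fine-striation regime the method targets. An
  optional sinusoidal class component emulates periodic grinding structure
  shared by tools of one manufacture.
* **Imprinting** (`imprint_mark()`): the edge profile replicated along the
  cut direction at a configurable striation angle, plus tilt (default 0.01,
  0.005 µm/µm), a 2 µm bow at 2 mm wavelength, 0.05 µm Gaussian noise, 0.1%
  spikes of ±20 µm, 1% dropouts, and a per-mark band-limited "wear"
  perturbation (SD 0.1 µm) emulating tool change between strikes.
* **Reference designs** (`make_km_knm_dataset()`): $b$ blades × $m$ marks,
  every unordered pair labelled KM/KNM; 4 × 2 gives the classic 4 KM + 24 KNM
  design. Marks of one blade imprint the same edge section, so only
  disturbances and wear separate them; each mark receives a ±3° striation
  angle jitter so the orientation stage is genuinely exercised.
* **Seeding**: one master seed fans out to per-object seeds through an
  integer hash (`child_seed()`), so regeneration is byte-identical and
  streams are independent.

What the simulator does **not** emulate: contact mechanics and material
response (plastic flow, bone anisotropy), cast replication fidelity,
substrate-dependent mark quality, scanner-specific artefact correlations, and
class/subclass structure beyond a single sinusoid. Passing tests therefore
demonstrate that the *algorithms* recover known ground truth and separate
same-tool from different-tool marks under realistic disturbance levels — not
that any particular real-world error rate holds. On real data the simulator's
clean separation (KM ≈ 0.98 vs KNM ≈ 0.3 at the defaults) will compress:
marks a few mm long yield fewer signatures to average, and tools with
pronounced class characteristics can push non-match scores up.

## Numerical choices

* **Moving average**: centred window that shrinks symmetrically at the ends,
  so a straight line is annihilated exactly everywhere and no padding values
  are invented. Short-period content is attenuated by $1 - D_W(f)$ with
  $D_W$ the Dirichlet kernel — the closed form the tests check against.
* **Zero-phase IIR filtering**: odd-reflection padding (≥60 samples or 10×
  the filter order) then forward and reverse passes. The impulse response is
  symmetric to 1e-9 and striae peak positions are unmoved.
* **Fast correlation**: FFT cross-products plus cumulative-sum window
  energies; the test suite holds it to 1e-12 against a literal double-loop
  evaluation of the definition. Best-lag ties (within 1e-12) resolve to the
  smallest |k|, then the negative lag.
* **Orientation search**: directional energy = count-weighted between-bin
  variance of the projected, high-passed profile minus the sampling-noise
  floor (within-bin variance / count); 1° grid search over ±45°, 0.1°
  refinement. Bins with a single pixel are dropped — they carry no signal
  and inflate the variance. Confidence compares the peak's excess over the
  across-angle baseline to the noise floor; isotropic surfaces flag as low
  confidence. A user-supplied angle always wins, matching practice where the
  examiner orients the scan.
* **Outlier defaults**: the slope threshold is 5× the *larger* of the two
  per-axis median absolute slopes (the along-striae axis is near-flat and
  would collapse a pooled median), and a pixel must rise *and* fall (opposite
  slope signs) to count as a spike — steep monotone striae flanks are left
  alone. Local-sigma uses k = 6 over a 7×7 window of valid pixels;
  statistics over valid pixels only make both methods idempotent.
* **Extraction ties**: equal disturbance scores resolve to the smallest row
  index; the chosen rows are cropped to their common fully-valid column
  window so no profile crosses an invalid pixel.
* **CMS `max_run`**: defined directly as the longest $L$ with
  $|p^a_{i+t} - p^b_{j+t}| \le \mathrm{tol}$ for $t = 0..L-1$, computed by
  dynamic programming over the tolerance matrix. A run harvested from the
  greedy one-to-one pairing (which is still reported as `matches`) can miss a
  longer run broken by an early pairing choice; the direct definition is
  unambiguous and has a trivial brute-force oracle.
* **Degenerate inputs**: all-zero overlap windows are excluded from the
  correlation with a warning; zero-variance score samples give a point
  interval with a warning; all-invalid grids and empty peak sets raise
  explicit errors.

## The decision rule and its interval

A questioned score is classified by membership in the 95% intervals of the
KM and KNM score samples. Two interval scopes are implemented
(`build_reference(interval = )`):

* `"scores"` (default): a t *prediction* interval,
  $\bar x \pm t_{0.975,\,n-1}\, s \sqrt{1 + 1/n}$ — the region where an
  individual score from that group is expected to fall. This is the scope
  the decision rule needs: the question is whether the questioned *score* is
  consistent with known-match scores.
* `"mean"`: the classical CI for the group mean,
  $\bar x \pm t_{0.975,\,n-1}\, s / \sqrt n$. It describes the precision of
  the mean and shrinks with $n$; with it, a perfectly typical new KM score is
  rejected with substantial probability (at $n = 4$, roughly one time in
  six), which is why it is not the classification default.

A `fisher_z` option performs the interval arithmetic on $\mathrm{atanh}$
scores, respecting the $[-1, 1]$ boundary for scores near 1. The verdict
vocabulary (`supports_identification` / `supports_exclusion` /
`inconclusive`) deliberately avoids formal conclusion scales: mapping scores
to evidential language is expert judgment outside this package's scope.
Overlapping intervals never error — membership in both is inconclusive.

## Problem sizes

The shipped defaults simulate 128 × 512-pixel grids (0.38 × 1.54 mm at
3 µm/px); the reference experiment compares 8 marks in 28 pairs and completes
in well under a minute on one core. These sizes were chosen so the full test
suite and the acceptance script rerun comfortably anywhere while leaving
hundreds of striae-scale features per signature; all of them scale up through
configuration (`mark_sim_config()`, `run_pipeline()` blocks).

## Known limitations

* The comparison assumes marks that are striated, roughly planar after
  detrending, and scanned on a regular grid; mesh surfaces and heavily curved
  marks are out of scope.
* Signatures compare *all* topography in band — class, subclass and
  individual characteristics alike. Tools with dominant class structure
  (e.g. serrated blades) can score high against non-matching tools.
* Filter settings influence the score; marks compared against each other must
  be pre-processed identically (the package refuses otherwise), and
  cross-study score comparisons require identical settings end to end.
* Reference distributions built from a handful of pairs (4 KM in the classic
  design) make wide prediction intervals; more reference pairs sharpen the
  verdict.
* Wear between mark and test mark degrades true-match scores and is only
  crudely modelled here (additive band-limited perturbation).
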