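---
title: "Species identification from MALDI-TOF fingerprints with a cross-correlation index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species identification from MALDI-TOF fingerprints with a cross-correlation index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccimatch)
```

## The problem and the model

A MALDI-TOF mass spectrum of an arthropod specimen is a protein
fingerprint: a trace of ion intensity against mass-to-charge (m/z) over,
here, 2000-20,000 Da. Specimens of one species share a fingerprint up to
specimen-level biological variation and spot-level technical variation
(one "spot" = one deposit of protein extract = one technical replicate
spectrum). Identification then reduces to a similarity search: compare the
query spectrum with a library of spectra from molecularly identified
specimens and report the species of the most similar reference, unless
even the best similarity is too poor to trust.

`ccimatch` quantifies similarity with a cross-correlation index. Both
spectra are preprocessed onto a common uniform mass grid, and compared on
a set of half-open mass intervals tiling a fixed range. Per interval, the
normalized cross-correlation function

$$C(\tau) \;=\; \frac{\sum_i x_i\, y_{i+\tau}}
{\sqrt{\sum_i x_i^2\; \sum_i y_i^2}},\qquad \tau = -L,\dots,L$$

is computed over the overlapping index range *without mean-centering*, so
$C \in [0,1]$ for non-negative spectra and $C(0)=1$ exactly for identical
segments. The interval's score is the largest **strict interior local
maximum** of $C$; if the correlation function is monotone or flat, no
local maximum exists and the interval scores 0. The CCI is the product of
the interval scores, so

$$\log_{10}(\mathrm{CCI}) \in [-\infty,\, 0],$$

with 0 for identical spectra and $-\infty$ as soon as a single interval
carries no evidence of shared structure. The product form means every
interval must agree for a high score - this is what gives the index its
specificity, and why the mass range is tiled with many intervals rather
than correlated globally.

Two properties are guaranteed by construction and enforced by tests:
symmetry (the lag window is symmetric and the overlap sums commute), and
exact self-similarity (self-comparison yields CCI = 1, log10 = 0, with no
floating-point slack).

## Preprocessing chain

Raw spectra pass through a fixed chain, each step recorded in the
spectrum's provenance:

1. **Resampling** - linear interpolation onto a uniform grid (default
   1 Da steps over 2000-20,000 Da, the acquisition range). This makes
   correlation lags commensurate across spectra and is robust to both
   profile and centroid input.
2. **Intensity transform** - square root by default (variance
   stabilization for count-like detector noise); `log1p` and `none` are
   available.
3. **Smoothing** - Savitzky-Golay, polynomial order 3, half-window 10
   grid points. An order-3 filter reproduces cubics exactly, so peak
   shapes survive while high-frequency noise is attenuated.
4. **Baseline removal** - SNIP (iterative clipping against the mean of
   symmetric neighbours with a window growing to 100 points). Narrow
   peaks ride on top of, and survive, the slowly varying chemical
   baseline; a pure baseline is removed entirely.
5. **TIC normalization** - intensities are scaled to sum to one, making
   spectra comparable across laser power and extract concentration.
   A spectrum that is all-zero after baseline removal carries no
   fingerprint; it is excluded from a batch with a logged reason rather
   than failing the whole run.
6. **Alignment** (dataset-level, optional, on by default) - one rigid
   mass shift per spectrum, chosen to maximize cross-correlation with the
   leave-one-out mean spectrum, bounded by a 10 Da tolerance. The
   spectrum's own (possibly miscalibrated) copy is excluded from the
   reference so it cannot pull the target toward itself. Shifts at the
   tolerance bound are clamped and reported. Warping is deliberately not
   implemented: the CCI's lag search already absorbs residual
   calibration error, and a rigid shift is the conservative complement.

The defaults above are standard MALDIquant-style choices; the literature
on fingerprint matching rarely pins these parameters down, so every one
of them is exposed in `preprocess_config()` and users can match other
parameterizations exactly.

## Tunable parameters that matter

| parameter | default | meaning |
|---|---|---|
| CCI mass range | 3000-12,000 Da | region rich in discriminative protein peaks |
| interval width | 500 Da | 18 intervals; every interval must match for a high CCI |
| `max_lag` | 20 grid points (20 Da) | residual calibration shift absorbed per interval |
| identification threshold | -14 (log10 scale) | below it, "no identification" is returned |
| spots per query | 1 | technical replicates considered jointly |
| simulation repeats | 1000 | spot-resampling repeats behind each credible interval |

The threshold comparison is `>=`: only values strictly below the
threshold return "no identification", so exact equality identifies. A
best score of $-\infty$ therefore identifies only at the degenerate
threshold $-\infty$, which is the correct boundary behaviour for ROC
sweeps. More stringent (higher) thresholds trade sensitivity for
specificity; more spots per query trade the reverse way, because the
specimen-level score is a maximum over spot-reference pairs and can only
grow when spots are added.

## Identification and evaluation

`identify_specimen()` scores every (selected spot x reference spectrum)
pair and takes the single best - no voting across spots, so one
high-quality replicate suffices. Ties are broken by lexicographic
reference id, deterministically.

`simulate_performance()` reproduces the evaluation design: per repeat,
sample `n_spots` spots per test specimen without replacement, identify,
classify against the molecular (PCR) label - TP/FP if identified
correctly/incorrectly, FN if missed although the species is referenced,
TN if unreferenced and not identified - and compute metrics over the
whole panel. Metrics are summarized *across* repeats by the median and
the equal-tailed 2.5/97.5 percentile interval. The "credible interval" is
thus the empirical percentile interval of the simulation - an interval
around the median of the repeats - and involves no posterior model. A
metric undefined in a repeat (zero denominator)
is dropped from that metric's summary and the dropped count reported.

A fully referenced test panel yields no true negatives, leaving
specificity and NPV inestimable. `simulate_unreferenced_specificity()`
therefore disables all same-species references for each query, making
every query behave like a species absent from the database: each result
is forced to be FP or TN and specificity becomes estimable. A specimen
whose species spans the entire database has no eligible reference left;
its best disabled-match is $-\infty$ and it is counted TN at any finite
threshold, with a logged note.

Reproducibility: each (repeat, specimen) spot draw uses its own RNG
substream derived by an integer hash from the master seed. Identical
seeds give bit-identical results, and the draws are shared across
thresholds and modes, which is what makes the per-repeat monotonicity
properties (sensitivity falls, specificity rises with stringency) hold
exactly rather than just in expectation.

## The synthetic generator: what it emulates, and what not

`generate_panels()` builds a world with exactly the structure the method
assumes: per species a fixed template of Gaussian peaks (1-3 peaks per
500 Da CCI interval, plus a few outside the range, heights lognormal
around a common scale, widths growing with mass as in linear-mode TOF);
per specimen, lognormal multiplicative jitter on peak heights; per spot,
a rigid mass-calibration drift (truncated Gaussian, sd 1.5 Da), a
low-order polynomial baseline, and non-negative additive noise. Defaults
state a deliberately low-noise world (noise sd 3% of the mean peak
height): 10 species, 2 reference specimens and 3 test specimens per
species, 10 spots each.

Under these defaults the generated data reproduce the qualitative
similarity hierarchy of real panels - replicate pairs more similar than
same-species pairs, different-species pairs scoring $-\infty$ - but the
*absolute* similarity levels are optimistic: replicate medians sit near
log10(CCI) of -0.03 where real mosquito data sit near -8. The generator
does not model detector saturation, isotope envelopes, matrix clusters,
peak-width irregularity or storage-related degradation. A green
end-to-end test therefore establishes that the pipeline's logic (scoring,
thresholding, classification, summarization) is correct and that
performance estimates respond to noise and thresholds in the right
direction - it does not establish field performance on real spectra,
which depends on a real reference database.

Species held out via `fraction_unreferenced` appear only in the test
panel, providing genuine true negatives for standard-mode evaluation. An
optional sibling pair (species 1 and 2 sharing ~80% of their peaks)
emulates sibling-species complexes whose spectra are nearly
indistinguishable.

## Numerical choices and degenerate inputs

- Per-interval correlation values are clamped to $[0,1]$ after
  normalization: batch computation uses BLAS matrix products whose
  summation order can land 1-2 ulp above 1. In the all-against-all case
  segment energies are taken from the lag-0 product's diagonal so
  self-similarity is exactly 1 before clamping.
- The CCI product is accumulated in log space (18 factors, each possibly
  ~0.1, would underflow a plain product long before $-\infty$ is
  warranted).
- $-\infty$ sorts below all finite values in medians and IQRs; a median
  landing on $-\infty$ is reported as $-\infty$ (the interpolating
  quantile is computed so that no NaN arises from $0 \cdot \infty$).
- Plateaus in the correlation function are not local maxima (strict
  inequality on both sides), so a flat function - e.g. against an
  all-zero segment - has no local maximum and the interval scores 0.
- An interval shorter than `max_lag + 2` grid points cannot support the
  lag search and is flagged absent (contributing 0) rather than scored
  on a truncated window.
- Specimens with fewer available spots than requested are evaluated with
  all available spots; sampling is always without replacement from what
  exists.
- `-Inf` serializes to the literal string `-Inf` in TSV output, which R
  and pandas both parse back to negative infinity.

## Design choices where the design was open

- **Correlation without mean-centering.** Centered correlation can be
  negative and its self-value is not exactly 1 on these non-negative
  traces; the uncentered form matches the stated range
  $[-\infty, 0]$ on the log scale with 0 for identical spectra.
- **Lag window 20 points.** The source does not state its search window;
  20 Da absorbs realistic calibration error without letting neighbouring
  peaks masquerade as matches. Config-exposed.
- **Tie-breaking** everywhere is lexicographic by spectrum id - arbitrary
  but deterministic, so results are invariant to row order.
- **Database QC** (`qc_filter()`) removes spectra whose median replicate
  similarity falls below a cutoff - the sensitivity analysis this mirrors
  found such filtering changed nothing, so the default pipeline keeps all
  spectra.
- **Configuration is JSON**, not YAML: the deployment environment
  provides a JSON parser but no YAML package, and the provenance contract
  (every output directory carries a full config snapshot) is unaffected.

## Known limitations

- mzXML and plain m/z-intensity tables are the only input dialects;
  vendor formats and mzML are out of scope, and compressed mzXML peak
  blocks are rejected rather than decoded.
- The pipeline operates on full traces; no peak picking is offered, so
  peak-list similarity scores (Biotyper-style log scores) cannot be
  reproduced with it.
- Performance estimates are conditional on the reference database: with
  near-exhaustive species coverage the standard mode cannot estimate
  specificity (no true negatives), and the unreferenced mode estimates it
  only for the hypothetical query of an absent species.
- The simulation treats spots as exchangeable within specimen; systematic
  spot-order effects (e.g. crystallization gradients) are not modelled.
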