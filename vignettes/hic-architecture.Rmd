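---
title: "Methods: contact-map models, estimators and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact-map models, estimators and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

hicogeny analyses binned Hi-C contact matrices along a developmental series —
the setting is germ-cell maturation (female germline stem cells through GV,
MI and MII oocytes), where the interesting biology is how distance decay,
A/B compartments, TADs and loops change between stages. Because raw
germ-cell Hi-C libraries at the depths such analyses need are not something
a desk validation can reproduce, every estimator here is validated on
synthetic maps with planted, known structure. This vignette records the
models, the tunable parameters, and the numerical decisions a maintainer
would want explained.

## The synthetic contact-map model

`simulate_contact_map()` builds a noise-free expected matrix and draws
independent Poisson counts around it. For bins $i, j$ on one chromosome at
separation $d = |i-j| \cdot \text{bin\_size}$,

$$E_{ij} = D \, d^{-\alpha}
  \cdot e^{\pm g}
  \cdot \tau^{[i,j \in \text{same TAD}]}
  \cdot \lambda^{[(i,j) \in \text{loops}]}
  \cdot b_i b_j,$$

where $D$ is the depth scale, $\alpha$ the decay exponent, $g = \ln(1+c)$
the log-symmetric compartment contrast ($+g$ for same-label pairs, $-g$ for
opposite ones, so the same/opposite ratio at equal distance is exactly
$e^{2g}$), $\tau$ the TAD enrichment applied when both bins lie strictly
inside one planted domain, $\lambda$ a focal loop enrichment, and
$\ln b_i \sim N(0, \sigma_b^2)$ multiplicative bin biases. Trans pixels get
a constant background times $b_i b_j$. The $d = 0$ diagonal reuses the
$d = 1$ value (the power law is singular there; every downstream statistic
excludes the diagonal anyway).

Choices worth noting:

* **Poisson counts.** Read sampling is Poisson at the pixel level; no
  overdispersion knob is provided. Real libraries are overdispersed, so
  passing the recovery checks here says the estimators work under sampling
  noise, not that their error bars transfer to real data.
* **One master seed, named streams.** Each stochastic component (biases,
  counts, tracks, expression) derives its own sub-seed from the master seed
  and a component name, so components can be tested in isolation and runs
  are bit-reproducible.
* **What is not emulated:** mappability holes, translocation artefacts,
  restriction-fragment geometry, copy-number variation, and distance-
  dependent noise correlations. Tests passing on this generator demonstrate
  correctness of the estimators, not robustness to those artefacts.

## Balancing (ICE)

`ice_normalize()` iteratively divides each pixel by its row-sum factors
until unmasked row sums agree to a relative tolerance (`tol = 1e-5` on the
maximum deviation, so the row-sum coefficient of variation ends well below
`1e-4`). Zero-coverage bins plus the lowest 2% of coverage are masked first;
both knobs are exposed. Non-convergence flags the result (`converged`
attribute) and warns instead of failing, so degraded inputs remain
inspectable.

A point that trips up validation: ICE factors equalise *row sums*. Planted
biases are recovered at $r > 0.999$ only when the bias-free expectation is
doubly balanced (e.g. a flat field). On a finite chromosome with a power
law, bins near the ends genuinely see fewer contacts, and on a structured
map TAD/compartment coverage differs between bins; ICE correctly absorbs
that into its factors, which *lowers* the correlation with the planted
biases without being an error. The bias-recovery checks therefore plant
biases on a flat expectation; the demo reports the confounded correlation on
its structured map alongside the balancing quality itself.

## Distance decay

`contact_probability()` averages values per separation over all unmasked
pixel positions (zeros included — the same inclusive convention used for
observed/expected and the replicate band correlation) and normalises the
curve to unit mass. `slope_curve()` smooths $\log_{10} p$ against
$\log_{10} s$ with LOWESS (span 0.3 by default; the smoother is standard for
these curves, the span is a choice) and takes centred finite differences of
the smoothed curve — simple, and testable against exact power laws, where
the recovered slope is within 0.02 of $-\alpha$.

## Compartments

`pc1_compartments()` computes, per chromosome, the Pearson correlation
matrix of observed/expected columns over unmasked bins and takes its first
eigenvector, scaled by the root eigenvalue. The sign of an eigenvector is
arbitrary, so it is fixed against an explicit orientation track (gene
density or mean expression per bin is the recommended convention — the A
compartment is the active one); positive PC1 is A, negative B. PCA is per
chromosome, not genome-wide, and no PC1-vs-PC2 diagnostic is applied by
default.

`saddle_strength()` ranks bins by PC1, cuts them into 5 quantile groups,
averages O/E per group pair, and reports the corner ratio
$(AA + BB)/(AB + BA)$ over the extreme 20% of quantiles. Two caveats the
tests made explicit:

* The per-distance expected absorbs part of a checkerboard whose block size
  is commensurate with the sampled distances: at separations where most
  pairs share a label the expected is itself elevated, pushing same-label
  O/E toward 1. The measured strength of a planted checkerboard therefore
  sits *below* the per-distance ratio $e^{2g}$ (about 1.9 for $g = \ln 2$,
  10-bin blocks, 500 bins through the full pipeline) and depends on block
  geometry. Strength comparisons are meaningful between stages on one
  geometry, not as absolute constants.
* Ranking by PC1 concentrates the corner quantiles on block-centre bins,
  whose short-range pairs are mostly within-block (O/E near 1). This can
  re-order strength between nearby contrasts; the monotonicity property is
  therefore checked with planted-label ranking, which isolates the saddle
  statistic from quantile-selection effects.

`switch_table()` counts joint A/B labels per 400-kb bin (bins, not merged
runs, are the accounting unit) and `ab_composition()` reports per-subset
percentages plus the ratio of contiguous A runs to B runs.

## TADs

`directionality_index()` uses the standard signed chi-square statistic with
a 2-Mb one-sided window: $A$ and $B$ are the balanced contact sums to the
upstream and downstream windows, $E = (A+B)/2$, and
$\mathrm{DI} = \mathrm{sign}(B-A)\,[(A-E)^2 + (B-E)^2]/E$, zero when
$A = B$, undefined when $A + B = 0$.

`hmm_call_tads()` fits a 3-state (downstream-bias / none / upstream-bias)
Gaussian hidden Markov chain per chromosome by EM from a deterministic
moment-based initialisation (state means at $-s, 0, +s$ for $s$ the DI
standard deviation; sticky transitions), then decodes with Viterbi. Two
numerical decisions matter:

* The DI is chi-square-scaled and spans orders of magnitude; Gaussian
  emissions on the raw values collapse onto the extreme spikes. The chain is
  fitted on $\mathrm{sign}(x)\log(1+|x|)$, which preserves sign structure
  and makes the three emission components well separated.
* A domain runs from the start of a maximal downstream-bias run to the end
  of the *last* upstream-bias run before the next downstream-bias run
  (no-bias runs are absorbed). Spans shorter than `min_domain` (200 kb)
  are discarded — inside boundary regions the directionality flickers and
  produces 1–2-bin runs that are not domains. Inter-domain gaps shorter than
  400 kb are boundaries. EM degeneration falls back to threshold
  segmentation at half a standard deviation, with a warning.

`insulation_score()` averages balanced contacts over the square window
crossing the diagonal at each bin (400 kb default), reports log2 over the
chromosome mean, and keeps a loess-smoothed copy (span 0.1). The loess span
is a visualisation-scale smoother — broader than a TAD period — so
`insulation_minima()` detects boundary candidates on the log2 track after
only a 3-bin running mean. `tad_profile()` rescales domains to unit length
with half-length flanks and averages the smoothed insulation over 100 shared
coordinates.

On maps that also carry a compartment checkerboard, DI picks up block
transitions at its 2-Mb window scale and boundary precision drops — visible
in the demo report, and a known limitation of DI-based calling rather than
of this implementation; the insulation track, being local (400 kb), is much
less affected.

## Loops

`call_loops()` is a deliberately simplified donut caller: one resolution,
two local expected models (donut annulus and lower-left quadrant) instead of
four, and one global Benjamini–Hochberg correction. Neighbourhood means are
taken on the decay-flattened field (each pixel divided by its per-distance
expected, then rescaled back), otherwise the convexity of the power law
inflates the donut mean. The larger of the two expected values, mapped to
raw-count space through the ICE biases, parameterises a Poisson upper-tail
test. Significant pixels additionally need observed/expected at least
`fold_min = 2`: at deep coverage, percent-level local model misfit is
otherwise always statistically significant, and the cited caller applies
fold filters for the same reason. 8-connected significant pixels merge into
one call; the summit is the most significant pixel, ties broken by larger
count then smaller upstream bin. Note that Poisson detection power grows
with depth, so calls are not literally invariant to count scaling; planted
peaks at $\lambda = 8$ are recovered across a four-fold depth range.

## Comparative operations

`deconvolve()` quantile-normalises the non-zero pixel values of all stage
matrices to their common average distribution (rank-based, ties averaged;
unequal pixel counts are matched through interpolated quantiles) and
subtracts one stage from another. `cluster_profiles()` uses
$1 - r$ correlation distance with average linkage.

`conserved_regions()` slides 2-Mb windows in 400-kb steps, computes Pearson
r between two PC1 tracks per window over co-defined bins (windows with fewer
than three such bins are skipped, not imputed), merges overlapping windows
exceeding $r > 0.6$, and annotates each merged region with the mean r of its
contributing windows. A 5-bin sample correlation is noisy (under the null it
exceeds 0.6 with probability ≈ 0.14) and neighbouring windows are dependent
over about two window widths, so noise excursions form short spurious
regions; merged regions must span at least `min_span = 3` windows, which in
the planted validation separates false regions (≤ 2 windows) from genuine
blocks (tens of windows) with a wide margin.

`fisher_enrichment()` classifies universe bins by region membership and
feature overlap (any-overlap, half-open coordinates) and applies the
two-sided Fisher exact test; batches are Benjamini–Hochberg adjusted.

## Problem sizes and determinism

The validation suite runs on 100–1000-bin chromosomes at 40-kb and 400-kb
resolutions with adjacent-bin depths around 1500 counts — large enough that
recovery targets (label accuracy ≥ 95%, boundary F1 ≥ 0.8, loop recall 1.0)
are comfortably attainable, small enough that the whole suite runs in a few
minutes on one core. `run_demo()` analyses a two-chromosome, 1000-bin genome
(24 + 16 Mb at 40 kb) carrying all structure classes at once — 2-Mb
compartment blocks with $g = \ln 2$, 20-bin TADs with $\tau = 3$ separated
by 2-bin gaps, loops at $\lambda = 8$, bias $\sigma_b = 0.3$ — and writes
standard-format outputs plus a truth-comparison report; two runs with one
seed are byte-identical.

## Known limitations

* Poisson-only noise; no overdispersion or artefact model.
* Single-resolution loop calling without APA-style aggregation.
* DI-based TAD calls degrade when compartment block scale matches the DI
  window (see above); no nested/hierarchical domain model.
* Saddle strength is geometry-dependent and should be compared within one
  study design only.
* The allelic analyses consume per-genome matrices/tracks as separate
  samples; SNP-level read assignment is upstream of this package.
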