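# hicogeny

Analysis of binned Hi-C contact matrices along a developmental series, built
for studying chromatin-architecture remodelling in germ-cell development
(female germline stem cells through GV, MI and MII oocytes), and validated
end-to-end on synthetic contact maps with planted, known structure.

The package covers the standard architecture read-outs:

* **Matrix model and I/O** — sparse-triplet text + BED4 bin tables, replicate
  merging, band-restricted replicate correlation, resolution coarsening.
* **ICE balancing** — iterative correction of multiplicative bin biases
  until unmasked row sums agree (`ice_normalize`), plus the
  observed/expected transform (`observed_expected`).
* **Distance decay** — the contact-probability curve *P(s)* and its LOWESS
  log–log slope track (`contact_probability`, `slope_curve`), cis
  short/long fractions, trans/cis partitions, chromosome-pair obs/exp
  enrichment against log2 length ratios.
* **A/B compartments** — per-chromosome PC1 of the O/E correlation matrix
  with explicit sign orientation (`pc1_compartments`), switch accounting
  between stages (`switch_table`), saddle-plot compartment strength
  (AA+BB)/(AB+BA) (`saddle_strength`), per-chromosome A/B composition.
* **TADs** — the signed chi-square directionality index
  DI = sign(B−A)·[(A−E)² + (B−E)²]/E with E = (A+B)/2
  (`directionality_index`), a 3-state Gaussian-emission HMM domain caller
  with Viterbi decoding (`hmm_call_tads`), insulation scores with boundary
  minima (`insulation_score`, `insulation_minima`), rescaled aggregate TAD
  profiles, and compartment-conditioned TAD switch classes.
* **Loops** — a simplified donut caller: local expected from the
  distance-flattened donut annulus and lower-left quadrant, Poisson
  upper-tail p-values, Benjamini–Hochberg control and 8-connected merging
  (`call_loops`), plus promoter-in-anchor gene annotation.
* **Comparative machinery** — quantile-normalised matrix deconvolution
  (`deconvolve`), sliding-window conserved-region detection from paired PC1
  tracks (r > 0.6 over 2-Mb windows; `conserved_regions`), hierarchical
  clustering of PC1 profiles, interval-set overlap, and Fisher-exact
  enrichment with BH adjustment.
* **Synthetic data** — `simulate_contact_map()` plants power-law decay,
  a log-symmetric compartment checkerboard, TAD blocks, focal loops,
  log-normal bin biases and trans background, returning the Poisson-sampled
  map together with a full truth set; companions simulate correlated PC1
  pairs and expression tables.

## Worked example

The demo simulates a two-chromosome genome (24 + 16 Mb at 40-kb bins) with
2-Mb compartment blocks (contrast g = ln 2), 20-bin TADs (τ = 3), focal
loops (λ = 8) and bin biases (σ = 0.3), then runs balance → O/E → P(s) →
compartments → saddle → DI/HMM TADs → insulation → loops → conserved
regions and compares every call to the planted truth:

```r
library(hicogeny)
report <- run_demo(seed = 7, out_dir = "demo_out")
str(report$compartments)
```

`demo_out/report.json` from that exact call:

```json
{
  "ice":          {"bias_correlation_planted": 0.218, "rowsum_cv": 7.08e-06, "converged": true},
  "decay":        {"mid_range_slope": -0.989},
  "compartments": {"label_accuracy": 1, "saddle_strength": 2.596},
  "tads":         {"n_domains": 57, "boundary_precision": 0.394,
                   "boundary_recall": 0.485, "boundary_f1": 0.435,
                   "insulation_minima_hit_rate": 0.930},
  "loops":        {"n_calls": 21, "n_tested": 42661, "recall": 0.786, "false_calls": 10},
  "conserved":    {"n_regions": 4, "jaccard": 0.897}
}
```

Reading these numbers: the balanced matrix's row sums agree to a CV of
7e-6; the planted decay exponent (α = 1) is recovered as a mid-range slope
of −0.99; every 400-kb bin gets the planted compartment label and the
checkerboard yields a saddle strength of 2.6; insulation minima localise 93%
of planted boundaries within one bin, while DI-based domain calls on this
*combined* map lose precision because compartment transitions at the 2-Mb DI
window mimic domain edges (on TAD-only maps the same caller reaches F1 = 1.0
— see the methods vignette); 11 of 14 planted loops are recovered among
42,661 tested pixels; and conserved PC1 blocks are recovered at Jaccard 0.90.
The correlation of ICE factors with planted biases is low *by construction*
on a structured map — ICE absorbs genuine TAD/end coverage into its factors —
which is why bias recovery is validated separately on a doubly balanced
expectation (see below).

A thin CLI covering simulation and the demo ships in `inst/cli/hicogeny`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","hicogeny",package="hicogeny"))')" \
    demo --seed 7 --out demo_out
```

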