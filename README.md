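# diffmnase

Simulation and analysis of **differential MNase-seq**: comparing partial
("low") and complete ("high") micrococcal-nuclease digestions of
chromatin to ask whether DNA accessibility differs between chromatin
domains — and to find the local, nucleosome-sized sites where it does.

MNase preferentially cuts linker DNA between nucleosomes. If chromatin
domains folded into distinct higher-order structures, compact domains
would resist a partial digestion. The package provides both sides of the
argument:

* a **stochastic digestion model** of a 50-nucleosome array (101
  candidate cleavage sites, linker cleavage 10× more likely than
  intra-nucleosomal cleavage, 20 vs 70 cutting events per template,
  180-bp fragments trimmed by 30 bp), with scenario variants for
  compacted domains, AT-driven nucleosome fragility and fragile
  hyper-accessible nucleosomes;
* an **analysis pipeline** from aligned fragment intervals (BED/BEDPE)
  to calls: size selection (140–200 bp mono, 250–500 bp di), clonal
  filtering, midpoint-extended occupancy maps (70/150 bp), depth and
  copy-number normalization, windowed regression of occupancy on GC with
  Cook's-distance influence filtering, LOESS GC-bias correction (250-bp
  windows, GC 30–70%), and differential site calling (width ≥ 70 bp,
  per-base p < 1e-2, Benjamini–Hochberg FDR < 0.05) separating MNase
  **hyper-accessible** (low-enriched) from **inaccessible**
  (high-enriched) sites;
* a **synthetic data generator** that emulates a two-condition
  experiment with known truth — GC-domain structure, condition-specific
  GC bias, planted fragile nucleosomes, 10-bp dinucleotide phasing — so
  every stage is testable without downloads.

The central statistic at the domain scale is the per-window model
`E[signal | gc] = a + b·gc`, assessed by adjusted R² after dropping
points with Cook's distance `D_i = e_i² h_i / (p s² (1−h_i)²) > 0.001`,
and the LOESS correction factor `global_mean / fitted(gc)` applied per
250-bp window. At the local scale, low vs high signals are compared by
the exact conditional form of the two-sided Poisson rate test
(`X | X+Y ~ Binomial(X+Y, ½)` under equal rates), with BH control across
all tested intervals.

## Worked example

Simulate a fragile nucleosome at the array centre and quantify its
differential extraction:

```r
library(diffmnase)

tpl <- build_template()      # 50 nucleosomes, sites at 0, 85, 180, ... 9000
tpl
#> ArrayTemplate: 50 nucleosomes (150 bp) / 30 bp linkers, 9000 bp, 101 sites

fragile <- apply_scenario(tpl, "fragile_site")
low  <- run_digestion(fragile, digest_params(20, 1e5, seed = 1), "low")
high <- run_digestion(fragile, digest_params(70, 1e5, seed = 2), "high")
lr <- condition_log_ratio(low, high, per = "nucleosome", template = tpl)
round(lr[23:27], 2)
#> [1] -0.08  0.18  2.27  0.18 -0.01
```

The central nucleosome (position 25) is ~4.8-fold (2^2.27) over-recovered
by the partial digestion — a fragile nucleosome visible in low but lost
in high — while its neighbours are essentially unchanged.

End-to-end on a synthetic genome with 10 planted fragile sites:

```r
spec <- genome_spec(chromosomes = c(chrS = 1e6), n_hyper = 10, seed = 7)
exp <- simulate_mnase_experiment(spec, n_low = 3.2e5, n_high = 3.2e5, seed = 7)
res <- run_differential_pipeline(exp$fragments, exp$genome, spec$chromosomes,
                                 window_sizes = c(1e4, 1e5))

res$regressions[["w1e+05"]]$high
#> gc regression (mean_high): slope 18.46, intercept 13.65, adj R2 0.9656 ...
res$regressions[["w1e+05"]]$low
#> gc regression (mean_low): slope 0.5807, intercept 22.12, adj R2 0.0000 ...
res$post_correction_r
#> [1] 0.01505294
nrow(res$sites)
#> [1] 10
recovery_report(res$sites, exp$hyper_sites)[c("recovery", "empirical_fdr")]
#> $recovery      [1] 1
#> $empirical_fdr [1] 0
```

Read: the high digestion is strongly GC-driven (adj. R² 0.97 at 100-kb
windows) while the low digestion is not (R² 0.00); after LOESS
correction the low/high log-ratio is decorrelated from GC (r = 0.015);
all 10 planted hyper-accessible sites are recovered at FDR < 0.05 with
no false calls. Domain-scale differences beyond the GC bias are absent
by construction — and the pipeline reports none.

## Command line

A single entry point with subcommands is installed at
`exec/diffmnase` (also callable as `diffmnase_cli()`):

```sh
diffmnase simulate-array --scenario fragile_site --fragments 1000000 \
    --seed 1 --out array
diffmnase synth-genome --length 5000000 --fragments 800000 --out truth/
diffmnase full-pipeline --length 1000000 --fragments 200000 \
    --n-hyper 10 --seed 1 --out run/
```

Outputs are bedGraph/BED/TSV with a provenance header (package version,
config hash, seed); configuration files are JSON with the fields of
`default_config()`.

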