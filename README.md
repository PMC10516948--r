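# cameta

Core-accessory metatranscriptomics for bacterial pangenomes.

## The problem

A bacterial taxon's gene pool splits into a **core** genome — gene
clusters detected in every genome — and an **accessory** genome carried by
subsets of strains. When a population responds transcriptionally to a
perturbation (the motivating case: marine microcosms amended with oil,
dispersant, and nutrients, sampled over six weeks against a biotic
control), the location of that response matters: differentially expressed
(DE) genes spread across the core indicate a species-wide, generalist
response, while a response concentrated in accessory clusters points to
strain-specific adaptation.

`cameta` quantifies this. It builds or imports a pangenome's gene-cluster
membership, partitions clusters into core and accessory bins, selects the
best reference genome by competitive read recruitment, calls DE genes per
treatment against the biotic control with a negative-binomial Wald test
(Benjamini–Hochberg corrected, Cook's-distance outlier control), projects
the DE calls onto gene clusters as per-treatment up/down layers, and
reports the headline statistic

```
core response (%) = 100 × |DE clusters in core| / |DE clusters|
```

For gene *g* in sample *j* the count model is NB with mean
`s_j · q_g(group)` (median-of-ratios size factors `s_j`, per-group means
`q_g`) and trend-shrunk method-of-moments dispersion; the Wald statistic
is `log2((q_trt + c)/(q_BC + c)) / se` with a delta-method standard error.
TPM normalization is provided for reporting; inference always runs on raw
counts. The methods vignette
(`vignettes/core-accessory-metatranscriptomics.Rmd`) derives the model and
records every design choice.

A synthetic-data generator (`sim_config()`, `generate_pangenome()`,
`generate_counts()`, `generate_reads()`) produces pangenomes, read
libraries, and treatment-structured count matrices with known truth, so
the whole pipeline is testable without external data.

## Worked example

```r
library(cameta)

cfg <- sim_config(n_genomes = 6, n_core_clusters = 40,
                  n_accessory_clusters = 60, n_de_genes = 30,
                  rho_core = 0.4, rng_seed = 101)
sim    <- generate_pangenome(cfg)
counts <- generate_counts(cfg, sim$truth)

membership <- cluster_genes(sim$gene_calls)          # de novo clustering
pg <- classify_core_accessory(pangenome(sim$gene_calls, membership))
pg
#> pangenome: 6 genomes, 469 gene calls, 100 gene clusters
#>   core: 46 clusters (core_fraction = 1), accessory: 54

de <- wald_test_all(counts$counts, counts$samples)   # vs biotic control
table(de$contrast, de$status)
#>          down ns up
#>   CEWAF    13 47 17
#>   CEWAFN   14 46 17
#>   DISP     13 47 17
#>   WAF      15 45 17

layers <- map_de_to_clusters(de, membership, "G01",
                             gene_calls = sim$gene_calls)
summarize_core_accessory(layers, pg)
#> CA summary: 32 DE clusters (18 core, 14 accessory)
#>   core response: 56.2%, accessory response: 43.8%
```

All 100 planted clusters are recovered, and the ~30 planted DE genes per
contrast are found. Of the 30 planted DE clusters, 40% carry the
generator's *core* label, but the pipeline reports 56.2% core response:
with only six genomes, several accessory clusters happen to occur in every
genome (probability 0.6⁶ each) and are — correctly, under the strict
occupancy rule — classified core, and a couple of false-positive clusters
join the tally. At the default 20-genome scale this gap disappears and the
estimate tracks the planted fraction closely.

Printed DE-cluster counts can be summarized directly, without rerunning
the pipeline:

```r
ca_summary_from_counts(653, 1598)$core_pct
#> [1] 40.86358
```

## Command line

A thin wrapper around the same functions ships in `inst/scripts/cameta`:

```sh
cameta simulate  --out sim --seed 1
cameta pangenome --gene-calls sim/gene_calls.tsv --out pan
cameta de        --counts sim/counts.tsv --samples sim/samples.tsv --out de
cameta ca        --de de/de_results.tsv --clusters pan/clusters.tsv \
                 --gene-calls sim/gene_calls.tsv --reference G01 --out ca
cameta run-all   --out run --seed 1     # the four steps chained
```

Every run writes a `manifest.json` echoing its parameters; reruns are
byte-identical.

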