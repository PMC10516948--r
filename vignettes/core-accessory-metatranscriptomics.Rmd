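---
title: "Core-accessory metatranscriptomics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core-accessory metatranscriptomics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cameta)
```

## The question the package answers

When a bacterial population responds to an environmental perturbation, the
responding genes can sit in two very different parts of its gene pool. The
*core* genome — gene clusters detected in every genome of the taxon —
encodes the shared physiology of the species; the *accessory* genome —
clusters carried by only a subset of strains — holds niche-specific and
strain-specific functions. Whether a transcriptional response is spread
across the core or concentrated in the accessory genome distinguishes a
generalist, species-wide response from a strain-level specialization.

`cameta` makes that distinction quantitative. Given (i) a pangenome
partitioned into core and accessory gene clusters, (ii) per-gene transcript
counts for one reference genome across treatments, and (iii) differential
expression (DE) calls of each treatment against a biotic control (BC), it
flags every cluster that contains at least one DE gene and reports the
headline statistic

> core response (%) = 100 x |DE clusters in the core| / |DE clusters|,

together with per-treatment and per-direction breakdowns. The motivating
experimental design is a marine oil-spill microcosm study: treatments BC,
DISP (dispersant), WAF (water-accommodated oil fraction), CEWAF
(chemically enhanced WAF) and CEWAFN (CEWAF plus nutrients), sampled in
triplicate at days 0, 7, 17, 28 and 42 (CEWAFN: 0, 7, 42).

## Pangenome construction

Real pangenomes are usually computed by dedicated programs (all-vs-all
protein alignment followed by graph clustering). `cameta` treats those as
the authoritative route and imports their membership tables verbatim via
`import_clusters()` (columns `gene_id`, `genome_id`, `cluster_id`). For
self-contained, desk-scale work it also ships its own clusterer,
`cluster_genes()`: deterministic greedy centroid assignment on amino-acid
k-mer Jaccard similarity.

* Genes are processed in lexicographic `gene_id` order (C collation), so
  results are platform-independent.
* A gene joins the first existing cluster whose *centroid* — the k-mer set
  of the cluster's founding gene — has Jaccard similarity at or above the
  threshold; otherwise it founds a new cluster.
* Defaults `kmer_size = 4`, `similarity_threshold = 0.7`. Four-residue
  k-mers give 160,000 possible words, enough that unrelated proteins share
  almost none, while 4 of every ~150 residues changed still leaves most
  words intact. The threshold 0.7 tolerates roughly 5% amino-acid
  divergence between two cluster members of average length; it is a
  homolog-collapsing radius, not a phylogenetic distance.

Because each gene is compared to fixed founders, the method is
order-deterministic and idempotent: re-clustering the founders at the same
threshold cannot merge or split clusters. The test suite checks the greedy
output against a brute-force all-pairs oracle on small inputs.

`classify_core_accessory()` implements the strict rule by default: a
cluster is core when it occurs in *all* genomes (`core_fraction = 1`). A
soft-core variant is exposed — core iff occupancy >=
`ceiling(core_fraction * n_genomes)` — because large genome collections
with uneven assembly quality often use 0.95-style soft cores; lowering
`core_fraction` can only grow the core set.

## Reference-genome selection by competitive recruitment

Metatranscriptomic reads are screened against every candidate genome
(all-against-all), and the best reference is the genome with the largest
mean mapped-read count across libraries; ties fall back to mean mapping
rate, then lexicographic genome id. The count-first ordering follows the
convention of reporting "average mapping counts and average mapping rates"
in that order; with equal library sizes the two criteria coincide.

The built-in `pseudo_map()` is an exact k-mer screen, not an aligner: a
read maps when at least `min_kmer_hits = 5` of its 21-mers (either strand)
occur in the genome, and a mapped read is attributed to the gene whose
interval contains the plurality of matched k-mer start positions (vote
ties are discarded from per-gene counts — conservative transcript
counting). 21-mers are long enough to be effectively unique in a bacterial
genome, and 5 hits from a 100 bp read tolerate ~1-2% sequencing error.
Summaries from real aligners enter through `import_recruitment()`, which
revalidates and recomputes mapping rates rather than trusting them.

## The expression model

Counts for gene *g* in sample *j* are modelled as negative binomial with
mean `s_j * q_g(group)` and dispersion `alpha_g`, where `s_j` is a
median-of-ratios size factor and `q_g` a per-group (BC vs treatment)
normalized mean. Inference always runs on raw counts with size-factor
offsets; TPM is computed by `tpm()` for reporting and export only. Feeding
within-sample TPM proportions to a count-based test discards the
mean-variance information the NB model needs, so the package deliberately
separates the two streams.

### Dispersion

`estimate_dispersion()` uses method-of-moments within condition groups:
`alpha = (s^2 - m) / m^2` on normalized counts, pooled across groups by
residual degrees of freedom. Gene-wise estimates at 3 replicates are very
noisy, so they are shrunk toward a mean-dispersion trend
`alpha(mu) = a0 + a1/mu` fitted by least squares to the *untruncated*
gene-wise estimates (truncating negatives first would bias the trend
upward); the blend weight is `w = 4 / (4 + df)` so shrinkage fades as
replication grows. Output dispersions are floored at 1e-8. This is a
deliberately simple stand-in for full empirical-Bayes machinery: it keeps
the estimator transparent and testable while holding the observed type-I
error of the downstream Wald test near its nominal level (checked by
simulation in the test suite).

### Wald test

With `q_hat = sum(K) / sum(s)` per group, the log2 fold change is
`log2((q_trt + c) / (q_BC + c))` with a pseudo-fraction stabilizer
`c = 0.5` normalized counts, and the standard error comes from the
delta-method NB variance of `q_hat`:

```
Var(log2 q_hat) = ( 1 / ((q + c) * S)  +  alpha * S2 / S^2 ) / ln(2)^2
```

where `S = sum(s)` and `S2 = sum(s^2)` over the group's samples. The Wald
statistic `lfc / se` is referred to the standard normal, two-sided. The
formula is symmetric in the two groups, so exchanging them exactly negates
every fold change.

### Outliers and filtering

Cook's distances are computed from Pearson residuals with leverage
`h_j = s_j / S`, `D = r^2/p * h/(1-h)^2` with `p = 2` coefficients, and a
gene whose maximum distance exceeds the 0.99 quantile of `F(2, n-2)` is
flagged `outlier`; its p-value is dropped, with no refitting. The
residuals use the *trend* dispersion rather than the gene-wise estimate: a
single aberrant replicate inflates its own gene's dispersion estimate
enough to mask itself, which defeats the purpose of the diagnostic.

Genes with mean normalized count below 1 are flagged `low_count` and
excluded before Benjamini-Hochberg adjustment (an independent-filtering
analogue). `bh_adjust()` delegates to the standard step-up implementation
and passes missing values through. Significance is `padj < 0.05`, with
`up`/`down` taken from the fold-change sign.

### Contrast structure

The design specifies contrasts "against the biotic control" without fixing
the time structure. The default pools all timepoints of a treatment
against all BC samples, which matches the headline counts' whole-experiment
scope; `time_days =` restricts both groups to one sampling day for a
per-timepoint reading. Duplicate libraries at a sampling point are treated
as replicates, not averaged.

## From DE genes to the core-accessory summary

`map_de_to_clusters()` joins DE calls to the reference genome's cluster
memberships: a cluster is flagged per treatment and direction when at
least one of its reference-genome members has that status. Reference genes
missing from every cluster are reported as orphans rather than dropped. A
cluster flagged in several treatments or both directions counts once in
the headline totals (the union rule), because the published totals span
all treatments; per-treatment tallies are emitted alongside. With zero DE
clusters the percentages are reported as missing, never 0/0.

`detection_profile()` averages per-gene covered fractions over a cluster's
reference members; for presence/absence displays a cluster counts as
detected at mean fraction >= 0.5 (a display convention — the underlying
continuous values are always exported).

## The synthetic-data generator

`sim_config()` fixes the study conditions the package is tested under:

* 20 genomes, 200 core + 300 accessory clusters; accessory occurrence
  probability 0.6 per genome (at least one carrier enforced). 0.6 keeps
  the reference genome carrying enough accessory clusters (~180 expected)
  to host the accessory share of 250 planted DE clusters at
  `rho_core = 0.4`.
* Gene lengths uniform in 300-1500 bp (codon-rounded); cluster members are
  copies of a seed coding sequence with per-base substitution rate 0.003,
  chosen so that two members' amino-acid 4-mer Jaccard stays near 0.9,
  comfortably above the 0.7 clustering threshold, while distinct seeds
  share essentially no k-mers. About 30% of genes sit on the minus strand;
  ~70% of clusters receive a KOfam annotation.
* Counts: NB with dispersion 0.1, per-gene baselines log-normal around a
  median of 50 (sdlog 1), library size multipliers log-uniform in
  [0.5, 2]. The design mirrors the microcosm experiment (5 treatments x
  triplicates x the timepoint sets above).
* DE truth: one DE gene per chosen cluster, `|lfc| = 2` with a random
  sign, applied in all four non-control treatments. Placing the effect in
  every treatment makes the planted cluster set — the quantity the
  summary estimates — unambiguous under the union rule.

Every artifact draws from its own RNG stream derived from the master seed
plus a file tag, so adding one output never perturbs another; identical
configurations produce byte-identical files, and `validate_truth()`
cross-checks every emitted truth record against the emitted data.

What the generator does *not* emulate: paralogs (one gene per cluster per
genome), horizontal transfer signatures, operon structure, indels or
realistic sequencing-error profiles, time trends within a treatment, and
multi-species communities. Passing tests on these simulations therefore
demonstrate the correctness of the pipeline's logic and statistics under
its stated model, not robustness to the full messiness of field data —
the import paths (`import_clusters()`, `import_recruitment()`,
`read_counts()`) exist precisely so that real upstream tools can supply
that messiness.

## Numerical and degenerate-input choices

* TPM columns sum to exactly 1e6 by construction; an all-zero sample
  yields an all-zero column rather than NaN.
* Size factors require at least one gene with no zero anywhere; otherwise
  the error suggests a pseudocount fallback instead of silently switching.
* All-zero genes get `NA` dispersion and are flagged `low_count`
  downstream; constant genes get dispersion 0 (raw) and the floor value
  (shrunk).
* Ties in the greedy clusterer are impossible by construction (first
  qualifying centroid wins); ties in the pseudo-mapper's gene vote discard
  the read from per-gene counts.
* Problem sizes in the test suite: the full-scale simulation used for
  partition and fraction recovery is 20 genomes / 500 clusters / ~7,600
  genes with a 69-sample count matrix, which the whole suite processes in
  well under a minute; the statistical checks use 2,000-gene two-group
  simulations.

## Known limitations

* The dispersion shrinkage is a fixed-weight trend blend, not empirical
  Bayes; at 2 replicates per group the Wald test is honest but
  low-powered, and the type-I calibration is validated at the simulated
  3-vs-3 design, not proven in general.
* The greedy clusterer is a homolog collapser for desk-scale and
  simulation use; real pangenomes should come in through
  `import_clusters()`.
* `pseudo_map()` performs no gapped alignment and no quality weighting;
  genomes with high within-genome repeat content will inflate ambiguous
  votes.
* Percentages are fractions of *cluster counts*; no uncertainty is
  attached to the core/accessory split itself.
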