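# hmcdyn

Locus-specific analysis of DNA methylation (5mC) and hydroxymethylation
(5hmC) enrichment peaks in a paired normal / cancer cell-line design.

Affinity-enrichment sequencing (MBD-seq for 5mC; selective chemical labeling
or immunoprecipitation for 5hmC) yields per-replicate peak sets rather than
base-resolution calls. `hmcdyn` implements the downstream integrative
analysis of such peak sets:

* **Feature annotation** with explicit window rules: promoter =
  `[TSS − 2500, TSS + 500)` (strand-aware), genic = TSS + 500 bp through the
  transcript end, exon/intron from gene models, intergenic = peak midpoint
  more than 100 kb from the nearest TSS, CpG-island and DNase-site proximity
  (DHS ± 5 kb). Labels are not exclusive; one peak may carry several.
* **Replicate consensus** (regions supported by ≥ *k* of *n* replicates) and
  **differential regions** between cell lines by a presence/absence rule,
  with an optional peak-score-ratio route.
* **Expression-tier association**: genes split into low/medium/high
  expression tiers; per genomic feature, the Cochran–Armitage chi-square
  test for trend on marked-gene proportions across tiers, Pearson
  correlation of peak counts with tier index, and the two-tailed Fisher
  exact test of the lowest versus highest tier.
* **5hmC fate classification** between cell lines: *absence* (normal 5hmC
  overlapping cancer 5mC), *retention* (normal 5hmC overlapping cancer
  5hmC), *gain* (normal 5mC overlapping cancer 5hmC). Each class is tested
  per feature against two marginal nulls — the feature distribution of the
  normal-cell source mark and of the cancer-cell source mark — by a 1-df
  two-cell goodness-of-fit chi-square with Bonferroni correction over the
  seven features, plus a 2×3 cross-class comparison per feature.
* **Co-incidence** of 5mC and 5hmC within one cell line, **inter-technique
  concordance** of two 5hmC assays (gene-level and strict same-region
  overlap fractions), and a **CpG-random background** comparison.
* **Region-based gene-set enrichment**: regions mapped to nearest-TSS
  genes, upper-tail hypergeometric test against a region-derived background,
  Benjamini–Hochberg FDR, and enrichment-map edges by Jaccard similarity of
  enriched-gene sets.
* **ΔΔCt quantification** for hMeSeal-qPCR validation:
  `fold = 2^(−ΔΔCt)` with input-percentage normalization.
* A **seeded synthetic-data generator** producing a toy genome (gene models
  with exon structure, CGI/DHS/CpG tracks), feature-biased peak sets with
  replicate jitter and dropout, cancer-specific 5hmC loss with planted
  intergenic gain, and expression tables coupled to mark presence through
  proportional tier-odds effects — so the whole pipeline is testable
  without any external data.

All intervals are `GenomicRanges::GRanges`; BED/BED12/GMT/TSV files are read
and written in their standard dialects (BED 0-based half-open).

## Worked example

```r
library(hmcdyn)

ds  <- simulate_dataset(synthetic_config(seed = 1))
res <- run_pipeline(ds, out_dir = "demo_out")

subset(res$association$table,
       mark == "5hmC" & condition == "normal" &
         feature %in% c("genic", "intergenic"),
       select = c(feature, n_low, n_medium, n_high, chi2_trend, p_trend,
                  pearson_r, direction))
#>     feature n_low n_medium n_high chi2_trend      p_trend  pearson_r direction
#>       genic   128      147    176   15.36008 8.884585e-05  0.9785000  positive
#>  intergenic   104       80     48   27.31778 1.726170e-07 -0.9976463  negative
```

Reading: of the 900 simulated genes (300 per expression tier), 128/147/176
low/medium/high-tier genes carry a genic 5hmC differential peak — a rising,
significant trend (chi-square for trend = 15.4, p = 8.9e-05), i.e. genic
hydroxymethylation tracks *higher* expression; intergenic 5hmC shows the
opposite, significant *negative* association. Both recover the effects the
generator plants.

```r
subset(res$dynamics$table,
       class == "gained" & feature == "intergenic" & null == "normal")
#>   class   null mark    feature observed total expected     chi2           p significant direction
#>  gained normal  5mC intergenic       46   110 31.33482 9.597484 0.001948441        TRUE         1
```

Reading: 110 normal-cell 5mC peaks overlap a cancer 5hmC peak ("gained"
regions); 46 of them are intergenic where the normal 5mC marginal predicts
31 — a significant excess (p < 0.05/7 after Bonferroni, direction +1),
recovering the intergenic gain the generator plants.

The run also writes `feature_distribution.tsv`, `association.tsv`,
`dynamics.tsv`, `coincidence.tsv` (+ BED), `concordance.tsv`,
`cpg_background.tsv`, `enrichment_*.tsv`, `enrichment_edges_*.tsv` and a
machine-readable `run_log.json` holding the seed and every threshold.

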