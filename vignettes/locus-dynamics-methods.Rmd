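---
title: "Methods: locus-specific 5mC/5hmC peak dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locus-specific 5mC/5hmC peak dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

`hmcdyn` analyses affinity-enrichment peak sets for 5-methylcytosine (5mC,
e.g. MBD-seq) and 5-hydroxymethylcytosine (5hmC, e.g. chemical-labeling or
antibody enrichment) in a paired normal/cancer cell-line design. The data
atom is a peak: a genomic interval called against an input control. The
package never touches reads; everything downstream of peak calling —
annotation, consensus, differential regions, expression integration, fate
classification, enrichment — is in scope.

## Genomic-feature annotation

A peak is annotated with every feature window it overlaps by at least 1 bp:

| label | window | default |
|---|---|---|
| promoter | `[TSS − u, TSS + d)` strand-aware | u = 2500, d = 500 bp |
| genic | TSS + d through the transcript end | d = 500 bp |
| exonic / intronic | exon blocks / gaps between them | from gene models |
| cgi / cgi_promoter | CpG island / CGI overlapping a promoter window | track |
| dhs | DNase hypersensitive site ± r | r = 5000 bp |
| intergenic | peak **midpoint** more than D from the nearest TSS | D = 100 kb |

Labels are deliberately non-exclusive: a peak inside an exon that is also a
CGI carries `{genic, exonic, cgi}`, so per-feature proportions need not sum
to one. Three choices were genuinely open and are resolved as follows:

* the genic window's 3′ limit is the transcript end (the definition names
  only its 5′ offset);
* intergenic distance is measured from the peak midpoint, consistent with
  the midpoint convention used for nearest-gene assignment;
* peaks 2.5 kb–100 kb from a TSS but outside every window carry no label
  (an "unassigned flanking" zone); they still count in the denominator of
  proportions.

Nearest-TSS assignment minimises `|midpoint − TSS|` with ties broken by the
lexicographically smallest gene name, making every result deterministic.
Multi-transcript genes are collapsed to the longest transcript at read time.

## Consensus and differential regions

Candidate regions are the merged union of replicate peaks; a region is kept
when at least *k* distinct replicates overlap it. The 5mC assay has three
replicates (default *k* = 3); the 5hmC assay has one (*k* = 1, where the
consensus degenerates to the replicate itself). Differential regions
between cell lines use a presence/absence rule: a consensus region is
unique to one line when it overlaps no consensus region of the other.
Read-count fold-change/FDR machinery is intentionally absent — peaks are
the input, so affinity modelling is out of reach; an optional mean-score
ratio filter approximates a fold-change rule when the BED files carry
scores.

## Expression-tier association

Genes are sorted by mean expression and cut into three equal tiers
(remainders to the lower tiers; ties broken by name). Each differential
peak is assigned to its nearest-TSS gene with **no distance cap** — the
intergenic stratum explicitly concerns peaks more than 100 kb out, so a cap
would empty it. Per feature the package reports:

* the Cochran–Armitage chi-square test for trend on marked-gene
  proportions across tiers, scores (0, 1, 2), 1 df, no continuity
  correction, upper-tail p;
* Pearson's r between tier index and peak counts;
* the two-tailed Fisher exact test comparing the lowest and highest tiers.

The direction call is `positive`/`negative` by the trend sign when
p < α, else `nonlinear`.

### Calibration of the trend test

The asymptotic chi-square is compared against the exact conditional
(multivariate hypergeometric) null in the test suite. Two numerical facts
are worth documenting. First, the permutation distribution is a lattice;
the chi-square p approximates its *mid-p* (half weight on ties), and the
suite compares against that convention. Second, conditioning on a single
marked-gene count M makes the exact size of the asymptotic test oscillate
with M — enumeration at tier size 300 gives sizes between 0.044 and 0.056
(e.g. 0.0549 at M = 466) — while across datasets, where M varies, the size
concentrates near the nominal 0.05. The null-calibration test therefore
samples datasets (a pool of generated mark sets crossed with expression
redraws), which is also what the null model means scientifically.

## 5hmC fate classification and dual-null tests

Overlap (≥ 1 bp, half-open convention) between cell lines defines three
classes: **absent** = normal 5hmC × cancer 5mC, **retained** = normal
5hmC × cancer 5hmC, **gained** = normal 5mC × cancer 5hmC. Classes are not
mutually exclusive and a source peak is counted once per class however many
partners it has. For each class and feature, the observed count of
participating source peaks in the feature is tested against `T · p(f)`
where `p(f)` is the marginal feature proportion of the full source peak
set — once with the normal-cell marginal, once with the cancer-cell
marginal — by a two-cell 1-df goodness-of-fit chi-square, Bonferroni
corrected over the seven features (intergenic, genic, exonic, intronic,
promoter, CGI, DHS). A per-feature test rather than a single 7-cell test is
used because the scientific output is one p-value per (class, null,
feature) cell; directions (± of observed − expected) are reported
alongside. A 2×3 chi-square per feature compares the three classes to each
other, falling back to the exact Freeman–Halton test when an expected cell
drops below 1.

## Concordance, co-incidence, CpG background

Two 5hmC techniques are compared at gene level (fraction of technique-1
genes redetected) and strictly (genes whose peaks also overlap in the same
region). The strict count is reported over both denominators — all
technique-1 genes, which is structurally ≤ the gene-level fraction, and
concordant genes only — because both conventions appear in practice.
Same-cell-line 5mC/5hmC co-incidence records the actual overlap spans and
their feature distribution. The CpG-random background test asks whether
peak placement across features could be explained by the distribution of
CpG positions, using the same two-cell chi-square.

## Region enrichment

Foreground and background region sets are mapped to nearest-TSS genes; each
gene set S is tested by the upper-tail hypergeometric
`P(X ≥ k)` for `k = |S ∩ fg|` drawn from `N = |bg|` with `K = |S ∩ bg|`
and `n = |fg|`, with Benjamini–Hochberg FDR across sets. The background is
the union of all 5hmC consensus regions of both cell lines, matching the
design where the background is "everything detectably marked", not the
whole genome. The pipeline tests the whole differential sets and the
intergenic-stratified region lists. Enrichment-map edges connect
significant sets (p < 0.05, FDR < 0.1) whose enriched-gene Jaccard
coefficient passes the cutoff (0.25). The conventional reading — edge when
J **≥** cutoff — is the default; the literal "below" reading is selectable
because the two appear inconsistently in figure legends in this literature.

## ΔΔCt quantification

`ΔCt = Ct(bound) − [Ct(input) − log2(1/input_fraction)]` normalises the
bound reaction to 100 % of input material; `ΔΔCt` subtracts the reference
locus and `fold = 2^(−mean ΔΔCt)` with the SD taken over per-replicate
folds. The input fraction is a parameter (default 0.027 %) because
protocols state it inconsistently; a no-label negative-control reaction is
carried through the same arithmetic and reported alongside, since it is
ambiguous whether it should enter the normalisation.

# The synthetic-data generator

The generator emulates the statistical structure of the assays, not their
chemistry. Defaults (all in `synthetic_config()`):

* **Genome**: 6 chromosomes × 10 Mb; 900 genes of 5–20 kb with 2–8 exons,
  placed in clusters of 6 separated by ~250–300 kb deserts. The deserts
  guarantee a populated intergenic stratum (> 100 kb from every TSS) and a
  set of desert-flanking genes that intergenic peaks can be assigned to.
  200 CGIs (60 % at TSSs), 200 DHSs, 20 000 CpG positions (half inside
  CGIs).
* **Peaks**: ~2000 per base set, widths 100–300 bp (sheared-fragment
  scale); placement biased across features by per-(mark, condition)
  weights. Three 5mC replicates and one 5hmC replicate per condition, each
  a dropout (10 %) + positional jitter (SD 30 bp) realisation of the base
  set. A second-technique emulation of normal 5hmC (70 % redetection with
  150 bp jitter and 200–600 bp fragments, 30 % novel peaks) supports the
  concordance analysis.
* **Cancer condition**: 5hmC count scaled by 0.5 (global loss); the
  intergenic placement weight doubled and 6 % of cancer 5hmC peaks placed
  directly over intergenic normal 5mC peaks — this is the planted
  "gained in intergenic regions" excess, defined against the normal 5mC
  marginal (the recovery experiment therefore reads the normal-marginal row
  of the fate table). The cancer 5mC CGI weight is doubled (CGI
  hypermethylation) and its peak count scaled by 1.25.
* **Expression**: log2 expression is a logistic latent
  (location 6, scale 1); a gene marked under an effect `(mark, feature,
  odds)` is shifted by `scale · log(odds)`, which for a logistic latent is
  *exactly* a proportional-odds multiplier per tier threshold — effects are
  specified on the same scale the tier-based statistics measure. Defaults
  plant odds 2 for genic and DHS 5hmC, odds 0.5 for intergenic 5hmC
  (mirroring the positive genic / negative intergenic association
  structure), and conventional 5mC effects (0.5 in CGIs, 2 in gene
  bodies). Three replicate columns add Gaussian noise (SD 0.25).

Sizes were chosen so that the full pipeline runs in a few seconds and the
200-seed recovery experiment in minutes on one CPU, while keeping the
marked-gene fraction per feature in the informative mid-range: at 900 genes
and ~2000 peaks/set roughly half to three-quarters of genes carry a genic
differential peak. A smaller gene count with the same peak counts saturates
markedness (nearly every gene marked) and destroys the tier contrast — the
regime matters more than the absolute size.

What the generator does **not** emulate: read-level noise, fragment
coverage, peak-caller behaviour, correlated placement beyond the planted
coincidences, probe-level microarray artefacts, and any nucleotide
sequence. Passing recovery tests therefore demonstrates that the pipeline's
statistics detect the planted structure at realistic sizes — not that the
assays themselves are unbiased.

# Numerical choices and degenerate inputs

* Intervals are half-open at the BED boundary; abutting intervals never
  overlap. Merging is idempotent and preserves covered bp.
* Nearest-TSS ties: smallest distance, then lexicographic gene name.
* `trend_test` returns p = 1 when nothing (or everything) is marked;
  `pearson_tier_correlation` returns 0 with a flag for constant counts;
  zero-margin Fisher tables give p = 1; a zero expected count with a
  positive observation reports p at the machine floor with an infinite
  statistic.
* Empty peak sets propagate as empty results, not errors; an empty CpG
  track or empty enrichment foreground is an error because the result would
  be undefined.
* Promoter windows are clipped at coordinate 0 with a warning.
* All generator randomness flows from one integer seed through fixed
  sub-seed offsets; outputs are byte-identical across runs.

# Test design notes

The oracle suite re-derives every interval operation from plain-vector
brute force (all-pairs loops, per-base occupancy) and every exact test from
enumeration. The hypergeometric check is exhaustive for all tables with
N ≤ 60; the Fisher check is exhaustive to total N = 30 and sampled to 60,
because a full 2×2 sweep at N = 60 costs more than its statistical value.
The permutation reference for the trend test uses `r2dtable` draws
conditioned on both margins and the mid-p convention discussed above; with
20 tables a per-table two-sigma gate would trip by chance in most runs, so
the gate is ≥ 19/20 tables within 2 Monte-Carlo SE and all within 4.
Recovery experiments run 200 generator seeds and require ≥ 90 % detection
of each planted effect; null calibration uses 2000 datasets (40 mark-set
pools × 50 expression redraws) for the trend test and 2000 binomial draws
at T = 400 per feature for the fate-class test.

# Known limitations

* Presence/absence differential calling cannot see quantitative affinity
  changes within shared regions unless peak scores are supplied.
* The dual-null chi-square treats features marginally; peaks carrying
  several labels contribute to several rows, so the seven tests per row are
  positively correlated and Bonferroni is conservative.
* Gene-level concordance with no distance cap saturates when peak density
  is high relative to gene count; the strict same-region fraction is the
  informative number in that regime.
* The enrichment background is mark-derived; sets of genes that are never
  marked in either cell line are untestable (skipped and flagged).
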