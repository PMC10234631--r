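---
title: "Methods: expression filtering, MS gene-set enrichment and py-tract analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression filtering, MS gene-set enrichment and py-tract analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`foxsplice` re-implements, as a tested pipeline over tabular summaries, the
computational analysis of a knockdown study of a splicing helicase in
primary CD4+ T cells: which genes change expression when the helicase is
depleted, whether those changes are enriched in multiple sclerosis (MS)
susceptibility genes and aligned with their direction of risk, and whether
the introns whose retention increases under depletion share a distinctive
polypyrimidine (py) tract composition. It operates strictly downstream of
read processing: inputs are gene-level expression/fold-change tables, SNP
-gene association tables, splicing-event tables, and a genome FASTA with
intron intervals. Read alignment, posterior fold-change estimation and PSI
quantification are out of scope; their outputs are consumed as columns.

# Differential expression filtering

A gene is called significantly changed for one shRNA if it passes two
cutoffs in *every* donor:

1. **Abundance**: mean RPKM over the comparison's libraries at least 2
   (the discard rule is "less than 2", so a mean of exactly 2 survives).
   The module also offers a control-libraries-only variant of the average
   (the rule used for ranked-list analyses); the default averages control
   and knockdown libraries of the comparison, which is the rule stated for
   DEG calling. Which libraries entered the published average is not
   stated precisely, so both variants are explicit options and neither is
   asserted as the historical choice.
2. **Effect**: |fold-change score| strictly greater than 0.3 for the
   effective shRNA (Sh3) and 0.1 for the weaker one (Sh5).

Donor intersection is on these magnitude criteria. Direction (up/down) is
computed afterwards from the score signs across donors; genes whose signs
disagree are kept in the intersection but quarantined as `discordant` and
excluded from directional splits, because directional analyses implicitly
assume concordance while the intersection rule itself does not mention
sign.

# MS gene classification

Each SNP-gene pair carries the MS odds ratio (OR) of the risk allele and
the eQTL normalized effect size (NES) of that allele on the gene in
lymphoblastoid cells. The consumed tables encode "risk allele associates
with higher expression" as NES < 0; with OR > 1 defining the risk allele,

* OR > 1 and NES < 0 → **pathogenic** pair (depletion-mimicking direction),
* OR > 1 and NES > 0 → **protective** pair.

Rows stored relative to the non-risk allele (OR < 1) are harmonized by
(OR, NES) → (1/OR, −NES) before the rule is applied; allele flipping
inverts both the association odds and the eQTL sign, so classification is
invariant under the transformation (`classify_pair(OR, NES) ==
classify_pair(1/OR, -NES)` is property-tested). The counter-intuitive NES
sign convention is isolated behind the single `flip_nes_sign` flag.

At the gene level, a gene takes a label if at least one of its pairs
carries it and none carries the opposite one. Genes with pairs of both
labels are reported in a `conflicted` set rather than silently assigned:
the source analyses never state a tie rule, and published pair/gene counts
(539 pairs; 250 + 262 = 512 labelled genes) imply that pairs and genes do
not map one-to-one, so the conflict set keeps that ambiguity auditable.

Because the published pair list is a supplementary download, the package
ships `synthetic_ms_pair_catalog()`: a deterministic, clearly-labelled
synthetic stand-in with the same aggregate structure (558 genes, 539
classifiable pairs, 250/262/4/1 pathogenic/protective/conflicted/
unclassified genes after collapse, 41 genes excluded for missing NES, and
OR<1 rows exercising harmonization). Tests against it verify the
classification machinery end-to-end; they do not certify the published
table itself.

# Overlap enrichment

The enrichment statistic is the observed overlap *k* between the DEG set
(*n1* genes) and an MS gene set (*n2* genes), both first restricted to the
expressed-gene universe (*N* genes passing the abundance filter — the
universe is configurable because no published value of *N* exists). The
null resamples *n1* genes **without replacement** from the universe
(matching a resample of genes from a finite detected set) and the
empirical p is the raw fraction of 100,000 draws with overlap ≥ *k*, as in
the original procedure; a raw zero is reported alongside its resolution
floor as "< 1/R" rather than substituted by the (r+1)/(R+1) estimator.
Sampling without replacement makes the hypergeometric upper tail an exact
oracle, and `hypergeom_tail()` is computed with the exact distribution
function; tests require agreement of the two routes within Monte-Carlo
error over an exhaustive small-universe grid, and that the resampled mode
equals the pmf argmax on enumerable instances.

Directional contrasts run the same test for up×pathogenic,
down×protective and the two flipped pairings, each with a distinct derived
seed.

# Splice-site windows and py tracts

Windows follow the junction conventions: 9-nt 5′SS (exon −3..−1 + intron
+1..+6) and 23-nt 3′SS (intron −20..−1 + exon +1..+3), with the G of the
3′SS AG at position −1; the py tract is intron −20..−3, i.e. the first 18
characters of the 3′SS window. Intervals are BED-style 0-based half-open
on the forward strand; minus-strand introns are reverse-complemented into
transcript orientation, and extraction is property-tested to be an exact
involution under genome reverse-complementation. Out-of-bounds records
are skipped and logged, never fatal; non-canonical junctions are flagged,
not dropped.

Position frequency matrices are column-stochastic over {A, C, G, U}
(T read as U internally, DNA alphabet on disk); `N` is excluded from
column denominators and sequences over 10% `N` are rejected. Information
content is `2 + Σ p log2 p` bits per position without a small-sample
correction, keeping the exact 0-2 bit bounds used by logo renderers.

**C-rich rule.** A tract is C-rich when its mean C frequency across the 18
positions strictly exceeds its mean U frequency (ties → `neither`). The
source analyses describe C-richness qualitatively and never formalize a
threshold, so this package commits to the simplest operational rule and
exposes it as one function; the expectation that 9 of 11 FOXP3 introns are
C-rich is contingent on the unstated original rule and is therefore not a
unit-test oracle here.

**Site strength.** The published analyses scored sites with an external
maximum-entropy model whose fitted tables are external artifacts. The
package's own scorer is a position weight matrix log-odds score (base-2,
pseudocount-shrunk toward the background), which preserves the only
property the downstream comparisons use — a monotone strength ordering —
and `retention_report()` accepts precomputed score columns so external
maximum-entropy scores can be plugged in unchanged. When the internal
scorer is used, the model is trained on the *pooled* retained + control
windows: training on one group alone inflates that group's in-sample
scores and fabricates a between-group difference (observed at p ≈ 0.003
under no planted signal during development), whereas pooled training
scores both groups in-sample and is unbiased under the null.

# Retained-vs-unaffected comparison

Events with MV|dPSI| (minimum |dPSI| at 95% confidence) ≥ 0.15 are
significant — the cutoff is inclusive, a decision the published wording
("using 0.15 as cutoff") does not disambiguate — and split by dPSI sign
into more/less retained. The control set is a seeded uniform sample of
500 unchanged events (all of them, with a warning, if fewer exist).

Outlier removal for scores approximates the original robust-regression
outlier step (Q = 0.5%) with a location-scale rule: values outside
median ± k·MAD with k = Φ⁻¹(1 − q/2), calibrated so the expected false
removal rate on Gaussian scores is q. For a single-sample score
distribution the original method's regression component reduces to exactly
this location-scale trimming; the step is switchable off
(`outlier_q = NULL`).

Group comparisons are two-sided Mann-Whitney rank-sum tests (sidedness is
unstated in the source; two-sided is the conservative default), exact for
small tie-free samples via the standard test implementation. Composition
comparisons test, per base, the per-intron mean frequency over positions
−20..−3 between groups, and report group mean profiles for plotting.

# Synthetic data: what it emulates and what it does not

The generator defaults are the package's fixed study conditions:

* **Expression**: ~10,000 genes, log-normal RPKM (log-mean 1.0, log-sd
  1.5, so roughly half the genes clear the 2-RPKM filter), two donors ×
  {control, Sh3, Sh5}, 5% spiked DEGs with per-comparison score
  ±(1.0 + |N(0, 0.1)|) and concordant sign, non-DEG scores N(0, 0.05).
  The score model is the simplest one reproducing the cutoff structure the
  filter tests; knockdown RPKMs are shifted consistently with the score so
  the table is internally coherent.
* **MS pairs**: 558 pairs with OR = exp|N(0, 0.2)| > 1, an expected
  250/512 fraction of pathogenic (NES < 0) pairs among non-missing ones,
  and 5% missing NES — matching the published catalog's aggregate shape.
* **Introns**: each intron is `gt` + 4 random bases + a 40-120-nt uniform
  spacer + an 18-nt py tract drawn position-wise from a configured profile
  + `ag`, with 3-nt exon flanks, placed on a synthetic chromosome on
  random strands. The C-rich profile puts P(C) = 0.5, P(U) = 0.2 at every
  position (mirrored for U-rich). Positions are independent — the
  downstream analysis is position-wise, so dinucleotide structure is
  deliberately not modelled.
* **Retention**: P(retained) = logistic(−4.2 + 8 × C-fraction of the py
  tract), i.e. ~45% marginal retention (~400 retained of 900 events,
  matching the shape of the published 397-retained vs 500-control
  comparison). The slope 8 was fixed by a pilot power calculation so that
  the planted effect — higher C *and* lower U frequency in retained
  introns — is detectable at p < 0.01 in ≥95% of seeds at n ≈ 900; the
  U-frequency decrease is the weaker signal (it arises only through the
  multinomial anticorrelation with C) and dominates that calculation.
  Retained events get dPSI > 0 and MV|dPSI| ≥ 0.15; unaffected events get
  MV|dPSI| < 0.15 by construction, so the event filter's recovery can be
  tested exactly.

Truth labels are returned beside every table and are consumed only by
tests. What the generator does **not** emulate: read-level noise,
gene-length and GC effects on RPKM, correlated eQTL structure and linkage
between SNPs, branch points and dinucleotide composition of real introns,
and any coupling between DEG status and MS-gene membership (the
directional-enrichment recovery tests plant their own overlap
construction). Passing recovery tests therefore demonstrates correctness
of the pipeline's logic under its assumed statistical structure, not
fidelity of any biological conclusion on real data.

# Numerical and reproducibility choices

* Every random operation takes an explicit integer seed; the pipeline
  expands one global seed into per-stage seeds by a fixed affine map
  modulo 2³¹ − 1 (`derive_seed()`), so one number reproduces a run
  byte-identically.
* Problem sizes used by the shipped test suite and acceptance script —
  10,000 genes, 900 introns, R = 100,000 resampling draws at study scale,
  R = 50,000 on the small-universe oracle grid, 100 power seeds and 500
  null seeds for the recovery properties — were chosen so the full suite
  completes in a few minutes on one CPU while keeping every tolerance a
  3-sigma (or stated) bound rather than a loosened one.
* Empirical p-values are raw fractions; exact tail probabilities come
  from the hypergeometric distribution function; rank tests defer to the
  standard implementation's exact/approximate switch.
* Degenerate inputs fail fast with named errors (invalid config, unknown
  labels, empty universe) or degrade with explicit warnings (short
  unchanged pool, <5 scores for outlier removal, single-sequence
  composition groups, out-of-bounds intervals).

# Known limitations

* The published headline numbers that depend on the deposited sequencing
  data (762 DEGs, the 41-gene overlap with empirical p = 0.00013 and null
  mode 23, 784 retention events split 397/387) require the original
  alignments and an unpublished universe size; they are not reproducible
  from tabular synthetic data and the package makes no claim to reproduce
  them numerically.
* The weight-matrix site score is not a maximum-entropy score; it is a
  monotone stand-in, and real analyses should supply external scores via
  `score_columns`.
* The C-rich/U-rich rule is one defensible operationalization of a
  qualitative published description; alternative thresholds plug in at a
  single function.
* `run_pipeline()` orchestrates the synthetic end-to-end path; analyses
  of external tables use the per-module functions directly (the
  command-line wrapper in `inst/cli/foxsplice.R` exposes both).

# Worked example

```{r example}
library(foxsplice)

cfg <- pipeline_config(seed = 1, outdir = tempfile("foxsplice"))
report <- run_pipeline(cfg)
print(report)

## classification of the packaged reference-structure catalog
collapse_to_genes(build_pairs(synthetic_ms_pair_catalog()))
```
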