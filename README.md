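# foxsplice

Depleting a spliceosomal helicase in primary CD4+ T cells reshapes the
transcriptome in two connected ways: many multiple sclerosis (MS)
susceptibility genes change expression in the direction of their risk
alleles, and a distinctive class of introns — those with **C-rich, U-poor
polypyrimidine (py) tracts**, such as the introns of *FOXP3* — becomes
retained. `foxsplice` is an R package for analysts who want to run (or
stress-test) that computational analysis on gene-level summary tables:
RNA-seq differential-expression filtering, eQTL-direction classification
of susceptibility genes, resampling overlap enrichment, and splice-site /
py-tract sequence comparison. A synthetic-data module generates every
input with known ground truth, so the whole pipeline is testable without
any external download.

## The statistics at the core

**DEG filter.** For each shRNA and donor, keep genes with mean RPKM ≥ 2
over the comparison's libraries, then call genes with |fold-change score|
> 0.3 (Sh3) or > 0.1 (Sh5); a gene is significant only if it passes in
every donor. Direction is annotated from score signs (discordant genes
are kept but excluded from directional splits).

**MS gene classification.** For a SNP–gene pair with risk-allele odds
ratio OR and eQTL normalized effect size NES (risk allele → higher
expression encoded as NES < 0), after harmonizing OR < 1 rows by
(OR, NES) → (1/OR, −NES):

- OR > 1 and NES < 0 → *pathogenic* gene
- OR > 1 and NES > 0 → *protective* gene

Genes with pairs of both labels are quarantined as *conflicted*.

**Overlap enrichment.** With N expressed genes, n₁ DEGs, n₂ MS genes and
observed overlap k, the null resamples n₁ genes without replacement R =
100,000 times; the empirical p is the raw fraction of draws with overlap
≥ k (reported "< 1/R" when zero), and the exact hypergeometric upper tail

&nbsp;&nbsp;P(X ≥ k) = Σ<sub>j≥k</sub> C(n₂, j) · C(N−n₂, n₁−j) / C(N, n₁)

serves as an oracle the resampler is tested against.

**Py-tract analysis.** 5′SS (9 nt: exon −3..−1 + intron +1..+6) and 3′SS
(23 nt: intron −20..−1 + exon +1..+3, AG guanine at −1) windows are
extracted strand-aware from FASTA + BED; the py tract is positions
−20..−3. Position frequency matrices, information content
(2 + Σ p log₂ p bits), a C-rich rule (mean C > mean U), a log-odds
weight-matrix site score, robust (median/MAD) outlier trimming, and
two-sided Mann–Whitney comparisons of score and per-base composition
between retained and unaffected introns.

## Worked example

```r
library(foxsplice)

## 1. gene-level classification of the packaged pair catalog
##    (a deterministic synthetic stand-in mirroring the published list's
##     aggregate structure)
sets <- collapse_to_genes(build_pairs(synthetic_ms_pair_catalog()))
print(sets)
#> MS gene sets: 558 susceptibility | 250 pathogenic | 262 protective | 4 conflicted | 1 unclassified | 41 excluded (missing NES) | 539 classifiable pairs

## 2. overlap enrichment of a DEG set in an MS gene set
universe <- sprintf("G%05d", 1:5000)
degs     <- universe[1:300]
ms_genes <- c(universe[250:500], universe[4000:4300])
print(enrich_test(degs, ms_genes, universe, R = 100000, seed = 7))
#> overlap enrichment: N=5000 n1=300 n2=552 k=51 | null mode 33 | empirical p 0.00099 (R=100000) | exact p 0.00088

## 3. retained-vs-unaffected py-tract comparison on synthetic introns
##    with a planted retention/C-content association
cfg <- simulation_config(seed = 1)
g   <- gen_intron_set(cfg, "crich")
ev  <- gen_retention_events(g$introns, cfg)
print(retention_report(ev$events, g$introns, n_control = 400, seed = 1))
#> retention comparison: 406 retained vs 400 unaffected controls (of 494 unchanged)
#>   5'SS score p = 0.895 | 3'SS score p = 1.04e-29 | 2 outliers removed
#>   A: 0.130 vs 0.167 (p = 4.58e-09)
#>   C: 0.551 vs 0.455 (p = 3.97e-31)
#>   G: 0.134 vs 0.163 (p = 2.13e-06)
#>   U: 0.185 vs 0.216 (p = 1.56e-05)
```

Reading the output: the 300-gene DEG set overlaps the 552-gene target set
in 51 genes where ~33 are expected by chance (empirical p ≈ 0.001,
matching the exact tail); and retained introns are markedly C-richer
(0.551 vs 0.455) and U-poorer (0.185 vs 0.216) than unaffected controls,
with no difference at the 5′ splice site but a large one at the 3′ splice
site score — the py-tract signature the pipeline is designed to detect.
`run_pipeline(pipeline_config(seed = 1))` chains all stages (simulate →
DEG → classify → enrich → splice sites → retention) and writes every
intermediate table plus a JSON run report; `inst/cli/foxsplice.R` exposes
the same operations as shell subcommands.

## Layout

- `R/` — modules: synthetic data, DEG filter, MS catalog, enrichment,
  splice sites, retention comparison, pipeline orchestration
- `tests/testthat/` — unit, property and acceptance suites (fixtures are
  generated in code)
- `vignettes/foxsplice-methods.Rmd` — the methods vignette: model,
  assumptions, parameter choices, numerical decisions, limitations
- `inst/cli/foxsplice.R` — thin command-line wrapper
- `scripts/acceptance.R` — end-to-end recomputation (above)
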