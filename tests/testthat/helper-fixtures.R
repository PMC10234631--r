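## Shared fixtures, built in code.

## Toy expression table with exactly known means and scores.
## Two donors (Donor1, Donor4), libraries NTC/Sh3/Sh5 each.
toy_expression <- function(gene_id, rpkm_mean, gfold_d1 = 0, gfold_d4 = 0) {
  n <- length(gene_id)
  gfold_d1 <- rep_len(gfold_d1, n)
  gfold_d4 <- rep_len(gfold_d4, n)
  tab <- data.frame(gene_id = gene_id, stringsAsFactors = FALSE)
  for (lib in c("Donor1_NTC", "Donor1_Sh3", "Donor1_Sh5",
                "Donor4_NTC", "Donor4_Sh3", "Donor4_Sh5")) {
    tab[[paste0("rpkm.", lib)]] <- rep_len(rpkm_mean, n)
  }
  tab$gfold.Donor1_Sh3 <- gfold_d1
  tab$gfold.Donor4_Sh3 <- gfold_d4
  tab$gfold.Donor1_Sh5 <- gfold_d1
  tab$gfold.Donor4_Sh5 <- gfold_d4
  tab
}

## Independent brute-force hypergeometric upper tail from binomial
## coefficients (oracle; deliberately not phyper).
choose_tail <- function(N, n1, n2, k) {
  j <- k:min(n1, n2)
  if (k <= 0) return(1)
  if (k > min(n1, n2)) return(0)
  sum(choose(n2, j) * choose(N - n2, n1 - j)) / choose(N, n1)
}

## Run select -> control-sample -> composition on a generated intron set;
## returns the per-base comparison table.
composition_run <- function(seed, slope, intercept, n_introns = 900,
                            n_control = 400) {
  cfg <- simulation_config(seed = seed, n_introns = n_introns,
                           retention_slope = slope,
                           retention_intercept = intercept)
  g <- gen_intron_set(cfg, "crich")
  ev <- gen_retention_events(g$introns, cfg)
  sel <- select_events(ev$events)
  ctl_ids <- sample_unaffected(sel$event_id[sel$class == "unchanged"],
                               n = n_control, seed = seed)
  tract <- function(genes) {
    g$introns$py_tract[match(genes, g$introns$gene_id)]
  }
  a <- tract(sel$gene_id[sel$class == "more_retained"])
  b <- tract(sel$gene_id[match(ctl_ids, sel$event_id)])
  compare_composition(a, b)$per_base
}

base_cols <- function(introns_df) {
  introns_df[, c("gene_id", "intron_index", "chrom", "start", "end",
                 "strand")]
}
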