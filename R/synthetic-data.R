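## Synthetic-data module: generates every pipeline input with the
## statistical structure the downstream analysis assumes, plus ground-truth
## labels for recovery testing. Truth labels are never consumed by the
## analysis stages themselves.

#' Default per-position py-tract base profile
#'
#' Column-stochastic 4 x 18 matrix over \{A, C, G, U\} describing a C-rich
#' or U-rich polypyrimidine tract (positions -20..-3 relative to the 3'SS
#' AG, G = -1). The C-rich profile puts probability 0.5 on C and 0.2 on U
#' at every position; the U-rich profile is its mirror image.
#'
#' @param kind `"crich"` or `"urich"`.
#' @param length Tract length in nucleotides (default 18).
#' @return A 4 x `length` matrix with rownames `A, C, G, U`, columns
#'   labelled by py-tract position (-20..-3 for length 18).
#' @export
pytract_profile <- function(kind = c("crich", "urich"), length = 18L) {
  kind <- match.arg(kind)
  col <- switch(kind,
    crich = c(A = 0.15, C = 0.50, G = 0.15, U = 0.20),
    urich = c(A = 0.15, C = 0.20, G = 0.15, U = 0.50))
  m <- matrix(rep(col, length), nrow = 4L,
              dimnames = list(names(col), NULL))
  colnames(m) <- as.character(seq(-2L - length, -3L))
  m
}

#' Simulation configuration
#'
#' Bundles and validates every parameter of the synthetic-data generators.
#' The defaults describe the study conditions the pipeline is built for:
#' two sequenced donors, three libraries per donor (non-targeting control
#' plus two knockdown shRNAs), ~10,000 expressed genes with a 5% spiked DEG
#' fraction, a 558-gene MS susceptibility catalog with roughly equal
#' pathogenic/protective split, and ~900 introns whose retention
#' probability rises with py-tract C content through a logistic link.
#'
#' @param seed Integer seed; every generator call is reproducible given the
#'   config.
#' @param n_genes Number of genes in the expression table.
#' @param n_ms_genes Number of SNP-gene susceptibility pairs.
#' @param frac_pathogenic Expected fraction of non-missing pairs with
#'   negative eQTL effect size (NES < 0, i.e. risk allele raises
#'   expression).
#' @param frac_missing_nes Expected fraction of pairs lacking an eQTL
#'   effect size.
#' @param n_donors Number of donors (>= 2; the first two are labelled
#'   Donor1 and Donor4, the sequenced donors).
#' @param deg_fraction Expected fraction of genes that are true DEGs.
#' @param deg_effect Mean absolute fold-change score for true DEGs
#'   (log2-scale units).
#' @param rpkm_log_mean,rpkm_log_sd Natural-log scale location and spread
#'   of baseline RPKM.
#' @param n_introns Number of introns for the retention simulation.
#' @param pytract_profile_crich,pytract_profile_urich 4 x 18
#'   column-stochastic matrices over \{A,C,G,U\} (see [pytract_profile()]).
#' @param retention_slope,retention_intercept Logistic-link coefficients:
#'   P(retained) = plogis(intercept + slope * C fraction of the py tract).
#' @return An object of class `simulation_config` (a validated list).
#' @examples
#' cfg <- simulation_config(seed = 1, n_genes = 100, n_introns = 50)
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 10000L,
                              n_ms_genes = 558L,
                              frac_pathogenic = 250 / 512,
                              frac_missing_nes = 0.05,
                              n_donors = 2L,
                              deg_fraction = 0.05,
                              deg_effect = 1.0,
                              rpkm_log_mean = 1.0,
                              rpkm_log_sd = 1.5,
                              n_introns = 900L,
                              pytract_profile_crich = pytract_profile("crich"),
                              pytract_profile_urich = pytract_profile("urich"),
                              retention_slope = 8,
                              retention_intercept = -4.2) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_ms_genes = as.integer(n_ms_genes),
              frac_pathogenic = frac_pathogenic,
              frac_missing_nes = frac_missing_nes,
              n_donors = as.integer(n_donors),
              deg_fraction = deg_fraction, deg_effect = deg_effect,
              rpkm_log_mean = rpkm_log_mean, rpkm_log_sd = rpkm_log_sd,
              n_introns = as.integer(n_introns),
              pytract_profile_crich = pytract_profile_crich,
              pytract_profile_urich = pytract_profile_urich,
              retention_slope = retention_slope,
              retention_intercept = retention_intercept)
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  counts <- c("n_genes", "n_ms_genes", "n_donors", "n_introns")
  for (nm in counts) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] < 1L) {
      stop_invalid("invalid config: %s must be a count >= 1 (got %s)",
                   nm, format(cfg[[nm]]))
    }
  }
  fracs <- c("frac_pathogenic", "frac_missing_nes", "deg_fraction")
  for (nm in fracs) {
    v <- cfg[[nm]]
    if (!is.finite(v) || v < 0 || v > 1) {
      stop_invalid("invalid config: %s must lie in [0, 1]", nm)
    }
  }
  for (nm in c("pytract_profile_crich", "pytract_profile_urich")) {
    p <- cfg[[nm]]
    if (!is.matrix(p) || nrow(p) != 4L ||
        !identical(rownames(p), c("A", "C", "G", "U"))) {
      stop_invalid("invalid config: %s must be a 4 x L matrix with rows A,C,G,U",
                   nm)
    }
    if (any(p < 0) || any(abs(colSums(p) - 1) > 1e-9)) {
      stop_invalid("invalid config: %s columns must each sum to 1", nm)
    }
  }
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config:",
      sprintf("%d genes (%.1f%% DEG), %d MS pairs, %d donors, %d introns, seed %d",
              x$n_genes, 100 * x$deg_fraction, x$n_ms_genes, x$n_donors,
              x$n_introns, x$seed), "\n")
  invisible(x)
}

## Donor labels: the two sequenced donors are Donor1 and Donor4; any
## additional donors get fresh sequential numbers.
donor_labels <- function(n) {
  base <- c("Donor1", "Donor4")
  if (n <= 2L) return(base[seq_len(n)])
  c(base, paste0("Donor", 4L + seq_len(n - 2L)))
}

#' Generate a gene-level expression/fold-change table
#'
#' Emulates a gene-level summary of knockdown RNA-seq: per-library RPKM
#' drawn log-normally, and a per-comparison signed fold-change score
#' ("gfold" columns, one per donor x shRNA). A seeded `deg_fraction` of
#' genes are true DEGs: their score in every comparison is
#' `sign * (deg_effect + |N(0, 0.1)|)` with a common sign, and their
#' knockdown libraries are shifted by the corresponding factor; non-DEG
#' scores are N(0, 0.05).
#'
#' @param config A [simulation_config()].
#' @return A list with elements `table` (data frame: `gene_id`,
#'   `rpkm.<donor>_<lib>` columns, `gfold.<donor>_<shRNA>` columns) and
#'   `truth` (data frame: `gene_id`, `is_deg`, `direction`).
#' @export
gen_expression_table <- function(config) {
  validate_simulation_config(config)
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_genes
  donors <- donor_labels(config$n_donors)
  shrnas <- c("Sh3", "Sh5")
  gene_id <- sprintf("G%05d", seq_len(n))

  is_deg <- runif(n) < config$deg_fraction
  sign_deg <- ifelse(runif(n) < 0.5, 1, -1)
  direction <- ifelse(!is_deg, "none", ifelse(sign_deg > 0, "up", "down"))

  base_rpkm <- exp(rnorm(n, config$rpkm_log_mean, config$rpkm_log_sd))
  tab <- data.frame(gene_id = gene_id, stringsAsFactors = FALSE)

  scores <- list()
  for (d in donors) {
    for (sh in shrnas) {
      s <- rnorm(n, 0, 0.05)
      spike <- sign_deg * (config$deg_effect + abs(rnorm(n, 0, 0.1)))
      s[is_deg] <- spike[is_deg]
      scores[[paste0(d, "_", sh)]] <- s
    }
  }
  for (d in donors) {
    tab[[paste0("rpkm.", d, "_NTC")]] <-
      base_rpkm * exp(rnorm(n, 0, 0.1))
    for (sh in shrnas) {
      fc <- 2^scores[[paste0(d, "_", sh)]]
      tab[[paste0("rpkm.", d, "_", sh)]] <-
        base_rpkm * fc * exp(rnorm(n, 0, 0.1))
    }
  }
  for (cmp in names(scores)) {
    tab[[paste0("gfold.", cmp)]] <- scores[[cmp]]
  }
  truth <- data.frame(gene_id = gene_id, is_deg = is_deg,
                      direction = direction, stringsAsFactors = FALSE)
  list(table = tab, truth = truth)
}

#' Generate a SNP-gene susceptibility pair table
#'
#' Emulates a merged GWAS + eQTL pair list: every row is one risk SNP
#' paired with one susceptibility gene, with an odds ratio OR > 1 by
#' construction (the risk allele defines the direction) and a signed eQTL
#' normalized effect size NES. An expected `frac_pathogenic` of non-missing
#' pairs have NES < 0 (risk allele raises expression); an expected
#' `frac_missing_nes` of pairs have NES absent.
#'
#' @param config A [simulation_config()].
#' @param gene_pool Optional character vector to draw gene ids from (e.g.
#'   the gene ids of an expression table); defaults to fresh `MSG...` ids.
#' @return A list with elements `table` (data frame: `snp_id`, `gene_id`,
#'   `odds_ratio`, `nes`) and `truth` (adds `true_label` among
#'   pathogenic/protective/excluded_missing).
#' @export
gen_ms_pair_table <- function(config, gene_pool = NULL) {
  validate_simulation_config(config)
  set.seed(derive_seed(config$seed, 2L))
  n <- config$n_ms_genes
  gene_id <- if (is.null(gene_pool)) {
    sprintf("MSG%04d", seq_len(n))
  } else {
    sample(gene_pool, n, replace = length(gene_pool) < n)
  }
  snp_id <- sprintf("rs%07d", sample.int(9999999L, n))
  odds_ratio <- exp(abs(rnorm(n, 0, 0.2)))
  missing <- runif(n) < config$frac_missing_nes
  pathogenic <- runif(n) < config$frac_pathogenic
  nes <- ifelse(pathogenic, -1, 1) * abs(rnorm(n, 0, 0.5))
  nes[missing] <- NA_real_
  true_label <- ifelse(missing, "excluded_missing",
                       ifelse(pathogenic, "pathogenic", "protective"))
  tab <- data.frame(snp_id = snp_id, gene_id = gene_id,
                    odds_ratio = odds_ratio, nes = nes,
                    stringsAsFactors = FALSE)
  truth <- cbind(tab[, c("snp_id", "gene_id")],
                 data.frame(true_label = true_label,
                            stringsAsFactors = FALSE))
  list(table = tab, truth = truth)
}

#' Generate a synthetic intron set with known py-tract composition
#'
#' Builds `n` introns embedded in a single synthetic chromosome. Each
#' transcript-orientation intron is `gt` + 4 random donor bases + a random
#' spacer + an 18-nt py tract drawn position-wise from the chosen profile +
#' `ag`, flanked by 3-nt exonic ends. Strands alternate between + and -;
#' minus-strand introns are reverse-complemented into the forward genome so
#' the extractor's strand handling is exercised.
#'
#' @param config A [simulation_config()].
#' @param profile `"crich"` or `"urich"` (which configured profile to use),
#'   or a 4 x 18 column-stochastic matrix.
#' @param n Number of introns (default `config$n_introns`).
#' @param spacer_range Integer range of random spacer lengths between the
#'   donor site and the py tract.
#' @return A list with `introns` (data frame: `gene_id`, `intron_index`,
#'   `chrom`, `start`, `end` (0-based half-open, forward strand), `strand`,
#'   `five_ss` (9 nt), `three_ss` (23 nt), `py_tract` (18 nt); exon bases
#'   upper-case, intron bases lower-case) and `genome` (a
#'   [Biostrings::DNAStringSet] with one chromosome).
#' @export
gen_intron_set <- function(config, profile = c("crich", "urich"),
                           n = config$n_introns,
                           spacer_range = c(40L, 120L)) {
  validate_simulation_config(config)
  if (is.character(profile)) {
    profile <- match.arg(profile)
    prof <- config[[paste0("pytract_profile_", profile)]]
  } else {
    prof <- profile
  }
  set.seed(derive_seed(config$seed, 3L))
  n <- as.integer(n)
  stopifnot(n >= 1L)

  exon5 <- random_dna(n, 3L)
  donor_rest <- random_dna(n, 4L)
  spacer_len <- sample(seq(spacer_range[1], spacer_range[2]), n,
                       replace = TRUE)
  spacer <- random_dna_var(spacer_len)
  py <- draw_from_profile(prof, n)
  exon3 <- random_dna(n, 3L)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  pad <- random_dna(n, 10L)

  intron_seq <- paste0("GT", donor_rest, spacer, py, "AG")
  intron_len <- nchar(intron_seq)
  block <- paste0(exon5, intron_seq, exon3)
  block_rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(block)))
  block_fwd <- ifelse(strand == "+", block, block_rc)

  pieces <- as.vector(rbind(pad, block_fwd))
  genome_seq <- paste0(paste0(pieces, collapse = ""),
                       paste0(random_dna(1L, 10L), collapse = ""))
  ## intron coordinates on the forward strand: the intron occupies the same
  ## offsets inside the block whether or not the block was flipped, because
  ## both exonic flanks have length 3.
  block_start <- cumsum(c(0L, head(nchar(pad) + nchar(block_fwd), -1L))) +
    nchar(pad)
  start <- block_start + 3L
  end <- start + intron_len

  introns <- data.frame(
    gene_id = sprintf("SYNT%04d", seq_len(n)),
    intron_index = 1L,
    chrom = "chrS",
    start = start,
    end = end,
    strand = strand,
    five_ss = paste0(exon5, tolower(substr(intron_seq, 1L, 6L))),
    three_ss = paste0(tolower(paste0(py, "ag")), exon3),
    py_tract = tolower(py),
    stringsAsFactors = FALSE)

  genome <- Biostrings::DNAStringSet(stats::setNames(genome_seq, "chrS"))
  list(introns = introns, genome = genome)
}

#' Generate differential intron-retention events with a planted
#' composition effect
#'
#' One event per intron. The retention indicator is Bernoulli with
#' `logit p = retention_intercept + retention_slope * (py-tract C
#' fraction)`. Retained events get `dpsi > 0` and `mv_dpsi >= 0.15`;
#' unaffected events get `mv_dpsi < 0.15`. `mv_dpsi` is the minimum |dPSI|
#' at 95% confidence used as the significance filter downstream.
#'
#' @param introns Intron data frame from [gen_intron_set()].
#' @param config A [simulation_config()].
#' @return A list with `events` (data frame: `event_id`, `gene_id`,
#'   `event_type`, `dpsi`, `mv_dpsi`) and `truth` (`event_id`,
#'   `is_retained`, `c_fraction`).
#' @export
gen_retention_events <- function(introns, config) {
  validate_simulation_config(config)
  if (nrow(introns) == 0L) stop_invalid("introns must be non-empty")
  set.seed(derive_seed(config$seed, 4L))
  n <- nrow(introns)
  up <- toupper(introns$py_tract)
  c_frac <- (nchar(up) - nchar(gsub("C", "", up, fixed = TRUE))) / nchar(up)
  p <- plogis(config$retention_intercept + config$retention_slope * c_frac)
  retained <- rbinom(n, 1L, p) == 1L

  dpsi <- rnorm(n, 0, 2)
  mv <- runif(n, 0, 0.15)
  dpsi[retained] <- runif(sum(retained), 5, 60)
  mv[retained] <- 0.15 + rexp(sum(retained), rate = 10)

  events <- data.frame(
    event_id = sprintf("EV%05d", seq_len(n)),
    gene_id = introns$gene_id,
    event_type = "retained_intron",
    dpsi = dpsi,
    mv_dpsi = mv,
    stringsAsFactors = FALSE)
  truth <- data.frame(event_id = events$event_id, is_retained = retained,
                      c_fraction = c_frac, stringsAsFactors = FALSE)
  list(events = events, truth = truth)
}

#' Deterministic synthetic stand-in for the published SNP-gene pair list
#'
#' Constructs, without randomness, a SNP-gene pair table with the same
#' aggregate structure as the published MS susceptibility pair list this
#' package is designed to consume: 558 distinct genes; 539 pairs with a
#' usable eQTL effect size (41 further genes carry only missing-NES pairs
#' and are excluded from classification); after gene-level collapse, 250
#' pathogenic genes, 262 protective genes, 4 genes with conflicting pair
#' labels and 1 unclassified gene (NES exactly 0). A subset of rows is
#' stored with OR < 1 and the eQTL sign flipped, so allele harmonization is
#' exercised. This is a synthetic fixture, not the published table.
#'
#' @return A data frame with columns `snp_id`, `gene_id`, `odds_ratio`,
#'   `nes`.
#' @export
synthetic_ms_pair_catalog <- function() {
  rows <- list()
  add <- function(gene, snp_suffix, or, nes) {
    rows[[length(rows) + 1L]] <<- data.frame(
      snp_id = sprintf("rsS%04d_%d", length(rows) + 1L, snp_suffix),
      gene_id = gene, odds_ratio = or, nes = nes,
      stringsAsFactors = FALSE)
  }
  ## 250 pathogenic genes (OR>1 & NES<0 after harmonization); the first 10
  ## carry a second concordant pair; every 7th row is stored flipped.
  for (i in seq_len(250L)) {
    gene <- sprintf("MSPATH%03d", i)
    or <- 1 + 0.1 + (i %% 17) / 40
    nes <- -(0.1 + (i %% 11) / 30)
    if (i %% 7L == 0L) add(gene, 1L, 1 / or, -nes) else add(gene, 1L, or, nes)
    if (i <= 10L) add(gene, 2L, or + 0.05, nes - 0.02)
  }
  ## 262 protective genes (OR>1 & NES>0); first 8 have a second pair.
  for (i in seq_len(262L)) {
    gene <- sprintf("MSPROT%03d", i)
    or <- 1 + 0.12 + (i %% 13) / 35
    nes <- 0.1 + (i %% 9) / 25
    if (i %% 7L == 0L) add(gene, 1L, 1 / or, -nes) else add(gene, 1L, or, nes)
    if (i <= 8L) add(gene, 2L, or + 0.04, nes + 0.03)
  }
  ## 4 conflicted genes: one pathogenic and one protective pair each.
  for (i in seq_len(4L)) {
    gene <- sprintf("MSCONF%02d", i)
    add(gene, 1L, 1.2, -0.15)
    add(gene, 2L, 1.3, +0.20)
  }
  ## 1 unclassified gene: NES exactly 0.
  add("MSZERO01", 1L, 1.25, 0)
  ## 41 genes whose only pairs lack NES (excluded before classification).
  for (i in seq_len(41L)) {
    add(sprintf("MSMISS%02d", i), 1L, 1.1 + (i %% 5) / 20, NA_real_)
  }
  do.call(rbind, rows)
}
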