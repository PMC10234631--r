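## MS catalog module: SNP-gene susceptibility pairs classified as
## pathogenic or protective from the eQTL direction of effect.
##
## Convention: the risk allele is the allele with OR > 1. A pair is
## "pathogenic" when the risk allele associates with HIGHER expression of
## the gene, which in the consumed eQTL tables is encoded as NES < 0; it is
## "protective" when the risk allele associates with lower expression
## (NES > 0). Rows stored with OR < 1 describe the non-risk allele and are
## harmonized by (OR, NES) -> (1/OR, -NES) before the rule is applied.

#' Classify one or more SNP-gene pairs from OR and eQTL effect size
#'
#' Vectorized. Pairs with `OR = 1` after harmonization, or `NES = 0`, are
#' `unclassified`; pairs with missing NES are `excluded_missing`.
#'
#' @param odds_ratio Positive numeric vector of odds ratios.
#' @param nes Numeric vector of eQTL normalized effect sizes (NA allowed).
#' @param flip_nes_sign Set `TRUE` if the supplied tables use the opposite
#'   NES sign convention (NES > 0 = higher expression on the risk allele).
#' @return Character vector of labels: `pathogenic`, `protective`,
#'   `unclassified`, `excluded_missing`.
#' @examples
#' classify_pair(c(1.3, 1.3, 0.8), c(-0.2, 0.2, 0.2))
#' @export
classify_pair <- function(odds_ratio, nes, flip_nes_sign = FALSE) {
  if (any(!is.finite(odds_ratio) | odds_ratio <= 0)) {
    stop_invalid("odds_ratio must be positive and finite")
  }
  if (flip_nes_sign) nes <- -nes
  ## harmonize to the risk allele
  flip <- odds_ratio < 1
  or_h <- ifelse(flip, 1 / odds_ratio, odds_ratio)
  nes_h <- ifelse(flip, -nes, nes)
  label <- rep("unclassified", length(or_h))
  label[or_h > 1 & nes_h < 0] <- "pathogenic"
  label[or_h > 1 & nes_h > 0] <- "protective"
  label[is.na(nes)] <- "excluded_missing"
  label
}

#' Build and classify SNP-gene pairs
#'
#' @param pairs Data frame with columns `snp_id`, `gene_id`, `odds_ratio`,
#'   `nes` (see [read_ms_pairs()] for column mapping from other layouts).
#' @param flip_nes_sign Passed to [classify_pair()].
#' @return The input with an added `label` column; duplicated
#'   `(snp_id, gene_id)` rows raise an error unless their values are
#'   identical (in which case one copy is kept).
#' @export
build_pairs <- function(pairs, flip_nes_sign = FALSE) {
  assert_columns(pairs, c("snp_id", "gene_id", "odds_ratio", "nes"),
                 "pair table")
  key <- paste(pairs$snp_id, pairs$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    uniq <- !duplicated(paste(key, pairs$odds_ratio, pairs$nes, sep = "\r"))
    pairs <- pairs[uniq, , drop = FALSE]
    key <- key[uniq]
    if (anyDuplicated(key)) {
      stop_invalid("duplicated (snp_id, gene_id) pair(s) with conflicting values: %s",
                   paste(head(unique(sub("\r", "/", key[duplicated(key)])), 5L),
                         collapse = ", "))
    }
  }
  pairs$label <- classify_pair(pairs$odds_ratio, pairs$nes,
                               flip_nes_sign = flip_nes_sign)
  pairs
}

#' Collapse classified pairs to gene-level MS gene sets
#'
#' A gene becomes pathogenic (resp. protective) if at least one of its
#' pairs carries that label and none carries the other; genes with pairs of
#' both labels are quarantined in `conflicted` rather than silently
#' assigned. `susceptibility` is every gene in the input, including genes
#' whose pairs were all excluded for missing NES.
#'
#' @param pairs Classified pair data frame from [build_pairs()].
#' @return An object of class `ms_gene_sets`: a list with character-vector
#'   elements `susceptibility`, `pathogenic`, `protective`, `conflicted`,
#'   `unclassified`, `excluded_missing`, plus `n_pairs_classifiable`.
#' @export
collapse_to_genes <- function(pairs) {
  assert_columns(pairs, c("gene_id", "label"), "classified pair table")
  has <- function(lbl) unique(pairs$gene_id[pairs$label == lbl])
  path_any <- has("pathogenic")
  prot_any <- has("protective")
  conflicted <- intersect(path_any, prot_any)
  pathogenic <- setdiff(path_any, conflicted)
  protective <- setdiff(prot_any, conflicted)
  classified <- union(path_any, prot_any)
  unclassified <- setdiff(has("unclassified"), classified)
  all_genes <- unique(pairs$gene_id)
  excluded <- setdiff(has("excluded_missing"),
                      union(classified, unclassified))
  out <- list(susceptibility = all_genes,
              pathogenic = pathogenic,
              protective = protective,
              conflicted = conflicted,
              unclassified = unclassified,
              excluded_missing = excluded,
              n_pairs_classifiable = sum(pairs$label != "excluded_missing"))
  class(out) <- "ms_gene_sets"
  out
}

#' @export
print.ms_gene_sets <- function(x, ...) {
  cat(sprintf(paste0(
    "MS gene sets: %d susceptibility | %d pathogenic | %d protective | ",
    "%d conflicted | %d unclassified | %d excluded (missing NES) | ",
    "%d classifiable pairs\n"),
    length(x$susceptibility), length(x$pathogenic), length(x$protective),
    length(x$conflicted), length(x$unclassified),
    length(x$excluded_missing), x$n_pairs_classifiable))
  invisible(x)
}

#' Read a SNP-gene pair table from TSV
#'
#' @param path TSV path with a header row.
#' @param columns Named character vector mapping the required names
#'   (`snp_id`, `gene_id`, `odds_ratio`, `nes`) to the file's column names;
#'   defaults to identity.
#' @return Data frame with the four required columns.
#' @export
read_ms_pairs <- function(path,
                          columns = c(snp_id = "snp_id",
                                      gene_id = "gene_id",
                                      odds_ratio = "odds_ratio",
                                      nes = "nes")) {
  raw <- read_tsv(path)
  assert_columns(raw, unname(columns), sprintf("pair table '%s'", path))
  out <- raw[, unname(columns), drop = FALSE]
  names(out) <- names(columns)
  out$odds_ratio <- as.numeric(out$odds_ratio)
  out$nes <- suppressWarnings(as.numeric(out$nes))
  out
}
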