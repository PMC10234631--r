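## DEG filter module: expression-level and fold-change-score cutoffs,
## intersected across donors.
##
## Expression tables are wide data frames with one row per gene:
##   gene_id | rpkm.<library> ... | gfold.<donor>_<shRNA> ...
## Library labels are <donor>_<condition> (e.g. Donor1_NTC, Donor1_Sh3);
## comparison labels are <donor>_<shRNA>.

default_gfold_cutoffs <- c(Sh3 = 0.3, Sh5 = 0.1)

rpkm_cols <- function(table) grep("^rpkm\\.", names(table), value = TRUE)

## Library labels that enter the RPKM average for one donor/shRNA
## comparison under a given rule.
comparison_libraries <- function(donor, shrna,
                                 rule = c("all_libraries", "control_only")) {
  rule <- match.arg(rule)
  switch(rule,
    all_libraries = paste0(donor, "_", c("NTC", shrna)),
    control_only = paste0(donor, "_NTC"))
}

#' Filter genes by mean expression
#'
#' Keeps genes whose mean RPKM over the named libraries is at least
#' `min_rpkm` (the discard rule is "less than `min_rpkm`", so a mean of
#' exactly `min_rpkm` is kept).
#'
#' @param table Expression data frame (see module header for the column
#'   contract).
#' @param libraries Character vector of library labels to average over.
#' @param min_rpkm Expression cutoff (default 2 RPKM).
#' @return Character vector of gene ids passing the filter.
#' @examples
#' tab <- data.frame(gene_id = c("a", "b"),
#'                   rpkm.D1_NTC = c(1, 5), rpkm.D1_Sh3 = c(1, 3))
#' filter_expressed(tab, c("D1_NTC", "D1_Sh3"))
#' @export
filter_expressed <- function(table, libraries, min_rpkm = 2) {
  assert_columns(table, "gene_id", "expression table")
  cols <- paste0("rpkm.", libraries)
  missing <- setdiff(cols, names(table))
  if (length(missing) > 0L) {
    stop_invalid("unknown library label(s): %s",
                 paste(sub("^rpkm\\.", "", missing), collapse = ", "))
  }
  means <- rowMeans(as.matrix(table[, cols, drop = FALSE]))
  table$gene_id[means >= min_rpkm]
}

#' Call differentially expressed genes for one donor/shRNA comparison
#'
#' Applies the secondary fold-change-score cutoff: |score| strictly greater
#' than 0.3 for Sh3 comparisons and 0.1 for Sh5 comparisons (the weaker
#' knockdown gets the lower cutoff).
#'
#' @param table Expression data frame.
#' @param shrna `"Sh3"` or `"Sh5"`.
#' @param donor Donor label (e.g. `"Donor1"`).
#' @param genes Optional gene-id restriction (typically the output of
#'   [filter_expressed()]).
#' @param cutoffs Named numeric vector of per-shRNA cutoffs.
#' @return Character vector of called gene ids.
#' @export
call_degs <- function(table, shrna, donor, genes = NULL,
                      cutoffs = default_gfold_cutoffs) {
  if (!shrna %in% names(cutoffs)) {
    stop_invalid("unknown shRNA label '%s' (expected one of: %s)", shrna,
                 paste(names(cutoffs), collapse = ", "))
  }
  col <- paste0("gfold.", donor, "_", shrna)
  assert_columns(table, c("gene_id", col), "expression table")
  keep <- abs(table[[col]]) > cutoffs[[shrna]]
  called <- table$gene_id[keep]
  if (!is.null(genes)) called <- intersect(called, genes)
  called
}

#' Intersect per-donor DEG calls and annotate direction
#'
#' A gene is significantly changed only if it passes the cutoffs in every
#' donor. Direction is computed from the signs of its scores across the
#' passing comparisons: all positive = up, all negative = down, otherwise
#' discordant. Discordant genes are retained in the intersection (the
#' magnitude criterion is what is intersected) but are excluded from
#' directional splits.
#'
#' @param per_donor_calls Named list (donor label -> character vector of
#'   called gene ids); at least two donors.
#' @param table Expression data frame (used to look up score signs).
#' @param shrna shRNA label whose comparisons define the direction.
#' @return Data frame of class `deg_calls`: `gene_id`, `direction`
#'   (up/down/discordant), `comparisons_passed` (comma-separated).
#' @export
intersect_donors <- function(per_donor_calls, table, shrna = "Sh3") {
  if (length(per_donor_calls) < 2L) {
    stop_invalid("intersection requires calls from at least 2 donors")
  }
  donors <- names(per_donor_calls)
  common <- Reduce(intersect, per_donor_calls)
  cols <- paste0("gfold.", donors, "_", shrna)
  assert_columns(table, c("gene_id", cols), "expression table")
  idx <- match(common, table$gene_id)
  signs <- sign(as.matrix(table[idx, cols, drop = FALSE]))
  direction <- apply(signs, 1L, function(s) {
    if (all(s > 0)) "up" else if (all(s < 0)) "down" else "discordant"
  })
  out <- data.frame(
    gene_id = common,
    direction = if (length(common)) unname(direction) else character(0),
    comparisons_passed = if (length(common)) {
      paste(paste0(donors, "_", shrna), collapse = ",")
    } else character(0),
    stringsAsFactors = FALSE)
  class(out) <- c("deg_calls", class(out))
  out
}

#' Split DEG calls by direction
#'
#' Partitions non-discordant calls into up- and down-regulated sets;
#' discordant genes appear in neither.
#'
#' @param calls Output of [intersect_donors()].
#' @return A list with character vectors `up` and `down`.
#' @export
split_by_direction <- function(calls) {
  list(up = calls$gene_id[calls$direction == "up"],
       down = calls$gene_id[calls$direction == "down"])
}

#' Run the full DEG filtering stage
#'
#' Convenience wrapper: expression filter per comparison, fold-change call
#' per donor, intersection across donors, directional split.
#'
#' @param table Expression data frame.
#' @param donors Donor labels (default `c("Donor1", "Donor4")`).
#' @param shrna shRNA label to analyse (default `"Sh3"`).
#' @param min_rpkm Expression cutoff.
#' @param rpkm_rule `"all_libraries"` (average control and knockdown; the
#'   rule used for DEG calling) or `"control_only"` (NTC libraries only,
#'   the variant used for ranked-list analyses).
#' @param cutoffs Per-shRNA fold-change-score cutoffs.
#' @return A list: `expressed` (gene ids passing the RPKM filter in every
#'   donor), `per_donor` (list of called sets), `calls` (intersected
#'   `deg_calls`), `up`, `down`.
#' @export
deg_pipeline <- function(table, donors = c("Donor1", "Donor4"),
                         shrna = "Sh3", min_rpkm = 2,
                         rpkm_rule = c("all_libraries", "control_only"),
                         cutoffs = default_gfold_cutoffs) {
  rpkm_rule <- match.arg(rpkm_rule)
  per_donor <- lapply(donors, function(d) {
    expressed <- filter_expressed(
      table, comparison_libraries(d, shrna, rpkm_rule), min_rpkm)
    call_degs(table, shrna, d, genes = expressed, cutoffs = cutoffs)
  })
  names(per_donor) <- donors
  expressed_all <- Reduce(intersect, lapply(donors, function(d) {
    filter_expressed(table, comparison_libraries(d, shrna, rpkm_rule),
                     min_rpkm)
  }))
  calls <- intersect_donors(per_donor, table, shrna)
  dirs <- split_by_direction(calls)
  list(expressed = expressed_all, per_donor = per_donor, calls = calls,
       up = dirs$up, down = dirs$down)
}
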