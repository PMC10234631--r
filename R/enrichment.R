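## Enrichment module: resampling test for the overlap between a DEG set
## and a target gene set, with an exact hypergeometric oracle.
##
## Both sets are first restricted to a gene universe (all genes passing
## the expression filter, by default). The null resamples n1 genes
## uniformly without replacement from the N-gene universe and counts the
## overlap with the n2 marked target genes; the empirical p is the raw
## fraction of null draws with overlap >= the observed k.

#' Observed overlap counts after universe restriction
#'
#' @param deg_set,target_set Character vectors of gene ids.
#' @param universe Non-empty character vector: the expressed-gene universe.
#' @return A list with `N`, `n1`, `n2`, `k`.
#' @examples
#' observed_overlap(c("A", "B"), c("B", "C"), c("A", "B", "C", "D"))
#' @export
observed_overlap <- function(deg_set, target_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop_invalid("universe must be non-empty")
  deg <- intersect(unique(deg_set), universe)
  target <- intersect(unique(target_set), universe)
  list(N = length(universe), n1 = length(deg), n2 = length(target),
       k = length(intersect(deg, target)))
}

#' Resample the null distribution of the overlap
#'
#' Draws `R` samples of `n1` genes without replacement from a universe of
#' `N` genes containing `n2` marked genes, and records each draw's overlap
#' with the marked set.
#'
#' @param N,n1,n2 Universe, sample and target-set sizes (`n1, n2 <= N`).
#' @param R Number of resampling draws (the study-scale default is
#'   100,000).
#' @param seed Integer seed.
#' @return Integer vector of length `R` of null overlap counts.
#' @export
resample_null <- function(N, n1, n2, R = 100000L, seed = 1L) {
  if (n1 > N) stop_invalid("n1 (%d) exceeds universe size N (%d)", n1, N)
  if (n2 > N) stop_invalid("n2 (%d) exceeds universe size N (%d)", n2, N)
  if (R < 1L) stop_invalid("R must be >= 1")
  set.seed(as.integer(seed))
  ## marked genes are, wlog, the first n2 labels of the universe
  vapply(seq_len(R), function(i) sum(sample.int(N, n1) <= n2), integer(1))
}

#' Empirical upper-tail p-value from null counts
#'
#' The raw fraction of null draws with overlap `>= k`. A value of zero is
#' reported alongside its resolution floor `1/R` (attribute `floor` and the
#' `report` string `"< 1/R"`).
#'
#' @param null_counts Integer vector from [resample_null()].
#' @param k Observed overlap.
#' @return Numeric p in \[0, 1\] with attributes `report` (formatted
#'   string) and `floor` (`1/R`).
#' @export
empirical_p <- function(null_counts, k) {
  if (length(null_counts) == 0L) stop_invalid("null_counts must be non-empty")
  R <- length(null_counts)
  p <- sum(null_counts >= k) / R
  report <- if (p == 0) sprintf("< %g", 1 / R) else format(p)
  structure(p, report = report, floor = 1 / R)
}

#' Exact hypergeometric upper tail
#'
#' Closed-form oracle for the resampling null: the probability that the
#' overlap between a uniform `n1`-gene draw and the `n2` marked genes is
#' `>= k`. Computed with the hypergeometric distribution function.
#'
#' @param N,n1,n2,k Counts as in [observed_overlap()].
#' @return Upper-tail probability.
#' @examples
#' hypergeom_tail(10, 4, 5, 4) # 1/42
#' @export
hypergeom_tail <- function(N, n1, n2, k) {
  if (N < 0 || n1 < 0 || n2 < 0 || n1 > N || n2 > N) {
    stop_invalid("invalid counts: need 0 <= n1, n2 <= N")
  }
  if (k <= 0) return(1)
  if (k > min(n1, n2)) return(0)
  phyper(k - 1, n2, N - n2, n1, lower.tail = FALSE)
}

#' Mode of a null-count histogram
#'
#' @param null_counts Integer vector of null overlap counts.
#' @return The most frequent overlap value (smallest, on ties).
#' @export
null_mode <- function(null_counts) {
  tab <- tabulate(null_counts + 1L)
  which.max(tab) - 1L
}

#' Run the full overlap-enrichment test
#'
#' Restricts both sets to the universe, resamples the null, and reports
#' the observed overlap, the null histogram and mode, the raw empirical p,
#' and the exact hypergeometric upper-tail probability.
#'
#' @inheritParams observed_overlap
#' @inheritParams resample_null
#' @return An object of class `enrichment_result`: a list with fields `N`,
#'   `n1`, `n2`, `k`, `R`, `seed`, `null_counts` (named histogram),
#'   `null_mode`, `empirical_p`, `empirical_p_report`, `exact_p`.
#' @export
enrich_test <- function(deg_set, target_set, universe, R = 100000L,
                        seed = 1L) {
  obs <- observed_overlap(deg_set, target_set, universe)
  draws <- resample_null(obs$N, obs$n1, obs$n2, R = R, seed = seed)
  p <- empirical_p(draws, obs$k)
  hist <- table(factor(draws, levels = 0:min(obs$n1, obs$n2)))
  out <- list(N = obs$N, n1 = obs$n1, n2 = obs$n2, k = obs$k,
              R = as.integer(R), seed = as.integer(seed),
              null_counts = hist,
              null_mode = null_mode(draws),
              empirical_p = as.numeric(p),
              empirical_p_report = attr(p, "report"),
              exact_p = hypergeom_tail(obs$N, obs$n1, obs$n2, obs$k))
  class(out) <- "enrichment_result"
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "overlap enrichment: N=%d n1=%d n2=%d k=%d | null mode %d | empirical p %s (R=%d) | exact p %.3g\n",
    x$N, x$n1, x$n2, x$k, x$null_mode, x$empirical_p_report, x$R,
    x$exact_p))
  invisible(x)
}

#' Directional enrichment: up/down DEGs against pathogenic/protective sets
#'
#' Runs the overlap test for the four directional contrasts:
#' up x pathogenic, down x protective (the biologically expected pairings
#' under a protective-regulator model) and the two flipped contrasts.
#'
#' @param up_set,down_set Directional DEG sets.
#' @param pathogenic_set,protective_set MS gene sets.
#' @param universe Expressed-gene universe.
#' @param R,seed Passed to [enrich_test()]; each contrast gets a distinct
#'   derived seed.
#' @return Named list of four `enrichment_result`s:
#'   `up_pathogenic`, `down_protective`, `up_protective`,
#'   `down_pathogenic`.
#' @export
directional_enrichment <- function(up_set, down_set, pathogenic_set,
                                   protective_set, universe,
                                   R = 100000L, seed = 1L) {
  contrasts <- list(
    up_pathogenic = list(up_set, pathogenic_set),
    down_protective = list(down_set, protective_set),
    up_protective = list(up_set, protective_set),
    down_pathogenic = list(down_set, pathogenic_set))
  out <- lapply(seq_along(contrasts), function(i) {
    enrich_test(contrasts[[i]][[1]], contrasts[[i]][[2]], universe,
                R = R, seed = derive_seed(seed, 10L + i))
  })
  names(out) <- names(contrasts)
  out
}
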