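## Retention-compare module: select helicase-sensitive vs unaffected
## introns from a differential-splicing event table and compare
## splice-site strength and py-tract composition between them.

#' Partition splicing events by significance and direction
#'
#' Events with `mv_dpsi >= cutoff` (minimum |dPSI| at 95% confidence;
#' inclusive comparison) are significant: `more_retained` when `dpsi > 0`,
#' `less_retained` when `dpsi < 0`; everything else is `unchanged`.
#'
#' @param events Data frame with columns `event_id`, `dpsi`, `mv_dpsi`.
#' @param cutoff MV|dPSI| significance cutoff (default 0.15).
#' @return The input with an added `class` column.
#' @export
select_events <- function(events, cutoff = 0.15) {
  assert_columns(events, c("event_id", "dpsi", "mv_dpsi"), "event table")
  sig <- events$mv_dpsi >= cutoff
  cls <- rep("unchanged", nrow(events))
  cls[sig & events$dpsi > 0] <- "more_retained"
  cls[sig & events$dpsi < 0] <- "less_retained"
  events$class <- cls
  events
}

#' Sample a control set of unaffected events
#'
#' Seeded uniform sample without replacement of `n` event ids from the
#' unchanged set; if fewer than `n` are available, all are taken with a
#' warning.
#'
#' @param unchanged Character vector of unchanged event ids (or a data
#'   frame with an `event_id` column).
#' @param n Control-set size (default 500, the study-scale choice).
#' @param seed Integer seed.
#' @return Character vector of sampled event ids.
#' @export
sample_unaffected <- function(unchanged, n = 500L, seed = 1L) {
  ids <- if (is.data.frame(unchanged)) unchanged$event_id else unchanged
  if (length(ids) <= n) {
    if (length(ids) < n) {
      warning(sprintf("only %d unchanged events available (< n = %d); taking all",
                      length(ids), n))
    }
    return(ids)
  }
  set.seed(as.integer(seed))
  sample(ids, n)
}

#' Remove score outliers with a calibrated median/MAD rule
#'
#' A robust stand-in for regression-based outlier removal at nominal false
#' removal rate `q`: values outside `median +/- k * MAD` are removed, with
#' `k = qnorm(1 - q/2)` so that on Gaussian data the expected fraction
#' removed is approximately `q` (MAD uses the usual 1.4826 consistency
#' constant). With fewer than 5 values nothing is removed.
#'
#' @param scores Numeric vector.
#' @param q Nominal two-sided false-removal rate (default 0.005, i.e.
#'   Q = 0.5%).
#' @return A list with `scores` (kept values), `removed` (values removed)
#'   and `n_removed`.
#' @export
remove_score_outliers <- function(scores, q = 0.005) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 5L) {
    warning("fewer than 5 values; no outlier removal performed")
    return(list(scores = scores, removed = numeric(0), n_removed = 0L))
  }
  med <- median(scores)
  s <- mad(scores)
  k <- qnorm(1 - q / 2)
  keep <- abs(scores - med) <= k * s
  list(scores = scores[keep], removed = scores[!keep],
       n_removed = sum(!keep))
}

#' Compare site-strength scores between two groups
#'
#' Two-sided two-sample rank-sum (Mann-Whitney) test: exact for small
#' tie-free samples, normal approximation with tie correction otherwise
#' (the default behaviour of [stats::wilcox.test()]).
#'
#' @param group_a,group_b Numeric score vectors (each of length >= 2).
#' @param a_label,b_label Group names for the report.
#' @return A list with `medians` (named), `n` (named), `p_value`,
#'   `statistic`.
#' @export
compare_scores <- function(group_a, group_b, a_label = "A", b_label = "B") {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop_invalid("each group needs >= 2 scores for a rank test")
  }
  wt <- suppressWarnings(wilcox.test(group_a, group_b,
                                     alternative = "two.sided"))
  list(medians = stats::setNames(c(median(group_a), median(group_b)),
                                 c(a_label, b_label)),
       n = stats::setNames(c(length(group_a), length(group_b)),
                           c(a_label, b_label)),
       p_value = wt$p.value,
       statistic = unname(wt$statistic))
}

per_intron_base_freq <- function(py_tracts) {
  m <- seq_matrix(py_tracts)
  data.frame(A = rowMeans(m == "A"), C = rowMeans(m == "C"),
             G = rowMeans(m == "G"), U = rowMeans(m == "U"))
}

#' Compare py-tract base composition between two intron groups
#'
#' For each intron, the mean frequency of each base over py-tract
#' positions -20..-3; per base, a two-sided rank-sum test between the
#' groups, plus group-level mean profiles for plotting. With any group of
#' fewer than 2 introns the report is emitted with tests suppressed.
#'
#' @param group_a,group_b Character vectors of 18-nt py tracts.
#' @param a_label,b_label Group names.
#' @return A list with `per_base` (data frame: base, mean per group,
#'   difference, `p_value`), `profiles` (named list of two 4 x 18 mean
#'   profiles), `n` (named group sizes).
#' @export
compare_composition <- function(group_a, group_b,
                                a_label = "retained",
                                b_label = "unaffected") {
  fa <- per_intron_base_freq(group_a)
  fb <- per_intron_base_freq(group_b)
  degenerate <- nrow(fa) < 2L || nrow(fb) < 2L
  if (degenerate) {
    warning("a group has fewer than 2 introns; rank tests suppressed")
  }
  per_base <- do.call(rbind, lapply(c("A", "C", "G", "U"), function(b) {
    p <- if (degenerate) NA_real_ else {
      suppressWarnings(wilcox.test(fa[[b]], fb[[b]])$p.value)
    }
    data.frame(base = b, mean_a = mean(fa[[b]]), mean_b = mean(fb[[b]]),
               difference = mean(fa[[b]]) - mean(fb[[b]]), p_value = p,
               stringsAsFactors = FALSE)
  }))
  names(per_base)[2:3] <- paste0("mean_", c(a_label, b_label))
  profiles <- list(
    unclass(position_frequency(group_a)),
    unclass(position_frequency(group_b)))
  names(profiles) <- c(a_label, b_label)
  list(per_base = per_base, profiles = profiles,
       n = stats::setNames(c(nrow(fa), nrow(fb)), c(a_label, b_label)))
}

#' Full retained-vs-unaffected comparison report
#'
#' Orchestrates the module: classify events, sample the unaffected
#' control set, optionally score 5'/3' splice sites (internal
#' position-weight-matrix score, or precomputed score columns such as
#' external maximum-entropy scores), remove score outliers, and run the
#' strength and composition comparisons.
#'
#' @param events Event table (see [select_events()]), with a `gene_id` or
#'   `event_id` join key matching `introns`.
#' @param introns Intron table with `gene_id`, `five_ss`, `three_ss`,
#'   `py_tract` columns ([gen_intron_set()] / [extract_splice_sites()]
#'   output). Events without a matching intron are excluded from sequence
#'   comparisons and counted in the report.
#' @param cutoff MV|dPSI| cutoff.
#' @param n_control Unaffected control-set size.
#' @param seed Integer seed (control sampling).
#' @param score_columns Optional length-2 character vector naming columns
#'   of `events` holding precomputed 5'SS and 3'SS strength scores; when
#'   `NULL`, a weight-matrix model is trained on the unchanged introns and
#'   used to score both groups.
#' @param outlier_q Outlier-removal rate (`NULL` disables removal).
#' @return A list of class `comparison_report`: group sizes, score
#'   comparisons (`five_ss`, `three_ss`), `composition`,
#'   `outliers_removed`, `missing_sequence` count.
#' @export
retention_report <- function(events, introns, cutoff = 0.15,
                             n_control = 500L, seed = 1L,
                             score_columns = NULL, outlier_q = 0.005) {
  ev <- select_events(events, cutoff = cutoff)
  retained <- ev[ev$class == "more_retained", , drop = FALSE]
  unchanged <- ev[ev$class == "unchanged", , drop = FALSE]
  control_ids <- sample_unaffected(unchanged$event_id, n = n_control,
                                   seed = seed)
  control <- unchanged[unchanged$event_id %in% control_ids, , drop = FALSE]

  key <- if ("gene_id" %in% names(ev) && "gene_id" %in% names(introns)) {
    "gene_id"
  } else "event_id"
  seq_of <- function(grp) {
    idx <- match(grp[[key]], introns[[key]])
    introns[idx[!is.na(idx)], , drop = FALSE]
  }
  ret_seq <- seq_of(retained)
  ctl_seq <- seq_of(control)
  missing_sequence <- (nrow(retained) - nrow(ret_seq)) +
    (nrow(control) - nrow(ctl_seq))

  ## the internal scorer is trained on the pooled groups so that both are
  ## scored in-sample; training on one group alone would inflate its own
  ## scores and fabricate a between-group difference
  scores <- function(grp, grp_seq, col, window_col) {
    if (!is.null(score_columns)) return(grp[[col]])
    model_env$model[[window_col]] <- model_env$model[[window_col]] %||%
      train_wmm(c(ret_seq[[window_col]], ctl_seq[[window_col]]))
    score_site(model_env$model[[window_col]], grp_seq[[window_col]])
  }
  model_env <- new.env()
  model_env$model <- list()

  clean <- function(x) {
    if (is.null(outlier_q)) {
      list(scores = x, n_removed = 0L)
    } else {
      remove_score_outliers(x, q = outlier_q)
    }
  }
  s5_ret <- clean(scores(retained, ret_seq, score_columns[1], "five_ss"))
  s5_ctl <- clean(scores(control, ctl_seq, score_columns[1], "five_ss"))
  s3_ret <- clean(scores(retained, ret_seq, score_columns[2], "three_ss"))
  s3_ctl <- clean(scores(control, ctl_seq, score_columns[2], "three_ss"))

  out <- list(
    n = c(more_retained = nrow(retained), less_retained =
            sum(ev$class == "less_retained"),
          unchanged = nrow(unchanged), control = nrow(control)),
    five_ss = compare_scores(s5_ret$scores, s5_ctl$scores,
                             "retained", "unaffected"),
    three_ss = compare_scores(s3_ret$scores, s3_ctl$scores,
                              "retained", "unaffected"),
    composition = compare_composition(ret_seq$py_tract, ctl_seq$py_tract),
    outliers_removed = s5_ret$n_removed + s5_ctl$n_removed +
      s3_ret$n_removed + s3_ctl$n_removed,
    missing_sequence = missing_sequence,
    cutoff = cutoff, seed = as.integer(seed))
  class(out) <- "comparison_report"
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(
    "retention comparison: %d retained vs %d unaffected controls (of %d unchanged)\n",
    x$n[["more_retained"]], x$n[["control"]], x$n[["unchanged"]]))
  cat(sprintf("  5'SS score p = %.3g | 3'SS score p = %.3g | %d outliers removed\n",
              x$five_ss$p_value, x$three_ss$p_value, x$outliers_removed))
  pb <- x$composition$per_base
  for (i in seq_len(nrow(pb))) {
    cat(sprintf("  %s: %.3f vs %.3f (p = %.3g)\n", pb$base[i], pb[i, 2],
                pb[i, 3], pb$p_value[i]))
  }
  invisible(x)
}
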