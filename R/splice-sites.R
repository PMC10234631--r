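## Splice-site module: strand-aware window extraction from genome +
## intervals, position-frequency/logo mathematics, py-tract
## classification, and a position-weight-matrix site-strength score.
##
## Window conventions (transcript orientation throughout):
##   5'SS: 9 nt  = exon -3..-1 + intron +1..+6
##   3'SS: 23 nt = intron -20..-1 + exon +1..+3, with the G of the 3'SS AG
##                 at intron position -1
##   py tract: 18 nt = intron -20..-3 = the first 18 characters of the 3'SS
## Output case convention: exon bases upper-case, intron bases lower-case.
## Genomic intervals are BED-style 0-based half-open on the forward strand.

PY_POSITIONS <- as.character(-20:-3)

#' Extract splice-site windows from a genome and intron intervals
#'
#' Minus-strand introns are reverse-complemented into transcript
#' orientation before windowing. Records whose windows would run off the
#' chromosome (fewer than 3 nt of exonic flank, or an intron shorter than
#' 20 nt) are skipped with a warning and reported in the `skipped`
#' attribute. Non-canonical junctions (5'SS not `gt`, or 3'SS not `ag`)
#' are flagged in the `canonical` column, not dropped.
#'
#' @param genome A [Biostrings::DNAStringSet] (names = chromosome names)
#'   or the path of a FASTA file.
#' @param introns Data frame with columns `chrom`, `start`, `end`,
#'   `strand` (0-based half-open), or a [GenomicRanges::GRanges] (1-based,
#'   converted internally). Extra columns (e.g. `gene_id`) are carried
#'   through.
#' @return Data frame with the input columns plus `five_ss`, `three_ss`,
#'   `py_tract`, `canonical`; attribute `skipped` holds the row indices of
#'   skipped records.
#' @export
extract_splice_sites <- function(genome, introns) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (methods::is(introns, "GRanges")) {
    introns <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(introns)),
      start = GenomicRanges::start(introns) - 1L,
      end = GenomicRanges::end(introns),
      strand = as.character(GenomicRanges::strand(introns)),
      stringsAsFactors = FALSE)
  }
  assert_columns(introns, c("chrom", "start", "end", "strand"),
                 "intron table")
  ## FASTA names may carry descriptions after whitespace
  names(genome) <- sub("\\s.*$", "", names(genome))

  n <- nrow(introns)
  five <- three <- rep(NA_character_, n)
  canonical <- rep(NA, n)
  skipped <- integer(0)
  for (i in seq_len(n)) {
    chrom <- introns$chrom[i]
    if (!chrom %in% names(genome)) {
      warning(sprintf("record %d: unknown chromosome '%s'; skipped", i,
                      chrom))
      skipped <- c(skipped, i)
      next
    }
    chr <- genome[[chrom]]
    s <- introns$start[i]   # 0-based
    e <- introns$end[i]
    len <- length(chr)
    if (s < 3L || e + 3L > len || e - s < 20L) {
      warning(sprintf(
        "record %d: interval [%d,%d) lacks flank or is too short on %s; skipped",
        i, s, e, chrom))
      skipped <- c(skipped, i)
      next
    }
    ## 1-based closed coordinates for subseq
    if (introns$strand[i] == "+") {
      e5 <- as.character(Biostrings::subseq(chr, s - 2L, s))
      i6 <- as.character(Biostrings::subseq(chr, s + 1L, s + 6L))
      i20 <- as.character(Biostrings::subseq(chr, e - 19L, e))
      e3 <- as.character(Biostrings::subseq(chr, e + 1L, e + 3L))
    } else {
      rc <- function(from, to) {
        as.character(Biostrings::reverseComplement(
          Biostrings::subseq(chr, from, to)))
      }
      e5 <- rc(e + 1L, e + 3L)
      i6 <- rc(e - 5L, e)
      i20 <- rc(s + 1L, s + 20L)
      e3 <- rc(s - 2L, s)
    }
    five[i] <- paste0(toupper(e5), tolower(i6))
    three[i] <- paste0(tolower(i20), toupper(e3))
    canonical[i] <- substr(tolower(i6), 1L, 2L) == "gt" &&
      substr(tolower(i20), 19L, 20L) == "ag"
  }
  out <- introns
  out$five_ss <- five
  out$three_ss <- three
  out$py_tract <- substr(three, 1L, 18L)
  out$canonical <- canonical
  if (length(skipped)) out <- out[-skipped, , drop = FALSE]
  attr(out, "skipped") <- skipped
  out
}

seq_matrix <- function(sequences) {
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop_invalid("all sequences must have the same length")
  }
  m <- do.call(rbind, strsplit(toupper(sequences), ""))
  m[m == "T"] <- "U"
  m
}

#' Position frequency matrix of an aligned sequence set
#'
#' Column-stochastic 4 x L matrix over \{A, C, G, U\} (T read as U).
#' `N` characters are excluded from the column denominators; sequences
#' with more than `max_n_frac` ambiguous positions are rejected.
#'
#' @param sequences Character vector of equal-length sequences.
#' @param positions Optional column labels; defaults to -20..-3 for
#'   18-mers (the py-tract convention) and 1..L otherwise.
#' @param max_n_frac Maximum tolerated fraction of `N`s per sequence.
#' @return An object of class `pfm`: the matrix, with attributes
#'   `n_sequences` and column names set to the position labels.
#' @examples
#' position_frequency(c("ACGU", "ACGA"))
#' @export
position_frequency <- function(sequences, positions = NULL,
                               max_n_frac = 0.1) {
  if (length(sequences) == 0L) stop_invalid("no sequences supplied")
  m <- seq_matrix(sequences)
  bad <- rowMeans(m == "N") > max_n_frac
  if (any(bad)) {
    warning(sprintf("%d sequence(s) with > %g%% N rejected", sum(bad),
                    100 * max_n_frac))
    m <- m[!bad, , drop = FALSE]
    if (nrow(m) == 0L) stop_invalid("no sequences left after N filtering")
  }
  unknown <- !(m %in% c("A", "C", "G", "U", "N"))
  if (any(unknown)) stop_invalid("non-ACGT/U/N character in input")
  L <- ncol(m)
  counts <- vapply(seq_len(L), function(j) {
    col <- m[, j]
    c(A = sum(col == "A"), C = sum(col == "C"),
      G = sum(col == "G"), U = sum(col == "U"))
  }, numeric(4))
  denom <- colSums(counts)
  if (any(denom == 0)) stop_invalid("a column contains only N characters")
  probs <- sweep(counts, 2L, denom, "/")
  if (is.null(positions)) {
    positions <- if (L == 18L) PY_POSITIONS else as.character(seq_len(L))
  }
  colnames(probs) <- positions
  structure(probs, n_sequences = nrow(m), class = c("pfm", "matrix"))
}

#' Per-gene average py-tract frequency matrix
#'
#' The per-gene logo matrix: the unweighted mean over a gene's introns of
#' each intron's per-position indicator columns, which (each intron counted
#' once) equals the pooled position frequency of its py tracts.
#'
#' @param sequences The gene's py-tract (or other equal-length) windows.
#' @param positions Optional position labels (see [position_frequency()]).
#' @return A `pfm`.
#' @export
gene_average_pfm <- function(sequences, positions = NULL) {
  position_frequency(sequences, positions = positions)
}

#' Information content and logo matrix of a PFM
#'
#' Per-position information content `IC = 2 + sum(p * log2(p))` bits (with
#' `0 * log 0 = 0` and no small-sample correction, so IC lies in
#' \[0, 2\]); logo letter heights are `p * IC`.
#'
#' @param pfm A [position_frequency()] matrix.
#' @return A list with `ic` (named numeric vector, bits) and `logo`
#'   (4 x L matrix of letter heights).
#' @export
information_content <- function(pfm) {
  plog <- function(p) ifelse(p > 0, p * log2(p), 0)
  ic <- 2 + colSums(plog(unclass(pfm)))
  logo <- sweep(unclass(pfm), 2L, ic, "*")
  list(ic = ic, logo = logo)
}

#' Classify a py tract (or py-tract set) as C-rich or U-rich
#'
#' Rule: mean C frequency across positions -20..-3 strictly greater than
#' mean U frequency = C-rich; strictly smaller = U-rich; tie = neither.
#' The paper-scale analyses never formalized a threshold, so the simple
#' mean comparison is the package's decided rule and is the single point
#' to change if another criterion is wanted.
#'
#' @param x A `pfm`, or a character vector of py-tract sequences (pooled
#'   into one PFM first).
#' @return A list with `label` (`"C-rich"`, `"U-rich"` or `"neither"`) and
#'   `mean_freq` (named numeric over A, C, G, U).
#' @export
classify_py_tract <- function(x) {
  pfm <- if (inherits(x, "pfm")) x else position_frequency(x)
  mean_freq <- rowMeans(unclass(pfm))
  label <- if (mean_freq[["C"]] > mean_freq[["U"]]) "C-rich"
           else if (mean_freq[["U"]] > mean_freq[["C"]]) "U-rich"
           else "neither"
  list(label = label, mean_freq = mean_freq)
}

#' Train a position-weight-matrix splice-site scorer
#'
#' A log-odds score table: `log2(p_adj / background)` per position and
#' base, where `p_adj = (n * p + pseudocount * background) / (n +
#' pseudocount)` shrinks the training frequencies toward the background.
#' This is the package's site-strength score; externally computed strength
#' scores (e.g. maximum-entropy scores) can be supplied downstream instead
#' via precomputed score columns.
#'
#' @param training_sites Aligned windows of one kind (9 nt for 5'SS, 23 nt
#'   for 3'SS).
#' @param background Base probabilities over A, C, G, U (default uniform).
#' @param pseudocount Non-negative shrinkage weight (default 0.5).
#' @param site_kind `"5ss"`, `"3ss"`, or `NULL` to infer from the window
#'   length.
#' @return An object of class `splice_score_model`: list with
#'   `score_table` (4 x L, bits), `background`, `pseudocount`,
#'   `site_kind`, `width`.
#' @export
train_wmm <- function(training_sites, background = rep(0.25, 4),
                      pseudocount = 0.5, site_kind = NULL) {
  if (length(training_sites) == 0L) stop_invalid("no training sites")
  width <- unique(nchar(training_sites))
  if (length(width) != 1L) stop_invalid("training windows differ in length")
  if (is.null(site_kind)) {
    site_kind <- if (width == 9L) "5ss" else if (width == 23L) "3ss"
                 else "custom"
  }
  background <- background / sum(background)
  names(background) <- c("A", "C", "G", "U")
  pfm <- position_frequency(training_sites,
                            positions = as.character(seq_len(width)))
  n <- attr(pfm, "n_sequences")
  p_adj <- (n * unclass(pfm) + pseudocount * background) / (n + pseudocount)
  score_table <- log2(sweep(p_adj, 1L, background, "/"))
  structure(list(score_table = score_table, background = background,
                 pseudocount = pseudocount, site_kind = site_kind,
                 width = width),
            class = "splice_score_model")
}

#' Score a splice-site window
#'
#' Sum of the model's per-position log-odds contributions, in bits.
#' Non-ACGT characters are skipped with a warning (or raise an error in
#' strict mode).
#'
#' @param model A [train_wmm()] model.
#' @param window Character vector of windows of the model's width.
#' @param strict Error on ambiguous characters instead of skipping them.
#' @return Numeric vector of scores.
#' @export
score_site <- function(model, window, strict = FALSE) {
  stopifnot(inherits(model, "splice_score_model"))
  if (any(nchar(window) != model$width)) {
    stop_invalid("window length must be %d for a %s model", model$width,
                 model$site_kind)
  }
  m <- seq_matrix(window)
  vapply(seq_len(nrow(m)), function(i) {
    total <- 0
    for (j in seq_len(ncol(m))) {
      b <- m[i, j]
      if (!b %in% c("A", "C", "G", "U")) {
        if (strict) stop_invalid("ambiguous base '%s' at position %d", b, j)
        warning(sprintf("ambiguous base at position %d skipped", j))
        next
      }
      total <- total + model$score_table[b, j]
    }
    total
  }, numeric(1))
}

#' Write intron windows as FASTA and intervals as BED
#'
#' @param introns Intron data frame (from [gen_intron_set()] or
#'   [extract_splice_sites()]).
#' @param genome Optional [Biostrings::DNAStringSet] genome to write.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the named vector of written paths.
#' @export
write_intron_files <- function(introns, genome = NULL, dir = ".",
                               prefix = "introns") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(bed = file.path(dir, paste0(prefix, ".bed")))
  bed <- data.frame(introns$chrom, introns$start, introns$end,
                    introns$gene_id %||% sprintf("intron%d", seq_len(nrow(introns))),
                    0L, introns$strand)
  write.table(bed, paths[["bed"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(genome)) {
    paths[["fasta"]] <- file.path(dir, paste0(prefix, "_genome.fa"))
    Biostrings::writeXStringSet(genome, paths[["fasta"]])
  }
  invisible(paths)
}

#' Read a BED file of intron intervals
#'
#' BED6 (or BED3/4/5), 0-based half-open, strand-aware.
#'
#' @param path BED file path.
#' @return Data frame with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (missing BED columns filled with defaults).
#' @export
read_intron_bed <- function(path) {
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(raw) <- cols[seq_len(min(ncol(raw), 6L))]
  if (is.null(raw$name)) raw$name <- sprintf("intron%d", seq_len(nrow(raw)))
  if (is.null(raw$score)) raw$score <- 0L
  if (is.null(raw$strand)) raw$strand <- "+"
  if (any(raw$start >= raw$end)) {
    stop_invalid("BED interval(s) with start >= end")
  }
  raw
}
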