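## Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a per-stage seed from a global seed
#'
#' Expands one user-facing seed into reproducible, distinct per-stage seeds,
#' kept inside the 32-bit integer range R requires.
#'
#' @param seed Integer global seed.
#' @param offset Integer stage offset (0, 1, 2, ...).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 7919 + offset * 104729) %% 2147483647)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_invalid("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", "))
  }
  invisible(df)
}

## Draw independent bases column-wise from a 4 x L probability profile.
## Returns a character vector of n sequences of length L (DNA alphabet).
draw_from_profile <- function(profile, n) {
  L <- ncol(profile)
  bases <- rownames(profile)
  bases[bases == "U"] <- "T"
  mat <- vapply(seq_len(L), function(j) {
    sample(bases, n, replace = TRUE, prob = profile[, j])
  }, character(n))
  if (n == 1L) mat <- matrix(mat, nrow = 1L)
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}

random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

## One random DNA string per requested length (single pooled draw).
random_dna_var <- function(lens) {
  big <- paste0(sample(c("A", "C", "G", "T"), sum(lens), replace = TRUE),
                collapse = "")
  ends <- cumsum(lens)
  substring(big, ends - lens + 1L, ends)
}

#' Write a data frame as tab-separated text
#'
#' All pipeline tables are TSV with a header row and no quoting, so that
#' artifacts round-trip byte-identically.
#'
#' @param df A data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a tab-separated table
#'
#' @param path Input path.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
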