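test_that("windows are extracted per the coordinate convention on a toy genome", {
  ## exon AAA | gt cgca ...spacer... ccctcc cctccc cctccc AG | TTT
  py <- "cctcccctcccctccccc"
  intron <- paste0("GTCGCA", "AAAAA", py, "AG")
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste0("GGGG", "AAA", intron, "TTT", "GGGG")))
  iv <- data.frame(chrom = "chr1", start = 7, end = 7 + nchar(intron),
                   strand = "+")
  rec <- extract_splice_sites(genome, iv)
  expect_identical(rec$five_ss, "AAAgtcgca")
  expect_identical(rec$three_ss, paste0(py, "ag", "TTT"))
  expect_identical(rec$py_tract, py)
  expect_true(rec$canonical)
})

test_that("minus-strand extraction is the strand involution of plus-strand", {
  cfg <- simulation_config(seed = 8)
  g <- gen_intron_set(cfg, "crich", n = 60)
  rec <- extract_splice_sites(g$genome, base_cols(g$introns))
  ## reverse-complement the whole genome and flip intervals/strands:
  ## transcript-orientation windows must be unchanged
  L <- Biostrings::width(g$genome)[1]
  rc_genome <- Biostrings::reverseComplement(g$genome)
  names(rc_genome) <- names(g$genome)
  flipped <- base_cols(g$introns)
  flipped$start <- L - g$introns$end
  flipped$end <- L - g$introns$start
  flipped$strand <- ifelse(g$introns$strand == "+", "-", "+")
  rec_rc <- extract_splice_sites(rc_genome, flipped)
  expect_identical(rec_rc$five_ss, rec$five_ss)
  expect_identical(rec_rc$three_ss, rec$three_ss)
})

test_that("generator and extractor agree after a FASTA/BED round trip", {
  cfg <- simulation_config(seed = 12)
  g <- gen_intron_set(cfg, "urich", n = 80)
  dir <- withr::local_tempdir()
  paths <- write_intron_files(g$introns, g$genome, dir = dir)
  bed <- read_intron_bed(paths[["bed"]])
  rec <- extract_splice_sites(paths[["fasta"]], bed)
  expect_identical(rec$five_ss, g$introns$five_ss)
  expect_identical(rec$three_ss, g$introns$three_ss)
  expect_identical(rec$py_tract, g$introns$py_tract)
  expect_true(all(rec$canonical))
})

test_that("out-of-bounds intervals are skipped with a warning, not fatal", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 30)))
  iv <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                   start = c(40, 1, 10), end = c(80, 25, 40),
                   strand = "+")
  w <- capture_warnings(rec <- extract_splice_sites(genome, iv))
  expect_length(w, 2)
  expect_match(w, "skipped", all = TRUE)
  expect_equal(nrow(rec), 1)
  expect_equal(attr(rec, "skipped"), c(2L, 3L))
})

test_that("position frequencies are column-stochastic and match sampling", {
  pfm <- position_frequency(c(strrep("C", 18), strrep("T", 18)))
  expect_true(all(abs(colSums(pfm) - 1) < 1e-9))
  expect_true(all(pfm["C", ] == 0.5 & pfm["U", ] == 0.5))
  expect_identical(colnames(pfm), as.character(-20:-3))

  single <- position_frequency("ACGT")
  expect_equal(unname(single[, 1]), c(1, 0, 0, 0))
  expect_equal(attr(single, "n_sequences"), 1)
  expect_error(position_frequency(character(0)), "no sequences")

  ## marginals of 1000 profile draws within 3 multinomial sd
  cfg <- simulation_config(seed = 15)
  g <- gen_intron_set(cfg, "crich", n = 1000)
  pfm2 <- position_frequency(g$introns$py_tract)
  prof <- pytract_profile("crich")
  sd3 <- 3 * sqrt(prof * (1 - prof) / 1000)
  expect_true(all(abs(unclass(pfm2) - prof) < sd3 + 1e-12))

  ## N handling: excluded from the denominator; N-heavy sequences rejected
  pfm3 <- expect_silent(position_frequency(c("ACGTACGTAC", "ACGTACGTAN")))
  expect_equal(unname(pfm3["C", 10]), 1)
  expect_warning(position_frequency(c("NNNNN", "ACGTA")), "rejected")
})

test_that("information content spans 0 to 2 bits with exact landmark values", {
  pfm <- structure(cbind(rep(0.25, 4), c(1, 0, 0, 0), c(0.5, 0.5, 0, 0)),
                   dimnames = list(c("A", "C", "G", "U"), 1:3),
                   n_sequences = 4L, class = c("pfm", "matrix"))
  ic <- information_content(pfm)
  expect_equal(unname(ic$ic), c(0, 2, 1))
  expect_equal(unname(ic$logo["A", 2]), 2)   # letter height = p * IC
  expect_true(all(ic$ic >= 0 & ic$ic <= 2))
})

test_that("py-tract classification compares mean C and U frequencies", {
  expect_identical(classify_py_tract(strrep("c", 18))$label, "C-rich")
  expect_identical(classify_py_tract(strrep("t", 18))$label, "U-rich")
  tie <- c(strrep("C", 18), strrep("T", 18))
  expect_identical(classify_py_tract(tie)$label, "neither")
  ## per-intron C-rich rate under the C-rich profile matches the exact
  ## multinomial enumeration P(#C > #U | n = 18, pC = 0.5, pU = 0.2)
  p0 <- 0
  for (nc in 0:18) {
    for (nu in 0:(18 - nc)) {
      if (nc > nu) {
        p0 <- p0 + dmultinom(c(nc, nu, 18 - nc - nu),
                             prob = c(0.5, 0.2, 0.3))
      }
    }
  }
  hits <- unlist(lapply(1:5, function(s) {
    g <- gen_intron_set(simulation_config(seed = s), "crich", n = 200)
    vapply(g$introns$py_tract,
           function(x) classify_py_tract(x)$label,
           character(1)) == "C-rich"
  }))
  sd3 <- 3 * sqrt(p0 * (1 - p0) / length(hits))
  expect_lt(abs(mean(hits) - p0), sd3)
})

test_that("weight-matrix scorer has the exact log-odds landmarks", {
  consensus <- strrep("GTAAGTCTT", 1)  # arbitrary 9-mer
  m0 <- train_wmm(rep(consensus, 5), pseudocount = 0)
  ## all-consensus training, uniform background: 2 bits per position
  expect_equal(unname(score_site(m0, consensus)), 18, tolerance = 1e-12)

  ## background equal to training frequencies: all scores zero
  sites <- c("AAAA", "CCCC", "GGGG", "TTTT")
  m1 <- train_wmm(sites, background = rep(0.25, 4), pseudocount = 0)
  expect_true(all(abs(m1$score_table) < 1e-12))

  ## additivity against brute force
  set.seed(61)
  train <- random_dna(50, 9)
  m2 <- train_wmm(train)
  w <- random_dna(5, 9)
  brute <- vapply(w, function(s) {
    b <- chartr("T", "U", strsplit(s, "")[[1]])
    sum(vapply(seq_along(b), function(j) m2$score_table[b[j], j],
               numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
  expect_equal(unname(score_site(m2, w)), brute)

  expect_error(score_site(m2, "ACGT"), "length")
  expect_warning(s <- score_site(m2, "ACGTNACGT"), "skipped")
  expect_error(score_site(m2, "ACGTNACGT", strict = TRUE), "ambiguous")
})

test_that("sites drawn from the trained profile outscore background sequences", {
  cfg <- simulation_config(seed = 18)
  g <- gen_intron_set(cfg, "crich", n = 1000)
  train <- g$introns$three_ss[1:500]
  held_out <- g$introns$three_ss[501:1000]
  model <- train_wmm(train)
  set.seed(19)
  background <- random_dna(500, 23)
  wt <- wilcox.test(score_site(model, held_out),
                    score_site(model, background),
                    alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})
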