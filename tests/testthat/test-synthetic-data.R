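test_that("config validation rejects invalid parameters", {
  expect_error(simulation_config(n_genes = 0), "count >= 1")
  expect_error(simulation_config(deg_fraction = 1.5), "\\[0, 1\\]")
  bad_prof <- pytract_profile("crich")
  bad_prof[1, 1] <- 0.9
  expect_error(simulation_config(pytract_profile_crich = bad_prof),
               "sum to 1")
})

test_that("generators are deterministic given the config", {
  cfg <- simulation_config(seed = 11, n_genes = 200, n_ms_genes = 50,
                           n_introns = 40)
  expect_identical(gen_expression_table(cfg), gen_expression_table(cfg))
  expect_identical(gen_ms_pair_table(cfg), gen_ms_pair_table(cfg))
  g1 <- gen_intron_set(cfg, "crich")
  g2 <- gen_intron_set(cfg, "crich")
  expect_identical(g1$introns, g2$introns)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(gen_retention_events(g1$introns, cfg),
                   gen_retention_events(g2$introns, cfg))
})

test_that("expression generator spikes the configured DEG structure", {
  ## no spiked effect: no truth labels, all scores small
  cfg0 <- simulation_config(seed = 3, n_genes = 500, deg_fraction = 0)
  e0 <- gen_expression_table(cfg0)
  expect_false(any(e0$truth$is_deg))
  gf <- as.matrix(e0$table[, grep("^gfold\\.", names(e0$table))])
  expect_lt(max(abs(gf)), 0.3)

  ## DEG count is binomial: 10000 * 0.05 within 3 sd
  cfg <- simulation_config(seed = 5, n_genes = 10000, deg_fraction = 0.05)
  e <- gen_expression_table(cfg)
  sd3 <- 3 * sqrt(10000 * 0.05 * 0.95)
  expect_lt(abs(sum(e$truth$is_deg) - 500), sd3)
  ## spiked genes carry |score| >= deg_effect in every comparison
  deg_rows <- e$table[e$truth$is_deg, grep("^gfold\\.", names(e$table))]
  expect_true(all(abs(as.matrix(deg_rows)) >= cfg$deg_effect))
})

test_that("MS pair generator respects sign structure and missingness", {
  cfg_all_missing <- simulation_config(seed = 2, n_ms_genes = 50,
                                       frac_missing_nes = 1)
  expect_true(all(is.na(gen_ms_pair_table(cfg_all_missing)$table$nes)))

  cfg_all_path <- simulation_config(seed = 2, n_ms_genes = 50,
                                    frac_pathogenic = 1,
                                    frac_missing_nes = 0)
  p <- gen_ms_pair_table(cfg_all_path)$table
  expect_true(all(p$nes < 0))
  expect_true(all(p$odds_ratio > 1))

  cfg <- simulation_config(seed = 9, n_ms_genes = 500,
                           frac_pathogenic = 0.5, frac_missing_nes = 0)
  tab <- gen_ms_pair_table(cfg)$table
  sd3 <- 3 * sqrt(500 * 0.25)
  expect_lt(abs(sum(tab$nes < 0) - 250), sd3)
})

test_that("intron generator enforces splice-site anatomy and profile marginals", {
  cfg <- simulation_config(seed = 4)
  all_c <- pytract_profile("crich")
  all_c[] <- 0; all_c["C", ] <- 1
  g <- gen_intron_set(cfg, all_c, n = 20)
  expect_true(all(g$introns$py_tract == strrep("c", 18)))
  ## 3'SS positions -2,-1 are a,g; 5'SS intron starts gt
  expect_true(all(substr(g$introns$three_ss, 19, 20) == "ag"))
  expect_true(all(substr(g$introns$five_ss, 4, 5) == "gt"))

  g2 <- gen_intron_set(cfg, "crich", n = 1000)
  pooled_c <- mean(strsplit(paste(g2$introns$py_tract, collapse = ""),
                            "")[[1]] == "c")
  sd3 <- 3 * sqrt(0.5 * 0.5 / (1000 * 18))
  expect_lt(abs(pooled_c - 0.5), sd3)
})

test_that("retention generator links retention to C content as configured", {
  cfg <- simulation_config(seed = 6, n_introns = 400)
  g <- gen_intron_set(cfg, "crich")

  ## extreme slope: retained set is almost exclusively high-C introns
  cfg_hi <- simulation_config(seed = 6, n_introns = 400,
                              retention_slope = 80,
                              retention_intercept = -44)
  ev_hi <- gen_retention_events(g$introns, cfg_hi)
  ret <- ev_hi$truth$is_retained
  expect_gte(min(ev_hi$truth$c_fraction[ret]), 0.5)
  expect_gt(mean(ev_hi$truth$c_fraction[ret]),
            mean(ev_hi$truth$c_fraction[!ret]))

  ## slope 0: retention independent of composition; association test
  ## non-significant at alpha = 0.01 in >= 95% of seeded runs
  sig <- vapply(1:40, function(s) {
    cfg0 <- simulation_config(seed = s, n_introns = 300,
                              retention_slope = 0,
                              retention_intercept = 0)
    gs <- gen_intron_set(cfg0, "crich")
    ev <- gen_retention_events(gs$introns, cfg0)
    hi <- ev$truth$c_fraction > median(ev$truth$c_fraction)
    suppressWarnings(
      chisq.test(table(hi, ev$truth$is_retained))$p.value) < 0.01
  }, logical(1))
  expect_gte(mean(!sig), 0.95)

  ## event table invariants: retained => dpsi > 0 & mv >= 0.15
  ev <- gen_retention_events(g$introns, cfg)
  r <- ev$truth$is_retained
  expect_true(all(ev$events$dpsi[r] > 0))
  expect_true(all(ev$events$mv_dpsi[r] >= 0.15))
  expect_true(all(ev$events$mv_dpsi[!r] < 0.15))
})

test_that("synthetic pair catalog has the documented aggregate structure", {
  cat <- synthetic_ms_pair_catalog()
  expect_identical(cat, synthetic_ms_pair_catalog())
  expect_equal(length(unique(cat$gene_id)), 558)
  expect_equal(sum(!is.na(cat$nes)), 539)
  expect_true(all(cat$odds_ratio > 0))
})
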