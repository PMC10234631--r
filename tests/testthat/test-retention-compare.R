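test_that("event selection applies the inclusive MV|dPSI| cutoff", {
  ev <- data.frame(event_id = paste0("e", 1:4),
                   dpsi = c(10, -5, 3, 0.5),
                   mv_dpsi = c(0.14, 0.2, 0.15, 0.0))
  sel <- select_events(ev)
  expect_identical(sel$class, c("unchanged", "less_retained",
                                "more_retained", "unchanged"))

  ## generator round trip: partition equals truth labels
  cfg <- simulation_config(seed = 23, n_introns = 300)
  g <- gen_intron_set(cfg, "crich")
  gen <- gen_retention_events(g$introns, cfg)
  sel2 <- select_events(gen$events)
  expect_identical(sel2$class == "more_retained", gen$truth$is_retained)

  ## classification is stable under row permutation
  perm <- sample(nrow(gen$events))
  sel3 <- select_events(gen$events[perm, ])
  expect_identical(sel3$class, sel2$class[perm])
})

test_that("control sampling is seeded, uniform, and degenerate-safe", {
  ids <- sprintf("e%03d", 1:100)
  expect_setequal(sample_unaffected(ids, n = 100, seed = 1), ids)
  expect_warning(all_of_them <- sample_unaffected(ids[1:10], n = 20),
                 "taking all")
  expect_identical(all_of_them, ids[1:10])
  expect_identical(sample_unaffected(ids, n = 30, seed = 5),
                   sample_unaffected(ids, n = 30, seed = 5))

  ## per-element inclusion rate n/|U| across seeds (binomial tolerance)
  counts <- integer(100)
  n_runs <- 400
  for (s in seq_len(n_runs)) {
    picked <- sample_unaffected(ids, n = 50, seed = s)
    counts[match(picked, ids)] <- counts[match(picked, ids)] + 1L
  }
  rate <- counts / n_runs
  sd3 <- 3 * sqrt(0.5 * 0.5 / n_runs)
  expect_gte(mean(abs(rate - 0.5) < sd3), 0.99)
})

test_that("outlier removal is calibrated to its nominal rate", {
  expect_warning(r0 <- remove_score_outliers(c(1, 2)), "fewer than 5")
  expect_equal(r0$n_removed, 0)

  same <- rep(3.3, 20)
  expect_equal(remove_score_outliers(same)$n_removed, 0)

  one_out <- c(rnorm(99), 50 * mad(rnorm(99)) + 100)
  r1 <- remove_score_outliers(one_out)
  expect_equal(r1$n_removed, 1)
  expect_equal(r1$removed, one_out[100])

  ## Gaussian calibration: removal fraction ~ q within 3 binomial sd
  set.seed(71)
  x <- rnorm(10000)
  q <- 0.005
  frac <- remove_score_outliers(x, q = q)$n_removed / 10000
  expect_lt(abs(frac - q), 3 * sqrt(q * (1 - q) / 10000) + 0.002)
})

test_that("rank-sum score comparison has exact small-sample behavior", {
  same <- compare_scores(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  sep <- compare_scores(c(1, 2, 3), c(4, 5, 6))
  ## enumeration over C(6,3) = 20 rank assignments: 2/20 as or more extreme
  expect_equal(sep$p_value, 0.1)

  set.seed(81)
  a <- rnorm(200) + 10
  b <- rnorm(200)
  shift <- compare_scores(a, b)
  expect_lt(shift$p_value, 1e-6)
  expect_equal(unname(shift$medians), c(median(a), median(b)))
  expect_error(compare_scores(1, c(1, 2)), ">= 2")
})

test_that("composition comparison detects planted profile differences", {
  cfg <- simulation_config(seed = 25)
  a <- gen_intron_set(cfg, "crich", n = 400)$introns$py_tract
  b <- gen_intron_set(simulation_config(seed = 26), "urich",
                      n = 500)$introns$py_tract
  cmp <- compare_composition(a, b)
  pb <- cmp$per_base
  expect_gt(pb$difference[pb$base == "C"], 0)
  expect_lt(pb$difference[pb$base == "U"], 0)
  expect_lt(pb$p_value[pb$base == "C"], 0.01)
  expect_lt(pb$p_value[pb$base == "U"], 0.01)
  expect_equal(unname(cmp$n), c(400, 500))

  ## identical profiles: p-values roughly uniform (KS over seeds)
  ps <- vapply(1:60, function(s) {
    x <- gen_intron_set(simulation_config(seed = 100 + s), "crich",
                        n = 60)$introns$py_tract
    composition_null <- compare_composition(x[1:30], x[31:60])
    composition_null$per_base$p_value[2]
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)

  ## degenerate single-sequence group: report emitted, tests suppressed
  expect_warning(deg <- compare_composition(a[1], b[1:5]), "suppressed")
  expect_true(all(is.na(deg$per_base$p_value)))
})

test_that("retention_report composes the module end to end", {
  cfg <- simulation_config(seed = 27, n_introns = 500)
  g <- gen_intron_set(cfg, "crich")
  ev <- gen_retention_events(g$introns, cfg)
  rep <- retention_report(ev$events, g$introns, n_control = 150, seed = 5)
  expect_s3_class(rep, "comparison_report")
  expect_equal(unname(rep$n[["control"]]), 150)
  expect_equal(rep$missing_sequence, 0)
  ## planted association shows up in the composition comparison
  pb <- rep$composition$per_base
  expect_lt(pb$p_value[pb$base == "C"], 0.01)
  expect_gt(pb$difference[pb$base == "C"], 0)

  ## precomputed score columns bypass the internal scorer
  ev2 <- ev$events
  set.seed(28)
  ev2$maxent5 <- rnorm(nrow(ev2), 8, 1)
  ev2$maxent3 <- rnorm(nrow(ev2), 9, 1)
  rep2 <- retention_report(ev2, g$introns, n_control = 150, seed = 5,
                           score_columns = c("maxent5", "maxent3"))
  expect_gt(rep2$five_ss$p_value, 0.001)  # no planted score difference
})
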