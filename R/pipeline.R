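## Pipeline module: orchestrates simulate -> deg -> classify -> enrich ->
## splice-sites -> retention with a single config, deterministic per-stage
## seeds, persisted intermediate artifacts, and a machine-readable report.

#' Default pipeline configuration
#'
#' Returns the full configuration list: stage toggles, every stage
#' parameter, and the output directory. A single global `seed` expands
#' deterministically into per-stage seeds via [derive_seed()], so one
#' number reproduces the whole run. Values supplied in `overrides`
#' (possibly nested) replace the defaults.
#'
#' @param seed Global integer seed.
#' @param outdir Output directory for all artifacts.
#' @param overrides Named list of overrides, e.g.
#'   `list(enrich = list(R = 1000))`.
#' @return A config list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = "foxsplice_out",
                            overrides = list()) {
  cfg <- list(
    seed = as.integer(seed),
    outdir = outdir,
    stages = list(simulate = TRUE, deg = TRUE, classify = TRUE,
                  enrich = TRUE, splice_sites = TRUE, retention = TRUE),
    simulate = list(n_genes = 10000L, n_ms_genes = 558L,
                    frac_pathogenic = 250 / 512, frac_missing_nes = 0.05,
                    n_donors = 2L, deg_fraction = 0.05, deg_effect = 1.0,
                    rpkm_log_mean = 1.0, rpkm_log_sd = 1.5,
                    n_introns = 900L, retention_slope = 8,
                    retention_intercept = -4.2, profile = "crich"),
    deg = list(min_rpkm = 2, shrna = "Sh3",
               rpkm_rule = "all_libraries",
               cutoffs = list(Sh3 = 0.3, Sh5 = 0.1)),
    classify = list(flip_nes_sign = FALSE),
    enrich = list(R = 100000L),
    retention = list(cutoff = 0.15, n_control = 500L,
                     outlier_q = 0.005))
  cfg <- modify_list_deep(cfg, overrides)
  class(cfg) <- "pipeline_config"
  cfg
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

#' Read a pipeline config from a YAML file
#'
#' The file holds overrides of [pipeline_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  seed <- raw$seed %||% 1L
  outdir <- raw$outdir %||% "foxsplice_out"
  raw$seed <- NULL
  raw$outdir <- NULL
  pipeline_config(seed = seed, outdir = outdir, overrides = raw)
}

#' Validate pipeline input files
#'
#' Schema checks per input kind; returns diagnostics (first offending rows
#' per rule) instead of failing.
#'
#' @param paths Named list/vector of file paths; recognised names are
#'   `expression`, `pairs`, `events`, `bed`.
#' @return Data frame of diagnostics: `input`, `rule`, `rows` (first 5
#'   offending row numbers, comma-separated). Zero rows = all checks
#'   passed.
#' @export
validate_inputs <- function(paths) {
  diags <- list()
  note <- function(input, rule, rows) {
    diags[[length(diags) + 1L]] <<- data.frame(
      input = input, rule = rule,
      rows = paste(head(rows, 5L), collapse = ","),
      stringsAsFactors = FALSE)
  }
  for (nm in names(paths)) {
    path <- paths[[nm]]
    if (!file.exists(path)) {
      note(nm, "file exists", NA)
      next
    }
    if (nm == "expression") {
      tab <- read_tsv(path)
      if (!"gene_id" %in% names(tab)) note(nm, "has gene_id column", NA)
      rc <- grep("^rpkm\\.", names(tab), value = TRUE)
      if (length(rc) == 0L) note(nm, "has rpkm.* columns", NA)
      for (col in rc) {
        bad <- which(tab[[col]] < 0)
        if (length(bad)) note(nm, sprintf("%s >= 0", col), bad)
      }
    } else if (nm == "pairs") {
      tab <- read_tsv(path)
      need <- c("snp_id", "gene_id", "odds_ratio", "nes")
      miss <- setdiff(need, names(tab))
      if (length(miss)) {
        note(nm, paste("has columns", paste(miss, collapse = ",")), NA)
      } else {
        bad <- which(!is.finite(tab$odds_ratio) | tab$odds_ratio <= 0)
        if (length(bad)) note(nm, "odds_ratio > 0", bad)
      }
    } else if (nm == "events") {
      tab <- read_tsv(path)
      need <- c("event_id", "dpsi", "mv_dpsi")
      miss <- setdiff(need, names(tab))
      if (length(miss)) {
        note(nm, paste("has columns", paste(miss, collapse = ",")), NA)
      } else {
        bad <- which(tab$mv_dpsi < 0)
        if (length(bad)) note(nm, "mv_dpsi >= 0", bad)
      }
    } else if (nm == "bed") {
      tab <- tryCatch(read_intron_bed(path), error = function(e) NULL)
      if (is.null(tab)) {
        raw <- read.delim(path, header = FALSE)
        bad <- which(raw[[2]] >= raw[[3]])
        note(nm, "start < end", bad)
      }
    }
  }
  if (length(diags) == 0L) {
    return(data.frame(input = character(0), rule = character(0),
                      rows = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, diags)
}

#' Run the pipeline end-to-end
#'
#' Executes the toggled stages on synthetic data generated from the
#' config, writing every intermediate artifact (TSV/FASTA/BED/JSON) under
#' `config$outdir`, and returns a run report whose counts are all
#' re-derivable from the persisted files. Identical configs produce
#' byte-identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list: `version`, `config` echo, per-stage
#'   record counts and results. Also written as `report.json` in the
#'   output directory.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    version = as.character(utils::packageVersion("foxsplice")),
    config = unclass(config), stages = list())
  st <- config$stages

  sim <- NULL
  if (st$simulate) {
    sc <- config$simulate
    simcfg <- simulation_config(
      seed = derive_seed(config$seed, 100L),
      n_genes = sc$n_genes, n_ms_genes = sc$n_ms_genes,
      frac_pathogenic = sc$frac_pathogenic,
      frac_missing_nes = sc$frac_missing_nes, n_donors = sc$n_donors,
      deg_fraction = sc$deg_fraction, deg_effect = sc$deg_effect,
      rpkm_log_mean = sc$rpkm_log_mean, rpkm_log_sd = sc$rpkm_log_sd,
      n_introns = sc$n_introns, retention_slope = sc$retention_slope,
      retention_intercept = sc$retention_intercept)
    expr <- gen_expression_table(simcfg)
    pairs <- gen_ms_pair_table(simcfg, gene_pool = expr$table$gene_id)
    intr <- gen_intron_set(simcfg, profile = sc$profile)
    evs <- gen_retention_events(intr$introns, simcfg)
    write_tsv(expr$table, file.path(outdir, "expression.tsv"))
    write_tsv(expr$truth, file.path(outdir, "expression_truth.tsv"))
    write_tsv(pairs$table, file.path(outdir, "ms_pairs.tsv"))
    write_tsv(pairs$truth, file.path(outdir, "ms_pairs_truth.tsv"))
    write_tsv(intr$introns, file.path(outdir, "introns.tsv"))
    write_intron_files(intr$introns, intr$genome, dir = outdir,
                       prefix = "introns")
    write_tsv(evs$events, file.path(outdir, "events.tsv"))
    write_tsv(evs$truth, file.path(outdir, "events_truth.tsv"))
    sim <- list(expr = expr, pairs = pairs, intr = intr, evs = evs)
    report$stages$simulate <- list(
      n_genes = nrow(expr$table), n_pairs = nrow(pairs$table),
      n_introns = nrow(intr$introns), n_events = nrow(evs$events))
  }
  if (is.null(sim)) {
    stop_invalid("run_pipeline currently requires the simulate stage (external inputs enter via the per-module functions)")
  }

  deg <- NULL
  if (st$deg) {
    dc <- config$deg
    deg <- deg_pipeline(sim$expr$table, shrna = dc$shrna,
                        min_rpkm = dc$min_rpkm, rpkm_rule = dc$rpkm_rule,
                        cutoffs = unlist(dc$cutoffs))
    write_tsv(deg$calls, file.path(outdir, "deg_calls.tsv"))
    writeLines(deg$expressed, file.path(outdir, "universe.txt"))
    report$stages$deg <- list(
      n_input = nrow(sim$expr$table),
      n_expressed = length(deg$expressed),
      per_donor = lapply(deg$per_donor, length),
      n_deg = nrow(deg$calls), n_up = length(deg$up),
      n_down = length(deg$down),
      n_discordant = sum(deg$calls$direction == "discordant"))
  }

  sets <- NULL
  if (st$classify) {
    classified <- build_pairs(sim$pairs$table,
                              flip_nes_sign = config$classify$flip_nes_sign)
    sets <- collapse_to_genes(classified)
    write_tsv(classified, file.path(outdir, "ms_pairs_classified.tsv"))
    report$stages$classify <- list(
      n_pairs = nrow(classified),
      n_classifiable = sets$n_pairs_classifiable,
      n_susceptibility = length(sets$susceptibility),
      n_pathogenic = length(sets$pathogenic),
      n_protective = length(sets$protective),
      n_conflicted = length(sets$conflicted))
  }

  if (st$enrich) {
    if (is.null(deg) || is.null(sets)) {
      stop_invalid("enrich stage requires the deg and classify stages")
    }
    res <- enrich_test(deg$calls$gene_id, sets$susceptibility,
                       deg$expressed, R = config$enrich$R,
                       seed = derive_seed(config$seed, 200L))
    dres <- directional_enrichment(deg$up, deg$down, sets$pathogenic,
                                   sets$protective, deg$expressed,
                                   R = config$enrich$R,
                                   seed = derive_seed(config$seed, 201L))
    enr <- c(list(susceptibility = res), dres)
    enr_tab <- do.call(rbind, lapply(names(enr), function(nm) {
      e <- enr[[nm]]
      data.frame(contrast = nm, N = e$N, n1 = e$n1, n2 = e$n2, k = e$k,
                 null_mode = e$null_mode, empirical_p = e$empirical_p,
                 exact_p = e$exact_p, R = e$R, stringsAsFactors = FALSE)
    }))
    write_tsv(enr_tab, file.path(outdir, "enrichment.tsv"))
    jsonlite::write_json(
      lapply(enr, function(e) {
        e$null_counts <- as.integer(e$null_counts)
        unclass(e)
      }),
      file.path(outdir, "enrichment.json"), auto_unbox = TRUE, digits = NA)
    report$stages$enrich <- enr_tab
  }

  extracted <- NULL
  if (st$splice_sites) {
    extracted <- extract_splice_sites(sim$intr$genome, sim$intr$introns[
      , c("gene_id", "intron_index", "chrom", "start", "end", "strand")])
    pfm <- position_frequency(extracted$py_tract)
    ic <- information_content(pfm)
    pycls <- classify_py_tract(pfm)
    write_tsv(cbind(base = rownames(pfm), as.data.frame(unclass(pfm))),
              file.path(outdir, "pytract_pfm.tsv"))
    report$stages$splice_sites <- list(
      n_extracted = nrow(extracted),
      n_skipped = length(attr(extracted, "skipped")),
      n_noncanonical = sum(!extracted$canonical),
      pytract_class = pycls$label,
      mean_freq = as.list(round(pycls$mean_freq, 4)),
      mean_ic_bits = mean(ic$ic))
  }

  if (st$retention) {
    rc <- config$retention
    introns_for_cmp <- if (!is.null(extracted)) extracted else
      sim$intr$introns
    rep_cmp <- retention_report(sim$evs$events, introns_for_cmp,
                                cutoff = rc$cutoff,
                                n_control = rc$n_control,
                                seed = derive_seed(config$seed, 300L),
                                outlier_q = rc$outlier_q)
    write_tsv(rep_cmp$composition$per_base,
              file.path(outdir, "composition.tsv"))
    report$stages$retention <- list(
      n = as.list(rep_cmp$n),
      five_ss_p = rep_cmp$five_ss$p_value,
      three_ss_p = rep_cmp$three_ss$p_value,
      outliers_removed = rep_cmp$outliers_removed,
      missing_sequence = rep_cmp$missing_sequence,
      per_base = rep_cmp$composition$per_base)
  }

  class(report) <- "run_report"
  jsonlite::write_json(prepare_report_json(report),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  report
}

prepare_report_json <- function(report) {
  r <- unclass(report)
  r$config$pytract_profile_crich <- NULL
  r$config$pytract_profile_urich <- NULL
  r
}

#' @export
print.run_report <- function(x, ...) {
  cat("foxsplice run report (version", x$version, ")\n")
  for (nm in names(x$stages)) {
    cat("-", nm, ":")
    s <- x$stages[[nm]]
    if (is.data.frame(s)) {
      cat("\n")
      print(s)
    } else {
      flat <- unlist(s)
      cat(" ", paste(names(flat), unname(flat), sep = "=",
                     collapse = " "), "\n")
    }
  }
  invisible(x)
}
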