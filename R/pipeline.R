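# End-to-end orchestration: simulate (or load) -> lane QC -> normalize ->
# differential expression (tumor-only and tumor/normal ratio) -> FDR ->
# per-probe cutoffs and greedy panel -> cross-platform ERG concordance.

#' Pipeline configuration
#'
#' @param simulate A [sim_params()] object describing the synthetic cohort,
#'   or `NULL` when reading files via `paths`.
#' @param paths Optional named list (`counts`, `probes`, `samples`, and
#'   optionally `qpcr`, `ihc`) of input CSVs; overrides `simulate`.
#' @param q_cutoff_tumor,q_cutoff_ratio Significance cutoffs on the rounded
#'   q-values of the tumor-only and tumor-vs-normal analyses (published
#'   values 0.075 and 0.085).
#' @param min_specificity Specificity floor for per-probe cutoffs.
#' @param tolerance Specificity tolerance for panel acceptance.
#' @param platform_rule Combination rule for cross-platform calls.
#' @param erg_count_cutoff Fixed transcript-count cutoff for the ERG status
#'   call on the count platform (published value 20; counts below it are
#'   ERG negative).
#' @param test,n_permutations,s0_quantile Differential-expression options.
#' @param background_mode,pseudocount Normalization options.
#' @param seed Master seed: seeds the simulation and the permutations.
#' @return A validated list of class `bcr_config`.
#' @export
pipeline_config <- function(simulate = sim_params(),
                            paths = NULL,
                            q_cutoff_tumor = 0.075,
                            q_cutoff_ratio = 0.085,
                            min_specificity = 0.70,
                            tolerance = 0,
                            platform_rule = "any_negative",
                            erg_count_cutoff = 20,
                            test = "sam",
                            n_permutations = 10000,
                            s0_quantile = 0.5,
                            background_mode = "subtract",
                            pseudocount = 1,
                            seed = 1L) {
  cfg <- list(simulate = simulate, paths = paths,
              q_cutoff_tumor = q_cutoff_tumor, q_cutoff_ratio = q_cutoff_ratio,
              min_specificity = min_specificity, tolerance = tolerance,
              platform_rule = platform_rule,
              erg_count_cutoff = erg_count_cutoff,
              test = test, n_permutations = n_permutations,
              s0_quantile = s0_quantile, background_mode = background_mode,
              pseudocount = pseudocount, seed = as.integer(seed))
  for (f in c("q_cutoff_tumor", "q_cutoff_ratio")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v >= 1)
      abort(sprintf("invalid config `%s`: must lie in (0, 1)", f),
            class = "bcrpanel_validation_error")
  }
  if (cfg$min_specificity < 0 || cfg$min_specificity > 1)
    abort("invalid config `min_specificity`: must lie in [0, 1]",
          class = "bcrpanel_validation_error")
  if (cfg$tolerance < 0)
    abort("invalid config `tolerance`: must be >= 0",
          class = "bcrpanel_validation_error")
  if (!is.null(cfg$paths)) {
    need <- c("counts", "probes", "samples")
    miss <- setdiff(need, names(cfg$paths))
    if (length(miss))
      abort(sprintf("invalid config `paths`: missing %s", paste(miss, collapse = ", ")),
            class = "bcrpanel_validation_error")
    gone <- unlist(cfg$paths)[!file.exists(unlist(cfg$paths))]
    if (length(gone))
      abort(sprintf("invalid config `paths`: file(s) not found: %s",
                    paste(gone, collapse = ", ")),
            class = "bcrpanel_validation_error")
  } else if (!inherits(cfg$simulate, "sim_params")) {
    abort("invalid config `simulate`: need sim_params() or `paths`",
          class = "bcrpanel_validation_error")
  }
  class(cfg) <- "bcr_config"
  cfg
}

pipeline_stage <- function(name, expr) {
  tryCatch(force(expr), error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
          class = "bcrpanel_stage_error", parent = e)
  })
}

#' Run the full discovery pipeline
#'
#' @param config A [pipeline_config()]; identical config and seed give an
#'   identical report.
#' @return A list of class `bcr_run_report` holding the cohort, lane QC,
#'   normalized counts, both differential-expression/FDR tables, the
#'   significant sets, per-probe rules, the greedy panel, platform calls,
#'   confusion summaries, the concordance object and provenance.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "bcr_config")) abort("run_pipeline: need a pipeline_config()")

  cohort <- pipeline_stage("input", {
    if (!is.null(config$paths)) {
      cp <- read_counts(config$paths$counts, config$paths$probes)
      structure(list(
        counts = cp$counts, probes = cp$probes,
        samples = read_sample_sheet(config$paths$samples),
        qpcr = if (!is.null(config$paths$qpcr)) read_csv_quiet(config$paths$qpcr),
        ihc = if (!is.null(config$paths$ihc)) read_csv_quiet(config$paths$ihc),
        params = NULL), class = "bcr_cohort")
    } else {
      prm <- config$simulate
      prm$seed <- config$seed
      simulate_cohort(prm)
    }
  })

  qc <- pipeline_stage("lane_qc",
    lane_qc(cohort$counts, cohort$probes, cohort$samples))
  norm <- pipeline_stage("normalize",
    normalize_counts(cohort$counts, cohort$probes,
                     background_mode = config$background_mode))

  de_tumor <- pipeline_stage("diffexp_tumor",
    run_differential(norm, cohort$probes, cohort$samples, mode = "tumor_only",
                     test = config$test,
                     n_permutations = config$n_permutations,
                     seed = config$seed, s0_quantile = config$s0_quantile,
                     pseudocount = config$pseudocount))
  de_ratio <- pipeline_stage("diffexp_ratio",
    run_differential(norm, cohort$probes, cohort$samples,
                     mode = "tumor_vs_normal", test = config$test,
                     n_permutations = config$n_permutations,
                     seed = config$seed + 1L, s0_quantile = config$s0_quantile,
                     pseudocount = config$pseudocount))

  fdr_tumor <- pipeline_stage("fdr_tumor", compute_fdr(de_tumor))
  fdr_ratio <- pipeline_stage("fdr_ratio", compute_fdr(de_ratio))
  sig_tumor <- filter_significant(fdr_tumor, config$q_cutoff_tumor)
  sig_ratio <- filter_significant(fdr_ratio, config$q_cutoff_ratio)

  ## per-probe rules and greedy panel on tumor normalized counts
  tum <- cohort$samples[cohort$samples$tissue == "tumor", , drop = FALSE]
  m <- counts_to_matrix(norm)[, tum$sample, drop = FALSE]
  outcomes <- tibble::tibble(patient = tum$patient, outcome = tum$outcome)
  candidates <- sig_tumor$table$probe
  panel <- NULL; rules <- NULL; panel_calls <- NULL
  if (length(candidates) >= 1L) {
    res <- pipeline_stage("panel", {
      rules <- purrr::map_dfr(candidates, function(pr) {
        dir <- fdr_tumor$direction[match(pr, fdr_tumor$probe)]
        select_cutoff(m[pr, ], outcomes$outcome, direction = dir,
                      min_specificity = config$min_specificity, probe = pr)
      })
      calls <- purrr::map(rules$probe, function(pr)
        binarize_counts(m[pr, ], rules[rules$probe == pr, ]))
      calls <- tibble::as_tibble(setNames(calls, rules$probe))
      calls <- dplyr::bind_cols(tibble::tibble(patient = tum$patient), calls)
      list(rules = rules, calls = calls,
           panel = build_panel(calls, outcomes, tolerance = config$tolerance))
    })
    rules <- res$rules; panel_calls <- res$calls; panel <- res$panel
  }

  ## cross-platform ERG status
  platforms <- pipeline_stage("platforms", {
    if (!"Pan.ERG" %in% rownames(m))
      abort("no Pan.ERG probe in the count matrix")
    erg_counts <- m["Pan.ERG", ]
    ns_status <- ifelse(is.na(erg_counts), NA_character_,
                        ifelse(erg_counts < config$erg_count_cutoff,
                               "negative", "positive"))
    plat <- tibble::tibble(patient = outcomes$patient, nanostring = ns_status)
    if (!is.null(cohort$qpcr)) {
      qp <- score_qpcr(cohort$qpcr)
      plat$qpcr <- qp$call[match(plat$patient, qp$patient)]
    }
    if (!is.null(cohort$ihc))
      plat$ihc <- cohort$ihc$call[match(plat$patient, cohort$ihc$patient)]
    plat
  })
  combined <- if (ncol(platforms) >= 3L)
    combine_calls(platforms, rule = config$platform_rule) else NULL
  concord <- if (ncol(platforms) >= 3L) platform_concordance(platforms) else NULL

  ## per-platform BCR prediction (ERG negative predicts recurrence)
  to_bcr_call <- function(status)
    ifelse(is.na(status), NA_character_,
           ifelse(status == "negative", "positive", "negative"))
  platform_confusion <- purrr::map_dfr(
    setdiff(names(platforms), "patient"), function(pl) {
      cs <- confusion_summary(to_bcr_call(platforms[[pl]]), outcomes$outcome)
      dplyr::bind_cols(tibble::tibble(platform = pl), cs)
    })
  if (!is.null(combined)) {
    cs <- confusion_summary(combined$call, outcomes$outcome)
    platform_confusion <- dplyr::bind_rows(
      platform_confusion,
      dplyr::bind_cols(tibble::tibble(platform = "combined"), cs))
  }

  out <- list(
    cohort = cohort, lane_qc = qc, normalized = norm,
    diffexp = list(tumor_only = de_tumor, tumor_vs_normal = de_ratio),
    fdr = list(tumor_only = fdr_tumor, tumor_vs_normal = fdr_ratio),
    significant = list(tumor_only = sig_tumor, tumor_vs_normal = sig_ratio),
    rules = rules, panel = panel, panel_calls = panel_calls,
    platform_calls = platforms, combined_calls = combined,
    platform_confusion = platform_confusion, concordance = concord,
    provenance = list(seed = config$seed,
                      version = as.character(utils::packageVersion("bcrpanel")),
                      config_hash = rlang::hash(config)),
    config = config)
  class(out) <- "bcr_run_report"
  out
}

#' @export
print.bcr_run_report <- function(x, ...) {
  cat(sprintf("<bcr_run_report> seed %d, %d samples, %d probes\n",
              x$provenance$seed, ncol(x$normalized) - 1L, nrow(x$normalized)))
  cat(sprintf("  lanes passing QC: %d / %d\n",
              sum(x$lane_qc$pass), nrow(x$lane_qc)))
  cat(sprintf("  significant (tumor only): %d probe(s) / %d gene(s): %s\n",
              length(x$significant$tumor_only$probes),
              length(x$significant$tumor_only$genes),
              paste(x$significant$tumor_only$genes, collapse = ", ")))
  cat(sprintf("  significant (tumor vs normal): %d probe(s) / %d gene(s)\n",
              length(x$significant$tumor_vs_normal$probes),
              length(x$significant$tumor_vs_normal$genes)))
  if (!is.null(x$panel)) print(x$panel)
  invisible(x)
}

#' Persist a run report as CSV tables plus a markdown summary
#'
#' Writes every intermediate table (lane QC, normalized counts, both FDR
#' tables, probe rules, panel audit and calls, platform calls and confusion
#' summaries) and renders `report.md` from those persisted tables only, so
#' regeneration is idempotent and every reported number is recomputable.
#'
#' @param report A `bcr_run_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "bcr_run_report"))
    abort("write_report: need a bcr_run_report")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- report$provenance$seed
  write_table(report$lane_qc, file.path(dir, "lane_qc.csv"), seed)
  write_table(report$normalized, file.path(dir, "normalized_counts.csv"), seed)
  write_table(report$fdr$tumor_only, file.path(dir, "fdr_tumor_only.csv"), seed)
  write_table(report$fdr$tumor_vs_normal,
              file.path(dir, "fdr_tumor_vs_normal.csv"), seed)
  if (!is.null(report$rules))
    write_table(report$rules, file.path(dir, "probe_rules.csv"), seed)
  if (!is.null(report$panel)) {
    write_table(report$panel$audit, file.path(dir, "panel_audit.csv"), seed)
    write_table(report$panel_calls, file.path(dir, "panel_calls.csv"), seed)
  }
  write_table(report$platform_calls, file.path(dir, "platform_calls.csv"), seed)
  write_table(report$platform_confusion,
              file.path(dir, "platform_confusion.csv"), seed)
  if (!is.null(report$concordance))
    write_table(report$concordance$pairwise,
                file.path(dir, "platform_concordance.csv"), seed)
  render_report_md(dir)
  invisible(dir)
}

# Renders report.md from the persisted CSVs only.
render_report_md <- function(dir) {
  need <- c("lane_qc.csv", "fdr_tumor_only.csv", "fdr_tumor_vs_normal.csv",
            "platform_confusion.csv")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      abort(sprintf("render_report_md: missing intermediate %s", f),
            class = "bcrpanel_io_error")
  qc <- read_csv_quiet(file.path(dir, "lane_qc.csv"))
  ft <- read_csv_quiet(file.path(dir, "fdr_tumor_only.csv"))
  fr <- read_csv_quiet(file.path(dir, "fdr_tumor_vs_normal.csv"))
  pc <- read_csv_quiet(file.path(dir, "platform_confusion.csv"))
  md_tab <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) signif(v, 4))
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
  }
  lines <- c(
    "# Recurrence biomarker discovery report", "",
    sprintf("Lanes passing QC: %d / %d", sum(qc$pass), nrow(qc)), "",
    "## Differential expression, tumor only (top 15 by rank)", "",
    md_tab(utils::head(ft[, c("probe", "p_value", "q_value", "expected_fp",
                              "direction")], 15)), "",
    "## Differential expression, tumor vs normal (top 15 by rank)", "",
    md_tab(utils::head(fr[, c("probe", "p_value", "q_value", "expected_fp",
                              "direction")], 15)), "",
    "## Platform performance for predicting recurrence", "",
    md_tab(pc[, c("platform", "tp", "fp", "tn", "fn",
                  "sensitivity_pct", "specificity_pct")]))
  if (file.exists(file.path(dir, "panel_audit.csv"))) {
    audit <- read_csv_quiet(file.path(dir, "panel_audit.csv"))
    lines <- c(lines, "", "## Panel construction audit trail", "", md_tab(audit))
  }
  writeLines(lines, file.path(dir, "report.md"))
  invisible(file.path(dir, "report.md"))
}
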