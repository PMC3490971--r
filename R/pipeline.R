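# End-to-end orchestration: config, the full scan pipeline, and the
# validation (correlation) report.

#' Pipeline configuration
#'
#' Either a list of real input paths (`vcf`, `panel`, `annotations`,
#' `health_db` = list of three paths) or a [simulation_config] — exactly
#' one of the two. Thresholds default to the scan's standard values:
#' Fst > 0.25, FDR < 0.05, allele-count cutoffs >= 1 and >= 6.
#'
#' @param inputs named list of input paths, or `NULL` in simulate mode.
#' @param simulate a [simulation_config], or `NULL` in real-input mode.
#' @param fst_threshold,q_threshold combined-call cutoffs.
#' @param count_thresholds allele-count cutoffs for the classification
#'   summary.
#' @param pi0_mode passed to [storey_qvalues].
#' @param seed integer seed recorded in the manifest.
#' @param out_dir output directory.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs = NULL, simulate = NULL,
                            fst_threshold = 0.25, q_threshold = 0.05,
                            count_thresholds = c(1L, 6L),
                            pi0_mode = "fixed_1",
                            seed = 1L, out_dir = tempfile("freqscan_run_")) {
  if (is.null(inputs) == is.null(simulate)) {
    stop("exactly one of `inputs` and `simulate` must be given", call. = FALSE)
  }
  stopifnot_scalar_number(fst_threshold, "fst_threshold", 0, 1)
  stopifnot_scalar_number(q_threshold, "q_threshold", 0, 1)
  structure(list(inputs = inputs, simulate = simulate,
                 fst_threshold = fst_threshold, q_threshold = q_threshold,
                 count_thresholds = as.integer(count_thresholds),
                 pi0_mode = pi0_mode, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file; keys mirror the arguments of [pipeline_config],
#'   with `simulate` holding [simulation_config] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulate)) do.call(simulation_config, y$simulate)
  pipeline_config(inputs = y$inputs, simulate = sim,
                  fst_threshold = y$fst_threshold %||% 0.25,
                  q_threshold = y$q_threshold %||% 0.05,
                  count_thresholds = y$count_thresholds %||% c(1L, 6L),
                  pi0_mode = y$pi0_mode %||% "fixed_1",
                  seed = y$seed %||% 1L,
                  out_dir = y$out_dir %||% tempfile("freqscan_run_"))
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full enrichment pipeline
#'
#' Stages: load or simulate inputs; compute cohort allele statistics;
#' classify variants (functional category, deleteriousness, health tier);
#' scan against the panel (binomial + Fst + q-values + combined call);
#' summarise. Writes four tab-separated outputs plus a JSON manifest with
#' the config hash and seed; on any stage failure the partial outputs are
#' removed and a stage-named error is raised. A consistency check
#' (summary counts recomputed from the per-site table) runs at the end of
#' every run.
#'
#' @param cfg a [pipeline_config].
#' @return (invisibly) a list with `scan`, `classified`,
#'   `classification_summary`, `enrichment_summary`, `manifest`,
#'   `out_dir`, and `status` (`"ok"` or `"empty"` when no site survived
#'   filtering).
#' @export
run_enrichment_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  tryCatch({
    if (!is.null(cfg$simulate)) {
      ds <- pipeline_stage("simulate", simulate_dataset(cfg$simulate))
      ann <- pipeline_stage("simulate",
                            simulate_annotation_and_healthdb(ds))
      cohort <- ds$cohort; panel <- ds$panel_freq
      annotations <- ann$annotations; db <- ann$db
    } else {
      cohort <- pipeline_stage("read_vcf", read_cohort_vcf(cfg$inputs$vcf))
      panel <- pipeline_stage("read_panel",
                              read_panel_frequencies(cfg$inputs$panel))
      annotations <- pipeline_stage("read_annotations",
                                    read_annotation_table(cfg$inputs$annotations))
      db <- pipeline_stage("read_health_db",
                           do.call(read_health_db, as.list(cfg$inputs$health_db)))
    }
    stats <- pipeline_stage("allele_stats", cohort_allele_stats(cohort))
    stats$rsid <- cohort$sites$rsid
    classified <- pipeline_stage("classify",
                                 classify_variants(stats, annotations, db))
    cls_summary <- pipeline_stage("classification_summary",
                                  summarize_classification(classified,
                                                           cfg$count_thresholds))
    testable <- stats[stats$n_called > 0, , drop = FALSE]
    status <- "ok"
    if (nrow(testable) == 0L) {
      status <- "empty"
      scan <- NULL; enr_summary <- NULL
    } else {
      scan <- pipeline_stage("scan",
                             enrichment_scan(testable, panel,
                                             fst_threshold = cfg$fst_threshold,
                                             q_threshold = cfg$q_threshold,
                                             pi0_mode = cfg$pi0_mode))
      enr_summary <- pipeline_stage("summarize",
                                    summarize_enrichment(scan, classified))
      # internal consistency: summary must be reconstructible from the
      # per-site table
      stopifnot(enr_summary$union_enriched ==
                  length(unique(scan$key[scan$call != "not_enriched"])))
      stopifnot(sum(enr_summary$by_n_continents) == enr_summary$union_enriched)
    }

    hash <- config_hash(cfg[setdiff(names(cfg), "out_dir")])
    meta <- sprintf("config=%s seed=%d", hash, cfg$seed)
    f <- function(name) file.path(cfg$out_dir, name)
    written <- c(f("classification_summary.tsv"), f("enrichment_scan.tsv"),
                  f("enrichment_summary.tsv"), f("enriched_by_tier.tsv"),
                  f("manifest.json"))
    write_tsv_with_meta(as.data.frame(cls_summary),
                        f("classification_summary.tsv"), meta)
    if (!is.null(scan)) {
      write_tsv_with_meta(as.data.frame(scan), f("enrichment_scan.tsv"), meta)
      summary_df <- data.frame(
        metric = c(paste0("enriched_", names(enr_summary$per_continent)),
                   "union_enriched", names(enr_summary$by_n_continents),
                   "higher_vs_all", "lower_vs_all"),
        value = c(enr_summary$per_continent, enr_summary$union_enriched,
                  enr_summary$by_n_continents, enr_summary$higher_vs_all,
                  enr_summary$lower_vs_all))
      write_tsv_with_meta(summary_df, f("enrichment_summary.tsv"), meta)
      write_tsv_with_meta(enr_summary$by_tier, f("enriched_by_tier.tsv"), meta)
    } else {
      for (nm in c("enrichment_scan.tsv", "enrichment_summary.tsv",
                   "enriched_by_tier.tsv")) {
        writeLines(sprintf("# freqscan empty result %s", meta), f(nm))
      }
    }
    manifest <- list(tool = "freqscan",
                     version = as.character(utils::packageVersion("freqscan")),
                     config_hash = hash, seed = cfg$seed, status = status,
                     n_sites = nrow(stats),
                     n_tested = if (is.null(scan)) 0L else length(unique(scan$key)),
                     n_novel = if (is.null(scan)) NA else length(attr(scan, "novel")),
                     thresholds = list(fst = cfg$fst_threshold,
                                       fdr = cfg$q_threshold))
    jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(list(scan = scan, classified = classified,
                   classification_summary = cls_summary,
                   enrichment_summary = enr_summary, manifest = manifest,
                   out_dir = cfg$out_dir, status = status))
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
}

#' Correlation validation report for two frequency sources
#'
#' Joins two per-site frequency tables on site key and reports the
#' Pearson correlation with Fisher-z interval, t-test p-value and the
#' least-squares fit, together with the paired-frequency table.
#'
#' @param small,large data.frames with columns `key` and `freq`.
#' @param labels character(2): names of the two sources.
#' @return a list of class `validation_report`: `correlation`
#'   (a `correlation_result`) and `pairs`.
#' @export
run_validation_report <- function(small, large,
                                  labels = c("small", "large")) {
  shared <- intersect(small$key, large$key)
  if (length(shared) < 3L) {
    stop("fewer than 3 shared sites between the two sources", call. = FALSE)
  }
  pairs <- data.frame(key = shared,
                      f_small = small$freq[match(shared, small$key)],
                      f_large = large$freq[match(shared, large$key)],
                      stringsAsFactors = FALSE)
  names(pairs)[2:3] <- paste0("f_", labels)
  res <- pearson_with_inference(pairs[[2]], pairs[[3]])
  structure(list(correlation = res, pairs = pairs, labels = labels),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s vs %s, %d shared sites\n",
              x$labels[1], x$labels[2], nrow(x$pairs)))
  print(x$correlation)
  invisible(x)
}
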