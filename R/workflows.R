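# provenance block written next to every workflow output so a run can be
# reproduced bit-identically
.write_provenance <- function(out_dir, config) {
  config$package_version <- as.character(utils::packageVersion("refprimer"))
  jsonlite::write_json(config, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Reference-gene selection workflow over one or more datasets
#'
#' Runs the full per-dataset chain ([stability_report()]) on each course,
#' writes per-dataset reports and quintile selections, and — when two or
#' more datasets are supplied — the cross-dataset consensus
#' ([consensus_ranking()]). Rhythmicity and ANOVA stages are skipped
#' automatically where a dataset cannot support them (no replicates, no
#' rhythm calls, relative scale); skips are recorded in the report files and
#' provenance.
#'
#' @param datasets Named list of [time_course_matrix()] objects.
#' @param out_dir Output directory.
#' @param rhythm Optional named list (matching `datasets`) of rhythmicity
#'   call frames ([jtk_screen()] / [read_rhythm_calls()] output), or the
#'   string `"jtk"` to run [jtk_screen()] on every replicated dataset with
#'   at least `jtk_min_samples` samples.
#' @param cutoff,anova_alpha,rhythm_alpha,level,top_n,per_quintile The
#'   workflow thresholds: expression cutoff on mean log10 FPKM, ANOVA
#'   rejection level, rhythmicity q-value level, prediction-interval
#'   coverage, consensus top-n, and genes per quintile.
#' @param jtk_min_samples Minimum samples before `"jtk"` screening is
#'   attempted (default 6).
#' @param seed Seed for the JTK permutation null (only used with
#'   `rhythm = "jtk"`).
#' @return Invisibly, a list: `reports` (per dataset), `quintiles`,
#'   `consensus` (`NULL` with a single dataset).
#' @export
run_refgenes <- function(datasets, out_dir, rhythm = NULL, cutoff = -2,
                         anova_alpha = 0.05, rhythm_alpha = 0.05,
                         level = 0.95, top_n = 10, per_quintile = 2,
                         jtk_min_samples = 6, seed = 1) {
  if (is.null(names(datasets)) || any(names(datasets) == ""))
    stop("`datasets` must be a named list")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reports <- list(); quintiles <- list()
  for (nm in names(datasets)) {
    tcm <- datasets[[nm]]
    calls <- NULL
    if (identical(rhythm, "jtk")) {
      replicated <- any(table(tcm$samples$time, tcm$samples$course_id) >= 2)
      if (replicated && ncol(tcm$values) >= jtk_min_samples)
        calls <- .with_seed(seed, jtk_screen(tcm, alpha = rhythm_alpha))
    } else if (!is.null(rhythm)) {
      calls <- rhythm[[nm]]
    }
    rep_tab <- stability_report(tcm, rhythm = calls, cutoff = cutoff,
                                anova_alpha = anova_alpha, level = level)
    reports[[nm]] <- rep_tab
    utils::write.table(rep_tab, file.path(out_dir, paste0("report_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    scored <- rep_tab[rep_tab$is_encas, , drop = FALSE]
    if (tcm$scale == "absolute" && nrow(scored) >= 5) {
      q <- quintile_report(scored, per_quintile = per_quintile)
    } else {
      # relative scale (or too few genes): top-n overall instead of quintiles
      ord <- order(scored$pirs, scored$gene_id)
      q <- utils::head(scored[ord, c("gene_id", "mean_expr", "pirs")], top_n)
      q$quintile <- NA_integer_
    }
    quintiles[[nm]] <- q
    utils::write.table(q, file.path(out_dir, paste0("selection_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  consensus <- NULL
  if (length(datasets) >= 2) {
    consensus <- consensus_ranking(reports, top_n = top_n)
    utils::write.table(consensus$table,
                       file.path(out_dir, "consensus.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(consensus$candidates, file.path(out_dir, "candidates.txt"))
  }
  .write_provenance(out_dir, list(
    command = "refgenes", datasets = names(datasets), cutoff = cutoff,
    anova_alpha = anova_alpha, rhythm_alpha = rhythm_alpha, level = level,
    top_n = top_n, per_quintile = per_quintile, seed = seed,
    skipped = lapply(reports, attr, "skipped")))
  invisible(list(reports = reports, quintiles = quintiles,
                 consensus = consensus))
}

#' Primer-catalog workflow
#'
#' Thin wrapper over [build_catalog()] that writes the catalog TSV, the
#' JSON summary and a provenance block.
#'
#' @param fasta,gff3 Input paths.
#' @param out_dir Output directory.
#' @param engine A [builtin_engine()].
#' @param n_pairs Pairs per transcript (default 5).
#' @return Invisibly, the `primer_catalog`.
#' @export
run_primers <- function(fasta, gff3, out_dir, engine = builtin_engine(),
                        n_pairs = 5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cat_obj <- build_catalog(fasta, gff3, engine = engine, out_dir = out_dir,
                           n_pairs = n_pairs)
  .write_provenance(out_dir, list(command = "primers", fasta = fasta,
                                  gff3 = gff3, n_pairs = n_pairs,
                                  engine = unclass(engine)))
  invisible(cat_obj)
}

#' Ct-table analysis workflow
#'
#' Summarizes a Ct table ([summarize_ct()]), joins the primer catalog, and
#' writes the per-gene summary plus the penalty-vs-detection aggregate.
#' Genes in the Ct table without catalog entries are listed and skipped;
#' the run continues for matched genes.
#'
#' @param ct A [ct_table()] or a path readable by [read_ct_table()].
#' @param catalog A catalog pairs frame or the path to a `catalog.tsv`.
#' @param out_dir Output directory.
#' @param detect_threshold Detection cutoff in cycles (default 30).
#' @return Invisibly, a list: `summaries`, `penalty` (see
#'   [penalty_detection_summary()]), `unmatched` (gene IDs without catalog
#'   entries).
#' @export
run_ct <- function(ct, catalog, out_dir, detect_threshold = 30) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(ct)) ct <- read_ct_table(ct)
  if (is.character(catalog))
    catalog <- utils::read.table(catalog, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  unmatched <- setdiff(unique(ct$gene_id), unique(catalog$gene_id))
  if (length(unmatched) > 0) {
    message("no catalog entry for: ", paste(unmatched, collapse = ", "))
    ct <- ct_table(ct[!ct$gene_id %in% unmatched,
                      c("gene_id", "primer_rank", "replicate", "ct")])
  }
  summaries <- summarize_ct(ct, detect_threshold)
  pen <- penalty_detection_summary(summaries, catalog, ct)
  utils::write.table(summaries, file.path(out_dir, "ct_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(pen, file.path(out_dir, "penalty_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .write_provenance(out_dir, list(command = "ct",
                                  detect_threshold = detect_threshold,
                                  unmatched = unmatched))
  invisible(list(summaries = summaries, penalty = pen, unmatched = unmatched))
}
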