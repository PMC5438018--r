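## canonical JSON serialization of a config for provenance hashing
config_json <- function(config) {
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                   null = "null")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(config_json(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' Simulate a full synthetic dataset to disk
#'
#' Writes the cohort VCF, manifest, GFF3 gene models and per-sample depth
#' tracks for a [cohort_config()], plus a `provenance.json` sidecar
#' recording the full config, a config hash and per-file checksums, so any
#' downstream result can be traced to the exact generating parameters.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory; depth tracks go to `out_dir/depth/`.
#' @return Named character vector of written paths (invisibly includes the
#'   depth directory and provenance file).
#' @export
pipeline_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  message(sprintf("[simulate] %d cases / %d controls, seed %d",
                  config$n_case, config$n_control, config$seed))
  files <- generate_cohort(config, out_dir)
  attr(files, "cohort") <- NULL
  depth_dir <- file.path(out_dir, "depth")
  depth_files <- generate_depth_tracks(config, depth_dir)
  prov <- list(
    config = unclass(config),
    config_hash = config_hash(config),
    cnv_carriers = attr(depth_files, "cnv_carriers"),
    depth_region = attr(depth_files, "depth_region"),
    files = as.list(tools::md5sum(c(unname(files), unname(depth_files)))))
  prov_path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  message(sprintf("[simulate] wrote %d files to %s",
                  length(files) + length(depth_files) + 1, out_dir))
  c(files, depth = depth_dir, provenance = prov_path)
}

#' Run the full analysis on a dataset directory
#'
#' End-to-end orchestration: read the VCF and manifest, apply the
#' retention filters (writing the filtered VCF and a per-variant audit
#' log), classify variants against the gene models, run the variant-,
#' gene- and window-based association tests, run the per-nucleotide
#' coverage CNV test if depth tracks are present, estimate power at the
#' configured design, and write a machine-readable summary stating per
#' family whether any unit passed its Bonferroni threshold.
#'
#' @param input_dir Directory containing `cohort.vcf`, `manifest.tsv`,
#'   `genes.gff3` and optionally `depth/` (the layout written by
#'   [pipeline_simulate()]).
#' @param out_dir Results directory (created).
#' @param region Optional region list restricting variants.
#' @param qs_min_snv,qs_min_indel,max_pop_af,min_dataset_occurrence Filter
#'   thresholds, see [filter_variants()].
#' @param window_sizes Window widths for [window_test()].
#' @param alpha Family-wise error rate for every family.
#' @param min_control_age Optional control-age cutoff
#'   (see [run_association_suite()]).
#' @param loss_ratio,gain_ratio CNV dichotomization thresholds.
#' @param power_design List `p0`, `odds_ratio`, `reps`, `seed` for the
#'   power estimate written alongside the results.
#' @return Invisibly, a list with the suite, CNV result (or NULL), power
#'   estimate and the summary data frame.
#' @export
pipeline_run_all <- function(input_dir, out_dir,
                             region = NULL,
                             qs_min_snv = 50, qs_min_indel = 600,
                             max_pop_af = 0.30, min_dataset_occurrence = 2,
                             window_sizes = c(1000, 5000, 10000),
                             alpha = 0.05, min_control_age = NULL,
                             loss_ratio = 0.5, gain_ratio = 1.5,
                             power_design = list(p0 = 0.01, odds_ratio = 22,
                                                 reps = 20000, seed = 1)) {
  vcf <- file.path(input_dir, "cohort.vcf")
  manifest_path <- file.path(input_dir, "manifest.tsv")
  gff <- file.path(input_dir, "genes.gff3")
  for (f in c(vcf, manifest_path, gff)) {
    if (!file.exists(f)) {
      stop_hemiassoc(sprintf("[input] missing required file: %s", f),
                     "hemiassoc_missing_file")
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- read_cohort_vcf(vcf, manifest_path, region)
  message(sprintf("[read] %d calls, %d samples", nrow(cohort$variants),
                  nrow(cohort$manifest)))
  filtered <- filter_variants(cohort, qs_min_snv, qs_min_indel, max_pop_af,
                              min_dataset_occurrence)
  audit <- attr(filtered, "audit")
  message(sprintf("[filter] retained %d / %d (quality fail %d, pop-AF fail %d, singleton fail %d)",
                  nrow(filtered$variants), nrow(cohort$variants),
                  sum(!audit$pass_quality), sum(!audit$pass_pop_af),
                  sum(!audit$pass_occurrence)))
  write_filter_output(filtered, file.path(out_dir, "filtered.vcf"),
                      file.path(out_dir, "filter_audit.tsv"))
  cm <- build_carrier_matrix(filtered)

  models <- load_gene_models(gff, region)
  suite <- run_association_suite(cm, models, window_sizes, alpha,
                                 min_control_age)
  write_tsv(suite$annotations, file.path(out_dir, "annotations.tsv"))
  write_tsv(suite$variant, file.path(out_dir, "assoc_variant.tsv"))
  write_tsv(suite$gene, file.path(out_dir, "assoc_gene.tsv"))
  write_tsv(suite$window, file.path(out_dir, "assoc_window.tsv"))
  write_pvalue_track(suite$track, file.path(out_dir, "pvalue_track.bed"))
  for (i in seq_len(nrow(suite$summary))) {
    s <- suite$summary[i, ]
    message(sprintf("[associate] %s: %d units, min p = %.3g, threshold %.3g, %d significant",
                    s$family, s$n_units, s$min_p, s$threshold,
                    s$n_significant))
  }

  cnv <- NULL
  depth_dir <- file.path(input_dir, "depth")
  if (dir.exists(depth_dir)) {
    manifest <- cohort$manifest
    tracks <- normalize_tracks(read_depth_tracks(depth_dir, manifest))
    statuses <- call_position_status(tracks, loss_ratio, gain_ratio)
    cnv <- position_association(statuses, alpha)
    write_tsv(cnv$results, file.path(out_dir, "cnv_positions.tsv"))
    bed <- data.frame(chrom = cnv$intervals$chrom,
                      start = cnv$intervals$start - 1L,
                      end = cnv$intervals$end)
    write.table(bed, file.path(out_dir, "cnv_intervals.bed"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    message(sprintf("[cnv] %d positions tested, %d significant, %d interval(s)",
                    cnv$n_tested, sum(cnv$results$significant),
                    nrow(cnv$intervals)))
  }

  pw <- simulate_power(power_design$p0, power_design$odds_ratio,
                       sum(cm$samples$group == "case"),
                       sum(cm$samples$group == "control"),
                       alpha = 0.05, reps = power_design$reps %||% 20000,
                       seed = power_design$seed %||% 1)
  write_tsv(data.frame(p0 = pw$p0, odds_ratio = pw$odds_ratio, p1 = pw$p1,
                       n_case = pw$n_case, n_control = pw$n_control,
                       alpha = pw$alpha, reps = pw$reps, power = pw$power,
                       mc_se = pw$mc_se),
            file.path(out_dir, "power.tsv"))

  summary <- suite$summary
  if (!is.null(cnv)) {
    summary <- rbind(summary, data.frame(
      family = "cnv_position", n_units = cnv$n_tested,
      min_p = if (cnv$n_tested) min(cnv$results$p_value) else NA_real_,
      threshold = cnv$threshold,
      threshold_oom = 10^round(log10(cnv$threshold)),
      n_significant = sum(cnv$results$significant)))
  }
  summary$any_significant <- summary$n_significant > 0
  write_tsv(summary, file.path(out_dir, "summary.tsv"))
  jsonlite::write_json(
    list(n_case = suite$n_case, n_control = suite$n_control,
         families = summary,
         any_significant_overall = any(summary$any_significant),
         power_at_design = pw$power),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
  message(sprintf("[summary] %s",
                  if (any(summary$any_significant))
                    "at least one family has a significant unit"
                  else "no family has any unit above its threshold"))
  invisible(list(suite = suite, cnv = cnv, power = pw, summary = summary))
}

#' Render a human-readable report from a results directory
#'
#' Reads the TSVs written by [pipeline_run_all()] and writes `report.md`
#' with the top 10 units per family (by p-value), the family thresholds
#' and the overall verdict. Regenerating from the same results produces an
#' identical report.
#'
#' @param results_dir Directory written by [pipeline_run_all()].
#' @return The report path, invisibly.
#' @export
pipeline_report <- function(results_dir) {
  summary_path <- file.path(results_dir, "summary.tsv")
  if (!file.exists(summary_path)) {
    stop_hemiassoc(sprintf("no results found in %s", results_dir),
                   "hemiassoc_missing_results")
  }
  summary <- read_tsv(summary_path)
  lines <- c("# Association results", "",
             sprintf("- families tested: %d", nrow(summary)),
             sprintf("- any unit above its Bonferroni threshold: %s",
                     if (any(summary$any_significant)) "YES" else "no"),
             "")
  fam_files <- c(variant = "assoc_variant.tsv", gene = "assoc_gene.tsv",
                 window = "assoc_window.tsv")
  for (fam in names(fam_files)) {
    path <- file.path(results_dir, fam_files[fam])
    if (!file.exists(path)) next
    res <- read_tsv(path)
    res <- res[order(res$p_value), , drop = FALSE]
    top <- head(res, 10)
    lines <- c(lines, sprintf("## %s family (top %d of %d)", fam,
                              nrow(top), nrow(res)), "",
               "| unit | a | b | c | d | p | OR | threshold |",
               "|------|---|---|---|---|---|----|-----------|",
               sprintf("| %s | %d | %d | %d | %d | %.3g | %.3g | %.3g |",
                       top$unit_id, top$a, top$b, top$c, top$d,
                       top$p_value, top$odds_ratio, top$threshold),
               "")
  }
  cnv_path <- file.path(results_dir, "cnv_positions.tsv")
  if (file.exists(cnv_path)) {
    cnv <- read_tsv(cnv_path)
    lines <- c(lines, "## CNV position family", "",
               sprintf("- positions tested: %d", nrow(cnv)),
               sprintf("- significant positions: %d", sum(cnv$significant)),
               "")
  }
  report_path <- file.path(results_dir, "report.md")
  writeLines(lines, report_path)
  invisible(report_path)
}
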