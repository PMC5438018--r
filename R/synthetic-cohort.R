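#' Simulate a hemizygous case-control cohort in memory
#'
#' Draws the variant sites, per-variant annotations (population AF, caller,
#' quality score) and the samples-by-variants carrier structure described
#' by a [cohort_config()]. Background carrier status is independent across
#' loci and samples (no linkage disequilibrium) with carrier probability
#' equal to the locus population allele frequency — appropriate for a
#' hemizygous region, where each sample contributes exactly one allele. A
#' configured fraction of loci are dataset-singletons (exactly one
#' carrier). If a risk variant is configured, its carrier probability is
#' `raf_p0` in controls and `OR*p0 / (1 - p0 + OR*p0)` in cases.
#'
#' @param config A [cohort_config()].
#' @return An object of class `cohort_calls`: a list with elements
#'   `variants` (data frame: `variant_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `caller`, `qual`, `pop_af`), `geno` (logical carrier matrix, variants
#'   in rows, samples in columns), `manifest` (data frame `sample_id`,
#'   `group`, `age`) and `region`.
#' @seealso [generate_cohort()] for the on-disk version.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(derive_seed(config$seed, "cohort"))
  region <- config$region
  region_len <- region$end - region$start + 1
  n_samples <- config$n_case + config$n_control
  target_per_sample <- config$background_variant_rate * region_len

  mix <- config$pop_af_distribution
  mean_af <- mix$p_rare * mean(mix$rare_range) +
    (1 - mix$p_rare) * mean(mix$common_range)
  # expected variants carried per sample per locus, accounting for singleton loci
  per_locus <- (1 - config$singleton_fraction) * mean_af +
    config$singleton_fraction / n_samples
  n_loci <- max(1L, round(target_per_sample / per_locus))
  if (n_loci > region_len) {
    stop_hemiassoc("background variant rate too high for region size",
                   "hemiassoc_bad_config")
  }

  pos <- sort(sample.int(region_len, n_loci)) + region$start - 1L
  rare <- runif(n_loci) < mix$p_rare
  af <- ifelse(rare,
               runif(n_loci, mix$rare_range[1], mix$rare_range[2]),
               runif(n_loci, mix$common_range[1], mix$common_range[2]))
  singleton <- runif(n_loci) < config$singleton_fraction
  is_indel <- runif(n_loci) < config$indel_fraction

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_loci, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  if (any(is_indel)) {
    idx <- which(is_indel)
    ins <- runif(length(idx)) < 0.5
    ext <- vapply(idx, function(i)
      paste(sample(bases, sample(1:3, 1), replace = TRUE), collapse = ""),
      character(1))
    alt[idx[ins]] <- paste0(ref[idx[ins]], ext[ins])
    ref[idx[!ins]] <- paste0(ref[idx[!ins]], ext[!ins])
    alt[idx[!ins]] <- substr(ref[idx[!ins]], 1, 1)
  }

  qs <- config$qs_distribution
  qual <- ifelse(is_indel,
                 rnorm(n_loci, qs$indel_mean, qs$indel_sd),
                 rnorm(n_loci, qs$snv_mean, qs$snv_sd))
  qual <- round(pmax(qual, 1), 1)
  pop_af <- round(af, 4)
  pop_af[runif(n_loci) < config$missing_af_fraction] <- NA_real_

  geno <- matrix(runif(n_loci * n_samples) < rep(af, n_samples),
                 nrow = n_loci, ncol = n_samples)
  if (any(singleton)) {
    geno[singleton, ] <- FALSE
    geno[cbind(which(singleton),
               sample.int(n_samples, sum(singleton), replace = TRUE))] <- TRUE
  }

  variants <- data.frame(
    chrom = region$chrom, pos = pos, ref = ref, alt = alt,
    caller = ifelse(is_indel, "indel", "snv"),
    qual = qual, pop_af = pop_af, stringsAsFactors = FALSE)

  if (!is.null(config$risk_variant)) {
    rv <- config$risk_variant
    p0 <- rv$raf_p0
    p1 <- case_carrier_freq(p0, rv$odds_ratio)
    keep <- variants$pos != rv$position
    variants <- variants[keep, , drop = FALSE]
    geno <- geno[keep, , drop = FALSE]
    rv_geno <- c(runif(config$n_case) < p1, runif(config$n_control) < p0)
    rv_row <- data.frame(chrom = region$chrom, pos = rv$position,
                         ref = "A", alt = "G", caller = "snv",
                         qual = qs$snv_mean, pop_af = p0,
                         stringsAsFactors = FALSE)
    at <- findInterval(rv$position, variants$pos)
    variants <- rbind(variants[seq_len(at), , drop = FALSE], rv_row,
                      variants[seq_len(nrow(variants)) > at, , drop = FALSE])
    geno <- rbind(geno[seq_len(at), , drop = FALSE],
                  matrix(rv_geno, nrow = 1),
                  geno[seq_len(nrow(geno)) > at, , drop = FALSE])
  }

  variants$variant_id <- sprintf("%s:%d:%s>%s", variants$chrom, variants$pos,
                                 variants$ref, variants$alt)
  rownames(variants) <- NULL

  manifest <- make_sample_ids(config)
  ages <- rnorm(n_samples, config$age_distribution$mean,
                config$age_distribution$sd)
  # study inclusion floors: controls must be old enough to have passed part
  # of the risk window
  ages <- round(pmax(ages, ifelse(manifest$group == "control", 15, 8)), 1)
  manifest$age <- ages

  dimnames(geno) <- list(variants$variant_id, manifest$sample_id)
  structure(list(variants = variants, geno = geno, manifest = manifest,
                 region = region),
            class = "cohort_calls")
}

#' @export
print.cohort_calls <- function(x, ...) {
  cat(sprintf("<cohort_calls> %d variants x %d samples (%d case / %d control), %s:%d-%d\n",
              nrow(x$variants), nrow(x$manifest),
              sum(x$manifest$group == "case"),
              sum(x$manifest$group == "control"),
              x$region$chrom, x$region$start, x$region$end))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Materializes a [cohort_config()] as the file set the analysis pipeline
#' consumes: a multi-sample VCF 4.2 of hemizygous calls (haploid GT, INFO
#' keys `POP_AF` and `CALLER`, QUAL carrying the caller quality score), a
#' sample manifest TSV, and a GFF3 of synthetic gene models tiling the
#' region. Byte-identical outputs for identical config and seed.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of written paths (`vcf`, `manifest`,
#'   `gff3`), invisibly the cohort object as attribute `cohort`.
#' @export
generate_cohort <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop_hemiassoc(sprintf("cannot create output directory %s", out_dir),
                   "hemiassoc_io_error")
  }
  cohort <- simulate_cohort(config)
  vcf_path <- file.path(out_dir, "cohort.vcf")
  manifest_path <- file.path(out_dir, "manifest.tsv")
  gff_path <- file.path(out_dir, "genes.gff3")
  write_cohort_vcf(cohort, vcf_path)
  write_tsv(cohort$manifest, manifest_path)
  models <- simulate_gene_models(config)
  write_gene_models_gff3(models, gff_path, config$region$chrom)
  out <- c(vcf = vcf_path, manifest = manifest_path, gff3 = gff_path)
  attr(out, "cohort") <- cohort
  out
}

write_cohort_vcf <- function(cohort, path) {
  v <- cohort$variants
  info <- ifelse(is.na(v$pop_af),
                 paste0("CALLER=", v$caller),
                 sprintf("POP_AF=%s;CALLER=%s", format(v$pop_af, trim = TRUE,
                                                       scientific = FALSE),
                         v$caller))
  gt <- ifelse(cohort$geno, "1", "0")
  body <- paste(v$chrom, v$pos, v$variant_id, v$ref, v$alt,
                format(v$qual, trim = TRUE, scientific = FALSE), "PASS",
                info, "GT",
                do.call(paste, c(as.data.frame(gt, stringsAsFactors = FALSE),
                                 sep = "\t")),
                sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", cohort$region$chrom),
    "##INFO=<ID=POP_AF,Number=1,Type=Float,Description=\"Population allele frequency from public databases\">",
    "##INFO=<ID=CALLER,Number=1,Type=String,Description=\"Variant caller class (snv or indel)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype (haploid over the hemizygous region)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$manifest$sample_id), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate gene models tiling the configured region
#'
#' Lays out `config$n_genes` multi-exon genes across the region, with
#' alternating strand, 2-9 exons each and CDS trimmed inside the terminal
#' exons (UTRs), for exercising coding/splice-site classification.
#'
#' @param config A [cohort_config()].
#' @return A list of gene models (class `gene_models`); each element has
#'   `gene_id`, `strand`, `exons` and `cds` data frames of 1-based
#'   inclusive intervals.
#' @export
simulate_gene_models <- function(config) {
  set.seed(derive_seed(config$seed, "genes"))
  region <- config$region
  region_len <- region$end - region$start + 1
  n <- config$n_genes
  spacing <- region_len / n
  models <- vector("list", n)
  for (k in seq_len(n)) {
    n_exons <- sample(2:9, 1)
    exon_len <- round(runif(n_exons, 100, 300))
    intron_len <- round(runif(max(n_exons - 1, 0), 200,
                              max(300, min(3000, spacing / 4))))
    span <- sum(exon_len) + sum(intron_len)
    center <- region$start + (k - 0.5) * spacing + runif(1, -0.1, 0.1) * spacing
    gs <- max(region$start, round(center - span / 2))
    if (gs + span - 1 > region$end) gs <- region$end - span + 1
    starts <- gs + cumsum(c(0, head(exon_len, -1) + intron_len))
    ends <- starts + exon_len - 1
    utr5 <- round(runif(1, 10, exon_len[1] - 10))
    utr3 <- round(runif(1, 10, exon_len[n_exons] - 10))
    cds_start <- starts[1] + utr5
    cds_end <- ends[n_exons] - utr3
    cds <- data.frame(start = pmax(starts, cds_start),
                      end = pmin(ends, cds_end))
    cds <- cds[cds$start <= cds$end, , drop = FALSE]
    models[[k]] <- list(
      gene_id = sprintf("gene%02d", k),
      strand = if (k %% 2 == 0) "-" else "+",
      exons = data.frame(start = starts, end = ends),
      cds = cds)
  }
  structure(models, class = "gene_models")
}

write_gene_models_gff3 <- function(models, path, chrom) {
  rows <- character(0)
  for (m in models) {
    gs <- min(m$exons$start); ge <- max(m$exons$end)
    tid <- paste0(m$gene_id, ".t1")
    rows <- c(rows,
      sprintf("%s\themiassoc\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              chrom, gs, ge, m$strand, m$gene_id),
      sprintf("%s\themiassoc\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              chrom, gs, ge, m$strand, tid, m$gene_id),
      sprintf("%s\themiassoc\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
              chrom, m$exons$start, m$exons$end, m$strand, tid),
      sprintf("%s\themiassoc\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
              chrom, m$cds$start, m$cds$end, m$strand, tid))
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Write per-sample per-base depth tracks
#'
#' Emits one samtools-depth-style TSV (`chrom<TAB>pos<TAB>depth`, 1-based,
#' no header) per sample over the configured depth interval. Baseline depth
#' is negative-binomial around `config$depth$mean` with overdispersion; the
#' defaults keep about 99% of bases at 20x or above. If a CNV injection is
#' configured, the stated fraction of case samples has depth scaled by
#' `fold_change` over the CNV interval.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory for the `<sample_id>.depth.tsv` files.
#' @return Named character vector of written paths; attribute
#'   `cnv_carriers` lists the sample ids carrying the injected CNV.
#' @export
generate_depth_tracks <- function(config, out_dir) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(derive_seed(config$seed, "depth"))
  region <- config$region
  dr <- config$depth_region
  if (is.null(dr)) {
    if (!is.null(config$cnv_injection)) {
      ci <- config$cnv_injection
      pad <- 3 * (ci$end - ci$start + 1)
      dr <- list(chrom = region$chrom,
                 start = max(region$start, ci$start - pad),
                 end = min(region$end, ci$end + pad))
    } else {
      dr <- list(chrom = region$chrom, start = region$start,
                 end = min(region$end, region$start + 19999))
    }
  }
  if (dr$start < region$start || dr$end > region$end) {
    stop_hemiassoc("depth interval outside region", "hemiassoc_bad_config")
  }
  pos <- dr$start:dr$end
  samples <- make_sample_ids(config)
  cnv_samples <- character(0)
  in_cnv <- rep(FALSE, length(pos))
  if (!is.null(config$cnv_injection)) {
    ci <- config$cnv_injection
    case_ids <- samples$sample_id[samples$group == "case"]
    n_carry <- round(ci$case_fraction * length(case_ids))
    cnv_samples <- sort(sample(case_ids, n_carry))
    in_cnv <- pos >= ci$start & pos <= ci$end
  }
  paths <- setNames(file.path(out_dir, paste0(samples$sample_id, ".depth.tsv")),
                    samples$sample_id)
  for (i in seq_len(nrow(samples))) {
    depth <- stats::rnbinom(length(pos), mu = config$depth$mean,
                            size = config$depth$dispersion)
    if (samples$sample_id[i] %in% cnv_samples) {
      depth[in_cnv] <- round(depth[in_cnv] * config$cnv_injection$fold_change)
    }
    writeLines(paste(dr$chrom, pos, depth, sep = "\t"), paths[i])
  }
  attr(paths, "cnv_carriers") <- cnv_samples
  attr(paths, "depth_region") <- dr
  paths
}
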