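#' Read a multi-sample cohort VCF into carrier calls
#'
#' Parses a VCF 4.2 of calls over a hemizygous region into one call per
#' (site, ALT allele). A sample is a carrier of an allele iff its genotype
#' contains at least one copy of it: haploid `"1"`, and the diploid
#' dialects `"1/1"`, `"0/1"`, `"1|0"` emitted by callers run in default
#' diploid mode on hemizygous regions, all count as carriage; `"./."` and
#' `"."` are non-carriers. Multi-allelic records are split into one call
#' per ALT with carrier attribution per allele index. Records outside
#' `region` are dropped.
#'
#' Per-variant metadata is taken from `QUAL` (caller quality score) and the
#' INFO keys `POP_AF` (population allele frequency; missing allowed) and
#' `CALLER` (`snv` or `indel`). When `CALLER` is absent the class is
#' inferred from the alleles (both length 1 = snv).
#'
#' @param vcf_path Path to the VCF.
#' @param manifest_path Path to the sample manifest TSV
#'   (see [read_manifest()]).
#' @param region Optional list `chrom`, `start`, `end` restricting calls.
#' @return A `cohort_calls` object (see [simulate_cohort()]).
#' @export
read_cohort_vcf <- function(vcf_path, manifest_path, region = NULL) {
  if (!file.exists(vcf_path)) {
    stop_hemiassoc(sprintf("VCF not found: %s", vcf_path),
                   "hemiassoc_missing_file")
  }
  manifest <- read_manifest(manifest_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcf@gt
  vcf_samples <- colnames(gt)[-1]  # first column is FORMAT
  if (!setequal(vcf_samples, manifest$sample_id)) {
    stop_hemiassoc("VCF samples and manifest samples do not match",
                   "hemiassoc_sample_mismatch")
  }
  pos <- as.integer(fix$POS)
  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    keep <- fix$CHROM == region$chrom & pos >= region$start & pos <= region$end
  }
  fix <- fix[keep, , drop = FALSE]
  pos <- pos[keep]
  # genotype = first colon-separated FORMAT field, manifest column order
  gt_field <- sub(":.*$", "", gt[keep, -1, drop = FALSE])
  if (is.null(dim(gt_field))) gt_field <- matrix(gt_field, nrow = sum(keep))
  colnames(gt_field) <- vcf_samples
  gt_field <- gt_field[, manifest$sample_id, drop = FALSE]

  info_get <- function(info, key) {
    info[is.na(info)] <- ""
    hit <- regexpr(paste0("(^|;)", key, "=[^;]*"), info)
    out <- rep(NA_character_, length(info))
    out[hit > 0] <- sub(paste0("^;?", key, "="), "", regmatches(info, hit))
    out
  }
  pop_af_rec <- as.numeric(info_get(fix$INFO, "POP_AF"))
  caller_rec <- info_get(fix$INFO, "CALLER")

  alt_list <- strsplit(fix$ALT %||% character(0), ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  rec <- rep(seq_along(n_alt), n_alt)      # record index per expanded call
  allele <- sequence(n_alt)                # ALT allele index within record
  alt <- unlist(alt_list, use.names = FALSE)

  if (length(rec) == 0) {
    variants <- data.frame(chrom = character(0), pos = integer(0),
                           ref = character(0), alt = character(0),
                           caller = character(0), qual = numeric(0),
                           pop_af = numeric(0), variant_id = character(0),
                           stringsAsFactors = FALSE)
    geno <- matrix(FALSE, nrow = 0, ncol = nrow(manifest),
                   dimnames = list(NULL, manifest$sample_id))
  } else {
    geno <- matrix(FALSE, nrow = length(rec), ncol = nrow(manifest))
    for (k in sort(unique(allele))) {
      idx <- which(allele == k)
      pat <- paste0("(^|[/|])", k, "($|[/|])")
      geno[idx, ] <- grepl(pat, gt_field[rec[idx], , drop = FALSE])
    }
    caller <- caller_rec[rec]
    infer <- is.na(caller)
    caller[infer] <- ifelse(nchar(fix$REF[rec][infer]) == 1 &
                              nchar(alt[infer]) == 1, "snv", "indel")
    variants <- data.frame(
      chrom = fix$CHROM[rec], pos = pos[rec], ref = fix$REF[rec], alt = alt,
      caller = caller, qual = as.numeric(fix$QUAL[rec]),
      pop_af = pop_af_rec[rec], stringsAsFactors = FALSE)
    ord <- order(variants$pos, variants$alt)
    variants <- variants[ord, , drop = FALSE]
    geno <- geno[ord, , drop = FALSE]
    variants$variant_id <- sprintf("%s:%d:%s>%s", variants$chrom,
                                   variants$pos, variants$ref, variants$alt)
    rownames(variants) <- NULL
    dimnames(geno) <- list(variants$variant_id, manifest$sample_id)
  }
  if (is.null(region)) {
    region <- list(chrom = if (nrow(variants)) variants$chrom[1] else NA_character_,
                   start = if (nrow(variants)) min(variants$pos) else NA_integer_,
                   end = if (nrow(variants)) max(variants$pos) else NA_integer_)
  }
  structure(list(variants = variants, geno = geno, manifest = manifest,
                 region = region),
            class = "cohort_calls")
}

#' Apply the retention filters to cohort calls
#'
#' A variant is retained iff it passes all three of:
#' \describe{
#'   \item{quality}{caller quality score at or above the caller-specific
#'     cutoff: `qs_min_snv` (default 50) for SNVs, `qs_min_indel`
#'     (default 600) for indels. Bounds are inclusive.}
#'   \item{frequency}{population (database) allele frequency at or below
#'     `max_pop_af` (default 0.30); variants with no database annotation
#'     are retained — novel variants are exactly the hypothesis class.}
#'   \item{occurrence}{carried by at least `min_dataset_occurrence`
#'     (default 2) samples in the dataset, i.e. dataset-singletons are
#'     excluded.}
#' }
#'
#' @param cohort A `cohort_calls` object.
#' @param qs_min_snv,qs_min_indel Inclusive quality cutoffs per caller.
#' @param max_pop_af Inclusive population-AF ceiling.
#' @param min_dataset_occurrence Minimum carrier count in the dataset.
#' @return A `cohort_calls` object restricted to retained variants, with a
#'   per-variant audit data frame (`variant_id`, `n_carriers`,
#'   `pass_quality`, `pass_pop_af`, `pass_occurrence`, `retained`) as
#'   attribute `audit`.
#' @export
filter_variants <- function(cohort, qs_min_snv = 50, qs_min_indel = 600,
                            max_pop_af = 0.30, min_dataset_occurrence = 2) {
  stopifnot(inherits(cohort, "cohort_calls"),
            qs_min_snv > 0, qs_min_indel > 0, max_pop_af > 0,
            min_dataset_occurrence >= 1)
  v <- cohort$variants
  carriers <- if (nrow(v)) rowSums(cohort$geno) else integer(0)
  cutoff <- ifelse(v$caller == "indel", qs_min_indel, qs_min_snv)
  pass_quality <- v$qual >= cutoff
  pass_pop_af <- is.na(v$pop_af) | v$pop_af <= max_pop_af
  pass_occurrence <- carriers >= min_dataset_occurrence
  retained <- pass_quality & pass_pop_af & pass_occurrence
  audit <- data.frame(variant_id = v$variant_id,
                      n_carriers = carriers,
                      pass_quality = pass_quality,
                      pass_pop_af = pass_pop_af,
                      pass_occurrence = pass_occurrence,
                      retained = retained,
                      stringsAsFactors = FALSE)
  out <- cohort
  out$variants <- v[retained, , drop = FALSE]
  rownames(out$variants) <- NULL
  out$geno <- cohort$geno[retained, , drop = FALSE]
  attr(out, "audit") <- audit
  out
}

#' Build the samples-by-variants carrier matrix
#'
#' @param cohort A filtered `cohort_calls` object (see [filter_variants()]).
#' @return An object of class `carrier_matrix`: list with `indicator`
#'   (logical samples x variants matrix), `samples` (manifest data frame)
#'   and `variants` (variant data frame).
#' @export
build_carrier_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_calls"))
  if (nrow(cohort$variants) == 0) {
    stop_hemiassoc("no variants after filtering", "hemiassoc_no_variants")
  }
  structure(list(indicator = t(cohort$geno),
                 samples = cohort$manifest,
                 variants = cohort$variants),
            class = "carrier_matrix")
}

#' @export
print.carrier_matrix <- function(x, ...) {
  cat(sprintf("<carrier_matrix> %d samples x %d variants (%d case / %d control)\n",
              nrow(x$indicator), ncol(x$indicator),
              sum(x$samples$group == "case"),
              sum(x$samples$group == "control")))
  invisible(x)
}

#' Write retained variants and the filter audit log
#'
#' @param filtered A filtered `cohort_calls` (from [filter_variants()]).
#' @param vcf_path,audit_path Output paths for the filtered VCF and the
#'   per-variant pass/fail audit TSV.
#' @return Invisibly, the two paths.
#' @export
write_filter_output <- function(filtered, vcf_path, audit_path) {
  audit <- attr(filtered, "audit")
  if (is.null(audit)) {
    stop_hemiassoc("filtered cohort carries no audit attribute",
                   "hemiassoc_bad_argument")
  }
  write_cohort_vcf(filtered, vcf_path)
  write_tsv(audit, audit_path)
  invisible(c(vcf = vcf_path, audit = audit_path))
}
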