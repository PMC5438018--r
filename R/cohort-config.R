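#' Configuration for a synthetic hemizygous cohort
#'
#' Describes a case-control resequencing cohort over one hemizygous region:
#' group sizes, the target region, the background variant yield per sample,
#' the population allele-frequency spectrum and caller quality-score
#' distributions of background variants, an optional injected risk variant
#' of known odds ratio, an optional injected depth CNV, and the age
#' distribution for the sample manifest. Defaults describe a cohort of 40
#' cases and 48 controls over chr22:18,400,394-22,600,038 with about 4,600
#' hemizygous variants per sample and mean age 22.2 (sd 6.0) years.
#'
#' @param n_case,n_control Group sizes (default 40 and 48).
#' @param region Named list `chrom`, `start`, `end` (1-based inclusive).
#' @param background_variant_rate Expected background variants per sample
#'   per bp. Default `NULL` targets 4,600 variants per sample over the
#'   region.
#' @param pop_af_distribution Mixture for the population allele frequency
#'   of background variants: a fraction `p_rare` drawn uniformly from
#'   `rare_range`, the rest from `common_range`. The default (70% rare in
#'   0.0005-0.010, 30% common in 0.05-0.95) puts mass on both sides of
#'   the 0.30 retention ceiling so the frequency filter is exercised, and
#'   — together with the default background rate — reproduces the
#'   characteristic shape of targeted hemizygous cohort data: a
#'   per-sample yield dominated by common polymorphisms (most of which
#'   the frequency filter removes) alongside roughly 4,000-4,500
#'   dataset-wide variants that survive all three filters.
#' @param qs_distribution Normal means/sds for SNV and indel caller quality
#'   scores; defaults straddle the retention cutoffs of 50 (SNV) and 600
#'   (indel).
#' @param indel_fraction Fraction of background variants emitted as indels.
#' @param singleton_fraction Fraction of background loci emitted as
#'   dataset-singletons (exactly one carrier), exercising the singleton
#'   exclusion filter.
#' @param missing_af_fraction Fraction of background variants with no
#'   population-AF annotation (novel variants).
#' @param risk_variant Optional list `position`, `raf_p0`, `odds_ratio`:
#'   carrier probability is `raf_p0` in controls and
#'   `OR*p0 / (1 - p0 + OR*p0)` in cases.
#' @param cnv_injection Optional list `start`, `end`, `fold_change`,
#'   `case_fraction`: that fraction of case samples has read depth
#'   multiplied by `fold_change` over the interval.
#' @param age_distribution List `mean`, `sd` for manifest ages (years).
#'   Control ages are truncated at 15 (study inclusion minimum).
#' @param depth List `mean` (mean per-base read depth, default 50) and
#'   `dispersion` (negative-binomial size; smaller = noisier; the default
#'   gives mild extra-Poisson noise, variance/mean about 1.25). The
#'   defaults keep essentially all bases at the 20x coverage floor
#'   typical of targeted capture data; positional capture bias and
#'   capture gaps are deliberately not modelled.
#' @param depth_region Optional list `chrom`, `start`, `end`: the interval
#'   over which per-base depth tracks are emitted. Default: the injected
#'   CNV interval padded by three times its length on each side, or the
#'   first 20 kb of the region when no CNV is injected. Full-region
#'   per-base tracks are supported but bulky.
#' @param n_genes Number of synthetic gene models tiling the region.
#' @param seed Master RNG seed; all randomness (cohort, gene models, depth)
#'   flows from deterministic substreams of this seed.
#' @return An object of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(seed = 1)
#' cfg$n_case
#' @export
cohort_config <- function(n_case = 40,
                          n_control = 48,
                          region = list(chrom = "chr22",
                                        start = 18400394, end = 22600038),
                          background_variant_rate = NULL,
                          pop_af_distribution = list(
                            p_rare = 0.7,
                            rare_range = c(0.0005, 0.010),
                            common_range = c(0.05, 0.95)),
                          qs_distribution = list(
                            snv_mean = 150, snv_sd = 60,
                            indel_mean = 900, indel_sd = 250),
                          indel_fraction = 0.1,
                          singleton_fraction = 0.1,
                          missing_af_fraction = 0.05,
                          risk_variant = NULL,
                          cnv_injection = NULL,
                          age_distribution = list(mean = 22.2, sd = 6.0),
                          depth = list(mean = 50, dispersion = 200),
                          depth_region = NULL,
                          n_genes = 73,
                          seed = 1) {
  if (!is_count(n_case) || n_case < 1 || !is_count(n_control) || n_control < 1) {
    stop_hemiassoc("n_case and n_control must be positive integers",
                   "hemiassoc_bad_config")
  }
  stopifnot(is.list(region), all(c("chrom", "start", "end") %in% names(region)))
  if (region$start >= region$end) {
    stop_hemiassoc("region start must be < end", "hemiassoc_bad_config")
  }
  region_len <- region$end - region$start + 1
  if (is.null(background_variant_rate)) {
    background_variant_rate <- 4600 / region_len
  }
  if (!is.null(risk_variant)) {
    stopifnot(all(c("position", "raf_p0", "odds_ratio") %in% names(risk_variant)))
    if (risk_variant$raf_p0 <= 0 || risk_variant$raf_p0 >= 1) {
      stop_hemiassoc("risk_variant raf_p0 must be in (0, 1)",
                     "hemiassoc_bad_config")
    }
    if (risk_variant$odds_ratio <= 0) {
      stop_hemiassoc("risk_variant odds_ratio must be > 0",
                     "hemiassoc_bad_config")
    }
    if (risk_variant$position < region$start || risk_variant$position > region$end) {
      stop_hemiassoc("risk variant position outside region",
                     "hemiassoc_bad_config")
    }
  }
  if (!is.null(cnv_injection)) {
    stopifnot(all(c("start", "end", "fold_change", "case_fraction") %in%
                    names(cnv_injection)))
    if (cnv_injection$start < region$start || cnv_injection$end > region$end ||
        cnv_injection$start >= cnv_injection$end) {
      stop_hemiassoc("cnv_injection interval outside region",
                     "hemiassoc_bad_config")
    }
    stopifnot(cnv_injection$fold_change >= 0,
              cnv_injection$case_fraction >= 0,
              cnv_injection$case_fraction <= 1)
  }
  structure(list(
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    region = region,
    background_variant_rate = background_variant_rate,
    pop_af_distribution = pop_af_distribution,
    qs_distribution = qs_distribution,
    indel_fraction = indel_fraction,
    singleton_fraction = singleton_fraction,
    missing_af_fraction = missing_af_fraction,
    risk_variant = risk_variant,
    cnv_injection = cnv_injection,
    age_distribution = age_distribution,
    depth = depth,
    depth_region = depth_region,
    n_genes = as.integer(n_genes),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d cases / %d controls, %s:%d-%d, seed %d\n",
              x$n_case, x$n_control, x$region$chrom, x$region$start,
              x$region$end, x$seed))
  cat(sprintf("  background rate %.3g variants/sample/bp (~%.0f per sample)\n",
              x$background_variant_rate,
              x$background_variant_rate * (x$region$end - x$region$start + 1)))
  if (!is.null(x$risk_variant)) {
    cat(sprintf("  risk variant at %d: p0 = %g, OR = %g\n",
                x$risk_variant$position, x$risk_variant$raf_p0,
                x$risk_variant$odds_ratio))
  }
  if (!is.null(x$cnv_injection)) {
    cat(sprintf("  CNV injection %d-%d: fold %g in %.0f%% of cases\n",
                x$cnv_injection$start, x$cnv_injection$end,
                x$cnv_injection$fold_change,
                100 * x$cnv_injection$case_fraction))
  }
  invisible(x)
}

make_sample_ids <- function(config) {
  n <- config$n_case + config$n_control
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    group = rep(c("case", "control"), c(config$n_case, config$n_control)),
    stringsAsFactors = FALSE)
}
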