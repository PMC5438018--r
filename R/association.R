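## shared scaffolding for the three test families: case/control carrier
## counts -> exact p via the precomputed margin lookup -> Bonferroni flags
assoc_results <- function(unit_id, unit_kind, a, c, n_case, n_control,
                          alpha, m = length(unit_id), p_lut = NULL) {
  if (is.null(p_lut)) p_lut <- fisher_p_table(n_case, n_control)
  b <- n_case - a
  d <- n_control - c
  p <- p_lut[cbind(a + 1L, c + 1L)]
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  or <- ifelse(zero,
               ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)),
               (a * d) / (b * c))
  thr <- bonferroni_threshold(m, alpha)
  data.frame(unit_id = unit_id, unit_kind = unit_kind,
             a = a, b = b, c = c, d = d,
             p_value = p, odds_ratio = or,
             q_value = p.adjust(p, "BH"),
             threshold = thr$exact,
             threshold_oom = thr$order_of_magnitude,
             significant = p < thr$exact,
             stringsAsFactors = FALSE)
}

group_split_counts <- function(matrix) {
  case <- matrix$samples$group == "case"
  list(case = case,
       n_case = sum(case),
       n_control = sum(!case))
}

check_two_groups <- function(matrix) {
  g <- group_split_counts(matrix)
  if (g$n_case < 1 || g$n_control < 1) {
    stop_hemiassoc("carrier matrix must contain both cases and controls",
                   "hemiassoc_single_group")
  }
  g
}

#' Variant-based association test
#'
#' One two-sided Fisher exact test per retained variant, comparing carrier
#' frequency between cases and controls. The family-wise Bonferroni
#' threshold is `alpha / n_variants`; the order-of-magnitude form of the
#' threshold (nearest power of ten, the form such cutoffs are usually
#' quoted in) is reported alongside. Benjamini-Hochberg q-values are
#' reported for reference but never drive the `significant` flag.
#'
#' @param matrix A `carrier_matrix` (see [build_carrier_matrix()]).
#' @param alpha Family-wise error rate (default 0.05).
#' @return Data frame of association results, one row per variant:
#'   `unit_id`, `unit_kind`, cell counts `a`,`b`,`c`,`d` (case carriers,
#'   case non-carriers, control carriers, control non-carriers),
#'   `p_value`, `odds_ratio` (continuity-corrected when a cell is zero),
#'   `q_value`, `threshold`, `threshold_oom`, `significant`.
#' @export
variant_test <- function(matrix, alpha = 0.05) {
  stopifnot(inherits(matrix, "carrier_matrix"))
  g <- check_two_groups(matrix)
  ind <- matrix$indicator
  a <- colSums(ind[g$case, , drop = FALSE])
  c <- colSums(ind[!g$case, , drop = FALSE])
  assoc_results(matrix$variants$variant_id, "variant", a, c,
                g$n_case, g$n_control, alpha)
}

#' Gene-based burden test of coding and splice-site variants
#'
#' Per gene, a sample is a burden carrier iff it carries at least one
#' retained variant classified as `coding` or `splice_site` for that gene
#' (the per-sample union of qualifying variants, never the sum). Fisher's
#' exact test on the resulting 2x2; family threshold `alpha / n_genes`,
#' where the family size is the number of loaded gene models (genes with
#' zero qualifying variants are reported with p = 1 and flagged
#' `untestable`, and still count toward the correction).
#'
#' @param matrix A `carrier_matrix`.
#' @param annotations Data frame from [classify_variants()].
#' @param models A `gene_models` list defining the tested family, or a
#'   character vector of gene ids.
#' @param alpha Family-wise error rate.
#' @return Data frame of association results, one row per gene, with an
#'   extra logical column `untestable`.
#' @export
gene_burden_test <- function(matrix, annotations, models, alpha = 0.05) {
  stopifnot(inherits(matrix, "carrier_matrix"))
  g <- check_two_groups(matrix)
  gene_ids <- if (inherits(models, "gene_models")) {
    vapply(models, `[[`, character(1), "gene_id")
  } else as.character(models)
  qual <- annotations[annotations$class %in% c("coding", "splice_site"), ,
                      drop = FALSE]
  ind <- matrix$indicator
  a <- c <- integer(length(gene_ids))
  untestable <- logical(length(gene_ids))
  for (i in seq_along(gene_ids)) {
    vids <- unique(qual$variant_id[qual$gene_id == gene_ids[i]])
    vids <- intersect(vids, colnames(ind) %||% matrix$variants$variant_id)
    cols <- match(vids, matrix$variants$variant_id)
    cols <- cols[!is.na(cols)]
    if (length(cols) == 0) {
      untestable[i] <- TRUE
      next
    }
    burden <- rowSums(ind[, cols, drop = FALSE]) > 0
    a[i] <- sum(burden[g$case])
    c[i] <- sum(burden[!g$case])
  }
  res <- assoc_results(gene_ids, "gene", a, c, g$n_case, g$n_control, alpha)
  res$untestable <- untestable
  res
}

#' Variant-centred sliding-window burden test
#'
#' For each window size `w` and each retained variant, the tested unit is
#' the interval of width `w` centred on that variant's position; a sample
#' is a burden carrier iff it carries at least one retained variant inside
#' the window. The number of windows therefore equals the number of
#' variants for every window size, and each size forms its own family with
#' Bonferroni threshold `alpha / n_windows`.
#'
#' @param matrix A `carrier_matrix` (variants must be position-sorted).
#' @param window_sizes Window widths in bp (default 1 kb, 5 kb, 10 kb).
#' @param alpha Family-wise error rate per window-size family.
#' @return Data frame of association results with extra columns `family`
#'   (`window_<w>`), `window_size`, `pos`.
#' @export
window_test <- function(matrix, window_sizes = c(1000, 5000, 10000),
                        alpha = 0.05) {
  stopifnot(inherits(matrix, "carrier_matrix"), length(window_sizes) >= 1)
  g <- check_two_groups(matrix)
  pos <- matrix$variants$pos
  if (length(pos) == 0) {
    stop_hemiassoc("empty carrier matrix", "hemiassoc_no_variants")
  }
  if (is.unsorted(pos)) {
    stop_hemiassoc("variants must be position-sorted", "hemiassoc_bad_argument")
  }
  ind <- matrix$indicator
  n_samp <- nrow(ind)
  p_lut <- fisher_p_table(g$n_case, g$n_control)
  # per sample, sorted carried positions once; per window two rank lookups
  carried <- lapply(seq_len(n_samp), function(s) pos[ind[s, ]])
  out <- vector("list", length(window_sizes))
  for (wi in seq_along(window_sizes)) {
    w <- window_sizes[wi]
    half <- floor(w / 2)
    lo <- pos - half
    hi <- pos + half
    burden <- matrix(FALSE, nrow = length(pos), ncol = n_samp)
    for (s in seq_len(n_samp)) {
      cp <- carried[[s]]
      if (length(cp) == 0) next
      burden[, s] <- (findInterval(hi, cp) - findInterval(lo - 0.5, cp)) > 0
    }
    a <- rowSums(burden[, g$case, drop = FALSE])
    c <- rowSums(burden[, !g$case, drop = FALSE])
    res <- assoc_results(
      sprintf("%s:%d:w%d", matrix$variants$chrom, pos, w), "window",
      a, c, g$n_case, g$n_control, alpha, m = length(pos), p_lut = p_lut)
    res$family <- sprintf("window_%d", w)
    res$window_size <- w
    res$pos <- pos
    out[[wi]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full association suite
#'
#' Runs the variant-based, gene-burden and sliding-window tests on one
#' carrier matrix, optionally after dropping young controls (sensitivity
#' analysis for incomplete follow-up: controls below `min_control_age` may
#' not yet have passed the risk window for the phenotype). Emits a
#' per-position `-log10(p)` track suitable for genome-browser display.
#'
#' @param matrix A `carrier_matrix`.
#' @param models A `gene_models` list.
#' @param window_sizes Window widths in bp for [window_test()].
#' @param alpha Family-wise error rate.
#' @param min_control_age Optional: drop controls younger than this (in
#'   years) before testing. Cases are never dropped. The retained variant
#'   set is kept fixed. Hard error if fewer than 2 controls remain.
#' @param splice_flank Splice window width for [classify_variants()].
#' @return An object of class `association_suite`: list with elements
#'   `variant`, `gene`, `window` (result data frames), `annotations`,
#'   `track` (data frame `family`, `chrom`, `pos`, `p_value`,
#'   `neg_log10_p`), `summary` (per family: units, minimum p, threshold,
#'   number significant) and `n_case` / `n_control` actually tested.
#' @export
run_association_suite <- function(matrix, models,
                                  window_sizes = c(1000, 5000, 10000),
                                  alpha = 0.05, min_control_age = NULL,
                                  splice_flank = 6L) {
  stopifnot(inherits(matrix, "carrier_matrix"))
  if (!is.null(min_control_age)) {
    if (is.null(matrix$samples$age)) {
      stop_hemiassoc("manifest has no ages: cannot apply min_control_age",
                     "hemiassoc_bad_argument")
    }
    keep <- matrix$samples$group == "case" |
      matrix$samples$age >= min_control_age
    if (sum(matrix$samples$group[keep] == "control") < 2) {
      stop_hemiassoc("fewer than 2 controls left after age subset",
                     "hemiassoc_single_group")
    }
    matrix$indicator <- matrix$indicator[keep, , drop = FALSE]
    matrix$samples <- matrix$samples[keep, , drop = FALSE]
    message(sprintf("age subset: %d controls retained (age >= %s), %d cases",
                    sum(matrix$samples$group == "control"), min_control_age,
                    sum(matrix$samples$group == "case")))
  }
  annotations <- classify_variants(matrix$variants, models, splice_flank)
  res_v <- variant_test(matrix, alpha)
  res_g <- gene_burden_test(matrix, annotations, models, alpha)
  res_w <- window_test(matrix, window_sizes, alpha)

  gene_mid <- vapply(models, function(m)
    as.integer(round((min(m$exons$start) + max(m$exons$end)) / 2)), integer(1))
  chrom <- if (nrow(matrix$variants)) matrix$variants$chrom[1] else NA_character_
  track <- rbind(
    data.frame(family = "variant", chrom = chrom, pos = matrix$variants$pos,
               p_value = res_v$p_value, stringsAsFactors = FALSE),
    data.frame(family = "gene", chrom = chrom, pos = gene_mid,
               p_value = res_g$p_value, stringsAsFactors = FALSE),
    data.frame(family = res_w$family, chrom = chrom, pos = res_w$pos,
               p_value = res_w$p_value, stringsAsFactors = FALSE))
  track$neg_log10_p <- -log10(track$p_value)

  fam_summary <- function(res, family) {
    data.frame(family = family, n_units = nrow(res),
               min_p = suppressWarnings(min(res$p_value)),
               threshold = res$threshold[1],
               threshold_oom = res$threshold_oom[1],
               n_significant = sum(res$significant),
               stringsAsFactors = FALSE)
  }
  summary <- rbind(
    fam_summary(res_v, "variant"),
    fam_summary(res_g, "gene"),
    do.call(rbind, lapply(split(res_w, res_w$family),
                          function(r) fam_summary(r, r$family[1]))))
  rownames(summary) <- NULL
  structure(list(variant = res_v, gene = res_g, window = res_w,
                 annotations = annotations, track = track, summary = summary,
                 n_case = sum(matrix$samples$group == "case"),
                 n_control = sum(matrix$samples$group == "control")),
            class = "association_suite")
}

#' @export
print.association_suite <- function(x, ...) {
  cat(sprintf("<association_suite> %d cases / %d controls\n",
              x$n_case, x$n_control))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a -log10(p) track as a BED-compatible file
#'
#' Positions are converted to 0-based half-open single-base intervals;
#' column 5 carries `-log10(p)`.
#'
#' @param track The `track` element of an [run_association_suite()] result.
#' @param path Output path.
#' @param family Which family to export (default `"variant"`).
#' @return Invisibly, the path.
#' @export
write_pvalue_track <- function(track, path, family = "variant") {
  tr <- track[track$family == family, , drop = FALSE]
  bed <- data.frame(chrom = tr$chrom, start = tr$pos - 1L, end = tr$pos,
                    name = sprintf("%s_p", family),
                    score = round(tr$neg_log10_p, 4))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
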