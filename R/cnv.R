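#' Read per-sample depth tracks
#'
#' Reads samtools-depth-style TSVs (`chrom<TAB>pos<TAB>depth`, 1-based, no
#' header), one per sample, named `<sample_id>.depth.tsv` inside `dir` (or
#' given explicitly as a named vector of paths). All tracks must cover the
#' same positions.
#'
#' @param dir Directory containing the tracks, or a named character vector
#'   of paths (names = sample ids).
#' @param manifest Data frame from [read_manifest()].
#' @return An object of class `depth_tracks`: list with `chrom`, `pos`
#'   (integer vector), `depth` (positions x samples integer matrix) and
#'   `samples` (the manifest).
#' @export
read_depth_tracks <- function(dir, manifest) {
  if (length(dir) == 1 && is.null(names(dir)) && dir.exists(dir)) {
    paths <- setNames(file.path(dir, paste0(manifest$sample_id, ".depth.tsv")),
                      manifest$sample_id)
  } else {
    paths <- dir
  }
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop_hemiassoc(sprintf("depth track missing for: %s",
                           paste(names(paths)[missing], collapse = ", ")),
                   "hemiassoc_missing_file")
  }
  paths <- paths[manifest$sample_id]
  first <- read.table(paths[1], sep = "\t",
                      col.names = c("chrom", "pos", "depth"),
                      colClasses = c("character", "integer", "integer"))
  depth <- matrix(0L, nrow = nrow(first), ncol = length(paths),
                  dimnames = list(NULL, names(paths)))
  depth[, 1] <- first$depth
  for (i in seq_along(paths)[-1]) {
    tr <- read.table(paths[i], sep = "\t",
                     col.names = c("chrom", "pos", "depth"),
                     colClasses = c("character", "integer", "integer"))
    if (nrow(tr) != nrow(first) || !identical(tr$pos, first$pos)) {
      stop_hemiassoc(sprintf("depth track %s does not cover the same positions",
                             names(paths)[i]),
                     "hemiassoc_bad_depth")
    }
    depth[, i] <- tr$depth
  }
  structure(list(chrom = first$chrom[1], pos = first$pos, depth = depth,
                 samples = manifest),
            class = "depth_tracks")
}

#' @export
print.depth_tracks <- function(x, ...) {
  cat(sprintf("<depth_tracks> %d positions x %d samples, %s:%d-%d\n",
              length(x$pos), ncol(x$depth), x$chrom, min(x$pos), max(x$pos)))
  invisible(x)
}

#' Normalize depth tracks by library size
#'
#' Normalized coverage at a nucleotide is the number of reads overlapping
#' it divided by the sample's total read count, removing library-size
#' differences between samples. By default the total is the sum of the
#' sample's track (the tracks are the only read evidence available here);
#' pass explicit totals when genome-wide read counts are known.
#'
#' @param tracks A `depth_tracks` object.
#' @param total_reads Optional named numeric vector of per-sample total
#'   read counts; default `colSums(tracks$depth)`.
#' @return The `depth_tracks` object with an added `normalized` matrix and
#'   `total_reads` vector.
#' @export
normalize_tracks <- function(tracks, total_reads = NULL) {
  stopifnot(inherits(tracks, "depth_tracks"))
  if (is.null(total_reads)) {
    total_reads <- colSums(tracks$depth)
  } else {
    total_reads <- total_reads[colnames(tracks$depth)]
  }
  if (any(is.na(total_reads)) || any(total_reads <= 0)) {
    stop_hemiassoc("total_reads must be positive for every sample",
                   "hemiassoc_bad_depth")
  }
  tracks$total_reads <- total_reads
  tracks$normalized <- sweep(tracks$depth, 2, total_reads, "/")
  tracks
}

#' Dichotomize normalized coverage into loss / normal / gain
#'
#' The per-nucleotide exact test needs a carrier-like dichotomy, so at each
#' position the cross-sample median of normalized coverage serves as the
#' reference level; a sample is `loss` when strictly below
#' `loss_ratio x reference` and `gain` when strictly above
#' `gain_ratio x reference` (standard read-depth CNV heuristics for a
#' single-copy loss/gain on a haploid background). Positions where the
#' reference is zero or where fewer than `min_covered_frac` of samples
#' have nonzero coverage (capture gaps) are skipped and logged.
#'
#' The defaults target complete events (a full loss of the remaining copy
#' has expected ratio near 0, far below 0.5). To detect an attenuated
#' event of expected fold `f`, place the decision boundary midway between
#' the two states: `loss_ratio = (1 + f) / 2` (e.g. 0.75 for a half-depth
#' loss), otherwise carriers sit exactly on the boundary and are flagged
#' at chance level.
#'
#' @param tracks A normalized `depth_tracks` (see [normalize_tracks()]).
#' @param loss_ratio,gain_ratio Dichotomization thresholds relative to the
#'   positional median (defaults 0.5 and 1.5).
#' @param min_covered_frac Minimum fraction of samples with nonzero depth
#'   for a position to be tested (default 0.8).
#' @return An object of class `position_status`: list with `chrom`, `pos`
#'   (tested positions), `status` (positions x samples integer matrix:
#'   -1 loss, 0 normal, +1 gain), `skipped` (positions excluded) and
#'   `samples`.
#' @export
call_position_status <- function(tracks, loss_ratio = 0.5, gain_ratio = 1.5,
                                 min_covered_frac = 0.8) {
  stopifnot(inherits(tracks, "depth_tracks"))
  if (is.null(tracks$normalized)) {
    stop_hemiassoc("tracks are not normalized; run normalize_tracks() first",
                   "hemiassoc_bad_argument")
  }
  if (ncol(tracks$normalized) < 3) {
    stop_hemiassoc("at least 3 samples required for a positional median",
                   "hemiassoc_bad_argument")
  }
  nm <- tracks$normalized
  ref <- apply(nm, 1, median)
  covered <- rowMeans(nm > 0) >= min_covered_frac
  tested <- ref > 0 & covered
  if (any(!tested)) {
    message(sprintf("skipping %d position(s) (zero reference or <%d%% samples covered)",
                    sum(!tested), round(100 * min_covered_frac)))
  }
  nm <- nm[tested, , drop = FALSE]
  ref <- ref[tested]
  status <- matrix(0L, nrow = nrow(nm), ncol = ncol(nm),
                   dimnames = list(NULL, colnames(nm)))
  status[nm < loss_ratio * ref] <- -1L
  status[nm > gain_ratio * ref] <- 1L
  structure(list(chrom = tracks$chrom, pos = tracks$pos[tested],
                 status = status, skipped = tracks$pos[!tested],
                 samples = tracks$samples),
            class = "position_status")
}

#' Per-nucleotide CNV association test
#'
#' At each tested position, samples are cross-tabulated as aberrant (loss
#' or gain) vs normal by diagnostic group and tested with the two-sided
#' Fisher exact test; the Bonferroni threshold is
#' `alpha / n_tested_positions`. Runs of adjacent significant positions
#' are merged into reported intervals.
#'
#' When a large fraction of one group carries the same event, the
#' positional median that anchors the dichotomy is dragged toward the
#' carriers, and samples on the other side of it acquire spurious
#' opposite-direction flags. A scan for a known direction should
#' therefore restrict the aberrant class with `direction = "loss"` (or
#' `"gain"`) so those artifacts do not dilute the contingency table.
#'
#' @param statuses A `position_status` object
#'   (see [call_position_status()]).
#' @param alpha Family-wise error rate (default 0.05).
#' @param direction Which statuses count as aberrant: `"both"` (default),
#'   `"loss"` or `"gain"`.
#' @return An object of class `cnv_association`: list with `results`
#'   (data frame: `pos`, `a`,`b`,`c`,`d`, `p_value`, `direction`,
#'   `significant`), `threshold`, `n_tested` and `intervals` (data frame
#'   `chrom`, `start`, `end` of merged significant runs; zero rows when
#'   nothing is significant).
#' @export
position_association <- function(statuses, alpha = 0.05,
                                 direction = c("both", "loss", "gain")) {
  stopifnot(inherits(statuses, "position_status"))
  direction <- match.arg(direction)
  case <- statuses$samples$group == "case"
  n_case <- sum(case); n_control <- sum(!case)
  aberr <- switch(direction,
                  both = statuses$status != 0L,
                  loss = statuses$status == -1L,
                  gain = statuses$status == 1L)
  a <- rowSums(aberr[, case, drop = FALSE])
  c <- rowSums(aberr[, !case, drop = FALSE])
  n_tested <- length(statuses$pos)
  if (n_tested == 0) {
    return(structure(list(results = data.frame(), threshold = NA_real_,
                          n_tested = 0L,
                          intervals = data.frame(chrom = character(0),
                                                 start = integer(0),
                                                 end = integer(0))),
                     class = "cnv_association"))
  }
  p_lut <- fisher_p_table(n_case, n_control)
  p <- p_lut[cbind(a + 1L, c + 1L)]
  losses <- rowSums(statuses$status == -1L)
  gains <- rowSums(statuses$status == 1L)
  direction <- ifelse(losses + gains == 0, "none",
                      ifelse(losses >= gains, "loss", "gain"))
  thr <- bonferroni_threshold(n_tested, alpha)$exact
  sig <- p < thr
  results <- data.frame(pos = statuses$pos, a = a, b = n_case - a,
                        c = c, d = n_control - c, p_value = p,
                        direction = direction, significant = sig,
                        stringsAsFactors = FALSE)
  intervals <- merge_position_runs(statuses$chrom, statuses$pos[sig])
  structure(list(results = results, threshold = thr, n_tested = n_tested,
                 intervals = intervals),
            class = "cnv_association")
}

## merge sorted positions into maximal runs of consecutive integers
merge_position_runs <- function(chrom, pos) {
  if (length(pos) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  pos <- sort(pos)
  first <- which(c(TRUE, diff(pos) > 1))
  data.frame(chrom = chrom,
             start = pos[first],
             end = pos[c(first[-1] - 1L, length(pos))],
             stringsAsFactors = FALSE)
}

#' @export
print.cnv_association <- function(x, ...) {
  cat(sprintf("<cnv_association> %d positions tested, threshold %.3g, %d significant\n",
              x$n_tested, x$threshold, sum(x$results$significant)))
  if (nrow(x$intervals)) {
    cat("significant intervals:\n")
    print(x$intervals, row.names = FALSE)
  }
  invisible(x)
}

#' Association test on externally called CNVs
#'
#' Ingestion hook for per-sample CNV calls from an external read-depth
#' caller, supplied as BED (0-based half-open: `chrom`, `start`, `end`,
#' `sample_id`). Overlapping calls are merged into candidate loci; for
#' each locus, carriers are the samples with any overlapping call, and the
#' same carrier-by-group exact test is applied with Bonferroni correction
#' over loci.
#'
#' @param bed_path Path to the BED file of calls.
#' @param manifest Data frame from [read_manifest()].
#' @param alpha Family-wise error rate.
#' @return Data frame: `chrom`, `start`, `end` (0-based half-open),
#'   `a`,`b`,`c`,`d`, `p_value`, `odds_ratio`, `threshold`, `significant`.
#' @export
external_cnv_association <- function(bed_path, manifest, alpha = 0.05) {
  if (!file.exists(bed_path)) {
    stop_hemiassoc(sprintf("BED not found: %s", bed_path),
                   "hemiassoc_missing_file")
  }
  bed <- read.table(bed_path, sep = "\t",
                    col.names = c("chrom", "start", "end", "sample_id"),
                    colClasses = c("character", "integer", "integer",
                                   "character"))
  unknown <- setdiff(bed$sample_id, manifest$sample_id)
  if (length(unknown)) {
    stop_hemiassoc(sprintf("CNV calls for samples not in manifest: %s",
                           paste(unknown, collapse = ", ")),
                   "hemiassoc_sample_mismatch")
  }
  calls <- GenomicRanges::GRanges(bed$chrom,
                                  IRanges::IRanges(bed$start + 1L, bed$end))
  loci <- GenomicRanges::reduce(calls)
  ov <- GenomicRanges::findOverlaps(loci, calls)
  case <- manifest$group == "case"
  n_case <- sum(case); n_control <- sum(!case)
  a <- c <- integer(length(loci))
  for (i in seq_along(loci)) {
    carriers <- unique(bed$sample_id[S4Vectors::subjectHits(ov)[
      S4Vectors::queryHits(ov) == i]])
    is_case <- manifest$group[match(carriers, manifest$sample_id)] == "case"
    a[i] <- sum(is_case)
    c[i] <- sum(!is_case)
  }
  fe <- fisher_exact(a, n_case - a, c, n_control - c)
  thr <- bonferroni_threshold(max(length(loci), 1L), alpha)$exact
  data.frame(chrom = as.character(GenomicRanges::seqnames(loci)),
             start = GenomicRanges::start(loci) - 1L,
             end = GenomicRanges::end(loci),
             a = a, b = n_case - a, c = c, d = n_control - c,
             p_value = fe$p_value, odds_ratio = fe$odds_ratio,
             threshold = thr, significant = fe$p_value < thr,
             stringsAsFactors = FALSE)
}
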