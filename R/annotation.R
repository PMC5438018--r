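#' Load gene models from a GFF3 file
#'
#' Reads `gene`/`mRNA`/`exon`/`CDS` features and assembles one model per
#' gene overlapping `region`. Exon and CDS intervals are merged per gene
#' across transcripts (the classifier works at the gene level, not per
#' isoform). A CDS interval falling outside the exon union is a hard error
#' naming the gene.
#'
#' @param gff3_path Path to a GFF3 file (1-based inclusive intervals).
#' @param region Optional list `chrom`, `start`, `end`; genes with no
#'   overlap are dropped.
#' @return A `gene_models` list; each element has `gene_id`, `strand`,
#'   `exons` and `cds` (data frames with `start`, `end`, sorted,
#'   non-overlapping).
#' @export
load_gene_models <- function(gff3_path, region = NULL) {
  if (!file.exists(gff3_path)) {
    stop_hemiassoc(sprintf("GFF3 not found: %s", gff3_path),
                   "hemiassoc_missing_file")
  }
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  if (length(gr) == 0) {
    warning("no features in GFF3: returning zero gene models")
    return(structure(list(), class = "gene_models"))
  }
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  id <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA, length(gr))
  parent <- if ("Parent" %in% names(md)) {
    vapply(as.list(md$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
  } else rep(NA_character_, length(gr))

  genes <- which(type == "gene")
  if (length(genes) == 0) {
    warning("no gene features in GFF3: returning zero gene models")
    return(structure(list(), class = "gene_models"))
  }
  # transcript -> gene map so exon/CDS Parent (an mRNA) resolves to its gene
  tx <- which(type %in% c("mRNA", "transcript"))
  tx_gene <- setNames(parent[tx], id[tx])
  owner <- parent
  is_sub <- type %in% c("exon", "CDS")
  owner[is_sub] <- ifelse(owner[is_sub] %in% names(tx_gene),
                          tx_gene[owner[is_sub]], owner[is_sub])

  merge_intervals <- function(start, end) {
    if (length(start) == 0) {
      return(data.frame(start = integer(0), end = integer(0)))
    }
    ir <- IRanges::reduce(IRanges::IRanges(start, end))
    data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
  }

  models <- list()
  for (g in genes) {
    gid <- id[g]
    sub <- which(is_sub & owner == gid)
    exons <- merge_intervals(GenomicRanges::start(gr)[sub][type[sub] == "exon"],
                             GenomicRanges::end(gr)[sub][type[sub] == "exon"])
    cds <- merge_intervals(GenomicRanges::start(gr)[sub][type[sub] == "CDS"],
                           GenomicRanges::end(gr)[sub][type[sub] == "CDS"])
    if (nrow(exons) == 0) {  # gene with no exon features: span is one exon
      exons <- data.frame(start = GenomicRanges::start(gr)[g],
                          end = GenomicRanges::end(gr)[g])
    }
    if (nrow(cds)) {
      covered <- vapply(seq_len(nrow(cds)), function(i)
        any(exons$start <= cds$start[i] & exons$end >= cds$end[i]), logical(1))
      if (!all(covered)) {
        stop_hemiassoc(sprintf("CDS outside exons for gene %s", gid),
                       "hemiassoc_bad_gene_model")
      }
    }
    if (!is.null(region)) {
      gchrom <- as.character(GenomicRanges::seqnames(gr))[g]
      gstart <- min(exons$start); gend <- max(exons$end)
      if (gchrom != region$chrom || gend < region$start || gstart > region$end)
        next
    }
    models[[length(models) + 1L]] <- list(
      gene_id = gid,
      strand = as.character(GenomicRanges::strand(gr))[g],
      exons = exons, cds = cds)
  }
  message(sprintf("loaded %d gene models from %s", length(models),
                  basename(gff3_path)))
  structure(models, class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d genes\n", length(x)))
  invisible(x)
}

## per-gene splice-site windows: the 6 intronic bases flanking each
## internal exon boundary (donor and acceptor ends of internal introns).
## Transcript start/end are not splice sites. The definition is symmetric
## in strand, so no strand dispatch is needed.
splice_windows <- function(model, flank = 6L) {
  ex <- model$exons
  if (nrow(ex) < 2) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  donor_like <- data.frame(start = ex$end[-nrow(ex)] + 1L,
                           end = ex$end[-nrow(ex)] + flank)
  acceptor_like <- data.frame(start = ex$start[-1] - flank,
                              end = ex$start[-1] - 1L)
  w <- rbind(donor_like, acceptor_like)
  # clip windows that would run past a short intron into the next exon
  intr_start <- ex$end[-nrow(ex)] + 1L
  intr_end <- ex$start[-1] - 1L
  w$end[seq_len(nrow(ex) - 1)] <- pmin(w$end[seq_len(nrow(ex) - 1)], intr_end)
  w$start[nrow(ex) - 1 + seq_len(nrow(ex) - 1)] <-
    pmax(w$start[nrow(ex) - 1 + seq_len(nrow(ex) - 1)], intr_start)
  w[w$start <= w$end, , drop = FALSE]
}

#' Classify variant positions against gene models
#'
#' For each (variant, gene) pair where the variant lies within the gene
#' span, assigns one class:
#' \describe{
#'   \item{coding}{position inside a CDS interval;}
#'   \item{splice_site}{position within 6 nt of an exon boundary on the
#'     intronic side, at either end of an internal intron, and not coding
#'     (coding takes precedence where windows touch CDS edges);}
#'   \item{other}{anywhere else in the gene span (UTR exon, deep intron).}
#' }
#' Indels are classified by their leftmost base (VCF left-alignment
#' convention). A variant overlapping several genes yields one row per
#' gene. The definition of the splice window is strand-symmetric.
#'
#' All CDS-overlapping positions count as coding; without transcript
#' sequence there is no synonymous/non-synonymous distinction here.
#'
#' @param variants Data frame with columns `variant_id` and `pos` (or a
#'   `cohort_calls` object).
#' @param models A `gene_models` list (see [load_gene_models()]).
#' @param splice_flank Width in nt of the intronic splice window
#'   (default 6).
#' @return Data frame with columns `variant_id`, `gene_id`, `class`.
#' @export
classify_variants <- function(variants, models, splice_flank = 6L) {
  if (inherits(variants, "cohort_calls")) variants <- variants$variants
  stopifnot(is.data.frame(variants), inherits(models, "gene_models"))
  if (nrow(variants) == 0 || length(models) == 0) {
    return(data.frame(variant_id = character(0), gene_id = character(0),
                      class = character(0), stringsAsFactors = FALSE))
  }
  pos <- variants$pos
  out <- vector("list", length(models))
  for (i in seq_along(models)) {
    m <- models[[i]]
    span <- c(min(m$exons$start), max(m$exons$end))
    hit <- which(pos >= span[1] & pos <= span[2])
    if (length(hit) == 0) next
    p <- pos[hit]
    in_intervals <- function(p, iv) {
      if (nrow(iv) == 0) return(rep(FALSE, length(p)))
      ends_sorted <- iv[order(iv$start), , drop = FALSE]
      j <- findInterval(p, ends_sorted$start)
      j > 0 & p <= ends_sorted$end[pmax(j, 1)]
    }
    coding <- in_intervals(p, m$cds)
    splice <- !coding & in_intervals(p, splice_windows(m, splice_flank))
    out[[i]] <- data.frame(
      variant_id = variants$variant_id[hit],
      gene_id = m$gene_id,
      class = ifelse(coding, "coding", ifelse(splice, "splice_site", "other")),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(variant_id = character(0), gene_id = character(0),
                      class = character(0), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Classify one position against gene models
#'
#' Scalar convenience wrapper around [classify_variants()].
#'
#' @param pos A single 1-based position.
#' @param models A `gene_models` list.
#' @param splice_flank Splice window width (default 6).
#' @return Named character vector: class per overlapping gene (empty if
#'   the position lies in no gene span).
#' @export
classify_position <- function(pos, models, splice_flank = 6L) {
  df <- classify_variants(
    data.frame(variant_id = "q", pos = as.integer(pos)), models, splice_flank)
  setNames(df$class, df$gene_id)
}
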