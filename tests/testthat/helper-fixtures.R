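# small cohort over 100 kb for fast tests; defaults otherwise identical to
# the full-size configuration
tiny_config <- function(seed = 1, ...) {
  cohort_config(region = list(chrom = "chr22",
                              start = 18400394, end = 18500393),
                n_genes = 6, seed = seed, ...)
}

# assemble a cohort_calls object by hand (variants data frame + carrier sets)
make_cohort <- function(variants, carrier_sets, manifest) {
  geno <- matrix(FALSE, nrow = nrow(variants), ncol = nrow(manifest),
                 dimnames = list(NULL, manifest$sample_id))
  for (i in seq_along(carrier_sets)) {
    geno[i, carrier_sets[[i]]] <- TRUE
  }
  variants$variant_id <- sprintf("%s:%d:%s>%s", variants$chrom, variants$pos,
                                 variants$ref, variants$alt)
  rownames(geno) <- variants$variant_id
  structure(list(variants = variants, geno = geno, manifest = manifest,
                 region = list(chrom = variants$chrom[1],
                               start = min(variants$pos),
                               end = max(variants$pos))),
            class = "cohort_calls")
}

toy_manifest <- function(n_case = 2, n_control = 2, age = 25) {
  data.frame(sample_id = sprintf("S%03d", seq_len(n_case + n_control)),
             group = rep(c("case", "control"), c(n_case, n_control)),
             age = age, stringsAsFactors = FALSE)
}

# independent Fisher oracle: exhaustive enumeration of all tables with the
# observed margins, probabilities from binomial coefficients (not dhyper)
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c; N <- m + n
  support <- max(0, k - n):min(k, m)
  pr <- choose(m, support) * choose(n, k - support) / choose(N, k)
  obs <- pr[support == a]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# independent per-base classification oracle: literal loops over intervals
oracle_classify <- function(pos, model, flank = 6) {
  cds <- model$cds
  for (i in seq_len(nrow(cds))) {
    if (pos >= cds$start[i] && pos <= cds$end[i]) return("coding")
  }
  ex <- model$exons[order(model$exons$start), , drop = FALSE]
  if (nrow(ex) >= 2) {
    for (i in seq_len(nrow(ex) - 1)) {
      donor <- (ex$end[i] + 1):(ex$end[i] + flank)
      acceptor <- (ex$start[i + 1] - flank):(ex$start[i + 1] - 1)
      intron <- (ex$end[i] + 1):(ex$start[i + 1] - 1)
      if (pos %in% intersect(donor, intron) ||
          pos %in% intersect(acceptor, intron)) {
        return("splice_site")
      }
    }
  }
  "other"
}

# build a depth_tracks object directly from a positions x samples matrix
make_tracks <- function(depth, manifest, chrom = "chr22", start = 1000L) {
  structure(list(chrom = chrom,
                 pos = seq.int(start, length.out = nrow(depth)),
                 depth = `colnames<-`(depth, manifest$sample_id),
                 samples = manifest),
            class = "depth_tracks")
}
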