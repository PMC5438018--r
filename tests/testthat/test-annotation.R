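toy_gff3 <- function(path, genes) {
  rows <- c("##gff-version 3")
  for (g in genes) {
    gs <- min(g$exons$start); ge <- max(g$exons$end)
    tid <- paste0(g$id, ".t1")
    rows <- c(rows,
      sprintf("chr22\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=%s", gs, ge, g$strand, g$id),
      sprintf("chr22\ttoy\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              gs, ge, g$strand, tid, g$id),
      sprintf("chr22\ttoy\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
              g$exons$start, g$exons$end, g$strand, tid),
      sprintf("chr22\ttoy\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
              g$cds$start, g$cds$end, g$strand, tid))
  }
  writeLines(rows, path)
  path
}

test_that("classification agrees with a brute-force oracle at every base", {
  d <- withr::local_tempdir()
  # two-exon toy gene: exon1 1000-1100 (CDS from 1040), intron 1101-1199,
  # exon2 1200-1300 (CDS to 1260); plus its mirrored minus-strand twin
  plus <- list(id = "toyA", strand = "+",
               exons = data.frame(start = c(1000, 1200), end = c(1100, 1300)),
               cds = data.frame(start = c(1040, 1200), end = c(1100, 1260)))
  span <- 2000:2300  # mirror of 1000:1300 around 2150... constructed directly
  minus <- list(id = "toyB", strand = "-",
                exons = data.frame(start = c(2000, 2200), end = c(2100, 2300)),
                cds = data.frame(start = c(2040, 2200), end = c(2100, 2260)))
  path <- toy_gff3(file.path(d, "toy.gff3"), list(plus, minus))
  models <- load_gene_models(path)
  expect_length(models, 2)

  for (m in models) {
    span <- min(m$exons$start):max(m$exons$end)
    got <- vapply(span, function(p) {
      cl <- classify_position(p, models)
      unname(cl[m$gene_id])
    }, character(1))
    want <- vapply(span, oracle_classify, character(1), model = m)
    expect_identical(got, want)
    # the window definition is strand-symmetric: same class layout
    expect_equal(sum(got == "splice_site"), 12)
  }

  # classification of the two mirrored genes is positionally identical
  plus_m <- models[[1]]; minus_m <- models[[2]]
  cls_p <- vapply(1000:1300, function(p)
    unname(classify_position(p, models)[plus_m$gene_id]), character(1))
  cls_m <- vapply(2000:2300, function(p)
    unname(classify_position(p, models)[minus_m$gene_id]), character(1))
  expect_identical(cls_p, cls_m)
})

test_that("splice windows sit on the intronic side only, 6 nt deep", {
  d <- withr::local_tempdir()
  g <- list(id = "g1", strand = "+",
            exons = data.frame(start = c(500, 800), end = c(600, 900)),
            cds = data.frame(start = c(520, 800), end = c(600, 880)))
  models <- load_gene_models(toy_gff3(file.path(d, "g.gff3"), list(g)))
  cls <- function(p) unname(classify_position(p, models)["g1"])
  expect_equal(cls(601), "splice_site")  # first intronic base past donor
  expect_equal(cls(606), "splice_site")  # 6 nt in
  expect_equal(cls(607), "other")        # 7 nt in: outside the window
  expect_equal(cls(794), "splice_site")  # acceptor side, 6 nt out
  expect_equal(cls(799), "splice_site")  # last intronic base
  expect_equal(cls(600), "coding")       # exonic boundary base is CDS
  expect_equal(cls(500), "other")        # UTR exon start is not a splice site
})

test_that("coding takes precedence where a splice window touches CDS", {
  # exon boundary base inside CDS stays coding even though the window
  # starts one base later; nothing is double-classified
  d <- withr::local_tempdir()
  g <- list(id = "g1", strand = "+",
            exons = data.frame(start = c(100, 300), end = c(200, 400)),
            cds = data.frame(start = c(100, 300), end = c(200, 400)))
  models <- load_gene_models(toy_gff3(file.path(d, "g.gff3"), list(g)))
  df <- classify_variants(
    data.frame(variant_id = c("v1", "v2"), pos = c(200, 201)), models)
  expect_equal(df$class, c("coding", "splice_site"))
})

test_that("default gene simulation yields the configured number of models", {
  d <- withr::local_tempdir()
  cfg <- cohort_config(seed = 1)
  write_path <- file.path(d, "genes.gff3")
  hemiassoc:::write_gene_models_gff3(simulate_gene_models(cfg), write_path,
                                     "chr22")
  models <- load_gene_models(write_path, cfg$region)
  expect_length(models, 73)
})

test_that("genes outside the region are dropped; empty GFF3 warns", {
  d <- withr::local_tempdir()
  g_in <- list(id = "in", strand = "+",
               exons = data.frame(start = c(1000, 1500), end = c(1100, 1600)),
               cds = data.frame(start = 1050, end = 1080))
  g_out <- list(id = "out", strand = "+",
                exons = data.frame(start = c(9000, 9500), end = c(9100, 9600)),
                cds = data.frame(start = 9050, end = 9080))
  path <- toy_gff3(file.path(d, "t.gff3"), list(g_in, g_out))
  models <- load_gene_models(path, region = list(chrom = "chr22",
                                                 start = 500, end = 2000))
  expect_length(models, 1)
  expect_equal(models[[1]]$gene_id, "in")

  writeLines("##gff-version 3", file.path(d, "empty.gff3"))
  expect_warning(empty <- load_gene_models(file.path(d, "empty.gff3")),
                 "no features|no gene")
  expect_length(empty, 0)
})

test_that("CDS outside exons is a hard error naming the gene", {
  d <- withr::local_tempdir()
  bad <- list(id = "brokenGene", strand = "+",
              exons = data.frame(start = 100, end = 200),
              cds = data.frame(start = 150, end = 250))
  path <- toy_gff3(file.path(d, "bad.gff3"), list(bad))
  expect_error(load_gene_models(path), "brokenGene",
               class = "hemiassoc_bad_gene_model")
})

test_that("classification is a pure function", {
  d <- withr::local_tempdir()
  g <- list(id = "g1", strand = "+",
            exons = data.frame(start = c(100, 300), end = c(200, 400)),
            cds = data.frame(start = c(120, 300), end = c(200, 380)))
  models <- load_gene_models(toy_gff3(file.path(d, "g.gff3"), list(g)))
  v <- data.frame(variant_id = sprintf("v%d", 1:50),
                  pos = round(seq(90, 410, length.out = 50)))
  expect_identical(classify_variants(v, models), classify_variants(v, models))
})
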