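write_lines_vcf <- function(records, samples, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr22>",
    "##INFO=<ID=POP_AF,Number=1,Type=Float,Description=\"pop AF\">",
    "##INFO=<ID=CALLER,Number=1,Type=String,Description=\"caller\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

test_that("VCF parsing: carrier attribution across genotype dialects", {
  d <- withr::local_tempdir()
  samples <- sprintf("S%03d", 1:4)
  manifest <- data.frame(sample_id = samples,
                         group = c("case", "case", "control", "control"),
                         age = 25)
  write_tsv_path <- file.path(d, "manifest.tsv")
  write.table(manifest, write_tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  recs <- c(
    # haploid carriers for 3 of 4 samples
    "chr22\t100\t.\tA\tG\t90\tPASS\tPOP_AF=0.1;CALLER=snv\tGT\t1\t1\t1\t0",
    # diploid dialects all count as carriage; ./. and . do not
    "chr22\t200\t.\tC\tT\t90\tPASS\tPOP_AF=0.1;CALLER=snv\tGT\t1/1\t0/1\t./.\t.",
    # multi-allelic: disjoint carrier attribution per ALT
    "chr22\t300\t.\tG\tA,T\t90\tPASS\tPOP_AF=0.2;CALLER=snv\tGT\t1\t2\t1/2\t0",
    # missing POP_AF, no CALLER: class inferred from alleles
    "chr22\t400\t.\tGA\tG\t700\tPASS\t.\tGT\t0\t0\t1\t1")
  vcf_path <- write_lines_vcf(recs, samples, file.path(d, "toy.vcf"))
  co <- read_cohort_vcf(vcf_path, write_tsv_path)
  expect_equal(nrow(co$variants), 5)  # 4 records, one split in two
  expect_equal(unname(rowSums(co$geno)), c(3, 2, 2, 2, 2))
  m3a <- co$geno[co$variants$pos == 300 & co$variants$alt == "A", ]
  m3t <- co$geno[co$variants$pos == 300 & co$variants$alt == "T", ]
  expect_equal(unname(m3a), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unname(m3t), c(FALSE, TRUE, TRUE, FALSE))
  expect_true(is.na(co$variants$pop_af[co$variants$pos == 400]))
  expect_equal(co$variants$caller[co$variants$pos == 400], "indel")

  # region restriction drops out-of-range records
  co2 <- read_cohort_vcf(vcf_path, write_tsv_path,
                         region = list(chrom = "chr22", start = 150, end = 350))
  expect_equal(sort(unique(co2$variants$pos)), c(200, 300))

  # sample mismatch is a hard error
  bad <- manifest; bad$sample_id[1] <- "SXXX"
  bad_path <- file.path(d, "bad_manifest.tsv")
  write.table(bad, bad_path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_cohort_vcf(vcf_path, bad_path),
               class = "hemiassoc_sample_mismatch")
})

test_that("retention filters are boundary-inclusive and reasons are logged", {
  manifest <- toy_manifest(2, 2)
  v <- data.frame(
    chrom = "chr22", pos = 1:10 * 100, ref = "A",
    alt = c("G", "T", "C", "G", "T", "C", "G", "T", "C", "G"),
    caller = c("snv", "snv", "indel", "indel", "snv",
               "snv", "snv", "indel", "snv", "snv"),
    qual = c(50, 49, 600, 599, 120, 120, 120, 700, 120, 120),
    pop_af = c(0.30, 0.10, 0.10, 0.10, 0.31, 0.10, NA, 0.29, 0.10, 0.05),
    stringsAsFactors = FALSE)
  carriers <- list(c("S001", "S002"), c("S001", "S002"), c("S001", "S003"),
                   c("S001", "S003"), c("S002", "S004"), "S003",
                   c("S001", "S004"), c("S002", "S003"), c("S001", "S002"),
                   c("S002", "S003", "S004"))
  co <- make_cohort(v, carriers, manifest)
  # by construction exactly 4 variants violate exactly one filter each:
  # #2 (snv qual 49), #4 (indel qual 599), #5 (pop AF 0.31), #6 (singleton)
  f <- filter_variants(co)
  expect_equal(nrow(f$variants), 6)
  expect_setequal(f$variants$pos, c(100, 300, 700, 800, 900, 1000))
  audit <- attr(f, "audit")
  expect_equal(sum(!audit$pass_quality), 2)
  expect_equal(sum(!audit$pass_pop_af), 1)
  expect_equal(sum(!audit$pass_occurrence), 1)
  # boundary cases: qual 50 snv, qual 600 indel, pop AF 0.30, 2 carriers all retained
  expect_true(all(c(100, 300) %in% f$variants$pos))
  # missing pop AF retained
  expect_true(700 %in% f$variants$pos)
})

test_that("filtering is idempotent, order-independent and monotone", {
  co <- simulate_cohort(tiny_config(seed = 8))
  f1 <- filter_variants(co)
  f2 <- filter_variants(f1)
  expect_identical(f1$variants, f2$variants)
  expect_identical(f1$geno, f2$geno)

  set.seed(1)
  perm <- sample(nrow(co$variants))
  co_perm <- co
  co_perm$variants <- co$variants[perm, , drop = FALSE]
  co_perm$geno <- co$geno[perm, , drop = FALSE]
  f_perm <- filter_variants(co_perm)
  expect_setequal(f_perm$variants$variant_id, f1$variants$variant_id)

  # relaxing any single threshold never shrinks the retained set
  n0 <- nrow(f1$variants)
  expect_gte(nrow(filter_variants(co, qs_min_snv = 10)$variants), n0)
  expect_gte(nrow(filter_variants(co, qs_min_indel = 100)$variants), n0)
  expect_gte(nrow(filter_variants(co, max_pop_af = 0.9)$variants), n0)
  expect_gte(nrow(filter_variants(co, min_dataset_occurrence = 1)$variants), n0)
})

test_that("carrier matrix preserves carrier sets and bans singleton columns", {
  manifest <- toy_manifest(2, 1)
  v <- data.frame(chrom = "chr22", pos = c(100, 200), ref = "A",
                  alt = c("G", "T"), caller = "snv", qual = 99,
                  pop_af = 0.1, stringsAsFactors = FALSE)
  co <- make_cohort(v, list(c("S001", "S003"), c("S001", "S002")), manifest)
  cm <- build_carrier_matrix(co)
  expect_equal(dim(cm$indicator), c(3, 2))
  expect_equal(unname(colSums(cm$indicator)), c(2, 2))
  expect_true(cm$indicator["S003", 1])
  expect_false(cm$indicator["S002", 1])

  # empty retained set is a typed error
  co_empty <- filter_variants(co, qs_min_snv = 1e6)
  expect_error(build_carrier_matrix(co_empty), class = "hemiassoc_no_variants")

  # default synthetic cohorts never leave singleton columns after filtering
  for (s in 1:10) {
    f <- filter_variants(simulate_cohort(tiny_config(seed = s)))
    expect_true(all(rowSums(f$geno) >= 2))
  }
})

test_that("filter output files round-trip the audit", {
  d <- withr::local_tempdir()
  co <- simulate_cohort(tiny_config(seed = 2))
  f <- filter_variants(co)
  write_filter_output(f, file.path(d, "f.vcf"), file.path(d, "audit.tsv"))
  audit <- read.table(file.path(d, "audit.tsv"), sep = "\t", header = TRUE)
  expect_equal(nrow(audit), nrow(co$variants))
  expect_equal(sum(audit$retained), nrow(f$variants))
  reread <- vcfR::read.vcfR(file.path(d, "f.vcf"), verbose = FALSE)
  expect_equal(nrow(reread@fix), nrow(f$variants))
})
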