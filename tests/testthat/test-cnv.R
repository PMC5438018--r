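test_that("normalization divides by library size and is scale invariant", {
  m <- toy_manifest(2, 1)
  tr <- make_tracks(matrix(20L, nrow = 50, ncol = 3), m)
  norm <- normalize_tracks(tr, total_reads = setNames(rep(1e6, 3),
                                                      m$sample_id))
  expect_true(all(norm$normalized == 2e-5))
  # doubling one sample's depths and total changes nothing downstream
  tr2 <- tr; tr2$depth[, 2] <- tr2$depth[, 2] * 2L
  norm2 <- normalize_tracks(tr2, total_reads = setNames(c(1e6, 2e6, 1e6),
                                                        m$sample_id))
  expect_equal(norm2$normalized, norm$normalized)
  # default totals are the track sums, so global rescaling also cancels
  norm3a <- normalize_tracks(tr)
  tr3 <- tr; tr3$depth <- tr3$depth * 7L
  expect_equal(normalize_tracks(tr3)$normalized, norm3a$normalized)
  expect_error(normalize_tracks(tr, total_reads = setNames(c(0, 1, 1),
                                                           m$sample_id)),
               class = "hemiassoc_bad_depth")
})

test_that("hand-computed normalized matrix matches", {
  m <- toy_manifest(2, 1)
  depth <- matrix(c(10L, 20L, 30L,
                    5L, 10L, 15L,
                    1L, 2L, 3L), nrow = 3, byrow = TRUE)
  tr <- normalize_tracks(make_tracks(depth, m))
  totals <- c(16, 32, 48)
  expect_equal(unname(tr$normalized),
               sweep(depth, 2, totals, "/"), tolerance = 1e-12)
})

test_that("status calls respect the strict boundary and the median reference", {
  m <- toy_manifest(3, 2)
  # identical samples: everything normal
  tr <- normalize_tracks(make_tracks(matrix(30L, 20, 5), m))
  st <- call_position_status(tr)
  expect_true(all(st$status == 0L))
  # one sample at exactly loss_ratio x median stays normal (strict <)
  depth <- matrix(40L, 10, 5); depth[, 1] <- 20L
  tr <- normalize_tracks(make_tracks(depth, m),
                         total_reads = setNames(rep(1000, 5), m$sample_id))
  st <- call_position_status(tr, loss_ratio = 0.5)
  expect_true(all(st$status[, 1] == 0L))
  # just below the boundary flips to loss; far above flips to gain
  depth[, 1] <- 19L; depth[, 2] <- 70L
  tr <- normalize_tracks(make_tracks(depth, m),
                         total_reads = setNames(rep(1000, 5), m$sample_id))
  st <- call_position_status(tr)
  expect_true(all(st$status[, 1] == -1L))
  expect_true(all(st$status[, 2] == 1L))
  expect_error(call_position_status(
    normalize_tracks(make_tracks(matrix(10L, 5, 2), toy_manifest(1, 1)))),
    class = "hemiassoc_bad_argument")
})

test_that("uncovered or zero-reference positions are skipped and logged", {
  m <- toy_manifest(3, 2)
  depth <- matrix(25L, 10, 5)
  depth[3, ] <- 0L              # zero reference
  depth[7, c(1, 2)] <- 0L      # only 60% of samples covered
  tr <- normalize_tracks(make_tracks(depth, m))
  expect_message(st <- call_position_status(tr, min_covered_frac = 0.8),
                 "skipping 2")
  expect_equal(length(st$pos), 8)
  expect_equal(st$skipped, tr$pos[c(3, 7)])
})

test_that("a single aberrant sample never reaches Bonferroni significance", {
  m <- toy_manifest(40, 48)
  depth <- matrix(50L, 200, 88)
  depth[1:100, 1] <- 10L   # one case with a clear loss over half the track
  st <- call_position_status(normalize_tracks(
    make_tracks(depth, m),
    total_reads = setNames(rep(1e4, 88), m$sample_id)))
  res <- position_association(st)
  expect_true(all(res$results$a[1:100] == 1))
  expect_true(all(res$results$a[101:200] == 0))
  expect_equal(sum(res$results$significant), 0)
  expect_equal(nrow(res$intervals), 0)
})

test_that("noiseless shared CNVs give identical p at every affected position", {
  m <- toy_manifest(40, 48)
  depth <- matrix(50L, 100, 88)
  depth[41:60, m$group == "case"] <- 10L
  st <- call_position_status(normalize_tracks(
    make_tracks(depth, m),
    total_reads = setNames(rep(5000, 88), m$sample_id)))
  res <- position_association(st, direction = "loss")
  p_in <- res$results$p_value[41:60]
  expect_equal(length(unique(p_in)), 1)
  expect_true(all(res$results$significant[41:60]))
  expect_equal(res$intervals$start, st$pos[41])
  expect_equal(res$intervals$end, st$pos[60])
})

test_that("an injected half-depth CNV in a case subset is flagged as loss", {
  cfg <- tiny_config(seed = 17, cnv_injection = list(
    start = 18410001, end = 18412000, fold_change = 0.5,
    case_fraction = 0.25))
  d <- withr::local_tempdir()
  paths <- generate_depth_tracks(cfg, d)
  carriers <- attr(paths, "cnv_carriers")
  expect_length(carriers, 10)
  m <- toy_manifest(40, 48)
  tr <- normalize_tracks(read_depth_tracks(d, m))
  st <- call_position_status(tr, loss_ratio = 0.75)
  sel <- st$pos >= 18410001 & st$pos <= 18412000
  # carriers are flagged loss at the vast majority of CNV positions
  flag_rate <- mean(st$status[sel, carriers] == -1L)
  expect_gt(flag_rate, 0.95)
  # non-carriers essentially never are
  others <- setdiff(m$sample_id, carriers)
  expect_lt(mean(st$status[sel, others] == -1L), 0.05)
})

test_that("identity fold injections are never detected above chance", {
  hits <- vapply(1:5, function(s) {
    cfg <- tiny_config(seed = 100 + s, cnv_injection = list(
      start = 18410001, end = 18412000, fold_change = 1.0,
      case_fraction = 1))
    d <- withr::local_tempdir()
    generate_depth_tracks(cfg, d)
    m <- toy_manifest(40, 48)
    st <- call_position_status(normalize_tracks(read_depth_tracks(d, m)),
                               loss_ratio = 0.75)
    res <- position_association(st, direction = "loss")
    sum(res$results$significant)
  }, numeric(1))
  expect_equal(sum(hits), 0)
})

test_that("externally called CNVs feed the same carrier test", {
  d <- withr::local_tempdir()
  m <- toy_manifest(40, 48)
  cases <- m$sample_id[m$group == "case"][1:20]
  bed <- data.frame(chrom = "chr22",
                    start = 18410000L, end = 18412000L,
                    sample_id = cases)
  bed_path <- file.path(d, "calls.bed")
  write.table(bed, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  res <- external_cnv_association(bed_path, m)
  expect_equal(nrow(res), 1)
  expect_equal(res$a, 20)
  expect_equal(res$c, 0)
  expect_lt(res$p_value, 1e-5)
  bed$sample_id[1] <- "NOPE"
  write.table(bed, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  expect_error(external_cnv_association(bed_path, m),
               class = "hemiassoc_sample_mismatch")
})
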