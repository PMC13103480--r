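test_that("VCF round-trip preserves dosages and handcrafted GTs decode correctly", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t1|1\t0|0\t./."), vcf)
  g <- read_vcf(vcf)
  expect_equal(unname(g$dosages),
               matrix(c(0, 1, 2, 2, 0, NA), 3, 2))
  expect_equal(rownames(g$dosages), c("s1", "s2", "s3"))

  # round trip through the writer
  out <- tempfile(fileext = ".vcf")
  write_vcf(g, out)
  g2 <- read_vcf(out)
  expect_equal(unname(g2$dosages), unname(g$dosages))
  expect_equal(g2$chrom, g$chrom)
  expect_equal(g2$pos, g$pos)
})

test_that("multi-allelic records are skipped with a message", {
  vcf <- tempfile(fileext = ".vcf")
  recs <- sprintf("chr1\t%d\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1", c(1, 2, 4, 5))
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    recs[1:2],
    "chr1\t3\t.\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/2",
    recs[3:4]), vcf)
  expect_message(g <- read_vcf(vcf), "multi-allelic")
  expect_equal(ncol(g$dosages), 4)
})

test_that("filter_variants applies rules in order on a hand-countable fixture", {
  # 10 markers over 10 individuals: 2 at 30% missing, 1 singleton,
  # 1 at MAF 0.02 (needs n = 25 -> use explicit dosage design over n = 25)
  n <- 25
  d <- matrix(1, n, 10)
  d[, 1:8] <- rep(c(0, 1, 2), length.out = n)   # common markers
  d[1:8, 1] <- NA                                # 32% missing
  d[1:8, 2] <- NA                                # 32% missing
  d[, 3] <- 0; d[1, 3] <- 1                      # singleton (MAC 1)
  d[, 4] <- 0; d[1:2, 4] <- 1                    # MAF 2/50 = 0.04 < 0.05
  g <- geno_matrix(d, rep("chr1", 10), 1:10 * 100)
  f <- filter_variants(g, max_missing = 0.2, min_mac = 2,
                       drop_singletons = TRUE, min_maf = 0.05)
  rep_tab <- attr(f, "filter_report")
  expect_equal(rep_tab$count[rep_tab$rule == "missingness"], 2)
  expect_equal(rep_tab$count[rep_tab$rule == "retained"], 6)
  expect_equal(ncol(f$dosages), 6)

  # disabled thresholds leave the input unchanged
  f0 <- filter_variants(g, max_missing = 1, min_mac = 0,
                        drop_singletons = FALSE, min_maf = 0)
  expect_equal(f0$dosages, g$dosages)

  # idempotence
  f2 <- filter_variants(f, max_missing = 0.2, min_mac = 2,
                        drop_singletons = TRUE, min_maf = 0.05)
  expect_equal(f2$dosages, f$dosages)

  # a fully-missing marker is removed by the missingness rule
  d2 <- d; d2[, 5] <- NA
  g2 <- geno_matrix(d2, rep("chr1", 10), 1:10 * 100)
  f3 <- filter_variants(g2, max_missing = 0.2)
  expect_equal(ncol(f3$dosages), 7)  # cols 1, 2 (32% missing) and 5 (all) gone
  expect_false(anyNA(colMeans(f3$dosages, na.rm = TRUE)))
})

test_that("mean imputation fills missing calls with observed means", {
  g <- geno_matrix(matrix(c(0, 2, NA, 1, 1, 1), 3, 2), rep("chr1", 2), c(1, 2))
  gi <- impute_mean(g)
  expect_equal(unname(gi$dosages[3, 1]), 1.0)
  expect_equal(colMeans(gi$dosages), colMeans(g$dosages, na.rm = TRUE),
               ignore_attr = TRUE)
  # complete input unchanged
  expect_identical(impute_mean(gi)$dosages, gi$dosages)
})

test_that("allele frequencies ignore missing calls", {
  g <- geno_matrix(matrix(c(0, 1, 2, 2, 2, 2, 0, 1, NA), 3, 3),
                   rep("chr1", 3), 1:3)
  p <- allele_frequencies(g)
  expect_equal(unname(p), c(0.5, 1.0, 0.25))
})

test_that("GRM matches the VanRaden closed form and clone identity holds", {
  g <- geno_matrix(matrix(c(0, 1, 2), 3, 1), "chr1", 100)
  G <- compute_grm(g)
  expect_equal(G$denom, 0.5)
  expect_equal(unname(G$values),
               matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3, 3))

  # duplicated individuals: off-diagonal equals the diagonals
  pan <- make_grm_panel(30, 300, seed = 1)
  d <- pan$geno$dosages
  d[2, ] <- d[1, ]
  g2 <- geno_matrix(d, pan$geno$chrom, pan$geno$pos)
  G2 <- compute_grm(g2)$values
  expect_equal(G2[1, 2], G2[1, 1], tolerance = 1e-10)
  expect_equal(G2[1, 2], G2[2, 2], tolerance = 1e-10)

  # monomorphic marker rejected
  gm <- geno_matrix(cbind(c(0, 1, 2), c(2, 2, 2)), rep("chr1", 2), 1:2)
  expect_error(compute_grm(gm), "monomorphic")
})

test_that("GRM is invariant to marker order and allele relabeling", {
  pan <- make_grm_panel(40, 500, seed = 2)
  G <- compute_grm(pan$geno)$values
  # shuffle marker order
  set.seed(3)
  perm <- sample(ncol(pan$geno$dosages))
  gp <- geno_matrix(pan$geno$dosages[, perm], rep("chr1", length(perm)),
                    seq_along(perm))
  expect_equal(compute_grm(gp)$values, G, tolerance = 1e-12)
  # flip ref/alt at a third of the markers (dosage 2 - x)
  d <- pan$geno$dosages
  flip <- seq(1, ncol(d), by = 3)
  d[, flip] <- 2 - d[, flip]
  gf <- geno_matrix(d, pan$geno$chrom, pan$geno$pos)
  expect_equal(compute_grm(gf)$values, G, tolerance = 1e-12)
})

test_that("mean GRM diagonal is near 1 on large HWE panels", {
  for (s in 1:3) {
    pan <- make_grm_panel(200, 20000, seed = 10 + s)
    expect_gt(mean(diag(pan$grm$values)), 0.95)
    expect_lt(mean(diag(pan$grm$values)), 1.05)
  }
})

test_that("GRM text round-trip preserves values and IDs", {
  pan <- make_grm_panel(10, 100, seed = 4)
  path <- tempfile(fileext = ".tsv")
  write_grm(pan$grm, path)
  G2 <- read_grm(path)
  expect_equal(G2$values, pan$grm$values, tolerance = 1e-12)
})
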