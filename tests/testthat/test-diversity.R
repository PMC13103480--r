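test_that("GRM PCA reproduces the SVD of the centered dosage matrix", {
  pan <- make_grm_panel(20, 200, seed = 9)
  p <- pca_from_grm(pan$grm, 5)
  W <- sweep(pan$geno$dosages, 2, colMeans(pan$geno$dosages))
  sv <- svd(W / sqrt(pan$grm$denom))
  scores <- sv$u[, 1:5] %*% diag(sv$d[1:5])
  expect_lt(max(abs(abs(p$coords) - abs(scores))), 1e-6)
  # spectral ordering and mass
  expect_true(all(diff(p$var_frac) <= 1e-12))
  expect_lte(sum(p$var_frac), 1 + 1e-12)
  # coordinate orthogonality
  gram <- crossprod(p$coords)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
})

test_that("PCA of indistinguishable individuals has no variance on PC1", {
  G <- matrix(1, 4, 4)
  p <- pca_from_grm(G, 2)
  expect_equal(p$var_frac[1], 0)
})

test_that("pairwise r2 matches the two-locus haplotype formula", {
  # haplotype frequencies AB = 0.4, Ab = 0.1, aB = 0.1, ab = 0.4
  # => D = 0.15, r2 = 0.15^2 / 0.5^4 = 0.36
  l1 <- c(rep(1, 4), 1, 0, rep(0, 4))
  l2 <- c(rep(1, 4), 0, 1, rep(0, 4))
  H <- cbind(l1, l2)
  g <- geno_matrix(H[1:5, ] + H[6:10, ], rep("chr1", 2), c(1, 2),
                   hap1 = H[1:5, ], hap2 = H[6:10, ])
  pr <- pairwise_r2(g, phased = TRUE)
  expect_equal(pr$r2, 0.36)
  expect_equal(attr(pr, "mode"), "phased")

  # a marker paired with itself has r2 = 1 (duplicate the column)
  g2 <- geno_matrix(cbind(H[1:5, 1] + H[6:10, 1], H[1:5, 1] + H[6:10, 1]),
                    rep("chr1", 2), c(1, 2),
                    hap1 = H[1:5, c(1, 1)], hap2 = H[6:10, c(1, 1)])
  expect_equal(pairwise_r2(g2, phased = TRUE)$r2, 1)
})

test_that("independent markers show only sampling-level r2", {
  n <- 5000
  set.seed(13)
  d <- cbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.4))
  g <- geno_matrix(d, rep("chr1", 2), c(1, 2))
  pr <- pairwise_r2(g, phased = FALSE)
  expect_lt(pr$r2, 10 / (2 * n))
})

test_that("background threshold tracks the null quantile of squared correlation", {
  n <- 200
  geno <- sim_hwe_panel(n, 600, n_chromosomes = 3, seed = 14)
  thr <- background_threshold(geno, snps_per_chromosome = 200, seed = 2)
  # Monte-Carlo null: squared correlation of independent samples of size 2n
  # (haplotype mode doubles the sample) -- here genotypes are unphased so the
  # dosage correlation over n individuals is the null
  set.seed(15)
  null_r2 <- replicate(20000, cor(rbinom(n, 2, 0.3), rbinom(n, 2, 0.3))^2)
  q99 <- quantile(null_r2, 0.99, names = FALSE)
  expect_gt(thr, q99 * 0.7)
  expect_lt(thr, q99 * 1.3)

  # invariant to chromosome relabeling (no subsampling at 200 markers/chrom,
  # so the same unlinked pair set is evaluated)
  relab <- geno
  relab$chrom <- c(chr01 = "c3", chr02 = "c1", chr03 = "c2")[geno$chrom]
  thr2 <- background_threshold(relab, snps_per_chromosome = 200, seed = 2)
  expect_equal(as.numeric(thr), as.numeric(thr2), tolerance = 1e-12)
  expect_error(background_threshold(sim_hwe_panel(50, 50, seed = 1)), "two chromosomes")
})

test_that("ld_decay is flat at one for perfect LD and deterministic", {
  # all markers identical -> every pair has r2 = 1, curve never crosses
  set.seed(16)
  x <- rbinom(60, 2, 0.4)
  d <- matrix(x, 60, 10)
  g <- geno_matrix(d, rep("chr1", 10), (1:10) * 50)
  dec <- ld_decay(g, bin_width = 50, max_distance = 500, threshold = 0.5)
  occ <- !is.na(dec$curve$mean_r2)
  expect_true(all(abs(dec$curve$mean_r2[occ] - 1) < 1e-12))
  expect_true(is.na(dec$crossing_distance_bp))

  geno <- sim_hwe_panel(80, 300, n_chromosomes = 2, seed = 17)
  d1 <- ld_decay(geno, snps_per_chromosome = 100, bin_width = 1000,
                 max_distance = 5e4, seed = 5)
  d2 <- ld_decay(geno, snps_per_chromosome = 100, bin_width = 1000,
                 max_distance = 5e4, seed = 5)
  expect_identical(d1$curve, d2$curve)
})

test_that("effective SNP count hits its closed-form limits", {
  # exactly orthogonal dosage columns: Me = m
  d <- dosages_orthogonal(3)
  g <- geno_matrix(d, rep("chr1", 3), 1:3)
  expect_equal(effective_snp_count(g)$me, 3, tolerance = 1e-10)

  # duplicated marker pairs: lambda = {2, 0} per pair, Me = m / 2
  x <- dosages_orthogonal(2)
  dd <- cbind(x[, 1], x[, 1], x[, 2], x[, 2])
  g2 <- geno_matrix(dd, rep("chr1", 4), 1:4)
  expect_equal(effective_snp_count(g2)$me, 2, tolerance = 1e-10)

  # three markers with exact pairwise correlation 0.5:
  # lambda = {2, 0.5, 0.5}, Me = 3 - (2 - 1) = 2
  g3 <- geno_matrix(dosages_cor_half(), rep("chr1", 3), 1:3)
  expect_equal(effective_snp_count(g3)$me, 2, tolerance = 1e-10)
})

test_that("Me agrees with a direct eigen-oracle and decreases with LD", {
  pan <- make_grm_panel(100, 80, seed = 18)
  gec <- effective_snp_count(pan$geno, block_size = 80)
  lam <- eigen(cor(pan$geno$dosages), symmetric = TRUE, only.values = TRUE)$values
  me_oracle <- length(lam) - sum(pmax(lam - 1, 0))
  expect_equal(gec$me, me_oracle, tolerance = 1e-8)

  # two-marker family with increasing correlation: Me non-increasing
  set.seed(19)
  z <- rnorm(4000)
  me_r <- vapply(c(0, 0.3, 0.6, 0.9, 0.99), function(r) {
    x1 <- z + rnorm(4000)
    x2 <- r * scale(x1) + sqrt(1 - r^2) * rnorm(4000)
    # discretize to dosages, preserving the ordering of correlation
    d <- cbind(findInterval(x1, quantile(x1, c(1/3, 2/3))),
               findInterval(x2, quantile(x2, c(1/3, 2/3))))
    effective_snp_count(geno_matrix(d, rep("c", 2), 1:2))$me
  }, numeric(1))
  expect_true(all(diff(me_r) <= 1e-8))
})

test_that("significance thresholds derive from the effective test count", {
  expect_equal(gwas_thresholds(1), list(significant = 0.05, suggestive = 1))
  expect_equal(gwas_thresholds(100), list(significant = 5e-4, suggestive = 1e-2))
  expect_error(gwas_thresholds(0.5), "Me")
  thr <- gwas_thresholds(2000, m_total = 4000)
  expect_equal(thr$independent_fraction_pct, 50.0)
})
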