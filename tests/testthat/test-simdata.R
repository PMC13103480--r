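test_that("genotype simulation is deterministic and respects dosage ranges", {
  cfg <- sim_geno_config(collection_sizes = c(A = 30, B = 30), n_chromosomes = 2,
                         markers_per_chromosome = 100, clone_pairs = 0, seed = 5)
  s1 <- simulate_genotypes(cfg)
  s2 <- simulate_genotypes(cfg)
  expect_identical(s1$geno$dosages, s2$geno$dosages)
  expect_false(anyNA(s1$geno$dosages))
  expect_true(all(s1$geno$dosages %in% 0:2))
  expect_equal(as.vector(table(s1$collections)), c(30, 30))
  expect_identical(s1$geno$dosages, s1$geno$hap1 + s1$geno$hap2)
})

test_that("clone pairs are genotype-identical and show clone GRM identity", {
  cfg <- sim_geno_config(collection_sizes = c(A = 40, B = 30, C = 40),
                         n_chromosomes = 2, markers_per_chromosome = 250,
                         clone_pairs = 5, clone_collections = c(1, 3), seed = 6)
  sim <- simulate_genotypes(cfg)
  expect_equal(nrow(sim$clone_map), 5)
  for (i in seq_len(5)) {
    a <- sim$clone_map$id_a[i]; b <- sim$clone_map$id_b[i]
    expect_identical(sim$geno$dosages[a, ], sim$geno$dosages[b, ])
  }
  grm <- compute_grm(impute_mean(filter_variants(sim$geno, min_maf = 0.01)))
  a <- sim$clone_map$id_a[1]; b <- sim$clone_map$id_b[1]
  expect_equal(grm$values[a, b], grm$values[a, a], tolerance = 1e-10)
})

test_that("faster copying switch rate gives shorter LD-decay crossing", {
  shorter <- logical(5)
  for (s in 1:5) {
    # few ancestral templates give a short-range LD plateau (~1/16) well
    # above the unlinked background, so the crossing distance is informative
    cfg <- sim_geno_config(collection_sizes = c(slow = 100, fast = 100),
                           n_chromosomes = 2, markers_per_chromosome = 1000,
                           chromosome_length_bp = 1e8,
                           ancestral_pools = 4, haplotypes_per_pool = 4,
                           copying_switch_rate_per_bp = c(1e-8, 1e-7),
                           clone_pairs = 0, seed = 100 + s)
    sim <- simulate_genotypes(cfg)
    cross <- sapply(c("slow", "fast"), function(cl) {
      ix <- sim$collections == cl
      g <- sim$geno
      sub <- geno_matrix(g$dosages[ix, ], g$chrom, g$pos,
                         hap1 = g$hap1[ix, ], hap2 = g$hap2[ix, ])
      thr <- background_threshold(sub, seed = s)
      ld_decay(sub, snps_per_chromosome = 1000, bin_width = 1e6,
               max_distance = 1e8, threshold = thr,
               seed = s)$crossing_distance_bp
    })
    shorter[s] <- is.finite(cross["fast"]) &&
      (!is.finite(cross["slow"]) || cross["fast"] < cross["slow"])
  }
  expect_true(all(shorter))
})

test_that("missingness injection is calibrated, deterministic and bounded", {
  g <- sim_hwe_panel(100, 100, seed = 7)
  expect_identical(inject_missing(g, 0)$dosages, g$dosages)
  gm1 <- inject_missing(g, 0.2, seed = 3)
  gm2 <- inject_missing(g, 0.2, seed = 3)
  expect_identical(gm1$dosages, gm2$dosages)
  frac <- mean(is.na(gm1$dosages))
  expect_gt(frac, 0.18); expect_lt(frac, 0.22)   # binomial 99% band at 10^4 calls
  expect_error(inject_missing(g, 1), "rate")
})

test_that("recording protocols reduce draws as specified", {
  expect_equal(apply_protocol(5.5, "mean_of_k", 1), 5.5)
  expect_equal(apply_protocol(5.5, "max_of_k", 1), 5.5)
  expect_equal(apply_protocol(c(1, 2, 3, 9), "mean_of_k", 3), 2)
  expect_equal(apply_protocol(c(1, 2, 3), "max_of_k", 3), 3)
  expect_error(apply_protocol(c(1, 2), "max_of_k", 3), "at least")

  # Monte-Carlo expectation of the max of 15 standard normals
  set.seed(11)
  draws <- matrix(rnorm(15 * 1e5), ncol = 15)
  mx <- mean(apply(draws, 1, max))
  expect_equal(mx, 1.736, tolerance = 0.01)
})

test_that("phenotype simulation hits heritability and correlation targets", {
  # h2 = 1, no GxE: phenotype is the breeding value plus a constant
  pan <- make_grm_panel(300, 500, seed = 21)
  colls <- factor(rep(c("A", "B"), length.out = 300))
  names(colls) <- rownames(pan$geno$dosages)
  sim <- simulate_phenotypes(pan$geno, colls, pheno_sim_config("t", 1.0, seed = 3))
  for (cl in c("A", "B")) {
    ix <- colls == cl
    expect_equal(cor(sim$pheno$value[ix], sim$truth$breeding_values[ix, 1]), 1,
                 tolerance = 1e-12)
  }

  # perfect genetic correlation forces identical standardized breeding values
  S <- matrix(c(1, 1, 1, 1), 2)
  sim2 <- simulate_phenotypes(pan$geno, colls,
    pheno_sim_config(c("a", "b"), 0.5, genetic_correlation_target = S, seed = 4))
  bv <- scale(sim2$truth$breeding_values)
  expect_equal(bv[, 1], bv[, 2], tolerance = 1e-8)

  # non-PSD correlation target rejected
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(pheno_sim_config(c("a", "b"), 0.5, genetic_correlation_target = bad),
               "positive semi-definite")

  # realized h2 near target when averaged over seeds
  geno <- sim_hwe_panel(1000, 3000, seed = 22)
  collsL <- factor(rep(c("A", "B"), each = 500))
  names(collsL) <- rownames(geno$dosages)
  h2s <- vapply(1:10, function(s)
    simulate_phenotypes(geno, collsL,
      pheno_sim_config("t", 0.5, seed = s))$truth$realized_h2,
    numeric(1))
  expect_lt(abs(mean(h2s) - 0.5), 0.05)
})

test_that("GxE fraction calibrates the cross-collection effect correlation", {
  pan <- make_grm_panel(200, 800, seed = 23)
  colls <- factor(rep(c("A", "B"), each = 100))
  names(colls) <- rownames(pan$geno$dosages)
  for (g in c(0.2, 0.5)) {
    cors <- vapply(1:5, function(s) {
      sim <- simulate_phenotypes(pan$geno, colls,
        pheno_sim_config("t", 0.6, gxe_variance_fraction = g,
                         n_causal = 600, seed = 50 + s))
      cor(sim$truth$collection_effects$A[, 1],
          sim$truth$collection_effects$B[, 1])
    }, numeric(1))
    expect_lt(abs(mean(cors) - (1 - g)), 0.05)
  }
})

test_that("allele-frequency spectrum is polymorphic and spans the MAF range", {
  cfg <- sim_geno_config(collection_sizes = c(A = 60), n_chromosomes = 2,
                         markers_per_chromosome = 300, seed = 9)
  sim <- simulate_genotypes(cfg)
  p <- allele_frequencies(sim$geno)
  maf <- pmin(p, 1 - p)
  expect_gt(mean(maf > 0), 0.9)          # essentially no monomorphic markers
  expect_gt(max(maf), 0.4)               # spectrum reaches common variants
})
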