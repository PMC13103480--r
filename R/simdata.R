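#' Configuration for the multi-collection genotype simulator
#'
#' The simulator emulates several partially admixed germplasm collections by
#' Li-Stephens-style mosaic copying: each haplotype is a mosaic of ancestral
#' pool haplotypes, with a per-collection switch rate along the chromosome.
#' A larger switch rate produces shorter copied segments and therefore faster
#' within-collection LD decay. Defaults emulate the three-collection mango
#' setting: 225 (AUS), 224 (CHN) and 161 (USA) individuals, 20 clone pairs
#' shared between the first and third collections, and a faster-decaying
#' second (CHN) collection.
#'
#' @param collection_sizes named integer vector of individuals per collection.
#' @param n_chromosomes,markers_per_chromosome,chromosome_length_bp genome
#'   dimensions (positions are drawn uniformly and sorted per chromosome).
#' @param ancestral_pools number of ancestral populations contributing
#'   haplotype templates.
#' @param haplotypes_per_pool template haplotypes per ancestral pool; smaller
#'   values give stronger short-range LD (plateau roughly 1 / total templates).
#' @param admixture_concentration per-collection Dirichlet concentration for
#'   individual ancestry proportions; larger values give more even (more
#'   admixed) ancestry.
#' @param pool_bias multiplicative weight a collection places on its "own"
#'   ancestral pool (collection i favours pool `1 + (i-1) %% ancestral_pools`);
#'   1 means no collection structure.
#' @param copying_switch_rate_per_bp per-collection template switch rate per
#'   bp; controls LD decay length (roughly 1/rate).
#' @param clone_pairs number of individuals duplicated across the two
#'   collections in `clone_collections`.
#' @param clone_collections indices of the two collections sharing clones.
#' @param fst Balding-Nichols differentiation of pool allele frequencies from
#'   the global frequency.
#' @param missing_rate fraction of calls masked at random, in [0, 1).
#' @param seed integer seed; the simulation is a pure function of the config.
#' @return A list of class `sim_geno_config`.
#' @export
sim_geno_config <- function(collection_sizes = c(AUS = 225, CHN = 224, USA = 161),
                            n_chromosomes = 5,
                            markers_per_chromosome = 500,
                            chromosome_length_bp = 5e7,
                            ancestral_pools = 6,
                            haplotypes_per_pool = 6,
                            admixture_concentration = rep(1, length(collection_sizes)),
                            pool_bias = 1.5,
                            copying_switch_rate_per_bp = {
                              r <- rep(5e-8, length(collection_sizes))
                              if (length(r) >= 2) r[2] <- 1e-7
                              r
                            },
                            clone_pairs = if (length(collection_sizes) >= 2) 20 else 0,
                            clone_collections = if (length(collection_sizes) >= 3) c(1, 3) else c(1, 2),
                            fst = 0.15,
                            missing_rate = 0,
                            seed = 1) {
  if (is.null(names(collection_sizes)))
    names(collection_sizes) <- paste0("C", seq_along(collection_sizes))
  if (any(collection_sizes <= 0) || n_chromosomes <= 0 ||
      markers_per_chromosome <= 0 || chromosome_length_bp <= 0 ||
      ancestral_pools <= 0 || haplotypes_per_pool <= 0)
    stop("all sizes must be positive")
  if (any(copying_switch_rate_per_bp <= 0) || any(admixture_concentration <= 0))
    stop("switch rates and concentrations must be positive")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  nc <- length(collection_sizes)
  admixture_concentration <- rep_len(admixture_concentration, nc)
  copying_switch_rate_per_bp <- rep_len(copying_switch_rate_per_bp, nc)
  if (clone_pairs < 0) stop("clone_pairs must be non-negative")
  if (clone_pairs > 0) {
    if (length(clone_collections) != 2 || any(clone_collections > nc))
      stop("clone_collections must index two collections")
    if (clone_pairs > min(collection_sizes[clone_collections]))
      stop("clone_pairs exceeds the size of a linked collection")
  }
  structure(as.list(environment()), class = "sim_geno_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Simulate multi-collection mosaic genotypes
#'
#' Haplotypes are mosaics of ancestral-pool templates: between consecutive
#' markers a switch occurs with probability `1 - exp(-rate * distance)`; at
#' each switch a pool is drawn from the individual's ancestry proportions and
#' a template is drawn uniformly within the pool. Pool allele frequencies
#' follow a Balding-Nichols model around a shared frequency, creating mild
#' population structure; Dirichlet ancestry creates admixture. Clone pairs
#' receive bit-identical genotypes (and haplotypes) under distinct IDs.
#'
#' @param config a [sim_geno_config].
#' @return A list with `geno` (a phased [geno_matrix]), `collections`
#'   (factor of per-individual collection labels, names = IDs), and
#'   `clone_map` (data.frame id_a / id_b, possibly empty).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_geno_config"))
  set.seed(config$seed)
  sizes <- config$collection_sizes
  nc <- length(sizes)
  n <- sum(sizes)
  P <- config$ancestral_pools
  H <- config$haplotypes_per_pool
  mpc <- config$markers_per_chromosome
  m <- config$n_chromosomes * mpc

  collections <- factor(rep(names(sizes), sizes), levels = names(sizes))
  ids <- unlist(lapply(seq_len(nc), function(c)
    sprintf("%s_%03d", names(sizes)[c], seq_len(sizes[c]))))

  # ancestry proportions: Dirichlet with a mild bias toward an "own" pool
  coll_idx <- rep(seq_len(nc), sizes)
  ancestry <- t(vapply(coll_idx, function(c) {
    w <- rep(1, P)
    w[1 + (c - 1) %% P] <- config$pool_bias
    rdirichlet1(config$admixture_concentration[c] * w)
  }, numeric(P)))

  hap1 <- matrix(0L, n, m)
  hap2 <- matrix(0L, n, m)
  chrom <- rep(sprintf("chr%02d", seq_len(config$n_chromosomes)), each = mpc)
  pos <- integer(m)
  fst <- config$fst

  for (ch in seq_len(config$n_chromosomes)) {
    cols <- (ch - 1) * mpc + seq_len(mpc)
    pos_ch <- sort(sample.int(config$chromosome_length_bp, mpc))
    pos[cols] <- pos_ch
    p0 <- stats::runif(mpc, 0.05, 0.95)
    # Balding-Nichols pool frequencies, templates per pool
    templates <- matrix(0L, P * H, mpc)
    for (pool in seq_len(P)) {
      pf <- stats::rbeta(mpc, p0 * (1 - fst) / fst, (1 - p0) * (1 - fst) / fst)
      templates[(pool - 1) * H + seq_len(H), ] <-
        matrix(stats::rbinom(H * mpc, 1, rep(pf, each = H)), H, mpc)
    }
    gaps <- diff(pos_ch)
    for (i in seq_len(n)) {
      rate <- config$copying_switch_rate_per_bp[coll_idx[i]]
      p_sw <- 1 - exp(-rate * gaps)
      for (hap in 1:2) {
        sw <- stats::rbinom(mpc - 1, 1, p_sw)
        seg <- cumsum(c(1L, sw))         # segment id per marker
        nseg <- seg[mpc]
        pools <- sample.int(P, nseg, replace = TRUE, prob = ancestry[i, ])
        tmpl <- (pools - 1) * H + sample.int(H, nseg, replace = TRUE)
        h <- templates[cbind(tmpl[seg], seq_len(mpc))]
        if (hap == 1) hap1[i, cols] <- h else hap2[i, cols] <- h
      }
    }
  }

  # clone pairs: copy genotypes from collection A onto collection B
  clone_map <- data.frame(id_a = character(0), id_b = character(0))
  if (config$clone_pairs > 0) {
    a_idx <- which(coll_idx == config$clone_collections[1])[seq_len(config$clone_pairs)]
    b_idx <- which(coll_idx == config$clone_collections[2])[seq_len(config$clone_pairs)]
    hap1[b_idx, ] <- hap1[a_idx, ]
    hap2[b_idx, ] <- hap2[a_idx, ]
    clone_map <- data.frame(id_a = ids[a_idx], id_b = ids[b_idx])
  }

  dos <- hap1 + hap2
  rownames(dos) <- rownames(hap1) <- rownames(hap2) <- ids
  geno <- geno_matrix(dos, chrom, pos, hap1 = hap1, hap2 = hap2)
  if (config$missing_rate > 0)
    geno <- inject_missing(geno, config$missing_rate, seed = config$seed + 1L)
  names(collections) <- ids
  list(geno = geno, collections = collections, clone_map = clone_map)
}

#' Simulate an unstructured Hardy-Weinberg SNP panel
#'
#' Independent markers with dosages drawn Binomial(2, p), p uniform on a MAF
#' band; useful for calibration tests where LD and structure are nuisance.
#'
#' @param n,m individuals and markers.
#' @param maf_range range for allele frequencies.
#' @param n_chromosomes markers are split evenly across this many chromosomes.
#' @param seed integer seed.
#' @return A [geno_matrix].
#' @export
sim_hwe_panel <- function(n, m, maf_range = c(0.05, 0.5), n_chromosomes = 1,
                          seed = 1) {
  set.seed(seed)
  p <- stats::runif(m, maf_range[1], maf_range[2])
  dos <- matrix(stats::rbinom(n * m, 2, rep(p, each = n)), n, m)
  mpc <- ceiling(m / n_chromosomes)
  chrom <- sprintf("chr%02d", rep(seq_len(n_chromosomes), each = mpc))[seq_len(m)]
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix) seq_along(ix) * 1000L),
                use.names = FALSE)
  geno_matrix(dos, chrom, pos)
}

#' Mask genotype calls at random
#'
#' @param geno a [geno_matrix].
#' @param rate per-call missingness probability in [0, 1).
#' @param seed integer seed (the mask is a pure function of it).
#' @return A [geno_matrix] with masked calls set `NA` (haplotypes dropped,
#'   since phase is no longer complete).
#' @export
inject_missing <- function(geno, rate, seed = 1) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(geno)
  set.seed(seed)
  d <- geno$dosages
  mask <- stats::runif(length(d)) < rate
  d[mask] <- NA
  geno_matrix(d, geno$chrom, geno$pos, geno$ref, geno$alt)
}

#' Recording protocol for repeated within-tree measurements
#'
#' Collapses per-unit (e.g. per-fruit) draws to one recorded value: either
#' the arithmetic mean of the first `k` draws (`mean_of_k`, e.g. average
#' weight of 10 fruits) or their maximum (`max_of_k`, e.g. maximum weight of
#' at least 15 fruits). Recording a maximum adds an upward bias and inflates
#' the effective residual variance, which is what depresses the heritability
#' of max-recorded traits.
#'
#' @param per_unit_draws numeric vector of at least `k` draws.
#' @param protocol `"mean_of_k"` or `"max_of_k"`.
#' @param k number of draws used.
#' @return The recorded scalar.
#' @export
apply_protocol <- function(per_unit_draws, protocol = c("mean_of_k", "max_of_k"),
                           k) {
  protocol <- match.arg(protocol)
  if (k < 1) stop("k must be >= 1")
  if (length(per_unit_draws) < k)
    stop("need at least k = ", k, " draws, got ", length(per_unit_draws))
  x <- per_unit_draws[seq_len(k)]
  if (protocol == "mean_of_k") mean(x) else max(x)
}

#' Configuration for the phenotype simulator
#'
#' @param trait_names character vector of trait names.
#' @param h2_targets per-trait within-collection narrow-sense heritability
#'   targets in (0, 1].
#' @param genetic_correlation_target symmetric PSD matrix with unit diagonal
#'   (trait-by-trait additive-genetic correlations).
#' @param n_causal number of causal markers (a common causal set is shared by
#'   all traits so effects can be drawn jointly with the target correlation).
#' @param gxe_variance_fraction fraction g of genetic variance that is
#'   collection-specific; the cross-collection genetic correlation of true
#'   breeding values is 1 - g.
#' @param environment_means per-collection fixed offsets (recycled across
#'   traits, or a collections x traits matrix).
#' @param protocol optional named list (per trait) of
#'   `list(type = "mean_of_k"|"max_of_k", k = ...)`, or, to emulate
#'   collections that phenotyped the same trait differently, a named list of
#'   such entries keyed by collection label (collections without an entry
#'   fall back to the h2-calibrated residual). Traits without any entry get
#'   a single draw with the h2-calibrated residual. For protocol cells the
#'   residual is generated by the recording protocol itself: per-fruit
#'   value = individual mean + Normal(0, within_tree_cv * collection mean),
#'   so protocol cells require positive environment means.
#' @param within_tree_cv coefficient of variation of repeated within-tree
#'   measurements (free parameter; the source studies report none).
#' @param phenotype_sd per-trait phenotypic standard-deviation scale: the
#'   within-collection genetic variance is calibrated to
#'   `h2 * phenotype_sd^2`. Keep the default (1) for unit-scale traits; give
#'   protocol traits a realistic scale (e.g. tens of grams for fruit weight)
#'   so genetic and within-tree variation are commensurate.
#' @param seed integer seed.
#' @return A list of class `pheno_sim_config`.
#' @export
pheno_sim_config <- function(trait_names,
                             h2_targets,
                             genetic_correlation_target = diag(length(trait_names)),
                             n_causal = 200,
                             gxe_variance_fraction = 0,
                             environment_means = 0,
                             protocol = list(),
                             within_tree_cv = 0.15,
                             phenotype_sd = 1,
                             seed = 1) {
  t <- length(trait_names)
  h2_targets <- rep_len(h2_targets, t)
  phenotype_sd <- rep_len(phenotype_sd, t)
  if (any(phenotype_sd <= 0)) stop("phenotype_sd must be positive")
  if (any(h2_targets <= 0 | h2_targets > 1)) stop("h2 targets must be in (0, 1]")
  S <- as.matrix(genetic_correlation_target)
  if (nrow(S) != t || ncol(S) != t || any(abs(diag(S) - 1) > 1e-8) ||
      any(abs(S - t(S)) > 1e-8))
    stop("genetic_correlation_target must be symmetric with unit diagonal")
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("genetic_correlation_target is not positive semi-definite")
  if (gxe_variance_fraction < 0 || gxe_variance_fraction >= 1)
    stop("gxe_variance_fraction must be in [0, 1)")
  if (n_causal < 1) stop("n_causal must be positive")
  check_entry <- function(pr)
    is.list(pr) && !is.null(pr$type) &&
      pr$type %in% c("mean_of_k", "max_of_k") && !is.null(pr$k) && pr$k >= 1
  for (pr in protocol) {
    if (check_entry(pr)) next
    if (is.list(pr) && length(pr) > 0 && all(vapply(pr, check_entry, logical(1))))
      next
    stop("protocol entries must be list(type = 'mean_of_k'|'max_of_k', k >= 1),",
         " optionally nested per collection")
  }
  structure(as.list(environment()), class = "pheno_sim_config")
}

# PSD square root via eigendecomposition (chol fails on singular targets,
# e.g. a correlation of exactly 1)
psd_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate phenotypes over simulated (or real) genotypes
#'
#' Generative model per trait: a shared causal-effect matrix drawn from a
#' zero-mean multivariate normal matching the target genetic correlation,
#' plus collection-specific effect deviations scaled so that the
#' collection-specific share of genetic variance equals
#' `gxe_variance_fraction`; genetic values are rescaled so the mean
#' within-collection genetic variance is `h2`, and residual variance is
#' calibrated per collection so within-collection heritability hits its
#' target. Traits with a recording protocol are recorded as the mean or max
#' of `k` per-fruit draws instead of receiving an explicit residual.
#'
#' @param geno a [geno_matrix] (mean-imputed internally if needed).
#' @param collections factor of per-individual collection labels.
#' @param config a [pheno_sim_config].
#' @return list with `pheno` (long data.frame: individual_id, collection,
#'   trait, value) and `truth` (breeding_values n x t, collection_deviations,
#'   causal_effects, realized_h2 per trait).
#' @export
simulate_phenotypes <- function(geno, collections, config) {
  stopifnot(inherits(config, "pheno_sim_config"))
  set.seed(config$seed)
  d <- impute_mean(geno)$dosages
  n <- nrow(d); m <- ncol(d)
  collections <- as.factor(collections)
  coll_levels <- levels(collections)
  nc <- length(coll_levels)
  tn <- config$trait_names; t <- length(tn)
  g <- config$gxe_variance_fraction
  R <- psd_sqrt(config$genetic_correlation_target)

  if (config$n_causal > m) stop("n_causal exceeds the number of markers")
  causal <- sort(sample.int(m, config$n_causal))
  Wc <- scale(d[, causal, drop = FALSE], center = TRUE, scale = FALSE)

  B0 <- matrix(stats::rnorm(config$n_causal * t), config$n_causal, t) %*% R
  Bdev <- lapply(seq_len(nc), function(c)
    matrix(stats::rnorm(config$n_causal * t), config$n_causal, t) %*% R)

  G_shared <- Wc %*% B0
  G <- sqrt(1 - g) * G_shared
  dev <- matrix(0, n, t)
  for (c in seq_len(nc)) {
    rows <- which(collections == coll_levels[c])
    dev[rows, ] <- sqrt(g) * (Wc[rows, , drop = FALSE] %*% Bdev[[c]])
  }
  G <- G + dev

  # rescale each trait so mean within-collection genetic variance equals h2
  scale_t <- numeric(t)
  for (j in seq_len(t)) {
    vg <- mean(tapply(G[, j], collections, stats::var))
    scale_t[j] <- sqrt(config$h2_targets[j] * config$phenotype_sd[j]^2 / vg)
    G[, j] <- G[, j] * scale_t[j]
    dev[, j] <- dev[, j] * scale_t[j]
  }

  emeans <- config$environment_means
  if (is.matrix(emeans)) {
    if (nrow(emeans) != nc || ncol(emeans) != t)
      stop("environment_means matrix must be collections x traits")
  } else {
    emeans <- matrix(rep_len(emeans, nc), nc, t)
  }

  # resolve a trait's protocol for one collection: NULL (iid residual), a
  # flat entry (all collections), or a per-collection nested entry
  resolve_protocol <- function(pr, coll) {
    if (is.null(pr)) return(NULL)
    if (!is.null(pr$type)) return(pr)
    pr[[coll]]
  }

  Y <- matrix(NA_real_, n, t, dimnames = list(rownames(d), tn))
  for (j in seq_len(t)) {
    for (c in seq_len(nc)) {
      pr <- resolve_protocol(config$protocol[[tn[j]]], coll_levels[c])
      rows <- which(collections == coll_levels[c])
      mu <- emeans[c, j] + G[rows, j]
      if (is.null(pr)) {
        h2 <- config$h2_targets[j]
        sd_e <- sqrt(stats::var(G[rows, j]) * (1 - h2) / h2)
        Y[rows, j] <- mu + stats::rnorm(length(rows), 0, sd_e)
      } else {
        if (emeans[c, j] <= 0)
          stop("protocol traits need positive environment means (within-tree ",
               "noise scales with the collection mean)")
        sd_fruit <- config$within_tree_cv * emeans[c, j]
        Y[rows, j] <- vapply(mu, function(mi)
          apply_protocol(stats::rnorm(pr$k, mi, sd_fruit), pr$type, pr$k),
          numeric(1))
      }
    }
  }

  realized_h2 <- vapply(seq_len(t), function(j) {
    mean(tapply(seq_len(n), collections, function(ix)
      stats::var(G[ix, j]) / stats::var(Y[ix, j])))
  }, numeric(1))
  names(realized_h2) <- tn

  pheno <- data.frame(
    individual_id = rep(rownames(d), t),
    collection = rep(as.character(collections), t),
    trait = rep(tn, each = n),
    value = as.vector(Y),
    stringsAsFactors = FALSE)

  # per-collection total effect vectors (shared + deviation), on the final
  # scale; the correlation of two collections' effects is 1 - g by design
  coll_eff <- lapply(seq_len(nc), function(c)
    sweep(sqrt(1 - g) * B0 + sqrt(g) * Bdev[[c]], 2, scale_t, "*"))
  names(coll_eff) <- coll_levels

  truth <- list(breeding_values = G,
                collection_deviations = dev,
                causal_index = causal,
                causal_effects = B0,
                collection_effects = coll_eff,
                scale = scale_t,
                realized_h2 = realized_h2)
  list(pheno = pheno, truth = truth)
}
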