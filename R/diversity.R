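#' Principal-component analysis of a genomic relationship matrix
#'
#' Eigendecomposition of the double-centered GRM. Coordinates are the
#' eigenvectors scaled by the square root of their (non-negative)
#' eigenvalues, so they match, up to sign, the individual scores of an SVD
#' of the centered dosage matrix. Variance fractions are eigenvalues over
#' the sum of positive eigenvalues.
#'
#' @param grm a `grm` object (or a plain symmetric matrix).
#' @param n_components number of components to return.
#' @return list with `coords` (n x k matrix, ID rownames), `var_frac`
#'   (length-k fractions) and `eigenvalues`.
#' @export
pca_from_grm <- function(grm, n_components = 10) {
  G <- if (inherits(grm, "grm")) grm$values else as.matrix(grm)
  n <- nrow(G)
  if (n_components > n) stop("n_components exceeds the number of individuals")
  Gc <- sweep(sweep(G, 1, rowMeans(G)), 2, colMeans(G)) + mean(G)
  e <- eigen(Gc, symmetric = TRUE)
  lam <- e$values
  pos <- pmax(lam, 0)
  k <- seq_len(n_components)
  coords <- e$vectors[, k, drop = FALSE] %*% diag(sqrt(pos[k]), n_components)
  rownames(coords) <- rownames(G)
  colnames(coords) <- paste0("PC", k)
  total <- sum(pos)
  list(coords = coords,
       var_frac = if (total > 0) pos[k] / total else rep(0, n_components),
       eigenvalues = lam)
}

# standardized marker columns (zero mean, unit sd); zero-variance -> NA column
std_cols <- function(x) {
  mu <- colMeans(x)
  s <- sqrt(colMeans(x^2) - mu^2)
  s[s == 0] <- NA
  sweep(sweep(x, 2, mu), 2, s, "/")
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Phased mode computes the haplotype r^2 = D^2 / (p1 q1 p2 q2) (equivalently
#' the squared correlation of the 0/1 haplotype indicator columns); unphased
#' mode is the squared dosage correlation (composite LD). Pairs involving a
#' monomorphic marker are skipped and their count reported.
#'
#' @param geno a [geno_matrix].
#' @param markers integer indices of the markers to pair (all by default);
#'   must lie on one chromosome unless `within_chromosome = FALSE`.
#' @param phased use haplotypes (default: yes when available).
#' @param within_chromosome require all markers on one chromosome.
#' @return data.frame (i, j, distance_bp, r2) with attribute `n_skipped`
#'   and attribute `mode` (`"phased"` or `"unphased"`).
#' @export
pairwise_r2 <- function(geno, markers = NULL, phased = NULL,
                        within_chromosome = TRUE) {
  if (is.null(markers)) markers <- seq_len(ncol(geno$dosages))
  if (is.null(phased)) phased <- !is.null(geno$hap1)
  if (phased && is.null(geno$hap1))
    stop("phased r2 requested but the genotypes carry no haplotypes")
  if (within_chromosome && length(unique(geno$chrom[markers])) > 1)
    stop("markers span several chromosomes; use within_chromosome = FALSE")
  X <- if (phased) {
    rbind(geno$hap1[, markers, drop = FALSE], geno$hap2[, markers, drop = FALSE])
  } else {
    geno$dosages[, markers, drop = FALSE]
  }
  if (anyNA(X)) stop("r2 requires complete calls; filter or impute first")
  Z <- std_cols(X)
  R <- crossprod(Z) / nrow(Z)
  r2 <- R^2
  k <- length(markers)
  ut <- which(upper.tri(r2), arr.ind = TRUE)
  vals <- r2[ut]
  skip <- is.na(vals)
  out <- data.frame(i = markers[ut[, 1]][!skip], j = markers[ut[, 2]][!skip],
                    distance_bp = abs(geno$pos[markers[ut[, 2]]] -
                                        geno$pos[markers[ut[, 1]]])[!skip],
                    r2 = vals[!skip])
  attr(out, "n_skipped") <- sum(skip)
  attr(out, "mode") <- if (phased) "phased" else "unphased"
  out
}

#' Background LD threshold from unlinked marker pairs
#'
#' Samples markers per chromosome, computes r^2 for all pairs on *different*
#' chromosomes, and returns the 99th percentile: the level of apparent LD
#' expected between physically unlinked loci (driven by sample size and
#' population structure), below which decay curves are read as background.
#'
#' @param geno a complete [geno_matrix] with at least two chromosomes.
#' @param snps_per_chromosome markers sampled per chromosome.
#' @param phased use haplotype r^2 (default when haplotypes are present).
#' @param quantile_level percentile used (default 0.99).
#' @param seed sampling seed.
#' @return the threshold (scalar), with attribute `n_pairs`.
#' @export
background_threshold <- function(geno, snps_per_chromosome = 1000,
                                 phased = NULL, quantile_level = 0.99,
                                 seed = 1) {
  chroms <- unique(geno$chrom)
  if (length(chroms) < 2) stop("need at least two chromosomes for unlinked pairs")
  if (is.null(phased)) phased <- !is.null(geno$hap1)
  set.seed(seed)
  picked <- lapply(chroms, function(ch) {
    ix <- which(geno$chrom == ch)
    if (length(ix) > snps_per_chromosome)
      ix <- sort(sample(ix, snps_per_chromosome))
    ix
  })
  X <- if (phased) rbind(geno$hap1, geno$hap2) else geno$dosages
  if (anyNA(X)) stop("r2 requires complete calls; filter or impute first")
  Z <- std_cols(X)
  vals <- numeric(0)
  for (a in seq_along(chroms)[-length(chroms)]) {
    for (b in (a + 1):length(chroms)) {
      R <- crossprod(Z[, picked[[a]], drop = FALSE],
                     Z[, picked[[b]], drop = FALSE]) / nrow(Z)
      vals <- c(vals, as.vector(R^2))
    }
  }
  vals <- vals[!is.na(vals)]
  out <- stats::quantile(vals, quantile_level, names = FALSE)
  attr(out, "n_pairs") <- length(vals)
  out
}

#' LD-decay curve and threshold-crossing distance
#'
#' Bins within-chromosome pairwise r^2 by physical distance, averages per
#' bin, smooths by a running mean followed by a monotone (non-increasing)
#' envelope, and reports the first bin midpoint at which the smoothed curve
#' falls below the background threshold.
#'
#' @param geno a complete [geno_matrix].
#' @param snps_per_chromosome markers sampled per chromosome.
#' @param bin_width,max_distance binning of pair distance in bp.
#' @param threshold background r^2 threshold (see [background_threshold]);
#'   when `NULL` no crossing is computed.
#' @param smooth_window running-mean window, in bins.
#' @param phased use haplotype r^2 (default when haplotypes are present).
#' @param seed sampling seed.
#' @return list with `curve` (data.frame mid, mean_r2, n_pairs, smoothed),
#'   `threshold`, and `crossing_distance_bp` (`NA` when the curve never
#'   drops below the threshold within `max_distance`).
#' @export
ld_decay <- function(geno, snps_per_chromosome = 10000, bin_width = 100,
                     max_distance = 1e5, threshold = NULL, smooth_window = 5,
                     phased = NULL, seed = 1) {
  if (is.null(phased)) phased <- !is.null(geno$hap1)
  set.seed(seed)
  chroms <- unique(geno$chrom)
  breaks <- seq(0, max_distance, by = bin_width)
  nb <- length(breaks) - 1
  sum_r2 <- n_pair <- numeric(nb)
  X <- if (phased) rbind(geno$hap1, geno$hap2) else geno$dosages
  if (anyNA(X)) stop("r2 requires complete calls; filter or impute first")
  for (ch in chroms) {
    ix <- which(geno$chrom == ch)
    if (length(ix) > snps_per_chromosome)
      ix <- sort(sample(ix, snps_per_chromosome))
    pos <- geno$pos[ix]
    Z <- std_cols(X[, ix, drop = FALSE])
    keep <- which(!is.na(Z[1, ]))
    Z <- Z[, keep, drop = FALSE]; pos <- pos[keep]
    mch <- length(pos)
    if (mch < 2) next
    # two-pointer sweep over distance-limited pairs
    hi <- 1L
    for (i in seq_len(mch - 1)) {
      while (hi < mch && pos[hi + 1] - pos[i] <= max_distance) hi <- hi + 1L
      if (hi <= i) next
      jj <- (i + 1):hi
      r <- as.vector(crossprod(Z[, i], Z[, jj, drop = FALSE])) / nrow(Z)
      dbin <- pmin(pmax(ceiling((pos[jj] - pos[i]) / bin_width), 1L), nb)
      agg <- rowsum(cbind(r^2, 1), dbin)
      bi <- as.integer(rownames(agg))
      sum_r2[bi] <- sum_r2[bi] + agg[, 1]
      n_pair[bi] <- n_pair[bi] + agg[, 2]
    }
  }
  mid <- breaks[-1] - bin_width / 2
  mean_r2 <- ifelse(n_pair > 0, sum_r2 / n_pair, NA)
  # running mean over occupied bins, then non-increasing envelope
  occ <- which(!is.na(mean_r2))
  smoothed <- rep(NA_real_, nb)
  if (length(occ) > 0) {
    v <- mean_r2[occ]
    half <- floor(smooth_window / 2)
    sm <- vapply(seq_along(v), function(i)
      mean(v[max(1, i - half):min(length(v), i + half)]), numeric(1))
    smoothed[occ] <- cummin(sm)
  }
  crossing <- NA_real_
  if (!is.null(threshold)) {
    below <- which(!is.na(smoothed) & smoothed < threshold)
    if (length(below) > 0) crossing <- mid[below[1]]
  }
  list(curve = data.frame(mid = mid, mean_r2 = mean_r2, n_pairs = n_pair,
                          smoothed = smoothed),
       threshold = threshold,
       crossing_distance_bp = crossing)
}

#' Effective number of independent SNPs (eigenvalue block correction)
#'
#' Li-Ji/Galwey-family estimate: markers are processed in consecutive
#' within-chromosome blocks; for each block the eigenvalues of the marker
#' correlation matrix are computed and the block's effective count is
#' `m_block - sum over lambda > 1 of (lambda - 1)`; block counts are summed.
#' Independent markers give Me = m, fully duplicated pairs give m/2.
#'
#' @param geno a complete [geno_matrix].
#' @param block_size markers per block (consecutive, non-overlapping).
#' @param alpha significance level for the Bonferroni-style threshold.
#' @return list of class `gec_result`: `me`, `m` (markers used),
#'   `n_excluded` (zero-variance markers dropped), `significant_threshold`
#'   (= alpha/Me), `suggestive_threshold` (= 1/Me), `block_size`.
#' @export
effective_snp_count <- function(geno, block_size = 200, alpha = 0.05) {
  d <- geno$dosages
  if (anyNA(d)) stop("requires complete dosages; impute first")
  v <- apply(d, 2, stats::var)
  excl <- v == 0
  if (any(excl)) message(sum(excl), " zero-variance marker(s) excluded")
  me <- 0
  m_used <- 0
  for (ch in unique(geno$chrom)) {
    ix <- which(geno$chrom == ch & !excl)
    m_used <- m_used + length(ix)
    for (start in seq(1, length(ix), by = block_size)) {
      blk <- ix[start:min(start + block_size - 1, length(ix))]
      if (length(blk) == 1) { me <- me + 1; next }
      lam <- eigen(stats::cor(d[, blk, drop = FALSE]), symmetric = TRUE,
                   only.values = TRUE)$values
      me <- me + length(blk) - sum(pmax(lam - 1, 0))
    }
  }
  thr <- gwas_thresholds(me, alpha = alpha, m_total = m_used)
  structure(list(me = me, m = m_used, n_excluded = sum(excl),
                 significant_threshold = thr$significant,
                 suggestive_threshold = thr$suggestive,
                 block_size = block_size),
            class = "gec_result")
}

#' @exportS3Method base::print
print.gec_result <- function(x, ...) {
  cat(sprintf(
    "effective SNPs: Me = %.1f of m = %d (%.1f%%); significant p < %.3g, suggestive p < %.3g\n",
    x$me, x$m, 100 * x$me / x$m, x$significant_threshold,
    x$suggestive_threshold))
  invisible(x)
}

#' Genome-wide significance thresholds from the effective SNP count
#'
#' Bonferroni correction on the effective number of independent tests:
#' significant = alpha / Me; suggestive = 1 / Me (one false positive
#' expected per scan).
#'
#' @param me effective number of independent SNPs (>= 1).
#' @param alpha family-wise error rate (default 0.05).
#' @param m_total optional total marker count, used to report the
#'   independent fraction.
#' @return list with `significant`, `suggestive`, and (when `m_total` is
#'   given) `independent_fraction_pct` (= 100 Me / m, rounded to 0.1).
#' @export
gwas_thresholds <- function(me, alpha = 0.05, m_total = NULL) {
  if (me < 1) stop("Me must be >= 1")
  out <- list(significant = alpha / me, suggestive = 1 / me)
  if (!is.null(m_total))
    out$independent_fraction_pct <- round(100 * me / m_total, 1)
  out
}
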