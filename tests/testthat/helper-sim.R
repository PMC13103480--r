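# shared fixtures and independent oracles, all built in code

# polymorphic HWE panel plus its GRM
make_grm_panel <- function(n, m, seed, n_chromosomes = 1) {
  geno <- filter_variants(sim_hwe_panel(n, m, n_chromosomes = n_chromosomes,
                                        seed = seed), min_maf = 0.01)
  list(geno = geno, grm = compute_grm(geno))
}

# polygenic phenotype over all markers with a target h2 (realized exactly in
# sample variance terms)
sim_polygenic_y <- function(geno, h2, seed) {
  set.seed(seed)
  W <- sweep(geno$dosages, 2, colMeans(geno$dosages))
  gv <- drop(W %*% stats::rnorm(ncol(W)))
  gv <- gv / stats::sd(gv) * sqrt(h2)
  y <- gv + stats::rnorm(nrow(W), 0, sqrt(1 - h2))
  names(y) <- rownames(geno$dosages)
  attr(y, "gv") <- gv
  y
}

# two polygenic traits with genetic correlation rg and common h2
sim_corr_traits <- function(geno, rg, h2, seed) {
  set.seed(seed)
  m <- ncol(geno$dosages)
  W <- sweep(geno$dosages, 2, colMeans(geno$dosages))
  B <- matrix(stats::rnorm(m * 2), m, 2) %*% chol(matrix(c(1, rg, rg, 1), 2))
  gv <- W %*% B
  gv <- sweep(gv, 2, apply(gv, 2, stats::sd), "/") * sqrt(h2)
  Y <- gv + matrix(stats::rnorm(nrow(W) * 2), ncol = 2) * sqrt(1 - h2)
  rownames(Y) <- rownames(geno$dosages)
  Y
}

# dense closed-form REML log-likelihood, independent of the package's
# rotated implementation
dense_reml_ll <- function(K, X, y) {
  n <- length(y)
  function(s2g, s2e) {
    V <- s2g * K + s2e * diag(n)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    Vi <- chol2inv(ch)
    C <- t(X) %*% Vi %*% X
    beta <- solve(C, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    as.numeric(-0.5 * (2 * sum(log(diag(ch))) +
                         determinant(C, logarithm = TRUE)$modulus +
                         t(r) %*% Vi %*% r))
  }
}

# brute-force REML maximiser: zooming 2-D grid over (h2, total variance)
grid_reml_h2 <- function(K, X, y, n_zoom = 4, grid_n = 60) {
  ll_fun <- dense_reml_ll(K, X, y)
  vy <- stats::var(y)
  lo <- c(0.001, vy * 0.2); hi <- c(0.999, vy * 3)
  h2b <- vtb <- NA
  for (zoom in seq_len(n_zoom)) {
    h2g <- seq(lo[1], hi[1], length.out = grid_n)
    vtg <- seq(lo[2], hi[2], length.out = grid_n)
    ll <- outer(h2g, vtg, Vectorize(function(h, v) ll_fun(h * v, (1 - h) * v)))
    ix <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    h2b <- h2g[ix[1]]; vtb <- vtg[ix[2]]
    dh <- diff(h2g[1:2]) * 2; dv <- diff(vtg[1:2]) * 2
    lo <- c(max(1e-4, h2b - dh), max(vy * 0.01, vtb - dv))
    hi <- c(min(0.9999, h2b + dh), vtb + dv)
  }
  list(h2 = h2b, vtot = vtb)
}

# dosage matrix whose columns have exactly pairwise correlation 0.5:
# full factorial over 4 balanced bits, marker j = u_j + u_4
dosages_cor_half <- function() {
  u <- as.matrix(expand.grid(0:1, 0:1, 0:1, 0:1))
  cbind(u[, 1] + u[, 4], u[, 2] + u[, 4], u[, 3] + u[, 4])
}

# dosage matrix with exactly orthogonal (zero-correlation) columns:
# full factorial over k balanced bits, scaled to {0, 2}
dosages_orthogonal <- function(k = 3) {
  2 * as.matrix(expand.grid(rep(list(0:1), k)))
}
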