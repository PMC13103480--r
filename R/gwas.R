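#' Mixed-linear-model association scan
#'
#' Per-marker test of `y = X b + s beta + g + e` with a polygenic effect
#' `g ~ N(0, K sigma2_G)`. The GRM is eigendecomposed once. In the default
#' P3D mode the variance components are estimated once under the null model
#' (no marker) by [greml_single] and held fixed per marker, giving a
#' generalized-least-squares test in the rotated basis; in exact mode the
#' variance ratio is re-optimized for every marker by one-dimensional search
#' on the profiled restricted likelihood. Wald p-values against the normal.
#'
#' @param y complete numeric response.
#' @param geno a complete [geno_matrix] aligned with `y` (rows matched by
#'   name when both carry IDs).
#' @param grm a `grm` object or matrix.
#' @param X fixed covariates (intercept added automatically; pass e.g. a
#'   dataset-ID one-hot block for multi-collection scans).
#' @param maf_min minor-allele-frequency cutoff; markers below it are
#'   excluded from the result (default 0.05).
#' @param method `"p3d"` (default) or `"exact"`.
#' @return list of class `gwas_result`: `table` (data.frame marker, chrom,
#'   pos, maf, beta, se, stat, p), `lambda_gc`, `null_fit`, `method`, `n`,
#'   `maf_min`.
#' @export
mlm_scan <- function(y, geno, grm, X = NULL, maf_min = 0.05,
                     method = c("p3d", "exact")) {
  method <- match.arg(method)
  G <- if (inherits(grm, "grm")) grm$values else as.matrix(grm)
  d <- geno$dosages
  if (anyNA(d)) stop("scan requires complete dosages; impute first")
  if (!is.null(names(y)) && !is.null(rownames(d))) {
    d <- d[names(y), , drop = FALSE]
    G <- G[names(y), names(y)]
  }
  n <- length(y)
  X0 <- cbind(`(Intercept)` = rep(1, n), X)

  p <- colMeans(d) / 2
  maf <- pmin(p, 1 - p)
  keep <- which(maf > maf_min)

  null_fit <- greml_single(y, G, X0)
  e <- eigen(G, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  U <- e$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X0)
  St <- crossprod(U, d[, keep, drop = FALSE])

  if (method == "p3d") {
    w <- null_fit$sigma2_g * lambda + null_fit$sigma2_e
    Wi <- 1 / w
    C <- crossprod(Xt, Xt * Wi)
    Ci <- solve(C)
    # M = W^-1 - W^-1 X (X'W^-1X)^-1 X'W^-1, applied columnwise
    WiX <- Xt * Wi
    My <- yt * Wi - WiX %*% (Ci %*% crossprod(Xt, yt * Wi))
    MS <- St * Wi - WiX %*% (Ci %*% crossprod(WiX, St))
    sMs <- colSums(St * MS)
    sMy <- drop(crossprod(St, My))
    bad <- sMs < 1e-10
    beta <- ifelse(bad, NA, sMy / sMs)
    se <- ifelse(bad, NA, sqrt(1 / sMs))
  } else {
    m <- length(keep)
    beta <- se <- rep(NA_real_, m)
    pfix <- ncol(Xt) + 1
    for (j in seq_len(m)) {
      Xj <- cbind(Xt, St[, j])
      prof <- function(logdel) {
        w <- exp(logdel) * lambda + 1
        Wi <- 1 / w
        C <- crossprod(Xj, Xj * Wi)
        ch <- tryCatch(chol(C), error = function(e) NULL)
        if (is.null(ch)) return(1e10)
        b <- backsolve(ch, backsolve(ch, crossprod(Xj, yt * Wi),
                                     transpose = TRUE))
        r <- yt - Xj %*% b
        rss <- sum(r^2 * Wi)
        0.5 * ((n - pfix) * log(rss) + sum(log(w)) + 2 * sum(log(diag(ch))))
      }
      opt <- stats::optimize(prof, c(-12, 12))
      w <- exp(opt$minimum) * lambda + 1
      Wi <- 1 / w
      C <- crossprod(Xj, Xj * Wi)
      Ci <- tryCatch(solve(C), error = function(e) NULL)
      if (is.null(Ci)) next
      b <- Ci %*% crossprod(Xj, yt * Wi)
      s2 <- sum((yt - Xj %*% b)^2 * Wi) / (n - pfix)
      beta[j] <- b[pfix]
      se[j] <- sqrt(s2 * Ci[pfix, pfix])
    }
  }

  stat <- beta / se
  pval <- 2 * stats::pnorm(-abs(stat))
  tab <- data.frame(marker = keep, chrom = geno$chrom[keep],
                    pos = geno$pos[keep], maf = maf[keep],
                    beta = beta, se = se, stat = stat, p = pval,
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 lambda_gc = inflation_lambda(pval[!is.na(pval)]),
                 null_fit = null_fit, method = method, n = n,
                 maf_min = maf_min),
            class = "gwas_result")
}

#' @exportS3Method base::print
print.gwas_result <- function(x, ...) {
  cat(sprintf("MLM scan (%s): %d markers, n = %d, lambda_gc = %.3f\n",
              x$method, nrow(x$table), x$n, x$lambda_gc))
  invisible(x)
}

#' Genomic inflation factor
#'
#' `lambda_gc` = median observed 1-df chi-square statistic over its null
#' median (0.4549...). Values near 1 indicate a well-calibrated scan.
#'
#' @param p_values vector of p-values (>= 100 recommended; fewer triggers a
#'   warning but the statistic is still computed).
#' @return lambda_gc (scalar).
#' @export
inflation_lambda <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) < 100)
    warning("lambda_gc computed on fewer than 100 p-values")
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Cluster passing markers into QTLs by positional merging
#'
#' Markers below the suggestive threshold are sorted by position within
#' chromosome; consecutive passing markers at most `merge_window_bp` apart
#' join one cluster. A cluster is tiered `"significant"` when any member is
#' below the significant threshold, else `"suggestive"`. The lead marker is
#' the member with the smallest p-value.
#'
#' @param gwas a `gwas_result` (or its `$table`).
#' @param significant_threshold,suggestive_threshold p-value thresholds
#'   (see [gwas_thresholds]).
#' @param merge_window_bp merge distance (default 200 kb).
#' @return data.frame: chrom, start, end, n_markers, lead_marker, lead_pos,
#'   lead_p, tier. Zero rows when nothing passes.
#' @export
cluster_qtls <- function(gwas, significant_threshold, suggestive_threshold,
                         merge_window_bp = 2e5) {
  tab <- if (inherits(gwas, "gwas_result")) gwas$table else gwas
  hits <- tab[!is.na(tab$p) & tab$p < suggestive_threshold, , drop = FALSE]
  out <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                    n_markers = integer(0), lead_marker = integer(0),
                    lead_pos = integer(0), lead_p = numeric(0),
                    tier = character(0), stringsAsFactors = FALSE)
  if (nrow(hits) == 0) return(out)
  hits <- hits[order(hits$chrom, hits$pos), ]
  cl_id <- integer(nrow(hits))
  id <- 0
  for (i in seq_len(nrow(hits))) {
    if (i == 1 || hits$chrom[i] != hits$chrom[i - 1] ||
        hits$pos[i] - hits$pos[i - 1] > merge_window_bp) id <- id + 1
    cl_id[i] <- id
  }
  do.call(rbind, lapply(split(hits, cl_id), function(h) {
    lead <- which.min(h$p)
    data.frame(chrom = h$chrom[1], start = min(h$pos), end = max(h$pos),
               n_markers = nrow(h), lead_marker = h$marker[lead],
               lead_pos = h$pos[lead], lead_p = h$p[lead],
               tier = if (any(h$p < significant_threshold)) "significant"
                      else "suggestive",
               stringsAsFactors = FALSE)
  }))
}
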