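#' @useDynLib mangoGP, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# rotated REML machinery for y = Xb + g + e, Var = s2g * K + s2e * I.
# Everything is evaluated in the eigenbasis of K, so one likelihood
# evaluation is O(n p^2).
rotated_reml <- function(yt, Xt, lambda, s2g, s2e) {
  w <- s2g * lambda + s2e
  Wi <- 1 / w
  C <- crossprod(Xt, Xt * Wi)              # X' W^-1 X
  Ci <- solve(C)
  beta <- Ci %*% crossprod(Xt, yt * Wi)
  r <- yt - Xt %*% beta
  Py <- as.vector(r * Wi)                  # P y in the rotated basis
  ll <- -0.5 * (sum(log(w)) + determinant(C, logarithm = TRUE)$modulus +
                  sum(r * Py))
  list(ll = as.numeric(ll), Py = Py, Wi = Wi, Ci = Ci, Xt = Xt, beta = beta)
}

# tr(P dV) for dV diagonal (dv = lambda or 1) in the rotated basis
trace_P_diag <- function(state, dv) {
  WiX <- state$Xt * state$Wi
  sum(dv * state$Wi) - sum((WiX %*% state$Ci) * (WiX * dv))
}

#' Single-trait GREML by average-information REML
#'
#' Estimates the additive genomic variance and residual variance of
#' `y = X b + g + e`, `g ~ N(0, K sigma2_G)`, by AI-REML in the eigenbasis
#' of the GRM (one O(n^3) eigendecomposition, O(n) per iteration). When an
#' AI step proposes an out-of-bounds update, or would decrease the
#' restricted likelihood, an EM step (with step halving) is used instead, so
#' the accepted likelihood sequence is non-decreasing. Variances are
#' constrained to at least `1e-8 * var(y)`. Standard errors come from the
#' inverse AI matrix; the h2 standard error by the delta method.
#'
#' @param y numeric response (complete; names may carry individual IDs).
#' @param grm a `grm` object or n x n matrix aligned with `y` (when `y` has
#'   names and the GRM has dimnames, rows are matched by ID).
#' @param X fixed-effect design matrix (default: intercept only).
#' @param tol convergence tolerance on the change in restricted
#'   log-likelihood (default 1e-6).
#' @param max_iter maximum AI/EM iterations.
#' @return list of class `varcomp`: `sigma2_g`, `sigma2_e`, `h2`, standard
#'   errors, `beta`, `loglik`, `converged`, `n_iter`, `boundary` flag.
#' @export
greml_single <- function(y, grm, X = NULL, tol = 1e-6, max_iter = 100) {
  G <- if (inherits(grm, "grm")) grm$values else as.matrix(grm)
  if (!is.null(names(y)) && !is.null(rownames(G))) {
    if (!all(names(y) %in% rownames(G)))
      stop("individual(s) in y absent from the GRM")
    G <- G[names(y), names(y)]
  }
  n <- length(y)
  if (n < 30) warning("GREML with n < 30 is unreliable")
  vy <- stats::var(y)
  if (vy == 0) stop("y has zero variance")
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)

  e <- eigen(G, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  yt <- crossprod(e$vectors, y)
  Xt <- crossprod(e$vectors, X)

  lb <- 1e-8 * vy
  th <- c(vy / 2, vy / 2)                  # (sigma2_g, sigma2_e)
  st <- rotated_reml(yt, Xt, lambda, th[1], th[2])
  converged <- FALSE
  AI <- diag(2)
  iter <- 0
  for (iter in seq_len(max_iter)) {
    Py <- st$Py
    # scores and AI for dV = (Lambda, I)
    PdPy <- list(lambda * Py, Py)
    score <- vapply(1:2, function(k) {
      dv <- if (k == 1) lambda else rep(1, n)
      -0.5 * (trace_P_diag(st, dv) - sum(Py * dv * Py))
    }, numeric(1))
    # P applied to a vector
    Pv <- function(v) {
      u <- v * st$Wi
      u - (st$Xt * st$Wi) %*% (st$Ci %*% crossprod(st$Xt, u))
    }
    AI <- matrix(0, 2, 2)
    PdV <- lapply(PdPy, Pv)
    for (a in 1:2) for (b in 1:2)
      AI[a, b] <- 0.5 * sum(PdPy[[a]] * PdV[[b]])

    step_ok <- FALSE
    prop <- tryCatch(th + solve(AI, score), error = function(e) rep(NA, 2))
    if (all(is.finite(prop))) {
      # out-of-bounds AI proposals are projected onto the boundary first
      prop <- pmax(prop, lb)
      st2 <- rotated_reml(yt, Xt, lambda, prop[1], prop[2])
      if (st2$ll >= st$ll - 1e-10) step_ok <- TRUE
    }
    if (!step_ok) {
      # EM direction with step halving; guarantees non-decreasing likelihood
      em <- pmax(th + (2 * th^2 / n) * score, lb)
      repeat {
        st2 <- rotated_reml(yt, Xt, lambda, em[1], em[2])
        if (st2$ll >= st$ll - 1e-10) { prop <- em; break }
        em <- th + (em - th) / 2
        if (max(abs(em - th)) < 1e-14 * vy) { prop <- th; st2 <- st; break }
      }
    }
    dll <- st2$ll - st$ll
    th <- pmax(prop, lb)
    st <- st2
    if (abs(dll) < tol) { converged <- TRUE; break }
  }

  V <- tryCatch(solve(AI), error = function(e) matrix(NA, 2, 2))
  s2g <- th[1]; s2e <- th[2]
  h2 <- s2g / (s2g + s2e)
  grad <- c(s2e, -s2g) / (s2g + s2e)^2
  se_h2 <- sqrt(max(0, drop(t(grad) %*% V %*% grad)))
  structure(list(sigma2_g = s2g, sigma2_e = s2e, h2 = h2,
                 se_sigma2_g = sqrt(pmax(V[1, 1], 0)),
                 se_sigma2_e = sqrt(pmax(V[2, 2], 0)),
                 se_h2 = se_h2,
                 beta = drop(st$beta), loglik = st$ll,
                 converged = converged, n_iter = iter,
                 boundary = any(th <= lb * 1.01)),
            class = "varcomp")
}

#' @exportS3Method base::print
print.varcomp <- function(x, ...) {
  cat(sprintf("GREML: h2 = %.3f (SE %.3f), s2_G = %.4g, s2_e = %.4g, logL = %.3f%s\n",
              x$h2, x$se_h2, x$sigma2_g, x$sigma2_e, x$loglik,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Reliability gate on a heritability estimate
#'
#' A trait is admitted to bivariate genetic-correlation analysis only if the
#' standard deviation of its heritability estimate does not exceed the
#' estimate itself (boundary counts as reliable).
#'
#' @param h2_estimate estimated heritability.
#' @param h2_sd its standard deviation / standard error (>= 0).
#' @return logical: include the trait?
#' @export
reliability_gate <- function(h2_estimate, h2_sd) {
  if (any(h2_sd < 0)) stop("h2_sd must be non-negative")
  h2_sd <= h2_estimate
}

# bivariate REML log-likelihood in the GRM eigenbasis; th parameterises
# Cholesky factors of G0 and R0 (logs on the diagonals)
biv_theta_to_cov <- function(th) {
  L <- matrix(c(exp(th[1]), th[2], 0, exp(th[3])), 2, 2)
  M <- matrix(c(exp(th[4]), th[5], 0, exp(th[6])), 2, 2)
  list(G0 = L %*% t(L), R0 = M %*% t(M))
}

biv_loglik <- function(th, y1t, y2t, X1t, X2t, lambda) {
  cv <- biv_theta_to_cov(th)
  G0 <- cv$G0; R0 <- cv$R0
  a <- G0[1, 1] * lambda + R0[1, 1]
  b <- G0[2, 2] * lambda + R0[2, 2]
  cc <- G0[1, 2] * lambda + R0[1, 2]
  det_i <- a * b - cc^2
  if (any(det_i <= 0)) return(-1e10)
  ia <- b / det_i; ib <- a / det_i; ic <- -cc / det_i
  p1 <- ncol(X1t); p2 <- ncol(X2t)
  C <- matrix(0, p1 + p2, p1 + p2)
  C[1:p1, 1:p1] <- crossprod(X1t, X1t * ia)
  C[p1 + 1:p2, p1 + 1:p2] <- crossprod(X2t, X2t * ib)
  C12 <- crossprod(X1t, X2t * ic)
  C[1:p1, p1 + 1:p2] <- C12
  C[p1 + 1:p2, 1:p1] <- t(C12)
  bv <- c(crossprod(X1t, ia * y1t + ic * y2t),
          crossprod(X2t, ib * y2t + ic * y1t))
  yVy <- sum(ia * y1t^2 + ib * y2t^2 + 2 * ic * y1t * y2t)
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) return(-1e10)
  quad <- yVy - sum(backsolve(ch, bv, transpose = TRUE)^2)
  -0.5 * (sum(log(det_i)) + 2 * sum(log(diag(ch))) + quad)
}

#' Bivariate GREML: genetic correlation between two traits
#'
#' Fits 2x2 genetic and residual covariance matrices for two traits measured
#' on the same individuals, by direct restricted-likelihood maximisation
#' over Cholesky factors of the two covariance matrices (which enforces
#' positive semi-definiteness, hence `r_g` in [-1, 1], by construction). The
#' likelihood is evaluated in the GRM eigenbasis, where the rotated records
#' decouple into per-individual 2x2 blocks, so one evaluation is O(n).
#' Standard errors come from the numerical Hessian at the optimum with a
#' delta-method transform to `r_g`.
#'
#' Both traits must pass the [reliability_gate] on their univariate fits
#' unless `gate = FALSE`.
#'
#' @param y1,y2 numeric responses on the same individuals (same order).
#' @param grm a `grm` object or matrix aligned with the responses.
#' @param X1,X2 per-trait fixed-effect designs (default intercepts).
#' @param gate apply the reliability gate (default TRUE).
#' @return list of class `gencor`: `r_g`, `se_r_g`, `G0`, `R0`, per-trait
#'   `h2` (from the bivariate fit), univariate gate fits, `loglik`,
#'   `converged`.
#' @export
greml_bivariate <- function(y1, y2, grm, X1 = NULL, X2 = NULL, gate = TRUE) {
  G <- if (inherits(grm, "grm")) grm$values else as.matrix(grm)
  n <- length(y1)
  if (length(y2) != n)
    stop("y1 and y2 must be recorded on the same individuals (same length)")
  if (!is.null(names(y1)) && !is.null(rownames(G))) G <- G[names(y1), names(y1)]
  if (is.null(X1)) X1 <- matrix(1, n, 1)
  if (is.null(X2)) X2 <- matrix(1, n, 1)

  uni1 <- greml_single(y1, G, X1)
  uni2 <- greml_single(y2, G, X2)
  if (gate) {
    ok1 <- reliability_gate(uni1$h2, uni1$se_h2)
    ok2 <- reliability_gate(uni2$h2, uni2$se_h2)
    if (!ok1 || !ok2)
      stop("reliability gate failed (h2 SE exceeds h2) for trait ",
           paste(which(!c(ok1, ok2)), collapse = " and "),
           "; rerun with gate = FALSE to override")
  }

  s1 <- stats::sd(y1); s2 <- stats::sd(y2)
  e <- eigen(G, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  y1t <- drop(crossprod(e$vectors, y1 / s1))
  y2t <- drop(crossprod(e$vectors, y2 / s2))
  X1t <- crossprod(e$vectors, as.matrix(X1))
  X2t <- crossprod(e$vectors, as.matrix(X2))

  nll <- function(th) -biv_loglik(th, y1t, y2t, X1t, X2t, lambda)
  init <- c(0.5 * log(max(uni1$h2, 0.05)), 0,
            0.5 * log(max(uni2$h2, 0.05)),
            0.5 * log(max(1 - uni1$h2, 0.05)), 0,
            0.5 * log(max(1 - uni2$h2, 0.05)))
  lo <- c(-8, -20, -8, -8, -20, -8)
  hi <- c(4, 20, 4, 4, 20, 4)
  fit <- stats::optim(init, nll, method = "L-BFGS-B", lower = lo, upper = hi,
                      control = list(maxit = 500, factr = 1e4))
  cv <- biv_theta_to_cov(fit$par)
  S <- diag(c(s1, s2))
  G0 <- S %*% cv$G0 %*% S
  R0 <- S %*% cv$R0 %*% S
  r_g <- G0[1, 2] / sqrt(G0[1, 1] * G0[2, 2])
  h2 <- diag(G0) / (diag(G0) + diag(R0))

  # delta-method SE for r_g from the numerical Hessian
  se_r_g <- NA_real_
  H <- tryCatch(stats::optimHess(fit$par, nll), error = function(e) NULL)
  if (!is.null(H)) {
    Vp <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vp)) {
      rg_of <- function(th) {
        g0 <- biv_theta_to_cov(th)$G0
        g0[1, 2] / sqrt(g0[1, 1] * g0[2, 2])
      }
      gr <- numeric(6)
      hstep <- 1e-5
      for (k in 1:6) {
        tp <- fit$par; tp[k] <- tp[k] + hstep
        tm <- fit$par; tm[k] <- tm[k] - hstep
        gr[k] <- (rg_of(tp) - rg_of(tm)) / (2 * hstep)
      }
      se_r_g <- sqrt(max(0, drop(t(gr) %*% Vp %*% gr)))
    }
  }
  structure(list(r_g = r_g, se_r_g = se_r_g, G0 = G0, R0 = R0, h2 = h2,
                 univariate = list(uni1, uni2),
                 loglik = -fit$value, converged = fit$convergence == 0),
            class = "gencor")
}

#' @exportS3Method base::print
print.gencor <- function(x, ...) {
  cat(sprintf("bivariate GREML: r_g = %.3f (SE %.3f), h2 = %.3f / %.3f%s\n",
              x$r_g, x$se_r_g, x$h2[1], x$h2[2],
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}
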