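#' Kernel sets for the five genomic-prediction models
#'
#' Builds the record-level covariance kernels of the model family
#' \deqn{y = \mu + E + G + T + GE + GT + \varepsilon}
#' from a long phenotype table and a GRM:
#' `V_E = Z_E Z_E'` (environment incidence), `V_G = Z_G Grm Z_G'`,
#' `V_T = Z_T Z_T'` (trait incidence), and the Hadamard interaction kernels
#' `V_GE = V_G * V_E`, `V_GT = V_G * V_T` (elementwise products). Model IDs
#' select subsets: `Single` (G), `EG` (E, G), `GxE` (E, G, GE), `MT` (T, G),
#' `MxT` (T, G, GT).
#'
#' @param model_id one of `"Single"`, `"EG"`, `"GxE"`, `"MT"`, `"MxT"`.
#' @param records a `pheno_table` (columns genetic_id, collection, trait,
#'   value); every `genetic_id` must appear in the GRM.
#' @param grm a `grm` object or matrix with ID dimnames.
#' @return list of class `kernel_set`: `model_id`, `kernels` (named list of
#'   record-level matrices), `records`, `y` (record values, `NA` = masked).
#' @export
build_kernels <- function(model_id = c("Single", "EG", "GxE", "MT", "MxT"),
                          records, grm) {
  model_id <- match.arg(model_id)
  G <- if (inherits(grm, "grm")) grm$values else as.matrix(grm)
  if (is.null(records$genetic_id)) records$genetic_id <- records$individual_id
  if (!all(records$genetic_id %in% rownames(G)))
    stop("record individual(s) absent from the GRM")
  n <- nrow(records)
  VG <- G[records$genetic_id, records$genetic_id, drop = FALSE]
  dimnames(VG) <- NULL
  kernels <- list()
  incidence <- function(f) {
    f <- as.factor(f)
    Z <- matrix(0, length(f), nlevels(f))
    Z[cbind(seq_along(f), as.integer(f))] <- 1
    Z
  }
  if (model_id %in% c("EG", "GxE")) {
    env <- as.factor(records$collection)
    if (nlevels(droplevels(env)) < 2)
      warning(model_id, " model with a single environment: V_E is constant ",
              "and V_GE reduces to V_G")
    kernels$E <- tcrossprod(incidence(env))
  }
  if (model_id %in% c("MT", "MxT")) {
    tr <- as.factor(records$trait)
    if (nlevels(droplevels(tr)) < 2)
      warning(model_id, " model with a single trait: V_T is constant ",
              "and V_GT reduces to V_G")
    kernels$T <- tcrossprod(incidence(tr))
  }
  kernels$G <- VG
  if (model_id == "GxE") kernels$GE <- VG * kernels$E
  if (model_id == "MxT") kernels$GT <- VG * kernels$T
  structure(list(model_id = model_id, kernels = kernels,
                 records = records, y = records$value),
            class = "kernel_set")
}

#' MCMC configuration for the Gibbs sampler
#'
#' Defaults are a desk-scale chain (5000 + 5000, thinning 5); production
#' analyses of the kind this model family was designed for use 25000 burn-in
#' plus 25000 sampling iterations.
#'
#' @param n_burn,n_iter burn-in and sampling iterations.
#' @param thin thinning interval for stored draws.
#' @param df0 prior degrees of freedom of every scaled-inverse-chi-square
#'   variance prior.
#' @param r2 prior proportion of variance attributed to the random kernels
#'   jointly (prior modes split var(y) * r2 evenly across kernels).
#' @param seed integer seed; fits are deterministic given it.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_burn = 5000, n_iter = 5000, thin = 5, df0 = 5,
                        r2 = 0.5, seed = 1) {
  stopifnot(n_burn >= 0, n_iter >= thin, thin >= 1, df0 > 0, r2 > 0, r2 < 1)
  structure(list(n_burn = n_burn, n_iter = n_iter, thin = thin, df0 = df0,
                 r2 = r2, seed = seed), class = "mcmc_config")
}

# effective sample size from the autocorrelation function (initial positive
# sequence truncation)
ess <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  if (length(pos) > 0) ac <- ac[seq_len(pos[1] - 1)]
  n / (1 + 2 * sum(ac))
}

#' Fit a kernel-regression model by Gibbs sampling
#'
#' Bayesian RKHS regression: each kernel is eigendecomposed once and its
#' effect sampled in the rotated basis, where the full conditionals are
#' independent normals; variance components get scaled-inverse-chi-square
#' updates, and masked (`NA`) records are imputed by data augmentation each
#' iteration, so their genomic estimated breeding values (GEBVs) are defined.
#' The GEBV of a record is the posterior-mean sum of its genetic effect
#' components (G plus any GE/GT interaction component).
#'
#' @param kernel_set a [build_kernels] result.
#' @param y optional response overriding `kernel_set$y` (use `NA` to mask
#'   records for prediction).
#' @param config an [mcmc_config].
#' @param prior_pin optional named list `list(component = variance, ...,
#'   e = variance)` pinning variance components at fixed values with
#'   near-degenerate priors (df = 1e6); used for closed-form checks.
#' @return list of class `gp_fit`: `mu`, `effects` (records x kernels
#'   posterior means), `gebv`, `var_components` (posterior mean and SD per
#'   component), `ess_sigma2_g`, `records`, `model_id`, `config`.
#' @export
fit_gibbs <- function(kernel_set, y = NULL, config = mcmc_config(),
                      prior_pin = NULL) {
  stopifnot(inherits(kernel_set, "kernel_set"), inherits(config, "mcmc_config"))
  if (is.null(y)) y <- kernel_set$y
  n <- length(y)
  miss <- is.na(y)
  if (all(miss)) stop("all records masked; nothing to fit")
  kn <- names(kernel_set$kernels)
  K <- length(kn)

  Ulist <- list(); dlist <- list()
  for (k in seq_len(K)) {
    Vk <- kernel_set$kernels[[k]]
    e <- eigen(Vk, symmetric = TRUE)
    if (min(e$values) < -1e-6 * max(abs(e$values)))
      stop("kernel ", kn[k], " is not positive semi-definite")
    keep <- e$values > 1e-8 * max(e$values)
    Ulist[[k]] <- e$vectors[, keep, drop = FALSE]
    dlist[[k]] <- e$values[keep]
  }

  vy <- stats::var(y[!miss])
  df0 <- rep(config$df0, K)
  S0 <- rep(vy * config$r2 / K * (config$df0 + 2) / config$df0, K)
  dfe <- config$df0
  S0e <- vy * (1 - config$r2) * (config$df0 + 2) / config$df0
  if (!is.null(prior_pin)) {
    for (k in seq_len(K)) if (!is.null(prior_pin[[kn[k]]])) {
      df0[k] <- 1e6; S0[k] <- prior_pin[[kn[k]]]
    }
    if (!is.null(prior_pin$e)) { dfe <- 1e6; S0e <- prior_pin$e }
  }

  set.seed(config$seed)
  res <- rkhs_gibbs_cpp(as.numeric(y), miss, Ulist, dlist, df0, S0, dfe, S0e,
                        config$n_burn, config$n_iter, config$thin)
  effects <- res$effects
  colnames(effects) <- kn
  genetic <- kn %in% c("G", "GE", "GT")
  gebv <- rowSums(effects[, genetic, drop = FALSE])
  s2 <- res$s2_draws
  colnames(s2) <- c(kn, "e")
  vc <- data.frame(component = colnames(s2),
                   mean = colMeans(s2),
                   sd = apply(s2, 2, stats::sd))
  structure(list(mu = res$mu, effects = effects, gebv = gebv,
                 var_components = vc,
                 ess_sigma2_g = ess(s2[, "G"]),
                 records = kernel_set$records,
                 model_id = kernel_set$model_id,
                 config = config),
            class = "gp_fit")
}

#' @exportS3Method base::print
print.gp_fit <- function(x, ...) {
  cat(sprintf("gp_fit (%s): %d records, mu = %.3f; variance components:\n",
              x$model_id, length(x$gebv), x$mu))
  print(x$var_components, row.names = FALSE)
  invisible(x)
}

#' GEBVs of masked records
#'
#' @param fit a `gp_fit`.
#' @param which_records integer indices (into the fitted records) or a
#'   logical mask; the records must have been part of the fit.
#' @return named numeric vector of GEBVs.
#' @export
predict_gebv <- function(fit, which_records) {
  stopifnot(inherits(fit, "gp_fit"))
  if (is.logical(which_records)) which_records <- which(which_records)
  if (any(which_records < 1 | which_records > length(fit$gebv)))
    stop("record index outside the fitted record set")
  out <- fit$gebv[which_records]
  names(out) <- fit$records$genetic_id[which_records]
  out
}
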