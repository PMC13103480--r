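#' Cross-validation scheme
#'
#' CV1 masks whole individuals (all their trait/environment records),
#' emulating prediction of entirely new individuals; CV2 masks a fraction of
#' individuals independently within every trait/environment cell, emulating
#' incomplete phenotype records, so an individual can be observed for some
#' cells and masked for others.
#'
#' @param strategy `"CV1"` or `"CV2"`.
#' @param mask_fraction fraction masked (default 0.2).
#' @param n_replicates number of independent replicates (default 50).
#' @param seed integer seed; replicate masks are deterministic given it.
#' @return list of class `cv_scheme`.
#' @export
cv_scheme <- function(strategy = c("CV1", "CV2"), mask_fraction = 0.2,
                      n_replicates = 50, seed = 1) {
  strategy <- match.arg(strategy)
  stopifnot(mask_fraction > 0, mask_fraction < 1, n_replicates >= 1)
  structure(list(strategy = strategy, mask_fraction = mask_fraction,
                 n_replicates = n_replicates, seed = seed),
            class = "cv_scheme")
}

#' Per-replicate record masks
#'
#' @param scheme a [cv_scheme].
#' @param records a `pheno_table`.
#' @return list of `n_replicates` logical vectors over records (`TRUE` =
#'   masked / validation).
#' @export
make_masks <- function(scheme, records) {
  stopifnot(inherits(scheme, "cv_scheme"))
  if (is.null(records$genetic_id)) records$genetic_id <- records$individual_id
  cells <- interaction(records$trait, records$collection, drop = TRUE)
  lapply(seq_len(scheme$n_replicates), function(rep) {
    set.seed(scheme$seed + rep)
    mask <- rep(FALSE, nrow(records))
    if (scheme$strategy == "CV1") {
      ids <- unique(records$genetic_id)
      k <- round(scheme$mask_fraction * length(ids))
      if (k < 1) stop("mask_fraction yields zero masked individuals")
      mask <- records$genetic_id %in% sample(ids, k)
    } else {
      for (cl in levels(cells)) {
        ix <- which(cells == cl)
        k <- round(scheme$mask_fraction * length(ix))
        if (k < 1) stop("mask_fraction yields zero masked records in cell ", cl)
        mask[sample(ix, k)] <- TRUE
      }
    }
    mask
  })
}

#' Prediction accuracy: Pearson correlation of observed values and GEBVs
#'
#' @param observed,gebv numeric vectors of equal length >= 3.
#' @return Pearson r, or `NA` with attribute `reason` when either vector has
#'   zero variance.
#' @export
accuracy <- function(observed, gebv) {
  if (length(observed) != length(gebv)) stop("length mismatch")
  if (length(observed) < 3) stop("need at least 3 pairs")
  if (stats::sd(observed) == 0 || stats::sd(gebv) == 0)
    return(structure(NA_real_, reason = "zero variance"))
  stats::cor(observed, gebv)
}

# fit one model on records with masked y; return GEBVs for all records.
# "Single" is fitted independently per trait/environment cell.
fit_predict <- function(model, records, grm, y_masked, config) {
  n <- nrow(records)
  gebv <- rep(NA_real_, n)
  if (model == "Single") {
    cells <- interaction(records$trait, records$collection, drop = TRUE)
    for (cl in levels(cells)) {
      ix <- which(cells == cl)
      ks <- build_kernels("Single", records[ix, , drop = FALSE], grm)
      fit <- fit_gibbs(ks, y = y_masked[ix], config = config)
      gebv[ix] <- fit$gebv
    }
  } else {
    ks <- build_kernels(model, records, grm)
    fit <- fit_gibbs(ks, y = y_masked, config = config)
    gebv <- fit$gebv
  }
  gebv
}

#' Replicated cross-validation over a set of prediction models
#'
#' For each replicate a shared mask is drawn (identical across the compared
#' models), each model is fitted on the unmasked records and predicts the
#' masked ones, and Pearson accuracy is computed per trait/environment cell.
#' Aggregates mean and SD per model and cell, plus paired two-sided t-tests
#' between models on per-replicate mean accuracies.
#'
#' @param records a `pheno_table`.
#' @param grm a `grm` object or matrix.
#' @param models character vector from
#'   `c("Single", "EG", "GxE", "MT", "MxT")`.
#' @param scheme a [cv_scheme].
#' @param config an [mcmc_config]; each replicate/model gets a distinct
#'   derived seed.
#' @return list of class `cv_result`: `replicates` (data.frame replicate,
#'   model, trait, collection, accuracy, n), `summary` (mean/sd per model
#'   and cell), `comparisons` (pairwise paired t-tests), `scheme`.
#' @export
run_cv <- function(records, grm, models = "Single", scheme = cv_scheme(),
                   config = mcmc_config()) {
  if (is.null(records$genetic_id)) records$genetic_id <- records$individual_id
  masks <- make_masks(scheme, records)
  cells <- interaction(records$trait, records$collection, drop = TRUE)
  rows <- list()
  for (rep in seq_along(masks)) {
    mask <- masks[[rep]]
    y_masked <- ifelse(mask, NA, records$value)
    for (model in models) {
      cfg <- config
      cfg$seed <- config$seed + 1000L * rep + match(model, models)
      gebv <- tryCatch(fit_predict(model, records, grm, y_masked, cfg),
                       error = function(e) {
                         warning("replicate ", rep, " model ", model,
                                 " failed: ", conditionMessage(e))
                         NULL
                       })
      if (is.null(gebv)) next
      for (cl in levels(cells)) {
        v <- which(cells == cl & mask)
        if (length(v) < 3) next
        parts <- strsplit(cl, "\\.")[[1]]
        rows[[length(rows) + 1]] <- data.frame(
          replicate = rep, model = model,
          trait = parts[1], collection = parts[2],
          accuracy = as.numeric(accuracy(records$value[v], gebv[v])),
          n = length(v), stringsAsFactors = FALSE)
      }
    }
  }
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(
    split(reps, interaction(reps$model, reps$trait, reps$collection, drop = TRUE)),
    function(d) data.frame(model = d$model[1], trait = d$trait[1],
                           collection = d$collection[1],
                           mean_accuracy = mean(d$accuracy, na.rm = TRUE),
                           sd_accuracy = stats::sd(d$accuracy, na.rm = TRUE),
                           n_replicates = nrow(d), stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  comparisons <- NULL
  if (length(models) > 1) {
    per_rep <- tapply(reps$accuracy, list(reps$replicate, reps$model), mean,
                      na.rm = TRUE)
    cmb <- utils::combn(models, 2)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
      a <- per_rep[, cmb[1, k]]; b <- per_rep[, cmb[2, k]]
      tt <- compare_models(a, b)
      data.frame(model_a = cmb[1, k], model_b = cmb[2, k],
                 mean_diff = mean(a - b, na.rm = TRUE),
                 t = tt$t, p = tt$p, stringsAsFactors = FALSE)
    }))
  }
  structure(list(replicates = reps, summary = summ, comparisons = comparisons,
                 scheme = scheme), class = "cv_result")
}

#' Inter-collection prediction scenarios
#'
#' Fits on the records of the reference collections only (validation records
#' are masked) and reports Pearson accuracy per validation collection. When
#' `include_diagonal` is set and a collection appears as both reference and
#' validation, its cell is the within-collection CV1 accuracy from [run_cv].
#'
#' @param records a `pheno_table` (one trait).
#' @param grm a `grm` or matrix.
#' @param reference,validation character vectors of collection labels;
#'   they must not overlap (use `include_diagonal` for the diagonal cells).
#' @param model model ID for the joint fit (default `"Single"`, i.e. plain
#'   GBLUP on the pooled reference).
#' @param config an [mcmc_config].
#' @param clone_map optional clone pairs allowed to span the two sets.
#' @return data.frame (reference, validation, accuracy, n).
#' @export
run_intercollection <- function(records, grm, reference, validation,
                                model = "Single", config = mcmc_config(),
                                clone_map = NULL) {
  if (is.null(records$genetic_id)) records$genetic_id <- records$individual_id
  overlap <- intersect(reference, validation)
  if (length(overlap) > 0)
    stop("validation collection(s) also in the reference: ",
         paste(overlap, collapse = ", "))
  keep <- records$collection %in% c(reference, validation)
  rec <- records[keep, , drop = FALSE]
  is_val <- rec$collection %in% validation
  # clones of reference individuals inside the validation set are allowed,
  # but their reference record is what trains the model
  y_masked <- ifelse(is_val, NA, rec$value)
  # the joint fit pools environments; "Single" here is plain GBLUP on the
  # pooled reference records
  if (model == "Single") {
    ks <- build_kernels("Single", rec, grm)
    fit <- fit_gibbs(ks, y = y_masked, config = config)
    gebv <- fit$gebv
  } else {
    gebv <- fit_predict(model, rec, grm, y_masked, config)
  }
  do.call(rbind, lapply(validation, function(vc) {
    v <- which(rec$collection == vc)
    data.frame(reference = paste(reference, collapse = "+"), validation = vc,
               accuracy = as.numeric(accuracy(rec$value[v], gebv[v])),
               n = length(v), stringsAsFactors = FALSE)
  }))
}

#' Column means of a per-trait accuracy table
#'
#' @param tbl data.frame whose numeric columns are per-model accuracies
#'   (rows = traits).
#' @return named vector of column means, rounded to 2 decimals.
#' @export
summarize_accuracy_table <- function(tbl) {
  num <- vapply(tbl, is.numeric, logical(1))
  if (!any(num)) stop("no numeric columns")
  round(colMeans(tbl[, num, drop = FALSE], na.rm = TRUE), 2)
}

#' Paired comparison of two models' replicate accuracies
#'
#' Two-sided paired t-test on per-replicate accuracy differences (both
#' models saw identical masks within a replicate). Degenerate cases are
#' handled explicitly: identical vectors give t = 0, p = 1; a non-zero
#' constant difference has zero variance and is reported as p = 0 with a
#' `degenerate` flag.
#'
#' @param acc_a,acc_b equal-length (>= 2) paired accuracy vectors.
#' @return list with `t`, `p`, `mean_diff`, `degenerate`.
#' @export
compare_models <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b)) stop("unpaired accuracy vectors")
  if (length(acc_a) < 2) stop("need at least 2 paired replicates")
  d <- acc_a - acc_b
  d <- d[!is.na(d)]
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, mean_diff = 0, degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, p = 0, mean_diff = mean(d),
                degenerate = TRUE))
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), p = tt$p.value, mean_diff = mean(d),
       degenerate = FALSE)
}
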