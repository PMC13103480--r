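#' Hue angle from CIELAB chroma components
#'
#' `h = atan(b*/a*)` in degrees, where `a*` is redness and `b*` yellowness.
#' Implemented exactly as the colorimeter formula prints it (single-argument
#' arctangent), so the result lies in (-90, 90) and `a* = 0` is undefined.
#'
#' @param a_star redness component (non-zero).
#' @param b_star yellowness component.
#' @return hue angle in degrees.
#' @export
hue_angle <- function(a_star, b_star) {
  if (any(a_star == 0)) stop("hue angle undefined for a* = 0")
  atan(b_star / a_star) * 180 / pi
}

#' Pulp "percentage" as the fruit-to-stone weight ratio
#'
#' Computed exactly as defined by the source phenotyping protocol: the ratio
#' of fruit weight to stone weight. Note that this is a ratio (> 1 for any
#' fleshy fruit), not a true percentage; it is kept on the recorded scale.
#'
#' @param fruit_weight fruit weight (same units as `stone_weight`).
#' @param stone_weight stone weight, strictly positive.
#' @return the ratio fruit/stone.
#' @export
pulp_percentage <- function(fruit_weight, stone_weight) {
  if (any(stone_weight <= 0)) stop("stone_weight must be positive")
  fruit_weight / stone_weight
}

#' Stack per-collection phenotype tables into one long table
#'
#' Concatenates per-collection long tables (individual_id, trait, value) into
#' a single table with a collection factor. Clone pairs shared between
#' collections can be treated as distinct genetic entries (`clone_mode =
#' "distinct"`, the default) or merged onto one genetic ID observed in two
#' environments (`"merged"`): under merging, both records keep their
#' environment label but `genetic_id` is set to the first member's ID, which
#' is the ID used to look the individual up in the GRM.
#'
#' @param tables named list of data.frames, one per collection, each with
#'   columns individual_id, trait, value (a collection column is added from
#'   the list names).
#' @param clone_map data.frame with columns id_a / id_b (may be empty).
#' @param clone_mode `"distinct"` or `"merged"`.
#' @return A long data.frame (individual_id, genetic_id, collection, trait,
#'   value) of class `pheno_table`.
#' @export
harmonize_phenotypes <- function(tables, clone_map = NULL,
                                 clone_mode = c("distinct", "merged")) {
  clone_mode <- match.arg(clone_mode)
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("tables must be a named list (names are collection labels)")
  out <- do.call(rbind, lapply(names(tables), function(cl) {
    tb <- tables[[cl]]
    stopifnot(all(c("individual_id", "trait", "value") %in% names(tb)))
    data.frame(individual_id = tb$individual_id, collection = cl,
               trait = tb$trait, value = tb$value, stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(out[, c("individual_id", "collection", "trait")]))
    stop("duplicate (individual, collection, trait) record(s)")
  out$genetic_id <- out$individual_id
  if (clone_mode == "merged" && !is.null(clone_map) && nrow(clone_map) > 0) {
    idx <- match(out$individual_id, clone_map$id_b)
    hit <- !is.na(idx)
    out$genetic_id[hit] <- clone_map$id_a[idx[hit]]
  }
  rownames(out) <- NULL
  class(out) <- c("pheno_table", "data.frame")
  out
}

#' Convert the long phenotype output of [simulate_phenotypes] to a pheno_table
#' @param pheno long data.frame with individual_id, collection, trait, value.
#' @return the same data.frame with a `genetic_id` column and class
#'   `pheno_table`.
#' @export
as_pheno_table <- function(pheno) {
  stopifnot(all(c("individual_id", "collection", "trait", "value") %in% names(pheno)))
  if (is.null(pheno$genetic_id)) pheno$genetic_id <- pheno$individual_id
  class(pheno) <- c("pheno_table", "data.frame")
  pheno
}
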