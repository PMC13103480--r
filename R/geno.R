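#' Genotype matrix container
#'
#' Bundles an n x m additive dosage matrix (ALT-allele counts 0/1/2, `NA` for
#' missing calls) with its marker map. Positions are 1-based, as in VCF.
#' Optionally carries the two phased haplotype matrices (0/1) when phase is
#' known (simulated data, or fully phased VCF input); these are required only
#' by the phased LD estimator.
#'
#' @param dosages numeric n x m matrix with values in \{0, 1, 2, NA\};
#'   rownames are individual IDs (generated when absent).
#' @param chrom character vector of m chromosome labels.
#' @param pos integer vector of m 1-based physical positions.
#' @param ref,alt character vectors of m REF/ALT alleles.
#' @param hap1,hap2 optional n x m 0/1 haplotype matrices.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosages, chrom, pos, ref = NULL, alt = NULL,
                        hap1 = NULL, hap2 = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  if (length(chrom) != m || length(pos) != m)
    stop("marker map length does not match the number of dosage columns")
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("ind_%04d", seq_len(nrow(dosages)))
  if (anyDuplicated(rownames(dosages)))
    stop("individual IDs must be unique")
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  # positions strictly increasing within each chromosome
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  structure(list(dosages = dosages, chrom = as.character(chrom),
                 pos = as.integer(pos), ref = ref, alt = alt,
                 hap1 = hap1, hap2 = hap2),
            class = "geno_matrix")
}

#' @exportS3Method base::dim
dim.geno_matrix <- function(x) dim(x$dosages)

#' @exportS3Method base::print
print.geno_matrix <- function(x, ...) {
  d <- dim(x$dosages)
  miss <- mean(is.na(x$dosages))
  cat(sprintf(
    "geno_matrix: %d individuals x %d markers on %d chromosome(s); %.2f%% missing%s\n",
    d[1], d[2], length(unique(x$chrom)), 100 * miss,
    if (!is.null(x$hap1)) "; phased" else ""))
  invisible(x)
}

# subset markers (logical or integer index), keeping map and phase in step
subset_markers <- function(geno, idx) {
  geno_matrix(geno$dosages[, idx, drop = FALSE],
              geno$chrom[idx], geno$pos[idx], geno$ref[idx], geno$alt[idx],
              hap1 = if (!is.null(geno$hap1)) geno$hap1[, idx, drop = FALSE],
              hap2 = if (!is.null(geno$hap2)) geno$hap2[, idx, drop = FALSE])
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses GT fields into additive ALT-allele dosages. Multi-allelic records
#' are skipped (with a message reporting the count). Phase separators are
#' ignored for dosage, but when every retained call is phased the two
#' haplotype matrices are kept so that haplotype-based LD can be computed.
#'
#' @param path path to an (uncompressed or bgzipped) VCF with GT.
#' @return A [geno_matrix].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !grepl(",", alt) & nchar(ref) == 1 & nchar(alt) == 1
  n_skipped <- sum(!biallelic)
  if (n_skipped > 0)
    message(n_skipped, " multi-allelic or non-SNP record(s) skipped")
  if (!any(biallelic)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  chrom <- fix[biallelic, "CHROM"]
  pos <- as.integer(fix[biallelic, "POS"])
  ref <- ref[biallelic]; alt <- alt[biallelic]

  gt_chr <- gsub("\\|", "/", gt)
  valid <- gt_chr %in% c("0/0", "0/1", "1/0", "1/1", "./.") | is.na(gt_chr)
  if (!all(valid))
    stop("malformed GT value(s): ", paste(utils::head(unique(gt_chr[!valid])), collapse = ", "))
  dos <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), NULL))
  map <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)
  # "./." and NA both fall through to NA
  dos[] <- t(matrix(unname(map[gt_chr]), nrow = nrow(gt)))

  phased <- all(grepl("\\|", gt) | gt_chr == "./." | is.na(gt), na.rm = TRUE)
  hap1 <- hap2 <- NULL
  if (phased) {
    a1 <- suppressWarnings(as.integer(substr(gt, 1, 1)))
    a2 <- suppressWarnings(as.integer(substr(gt, 3, 3)))
    hap1 <- matrix(a1, nrow = nrow(gt)); hap2 <- matrix(a2, nrow = nrow(gt))
    hap1 <- t(hap1); hap2 <- t(hap2)
    rownames(hap1) <- rownames(hap2) <- colnames(gt)
  }
  geno_matrix(dos, chrom, pos, ref, alt, hap1 = hap1, hap2 = hap2)
}

#' Write a minimal VCF (GT only)
#'
#' Emits a valid VCF v4.2 with CHROM, POS, ID, REF, ALT and per-sample GT.
#' Dosages are written as unphased GT (0/0, 0/1, 1/1, ./.) unless the object
#' carries haplotypes, in which case phased GT (`|`) is written.
#'
#' @param geno a [geno_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  n <- nrow(geno$dosages); m <- ncol(geno$dosages)
  ids <- rownames(geno$dosages)
  if (!is.null(geno$hap1)) {
    gt <- matrix(paste0(t(geno$hap1), "|", t(geno$hap2)), nrow = m)
    gt[is.na(t(geno$dosages))] <- "./."
  } else {
    codes <- c("0/0", "0/1", "1/1")
    d <- t(geno$dosages)
    gt <- matrix("./.", nrow = m, ncol = n)
    obs <- !is.na(d)
    gt[obs] <- codes[d[obs] + 1]
  }
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  body <- paste(geno$chrom, geno$pos,
                sprintf("snp_%s_%d", geno$chrom, geno$pos),
                geno$ref, geno$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Per-marker ALT allele frequencies
#'
#' @param geno a [geno_matrix].
#' @return numeric vector p of length m: ALT-dosage sum over observed calls
#'   divided by twice the observed sample size; `NaN` for fully missing markers.
#' @export
allele_frequencies <- function(geno) {
  colMeans(geno$dosages, na.rm = TRUE) / 2
}

#' Filter markers on missingness, MAC, singletons and MAF
#'
#' Rules are applied in the order missingness -> minor allele count ->
#' singleton -> minor allele frequency, and the report counts removals per
#' rule in that order (a marker is charged to the first rule it fails).
#'
#' @param geno a [geno_matrix].
#' @param max_missing maximum tolerated missing fraction per marker
#'   (default 0.2: markers with more than 20\% missing calls are removed).
#' @param min_mac minimum minor allele count (0 disables).
#' @param drop_singletons remove markers whose minor allele occurs exactly once.
#' @param min_maf minimum minor allele frequency (0 disables).
#' @return A [geno_matrix] with attribute `"filter_report"`, a data.frame of
#'   per-rule removal counts.
#' @export
filter_variants <- function(geno, max_missing = 0.2, min_mac = 0,
                            drop_singletons = FALSE, min_maf = 0) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_mac >= 0,
            min_maf >= 0, min_maf <= 0.5)
  d <- geno$dosages
  n_obs <- colSums(!is.na(d))
  miss_frac <- 1 - n_obs / nrow(d)
  alt_count <- colSums(d, na.rm = TRUE)
  mac <- pmin(alt_count, 2 * n_obs - alt_count)
  maf <- ifelse(n_obs > 0, pmin(alt_count / (2 * n_obs),
                                1 - alt_count / (2 * n_obs)), 0)

  fail_miss <- miss_frac > max_missing | n_obs == 0
  fail_mac <- !fail_miss & mac < min_mac
  fail_single <- !fail_miss & !fail_mac & drop_singletons & mac == 1
  fail_maf <- !fail_miss & !fail_mac & !fail_single & maf < min_maf
  keep <- !(fail_miss | fail_mac | fail_single | fail_maf)

  report <- data.frame(
    rule = c("missingness", "mac", "singleton", "maf", "retained"),
    count = c(sum(fail_miss), sum(fail_mac), sum(fail_single), sum(fail_maf),
              sum(keep)))
  if (!any(keep))
    warning("all markers removed by the requested filters")
  out <- subset_markers(geno, keep)
  attr(out, "filter_report") <- report
  out
}

#' Mean-impute residual missing dosages
#'
#' Replaces each missing call by the mean observed dosage at that marker.
#' Intended for low residual missingness after [filter_variants]; it is not a
#' substitute for haplotype-aware imputation.
#'
#' @param geno a [geno_matrix].
#' @return A complete [geno_matrix] (columns may hold non-integer dosages).
#' @export
impute_mean <- function(geno) {
  d <- geno$dosages
  if (!anyNA(d)) return(geno)
  mu <- colMeans(d, na.rm = TRUE)
  if (anyNA(mu) || any(is.nan(mu)))
    stop("marker(s) with all calls missing; run filter_variants first")
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2]]
  out <- geno
  out$dosages <- d
  out
}

#' VanRaden genomic relationship matrix
#'
#' Method-1 GRM from observed-sample allele frequencies:
#' \deqn{G = W W' / (2 \sum_k p_k (1 - p_k))}
#' where column k of W is the dosage column centered by \eqn{2 p_k}.
#'
#' @param geno a complete [geno_matrix] (see [impute_mean]).
#' @return An object of class `grm`: the n x n matrix in `$values` (with ID
#'   dimnames), the frequencies used in `$p`, and the scaling constant
#'   `$denom`.
#' @export
compute_grm <- function(geno) {
  d <- geno$dosages
  if (anyNA(d)) stop("GRM requires complete dosages; run impute_mean first")
  p <- colMeans(d) / 2
  if (any(p <= 0 | p >= 1))
    stop("monomorphic marker(s) present (p = 0 or 1); run filter_variants first")
  W <- sweep(d, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(W) / denom
  dimnames(G) <- list(rownames(d), rownames(d))
  structure(list(values = G, p = p, denom = denom), class = "grm")
}

#' @exportS3Method base::print
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d individuals, %d markers, mean diagonal %.3f\n",
              nrow(x$values), length(x$p), mean(diag(x$values))))
  invisible(x)
}

#' Write / read a GRM as a square tab-separated matrix with an ID header
#' @param grm a `grm` object.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_grm <- function(grm, path) {
  utils::write.table(grm$values, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  structure(list(values = m, p = NULL, denom = NULL), class = "grm")
}
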