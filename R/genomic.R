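#' @title SNP genotype utilities and the VanRaden genomic relationship matrix
#' @description Genotypes are held as a plain numeric matrix, trees in rows and
#'   SNPs in columns, dosages coded 0/1/2 (count of the alternative allele)
#'   with `NA` for missing calls. All functions below validate that coding.
#' @name genomic
NULL

check_genotypes <- function(M) {
  if (!is.matrix(M) || !is.numeric(M)) stop("genotypes must be a numeric matrix")
  if (is.null(rownames(M))) stop("genotype matrix must have tree ids as rownames")
  if (is.null(colnames(M))) colnames(M) <- paste0("snp", seq_len(ncol(M)))
  ok <- is.na(M) | M == 0 | M == 1 | M == 2
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid dosage %s at tree '%s', SNP '%s' (allowed: 0, 1, 2, NA)",
                 format(M[bad[1L], bad[2L]]), rownames(M)[bad[1L]], colnames(M)[bad[2L]]))
  }
  M
}

#' Per-SNP alternative allele frequency from observed dosages
#'
#' @param M genotype matrix (trees x SNPs, dosages 0/1/2, `NA` missing).
#' @return numeric vector `p_k = mean(dosage)/2` over non-missing entries.
#' @export
allele_freq <- function(M) {
  M <- check_genotypes(M)
  colMeans(M, na.rm = TRUE) / 2
}

#' Filter SNPs on missingness and minor allele frequency
#'
#' Drops SNPs whose missing-data proportion exceeds `max_missing` or whose
#' minor allele frequency `min(p, 1 - p)` falls below `min_maf` (computed from
#' observed entries). Defaults mirror routine GBS panel cleaning: at most 30%
#' missing data and MAF of at least 1%.
#'
#' @param M genotype matrix.
#' @param max_missing maximum tolerated missing proportion per SNP.
#' @param min_maf minimum minor allele frequency per SNP.
#' @return The filtered matrix, with attribute `filter_report` (a list with
#'   counts `n_input`, `n_dropped_missing`, `n_dropped_maf`, `n_retained`).
#' @export
filter_snps <- function(M, max_missing = 0.30, min_maf = 0.01) {
  M <- check_genotypes(M)
  if (ncol(M) == 0L) stop("genotype matrix has no SNPs")
  miss <- colMeans(is.na(M))
  p <- colMeans(M, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0  # fully missing SNP: caught by the missingness rule
  maf <- pmin(p, 1 - p)
  drop_missing <- miss > max_missing
  drop_maf <- !drop_missing & maf < min_maf
  keep <- !(drop_missing | drop_maf)
  if (!any(keep)) stop("all SNPs removed by filtering; empty panel")
  out <- M[, keep, drop = FALSE]
  attr(out, "filter_report") <- list(
    n_input = ncol(M),
    n_dropped_missing = sum(drop_missing),
    n_dropped_maf = sum(drop_maf),
    n_retained = sum(keep))
  out
}

#' Mean imputation of missing genotype calls
#'
#' Replaces each missing dosage by twice the observed allele frequency of its
#' SNP (the column mean), leaving column means unchanged.
#'
#' @param M genotype matrix.
#' @return matrix with no missing entries.
#' @export
impute_mean <- function(M) {
  M <- check_genotypes(M)
  nobs <- colSums(!is.na(M))
  if (any(nobs == 0L)) {
    stop("SNP(s) with no observed genotypes, cannot compute allele frequency: ",
         paste(utils::head(colnames(M)[nobs == 0L], 10L), collapse = ", "))
  }
  na_idx <- which(is.na(M))
  if (length(na_idx)) {
    fill <- colMeans(M, na.rm = TRUE)
    M[na_idx] <- fill[(na_idx - 1L) %/% nrow(M) + 1L]
  }
  M
}

#' VanRaden genomic relationship matrix
#'
#' Computes `G = W W' / (2 * sum(p_k (1 - p_k)))` where `W = M - P`, `M` is the
#' imputed dosage matrix and `P` the matrix of twice the allele frequencies.
#' Frequencies are the observed sample frequencies (recorded in the result's
#' provenance). If the smallest eigenvalue of G is at or below zero, a small
#' ridge `epsilon` is added to the diagonal so the matrix can be inverted and
#' Cholesky-factorised downstream; the value actually applied is recorded.
#'
#' @param M genotype matrix with no missing entries (run [impute_mean()] first).
#' @param epsilon diagonal ridge applied when G is not positive definite.
#' @return symmetric matrix of class `kinship_matrix`, attributes `kind = "G"`,
#'   `epsilon` (0 when no repair was needed) and `p` (allele frequencies used).
#' @export
build_G <- function(M, epsilon = 1e-6) {
  # mean-imputed dosages are fractional, so only the [0, 2] range is checked
  if (!is.matrix(M) || !is.numeric(M)) stop("genotypes must be a numeric matrix")
  if (is.null(rownames(M))) stop("genotype matrix must have tree ids as rownames")
  if (anyNA(M)) stop("genotypes contain missing entries; run impute_mean() first")
  if (any(M < 0 | M > 2)) stop("dosages must lie in [0, 2]")
  p <- colMeans(M) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all SNPs are monomorphic; G denominator is zero")
  W <- sweep(M, 2L, 2 * p, "-")
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  # centering W on sample frequencies makes 1 an exact null vector of G, so
  # the matrix always needs a small ridge before inversion / Cholesky
  eps_applied <- 0
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8 * max(ev)) {
    G <- G + diag(epsilon, nrow(G))
    eps_applied <- epsilon
  }
  structure(G, kind = "G", epsilon = eps_applied, p = p,
            class = c("kinship_matrix", "matrix", "array"))
}
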