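#' Encode genotypes as the model input matrix
#'
#' Produces the additive minor-allele input matrix with entries in
#' \{-1, 0, 1, 2\}: homozygous minor 2, heterozygous 1, homozygous major 0,
#' missing -1. Missing codes are fed to the model as-is; no imputation.
#'
#' The minor allele of each variant is (re-)designated from the pooled
#' case+control allele frequency of this cohort: if the stored allele's
#' frequency exceeds 0.5 the column is recoded `g -> 2 - g` and the allele
#' labels swap; an exact tie at 0.5 is broken lexicographically, the
#' alphabetically smaller allele character becoming the minor allele.
#' Columns follow the feature set's genomic order.
#'
#' @param cohort A `cohort` object.
#' @param features A `feature_set`; every feature variant must exist in the
#'   cohort.
#' @return An `encoded_matrix`: an integer matrix (samples x SNPs) with
#'   `dimnames` of sample ids and rsids and attributes `minor_allele` /
#'   `major_allele` recording the per-column designation.
#' @export
encode_genotypes <- function(cohort, features) {
  stopifnot(inherits(cohort, "cohort"), inherits(features, "feature_set"))
  cols <- match(features$rsid, cohort$variants$rsid)
  if (anyNA(cols)) {
    stopf("feature variant absent from cohort: %s",
          features$rsid[which(is.na(cols))[1]])
  }
  g <- cohort$genotypes[, cols, drop = FALSE]
  minor <- cohort$variants$minor_allele[cols]
  major <- cohort$variants$major_allele[cols]
  freq <- colMeans(g, na.rm = TRUE) / 2
  flip <- freq > 0.5 | (freq == 0.5 & minor > major)
  if (any(flip)) {
    g[, flip] <- 2L - g[, flip]
    tmp <- minor[flip]
    minor[flip] <- major[flip]
    major[flip] <- tmp
  }
  g[is.na(g)] <- -1L
  dimnames(g) <- list(cohort$samples$sample_id, features$rsid)
  attr(g, "minor_allele") <- minor
  attr(g, "major_allele") <- major
  class(g) <- c("encoded_matrix", class(matrix()))
  g
}

#' Per-variant genotype code counts
#'
#' Tabulates the \{0, 1, 2, -1\} codes of every column of an encoded matrix;
#' used by QC and by association cross-checks. Counts per column always sum
#' to the sample count.
#'
#' @param X An `encoded_matrix`.
#' @return A data.frame with columns rsid, n0, n1, n2, n_missing, maf (minor
#'   allele frequency over non-missing calls).
#' @export
decode_counts <- function(X) {
  n0 <- colSums(X == 0L)
  n1 <- colSums(X == 1L)
  n2 <- colSums(X == 2L)
  nm <- colSums(X == -1L)
  called <- n0 + n1 + n2
  data.frame(
    rsid = colnames(X),
    n0 = n0, n1 = n1, n2 = n2, n_missing = nm,
    maf = ifelse(called > 0, (n1 + 2 * n2) / (2 * called), NA_real_),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Export an encoded matrix as a text table
#'
#' @param X An `encoded_matrix`.
#' @param path Output path; header row of rsids, one sample per line.
#' @return Invisibly, `path`.
#' @export
write_encoded_matrix <- function(X, path) {
  utils::write.table(as.data.frame(unclass(X)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
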