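#' Write a cohort as a PLINK-dialect text triplet
#'
#' Writes four files under `dir` with basename `prefix`:
#' \describe{
#'   \item{`<prefix>.bim`}{variant table, PLINK column order: chrom, rsid,
#'     0 (cM placeholder), bp, allele1 (minor), allele2 (major).}
#'   \item{`<prefix>.fam`}{sample table: family id, within-family id, paternal
#'     and maternal ids (0), sex code (1 = male, 2 = female), phenotype
#'     (2 = case, 1 = control).}
#'   \item{`<prefix>.dosage.txt`}{plain-text additive dosage matrix, one
#'     sample per row, whitespace-separated minor-allele counts, `NA` for
#'     missing calls.}
#'   \item{`<prefix>.covar.tsv`}{covariates: sample_id, registration_index,
#'     age, sex.}
#' }
#' If the cohort carries simulation ground truth, a JSON sidecar
#' `<prefix>.truth.json` (true log-ORs, block ids, seed) is written as well.
#' Coordinates are 1-based inclusive throughout.
#'
#' @param cohort A `cohort` object.
#' @param dir Output directory (created if absent).
#' @param prefix File basename.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    bim = file.path(dir, paste0(prefix, ".bim")),
    fam = file.path(dir, paste0(prefix, ".fam")),
    dosage = file.path(dir, paste0(prefix, ".dosage.txt")),
    covar = file.path(dir, paste0(prefix, ".covar.tsv"))
  )
  v <- cohort$variants
  bim <- data.frame(v$chrom, v$rsid, 0L, v$bp, v$minor_allele, v$major_allele)
  utils::write.table(bim, paths[["bim"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  s <- cohort$samples
  fam <- data.frame(s$sample_id, s$sample_id, 0L, 0L,
                    ifelse(s$sex == "M", 1L, 2L),
                    ifelse(s$status == 1L, 2L, 1L))
  utils::write.table(fam, paths[["fam"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  geno <- cohort$genotypes
  lines <- apply(geno, 1, function(row) paste(ifelse(is.na(row), "NA", row), collapse = " "))
  writeLines(lines, paths[["dosage"]])
  covar <- data.frame(sample_id = s$sample_id,
                      registration_index = s$registration_index,
                      age = s$age, sex = s$sex)
  utils::write.table(covar, paths[["covar"]], sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- attr(cohort, "truth")
  if (!is.null(truth)) {
    paths <- c(paths, truth = file.path(dir, paste0(prefix, ".truth.json")))
    jsonlite::write_json(
      list(log_or = as.list(truth$log_or),
           block_id = as.list(truth$block_id),
           maf = as.list(truth$maf),
           baseline_log_odds = truth$baseline_log_odds,
           seed = truth$seed),
      paths[["truth"]], auto_unbox = TRUE, digits = NA, na = "null"
    )
  }
  invisible(paths)
}

#' Read a cohort from its PLINK-dialect text triplet
#'
#' Counterpart of [write_cohort()]. Validates that the variant table, sample
#' table, and dosage matrix agree in dimension, that rsids are unique, and
#' that every genotype code is in \{0, 1, 2, NA\}; violations fail naming the
#' file (and line, for malformed dosage values).
#'
#' @param dir Directory holding the files.
#' @param prefix File basename used at write time.
#' @return A `cohort` object (with ground truth re-attached when the sidecar
#'   is present).
#' @export
read_cohort <- function(dir, prefix = "cohort") {
  bim_path <- file.path(dir, paste0(prefix, ".bim"))
  fam_path <- file.path(dir, paste0(prefix, ".fam"))
  dosage_path <- file.path(dir, paste0(prefix, ".dosage.txt"))
  covar_path <- file.path(dir, paste0(prefix, ".covar.tsv"))
  for (p in c(bim_path, fam_path, dosage_path, covar_path)) {
    if (!file.exists(p)) stopf("missing cohort file: %s", p)
  }
  bim <- utils::read.table(bim_path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "rsid", "cm", "bp", "a1", "a2"),
                           colClasses = c("character", "character", "integer",
                                          "integer", "character", "character"))
  if (anyDuplicated(bim$rsid)) {
    stopf("duplicate rsid in %s: %s", bim_path, bim$rsid[anyDuplicated(bim$rsid)])
  }
  fam <- utils::read.table(fam_path, sep = "\t", header = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"))
  covar <- utils::read.table(covar_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  lines <- readLines(dosage_path)
  if (length(lines) != nrow(fam)) {
    stopf("dimension mismatch: %d samples in %s but %d rows in %s",
          nrow(fam), fam_path, length(lines), dosage_path)
  }
  geno <- matrix(NA_integer_, length(lines), nrow(bim))
  for (i in seq_along(lines)) {
    vals <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(vals) != nrow(bim)) {
      stopf("dimension mismatch: %d variants in %s but %d fields on line %d of %s",
            nrow(bim), bim_path, length(vals), i, dosage_path)
    }
    suppressWarnings(num <- as.integer(vals))
    bad <- which(!(vals == "NA" | (!is.na(num) & num %in% 0:2)))
    if (length(bad)) {
      stopf("malformed genotype code '%s' at line %d, field %d of %s (must be 0/1/2/NA)",
            vals[bad[1]], i, bad[1], dosage_path)
    }
    geno[i, ] <- num
  }
  samples <- data.frame(
    sample_id = as.character(fam$fid),
    status = ifelse(fam$pheno == 2L, 1L, 0L),
    registration_index = covar$registration_index,
    age = covar$age,
    sex = as.character(covar$sex),
    stringsAsFactors = FALSE
  )
  variants <- data.frame(
    rsid = bim$rsid, chrom = bim$chrom, bp = bim$bp,
    minor_allele = bim$a1, major_allele = bim$a2,
    maf = colMeans(geno, na.rm = TRUE) / 2,
    stringsAsFactors = FALSE
  )
  rownames(geno) <- samples$sample_id
  colnames(geno) <- variants$rsid
  out <- structure(list(samples = samples, variants = variants, genotypes = geno),
                   class = "cohort")
  truth_path <- file.path(dir, paste0(prefix, ".truth.json"))
  if (file.exists(truth_path)) {
    tr <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    attr(out, "truth") <- list(
      log_or = unlist(tr$log_or), block_id = unlist(tr$block_id),
      maf = unlist(tr$maf), baseline_log_odds = tr$baseline_log_odds,
      seed = tr$seed
    )
  }
  out
}

#' Read a GWAS summary-statistics TSV
#'
#' Expects a tab-separated header file with columns `rsid`, `chrom`, `bp`,
#' `effect_allele`, `other_allele`, `p_value` (or `p`), and either
#' `odds_ratio` (or `OR`) or a log-odds column `beta` (in which case
#' `OR = exp(beta)`). Rows with non-positive odds ratio or p-value outside
#' (0, 1] are rejected; the rejection count is reported via a message and
#' stored as `attr(, "n_rejected")`.
#'
#' @param path Path to the TSV.
#' @param source_label Provenance label stored on the table.
#' @return A `summary_stats` data.frame.
#' @export
read_summary_stats <- function(path, source_label = basename(path)) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  names(tab) <- tolower(names(tab))
  if ("p" %in% names(tab) && !"p_value" %in% names(tab)) tab$p_value <- tab$p
  if ("or" %in% names(tab) && !"odds_ratio" %in% names(tab)) tab$odds_ratio <- tab$or
  if (!"odds_ratio" %in% names(tab) && "beta" %in% names(tab)) {
    tab$odds_ratio <- exp(tab$beta)
  }
  required <- c("rsid", "chrom", "bp", "effect_allele", "other_allele",
                "odds_ratio", "p_value")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stopf("summary-statistics file %s lacks required column(s): %s",
          path, paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tab$rsid)) stopf("duplicate rsid in %s", path)
  ok <- is.finite(tab$odds_ratio) & tab$odds_ratio > 0 &
    is.finite(tab$p_value) & tab$p_value > 0 & tab$p_value <= 1
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    message(sprintf("read_summary_stats: rejected %d row(s) with invalid OR or p-value", n_rejected))
  }
  out <- tab[ok, required]
  out$effect_allele <- toupper(out$effect_allele)
  out$other_allele <- toupper(out$other_allele)
  rownames(out) <- NULL
  attr(out, "source_label") <- source_label
  attr(out, "n_rejected") <- n_rejected
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Write a summary-statistics table as TSV
#'
#' @param stats A `summary_stats` data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_summary_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
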