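#' Harmonize external summary statistics onto a cohort
#'
#' Intersects the summary-statistics table with the cohort on rsid and aligns
#' effect alleles to the cohort's minor allele. Each input row receives a
#' harmonization flag:
#' \describe{
#'   \item{`match`}{effect allele equals the cohort minor allele; OR kept.}
#'   \item{`flipped`}{effect allele equals the cohort major allele; the OR is
#'     inverted (log-OR negated) so effects are per cohort minor allele.}
#'   \item{`dropped_ambiguous`}{strand-ambiguous allele pair (A/T or C/G);
#'     dropped regardless of frequency.}
#'   \item{`dropped_unmatched`}{rsid absent from the cohort, or the allele
#'     pair disagrees with the cohort's.}
#' }
#' Strand is assumed forward-consistent between cohort and statistics;
#' ambiguous pairs are dropped rather than frequency-resolved.
#'
#' @param cohort A `cohort` object.
#' @param stats A `summary_stats` data.frame.
#' @return A `summary_stats` data.frame containing every input row with an
#'   added `flag` column and, for retained rows, cohort coordinates and the
#'   harmonized `odds_ratio`. Retained rows are those flagged `match` or
#'   `flipped`.
#' @export
harmonize_stats <- function(cohort, stats) {
  stopifnot(inherits(cohort, "cohort"))
  if (nrow(stats) == 0 || nrow(cohort$variants) == 0) stopf("empty input to harmonization")
  v <- cohort$variants
  i <- match(stats$rsid, v$rsid)
  ea <- toupper(stats$effect_allele)
  oa <- toupper(stats$other_allele)
  pair <- paste(pmin(ea, oa), pmax(ea, oa))
  ambiguous <- pair %in% c("A T", "C G")
  flag <- rep("dropped_unmatched", nrow(stats))
  flag[ambiguous] <- "dropped_ambiguous"
  matched <- !is.na(i) & !ambiguous
  minor <- v$minor_allele[i]
  major <- v$major_allele[i]
  flag[matched & ea == minor & oa == major] <- "match"
  flag[matched & ea == major & oa == minor] <- "flipped"

  out <- stats
  out$flag <- flag
  keep <- flag %in% c("match", "flipped")
  out$chrom[keep] <- v$chrom[i[keep]]
  out$bp[keep] <- v$bp[i[keep]]
  flip <- flag == "flipped"
  out$odds_ratio[flip] <- 1 / out$odds_ratio[flip]
  out$effect_allele[flip] <- minor[flip]
  out$other_allele[flip] <- major[flip]
  if (!any(keep)) stopf("no summary-statistics SNPs could be harmonized onto the cohort")
  attr(out, "source_label") <- attr(stats, "source_label")
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Select the SNP feature set at a p-value threshold
#'
#' For a standard threshold `t`, retains harmonized SNPs with `p < t`
#' (strict). With `control = TRUE`, retains the non-significant control
#' subset, `p >= 0.99`. Output is ordered by genomic coordinate
#' (chromosome, then base pair), which is the column order the encoder and
#' classifier consume.
#'
#' @param stats A harmonized `summary_stats` table (see [harmonize_stats()]);
#'   rows flagged other than `match`/`flipped` are ignored.
#' @param threshold P-value cut-off (ignored when `control = TRUE`).
#' @param control If `TRUE`, apply the non-significant rule `p >= 0.99`.
#' @return A `feature_set` object: list with `threshold` (numeric or the
#'   string `">=0.99"`), `rsid` (genomic order), and `table` (rsid, chrom,
#'   bp, p_value, odds_ratio, flag).
#' @export
select_features <- function(stats, threshold = NULL, control = FALSE) {
  if (!is.null(stats$flag)) stats <- stats[stats$flag %in% c("match", "flipped"), ]
  if (control) {
    keep <- stats$p_value >= 0.99
    label <- ">=0.99"
  } else {
    if (is.null(threshold)) stopf("threshold required unless control = TRUE")
    keep <- stats$p_value < threshold
    label <- threshold
  }
  if (!any(keep)) stopf("no SNPs selected at threshold %s", format(label))
  tab <- stats[keep, c("rsid", "chrom", "bp", "p_value", "odds_ratio", "flag")]
  tab <- tab[genomic_order(tab$chrom, tab$bp, tab$rsid), ]
  rownames(tab) <- NULL
  structure(list(threshold = label, rsid = tab$rsid, table = tab),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d SNPs at threshold %s\n",
              length(x$rsid), format(x$threshold)))
  invisible(x)
}

#' Write a feature set as TSV
#'
#' @param features A `feature_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_set <- function(features, path) {
  utils::write.table(features$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
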