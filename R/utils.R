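#' Derive a stage-specific random seed from a master seed
#'
#' All stochastic stages of the pipeline draw their seed from a single master
#' seed through this declared scheme, so that an entire experiment is
#' reproducible from one integer while stages remain independently seeded.
#' The scheme is `(seed + 7919 * stage) mod (2^31 - 1)`, with 7919 (the
#' 1000th prime) as a fixed stride.
#'
#' @param seed Master seed (integer).
#' @param stage Stage index (non-negative integer); each named pipeline stage
#'   uses a fixed index.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(stage)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Order variant rows genomically
#'
#' Chromosome labels that parse as integers are ordered numerically; the
#' remainder (e.g. "X") follow in lexicographic order. Within a chromosome,
#' ordering is by base-pair position, then rsid.
#'
#' @param chrom Chromosome labels.
#' @param bp Base-pair positions (1-based).
#' @param rsid Variant identifiers used as the final tie-break.
#' @return An integer permutation, as from [order()].
#' @export
genomic_order <- function(chrom, bp, rsid = seq_along(chrom)) {
  chrom_num <- suppressWarnings(as.integer(as.character(chrom)))
  chrom_rank <- ifelse(is.na(chrom_num), .Machine$integer.max, chrom_num)
  order(chrom_rank, as.character(chrom), bp, rsid)
}

clip01 <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x > 0
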