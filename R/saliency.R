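#' Grad-CAM per-SNP saliency of the trained CNN
#'
#' Attributes the network's case score to SNP positions, per patient.
#' For each sample, with `A[u, f]` the convolutional activation of filter
#' `f` at position `u` and `y` the pre-sigmoid case score: the filter weight
#' is the position-averaged gradient `alpha_f = mean_u dy/dA[u, f]`; the
#' localization map is `L_u = ReLU(sum_f alpha_f * A[u, f])`; and `L` (of
#' conv-output length) is upsampled to the SNP length N by linear
#' interpolation at the window centers. Gradients are taken at the logit,
#' not the probability, so saturated outputs do not vanish the map.
#'
#' @param model A `cnn_model` (must contain a convolutional layer, which this
#'   architecture always does).
#' @param X Matrix of the patients to attribute (typically the true cases),
#'   non-empty, column count matching the model input width.
#' @param chunk Samples per forward block (memory bound).
#' @return A `saliency_map`: list with `per_patient` (patients x SNPs matrix
#'   `S`, all entries >= 0), `mean_per_snp` (column means of `S`),
#'   `normalized_mean` (`mean_per_snp` divided by its maximum, so the top SNP
#'   scores 1 whenever any score is nonzero), and `rsid`.
#' @export
grad_cam <- function(model, X, chunk = 512L) {
  stopifnot(inherits(model, "cnn_model"))
  rsid <- colnames(X)
  X <- unclass(X)
  storage.mode(X) <- "double"
  if (nrow(X) == 0) stopf("grad_cam needs at least one patient")
  if (ncol(X) != model$dims$N) {
    stopf("input width %d does not match model input width %d", ncol(X), model$dims$N)
  }
  dims <- model$dims
  idx <- nn_im2col_index(dims)
  centers <- (seq_len(dims$L) - 1L) * dims$s + (dims$k + 1) / 2
  S <- matrix(0, nrow(X), dims$N)
  w2 <- model$params$w2
  W1 <- model$params$W1

  start <- 1L
  while (start <= nrow(X)) {
    end <- min(start + chunk - 1L, nrow(X))
    Xi <- X[start:end, , drop = FALSE]
    B <- nrow(Xi)
    fwd <- nn_forward(model$params, Xi, dims, idx)
    # dy/dAflat: back through the (ungated-at-inference) dense head
    d_h <- matrix(w2, B, dims$H, byrow = TRUE) * (fwd$Hpre > 0)
    d_Aflat <- d_h %*% t(W1)                       # B x (L*F)
    dAf <- array(d_Aflat, c(B, dims$L, dims$F))
    alpha <- colMeans(aperm(dAf, c(2, 1, 3)))      # B x F (mean over u)
    # contract A[b, u, f] with alpha[b, f]
    alpha_big <- alpha[((seq_len(B * dims$L) - 1L) %% B) + 1L, , drop = FALSE]
    Lvec <- rowSums(fwd$A * alpha_big)
    Lmap <- pmax(matrix(Lvec, B, dims$L), 0)
    if (dims$L == 1L) {
      S[start:end, ] <- matrix(Lmap[, 1], B, dims$N)
    } else {
      for (b in seq_len(B)) {
        S[start + b - 1L, ] <- stats::approx(centers, Lmap[b, ],
                                             xout = seq_len(dims$N),
                                             rule = 2)$y
      }
    }
    start <- end + 1L
  }
  mean_per_snp <- colMeans(S)
  mx <- max(mean_per_snp)
  normalized <- if (mx > 0) mean_per_snp / mx else mean_per_snp
  structure(
    list(per_patient = S, mean_per_snp = mean_per_snp,
         normalized_mean = normalized, rsid = rsid),
    class = "saliency_map"
  )
}

#' @export
print.saliency_map <- function(x, ...) {
  top <- order(x$normalized_mean, decreasing = TRUE)[seq_len(min(5, length(x$normalized_mean)))]
  cat(sprintf("<saliency_map> %d patients x %d SNPs; top SNPs: %s\n",
              nrow(x$per_patient), ncol(x$per_patient),
              paste(sprintf("%s (%.3f)", x$rsid[top] %||% top,
                            x$normalized_mean[top]), collapse = ", ")))
  invisible(x)
}

#' Compare saliency with association statistics
#'
#' Pearson correlation between the max-normalized mean saliency and
#' `-log10(p)` from the association scan (capped at `cap` to bound
#' genome-wide-significant p-values), plus the top-5% saliency SNP list and
#' its overlap with SNPs passing standard association thresholds.
#'
#' @param map A `saliency_map`.
#' @param stats An [assoc_scan()] table over the same SNP universe and order.
#' @param cap Cap applied to `-log10(p)` before correlating.
#' @param assoc_thresholds Association p-value thresholds for the overlap
#'   counts.
#' @return A list: `correlation` (NA with `note = "zero variance"` when
#'   either vector is constant), `top5_rsid`, `overlap` (per-threshold counts
#'   of top-5% saliency SNPs that also pass the association threshold), `n`.
#' @export
saliency_vs_association <- function(map, stats, cap = 30,
                                    assoc_thresholds = c(5e-8, 1e-5, 0.05)) {
  if (length(map$normalized_mean) != nrow(stats)) {
    stopf("saliency length %d does not match association table rows %d",
          length(map$normalized_mean), nrow(stats))
  }
  if (!is.null(map$rsid) && !identical(as.character(map$rsid), as.character(stats$rsid))) {
    stopf("saliency map and association table disagree on SNP order")
  }
  neglogp <- pmin(-log10(stats$p_value), cap)
  sal <- map$normalized_mean
  note <- NULL
  if (stats::sd(sal) == 0 || stats::sd(neglogp) == 0) {
    correlation <- NA_real_
    note <- "zero variance"
  } else {
    correlation <- stats::cor(sal, neglogp, method = "pearson")
  }
  n_top <- max(1L, ceiling(0.05 * length(sal)))
  top_idx <- order(sal, decreasing = TRUE)[seq_len(n_top)]
  overlap <- vapply(assoc_thresholds, function(t) {
    sum(stats$p_value[top_idx] < t)
  }, numeric(1))
  names(overlap) <- format(assoc_thresholds)
  list(correlation = correlation, note = note,
       top5_rsid = stats$rsid[top_idx], overlap = overlap,
       n = length(sal))
}

#' Write a saliency table as TSV
#'
#' @param map A `saliency_map`.
#' @param stats Association table supplying coordinates (same order).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_saliency_table <- function(map, stats, path) {
  tab <- data.frame(
    rsid = stats$rsid, chrom = stats$chrom, bp = stats$bp,
    mean_saliency = map$mean_per_snp,
    normalized_saliency = map$normalized_mean,
    rank = rank(-map$normalized_mean, ties.method = "min")
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
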