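# Signature-based cell-type scoring: a single-sample GSEA (ssGSEA) engine
# over user-supplied GMT signatures, with immune/stroma/microenvironment
# aggregates and the Th1/Th2 indicator. This is deliberately an
# ssGSEA-over-signatures engine, not a reimplementation of any curated
# 64-signature compendium or spillover compensation; its validity surface is
# recovery of planted cell-type profiles.

#' Single-sample GSEA enrichment score
#'
#' Genes are ranked by descending expression (ties broken by original
#' order); the score is the sum over ranks of the difference between the
#' weighted in-set ECDF (weights = rank^alpha, largest expression = largest
#' rank) and the unweighted out-of-set ECDF, normalized by the number of
#' out-of-set genes. With `alpha = 0` the score depends only on ranks and is
#' invariant to monotone transforms of the expression vector.
#'
#' @param expression named numeric vector (one sample).
#' @param gene_set character vector of gene symbols.
#' @param alpha rank-weighting exponent (default 0.25).
#' @param min_overlap minimum genes of the set present among the features
#'   (default 10); below it the score is `NA` with a flag attribute.
#' @return numeric enrichment score (attribute `flag` = "low_overlap" when
#'   skipped).
#' @export
ssgsea_score <- function(expression, gene_set, alpha = 0.25, min_overlap = 10) {
  genes <- names(expression)
  if (is.null(genes)) stop("expression must be a named vector")
  in_set <- genes %in% gene_set
  n <- length(expression)
  n_in <- sum(in_set)
  if (n_in < min_overlap) {
    out <- NA_real_
    attr(out, "flag") <- "low_overlap"
    return(out)
  }
  if (n_in == n) stop("gene set covers every feature; out-of-set ECDF undefined")
  ord <- order(-expression)            # descending; ties keep original order
  in_ord <- in_set[ord]
  rk <- seq(n, 1)                      # rank weight: top gene gets n
  w <- ifelse(in_ord, rk^alpha, 0)
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_ord) / (n - n_in)
  sum(p_in - p_out) / (n - n_in)
}

#' Cell-type scores and aggregates per sample
#'
#' ssGSEA per sample and signature; aggregate columns are the mean of the
#' immune-category scores (`immune_score`), the mean of the stroma-category
#' scores (`stroma_score`), and their sum (`microenvironment_score`).
#'
#' @param x log2-scale [abundance_matrix()] (imputed) — the proteome.
#' @param signatures a [signature_set()] with category labels; at least one
#'   immune-category signature is required.
#' @param alpha,min_overlap passed to [ssgsea_score()].
#' @return data.frame of class `CellScoreTable`: one row per sample, one
#'   column per signature, plus the aggregates.
#' @export
cell_scores <- function(x, signatures, alpha = 0.25, min_overlap = 10) {
  stopifnot(inherits(x, "AbundanceMatrix"), inherits(signatures, "SignatureSet"))
  v <- x$values
  imm <- names(signatures$sets)[signatures$category == "immune"]
  if (!length(imm)) stop("no immune-category signatures; aggregates undefined")
  str_ <- names(signatures$sets)[signatures$category == "stroma"]
  scores <- sapply(names(signatures$sets), function(nm)
    apply(v, 2, function(col) {
      s <- ssgsea_score(col, signatures$sets[[nm]], alpha, min_overlap)
      as.numeric(s)
    }))
  out <- data.frame(sample = colnames(v), scores, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out$immune_score <- rowMeans(out[, imm, drop = FALSE])
  out$stroma_score <- if (length(str_)) rowMeans(out[, str_, drop = FALSE]) else 0
  out$microenvironment_score <- out$immune_score + out$stroma_score
  rownames(out) <- NULL
  class(out) <- c("CellScoreTable", "data.frame")
  out
}

#' Th1/Th2 ratio per sample
#'
#' ratio = (Th1 + eps) / (Th2 + eps). With `eps = 0` (the default; ssGSEA
#' scores of expressed toy signatures are positive by construction) samples
#' with a nonpositive Th2 + eps are returned as `NA` with a warning.
#'
#' @param scores a [cell_scores()] table with `Th1` and `Th2` columns.
#' @param eps stabilizer added to both scores (default 0).
#' @return named numeric vector of per-sample ratios.
#' @export
th1_th2_ratio <- function(scores, eps = 0) {
  if (!all(c("Th1", "Th2") %in% names(scores)))
    stop("Th1 and Th2 score columns required")
  den <- scores$Th2 + eps
  bad <- !is.finite(den) | den <= 0
  if (any(bad)) warning(sum(bad), " sample(s) with undefined Th1/Th2 ratio")
  r <- (scores$Th1 + eps) / den
  r[bad] <- NA_real_
  setNames(r, scores$sample)
}
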