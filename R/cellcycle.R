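# Cell-cycle module scoring and phase assignment.
#
# The module score follows the Tirosh/Seurat construction: genes are binned
# by average expression, each module gene draws control genes from its bin,
# and the per-sample score is mean(module genes) - mean(control genes). A
# sample is S when s_score > g2m_score and s_score > 0; G2M when
# g2m_score >= s_score and g2m_score > 0; otherwise G1.

#' Expression-bin-matched module score
#'
#' @param x log2-scale imputed [abundance_matrix()] or matrix.
#' @param gene_set module genes (>= 2 must be quantified).
#' @param n_bins expression bins over the per-gene average (default 24).
#' @param n_ctrl control genes drawn per module gene, with replacement
#'   (default 100). A bin with no non-module genes falls back to the nearest
#'   non-empty bin with a warning.
#' @param seed integer seed for the control draws.
#' @return named numeric vector: one score per sample.
#' @export
module_score <- function(x, gene_set, n_bins = 24, n_ctrl = 100, seed = 1) {
  if (inherits(x, "AbundanceMatrix")) {
    stopifnot(x$scale == "log2")
    x <- x$values
  }
  genes <- rownames(x)
  mod <- intersect(gene_set, genes)
  if (length(mod) < 2) stop("fewer than 2 module genes quantified")
  avg <- rowMeans(x)
  # equal-occupancy bins on the rank of average expression
  bin <- cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  names(bin) <- genes
  non_mod <- setdiff(genes, mod)
  set.seed(as.integer(seed))
  ctrl <- unlist(lapply(mod, function(g) {
    b <- bin[[g]]
    pool <- non_mod[bin[non_mod] == b]
    if (!length(pool)) {
      warning("bin without non-module genes; drawing from nearest bin")
      db <- abs(bin[non_mod] - b)
      pool <- non_mod[db == min(db)]
    }
    sample(pool, n_ctrl, replace = TRUE)
  }), use.names = FALSE)
  colMeans(x[mod, , drop = FALSE]) - colMeans(x[ctrl, , drop = FALSE])
}

#' Assign cell-cycle phase from S and G2/M scores
#'
#' @param s_score,g2m_score numeric vectors (same length / names).
#' @return character vector in `{G1, S, G2M}` per the rule: S iff
#'   s > g2m and s > 0; G2M iff g2m >= s and g2m > 0; else G1.
#' @export
assign_phase <- function(s_score, g2m_score) {
  if (length(s_score) != length(g2m_score)) stop("score vectors must align")
  out <- ifelse(s_score > g2m_score & s_score > 0, "S",
                ifelse(g2m_score >= s_score & g2m_score > 0, "G2M", "G1"))
  names(out) <- names(s_score)
  out
}

#' Score and phase every sample
#'
#' @inheritParams module_score
#' @param s_genes,g2m_genes the two phase modules (e.g. from a GMT).
#' @return data.frame of class `PhaseAssignment`: `sample`, `s_score`,
#'   `g2m_score`, `phase`.
#' @export
cellcycle_phases <- function(x, s_genes, g2m_genes, n_bins = 24, n_ctrl = 100,
                             seed = 1) {
  s <- module_score(x, s_genes, n_bins, n_ctrl, seed)
  g <- module_score(x, g2m_genes, n_bins, n_ctrl, seed + 1L)
  out <- data.frame(sample = names(s), s_score = unname(s),
                    g2m_score = unname(g),
                    phase = unname(assign_phase(s, g)),
                    stringsAsFactors = FALSE)
  class(out) <- c("PhaseAssignment", "data.frame")
  out
}
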