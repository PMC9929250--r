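# TFRE enrichment, master-TF nomination and the kinase-TF correlation
# network.
#
# The TF-activity layer is an MS readout of DNA-binding activity (a TFRE
# pull-down), so a protein strongly over-represented there relative to the
# whole proteome is "TFRE enriched". Master TFs of a subtype must pass three
# criteria jointly: (a) activity up in tumors vs paired NATs, (b) activity up
# in the subtype vs the rest, (c) target genes enriched among the relevant
# differentially expressed proteins.

#' TFRE enrichment call
#'
#' Per protein shared by the two layers, ratio = mean normalized abundance in
#' the TF-activity layer / mean normalized abundance in the proteome;
#' enriched iff ratio > `threshold` (strictly). Annotated TFs are always
#' reported regardless of ratio. Proteins absent from the proteome are
#' flagged, not scored. Both layers should be on comparable relative scales
#' (FOT / quantile normalized, raw scale).
#'
#' @param tf_layer,proteome raw-scale normalized [abundance_matrix()]s.
#' @param annotated_tfs optional character vector of known TF symbols.
#' @param threshold enrichment ratio cutoff (default 4).
#' @return data.frame: `protein`, `ratio`, `enriched`, `is_annotated_tf`,
#'   `flag` (`ratio_undefined` for TF-layer proteins missing from the proteome).
#' @export
tfre_enrichment <- function(tf_layer, proteome, annotated_tfs = NULL,
                            threshold = 4) {
  stopifnot(inherits(tf_layer, "AbundanceMatrix"),
            inherits(proteome, "AbundanceMatrix"))
  if (tf_layer$scale != "raw" || proteome$scale != "raw")
    stop("tfre_enrichment expects raw-scale (normalized) matrices")
  prots <- rownames(tf_layer$values)
  in_prot <- prots %in% rownames(proteome$values)
  mean_tf <- rowMeans(tf_layer$values, na.rm = TRUE)
  mean_pr <- rep(NA_real_, length(prots))
  mean_pr[in_prot] <- rowMeans(proteome$values[prots[in_prot], , drop = FALSE],
                               na.rm = TRUE)
  ratio <- mean_tf / mean_pr
  out <- data.frame(protein = prots, ratio = ratio,
                    enriched = !is.na(ratio) & ratio > threshold,
                    is_annotated_tf = prots %in% annotated_tfs,
                    flag = ifelse(in_prot, NA_character_, "ratio_undefined"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Upper-tail hypergeometric enrichment
#'
#' P(X >= observed overlap) for drawing `|target_genes|` genes from the
#' universe containing `|dep_set|` successes.
#'
#' @param target_genes,dep_set,universe character vectors;
#'   `target_genes` and `dep_set` are intersected with `universe`.
#' @return upper-tail p-value.
#' @export
hypergeom_enrichment <- function(target_genes, dep_set, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  targets <- intersect(unique(target_genes), universe)
  deps <- intersect(unique(dep_set), universe)
  if (!length(targets)) stop("no target genes in the universe")
  q <- length(intersect(targets, deps))
  stats::phyper(q - 1, m = length(deps), n = length(universe) - length(deps),
                k = length(targets), lower.tail = FALSE)
}

#' Nominate master TFs
#'
#' Evaluates, per TF and subtype: (a) paired tumor-vs-NAT upregulation of
#' activity (signed-rank p < `alpha`, fold change > `fc_tumor`); (b)
#' subtype-vs-rest upregulation (rank-sum p < `alpha`, fold change >
#' `fc_subtype`); (c) hypergeometric enrichment of the TF's target genes
#' among the supplied DEP set (p < `alpha`). Nominated iff all three pass.
#' TFs with no targets in the network are flagged and never nominated.
#'
#' @param tf_layer log2-scale imputed TF-activity [abundance_matrix()]
#'   covering paired tumor/NAT samples.
#' @param samples [sample_info()].
#' @param subtype_labels named integer/character vector: tumor patient id ->
#'   subtype label (one histology stratum at a time).
#' @param network TF -> target-gene list.
#' @param deps DEP gene set for criterion (c): either a character vector used
#'   for every subtype, or a named list with one set per subtype level. Use
#'   the up- or down-regulated set as the biological query demands.
#' @param universe gene universe for the hypergeometric test; default all
#'   quantified proteins supplied here explicitly.
#' @param alpha p-value threshold shared by all three criteria (default 0.05).
#' @param fc_tumor,fc_subtype fold-change thresholds for (a) and (b); the
#'   subtype bar is lower (1.5) because activity readouts are noisier.
#' @return data.frame of class `MasterTFResult`: per TF x subtype, the three
#'   criteria's p-values and fold changes, `nominated`, `flag`.
#' @export
nominate_master_tfs <- function(tf_layer, samples, subtype_labels, network,
                                deps, universe, alpha = 0.05,
                                fc_tumor = 2, fc_subtype = 1.5) {
  stopifnot(inherits(tf_layer, "AbundanceMatrix"), tf_layer$scale == "log2")
  v <- tf_layer$values
  si <- as.data.frame(samples)
  pats <- names(subtype_labels)
  si <- si[si$patient_id %in% pats, ]
  tum <- si[si$tissue == "tumor", ]; nat <- si[si$tissue == "NAT", ]
  common <- intersect(tum$patient_id, nat$patient_id)
  tcol <- tum$sample_id[match(common, tum$patient_id)]
  ncol_ <- nat$sample_id[match(common, nat$patient_id)]
  subtypes <- sort(unique(subtype_labels))
  tum_pat <- tum$patient_id[match(tum$sample_id, tum$sample_id)]
  rows <- list(); i <- 0L
  for (tf in rownames(v)) {
    # criterion (a): tumor vs NAT, shared across subtypes. The fold change
    # uses the mean ratio: a master TF's activity gain is concentrated in
    # its subtype, and the median would discard exactly that signal.
    wa <- paired_wilcoxon(v[tf, tcol], v[tf, ncol_])
    fca <- fold_change(2^v[tf, tcol], 2^v[tf, ncol_], "mean_ratio")
    pass_a <- wa$p_value < alpha && fca > fc_tumor
    targets <- network[[tf]]
    no_targets <- is.null(targets) || !length(targets)
    for (s in subtypes) {
      in_s <- tum$sample_id[subtype_labels[tum$patient_id] == s]
      out_s <- setdiff(tum$sample_id, in_s)
      wb <- ranksum(v[tf, in_s], v[tf, out_s])
      fcb <- fold_change(2^v[tf, in_s], 2^v[tf, out_s], "median_ratio")
      pass_b <- wb$p_value < alpha && fcb > fc_subtype
      dep_s <- if (is.list(deps)) deps[[as.character(s)]] else deps
      pc <- if (no_targets) NA_real_
            else hypergeom_enrichment(targets, dep_s, universe)
      pass_c <- !is.na(pc) && pc < alpha
      i <- i + 1L
      rows[[i]] <- data.frame(
        tf = tf, subtype = s,
        tumor_p = wa$p_value, tumor_fc = fca,
        subtype_p = wb$p_value, subtype_fc = fcb,
        target_enrichment_p = pc,
        nominated = pass_a && pass_b && pass_c,
        flag = if (no_targets) "no_targets" else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("MasterTFResult", "data.frame")
  out
}

#' Spearman correlation with the field's two-sided p convention
#'
#' Exact permutation null for n <= 9 without ties, t-approximation otherwise
#' (the stats::cor.test behavior). Constant vectors yield `NA` with a flag.
#'
#' @param x,y numeric vectors.
#' @return list `rho`, `p_value`, `flag`.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, flag = "constant_or_short"))
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = length(x) <= 9))
  list(rho = unname(ht$estimate), p_value = ht$p.value, flag = NA_character_)
}

#' Kinase-TF signaling network from activity/phospho-site correlations
#'
#' Pairwise Spearman correlation between each kinase's per-sample activity
#' and each TF phospho-site; retained edges have rho > 0 and p < `alpha`.
#' Pairs with fewer than `min_samples` shared samples, or a constant vector,
#' are skipped with a flag.
#'
#' @param kinase_activity kinase x sample numeric matrix.
#' @param tf_sites site x sample numeric matrix (phospho-sites on TFs).
#' @param alpha significance threshold (default 0.05).
#' @param min_samples minimum shared samples per pair (default 5).
#' @return data.frame of class `KinaseTFEdge`: `kinase`, `site`,
#'   `spearman_rho`, `p_value`, `retained`, `flag`.
#' @export
kinase_tf_network <- function(kinase_activity, tf_sites, alpha = 0.05,
                              min_samples = 5) {
  shared <- intersect(colnames(kinase_activity), colnames(tf_sites))
  rows <- list(); i <- 0L
  for (k in rownames(kinase_activity)) for (s in rownames(tf_sites)) {
    xa <- kinase_activity[k, shared]; ys <- tf_sites[s, shared]
    ok <- is.finite(xa) & is.finite(ys)
    i <- i + 1L
    if (sum(ok) < min_samples) {
      rows[[i]] <- data.frame(kinase = k, site = s, spearman_rho = NA_real_,
                              p_value = NA_real_, retained = FALSE,
                              flag = "too_few_samples", stringsAsFactors = FALSE)
      next
    }
    sc <- spearman_cor(xa[ok], ys[ok])
    rows[[i]] <- data.frame(kinase = k, site = s, spearman_rho = sc$rho,
                            p_value = sc$p_value,
                            retained = !is.na(sc$rho) && sc$rho > 0 &&
                              !is.na(sc$p_value) && sc$p_value < alpha,
                            flag = sc$flag, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("KinaseTFEdge", "data.frame")
  out
}

#' Per-sample kinase activity matrix
#'
#' Simple substrate-mean activity: for each kinase, the mean (across its
#' quantified substrate sites) of centered log2 site abundances, per sample.
#' Used as the kinase axis of [kinase_tf_network()].
#'
#' @param x log2-scale imputed phospho [abundance_matrix()].
#' @param map kinase-substrate map.
#' @param min_substrates minimum quantified substrates (default 3).
#' @return kinase x sample matrix.
#' @export
kinase_sample_activity <- function(x, map, min_substrates = 3) {
  stopifnot(inherits(x, "AbundanceMatrix"), x$scale == "log2")
  v <- x$values - rowMeans(x$values, na.rm = TRUE)
  rows <- lapply(names(map), function(k) {
    subs <- intersect(map[[k]], rownames(v))
    if (length(subs) < min_substrates) return(NULL)
    colMeans(v[subs, , drop = FALSE], na.rm = TRUE)
  })
  keep <- !vapply(rows, is.null, TRUE)
  out <- do.call(rbind, rows[keep])
  rownames(out) <- names(map)[keep]
  out
}
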