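# Differential screens: paired tumor-vs-NAT (Wilcoxon signed-rank) and
# unpaired group contrasts (Wilcoxon rank-sum), BH correction, fold changes,
# DEP calling, and the six-group histology partition.

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided p-value for paired vectors. Zero differences are dropped
#' (Wilcoxon's convention). The exact signed-rank null is used for n <= 25
#' without tied |differences|; with ties, an explicit sign-flip enumeration
#' is used up to n = 14; beyond those, the normal approximation with
#' continuity and tie correction. Two-sided p is 2 * min(tail), capped at 1.
#'
#' @param tumor,nat equal-length paired numeric vectors.
#' @return list with `p_value`, `n_used` (pairs after dropping zero
#'   differences), `statistic` (V, sum of positive ranks) and `all_zero` flag
#'   (in which case p = 1).
#' @export
paired_wilcoxon <- function(tumor, nat) {
  if (length(tumor) != length(nat)) stop("paired vectors must have equal length")
  ok <- is.finite(tumor) & is.finite(nat)
  d <- tumor[ok] - nat[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(p_value = 1, n_used = 0L, statistic = NA_real_,
                          all_zero = TRUE))
  if (n < 3) stop("need >= 3 nonzero paired differences")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  if (!ties && n <= 25) {
    p <- suppressWarnings(stats::wilcox.test(d, exact = TRUE)$p.value)
  } else if (ties && n <= 14) {
    # exact sign-flip enumeration conditional on the observed |d| midranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    W <- signs %*% r
    p <- min(1, 2 * min(mean(W <= V + 1e-9), mean(W >= V - 1e-9)))
  } else {
    p <- suppressWarnings(stats::wilcox.test(d, exact = FALSE, correct = TRUE)$p.value)
  }
  list(p_value = p, n_used = n, statistic = V, all_zero = FALSE)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided p; exact null when both groups are untied and the smaller group
#' has <= 10 observations, otherwise the tie-corrected normal approximation
#' with continuity correction.
#'
#' @param a,b numeric vectors (both non-empty).
#' @return list with `p_value`, `statistic` (W for group `a`), group sizes.
#' @export
ranksum <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && min(length(a), length(b)) <= 10
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(p_value = ht$p.value, statistic = unname(ht$statistic),
       n_a = length(a), n_b = length(b))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, capped at 1 and monotone in rank; invariant to
#' the input order. `NA`s propagate.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fold change between paired or grouped positive values
#'
#' @param tumor,nat positive numeric vectors (imputed; zero denominators are
#'   rejected). For `paired_median_of_ratios` the vectors must be paired.
#' @param method `mean_ratio` (ratio of group means), `median_ratio` (ratio
#'   of group medians) or `paired_median_of_ratios` (median of per-pair
#'   tumor/NAT ratios).
#' @return fold change on the linear (ratio) scale.
#' @export
fold_change <- function(tumor, nat,
                        method = c("paired_median_of_ratios", "median_ratio",
                                   "mean_ratio")) {
  method <- match.arg(method)
  tumor <- tumor[is.finite(tumor)]; nat <- nat[is.finite(nat)]
  if (any(tumor <= 0) || any(nat <= 0))
    stop("fold change requires strictly positive values (impute first)")
  switch(method,
         mean_ratio = mean(tumor) / mean(nat),
         median_ratio = stats::median(tumor) / stats::median(nat),
         paired_median_of_ratios = {
           if (length(tumor) != length(nat))
             stop("paired_median_of_ratios needs paired vectors")
           stats::median(tumor / nat)
         })
}

#' Feature-wise differential screen
#'
#' For `tumor_vs_nat`: paired signed-rank test per feature across the
#' tumor/NAT pairs of the selected histology (or all). For `group_vs_group`
#' (e.g. DGC vs IGC tumors, or subtype vs rest): rank-sum test. Tests run on
#' log2 values; fold changes on the linear scale. BH correction is applied
#' across all tested features.
#'
#' @param x log2-scale imputed [abundance_matrix()].
#' @param samples [sample_info()] covering all columns.
#' @param contrast `"tumor_vs_nat"` or `"group_vs_group"`.
#' @param histology optional subset (`"DGC"`, `"IGC"`) for the paired contrast.
#' @param groups for `group_vs_group`: named vector/factor over a subset of
#'   sample ids with exactly two levels; level order defines the ratio
#'   (first / second).
#' @param fc_method see [fold_change()]; the paired default is the median of
#'   per-pair ratios, the unpaired default the ratio of group medians.
#' @param fc_threshold,alpha thresholds used to annotate `direction`
#'   (up / down / ns) per the DEP convention.
#' @return data.frame of class `DifferentialResult`: `feature`, `p_value`,
#'   `bh_adjusted_p`, `fold_change`, `direction`, `n`.
#' @export
differential_expression <- function(x, samples,
                                    contrast = c("tumor_vs_nat", "group_vs_group"),
                                    histology = NULL, groups = NULL,
                                    fc_method = NULL,
                                    fc_threshold = 2, alpha = 0.05) {
  stopifnot(inherits(x, "AbundanceMatrix"))
  if (x$scale != "log2") stop("differential screens expect a log2 matrix")
  contrast <- match.arg(contrast)
  v <- x$values
  si <- as.data.frame(samples)
  if (contrast == "tumor_vs_nat") {
    if (is.null(fc_method)) fc_method <- "paired_median_of_ratios"
    if (!is.null(histology)) si <- si[si$histology %in% histology, ]
    tum <- si[si$tissue == "tumor", ]
    nat <- si[si$tissue == "NAT", ]
    pats <- intersect(tum$patient_id, nat$patient_id)
    tcol <- tum$sample_id[match(pats, tum$patient_id)]
    ncol_ <- nat$sample_id[match(pats, nat$patient_id)]
    keep <- tcol %in% colnames(v) & ncol_ %in% colnames(v)
    tcol <- tcol[keep]; ncol_ <- ncol_[keep]
    if (length(tcol) < 3) stop("need >= 3 complete pairs")
    a <- v[, tcol, drop = FALSE]; b <- v[, ncol_, drop = FALSE]
    res <- lapply(seq_len(nrow(v)), function(i) {
      # features with < 3 nonzero differences (e.g. mostly imputed to the
      # layer minimum) carry no paired signal: p = NA -> direction ns
      w <- tryCatch(paired_wilcoxon(a[i, ], b[i, ]),
                    error = function(e) list(p_value = NA_real_, n_used = 0L))
      fc <- fold_change(2^a[i, ], 2^b[i, ], method = fc_method)
      c(p = w$p_value, fc = fc, n = w$n_used)
    })
  } else {
    if (is.null(fc_method)) fc_method <- "median_ratio"
    if (is.null(groups)) stop("'groups' required for group_vs_group")
    g <- factor(groups)
    if (nlevels(g) != 2) stop("'groups' must have exactly two levels")
    ga <- names(groups)[g == levels(g)[1]]
    gb <- names(groups)[g == levels(g)[2]]
    ga <- intersect(ga, colnames(v)); gb <- intersect(gb, colnames(v))
    res <- lapply(seq_len(nrow(v)), function(i) {
      w <- ranksum(v[i, ga], v[i, gb])
      fc <- fold_change(2^v[i, ga], 2^v[i, gb], method = fc_method)
      c(p = w$p_value, fc = fc, n = length(ga) + length(gb))
    })
  }
  res <- do.call(rbind, res)
  out <- data.frame(feature = rownames(v), p_value = res[, "p"],
                    bh_adjusted_p = bh_adjust(res[, "p"]),
                    fold_change = res[, "fc"], n = res[, "n"],
                    stringsAsFactors = FALSE)
  out$direction <- with(out, ifelse(
    !is.na(bh_adjusted_p) & bh_adjusted_p < alpha & fold_change > fc_threshold, "up",
    ifelse(!is.na(bh_adjusted_p) & bh_adjusted_p < alpha &
             fold_change < 1 / fc_threshold, "down", "ns")))
  rownames(out) <- NULL
  class(out) <- c("DifferentialResult", "data.frame")
  out
}

#' Call differentially expressed features
#'
#' `up` = fold change strictly above the threshold and adjusted p below
#' alpha; `down` = fold change strictly below 1/threshold. Defaults mirror
#' the usual screen (2-fold, BH p < 0.05). A feature at exactly the
#' threshold is not called.
#'
#' @param results a [differential_expression()] table (BH already applied).
#' @param fc_threshold ratio-scale threshold (> 1).
#' @param alpha significance level on the adjusted p.
#' @return list with character vectors `up` and `down`.
#' @export
screen_deps <- function(results, fc_threshold = 2, alpha = 0.05) {
  if (fc_threshold <= 1) stop("fc_threshold must be > 1")
  need <- c("feature", "bh_adjusted_p", "fold_change")
  if (!all(need %in% names(results))) stop("not a DifferentialResult table")
  sig <- !is.na(results$bh_adjusted_p) & results$bh_adjusted_p < alpha
  list(up = results$feature[sig & results$fold_change > fc_threshold],
       down = results$feature[sig & results$fold_change < 1 / fc_threshold])
}

#' Six-group partition of histology-differential features
#'
#' Features whose tumor/NAT ratios differ by >= 2-fold between the two
#' histologies (ratio of ratios) are partitioned by direction pattern:
#' group 1 = up in both, DGC-dominant (DGC ratio >= 2x IGC ratio);
#' group 2 = up in both, IGC-dominant; group 3 = up in DGC, down in IGC;
#' group 4 = down in both, DGC-dominant (DGC ratio <= IGC ratio / 2);
#' group 5 = down in both, IGC-dominant; group 6 = down in DGC, up in IGC.
#' The dominance rule is a declared convention (2-fold ratio of ratios);
#' features lacking either ratio or with a non-significant direction in
#' either histology are excluded with a flag.
#'
#' @param dgc,igc [differential_expression()] tables (tumor_vs_nat within
#'   each histology) sharing a `feature` column.
#' @return list of class `SixGroupPartition`: `groups` (data.frame feature,
#'   group), `counts` (per-group), `excluded` (data.frame feature, flag).
#' @export
partition_six_groups <- function(dgc, igc) {
  m <- merge(dgc[, c("feature", "fold_change", "direction")],
             igc[, c("feature", "fold_change", "direction")],
             by = "feature", suffixes = c("_dgc", "_igc"), all = TRUE)
  lack <- is.na(m$fold_change_dgc) | is.na(m$fold_change_igc)
  rr <- m$fold_change_dgc / m$fold_change_igc
  pass2fold <- !lack & (rr >= 2 | rr <= 0.5)
  dir_ok <- !lack & m$direction_dgc != "ns" & m$direction_igc != "ns"
  keep <- pass2fold & dir_ok
  grp <- rep(NA_integer_, nrow(m))
  up_d <- m$direction_dgc == "up"; up_i <- m$direction_igc == "up"
  grp[keep & up_d & up_i & rr >= 2] <- 1L
  grp[keep & up_d & up_i & rr <= 0.5] <- 2L
  grp[keep & up_d & !up_i] <- 3L
  grp[keep & !up_d & !up_i & rr <= 0.5] <- 4L
  grp[keep & !up_d & !up_i & rr >= 2] <- 5L
  grp[keep & !up_d & up_i] <- 6L
  flag <- ifelse(lack, "missing_ratio",
                 ifelse(!pass2fold, "below_2fold",
                        ifelse(!dir_ok, "ns_direction", NA)))
  # up-up features with 0.5 < rr < 2 can't occur here (filtered), but a
  # kept feature could still miss both dominance arms only if rr is NA
  out <- list(groups = data.frame(feature = m$feature[!is.na(grp)],
                                  group = grp[!is.na(grp)],
                                  stringsAsFactors = FALSE),
              counts = table(factor(grp[!is.na(grp)], levels = 1:6)),
              excluded = data.frame(feature = m$feature[is.na(grp)],
                                    flag = flag[is.na(grp)],
                                    stringsAsFactors = FALSE))
  class(out) <- "SixGroupPartition"
  out
}

#' @export
print.SixGroupPartition <- function(x, ...) {
  cat("SixGroupPartition:", paste(sprintf("g%d=%d", 1:6, as.integer(x$counts)),
                                  collapse = " "), "\n")
  invisible(x)
}
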