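# Consensus-clustering subtype discovery (Monti resampling construction),
# CDF/delta-area k selection, subtype signature extraction, and
# cross-classification concordance.

#' Consensus clustering by resampled hierarchical clustering
#'
#' For each of `reps` repetitions, a fraction of the samples is drawn
#' without replacement, clustered by agglomerative linkage on Euclidean
#' distance, and cut at every k in `k_range`. consensus(i, j) = co-cluster
#' count / co-sample count. Final labels per k come from hierarchical
#' clustering of (1 - consensus). The per-k consensus CDF area and the
#' relative delta-area follow the Monti construction: A(k) is the integral
#' of the empirical CDF of the upper-triangle consensus entries over [0, 1]
#' (equivalently 1 - mean consensus), delta(2) = A(2), and
#' delta(k) = (A(k) - A(k-1)) / A(k-1) for k > 2.
#'
#' @param x feature x sample numeric matrix (log2 scale), or a log2
#'   [abundance_matrix()]; features are pre-filtered by the caller.
#' @param k_range integer cluster numbers to evaluate (within \[2, n-1\]).
#' @param reps resampling repetitions (>= 2; default 1000).
#' @param subsample_fraction fraction of samples drawn per repetition.
#' @param feature_fraction fraction of features drawn per repetition
#'   (default 0.8). Item resampling alone leaves the pairwise geometry of
#'   the retained samples fixed, so structureless data can yield a crisp
#'   consensus; feature resampling re-randomizes the noise per repetition,
#'   which makes the PAC ambiguity diagnostic of [select_k()] informative.
#'   Set to 1 to disable.
#' @param linkage agglomerative linkage for both the inner clustering and
#'   the final consensus clustering (default "average").
#' @param seed integer seed; results are deterministic given the seed.
#' @return object of class `ConsensusResult`: `consensus` (list of per-k
#'   matrices), `labels` (list of per-k named label vectors), `cdf_area`,
#'   `delta_area`, `k_range`, `params`, `seed`. Pairs never co-sampled are
#'   flagged (`n_never_cosampled`) and treated as consensus 0 with a warning.
#' @export
consensus_cluster <- function(x, k_range = 2:6, reps = 1000,
                              subsample_fraction = 0.8, feature_fraction = 0.8,
                              linkage = "average", seed = 1) {
  if (inherits(x, "AbundanceMatrix")) x <- x$values
  n <- ncol(x)
  if (reps < 2) stop("reps must be >= 2")
  if (min(k_range) < 2 || max(k_range) > n - 1)
    stop("k_range must lie within [2, n-1]")
  ids <- colnames(x)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  m <- max(2, floor(subsample_fraction * n))
  nf <- nrow(x)
  mf <- max(2, floor(feature_fraction * nf))
  set.seed(as.integer(seed))
  nk <- length(k_range)
  I <- array(0L, c(n, n, nk))
  M <- matrix(0L, n, n)
  for (r in seq_len(reps)) {
    idx <- sort(sample.int(n, m))
    fidx <- if (mf < nf) sample.int(nf, mf) else seq_len(nf)
    hc <- stats::hclust(stats::dist(t(x[fidx, idx, drop = FALSE])),
                        method = linkage)
    M[idx, idx] <- M[idx, idx] + 1L
    for (ki in seq_along(k_range)) {
      cl <- stats::cutree(hc, k_range[ki])
      for (g in unique(cl)) {
        ii <- idx[cl == g]
        I[ii, ii, ki] <- I[ii, ii, ki] + 1L
      }
    }
  }
  never <- M == 0 & upper.tri(M)
  if (any(never))
    warning(sum(never), " sample pair(s) never co-sampled; consensus set to 0")
  consensus <- labels <- vector("list", nk)
  A <- numeric(nk)
  for (ki in seq_len(nk)) {
    cm <- I[, , ki] / pmax(M, 1L)
    diag(cm) <- 1
    dimnames(cm) <- list(ids, ids)
    consensus[[ki]] <- cm
    hc <- stats::hclust(stats::as.dist(1 - cm), method = linkage)
    labels[[ki]] <- setNames(stats::cutree(hc, k_range[ki]), ids)
    A[ki] <- 1 - mean(cm[upper.tri(cm)])   # integral of the consensus ECDF
  }
  delta <- A
  if (nk > 1)
    for (ki in 2:nk) delta[ki] <- (A[ki] - A[ki - 1]) / A[ki - 1]
  names(consensus) <- names(labels) <- names(A) <- names(delta) <-
    paste0("k", k_range)
  structure(list(consensus = consensus, labels = labels, cdf_area = A,
                 delta_area = delta, k_range = k_range,
                 n_never_cosampled = sum(never),
                 params = list(reps = reps,
                               subsample_fraction = subsample_fraction,
                               feature_fraction = feature_fraction,
                               distance = "euclidean", linkage = linkage),
                 seed = as.integer(seed)),
            class = "ConsensusResult")
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat("ConsensusResult over k =", paste(x$k_range, collapse = ","),
      sprintf("(%d reps, fraction %.2f, %s linkage)\n", x$params$reps,
              x$params$subsample_fraction, x$params$linkage))
  print(round(rbind(cdf_area = x$cdf_area, delta_area = x$delta_area), 3))
  invisible(x)
}

#' Select the number of clusters from a consensus result
#'
#' chosen_k = argmax of the relative delta-area over the evaluated k; the
#' argmax is always returned, never silently overridden. Structureless data
#' are flagged via the proportion of ambiguous clustering (PAC): the
#' fraction of a consensus matrix's entries falling strictly inside
#' (0.1, 0.9). Real structure makes the consensus crisp at the true k, so
#' the minimum PAC across the evaluated k is near 0; with no structure no k
#' is crisp and the minimum stays high. The report sets `ambiguous` when
#' `min_k PAC > pac_threshold`. If survival endpoints are supplied, a per-k
#' log-rank p-value is reported as an advisory column (mirroring how a
#' clear survival split can support a manual choice), without affecting
#' chosen_k.
#'
#' @param result a [consensus_cluster()] object.
#' @param times,events optional per-sample survival endpoints, named by
#'   sample id (or in the column order of the clustered matrix).
#' @param pac_threshold minimum-PAC level above which the profile is flagged
#'   ambiguous (default 0.1).
#' @return list: `chosen_k`, `ambiguous`, `pac` (at the chosen k), `report`
#'   (data.frame k, cdf_area, delta_area, pac, and logrank_p when survival
#'   was supplied).
#' @export
select_k <- function(result, times = NULL, events = NULL, pac_threshold = 0.1) {
  stopifnot(inherits(result, "ConsensusResult"))
  delta <- result$delta_area
  chosen <- result$k_range[which.max(delta)]
  pac <- vapply(result$consensus, function(cm) {
    v <- cm[upper.tri(cm)]
    mean(v > 0.1 & v < 0.9)
  }, 0)
  pac_chosen <- unname(pac[paste0("k", chosen)])
  ambiguous <- min(pac) > pac_threshold
  report <- data.frame(k = result$k_range, cdf_area = unname(result$cdf_area),
                       delta_area = unname(delta), pac = unname(pac))
  if (!is.null(times)) {
    if (is.null(events)) stop("events required with times")
    report$logrank_p <- vapply(seq_along(result$k_range), function(ki) {
      lab <- result$labels[[ki]]
      tt <- if (!is.null(names(times))) times[names(lab)] else times
      ee <- if (!is.null(names(events))) events[names(lab)] else events
      ok <- is.finite(tt) & is.finite(ee)
      if (sum(ee[ok]) == 0 || length(unique(lab[ok])) < 2) return(NA_real_)
      logrank_test(tt[ok], ee[ok], lab[ok])$p_value
    }, 0)
  }
  list(chosen_k = chosen, ambiguous = ambiguous, pac = pac_chosen,
       report = report)
}

#' Subtype signature features
#'
#' One-vs-rest rank-sum p and fold change per feature and subtype; signature
#' = fold change > `fc_threshold` and p < `alpha`. With `top_n`, the top n
#' by ascending p (fold change breaking ties) are returned per subtype —
#' the cross-cohort projection convention.
#'
#' @param x log2-scale imputed [abundance_matrix()] or matrix (tumors only).
#' @param labels named subtype label vector over the columns of `x`.
#' @param fc_threshold,alpha signature thresholds (defaults 2 and 0.05; raw,
#'   not BH-adjusted p, per the signature convention).
#' @param top_n optional cap per subtype (e.g. 200 for projection).
#' @return named list (one element per subtype) of data.frames `feature`,
#'   `p_value`, `fold_change`, ordered by ascending p.
#' @export
signature_proteins <- function(x, labels, fc_threshold = 2, alpha = 0.05,
                               top_n = NULL) {
  if (inherits(x, "AbundanceMatrix")) {
    stopifnot(x$scale == "log2")
    x <- x$values
  }
  labels <- labels[intersect(names(labels), colnames(x))]
  subtypes <- sort(unique(labels))
  if (length(subtypes) < 2) stop("need >= 2 subtypes")
  if (any(table(labels) < 3)) warning("subtype with fewer than 3 samples")
  out <- lapply(subtypes, function(s) {
    in_s <- names(labels)[labels == s]
    out_s <- names(labels)[labels != s]
    res <- t(vapply(rownames(x), function(f) {
      c(p = ranksum(x[f, in_s], x[f, out_s])$p_value,
        fc = fold_change(2^x[f, in_s], 2^x[f, out_s], "median_ratio"))
    }, c(p = 0, fc = 0)))
    df <- data.frame(feature = rownames(x), p_value = res[, "p"],
                     fold_change = res[, "fc"], stringsAsFactors = FALSE)
    df <- df[which(df$fold_change > fc_threshold & df$p_value < alpha), ]
    df <- df[order(df$p_value, -df$fold_change), ]
    if (!is.null(top_n)) df <- utils::head(df, top_n)
    rownames(df) <- NULL
    df
  })
  names(out) <- as.character(subtypes)
  out
}

#' Round a percentage half away from zero
#'
#' @param count,total nonnegative counts.
#' @param digits decimal places of the reported percentage (default 0).
#' @return `100 * count / total`, rounded half away from zero.
#' @export
subset_percentage <- function(count, total, digits = 0) {
  if (any(total <= 0)) stop("total must be positive")
  x <- 100 * count / total
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Classification concordance between two labelings
#'
#' Pearson chi-square (no continuity correction) on the contingency table of
#' two cluster assignments over shared items, plus, per cluster of the first
#' labeling, the percentage of its members falling in their modal cluster of
#' the second labeling (rounded half away from zero).
#'
#' @param labels_a,labels_b named label vectors; intersected on names.
#' @param digits decimal places for the subset percentages.
#' @return list: `chi2`, `df`, `p_value`, `table`, `subset_percentages`
#'   (data.frame cluster_a, modal_cluster_b, count, total, percent).
#' @export
concordance_test <- function(labels_a, labels_b, digits = 0) {
  shared <- intersect(names(labels_a), names(labels_b))
  if (length(shared) < 2) stop("need >= 2 shared items")
  a <- factor(labels_a[shared]); b <- factor(labels_b[shared])
  tab <- table(a, b)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("degenerate contingency table (single row or column)")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  sp <- do.call(rbind, lapply(rownames(tab), function(ca) {
    row <- tab[ca, ]
    mb <- names(row)[which.max(row)]
    data.frame(cluster_a = ca, modal_cluster_b = mb,
               count = as.integer(max(row)), total = as.integer(sum(row)),
               percent = subset_percentage(max(row), sum(row), digits),
               stringsAsFactors = FALSE)
  }))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, table = tab, subset_percentages = sp)
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted-for-chance agreement; 1 = identical partitions up
#' to relabeling, ~0 = random agreement.
#'
#' @param a,b label vectors of equal length (names, if present, are aligned).
#' @return numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  if (length(a) != length(b)) stop("label vectors must align")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_idx - expected)
}
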