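# Kinase-substrate enrichment analysis (KSEA).
#
# Kinase activity is inferred from the log2 tumor/NAT fold changes of its
# quantified substrate phospho-sites: z = (s_bar - p_bar) * sqrt(m) / delta,
# where s_bar is the mean substrate log2FC, and p_bar / delta the mean and SD
# of all quantified site log2FCs. Sites mapped to several kinases contribute
# to each. Significance comes from a permutation null: |z| under random
# substrate sets of the same size drawn without replacement from all sites.

#' KSEA z-scores
#'
#' @param site_log2fc named numeric vector: one log2 fold change per
#'   quantified phospho-site.
#' @param map kinase-substrate map (named list kinase -> site ids).
#' @param min_substrates kinases with fewer quantified substrates are
#'   omitted (reported in the `omitted` attribute). Default 3.
#' @return data.frame of class `KinaseActivity`: `kinase`, `z_score`, `m`
#'   (substrates used), `mean_substrate_log2fc`, `background_mean`,
#'   `background_sd`; attribute `omitted` lists under-covered kinases.
#' @export
ksea_zscores <- function(site_log2fc, map, min_substrates = 3) {
  if (is.null(names(site_log2fc))) stop("site_log2fc must be a named vector")
  site_log2fc <- site_log2fc[is.finite(site_log2fc)]
  if (length(site_log2fc) < 2) stop("need >= 2 quantified sites")
  p_bar <- mean(site_log2fc)
  delta <- stats::sd(site_log2fc)
  if (delta == 0) stop("background SD of site log2FCs is zero")
  rows <- lapply(names(map), function(k) {
    subs <- intersect(map[[k]], names(site_log2fc))
    m <- length(subs)
    if (m < min_substrates) return(NULL)
    s_bar <- mean(site_log2fc[subs])
    data.frame(kinase = k, z_score = (s_bar - p_bar) * sqrt(m) / delta,
               m = m, mean_substrate_log2fc = s_bar,
               background_mean = p_bar, background_sd = delta,
               stringsAsFactors = FALSE)
  })
  omitted <- names(map)[vapply(rows, is.null, TRUE)]
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(kinase = character(), z_score = numeric(), m = integer(),
                      mean_substrate_log2fc = numeric(),
                      background_mean = numeric(), background_sd = numeric())
  rownames(out) <- NULL
  attr(out, "omitted") <- omitted
  class(out) <- c("KinaseActivity", "data.frame")
  out
}

#' Permutation p-value for one kinase's KSEA score
#'
#' Two-sided p for the null that the kinase's substrates are an arbitrary
#' size-m subset of all quantified sites: random subsets are drawn without
#' replacement, |z| compared, with add-one correction
#' p = (b + 1) / (n_perm + 1).
#'
#' @inheritParams ksea_zscores
#' @param substrates site ids of the kinase (or a kinase name present in
#'   `map`, in which case `map` must be given).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the subset draws.
#' @return two-sided permutation p-value.
#' @export
ksea_permutation_p <- function(site_log2fc, substrates, n_perm = 1000, seed = 1,
                               map = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (length(substrates) == 1 && !is.null(map) && substrates %in% names(map))
    substrates <- map[[substrates]]
  site_log2fc <- site_log2fc[is.finite(site_log2fc)]
  if (length(unique(substrates)) > length(site_log2fc))
    stop("more substrates than quantified sites")
  subs <- intersect(substrates, names(site_log2fc))
  m <- length(subs)
  if (m == 0) stop("no quantified substrates")
  p_bar <- mean(site_log2fc); delta <- stats::sd(site_log2fc)
  if (delta == 0) stop("background SD of site log2FCs is zero")
  z_obs <- (mean(site_log2fc[subs]) - p_bar) * sqrt(m) / delta
  set.seed(as.integer(seed))
  z_null <- replicate(n_perm, {
    s <- sample(site_log2fc, m)
    (mean(s) - p_bar) * sqrt(m) / delta
  })
  (sum(abs(z_null) >= abs(z_obs) - 1e-12) + 1) / (n_perm + 1)
}

#' Full KSEA: z-scores, permutation p-values and BH adjustment
#'
#' @inheritParams ksea_zscores
#' @inheritParams ksea_permutation_p
#' @return `KinaseActivity` table with `permutation_p` and `bh_adjusted_p`.
#' @export
ksea <- function(site_log2fc, map, min_substrates = 3, n_perm = 1000, seed = 1) {
  out <- ksea_zscores(site_log2fc, map, min_substrates)
  out$permutation_p <- vapply(out$kinase, function(k)
    ksea_permutation_p(site_log2fc, map[[k]], n_perm = n_perm, seed = seed), 0)
  out$bh_adjusted_p <- bh_adjust(out$permutation_p)
  out
}

#' Site-level log2 tumor/NAT fold changes for KSEA
#'
#' Mean over pairs of (tumor - NAT) log2 values per site, within an optional
#' histology stratum.
#'
#' @param x log2-scale imputed phospho [abundance_matrix()].
#' @param samples [sample_info()].
#' @param histology optional histology subset.
#' @return named numeric vector of per-site log2 fold changes.
#' @export
site_log2fc <- function(x, samples, histology = NULL) {
  stopifnot(inherits(x, "AbundanceMatrix"), x$scale == "log2")
  si <- as.data.frame(samples)
  if (!is.null(histology)) si <- si[si$histology %in% histology, ]
  tum <- si[si$tissue == "tumor", ]; nat <- si[si$tissue == "NAT", ]
  pats <- intersect(tum$patient_id, nat$patient_id)
  tcol <- tum$sample_id[match(pats, tum$patient_id)]
  ncol_ <- nat$sample_id[match(pats, nat$patient_id)]
  keep <- tcol %in% colnames(x$values) & ncol_ %in% colnames(x$values)
  rowMeans(x$values[, tcol[keep], drop = FALSE] -
           x$values[, ncol_[keep], drop = FALSE])
}
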