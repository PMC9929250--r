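# Normalization and sample-level QC.
#
# Layer conventions: the proteome is FOT-normalized (fraction of total,
# scaled to 1e6), the phospho and TF-activity layers are quantile-normalized;
# analysis then proceeds on log2 values with minimum-value imputation. The
# ordering of imputation vs transform is up to the caller, because published
# practice is not uniform; the helpers compose freely.

#' Fraction-of-total (FOT) normalization
#'
#' Each sample column is divided by its sum over non-missing entries and
#' multiplied by 1e6 (parts-per-million of total signal). Missing entries
#' stay missing; column sums of the result equal 1e6 exactly.
#'
#' @param x raw-scale [abundance_matrix()].
#' @return raw-scale AbundanceMatrix.
#' @export
fot_normalize <- function(x) {
  stopifnot(inherits(x, "AbundanceMatrix"))
  if (x$scale != "raw") stop("FOT normalization applies to raw-scale matrices")
  cs <- colSums(x$values, na.rm = TRUE)
  all_na <- colSums(!is.na(x$values)) == 0
  if (any(all_na | cs <= 0))
    stop("sample(s) with no observed signal: ",
         paste(colnames(x$values)[all_na | cs <= 0], collapse = ", "))
  x$values <- sweep(x$values, 2, cs, "/") * 1e6
  x
}

#' Quantile normalization
#'
#' After normalization every column's sorted values equal the cross-column
#' mean of order statistics; ties within a column receive the mean of the
#' reference values they span, and missing entries are excluded from ranking
#' and remain missing (the limma convention, which this wraps).
#'
#' @param x an [abundance_matrix()] (any scale).
#' @return AbundanceMatrix of the same scale.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "AbundanceMatrix"))
  if (ncol(x$values) < 2) {
    warning("single-column matrix: quantile normalization is the identity")
    return(x)
  }
  v <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(v) <- dimnames(x$values)
  x$values <- v
  x
}

#' Log2 transform
#'
#' @param x raw-scale AbundanceMatrix with strictly positive observed values
#'   (impute first if zeros are possible).
#' @return log2-scale AbundanceMatrix.
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "AbundanceMatrix"))
  if (x$scale != "raw") stop("matrix is already on the log2 scale")
  if (any(x$values <= 0, na.rm = TRUE))
    stop("non-positive values present; impute before log2 transform")
  x$values <- log2(x$values)
  x$scale <- "log2"
  x
}

#' Inverse of [log2_transform()]
#' @param x log2-scale AbundanceMatrix.
#' @export
unlog2_transform <- function(x) {
  stopifnot(inherits(x, "AbundanceMatrix"), x$scale == "log2")
  x$values <- 2^x$values
  x$scale <- "raw"
  x
}

#' Minimum-value imputation
#'
#' Every missing entry is replaced by the global minimum observed value of
#' the layer (per-layer minimum, the convention for detection-limit-driven
#' missingness).
#'
#' @param x AbundanceMatrix with at least one observed value.
#' @return AbundanceMatrix without missing values.
#' @export
impute_min <- function(x) {
  stopifnot(inherits(x, "AbundanceMatrix"))
  if (all(is.na(x$values))) stop("fully missing matrix cannot be imputed")
  x$values[is.na(x$values)] <- min(x$values, na.rm = TRUE)
  x
}

#' Hartigan-style dip statistic (opt-in bimodality screen)
#'
#' Max deviation between the empirical CDF and the closest fitted unimodal
#' (here: Gaussian at the sample mean/sd) CDF — a light screen for clearly
#' bimodal per-sample distributions. Disabled by default in
#' [qc_filter_samples()] because no published criterion exists.
#'
#' @param v numeric vector of observed log2 abundances.
#' @return nonnegative statistic; larger = less unimodal.
#' @keywords internal
bimodality_stat <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) < 10) return(0)
  max(abs(stats::ecdf(v)(sort(v)) - stats::pnorm(sort(v), mean(v), stats::sd(v))))
}

#' Sample-level quality control
#'
#' Flags samples whose median observed log2 abundance exceeds Q3 + 1.5*IQR
#' of the cohort's median distribution (quartiles by linear interpolation,
#' quantile type 7), optionally flags clearly bimodal samples, and
#' propagates every exclusion to the paired partner so that the retained
#' set contains only complete tumor/NAT pairs.
#'
#' @param x AbundanceMatrix (log2 medians are used; a raw matrix is
#'   log2-ranked internally on observed values).
#' @param samples [sample_info()] table covering all columns.
#' @param bimodal_threshold optional numeric; if given, samples with
#'   [bimodality_stat()] above it are excluded (`NULL` disables the screen).
#' @return list of class `QCReport`: `medians` (per sample),
#'   `flags` (data.frame sample_id, excluded, reason in
#'   `median_outlier`/`bimodal`/`partner_failed`), `retained` (sample ids).
#' @export
qc_filter_samples <- function(x, samples, bimodal_threshold = NULL) {
  stopifnot(inherits(x, "AbundanceMatrix"))
  v <- x$values
  if (x$scale == "raw") {
    if (any(v <= 0, na.rm = TRUE)) v[v <= 0] <- NA
    v <- log2(v)
  }
  if (ncol(v) < 4) stop("need >= 4 samples to define quartiles")
  med <- apply(v, 2, stats::median, na.rm = TRUE)
  q <- stats::quantile(med, c(0.25, 0.75), type = 7, names = FALSE)
  hi <- q[2] + 1.5 * (q[2] - q[1])
  reason <- setNames(rep(NA_character_, ncol(v)), colnames(v))
  reason[med > hi] <- "median_outlier"
  if (!is.null(bimodal_threshold)) {
    dip <- apply(v, 2, bimodality_stat)
    reason[is.na(reason) & dip > bimodal_threshold] <- "bimodal"
  }
  # pair propagation: a sample is retained iff its partner is retained
  si <- as.data.frame(samples)
  si <- si[match(colnames(v), si$sample_id), ]
  partner <- vapply(seq_len(nrow(si)), function(i) {
    j <- which(si$patient_id == si$patient_id[i] & si$sample_id != si$sample_id[i])
    if (length(j) == 1) si$sample_id[j] else NA_character_
  }, "")
  failed <- names(reason)[!is.na(reason)]
  orphan <- is.na(partner) | !(partner %in% colnames(v))
  partner_failed <- (partner %in% failed | orphan) & is.na(reason)
  reason[partner_failed] <- "partner_failed"
  flags <- data.frame(sample_id = colnames(v), median = unname(med),
                      excluded = !is.na(reason), reason = unname(reason),
                      stringsAsFactors = FALSE)
  structure(list(medians = med, flags = flags,
                 retained = flags$sample_id[!flags$excluded]),
            class = "QCReport")
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf("QCReport: %d/%d samples retained\n",
              length(x$retained), nrow(x$flags)))
  if (any(x$flags$excluded)) print(x$flags[x$flags$excluded, ])
  invisible(x)
}

#' Filter features by detection rate
#'
#' Keeps features observed (non-missing) in more than `min_frac` of the
#' samples — the usual ">50% of patients" detection rule applied before
#' differential screens, clustering feature selection and enrichment.
#' Apply before imputation, while the missing mask is still present.
#'
#' @param x AbundanceMatrix (any scale, un-imputed).
#' @param min_frac detection fraction strictly required (default 0.5).
#' @param sample_ids optional subset of columns over which detection is
#'   computed (e.g. one histology's samples); all columns are returned.
#' @return AbundanceMatrix restricted to detected features.
#' @export
filter_by_detection <- function(x, min_frac = 0.5, sample_ids = NULL) {
  stopifnot(inherits(x, "AbundanceMatrix"))
  v <- x$values
  cols <- if (is.null(sample_ids)) seq_len(ncol(v)) else
    match(intersect(sample_ids, colnames(v)), colnames(v))
  det <- rowMeans(!is.na(v[, cols, drop = FALSE]))
  x$values <- v[det > min_frac, , drop = FALSE]
  x
}

#' Feature selection for subtype clustering
#'
#' The package's clustering convention: among features fully quantified in
#' the samples to be clustered (no imputed cells, so minimum-imputation
#' outliers cannot dominate the Euclidean geometry), take the `top_n` most
#' variable. Returns the normalized log2 submatrix restricted to those
#' samples, ready for [consensus_cluster()].
#'
#' @param x raw-scale un-imputed [abundance_matrix()].
#' @param sample_ids columns to cluster (e.g. one histology's tumors).
#' @param top_n number of features to keep (default 300).
#' @param min_detection detection fraction required within `sample_ids`
#'   (default 0.999, i.e. fully quantified).
#' @return log2 feature x sample matrix (features x `sample_ids`).
#' @export
clustering_features <- function(x, sample_ids, top_n = 300,
                                min_detection = 0.999) {
  stopifnot(inherits(x, "AbundanceMatrix"))
  full <- filter_by_detection(x, min_detection, sample_ids)
  norm <- normalize_layer(full)
  v <- norm$values[, intersect(sample_ids, colnames(norm$values)), drop = FALSE]
  v[order(-apply(v, 1, stats::var))[seq_len(min(top_n, nrow(v)))], , drop = FALSE]
}

#' Standard per-layer normalization pipeline
#'
#' Proteome: FOT -> impute -> log2. Phospho / TF activity: quantile
#' normalization -> impute -> log2. Returns a log2-scale matrix ready for
#' the differential and clustering stages.
#'
#' @param x raw-scale AbundanceMatrix.
#' @param impute replace missing values by the layer minimum before the log2
#'   transform (default TRUE; set FALSE to keep the missing mask, in which
#'   case the result may contain `NA`).
#' @return log2-scale AbundanceMatrix.
#' @export
normalize_layer <- function(x, impute = TRUE) {
  stopifnot(inherits(x, "AbundanceMatrix"))
  x <- if (x$layer == "proteome") fot_normalize(x) else quantile_normalize(x)
  if (impute) x <- impute_min(x)
  if (any(x$values <= 0, na.rm = TRUE))  # guard against zero intensities
    x$values[x$values <= 0] <- min(x$values[x$values > 0], na.rm = TRUE)
  v <- log2(x$values)
  x$values <- v
  x$scale <- "log2"
  x
}
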