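#' multiprot: multilevel proteomic analysis of paired tumor cohorts
#'
#' Normalization, QC, differential screens, kinase-activity (KSEA) scoring,
#' TF-activity enrichment and master-TF nomination, consensus-clustering
#' subtype discovery, a Bayes-rule LPS classifier, signature-based immune
#' scoring, cell-cycle phase assignment, mutation cis/trans-effect testing,
#' and survival statistics, together with a synthetic cohort generator that
#' carries a ground-truth ledger for recovery testing.
#'
#' @keywords internal
#' @aliases multiprot-package
"_PACKAGE"

VALID_LAYERS <- c("proteome", "phospho", "tf_activity")
VALID_SCALES <- c("raw", "log2")
VALID_TISSUES <- c("tumor", "NAT")
VALID_HISTOLOGY <- c("DGC", "IGC", "MGC")
VALID_CATEGORIES <- c("immune", "stroma", "pathway", "other")

#' Construct a validated abundance matrix
#'
#' The basic container for one omic layer: a numeric matrix with unique
#' feature row names and sample column names, `NA` marking missing cells,
#' plus a scale flag (`raw` intensities are nonnegative, `log2` values are
#' unrestricted) and a layer tag.
#'
#' @param values Numeric matrix, features in rows (unique rownames), samples
#'   in columns (colnames). `NA` = missing.
#' @param scale `"raw"` or `"log2"`.
#' @param layer One of `"proteome"`, `"phospho"`, `"tf_activity"`.
#' @param samples Optional `SampleInfo` table; if given, every column name
#'   must resolve to a known `sample_id`.
#' @return An object of class `AbundanceMatrix`.
#' @export
abundance_matrix <- function(values, scale = c("raw", "log2"),
                             layer = c("proteome", "phospho", "tf_activity"),
                             samples = NULL) {
  scale <- match.arg(scale)
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature_ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample_ids in matrix columns")
  if (scale == "raw" && any(values < 0, na.rm = TRUE))
    stop("raw-scale abundance values must be nonnegative")
  if (!is.null(samples)) {
    unknown <- setdiff(colnames(values), samples$sample_id)
    if (length(unknown))
      stop("sample_ids absent from metadata: ", paste(unknown, collapse = ", "))
  }
  structure(list(values = values, scale = scale, layer = layer),
            class = "AbundanceMatrix")
}

#' @export
dim.AbundanceMatrix <- function(x) dim(x$values)

#' @export
print.AbundanceMatrix <- function(x, ...) {
  cat(sprintf("AbundanceMatrix [%s, %s]: %d features x %d samples, %.1f%% missing\n",
              x$layer, x$scale, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Construct a validated sample-information table
#'
#' @param df data.frame with columns `sample_id`, `patient_id`, `tissue`
#'   (tumor/NAT) and `histology` (DGC/IGC/MGC).
#' @return The validated data.frame with class `SampleInfo` prepended.
#' @export
sample_info <- function(df) {
  need <- c("sample_id", "patient_id", "tissue", "histology")
  if (!all(need %in% names(df)))
    stop("sample table must have columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (cc in need) df[[cc]] <- as.character(df[[cc]])
  if (anyDuplicated(df$sample_id)) stop("sample_id values must be unique")
  if (!all(df$tissue %in% VALID_TISSUES))
    stop("tissue must be one of: ", paste(VALID_TISSUES, collapse = ", "))
  if (!all(df$histology %in% VALID_HISTOLOGY))
    stop("histology must be one of: ", paste(VALID_HISTOLOGY, collapse = ", "))
  tab <- table(df$patient_id, df$tissue)
  if (any(tab > 1))
    stop("a patient may have at most one tumor and one NAT sample")
  nh <- tapply(df$histology, df$patient_id, function(h) length(unique(h)))
  if (any(nh > 1)) stop("histology must be constant within a patient")
  class(df) <- c("SampleInfo", "data.frame")
  df
}

#' Construct a validated clinical table
#'
#' One row per patient with disease-free and overall survival endpoints.
#' Missing survival fields are allowed (flagged downstream, never dropped
#' silently); negative times and non-binary events are rejected.
#'
#' @param df data.frame with columns `patient_id`, `dfs_time`, `dfs_event`,
#'   `os_time`, `os_event`, `chemotherapy`, `stage`, `age`, `gender`.
#' @return data.frame with class `ClinicalTable` prepended.
#' @export
clinical_table <- function(df) {
  need <- c("patient_id", "dfs_time", "dfs_event", "os_time", "os_event",
            "chemotherapy", "stage", "age", "gender")
  if (!all(need %in% names(df)))
    stop("clinical table must have columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$patient_id)) stop("duplicate patient_id in clinical table")
  for (cc in c("dfs_time", "os_time")) {
    df[[cc]] <- as.numeric(df[[cc]])
    if (any(df[[cc]] < 0, na.rm = TRUE)) stop(cc, " must be >= 0")
  }
  for (cc in c("dfs_event", "os_event")) {
    df[[cc]] <- as.numeric(df[[cc]])
    bad <- !is.na(df[[cc]]) & !df[[cc]] %in% c(0, 1)
    if (any(bad)) stop(cc, " must be 0 or 1")
  }
  if (!all(df$stage %in% c("I", "II", "III", "IV", NA)))
    stop("stage must be one of I..IV")
  df$chemotherapy <- as.logical(df$chemotherapy)
  class(df) <- c("ClinicalTable", "data.frame")
  df
}

#' Construct a signature set collection
#'
#' Named gene sets with a category label each (`immune`, `stroma`,
#' `pathway`, `other`); genes are deduplicated, and every set must keep at
#' least 2 genes.
#'
#' @param sets named list of character vectors.
#' @param category named character vector (or single value recycled).
#' @return An object of class `SignatureSet`.
#' @export
signature_set <- function(sets, category = "other") {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("signature sets must have unique names")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(vapply(sets, length, 1L) < 2))
    stop("every signature set must have >= 2 genes")
  if (length(category) == 1) category <- setNames(rep(category, length(sets)), names(sets))
  category <- category[names(sets)]
  if (any(is.na(category)) || !all(category %in% VALID_CATEGORIES))
    stop("category must be one of: ", paste(VALID_CATEGORIES, collapse = ", "))
  structure(list(sets = sets, category = category), class = "SignatureSet")
}

#' @export
print.SignatureSet <- function(x, ...) {
  cat(sprintf("SignatureSet: %d sets (%s)\n", length(x$sets),
              paste(sprintf("%s=%d", names(table(x$category)), table(x$category)),
                    collapse = ", ")))
  invisible(x)
}

#' Render a phospho-site identifier
#'
#' Canonical form `protein_residue+position`, e.g. `"RB1_S807"`. Positions
#' are 1-based residue indices on the protein sequence.
#'
#' @param protein character vector of protein symbols.
#' @param residue `"S"`, `"T"` or `"Y"`.
#' @param position positive integer residue index.
#' @return character vector of site ids.
#' @export
phospho_site_id <- function(protein, residue, position) {
  if (!all(residue %in% c("S", "T", "Y"))) stop("residue must be S, T or Y")
  position <- as.integer(position)
  if (any(position < 1)) stop("position must be >= 1")
  paste0(protein, "_", residue, position)
}

#' Parse phospho-site identifiers
#'
#' @param site_id character vector in the canonical `PROT_S123` form.
#' @return data.frame with columns `site_id`, `protein`, `residue`, `position`.
#' @export
parse_phospho_site <- function(site_id) {
  m <- regmatches(site_id, regexec("^(.+)_([STY])([0-9]+)$", site_id))
  bad <- vapply(m, length, 1L) != 4
  if (any(bad)) stop("malformed phospho-site id: ", paste(site_id[bad], collapse = ", "))
  data.frame(site_id = site_id,
             protein = vapply(m, `[`, "", 2),
             residue = vapply(m, `[`, "", 3),
             position = as.integer(vapply(m, `[`, "", 4)),
             stringsAsFactors = FALSE)
}
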