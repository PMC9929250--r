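# Readers/writers for the TSV/GMT bundle. All tables are UTF-8,
# tab-separated with a header row; empty cells and the string "NA" both
# denote missing values (both occur in proteomics supplementary tables).

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("", "NA"))
}

#' Read a feature-by-sample abundance matrix from TSV
#'
#' First column holds feature ids, remaining columns one sample each.
#' Empty cells or `"NA"` are missing. Duplicate feature rows are rejected
#' rather than merged (site-level ambiguity is never guessed at).
#'
#' @inheritParams abundance_matrix
#' @param path TSV file path.
#' @return An [abundance_matrix()].
#' @export
read_abundance_matrix <- function(path, layer = c("proteome", "phospho", "tf_activity"),
                                  scale = c("raw", "log2"), samples = NULL) {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2) stop("malformed abundance TSV: need feature column plus >= 1 sample")
  if (names(df)[1] == "" || anyDuplicated(names(df)[-1]))
    stop("malformed header: first column must name features, sample columns unique")
  feats <- as.character(df[[1]])
  if (anyDuplicated(feats)) stop("duplicate feature rows in ", path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    suppressWarnings(storage.mode(vals) <- "double")
    if (any(is.na(vals) & !(is.na(df[, -1, drop = FALSE]))))
      stop("non-numeric abundance cell in ", path)
  }
  rownames(vals) <- feats
  abundance_matrix(vals, scale = match.arg(scale), layer = match.arg(layer),
                   samples = samples)
}

#' Write an abundance matrix to TSV
#'
#' Missing cells are written as empty strings; full double precision is kept
#' so that write/read round-trips are value-exact.
#'
#' @param x AbundanceMatrix.
#' @param path output file.
#' @export
write_abundance_matrix <- function(x, path) {
  stopifnot(inherits(x, "AbundanceMatrix"))
  df <- data.frame(feature_id = rownames(x$values),
                   format(x$values, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[-1][is.na(x$values)] <- ""
  names(df) <- c("feature_id", colnames(x$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated genes. Genes are
#' deduplicated within a set. The description field is used as the category
#' when it is one of `immune`/`stroma`/`pathway`, otherwise `other`.
#'
#' @param path GMT file.
#' @return A [signature_set()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3
  if (any(bad)) stop("GMT line with fewer than 3 fields at line ", which(bad)[1])
  nm <- vapply(parts, `[`, "", 1)
  desc <- vapply(parts, `[`, "", 2)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  cat_from_desc <- ifelse(desc %in% VALID_CATEGORIES, desc, "other")
  signature_set(sets, setNames(cat_from_desc, nm))
}

#' Write gene sets in GMT format
#'
#' The category is stored in the description field so [read_gmt()] round-trips.
#'
#' @param x SignatureSet.
#' @param path output file.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "SignatureSet"))
  lines <- vapply(names(x$sets), function(nm)
    paste(c(nm, x$category[[nm]], x$sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read the clinical table from TSV
#'
#' @param path TSV with columns `patient_id`, `dfs_time`, `dfs_event`,
#'   `os_time`, `os_event`, `chemotherapy`, `stage`, `age`, `gender`.
#' @return A [clinical_table()].
#' @export
read_clinical <- function(path) clinical_table(read_tsv_checked(path))

#' @rdname read_clinical
#' @param x ClinicalTable to write.
#' @export
write_clinical <- function(x, path) {
  stopifnot(inherits(x, "ClinicalTable"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read the sample metadata table from TSV
#'
#' @param path TSV with columns `sample_id`, `patient_id`, `tissue`, `histology`.
#' @return A [sample_info()] table.
#' @export
read_sample_info <- function(path) sample_info(read_tsv_checked(path))

#' @rdname read_sample_info
#' @param x SampleInfo to write.
#' @export
write_sample_info <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a binary mutation table
#'
#' TSV with first column `patient_id` and one 0/1 column per panel gene.
#'
#' @param path TSV file.
#' @return logical matrix, patients in rows, genes in columns.
#' @export
read_mutation_table <- function(path) {
  df <- read_tsv_checked(path)
  if (names(df)[1] != "patient_id") stop("first column must be patient_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!all(m %in% c(0, 1))) stop("mutation calls must be 0/1")
  storage.mode(m) <- "logical"
  rownames(m) <- df$patient_id
  m
}

#' @rdname read_mutation_table
#' @param x logical patient-by-gene matrix to write.
#' @export
write_mutation_table <- function(x, path) {
  df <- data.frame(patient_id = rownames(x), x * 1L, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Two-column edge tables (regulator, member), one pair per line, collapse
# to a named list of character vectors.
read_edge_map <- function(path, from, to) {
  df <- read_tsv_checked(path)
  if (!all(c(from, to) %in% names(df)))
    stop("expected columns '", from, "' and '", to, "' in ", path)
  split(as.character(df[[to]]), as.character(df[[from]]))
}

write_edge_map <- function(map, path, from, to) {
  df <- data.frame(a = rep(names(map), lengths(map)), b = unlist(map, use.names = FALSE))
  names(df) <- c(from, to)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a TF-to-target-gene network (CellNet-like)
#'
#' TSV columns `tf`, `target`, one edge per line; returned as a named list
#' mapping each TF to its target-gene symbols.
#'
#' @param path TSV file.
#' @export
read_tf_network <- function(path) {
  net <- read_edge_map(path, "tf", "target")
  if (any(lengths(net) == 0)) stop("TF with empty target set")
  lapply(net, unique)
}

#' @rdname read_tf_network
#' @param map named list TF -> targets.
#' @export
write_tf_network <- function(map, path) write_edge_map(map, path, "tf", "target")

#' Read/write a kinase-to-substrate-site map
#'
#' TSV columns `kinase`, `site` (canonical `PROT_S123` ids). A site may
#' belong to several kinases.
#'
#' @param path TSV file.
#' @export
read_ks_map <- function(path) {
  map <- read_edge_map(path, "kinase", "site")
  parse_phospho_site(unique(unlist(map, use.names = FALSE)))  # validates ids
  lapply(map, unique)
}

#' @rdname read_ks_map
#' @param map named list kinase -> sites.
#' @export
write_ks_map <- function(map, path) write_edge_map(map, path, "kinase", "site")

#' Write a full synthetic cohort as a TSV/GMT bundle
#'
#' Produces the on-disk dataset layout the readers expect: one TSV per
#' abundance layer, sample/clinical/mutation tables, the two annotation
#' maps, and the signature GMT.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "SyntheticCohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_abundance_matrix(cohort$proteome, file.path(dir, "proteome.tsv"))
  write_abundance_matrix(cohort$phospho, file.path(dir, "phospho.tsv"))
  write_abundance_matrix(cohort$tf_activity, file.path(dir, "tf_activity.tsv"))
  write_sample_info(cohort$samples, file.path(dir, "samples.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_mutation_table(cohort$mutations, file.path(dir, "mutations.tsv"))
  write_tf_network(cohort$tf_network, file.path(dir, "tf_network.tsv"))
  write_ks_map(cohort$ks_map, file.path(dir, "kinase_substrates.tsv"))
  write_gmt(cohort$signatures, file.path(dir, "signatures.gmt"))
  invisible(dir)
}

#' Validate a dataset bundle directory
#'
#' Reads every table of a bundle written by [write_cohort()] (or assembled
#' by hand in the same layout) and cross-checks sample ids, annotation
#' coverage and clinical coverage. Errors on the first violation.
#'
#' @param dir bundle directory.
#' @return invisibly, a list with the loaded tables.
#' @export
validate_bundle <- function(dir) {
  samples <- read_sample_info(file.path(dir, "samples.tsv"))
  prot <- read_abundance_matrix(file.path(dir, "proteome.tsv"), "proteome", "raw",
                                samples = samples)
  phos <- read_abundance_matrix(file.path(dir, "phospho.tsv"), "phospho", "raw",
                                samples = samples)
  tfa <- read_abundance_matrix(file.path(dir, "tf_activity.tsv"), "tf_activity", "raw",
                               samples = samples)
  clin <- read_clinical(file.path(dir, "clinical.tsv"))
  missing_clin <- setdiff(samples$patient_id, clin$patient_id)
  if (length(missing_clin))
    stop("patients without clinical record: ", paste(missing_clin, collapse = ", "))
  mut <- read_mutation_table(file.path(dir, "mutations.tsv"))
  net <- read_tf_network(file.path(dir, "tf_network.tsv"))
  ks <- read_ks_map(file.path(dir, "kinase_substrates.tsv"))
  sites_unknown <- setdiff(unlist(ks, use.names = FALSE), rownames(phos$values))
  if (length(sites_unknown))
    warning(length(sites_unknown), " mapped substrate sites not quantified in the phospho layer")
  sigs <- read_gmt(file.path(dir, "signatures.gmt"))
  invisible(list(samples = samples, proteome = prot, phospho = phos,
                 tf_activity = tfa, clinical = clin, mutations = mut,
                 tf_network = net, ks_map = ks, signatures = sigs))
}
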