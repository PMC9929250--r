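# Shared synthetic cohorts, generated once per test run and cached.

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(seed = 11, effect_scale = 1) {
  key <- paste0("co_", seed, "_", effect_scale)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- generate_cohort(
      cohort_params(effect_scale = effect_scale), seed = seed)
  .cohort_cache[[key]]
}

small_cohort <- function(seed = 7) {
  key <- paste0("small_", seed)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- generate_cohort(
      cohort_params(n_dgc = 12, n_igc = 12), seed = seed)
  .cohort_cache[[key]]
}

cached_norm_layer <- function(co, layer, tag, min_detection = 0.5,
                              sample_ids = NULL) {
  key <- paste0(tag, "_", layer, "_", min_detection)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- normalize_layer(
      filter_by_detection(co[[layer]], min_detection, sample_ids))
  .cohort_cache[[key]]
}

# truth subtype labels for one histology, keyed by tumor sample id
truth_tumor_labels <- function(co, h) {
  st <- co$truth$subtype_labels
  setNames(st$subtype[st$histology == h],
           paste0(st$patient_id[st$histology == h], "_T"))
}

# every feature with a planted upward effect in tumors of histology h
planted_up_features <- function(co, h) {
  tr <- co$truth
  mt <- tr$master_tfs$tf[tr$master_tfs$histology == h]
  trans <- tr$mutated_gene_effects$targets[
    tr$mutated_gene_effects$effect_class == "trans"]
  unique(c(
    tr$de_features$feature[tr$de_features$histology == h &
                             tr$de_features$log2_effect > 0],
    tr$subtype_signatures$feature[tr$subtype_signatures$histology == h],
    unlist(co$tf_network[mt], use.names = FALSE),
    if (length(trans)) unlist(strsplit(trans, ","), use.names = FALSE),
    unlist(co$signatures$sets, use.names = FALSE)))
}

planted_down_features <- function(co, h) {
  tr <- co$truth
  unique(c(
    tr$de_features$feature[tr$de_features$histology == h &
                             tr$de_features$log2_effect < 0],
    tr$mutated_gene_effects$gene[tr$mutated_gene_effects$effect_class == "cis"]))
}
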