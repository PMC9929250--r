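# Synthetic paired-cohort generator.
#
# Emulates the statistical structure every downstream stage assumes: paired
# log-normal intensities with abundance-dependent (MNAR-style) missingness,
# planted tumor-vs-NAT effects per histology, planted proteomic subtypes with
# signature proteins, kinase-activity shifts propagated to substrate
# phospho-sites, master-TF activity shifts propagated to target-gene
# proteins, mutation cis/trans effects, planted cell-type weight profiles and
# cell-cycle phases, and subtype-dependent exponential survival with uniform
# censoring. Every planted effect is recorded in a ground-truth ledger so
# recovery tests never have to re-derive it.
#
# All planted feature identities are deterministic reserved index blocks
# (documented below); the seed drives only noise, patient assignment,
# missingness, mutations and survival. A single Mersenne-Twister stream is
# consumed in a fixed order, so equal seeds give bitwise-equal cohorts.

#' Parameters of the synthetic cohort generator
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: 40 diffuse-type (DGC) and 50 intestinal-type (IGC) patients, each
#' with a paired tumor and NAT sample; 2,000 proteins, 3,000 phospho-sites
#' and 150 TF-activity features; per-feature Gaussian log2 baselines with
#' per-sample offsets; and the planted effects listed below.
#'
#' @param n_dgc,n_igc patients per histology (each contributes a tumor/NAT pair).
#' @param n_proteins,n_phospho,n_tf features per layer (`n_proteins >= 1300`,
#'   `n_tf >= 20` so the reserved blocks fit).
#' @param sigma per-feature biological + technical log2 SD.
#' @param sample_offset_sd SD of the per-sample additive log2 offset (a
#'   loading/depth artifact; removed exactly by FOT or quantile normalization).
#' @param de_effect reference planted tumor/NAT log2 effect (blocks are planted
#'   at 1.4x, 1x and 0.75x this value to create histology-dominant patterns).
#' @param k_dgc,k_igc planted subtype counts per histology.
#' @param subtype_effect planted log2 shift of each subtype's 60 signature
#'   proteins in that subtype's tumors.
#' @param n_subtype_sig signature proteins per subtype.
#' @param kinase_shifts named log2 shifts of the active kinases' substrate
#'   sites (applied in each kinase's designated subtype's tumors).
#' @param n_kinases,substrates_per_kinase size of the kinase-substrate map.
#' @param kinase_latent_sd SD of the shared per-sample latent coupling an
#'   active kinase's substrates to its planted TF phospho-site.
#' @param master_tumor_shift,master_subtype_shift,target_shift log2 shifts of a
#'   master TF's activity in all tumors of its histology, additionally in its
#'   own subtype, and of its target-gene proteins in that subtype.
#' @param n_targets target genes per master TF.
#' @param decoy_tumor_tf_shift log2 tumor shift of ten decoy TFs that are
#'   tumor-up but not subtype-specific (must fail master-TF nomination).
#' @param tf_noise,tf_protein_loading extra Gaussian noise of the TF-activity
#'   layer and its loading on the TF's own protein row (activity is a noisier
#'   correlate of abundance, reflecting a DNA-binding readout).
#' @param mut_cis_effect,mut_trans_effect log2 effects of the planted cis and
#'   trans mutations on tumor samples of mutation carriers.
#' @param cellcycle_shift log2 elevation of S / G2M module genes in tumors
#'   assigned to that phase.
#' @param celltype_gain log2 units added to a cell type's signature genes per
#'   unit of planted cell-type weight (tumor samples).
#' @param miss_quantile,miss_scale missingness midpoint (quantile of the
#'   layer's log2 values at which a cell is missing with probability 0.5) and
#'   logistic scale; missingness decreases with abundance.
#' @param dfs_median,os_median baseline exponential median survival (months)
#'   for subtype-1 patients.
#' @param hazard_mult_dgc,hazard_mult_igc hazard multipliers per subtype.
#' @param censor_max uniform censoring horizon (months).
#' @param effect_scale global multiplier on every planted log2 effect; hazard
#'   multipliers are raised to this power. `0` yields a null cohort.
#' @return list of validated parameters (class `cohort_params`).
#' @export
cohort_params <- function(n_dgc = 40, n_igc = 50,
                          n_proteins = 2000, n_phospho = 3000, n_tf = 150,
                          sigma = 0.5, sample_offset_sd = 0.15,
                          de_effect = 2.0,
                          k_dgc = 3, k_igc = 2,
                          subtype_effect = 2.0, n_subtype_sig = 60,
                          kinase_shifts = c(KIN01 = 2.0, KIN02 = -2.0, KIN03 = 1.5),
                          n_kinases = 20, substrates_per_kinase = 25,
                          kinase_latent_sd = 0.8,
                          master_tumor_shift = 1.0, master_subtype_shift = 2.0,
                          target_shift = 1.5, n_targets = 30,
                          decoy_tumor_tf_shift = 1.5,
                          tf_noise = 0.6, tf_protein_loading = 0.6,
                          mut_cis_effect = -1.5, mut_trans_effect = 1.2,
                          cellcycle_shift = 1.2, celltype_gain = 5,
                          miss_quantile = 0.1, miss_scale = 1.0,
                          dfs_median = 24, os_median = 36,
                          hazard_mult_dgc = c(1, 2, 4), hazard_mult_igc = c(1, 2.5),
                          censor_max = 60, effect_scale = 1) {
  p <- as.list(environment())
  if (p$k_dgc > p$n_dgc || p$k_igc > p$n_igc)
    stop("number of subtypes cannot exceed number of patients")
  if (p$k_dgc < 2 || p$k_igc < 2) stop("need >= 2 subtypes per histology")
  if (any(c(p$hazard_mult_dgc, p$hazard_mult_igc) <= 0))
    stop("hazard multipliers must be positive")
  if (length(p$hazard_mult_dgc) != p$k_dgc || length(p$hazard_mult_igc) != p$k_igc)
    stop("one hazard multiplier per subtype required")
  if (p$miss_quantile < 0 || p$miss_quantile > 1)
    stop("miss_quantile must lie in [0, 1]")
  if (p$sigma <= 0 || p$miss_scale <= 0 || p$censor_max <= 0)
    stop("sigma, miss_scale and censor_max must be positive")
  # reserved index blocks must fit inside the feature universes
  if (p$n_proteins < 1400)
    stop("planted effect blocks exceed n_proteins (fraction > 1); need >= 1400")
  if (length(p$kinase_shifts) > 3 || is.null(names(p$kinase_shifts)))
    stop("kinase_shifts must be a named vector of at most 3 planted kinases")
  if (p$n_phospho < 200 + p$n_kinases * p$substrates_per_kinase + 4)
    stop("planted phospho blocks exceed n_phospho")
  if (p$n_tf < 20) stop("need n_tf >= 20")
  if (p$n_kinases < length(p$kinase_shifts)) stop("fewer kinases than planted shifts")
  structure(p, class = "cohort_params")
}

# Reserved proteome blocks (indices into GENE0001..GENE<n>):
#   1:30    up both histologies, DGC-dominant      (+1.4e DGC, +0.75e IGC)
#   31:60   up both, IGC-dominant                  (+0.75e, +1.4e)
#   61:70   up DGC / down IGC                      (+e, -e)
#   71:100  down both, DGC-dominant                (-1.4e, -0.75e)
#   101:130 down both, IGC-dominant                (-0.75e, -1.4e)
#   131:135 down DGC / up IGC                      (-e, +e)
#   136:165 up both, equal (+e); 166:195 down both, equal (-e)
#   201.. subtype signature blocks (60 per subtype: DGC s1..s3, IGC s1..s2)
#   601.. master-TF target blocks (30 per master TF)
#   801:875 cell-type signature genes (5 types x 15)
#   901:930 cell-cycle module genes (S = 901:915, G2M = 916:930)
#   1001/1002 planted cis / trans mutation genes; 1011:1030 trans targets
#   1101:(1100+n_tf) TF genes (TF-activity layer mirrors these proteins)
proteome_truth_blocks <- function(p) {
  e <- p$de_effect * p$effect_scale
  blocks <- list(
    list(idx = 1:30,    dgc =  1.4 * e, igc =  0.75 * e),
    list(idx = 31:60,   dgc =  0.75 * e, igc = 1.4 * e),
    list(idx = 61:70,   dgc =  e,       igc = -e),
    list(idx = 71:100,  dgc = -1.4 * e, igc = -0.75 * e),
    list(idx = 101:130, dgc = -0.75 * e, igc = -1.4 * e),
    list(idx = 131:135, dgc = -e,      igc =  e),
    list(idx = 136:165, dgc =  e,      igc =  e),
    list(idx = 166:195, dgc = -e,      igc = -e))
  do.call(rbind, lapply(blocks, function(b)
    data.frame(index = b$idx, dgc_log2 = b$dgc, igc_log2 = b$igc)))
}

gene_ids <- function(n) sprintf("GENE%04d", seq_len(n))

#' Generate a synthetic multilevel cohort
#'
#' @param params a [cohort_params()] list.
#' @param seed integer seed; equal seeds give identical cohorts.
#' @return An object of class `SyntheticCohort`: the three raw-scale
#'   abundance layers, sample/clinical/mutation tables, kinase-substrate map,
#'   TF-target network, toy cell-type + cell-cycle signature sets, and a
#'   `truth` ledger of every planted effect.
#' @seealso [truth_report()], [write_cohort()]
#' @export
generate_cohort <- function(params = cohort_params(), seed = 1) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  es <- p$effect_scale

  ## -- patients and samples ------------------------------------------------
  n_pat <- p$n_dgc + p$n_igc
  patients <- sprintf("P%03d", seq_len(n_pat))
  histology <- rep(c("DGC", "IGC"), c(p$n_dgc, p$n_igc))
  samples <- sample_info(data.frame(
    sample_id = c(paste0(patients, "_T"), paste0(patients, "_N")),
    patient_id = rep(patients, 2),
    tissue = rep(c("tumor", "NAT"), each = n_pat),
    histology = rep(histology, 2), stringsAsFactors = FALSE))
  tumor_col <- paste0(patients, "_T")   # column order: all tumors, all NATs
  nat_col <- paste0(patients, "_N")
  n_samp <- 2 * n_pat

  # balanced subtype sizes, randomly assigned to patients within histology
  subtype <- integer(n_pat)
  subtype[histology == "DGC"] <- sample(sort(rep(seq_len(p$k_dgc), length.out = p$n_dgc)))
  subtype[histology == "IGC"] <- sample(sort(rep(seq_len(p$k_igc), length.out = p$n_igc)))
  names(subtype) <- patients

  ## -- proteome layer (log2) -----------------------------------------------
  genes <- gene_ids(p$n_proteins)
  mu_prot <- rnorm(p$n_proteins, 20, 1.5)
  # single-feature planted anchors sit in the well-quantified regime: an
  # undetectable master TF or mutation-effect gene would make its own planted
  # truth unobservable (block-planted effects keep random baselines)
  mu_prot[1001:1002] <- 21
  offsets <- rnorm(n_samp, 0, p$sample_offset_sd)
  prot <- matrix(rnorm(p$n_proteins * n_samp, 0, p$sigma), p$n_proteins, n_samp,
                 dimnames = list(genes, c(tumor_col, nat_col)))
  prot <- prot + mu_prot + rep(offsets, each = p$n_proteins)

  tb <- proteome_truth_blocks(p)
  is_dgc_t <- colnames(prot) %in% tumor_col[histology == "DGC"]
  is_igc_t <- colnames(prot) %in% tumor_col[histology == "IGC"]
  prot[tb$index, is_dgc_t] <- prot[tb$index, is_dgc_t] + tb$dgc_log2
  prot[tb$index, is_igc_t] <- prot[tb$index, is_igc_t] + tb$igc_log2

  # subtype signature blocks
  sig_blocks <- list()
  blk <- 0L
  for (h in c("DGC", "IGC")) {
    K <- if (h == "DGC") p$k_dgc else p$k_igc
    for (s in seq_len(K)) {
      idx <- if (h == "DGC") 200 + (s - 1) * p$n_subtype_sig + seq_len(p$n_subtype_sig)
             else 400 + (s - 1) * p$n_subtype_sig + seq_len(p$n_subtype_sig)
      cols <- tumor_col[histology == h & subtype == s]
      prot[idx, cols] <- prot[idx, cols] + p$subtype_effect * es
      blk <- blk + 1L
      sig_blocks[[blk]] <- data.frame(feature = genes[idx], histology = h,
                                      subtype = s,
                                      log2_effect = p$subtype_effect * es)
    }
  }

  # master TFs: one per (histology, subtype); reserved TF genes and targets
  tf_genes <- genes[1100 + seq_len(p$n_tf)]
  masters <- data.frame(
    tf = tf_genes[seq_len(p$k_dgc + p$k_igc)],
    histology = rep(c("DGC", "IGC"), c(p$k_dgc, p$k_igc)),
    subtype = c(seq_len(p$k_dgc), seq_len(p$k_igc)),
    stringsAsFactors = FALSE)
  masters$target_start <- 600 + (seq_len(nrow(masters)) - 1) * p$n_targets + 1
  tf_network <- list()
  for (i in seq_len(nrow(masters))) {
    idx <- masters$target_start[i] + seq_len(p$n_targets) - 1
    tf_network[[masters$tf[i]]] <- genes[idx]
    cols <- tumor_col[histology == masters$histology[i] & subtype == masters$subtype[i]]
    prot[idx, cols] <- prot[idx, cols] + p$target_shift * es
  }
  # decoy TFs get random target sets drawn outside the planted blocks
  decoy_pool <- genes[1301:p$n_proteins]
  for (tf in setdiff(tf_genes, masters$tf))
    tf_network[[tf]] <- sample(decoy_pool, 20)

  # cell-type weights (tumor compartment) and signature genes
  cell_types <- c("Th1", "Th2", "CD8T", "Fibroblast", "Epithelial")
  ct_genes <- lapply(seq_along(cell_types), function(i)
    genes[800 + (i - 1) * 15 + seq_len(15)])
  names(ct_genes) <- cell_types
  w <- matrix(abs(rnorm(n_pat * 5, 0.10, 0.02)), n_pat, 5,
              dimnames = list(patients, cell_types))
  th_group <- sample(rep(c("th1_skew", "th2_skew", "balanced"), length.out = n_pat))
  w[th_group == "th1_skew", "Th1"] <- 0.35
  w[th_group == "th1_skew", "Th2"] <- 0.03
  w[th_group == "th2_skew", "Th2"] <- 0.35
  w[th_group == "th2_skew", "Th1"] <- 0.03
  for (ct in cell_types)
    prot[ct_genes[[ct]], tumor_col] <-
      prot[ct_genes[[ct]], tumor_col] +
      p$celltype_gain * es * rep(w[, ct], each = 15)

  # cell-cycle phases
  s_genes <- genes[901:915]; g2m_genes <- genes[916:930]
  phase <- sample(c("G1", "S", "G2M"), n_pat, replace = TRUE, prob = c(0.4, 0.3, 0.3))
  names(phase) <- patients
  prot[s_genes, tumor_col[phase == "S"]] <-
    prot[s_genes, tumor_col[phase == "S"]] + p$cellcycle_shift * es
  prot[g2m_genes, tumor_col[phase == "G2M"]] <-
    prot[g2m_genes, tumor_col[phase == "G2M"]] + p$cellcycle_shift * es

  # mutations: planted cis gene (own protein down) and trans gene (targets up)
  panel <- genes[1001:1010]
  mut <- matrix(FALSE, n_pat, length(panel), dimnames = list(patients, panel))
  mut[, 1] <- runif(n_pat) < 0.35
  mut[, 2] <- runif(n_pat) < 0.30
  for (j in 3:length(panel)) mut[, j] <- runif(n_pat) < 0.15
  trans_targets <- genes[1011:1030]
  prot[panel[1], tumor_col[mut[, 1]]] <-
    prot[panel[1], tumor_col[mut[, 1]]] + p$mut_cis_effect * es
  prot[trans_targets, tumor_col[mut[, 2]]] <-
    prot[trans_targets, tumor_col[mut[, 2]]] + p$mut_trans_effect * es

  ## -- phospho layer (log2) ------------------------------------------------
  prot_of_site <- ((seq_len(p$n_phospho) - 1) %% p$n_proteins) + 1
  pos_of_site <- ((seq_len(p$n_phospho) - 1) %/% p$n_proteins) + 1
  sites <- phospho_site_id(genes[prot_of_site], "S", pos_of_site)
  # reserved TF phospho-sites for the kinase-TF coupling
  tf_site_idx <- 701:704
  sites[tf_site_idx] <- phospho_site_id(tf_genes[1:4], "S", 999)
  mu_phos <- rnorm(p$n_phospho, 18, 1.5)
  mu_phos[tf_site_idx] <- 19          # coupled TF sites must be quantifiable
  phos <- matrix(rnorm(p$n_phospho * n_samp, 0, p$sigma), p$n_phospho, n_samp,
                 dimnames = list(sites, c(tumor_col, nat_col)))
  phos <- phos + mu_phos + rep(offsets, each = p$n_phospho)
  # tumor/NAT differential sites (both histologies)
  e <- p$de_effect * es
  phos[1:60, c(which(is_dgc_t), which(is_igc_t))] <-
    phos[1:60, c(which(is_dgc_t), which(is_igc_t))] + e
  phos[61:120, c(which(is_dgc_t), which(is_igc_t))] <-
    phos[61:120, c(which(is_dgc_t), which(is_igc_t))] - e

  # kinase-substrate map: disjoint blocks of sites from 201 up
  kin <- sprintf("KIN%02d", seq_len(p$n_kinases))
  ks_map <- lapply(seq_len(p$n_kinases), function(k)
    sites[200 + (k - 1) * p$substrates_per_kinase + seq_len(p$substrates_per_kinase)])
  names(ks_map) <- kin
  # active kinases: shift substrates in the designated subtype's tumors
  active <- data.frame(kinase = names(p$kinase_shifts),
                       histology = c("DGC", "DGC", "IGC")[seq_along(p$kinase_shifts)],
                       subtype = c(1, 2, 1)[seq_along(p$kinase_shifts)],
                       log2_shift = unname(p$kinase_shifts) * es,
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(active))) {
    cols <- tumor_col[histology == active$histology[i] & subtype == active$subtype[i]]
    phos[ks_map[[active$kinase[i]]], cols] <-
      phos[ks_map[[active$kinase[i]]], cols] + active$log2_shift[i]
  }
  # a patient-level latent couples the first two active kinases to a TF
  # phospho-site: shared by the patient's tumor and NAT samples, so it
  # drives cross-sample correlation without perturbing paired fold changes
  kin_tf_edges <- data.frame(kinase = kin[1:2], site = sites[701:702],
                             stringsAsFactors = FALSE)
  for (i in 1:2) {
    u <- rep(rnorm(n_pat, 0, p$kinase_latent_sd), 2)   # tumor + NAT columns
    phos[ks_map[[kin[i]]], ] <- phos[ks_map[[kin[i]]], ] +
      rep(u, each = p$substrates_per_kinase)
    phos[tf_site_idx[i], ] <- phos[tf_site_idx[i], ] + u
  }

  ## -- TF-activity layer (log2) --------------------------------------------
  # activity = noisier correlate of the TF's own protein abundance
  mu_tf <- rnorm(p$n_tf, 15, 1.5)
  mu_tf[seq_len(p$k_dgc + p$k_igc)] <- 16    # master TFs quantifiable
  prot_tf <- prot[tf_genes, , drop = FALSE]
  tfa <- mu_tf + p$tf_protein_loading * (prot_tf - rowMeans(prot_tf)) +
    matrix(rnorm(p$n_tf * n_samp, 0, p$tf_noise), p$n_tf, n_samp)
  dimnames(tfa) <- list(tf_genes, colnames(prot))
  for (i in seq_len(nrow(masters))) {
    h_cols <- tumor_col[histology == masters$histology[i]]
    tfa[masters$tf[i], h_cols] <- tfa[masters$tf[i], h_cols] + p$master_tumor_shift * es
    s_cols <- tumor_col[histology == masters$histology[i] & subtype == masters$subtype[i]]
    tfa[masters$tf[i], s_cols] <- tfa[masters$tf[i], s_cols] + p$master_subtype_shift * es
  }
  decoy_up_tfs <- tf_genes[(p$k_dgc + p$k_igc + 1):(p$k_dgc + p$k_igc + 10)]
  tfa[decoy_up_tfs, tumor_col] <- tfa[decoy_up_tfs, tumor_col] + p$decoy_tumor_tf_shift * es

  ## -- survival and clinical ------------------------------------------------
  mult <- ifelse(histology == "DGC",
                 p$hazard_mult_dgc[subtype], p$hazard_mult_igc[subtype]) ^ es
  lam_dfs <- log(2) / p$dfs_median * mult
  lam_os <- log(2) / p$os_median * mult
  t_dfs <- rexp(n_pat, lam_dfs); c_dfs <- runif(n_pat, 0, p$censor_max)
  t_os <- rexp(n_pat, lam_os); c_os <- runif(n_pat, 0, p$censor_max)
  clinical <- clinical_table(data.frame(
    patient_id = patients,
    dfs_time = pmin(t_dfs, c_dfs), dfs_event = as.numeric(t_dfs <= c_dfs),
    os_time = pmin(t_os, c_os), os_event = as.numeric(t_os <= c_os),
    chemotherapy = runif(n_pat) < 0.5,
    stage = sample(c("I", "II", "III", "IV"), n_pat, replace = TRUE,
                   prob = c(0.15, 0.3, 0.4, 0.15)),
    age = round(rnorm(n_pat, 60, 8)),
    gender = sample(c("F", "M"), n_pat, replace = TRUE),
    stringsAsFactors = FALSE))

  ## -- abundance-dependent missingness, then raw scale ----------------------
  drop_missing <- function(x, p) {
    mid <- stats::quantile(x, p$miss_quantile, na.rm = TRUE)
    pm <- stats::plogis((mid - x) / p$miss_scale)
    x[matrix(runif(length(x)), nrow(x)) < pm] <- NA
    x
  }
  prot <- drop_missing(prot, p); phos <- drop_missing(phos, p)
  tfa <- drop_missing(tfa, p)

  signatures <- signature_set(
    c(ct_genes, list(S_phase = s_genes, G2M_phase = g2m_genes)),
    c(Th1 = "immune", Th2 = "immune", CD8T = "immune",
      Fibroblast = "stroma", Epithelial = "other",
      S_phase = "pathway", G2M_phase = "pathway"))

  truth <- list(
    de_features = rbind(
      data.frame(feature = genes[tb$index], histology = "DGC", log2_effect = tb$dgc_log2),
      data.frame(feature = genes[tb$index], histology = "IGC", log2_effect = tb$igc_log2)),
    de_sites = rbind(
      data.frame(feature = sites[1:60], log2_effect = e),
      data.frame(feature = sites[61:120], log2_effect = -e)),
    subtype_labels = data.frame(patient_id = patients, histology = histology,
                                subtype = unname(subtype), stringsAsFactors = FALSE),
    subtype_signatures = do.call(rbind, sig_blocks),
    active_kinases = active,
    master_tfs = data.frame(masters[, c("tf", "histology", "subtype")],
                            activity_shift = (p$master_tumor_shift + p$master_subtype_shift) * es,
                            target_shift = p$target_shift * es),
    kinase_tf_edges = kin_tf_edges,
    mutated_gene_effects = data.frame(
      gene = panel[1:2], effect_class = c("cis", "trans"),
      targets = c(panel[1], paste(trans_targets, collapse = ",")),
      log2_effect = c(p$mut_cis_effect, p$mut_trans_effect) * es,
      stringsAsFactors = FALSE),
    survival_hazard_multipliers = rbind(
      data.frame(histology = "DGC", subtype = seq_len(p$k_dgc),
                 multiplier = p$hazard_mult_dgc ^ es),
      data.frame(histology = "IGC", subtype = seq_len(p$k_igc),
                 multiplier = p$hazard_mult_igc ^ es)),
    cell_fraction_profiles = w,
    th_group = setNames(th_group, patients),
    phases = phase)
  if (es == 0) {   # a null cohort plants nothing
    for (nm in c("de_features", "de_sites", "subtype_signatures", "active_kinases",
                 "master_tfs", "kinase_tf_edges", "mutated_gene_effects",
                 "survival_hazard_multipliers"))
      truth[[nm]] <- truth[[nm]][0, , drop = FALSE]
  }

  structure(list(
    proteome = abundance_matrix(2^prot, "raw", "proteome", samples),
    phospho = abundance_matrix(2^phos, "raw", "phospho", samples),
    tf_activity = abundance_matrix(2^tfa, "raw", "tf_activity", samples),
    samples = samples, clinical = clinical, mutations = mut,
    ks_map = ks_map, tf_network = tf_network, signatures = signatures,
    truth = truth, params = p, seed = as.integer(seed)),
    class = "SyntheticCohort")
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf("SyntheticCohort (seed %d): %d patients (%s), layers %d/%d/%d features\n",
              x$seed, nrow(x$mutations),
              paste(sprintf("%s=%d", names(table(x$samples$histology[x$samples$tissue == "tumor"])),
                            table(x$samples$histology[x$samples$tissue == "tumor"])), collapse = ", "),
              nrow(x$proteome$values), nrow(x$phospho$values), nrow(x$tf_activity$values)))
  invisible(x)
}

#' Tabulate every planted effect of a synthetic cohort
#'
#' One row per planted effect (differential feature, subtype signature,
#' active kinase, master TF, kinase-TF edge, mutation effect, hazard
#' multiplier), machine-readable for recovery tests.
#'
#' @param cohort a [generate_cohort()] result.
#' @return data.frame with columns `type`, `target`, `context`, `magnitude`.
#' @export
truth_report <- function(cohort) {
  stopifnot(inherits(cohort, "SyntheticCohort"))
  tr <- cohort$truth
  paste_n <- function(...) {   # paste0 that keeps zero length (no recycling)
    args <- list(...)
    if (any(lengths(args) == 0)) character(0) else paste0(...)
  }
  mk_rows <- function(type, target, context, magnitude)
    data.frame(type = rep(type, length(target)), target = target,
               context = rep_len(as.character(context), length(target)),
               magnitude = rep_len(as.numeric(magnitude), length(target)),
               stringsAsFactors = FALSE)
  rows <- list(
    mk_rows("de_protein", tr$de_features$feature, tr$de_features$histology,
            tr$de_features$log2_effect),
    mk_rows("de_site", tr$de_sites$feature, "both", tr$de_sites$log2_effect),
    mk_rows("subtype_signature", tr$subtype_signatures$feature,
            paste_n(tr$subtype_signatures$histology, ":s",
                    tr$subtype_signatures$subtype),
            tr$subtype_signatures$log2_effect),
    mk_rows("active_kinase", tr$active_kinases$kinase,
            paste_n(tr$active_kinases$histology, ":s", tr$active_kinases$subtype),
            tr$active_kinases$log2_shift),
    mk_rows("master_tf", tr$master_tfs$tf,
            paste_n(tr$master_tfs$histology, ":s", tr$master_tfs$subtype),
            tr$master_tfs$activity_shift),
    mk_rows("kinase_tf_edge", tr$kinase_tf_edges$site,
            tr$kinase_tf_edges$kinase, NA_real_),
    mk_rows("mutation_effect", tr$mutated_gene_effects$gene,
            tr$mutated_gene_effects$effect_class,
            tr$mutated_gene_effects$log2_effect),
    mk_rows("hazard_multiplier",
            paste_n(tr$survival_hazard_multipliers$histology, ":s",
                    tr$survival_hazard_multipliers$subtype),
            "dfs", tr$survival_hazard_multipliers$multiplier))
  out <- do.call(rbind, rows[vapply(rows, nrow, 1L) > 0])
  if (is.null(out)) out <- data.frame(type = character(), target = character(),
                                      context = character(), magnitude = numeric())
  rownames(out) <- NULL
  out
}
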