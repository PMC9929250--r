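# TFRE enrichment, hypergeometric ORA, master-TF nomination, kinase-TF edges.

test_that("TFRE enrichment uses a strict 4-fold ratio and flags absences", {
  tf_v <- matrix(c(40, 40, 41, 39, 100, 100), 3, 2, byrow = TRUE,
                 dimnames = list(c("A", "B", "X"), c("s1", "s2")))
  pr_v <- matrix(c(10, 10, 10, 10), 2, 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("s1", "s2")))
  tf <- abundance_matrix(tf_v, "raw", "tf_activity")
  pr <- abundance_matrix(pr_v, "raw", "proteome")
  res <- tfre_enrichment(tf, pr, annotated_tfs = "B")
  expect_false(res$enriched[res$protein == "A"])   # ratio exactly 4: strict
  expect_false(res$enriched[res$protein == "B"])   # mean(41,39)/10 = 4: strict
  expect_true(res$protein[res$is_annotated_tf] == "B")  # reported regardless
  expect_true(res$is_annotated_tf[res$protein == "B"])
  expect_equal(res$flag[res$protein == "X"], "ratio_undefined")
  expect_true(is.na(res$ratio[res$protein == "X"]))
  # 10x case is enriched
  tf_v["A", ] <- 100
  res2 <- tfre_enrichment(abundance_matrix(tf_v, "raw", "tf_activity"), pr)
  expect_true(res2$enriched[res2$protein == "A"])
  # re-applying FOT to both layers leaves ratios unchanged (columns already
  # sum to the same total after FOT, so the ratio is normalization-stable)
  tfn <- fot_normalize(abundance_matrix(tf_v, "raw", "tf_activity"))
  prn <- fot_normalize(pr)
  r1 <- tfre_enrichment(tfn, prn)
  r2 <- tfre_enrichment(fot_normalize(tfn), fot_normalize(prn))
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-12)
})

test_that("hypergeometric enrichment equals the combinatorial tail", {
  expect_equal(hypergeom_enrichment(c("a", "b"), c("x", "y"),
                                    c("a", "b", "x", "y", "z")), 1)
  # |U|=10, |deps|=5, |targets|=4, overlap 4: C(5,4)/C(10,4) = 5/210
  u <- paste0("g", 1:10)
  expect_equal(hypergeom_enrichment(u[1:4], u[1:5], u), 5 / 210,
               tolerance = 1e-12)
  set.seed(15)
  for (i in 1:5) {
    u <- paste0("g", 1:20)
    deps <- sample(u, 7); targ <- sample(u, 6)
    ov <- length(intersect(deps, targ))
    expect_equal(hypergeom_enrichment(targ, deps, u),
                 oracle_hyper_tail(ov, 7, 20, 6), tolerance = 1e-10)
  }
  expect_error(hypergeom_enrichment(character(0), "a", c("a", "b")), "target")
  expect_error(hypergeom_enrichment("a", "b", character(0)), "universe")
})

test_that("master-TF nomination is a strict conjunction and recovers the plant", {
  co <- small_cohort()
  tfa <- cached_norm_layer(co, "tf_activity", "small7")
  prot <- cached_norm_layer(co, "proteome", "small7")
  st <- co$truth$subtype_labels
  for (h in c("DGC", "IGC")) {
    labs <- setNames(st$subtype[st$histology == h], st$patient_id[st$histology == h])
    tum <- paste0(names(labs), "_T")
    sigs <- signature_proteins(prot$values[, tum], setNames(labs, tum))
    deps <- lapply(sigs, function(d) d$feature)
    res <- nominate_master_tfs(tfa, co$samples[co$samples$histology == h, ],
                               labs, co$tf_network, deps,
                               universe = rownames(prot$values))
    truth_m <- co$truth$master_tfs[co$truth$master_tfs$histology == h, ]
    nom <- res[res$nominated, ]
    expect_setequal(paste0(nom$tf, ":", nom$subtype),
                    paste0(truth_m$tf, ":", truth_m$subtype))
    # conjunction: anything failing a criterion is not nominated
    fails <- !(res$tumor_p < 0.05 & res$tumor_fc > 2 &
                 res$subtype_p < 0.05 & res$subtype_fc > 1.5 &
                 !is.na(res$target_enrichment_p) & res$target_enrichment_p < 0.05)
    expect_true(all(!res$nominated[fails]))
    # monotonicity: relaxing thresholds never drops a nominated TF
    res_lo <- nominate_master_tfs(tfa, co$samples[co$samples$histology == h, ],
                                  labs, co$tf_network, deps,
                                  universe = rownames(prot$values),
                                  alpha = 0.2, fc_tumor = 1.2, fc_subtype = 1.1)
    key <- function(r) paste0(r$tf, ":", r$subtype)
    expect_true(all(key(nom) %in% key(res_lo[res_lo$nominated, ])))
  }
})

test_that("spearman edges: sign filter, oracle rho, planted edge recovery", {
  expect_equal(spearman_cor(1:8, 1:8)$rho, 1)
  rev_ <- spearman_cor(1:8, 8:1)
  expect_equal(rev_$rho, -1)
  x5 <- c(1.2, 3.4, 0.5, 2.2, 9.1); y5 <- c(2.0, 3.1, 1.1, 2.5, 7.7)
  expect_equal(spearman_cor(x5, y5)$rho, oracle_spearman_rho(x5, y5),
               tolerance = 1e-12)
  expect_equal(spearman_cor(rep(1, 6), 1:6)$flag, "constant_or_short")

  co <- small_cohort()
  phos <- cached_norm_layer(co, "phospho", "small7")
  kin_act <- kinase_sample_activity(phos, co$ks_map)
  edges_truth <- co$truth$kinase_tf_edges
  tf_sites <- phos$values[rownames(phos$values) %in%
                            grep("_S999$", rownames(phos$values), value = TRUE), ,
                          drop = FALSE]
  net <- kinase_tf_network(kin_act[edges_truth$kinase, , drop = FALSE], tf_sites)
  for (i in seq_len(nrow(edges_truth))) {
    e <- net[net$kinase == edges_truth$kinase[i] & net$site == edges_truth$site[i], ]
    expect_true(e$retained)
  }
  # an exactly anti-correlated pair is excluded by the positivity filter
  fake_site <- matrix(-kin_act[1, ], 1, dimnames = list("FAKE_S1", colnames(kin_act)))
  net2 <- kinase_tf_network(kin_act[1, , drop = FALSE], fake_site)
  expect_false(net2$retained)
  expect_lt(net2$spearman_rho, 0)
})
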