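# Consensus clustering, k selection, signatures, concordance, ARI.

blob_data <- function(n_per = 10, k = 2, sep = 4, p = 40, seed = 20) {
  set.seed(seed)
  x <- matrix(rnorm(p * n_per * k, 0, 0.5), p, n_per * k)
  for (g in seq_len(k))
    x[((g - 1) * 10 + 1):(g * 10), ((g - 1) * n_per + 1):(g * n_per)] <-
      x[((g - 1) * 10 + 1):(g * 10), ((g - 1) * n_per + 1):(g * n_per)] + sep
  colnames(x) <- sprintf("s%02d", seq_len(ncol(x)))
  rownames(x) <- sprintf("f%02d", seq_len(nrow(x)))
  x
}

test_that("consensus matrices are valid and recover well-separated blobs", {
  x <- blob_data(k = 2)
  cc <- consensus_cluster(x, k_range = 2:4, reps = 200, seed = 21)
  for (cm in cc$consensus) {
    expect_true(isSymmetric(cm))
    expect_true(all(diag(cm) == 1))
    expect_true(all(cm >= 0 & cm <= 1))
  }
  truth <- rep(1:2, each = 10)
  cm2 <- cc$consensus$k2
  expect_true(all(cm2[truth == 1, truth == 1] > 0.95))
  expect_true(all(cm2[truth == 1, truth == 2] < 0.05))
  expect_equal(adjusted_rand_index(cc$labels$k2, truth), 1)
  # determinism under a fixed seed
  cc2 <- consensus_cluster(x, k_range = 2:4, reps = 200, seed = 21)
  expect_identical(cc$consensus, cc2$consensus)
  expect_error(consensus_cluster(x, k_range = 2:25, reps = 10), "k_range")
  expect_error(consensus_cluster(x, reps = 1), "reps")
})

test_that("select_k picks the planted k and flags structureless data", {
  x2 <- blob_data(k = 2, seed = 22)
  s2 <- select_k(consensus_cluster(x2, 2:5, reps = 300, seed = 23))
  expect_equal(s2$chosen_k, 2)
  expect_false(s2$ambiguous)
  x3 <- blob_data(k = 3, seed = 24, p = 60)
  s3 <- select_k(consensus_cluster(x3, 2:5, reps = 300, seed = 25))
  expect_equal(s3$chosen_k, 3)
  expect_false(s3$ambiguous)
  set.seed(26)                                   # flat data
  xf <- matrix(rnorm(40 * 30, 0, 0.5), 40, 30,
               dimnames = list(NULL, sprintf("s%d", 1:30)))
  sf <- select_k(consensus_cluster(xf, 2:5, reps = 300, seed = 27))
  expect_true(sf$ambiguous)
  # advisory log-rank column appears when survival is supplied
  tm <- setNames(rexp(20, 0.05), colnames(x2))
  ev <- setNames(rbinom(20, 1, 0.8), colnames(x2))
  s2b <- select_k(consensus_cluster(x2, 2:3, reps = 100, seed = 28),
                  times = tm, events = ev)
  expect_true("logrank_p" %in% names(s2b$report))
})

test_that("cluster relabeling changes neither consensus use nor chi-square", {
  a <- setNames(rep(1:3, each = 5), paste0("p", 1:15))
  b <- setNames(rep(c(2, 1, 3), each = 5), paste0("p", 1:15))
  ct1 <- concordance_test(a, b)
  relab <- c("3", "1", "2")[a]
  names(relab) <- names(a)
  ct2 <- concordance_test(relab, b)
  expect_equal(ct1$chi2, ct2$chi2)
  expect_equal(adjusted_rand_index(a, b), 1)
})

test_that("subtype signatures recover the planted blocks", {
  co <- cached_cohort(11)
  prot <- cached_norm_layer(co, "proteome", "def11")
  for (h in c("DGC", "IGC")) {
    labs <- truth_tumor_labels(co, h)
    sigs <- signature_proteins(prot$values[, names(labs)], labs)
    tr <- co$truth$subtype_signatures
    mt <- co$truth$master_tfs
    for (s in unique(labs)) {
      # subtype-up truth: the signature block plus the subtype's planted
      # master-TF target genes (also elevated only in that subtype)
      planted <- c(tr$feature[tr$histology == h & tr$subtype == s],
                   co$tf_network[[mt$tf[mt$histology == h & mt$subtype == s]]])
      planted <- intersect(planted, rownames(prot$values))
      got <- sigs[[as.character(s)]]$feature
      jac <- length(intersect(got, planted)) / length(union(got, planted))
      expect_gte(jac, 0.9)
    }
  }
  # top_n truncates by ascending p
  labs <- truth_tumor_labels(co, "DGC")
  s5 <- signature_proteins(prot$values[, names(labs)], labs, top_n = 5)
  expect_true(all(vapply(s5, nrow, 1L) <= 5))
  # a feature identical across subtypes is never a signature, and an
  # undersized subtype warns
  flat <- matrix(as.numeric(1:10), 10, 12,
                 dimnames = list(paste0("f", 1:10), names(labs)[1:12]))
  labs12 <- setNames(c(1, 1, 2, 2, 2, 2, 3, 3, 3, 3, 3, 3), colnames(flat))
  expect_warning(sflat <- signature_proteins(flat, labs12), "fewer than 3")
  expect_true(all(vapply(sflat, nrow, 1L) == 0))
})

test_that("concordance reproduces printed subset percentages and the chi-square formula", {
  expect_equal(subset_percentage(15, 23), 65)
  expect_equal(subset_percentage(27, 28), 96)
  expect_equal(subset_percentage(11, 18), 61)
  expect_equal(subset_percentage(21, 25), 84)
  expect_equal(subset_percentage(18, 28), 64)
  expect_equal(subset_percentage(2212, 2512, digits = 1), 88.1)
  expect_equal(subset_percentage(686, 1106, digits = 1), 62.0)
  # half-away-from-zero rounding at the boundary
  expect_equal(subset_percentage(1, 8), 13)      # 12.5 -> 13
  # chi-square equals the hand O/E formula on the contingency table
  a <- setNames(c(rep(1, 23), rep(2, 28), rep(3, 28)), paste0("p", 1:79))
  b <- setNames(c(rep(1, 15), rep(2, 8), rep(1, 18), rep(2, 10),
                  rep(2, 27), rep(1, 1)), paste0("p", 1:79))
  ct <- concordance_test(a, b)
  tab <- table(a, b)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(ct$chi2, sum((tab - expected)^2 / expected), tolerance = 1e-12)
  sp <- ct$subset_percentages
  expect_equal(sp$percent[sp$cluster_a == "1"], 65)
  expect_equal(sp$percent[sp$cluster_a == "3"], 96)
  # identical labelings: every subset percentage 100
  ct2 <- concordance_test(a, a)
  expect_true(all(ct2$subset_percentages$percent == 100))
  expect_error(concordance_test(setNames(rep(1, 5), paste0("p", 1:5)),
                                setNames(rep(1:0, c(3, 2)), paste0("p", 1:5))),
               "degenerate")
})

test_that("adjusted Rand index agrees with the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(29)
  for (i in 1:5) {
    a <- sample(1:3, 30, replace = TRUE)
    b <- sample(1:4, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10 %% 2, (1:10 %% 2 + 1) %% 2), 1)
})
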