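# Normalization and QC: conservation, multiset sharing, pair symmetry.

mk <- function(v, scale = "raw", layer = "proteome") {
  if (is.null(dim(v))) v <- matrix(v, ncol = 1)
  if (is.null(rownames(v))) rownames(v) <- sprintf("f%d", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- sprintf("s%d", seq_len(ncol(v)))
  abundance_matrix(v, scale, layer)
}

test_that("FOT scales every column to one million", {
  expect_equal(unname(fot_normalize(mk(5))$values[1, 1]), 1e6)
  expect_equal(unname(fot_normalize(mk(c(3, 3)))$values[, 1]), c(5e5, 5e5))
  set.seed(2)
  v <- matrix(rlnorm(80, 8, 1.5), 20, 4)
  v[sample(80, 10)] <- NA
  f <- fot_normalize(mk(v))
  expect_equal(colSums(f$values, na.rm = TRUE), rep(1e6, 4),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(unname(is.na(f$values)), is.na(v))  # missing stays missing
  v[, 2] <- NA
  expect_error(fot_normalize(mk(v)), "s2")
})

test_that("quantile normalization matches the mean-order-statistics oracle", {
  # identical columns unchanged
  v <- matrix(rep(c(1, 5, 9, 2), 3), 4, 3)
  q <- quantile_normalize(mk(v))
  expect_equal(q$values, mk(v)$values, ignore_attr = TRUE)
  # a permuted column acquires exactly the same multiset
  set.seed(3)
  a <- rlnorm(30)
  v <- matrix(c(a, sample(a), sample(a)), ncol = 3)
  q <- quantile_normalize(mk(v))
  expect_equal(unname(sort(q$values[, 1])), unname(sort(q$values[, 2])),
               tolerance = 1e-12)
  expect_equal(unname(sort(q$values[, 2])), unname(sort(q$values[, 3])),
               tolerance = 1e-12)
  # 4x3 with a tie: hand oracle (ties take the mean of spanned references)
  v <- matrix(c(1, 2, 2, 4,
                4, 3, 2, 1,
                10, 20, 30, 40), 4, 3)
  q <- quantile_normalize(mk(v))
  expect_equal(q$values, oracle_quantile_norm(v), ignore_attr = TRUE,
               tolerance = 1e-12)
  # random complete matrix against the oracle
  set.seed(4)
  v <- matrix(rlnorm(60), 12, 5)
  expect_equal(quantile_normalize(mk(v))$values, oracle_quantile_norm(v),
               ignore_attr = TRUE, tolerance = 1e-10)
  # idempotence
  q1 <- quantile_normalize(mk(v))
  q2 <- quantile_normalize(q1)
  expect_equal(q1$values, q2$values, tolerance = 1e-10)
  # single column: identity with warning
  expect_warning(s <- quantile_normalize(mk(c(1, 2, 3))), "identity")
  expect_equal(s$values, mk(c(1, 2, 3))$values, ignore_attr = TRUE)
})

test_that("log2 transform and its inverse", {
  expect_equal(unname(log2_transform(mk(8))$values[1, 1]), 3)
  expect_equal(unname(log2_transform(mk(1))$values[1, 1]), 0)
  set.seed(5)
  v <- matrix(rlnorm(40), 8, 5)
  x <- log2_transform(mk(v))
  expect_equal(x$scale, "log2")
  expect_equal(unlog2_transform(x)$values, v, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_error(log2_transform(mk(c(0, 1))), "impute")
})

test_that("minimum imputation fills exactly the missing cells with the layer minimum", {
  v <- matrix(c(0.2, 5, 3, 7), 2, 2)
  expect_equal(impute_min(mk(v))$values, v, ignore_attr = TRUE)
  v[1, 2] <- NA
  expect_equal(unname(impute_min(mk(v))$values[1, 2]), 0.2)
  set.seed(6)
  v <- matrix(rlnorm(100), 20, 5)
  mask <- matrix(runif(100) < 0.2, 20, 5)
  v[mask] <- NA
  imp <- impute_min(mk(v))
  expect_true(all(imp$values[mask] == min(v, na.rm = TRUE)))
  expect_equal(imp$values[!mask], v[!mask])
  expect_error(impute_min(mk(matrix(NA_real_, 2, 2))), "fully missing")
})

test_that("QC excludes median outliers and keeps only complete pairs", {
  set.seed(7)
  # 4 patients x (tumor, NAT); sample 8 (P4 NAT) has a grossly high median
  meds <- c(1, 1, 1, 1, 1, 1, 1, 10)
  v <- sapply(meds, function(m) 2^(m + rnorm(200, 0, 1e-3)))
  rownames(v) <- sprintf("f%d", 1:200)
  colnames(v) <- c(paste0("P", 1:4, "_T"), paste0("P", 1:4, "_N"))
  si <- sample_info(data.frame(
    sample_id = colnames(v), patient_id = rep(paste0("P", 1:4), 2),
    tissue = rep(c("tumor", "NAT"), each = 4), histology = "DGC"))
  qc <- qc_filter_samples(mk(v), si)
  fl <- setNames(qc$flags$reason, qc$flags$sample_id)
  expect_equal(unname(fl[["P4_N"]]), "median_outlier")
  expect_equal(unname(fl[["P4_T"]]), "partner_failed")
  expect_setequal(qc$retained, c(paste0("P", 1:3, "_T"), paste0("P", 1:3, "_N")))
  # retained set always contains complete pairs
  pat <- sub("_.$", "", qc$retained)
  expect_true(all(table(pat) == 2))
  # all-equal medians: nothing excluded
  qc3 <- qc_filter_samples(mk(matrix(2, 10, 8,
                                     dimnames = list(sprintf("f%d", 1:10),
                                                     colnames(v)))), si)
  expect_equal(length(qc3$retained), 8L)
  expect_error(qc_filter_samples(mk(matrix(1:6, 2, 3)), si), ">= 4 samples")
})

test_that("detection filter keeps features observed above the threshold", {
  v <- matrix(1, 4, 4, dimnames = list(paste0("f", 1:4), paste0("s", 1:4)))
  v[1, 1:3] <- NA      # 25% detection
  v[2, 1:2] <- NA      # 50% detection (not > 0.5)
  v[3, 1] <- NA        # 75% detection
  out <- filter_by_detection(mk(v), 0.5)
  expect_setequal(rownames(out$values), c("f3", "f4"))
  out2 <- filter_by_detection(mk(v), 0.5, sample_ids = c("s3", "s4"))
  expect_setequal(rownames(out2$values), c("f2", "f3", "f4"))
})
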