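# LPS Bayes classifier: hand arithmetic, closed-form posterior, symmetry,
# self-consistency, cross-cohort recovery.

toy_matrix <- function() {
  # one feature, two clearly separated classes of 4
  x <- matrix(c(1, 2, 3, 2, 8, 9, 10, 9), 1,
              dimnames = list("TFX", paste0("s", 1:8)))
  labs <- setNames(rep(c("lo", "hi"), each = 4), colnames(x))
  list(x = x, labs = labs)
}

test_that("single-feature fit matches hand arithmetic", {
  d <- toy_matrix()
  m <- fit_lps(d$x, d$labs, cutoff = 0.75)
  z <- (d$x[1, ] - mean(d$x[1, ])) / sd(d$x[1, ])
  tt <- unname(t.test(z[5:8], z[1:4])$statistic)     # class order: hi first
  expect_equal(unname(m$weights["TFX"]), tt, tolerance = 1e-12)
  lps <- tt * z
  expect_equal(unname(m$training_lps), unname(lps), tolerance = 1e-12)
  for (cl in c("hi", "lo")) {
    s <- lps[d$labs == cl]
    expect_equal(m$gaussians[[cl]]$mean, mean(s), tolerance = 1e-12)
    expect_equal(m$gaussians[[cl]]$sd, sqrt(mean((s - mean(s))^2)),
                 tolerance = 1e-12)
  }
  expect_equal(sum(m$priors), 1)
})

test_that("swapping class labels negates weights and swaps the Gaussians", {
  d <- toy_matrix()
  m1 <- fit_lps(d$x, d$labs)
  swapped <- setNames(ifelse(d$labs == "hi", "zlo", "ahi"), names(d$labs))
  m2 <- fit_lps(d$x, swapped)
  expect_equal(unname(m1$weights), -unname(m2$weights), tolerance = 1e-10)
  # "zlo" is the old "hi" class: its Gaussian appears with negated mean
  expect_equal(m1$gaussians$hi$sd, m2$gaussians$zlo$sd, tolerance = 1e-10)
  expect_equal(m1$gaussians$hi$mean, -m2$gaussians$zlo$mean, tolerance = 1e-10)
  expect_equal(m1$gaussians$lo$mean, -m2$gaussians$ahi$mean, tolerance = 1e-10)
})

test_that("posterior matches the logistic closed form for equal-sd Gaussians", {
  # mu = +/-1, sd = 1, equal priors: P1(lps) = 1 / (1 + exp(-2 * lps))
  m <- structure(list(weights = c(F1 = 1), feature_means = c(F1 = 0),
                      feature_sds = c(F1 = 1), classes = c("c1", "c2"),
                      gaussians = list(c1 = list(mean = 1, sd = 1),
                                       c2 = list(mean = -1, sd = 1)),
                      priors = c(c1 = 0.5, c2 = 0.5), cutoff = 0.75),
                 class = "lps_model")
  lps_grid <- seq(-3, 3, by = 0.5)
  newdata <- matrix(lps_grid, 1, dimnames = list("F1", paste0("n", seq_along(lps_grid))))
  pred <- classify_lps(m, newdata, standardize = "training")
  expect_equal(pred$posterior_c1, 1 / (1 + exp(-2 * lps_grid)), tolerance = 1e-12)
  # monotone in LPS when class-1 mean exceeds class-2 mean at equal sd
  expect_true(all(diff(pred$posterior_c1) > 0))
  # equidistant sample: posterior 1/2, unclassified at the 0.75 cutoff
  mid <- classify_lps(m, matrix(0, 1, dimnames = list("F1", "m")),
                      standardize = "training")
  expect_equal(mid$posterior_c1, 0.5)
  expect_equal(mid$call, "unclassified")
  # strict mode always assigns the argmax class
  strict <- classify_lps(m, newdata, standardize = "training", strict = TRUE)
  expect_setequal(unique(strict$call), c("c1", "c2"))
})

test_that("training data reproduce their class-wise LPS summaries and calls", {
  d <- toy_matrix()
  m <- fit_lps(d$x, d$labs, cutoff = 0.75)
  pred <- classify_lps(m, d$x, standardize = "training")
  expect_equal(pred$lps, unname(m$training_lps), tolerance = 1e-12)
  # perfectly separated training samples are all called correctly
  expect_equal(pred$call, unname(d$labs))
  for (cl in c("hi", "lo"))
    expect_equal(mean(pred$lps[d$labs == cl]), m$gaussians[[cl]]$mean,
                 tolerance = 1e-12)
  # posterior equals the Bayes ratio of the two fitted class densities
  d1 <- 0.5 * dnorm(pred$lps, m$gaussians$hi$mean, m$gaussians$hi$sd)
  d2 <- 0.5 * dnorm(pred$lps, m$gaussians$lo$mean, m$gaussians$lo$sd)
  expect_equal(pred$posterior_hi, d1 / (d1 + d2), tolerance = 1e-12)
})

test_that("degenerate fits and missing features are rejected", {
  d <- toy_matrix()
  expect_error(fit_lps(d$x, d$labs[1:5]), ">= 3")
  x0 <- d$x; x0[1, ] <- 5
  expect_error(fit_lps(x0, d$labs), "zero variance")
  expect_error(fit_lps(d$x, d$labs, features = "NOPE"), "absent")
  m <- fit_lps(d$x, d$labs)
  bad <- matrix(NA_real_, 1, 1, dimnames = list("TFX", "n1"))
  expect_error(classify_lps(m, bad), "missing feature")
})

test_that("a second synthetic cohort is classified accurately at the 75% cutoff", {
  co1 <- cached_cohort(11)
  co2 <- cached_cohort(12)
  tfa1 <- cached_norm_layer(co1, "tf_activity", "def11")
  tfa2 <- cached_norm_layer(co2, "tf_activity", "def12")
  feats <- co1$truth$master_tfs$tf[co1$truth$master_tfs$histology == "IGC"]
  l1 <- truth_tumor_labels(co1, "IGC")
  l2 <- truth_tumor_labels(co2, "IGC")
  m <- fit_lps(tfa1$values[, names(l1)], setNames(paste0("s", l1), names(l1)),
               features = feats)
  pred <- classify_lps(m, tfa2$values[, names(l2)])
  acc <- mean(pred$call == paste0("s", l2[pred$sample]))
  expect_gte(acc, 0.9)
})
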