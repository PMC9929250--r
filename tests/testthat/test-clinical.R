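# Survival statistics and mutation cis/trans effects.

test_that("KM estimates equal the hand product-limit, censoring handled", {
  f <- km_estimate(c(5, 8, 12), c(0, 0, 0))$groups$all
  expect_true(all(f$surv == 1) || nrow(f) == 0)
  f <- km_estimate(c(1, 2, 3), c(1, 1, 1))$groups$all
  expect_equal(f$surv, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  # censoring after the last event adds no drops: curve flat past t = 3
  f2 <- km_estimate(c(1, 2, 3, 10), c(1, 1, 1, 0))$groups$all
  expect_equal(f2$surv[f2$n_event > 0], oracle_km(c(1, 2, 3, 10),
                                                  c(1, 1, 1, 0))$surv,
               tolerance = 1e-12)
  expect_equal(f2$surv[f2$time > 3], min(f2$surv[f2$n_event > 0]))
  set.seed(33)
  tm <- round(rexp(40, 0.1), 1); ev <- rbinom(40, 1, 0.7)
  got <- km_estimate(tm, ev)$groups$all
  want <- oracle_km(tm, ev)
  expect_equal(got$surv[got$n_event > 0], want$surv, tolerance = 1e-10)
  expect_true(all(diff(got$surv) <= 1e-12))          # monotone non-increasing
  expect_error(km_estimate(c(-1, 2), c(1, 1)), ">= 0")
})

test_that("log-rank matches the O/E/V tally and is time-transform invariant", {
  tm <- c(1, 2, 3, 4, 5, 6); ev <- rep(1, 6); gr <- rep(c("a", "b"), 3)
  dup <- logrank_test(c(tm, tm), c(ev, ev), c(gr, gr))
  got <- logrank_test(tm, ev, gr)
  want <- oracle_logrank(tm, ev, gr)
  expect_equal(got$chi2, want$chi2, tolerance = 1e-10)
  expect_equal(got$p_value, want$p, tolerance = 1e-10)
  # identical groups (duplicated data): chi2 = 0, p = 1
  same <- logrank_test(rep(tm, 2), rep(ev, 2), rep(c("x", "y"), each = 6))
  expect_equal(same$chi2, 0, tolerance = 1e-10)
  expect_equal(same$p_value, 1, tolerance = 1e-10)
  # invariance under a strictly increasing time transform
  set.seed(34)
  tm2 <- rexp(30); ev2 <- rbinom(30, 1, 0.8); gr2 <- rep(1:2, 15)
  a <- logrank_test(tm2, ev2, gr2)
  b <- logrank_test(tm2^3 + 2 * tm2, ev2, gr2)
  expect_equal(a$chi2, b$chi2, tolerance = 1e-10)
  expect_error(logrank_test(tm, rep(0, 6), gr), "no events")
})

test_that("Cox hazard ratios match an independent Newton-Raphson fit", {
  # tiny no-ties fixture: Efron = Breslow = exact partial likelihood
  tm <- c(2, 4, 5, 7, 9); ev <- c(1, 1, 0, 1, 1); x <- c(0, 1, 1, 0, 1)
  got <- cox_hr(tm, ev, data.frame(x = x))
  expect_equal(got$beta, oracle_cox_beta(tm, ev, x), tolerance = 1e-6)
  expect_equal(got$hr, exp(got$beta), tolerance = 1e-12)
  # identically distributed arms: CI covers 1
  set.seed(35)
  tm2 <- rexp(100); ev2 <- rbinom(100, 1, 0.8); arm <- rep(0:1, 50)
  ci <- cox_hr(tm2, ev2, data.frame(arm = arm))
  expect_true(ci$ci_lower < 1 && ci$ci_upper > 1)
  # exponential arms with true HR 2: CI covers 2
  set.seed(36)
  arm <- rep(0:1, 100)
  tm3 <- rexp(200, rate = 0.05 * 2^arm)
  cens <- runif(200, 0, 40)
  ev3 <- as.numeric(tm3 <= cens)
  hr <- cox_hr(pmin(tm3, cens), ev3, data.frame(arm = arm))
  expect_true(hr$ci_lower < 2 && hr$ci_upper > 2)
  expect_error(cox_hr(tm, ev, data.frame(k = rep(1, 5))), "constant")
})

test_that("optimal cutpoint finds planted steps and respects invariances", {
  set.seed(37)
  n <- 50
  marker <- sort(runif(n))
  step_at <- marker[20]                       # planted step at the 40th pctile
  hazard <- ifelse(marker > step_at, 0.02, 0.2)
  tm <- rexp(n, hazard); ev <- rep(1, n)
  oc <- optimal_cutpoint(marker, tm, ev)
  expect_lte(abs(which(sort(marker) == oc$cutpoint) - 20), 1)
  # monotone marker transform maps the cutpoint, statistic unchanged
  oc2 <- optimal_cutpoint(exp(3 * marker), tm, ev)
  expect_equal(oc2$statistic, oc$statistic, tolerance = 1e-10)
  expect_equal(oc2$cutpoint, exp(3 * oc$cutpoint), tolerance = 1e-10)
  # separation fixture: cutpoint lies between the groups
  mk <- c(rep(1, 10), rep(10, 10))
  tms <- c(rexp(10, 0.5), rexp(10, 0.01) + 1)
  oc3 <- optimal_cutpoint(mk + seq_along(mk) * 1e-4, tms, rep(1, 20))
  expect_true(oc3$cutpoint > 1 && oc3$cutpoint < 10)
  # independent marker: permutation reference is non-significant
  set.seed(38)
  oc4 <- optimal_cutpoint(rnorm(40), rexp(40), rbinom(40, 1, 0.8),
                          n_perm = 200, seed = 2)
  expect_gt(oc4$permutation_p, 0.1)
  expect_error(optimal_cutpoint(rep(1, 12), rexp(12), rep(1, 12)), "equal")
})

test_that("Fisher exact p equals full enumeration for small tables", {
  expect_equal(fisher_exact(matrix(c(3, 0, 0, 3), 2))$p_value, 0.1,
               tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(2, 2, 2, 2), 2))$p_value, 1)
  deg <- fisher_exact(matrix(c(0, 0, 3, 4), 2))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  set.seed(39)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 2.5), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p_value, oracle_fisher(tab),
                 tolerance = 1e-10)
  }
})

test_that("cis/trans screen labels effects and recovers the planted cis gene", {
  co <- small_cohort()
  prot <- cached_norm_layer(co, "proteome", "small7")
  tum <- paste0(rownames(co$mutations), "_T")
  v <- prot$values[, tum]
  colnames(v) <- rownames(co$mutations)
  status <- sweep(t(v), 2, apply(v, 1, median), ">")
  genes <- co$truth$mutated_gene_effects$gene
  keep_prot <- unique(c(colnames(co$mutations),
                        rownames(v)[seq_len(300)]))
  res <- cis_trans_fisher(co$mutations, status[, intersect(keep_prot, colnames(status))])
  expect_true(all(res$effect_class[res$gene == res$protein] == "cis"))
  expect_true(all(res$effect_class[res$gene != res$protein] == "trans"))
  cis <- res[res$effect_class == "cis", ]
  cis_gene <- genes[co$truth$mutated_gene_effects$effect_class == "cis"]
  expect_equal(cis$gene[which.min(cis$p_value)], cis_gene)
  expect_equal(cis$direction[cis$gene == cis_gene], "down")
  # BH is applied within each mutated gene
  one <- res[res$gene == genes[1], ]
  expect_equal(one$bh_adjusted_p, bh_adjust(one$p_value))
})
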