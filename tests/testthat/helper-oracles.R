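# Independent brute-force / enumeration oracles. These deliberately share no
# code with the package: every statistic is recomputed from first principles
# on small inputs.

# two-sided signed-rank p by exhaustive sign-flip enumeration (midranks)
oracle_signed_rank <- function(x, y) {
  d <- (x - y)[x != y]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- as.vector(signs %*% r)
  min(1, 2 * min(mean(W <= V + 1e-9), mean(W >= V - 1e-9)))
}

# two-sided rank-sum p by enumerating all group labelings
oracle_ranksum <- function(a, b) {
  v <- c(a, b)
  r <- rank(v)
  na <- length(a)
  Wobs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(length(v), na)
  W <- apply(combs, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(W <= Wobs + 1e-9), mean(W >= Wobs - 1e-9)))
}

# two-sided Fisher p by enumerating the hypergeometric support
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# upper-tail hypergeometric by direct combinatorial summation
oracle_hyper_tail <- function(overlap, n_deps, n_universe, n_targets) {
  ks <- overlap:min(n_deps, n_targets)
  sum(choose(n_deps, ks) * choose(n_universe - n_deps, n_targets - ks)) /
    choose(n_universe, n_targets)
}

# BH step-up by the direct min-k formula
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    ks <- which(rank(p, ties.method = "first") >= rank(p, ties.method = "first")[i])
    adj[i] <- min(1, min(p[ks] * n / rank(p, ties.method = "first")[ks]))
  }
  # equivalent direct computation on sorted values
  ps <- p[o]
  a <- pmin(1, ps * n / seq_len(n))
  a <- rev(cummin(rev(a)))
  out <- numeric(n); out[o] <- a
  out
}

# Kaplan-Meier product-limit by a hand loop
oracle_km <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

# two-group log-rank chi-square by an O/E/V tally
oracle_logrank <- function(times, events, groups) {
  g <- as.integer(factor(groups))
  ut <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in ut) {
    n <- sum(times >= t)
    n1 <- sum(times >= t & g == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- (O - E)^2 / V
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

# Cox partial-likelihood MLE for one covariate, no ties, by Newton-Raphson
oracle_cox_beta <- function(times, events, x) {
  stopifnot(!anyDuplicated(times[events == 1]))
  beta <- 0
  for (it in 1:50) {
    U <- 0; Iinfo <- 0
    for (i in which(events == 1)) {
      risk <- which(times >= times[i])
      w <- exp(beta * x[risk])
      xbar <- sum(w * x[risk]) / sum(w)
      U <- U + x[i] - xbar
      Iinfo <- Iinfo + sum(w * x[risk]^2) / sum(w) - xbar^2
    }
    step <- U / Iinfo
    beta <- beta + step
    if (abs(step) < 1e-12) break
  }
  beta
}

# Spearman rho by the explicit rank formula (with midranks)
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# mean-of-order-statistics quantile normalization for complete matrices,
# ties replaced by the mean of the reference values they span
oracle_quantile_norm <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j], ties.method = "average")
    # value at (possibly fractional) rank r: mean of the spanned ref values
    out[, j] <- vapply(r, function(ri) {
      lo <- floor(ri); hi <- ceiling(ri)
      mean(ref[lo:hi])
    }, 0)
  }
  out
}

# KSEA z from the plain formula, no shared code
oracle_ksea_z <- function(fc, subs) {
  s <- fc[subs]
  (mean(s) - mean(fc)) * sqrt(length(s)) / stats::sd(fc)
}
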