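# Survival estimation and testing, optimal dichotomization, hazard ratios,
# and mutation cis/trans-effect testing. The estimators delegate to the
# survival package (product-limit with Greenwood variance, log-rank,
# Cox partial likelihood with Efron ties); the surrounding conventions —
# cutpoint search window, tie-breaks, per-gene BH across protein partners —
# live here.

#' Kaplan-Meier estimate per group
#'
#' @param times,events numeric survival times (>= 0) and 0/1 event flags.
#' @param groups optional group labels (default: one group).
#' @return object of class `SurvivalFit`: per group, data.frame `time`,
#'   `n_risk`, `n_event`, `surv`, `std_err` (Greenwood).
#' @export
km_estimate <- function(times, events, groups = NULL) {
  if (any(times < 0, na.rm = TRUE)) stop("times must be >= 0")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  if (is.null(groups)) groups <- rep("all", length(times))
  if (any(table(groups) == 0) || length(times) == 0) stop("empty group")
  g <- factor(groups)
  fits <- lapply(levels(g), function(lv) {
    i <- g == lv
    sf <- survival::survfit(survival::Surv(times[i], events[i]) ~ 1,
                            conf.type = "log")
    data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
               surv = sf$surv, std_err = sf$std.err * sf$surv)
  })
  names(fits) <- levels(g)
  structure(list(groups = fits), class = "SurvivalFit")
}

#' @export
print.SurvivalFit <- function(x, ...) {
  for (g in names(x$groups)) {
    f <- x$groups[[g]]
    cat(sprintf("%s: %d event times, S(last) = %.3f\n", g, nrow(f),
                if (nrow(f)) f$surv[nrow(f)] else 1))
  }
  invisible(x)
}

#' Log-rank test
#'
#' Standard observed-minus-expected chi-square with hypergeometric variance,
#' df = groups - 1.
#'
#' @inheritParams km_estimate
#' @param groups group labels (>= 2 groups).
#' @return list `chi2`, `df`, `p_value`.
#' @export
logrank_test <- function(times, events, groups) {
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  if (sum(events) == 0) stop("no events; log-rank undefined")
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need >= 2 groups")
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- length(sd_$n) - 1
  list(chi2 = unname(sd_$chisq), df = df,
       p_value = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards hazard ratios
#'
#' Partial-likelihood estimates with Efron tie handling; HR = exp(beta) with
#' Wald 95% confidence intervals. Covariates may be numeric or categorical
#' (factors are expanded as usual).
#'
#' @inheritParams km_estimate
#' @param covariates data.frame of covariates (no constant column).
#' @return data.frame: `term`, `beta`, `se`, `hr`, `ci_lower`, `ci_upper`,
#'   `p_value`.
#' @export
cox_hr <- function(times, events, covariates) {
  covariates <- as.data.frame(covariates)
  const <- vapply(covariates, function(v) length(unique(v[!is.na(v)])) < 2, TRUE)
  if (any(const)) stop("constant covariate: ",
                       paste(names(covariates)[const], collapse = ", "))
  if (sum(events) < ncol(covariates) + 1)
    stop("fewer events than covariates + 1")
  df <- data.frame(.time = times, .event = events, covariates)
  fit <- tryCatch(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = df,
                    ties = "efron"),
    warning = function(w) stop("Cox fit unstable: ", conditionMessage(w)),
    error = function(e) stop("Cox fit failed: ", conditionMessage(e)))
  s <- summary(fit)
  out <- data.frame(term = rownames(s$coefficients),
                    beta = s$coefficients[, "coef"],
                    se = s$coefficients[, "se(coef)"],
                    hr = s$coefficients[, "exp(coef)"],
                    ci_lower = s$conf.int[, "lower .95"],
                    ci_upper = s$conf.int[, "upper .95"],
                    p_value = s$coefficients[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Optimal survival cutpoint for a continuous marker
#'
#' Maximally selected log-rank statistic: every candidate cutpoint between
#' the 10th and 90th percentile of the marker is scored by the standardized
#' two-group log-rank statistic |O - E| / sqrt(V); the argmax is returned,
#' ties broken toward the marker median. The selection-bias-corrected
#' p-value of the maximal statistic is out of scope; an optional permutation
#' reference (`n_perm > 0`) reports how often permuted markers reach the
#' observed maximum.
#'
#' @inheritParams km_estimate
#' @param marker numeric marker values (>= 10 subjects, not all equal).
#' @param quantile_range candidate window (default 10th-90th percentile).
#' @param n_perm optional permutation count for the reference p-value.
#' @param seed seed for the permutation reference.
#' @return list: `cutpoint`, `statistic` (standardized log-rank at the
#'   cutpoint), `candidates` (data.frame cutpoint, statistic), and
#'   `permutation_p` when requested.
#' @export
optimal_cutpoint <- function(marker, times, events,
                             quantile_range = c(0.1, 0.9), n_perm = 0,
                             seed = 1) {
  ok <- is.finite(marker) & is.finite(times) & is.finite(events)
  marker <- marker[ok]; times <- times[ok]; events <- events[ok]
  if (length(marker) < 10) stop("need >= 10 subjects")
  if (length(unique(marker)) < 2) stop("all marker values equal")
  q <- stats::quantile(marker, quantile_range, names = FALSE)
  cands <- sort(unique(marker))
  cands <- cands[cands >= q[1] & cands < q[2]]
  if (!length(cands)) stop("no candidate cutpoints inside the quantile window")
  stat_at <- function(cut, mk) {
    hi <- mk > cut
    if (!any(hi) || all(hi)) return(NA_real_)
    sd_ <- survival::survdiff(survival::Surv(times, events) ~ hi)
    sqrt(unname(sd_$chisq))
  }
  stats_ <- vapply(cands, stat_at, 0, mk = marker)
  valid <- is.finite(stats_)
  if (!any(valid)) stop("log-rank statistic undefined at every candidate")
  best <- max(stats_[valid])
  at_best <- cands[valid][stats_[valid] >= best - 1e-12]
  med <- stats::median(marker)
  cut <- at_best[which.min(abs(at_best - med))]
  out <- list(cutpoint = cut, statistic = best,
              candidates = data.frame(cutpoint = cands, statistic = stats_))
  if (n_perm > 0) {
    set.seed(as.integer(seed))
    null_max <- replicate(n_perm, {
      pm <- sample(marker)
      s <- vapply(cands, stat_at, 0, mk = pm)
      if (all(!is.finite(s))) 0 else max(s, na.rm = TRUE)
    })
    out$permutation_p <- (sum(null_max >= best - 1e-12) + 1) / (n_perm + 1)
  }
  out
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' A degenerate margin (a row or column of zeros) returns p = 1 with a flag.
#'
#' @param tab 2x2 integer matrix.
#' @return list `p_value`, `odds_ratio`, `degenerate`.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("2x2 table required")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(p_value = 1, odds_ratio = NA_real_, degenerate = TRUE))
  ht <- stats::fisher.test(tab)
  list(p_value = min(1, ht$p.value), odds_ratio = unname(ht$estimate),
       degenerate = FALSE)
}

#' Mutation cis/trans effect screen
#'
#' For every (mutated gene, protein) pair: two-sided Fisher exact test on
#' the 2x2 table mutated/wild-type x protein up/not-up, BH-adjusted across
#' proteins within each mutated gene. `cis` iff the protein symbol equals
#' the mutated gene. Direction is the sign of the odds ratio association
#' (`up` when carriers are enriched for up-status).
#'
#' @param mutations logical patient x gene matrix.
#' @param protein_status logical patient x protein matrix (TRUE = "up";
#'   the dichotomization — e.g. above cohort median — is the caller's).
#' @return data.frame of class `CisTransResult`: `gene`, `protein`,
#'   `effect_class`, `p_value`, `bh_adjusted_p`, `direction`, `degenerate`.
#' @export
cis_trans_fisher <- function(mutations, protein_status) {
  pats <- intersect(rownames(mutations), rownames(protein_status))
  if (length(pats) < 4) stop("need >= 4 shared patients")
  mutations <- mutations[pats, , drop = FALSE]
  protein_status <- protein_status[pats, , drop = FALSE]
  rows <- list(); i <- 0L
  for (g in colnames(mutations)) {
    mt <- mutations[, g]
    res_g <- lapply(colnames(protein_status), function(pr) {
      up <- protein_status[, pr]
      tab <- table(factor(mt, c(FALSE, TRUE)), factor(up, c(FALSE, TRUE)))
      fe <- fisher_exact(tab)
      up_rate_mut <- if (any(mt)) mean(up[mt]) else NA_real_
      up_rate_wt <- if (any(!mt)) mean(up[!mt]) else NA_real_
      data.frame(gene = g, protein = pr,
                 effect_class = if (pr == g) "cis" else "trans",
                 p_value = fe$p_value,
                 direction = ifelse(is.na(up_rate_mut) | is.na(up_rate_wt), NA,
                                    ifelse(up_rate_mut >= up_rate_wt, "up", "down")),
                 degenerate = fe$degenerate, stringsAsFactors = FALSE)
    })
    res_g <- do.call(rbind, res_g)
    res_g$bh_adjusted_p <- bh_adjust(res_g$p_value)
    i <- i + 1L
    rows[[i]] <- res_g
  }
  out <- do.call(rbind, rows)
  out <- out[, c("gene", "protein", "effect_class", "p_value",
                 "bh_adjusted_p", "direction", "degenerate")]
  rownames(out) <- NULL
  class(out) <- c("CisTransResult", "data.frame")
  out
}
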