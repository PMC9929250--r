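# Bayes-rule linear-predictor-score (LPS) subtype classifier.
#
# Two-class predictor in the Wright et al. LPS tradition: features are
# z-scored, weighted by their two-sample t-statistic, and summed into a
# per-sample linear predictor score; a Gaussian is fitted to the LPS within
# each training class, and new samples are assigned by the Bayes posterior
# with an abstention ("unclassified") band below the certainty cutoff.

#' Fit an LPS classifier
#'
#' @param x feature x sample numeric matrix of activity values (any
#'   monotone scale; z-scoring is internal). Typically two TF-activity rows.
#' @param labels named two-level factor/vector over the columns of `x`;
#'   each class needs >= 3 samples.
#' @param features rows of `x` to use (default: all rows).
#' @param cutoff posterior certainty required for a class call, in (0.5, 1];
#'   default 0.75.
#' @return object of class `lps_model`: per-feature weights (two-sample
#'   t-statistics on training z-scores), training standardization parameters,
#'   per-class LPS Gaussians, uniform priors, the cutoff, and the training
#'   scores.
#' @export
fit_lps <- function(x, labels, features = NULL, cutoff = 0.75) {
  if (cutoff <= 0.5 || cutoff > 1) stop("cutoff must lie in (0.5, 1]")
  if (!is.null(features)) {
    missing_f <- setdiff(features, rownames(x))
    if (length(missing_f)) stop("features absent: ", paste(missing_f, collapse = ", "))
    x <- x[features, , drop = FALSE]
  }
  labels <- labels[intersect(names(labels), colnames(x))]
  g <- factor(labels)
  if (nlevels(g) != 2) stop("exactly two classes required")
  if (any(table(g) < 3)) stop("each class needs >= 3 samples")
  x <- x[, names(labels), drop = FALSE]
  mu <- rowMeans(x)
  sd_ <- apply(x, 1, stats::sd)
  if (any(sd_ == 0)) stop("feature with zero variance in training data")
  z <- (x - mu) / sd_
  cls <- levels(g)
  a <- vapply(rownames(z), function(f) {
    unname(stats::t.test(z[f, g == cls[1]], z[f, g == cls[2]])$statistic)
  }, 0)
  lps <- as.vector(a %*% z)
  names(lps) <- colnames(z)
  gauss <- lapply(cls, function(cl) {
    s <- lps[g == cl]
    if (stats::sd(s) == 0) stop("zero within-class LPS variance")
    # MLE sd (divide by n), matching a plain Gaussian likelihood fit
    list(mean = mean(s), sd = sqrt(mean((s - mean(s))^2)))
  })
  names(gauss) <- cls
  structure(list(weights = a, feature_means = mu, feature_sds = sd_,
                 classes = cls, gaussians = gauss,
                 priors = setNames(c(0.5, 0.5), cls), cutoff = cutoff,
                 training_lps = lps, training_labels = g),
            class = "lps_model")
}

#' @export
print.lps_model <- function(x, ...) {
  cat("LPS classifier:", paste(names(x$weights), collapse = " + "), "\n")
  cat(sprintf("  weights: %s\n",
              paste(sprintf("%s=%.3f", names(x$weights), x$weights), collapse = ", ")))
  for (cl in x$classes)
    cat(sprintf("  class %s: LPS ~ N(%.3f, %.3f), prior %.2f\n", cl,
                x$gaussians[[cl]]$mean, x$gaussians[[cl]]$sd, x$priors[[cl]]))
  cat(sprintf("  certainty cutoff: %.2f\n", x$cutoff))
  invisible(x)
}

#' Classify samples with a fitted LPS model
#'
#' Posterior for class 1 is `p1*phi1(LPS) / (p1*phi1 + p2*phi2)`; a sample is
#' called for a class when its posterior reaches the cutoff, otherwise
#' `unclassified` (or the argmax class in `strict` mode). By default new
#' cohorts are standardized with their own feature means/sds (per-cohort
#' z-scores, the cross-cohort convention); `standardize = "training"` reuses
#' the training parameters instead.
#'
#' @param model an [fit_lps()] object.
#' @param newdata feature x sample matrix containing the model's features;
#'   missing feature values are an error (no imputation at classify time).
#' @param standardize `"cohort"` (default) or `"training"`.
#' @param strict if TRUE, always call the maximum-posterior class.
#' @return data.frame: `sample`, `lps`, `posterior_<class1>`, `call`.
#' @export
classify_lps <- function(model, newdata, standardize = c("cohort", "training"),
                         strict = FALSE) {
  stopifnot(inherits(model, "lps_model"))
  standardize <- match.arg(standardize)
  feats <- names(model$weights)
  missing_f <- setdiff(feats, rownames(newdata))
  if (length(missing_f)) stop("features absent: ", paste(missing_f, collapse = ", "))
  x <- newdata[feats, , drop = FALSE]
  if (any(!is.finite(x))) stop("missing feature values at classify time")
  if (standardize == "cohort") {
    mu <- rowMeans(x); sd_ <- apply(x, 1, stats::sd)
    if (any(sd_ == 0)) stop("feature with zero variance in the new cohort")
  } else {
    mu <- model$feature_means[feats]; sd_ <- model$feature_sds[feats]
  }
  z <- (x - mu) / sd_
  lps <- as.vector(model$weights %*% z)
  c1 <- model$classes[1]; c2 <- model$classes[2]
  d1 <- model$priors[[c1]] * stats::dnorm(lps, model$gaussians[[c1]]$mean,
                                          model$gaussians[[c1]]$sd)
  d2 <- model$priors[[c2]] * stats::dnorm(lps, model$gaussians[[c2]]$mean,
                                          model$gaussians[[c2]]$sd)
  p1 <- d1 / (d1 + d2)
  call <- ifelse(p1 >= model$cutoff, c1,
                 ifelse(1 - p1 >= model$cutoff, c2, "unclassified"))
  if (strict) call <- ifelse(p1 >= 0.5, c1, c2)
  out <- data.frame(sample = colnames(x), lps = lps, posterior = p1,
                    call = call, stringsAsFactors = FALSE)
  names(out)[3] <- paste0("posterior_", c1)
  rownames(out) <- NULL
  out
}

#' @export
predict.lps_model <- function(object, newdata,
                              standardize = c("cohort", "training"),
                              strict = FALSE, ...) {
  classify_lps(object, newdata, standardize = standardize, strict = strict)
}
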