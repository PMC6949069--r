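#' Leave-one-out cross-validated SVM AUC
#'
#' Trains a linear-kernel SVM (cost 1) on standardized features for every
#' leave-one-out fold (standardization fit on the training fold only),
#' records each left-out sample's decision value, and computes the AUC of
#' the pooled decision values against the labels (tumor = positive). The
#' ROC curve is built from the pooled values and integrated by the
#' trapezoidal rule.
#'
#' @param expr an [expression_matrix].
#' @param features gene symbols used as features; unmeasured features are
#'   dropped with a warning.
#' @param labels optional per-sample labels (`"tumor"`/`"normal"`);
#'   defaults to the annotation of `expr`.
#' @return list with `auc`, `roc_points` (data.frame `fpr`, `tpr`),
#'   `n_features`, `feature_genes`, `decision_values`.
#' @export
loocv_auc <- function(expr, features, labels = NULL) {
  features <- unique(as.character(features))
  present <- intersect(features, rownames(expr$values))
  if (length(present) == 0) {
    abort_riskmod("no feature gene has expression data",
                  "riskmod_config_error")
  }
  if (length(present) < length(features)) {
    warning(sprintf("dropping %d unmeasured feature(s)",
                    length(features) - length(present)))
  }
  if (is.null(labels)) {
    labels <- expr$samples$condition
  }
  y <- factor(labels, levels = c("normal", "tumor"))
  if (any(table(y) < 2)) {
    abort_riskmod("need at least 2 samples per class",
                  "riskmod_insufficient_data_error")
  }
  X <- t(expr$values[present, , drop = FALSE])
  n <- nrow(X)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    tr <- X[-i, , drop = FALSE]
    mu <- colMeans(tr)
    sg <- apply(tr, 2, sd)
    sg[sg == 0] <- 1
    trs <- scale(tr, center = mu, scale = sg)
    tes <- (X[i, ] - mu) / sg
    fit <- e1071::svm(x = trs, y = y[-i], kernel = "linear", cost = 1,
                      scale = FALSE)
    dv <- attr(stats::predict(fit, newdata = matrix(tes, nrow = 1),
                              decision.values = TRUE),
               "decision.values")
    # e1071 orients the decision value toward the first class of the
    # "A/B" column name; flip so larger always means more tumor-like
    lab <- colnames(dv)[1]
    scores[i] <- if (startsWith(lab, "tumor")) dv[1] else -dv[1]
  }
  roc <- roc_points(scores, y == "tumor")
  list(auc = trapezoid_auc(roc), roc_points = roc,
       n_features = length(present), feature_genes = present,
       decision_values = scores)
}

# ROC curve (fpr, tpr) over the unique score thresholds, descending
roc_points <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  pos <- positive[ord]
  thr_last <- !duplicated(scores[ord], fromLast = TRUE)
  tpr <- cumsum(pos) / sum(pos)
  fpr <- cumsum(!pos) / sum(!pos)
  data.frame(fpr = c(0, fpr[thr_last]), tpr = c(0, tpr[thr_last]))
}

trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' AUC baseline from random gene sets
#'
#' Samples `count` gene sets of size `n_features` uniformly from the
#' network nodes measured in `expr` and records each set's LOOCV SVM AUC;
#' the observed module AUC is judged against this distribution.
#'
#' @param expr an [expression_matrix].
#' @param network an [interaction_network].
#' @param n_features random set size.
#' @param labels optional labels passed to [loocv_auc].
#' @param count number of random sets (default 100).
#' @param rng_seed integer seed.
#' @return numeric vector of `count` AUC values.
#' @export
random_featureset_baseline <- function(expr, network, n_features,
                                       labels = NULL, count = 100,
                                       rng_seed = 1) {
  pool <- intersect(network$nodes, rownames(expr$values))
  if (n_features > length(pool)) {
    abort_riskmod("n_features exceeds measured network genes",
                  "riskmod_sampling_error")
  }
  sets <- with_rng_seed(rng_seed, {
    lapply(seq_len(count), function(i) sample(pool, n_features))
  })
  vapply(sets, function(s) loocv_auc(expr, s, labels = labels)$auc,
         numeric(1))
}
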