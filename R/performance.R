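#' ROC curve and AUC
#'
#' AUC in the Mann-Whitney form: the probability that a random positive
#' sample outscores a random negative one, ties counted one half. The ROC
#' holds all threshold points.
#'
#' @param scores numeric classification scores.
#' @param labels 2-level sample labels (both classes present).
#' @param positive positive class label (default second factor level).
#' @return list with \code{auc} and \code{roc} (data.frame threshold, fpr,
#'   tpr).
#' @export
rocAUC <- function(scores, labels, positive = NULL) {
  g <- .as_group(labels, positive)
  positive <- levels(g)[2L]
  r <- pROC::roc(response = g, predictor = scores, levels = levels(g),
                 direction = "<", quiet = TRUE)
  list(auc = as.numeric(pROC::auc(r)),
       roc = data.frame(threshold = r$thresholds,
                        fpr = 1 - r$specificities, tpr = r$sensitivities),
       roc_obj = r)
}

#' DeLong confidence interval for the AUC
#'
#' Variance from DeLong placement values; the interval is AUC +/- z * SE,
#' truncated to [0, 1]. Perfect separation gives zero variance and a
#' degenerate interval with a warning.
#'
#' @param scores,labels,positive as in \code{\link{rocAUC}}.
#' @param level confidence level (default 0.95).
#' @return numeric vector \code{c(lo, hi)} with attribute \code{auc}.
#' @export
delongCI <- function(scores, labels, level = 0.95, positive = NULL) {
  g <- .as_group(labels, positive)
  if (min(table(g)) < 2) stop("need >= 2 samples per class")
  r <- pROC::roc(response = g, predictor = scores, levels = levels(g),
                 direction = "<", quiet = TRUE)
  a <- as.numeric(pROC::auc(r))
  ci <- suppressWarnings(
    tryCatch(as.numeric(pROC::ci.auc(r, conf.level = level,
                                     method = "delong")),
             error = function(e) c(a, a, a)))
  if (!all(is.finite(ci)) || ci[3L] - ci[1L] < 1e-12) {
    warning("zero DeLong variance (perfect separation); degenerate interval")
    ci <- c(a, a, a)
  }
  out <- c(lo = max(0, ci[1L]), hi = min(1, ci[3L]))
  attr(out, "auc") <- a
  out
}

#' Accuracy-maximizing threshold
#'
#' Scans all midpoints between adjacent sorted unique scores (plus sentinels
#' below and above the range, so all-positive and all-negative calls are
#' considered) and returns the threshold maximizing (TP + TN) / n; ties break
#' to the lowest threshold. Samples at or above the threshold are called
#' positive.
#'
#' @param scores,labels,positive as in \code{\link{rocAUC}}.
#' @return list with \code{threshold} and \code{accuracy}.
#' @export
bestAccuracy <- function(scores, labels, positive = NULL) {
  g <- .as_group(labels, positive)
  positive <- levels(g)[2L]
  u <- sort(unique(scores))
  cand <- c(u[1L] - 1, if (length(u) > 1) (u[-1L] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  acc <- vapply(cand, function(thr)
    mean((scores >= thr) == (g == positive)), numeric(1))
  best <- which.max(acc)   # which.max takes the first (lowest) on ties
  list(threshold = cand[best], accuracy = acc[best])
}

#' Leave-one-out cross validation with locked artifacts
#'
#' Each round refits only the SVM on n - 1 training samples (gene panel,
#' normalization and cost/gamma stay locked) and scores the left-out sample;
#' n rounds give n predictions.
#'
#' @param feat sample-by-gene feature matrix (locked-panel logCPM).
#' @param labels 2-level training labels.
#' @param cost,gamma locked SVM parameters.
#' @param positive positive class label.
#' @return data.frame with sample, label and score.
#' @export
loocv <- function(feat, labels, cost, gamma, positive = NULL) {
  g <- .as_group(labels, positive)
  positive <- levels(g)[2L]
  n <- nrow(feat)
  scores <- vapply(seq_len(n), function(i) {
    fit <- e1071::svm(feat[-i, , drop = FALSE], g[-i], kernel = "radial",
                      cost = cost, gamma = gamma, scale = FALSE)
    dtr <- .svm_decision(fit, feat[-i, , drop = FALSE], positive)
    calib <- .platt_fit(dtr, g[-i] == positive)
    .platt_apply(calib,
                 .svm_decision(fit, feat[i, , drop = FALSE], positive))
  }, numeric(1))
  data.frame(sample = rownames(feat) %||% as.character(seq_len(n)),
             label = as.character(g), score = scores,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permutation null for validation performance
#'
#' Class labels of the training samples are randomly permuted while the
#' swarm-guided gene panel (and cost/gamma) are maintained; the SVM is refit
#' and the validation AUC recorded. The p value uses the add-one estimator
#' p = (1 + #(perm AUC >= observed)) / (1 + n_perm).
#'
#' @param feat training sample-by-gene feature matrix (locked panel).
#' @param labels training labels.
#' @param valid_feat,valid_labels validation features and labels.
#' @param cost,gamma locked SVM parameters.
#' @param observed_auc observed validation AUC of the unpermuted model.
#' @param n_perm number of permutations (default 1000).
#' @param positive positive class label.
#' @param seed RNG seed.
#' @return list with \code{p_value} and \code{perm_auc}.
#' @export
permutationNull <- function(feat, labels, valid_feat, valid_labels,
                            cost, gamma, observed_auc, n_perm = 1000,
                            positive = NULL, seed = 1) {
  stopifnot(n_perm >= 1)
  g <- .as_group(labels, positive)
  positive <- levels(g)[2L]
  gv <- as.character(valid_labels)
  set.seed(seed)
  perm_auc <- vapply(seq_len(n_perm), function(i) {
    gp <- sample(g)
    fit <- e1071::svm(feat, gp, kernel = "radial", cost = cost,
                      gamma = gamma, scale = FALSE)
    d <- .svm_decision(fit, valid_feat, positive)
    .auc_mw(d, gv, positive)
  }, numeric(1))
  perm_auc <- perm_auc[!is.na(perm_auc)]
  list(p_value = (1 + sum(perm_auc >= observed_auc)) /
         (1 + length(perm_auc)),
       perm_auc = perm_auc)
}

#' Training-resample stability
#'
#' Repeatedly redraws the training cohort (stratified, without replacement)
#' while maintaining the validation cohort and the swarm-guided gene panel,
#' refits the SVM and records the validation AUC.
#'
#' @param feat sample-by-gene features of the available training pool.
#' @param labels pool labels.
#' @param valid_feat,valid_labels fixed validation features and labels.
#' @param cost,gamma locked SVM parameters.
#' @param train_size samples drawn per replicate (<= pool size).
#' @param n_resample number of replicates (default 1000).
#' @param positive positive class label.
#' @param seed RNG seed.
#' @return list with \code{auc} (vector), \code{median} and \code{iqr}.
#' @export
resampleStability <- function(feat, labels, valid_feat, valid_labels,
                              cost, gamma, train_size,
                              n_resample = 1000, positive = NULL, seed = 1) {
  g <- .as_group(labels, positive)
  positive <- levels(g)[2L]
  stopifnot(train_size <= nrow(feat), train_size >= 4)
  gv <- as.character(valid_labels)
  frac <- train_size / nrow(feat)
  set.seed(seed)
  aucs <- vapply(seq_len(n_resample), function(i) {
    idx <- unlist(lapply(levels(g), function(lv) {
      cls <- which(g == lv)
      sample(cls, max(2L, round(frac * length(cls))))
    }))
    fit <- e1071::svm(feat[idx, , drop = FALSE], g[idx], kernel = "radial",
                      cost = cost, gamma = gamma, scale = FALSE)
    d <- .svm_decision(fit, valid_feat, positive)
    .auc_mw(d, gv, positive)
  }, numeric(1))
  list(auc = aucs, median = stats::median(aucs, na.rm = TRUE),
       iqr = stats::IQR(aucs, na.rm = TRUE))
}
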