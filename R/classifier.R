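# Fast rank-based AUC (Mann-Whitney, ties counted 1/2) used inside CV loops.
.auc_mw <- function(scores, labels, positive) {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Mean 2-fold (stratified) CV AUC of an RBF SVM at (cost, gamma).
.cv_auc <- function(feat, labels, cost, gamma, folds, positive) {
  aucs <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    if (length(unique(labels[tr])) < 2 || length(unique(labels[!tr])) < 2)
      return(NA_real_)
    fit <- e1071::svm(feat[tr, , drop = FALSE], labels[tr],
                      kernel = "radial", cost = cost, gamma = gamma,
                      scale = FALSE)
    d <- .svm_decision(fit, feat[!tr, , drop = FALSE], positive)
    .auc_mw(d, labels[!tr], positive)
  }, numeric(1))
  mean(aucs)
}

#' Initial gene panel by likelihood-ratio ANOVA
#'
#' Runs the negative-binomial GLM likelihood-ratio test on the training
#' samples (raw counts, TMM-scaled library sizes) and returns the genes
#' passing the FDR threshold, ordered by likelihood-ratio statistic
#' descending.
#'
#' @param counts gene-by-sample raw training counts.
#' @param group 2-level training labels.
#' @param fdr_threshold FDR cutoff (strict <).
#' @param prior_df tagwise dispersion shrinkage prior.
#' @return a \linkS4class{GenePanel}.
#' @export
rankGenesANOVA <- function(counts, group, fdr_threshold = 0.05,
                           prior_df = 10) {
  res <- diffSplicing(counts, group, prior_df = prior_df)
  sel <- res[!is.na(res$FDR) & res$FDR < fdr_threshold, , drop = FALSE]
  if (nrow(sel) == 0L)
    stop("empty ANOVA panel at FDR < ", fdr_threshold,
         "; raise the threshold")
  ord <- order(-sel$LR)
  methods::new("GenePanel", genes = sel$gene_id[ord], scores = sel$LR[ord],
               provenance = list(stage = "anova", fdr = fdr_threshold))
}

#' Remove highly inter-correlated panel genes
#'
#' Greedy filter on the pairwise absolute Pearson correlations of the panel
#' genes' logCPM values: while any pair exceeds the cutoff, the member of the
#' worst (largest |r|) pair with the larger mean absolute correlation to the
#' remaining genes is removed (ties break to the later panel position).
#' Highly redundant genes contribute noise to SVM models.
#'
#' @param logcpm gene-by-sample matrix restricted to the panel genes.
#' @param panel a \linkS4class{GenePanel} (order defines tie-breaking).
#' @param cutoff correlation cutoff in (0, 1].
#' @return the surviving \linkS4class{GenePanel} (original order).
#' @export
removeCorrelatedGenes <- function(logcpm, panel, cutoff = 0.9) {
  stopifnot(cutoff > 0, cutoff <= 1)
  genes <- panel@genes
  stopifnot(all(genes %in% rownames(logcpm)))
  cm <- abs(stats::cor(t(logcpm[genes, , drop = FALSE])))
  cm[is.na(cm)] <- 0
  diag(cm) <- 0
  alive <- rep(TRUE, length(genes))
  repeat {
    sub <- cm[alive, alive, drop = FALSE]
    if (!length(sub) || max(sub) <= cutoff) break
    idx <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
    pair <- which(alive)[as.integer(idx)]
    mac <- vapply(pair, function(i)
      mean(cm[i, alive & seq_along(alive) != i]), numeric(1))
    drop_local <- if (abs(diff(mac)) < 1e-12) which.max(pair)
                  else which.max(mac)
    alive[pair[drop_local]] <- FALSE
  }
  keep <- genes[alive]
  methods::new("GenePanel", genes = keep,
               scores = panel@scores[match(keep, genes)],
               provenance = c(panel@provenance, list(corr_cutoff = cutoff)))
}

#' SVM recursive feature elimination
#'
#' Iteratively fits a linear-kernel SVM on the current genes, ranks genes by
#' squared weight and drops the lowest-ranked 10 percent (at least one gene)
#' per iteration until \code{target_size} genes remain. The returned panel is
#' ordered by the last iteration's ranking. A linear kernel supplies the
#' weight-based ranking criterion even though the final classifier kernel is
#' radial.
#'
#' @param logcpm gene-by-sample matrix restricted to the panel.
#' @param panel a \linkS4class{GenePanel}.
#' @param labels 2-level sample labels.
#' @param target_size panel size to retain (<= panel size).
#' @param cost linear SVM cost used for ranking fits.
#' @return a \linkS4class{GenePanel} of \code{target_size} genes.
#' @export
svmRFE <- function(logcpm, panel, labels, target_size, cost = 1) {
  genes <- panel@genes
  stopifnot(target_size >= 1, target_size <= length(genes))
  labels <- .as_group(labels)
  current <- genes
  w2 <- NULL
  repeat {
    feat <- t(logcpm[current, , drop = FALSE])
    fit <- e1071::svm(feat, labels, kernel = "linear", cost = cost,
                      scale = FALSE)
    w <- crossprod(fit$coefs, fit$SV)[1L, ]
    w2 <- w^2
    names(w2) <- current
    if (length(current) <= target_size) break
    n_drop <- min(max(1L, floor(0.1 * length(current))),
                  length(current) - target_size)
    # drop smallest w^2; ties resolved against later panel positions
    ord <- order(w2, -match(current, genes))
    current <- current[-ord[seq_len(n_drop)]]
  }
  final <- current[order(-w2[current])]
  methods::new("GenePanel", genes = final, scores = unname(w2[final]),
               provenance = c(panel@provenance,
                              list(rfe_size = as.integer(target_size))))
}

#' Grid search for SVM cost and gamma
#'
#' Evaluates a radial-basis SVM over the powers-of-two (gamma, cost) grid
#' (defaults 2^(-20:0) and 2^(0:20)) with stratified 2-fold internal cross
#' validation, returning the cell with the highest mean CV AUC; ties break to
#' the smaller cost, then the larger gamma. Fold assignment is deterministic
#' given the seed; a fold degenerating to a single class triggers refolding
#' (at most 5 attempts).
#'
#' @param logcpm gene-by-sample matrix restricted to the panel.
#' @param labels 2-level sample labels (>= 2 per class).
#' @param gamma_exp,cost_exp exponent grids (base 2).
#' @param folds number of internal CV folds (default 2).
#' @param seed fold seed.
#' @return list with \code{kernel}, \code{cost}, \code{gamma},
#'   \code{cost_exp}, \code{gamma_exp}, \code{folds}, \code{cv_auc} and the
#'   full \code{grid} data.frame.
#' @export
gridSearchSVM <- function(logcpm, labels, gamma_exp = -20:0,
                          cost_exp = 0:20, folds = 2, seed = 1) {
  labels <- .as_group(labels)
  if (min(table(labels)) < 2) stop("need >= 2 samples per class")
  positive <- levels(labels)[2L]
  feat <- t(logcpm)
  fold_id <- NULL
  for (attempt in seq_len(5L)) {
    cand <- .stratified_folds(labels, folds, seed + attempt - 1L)
    ok <- all(vapply(seq_len(folds), function(f)
      length(unique(labels[cand == f])) == 2L, logical(1)))
    if (ok) { fold_id <- cand; break }
  }
  if (is.null(fold_id)) stop("could not form two-class folds in 5 attempts")
  grid <- expand.grid(cost_exp = cost_exp, gamma_exp = gamma_exp)
  grid$cv_auc <- mapply(function(ce, ge)
    .cv_auc(feat, labels, 2^ce, 2^ge, fold_id, positive),
    grid$cost_exp, grid$gamma_exp)
  # tie-break: smaller cost, then larger gamma
  ord <- order(-grid$cv_auc, grid$cost_exp, -grid$gamma_exp)
  best <- grid[ord[1L], ]
  list(kernel = "radial", cost = 2^best$cost_exp, gamma = 2^best$gamma_exp,
       cost_exp = best$cost_exp, gamma_exp = best$gamma_exp, folds = folds,
       fold_id = fold_id, cv_auc = best$cv_auc, grid = grid)
}

#' PSO refinement of cost and gamma around the grid optimum
#'
#' Continuous particle-swarm search over (log2 gamma, log2 cost) in a box of
#' +/- \code{box_pad} powers of two around the grid optimum, maximizing the
#' same internal cross-validation AUC (identical folds). The grid optimum is
#' seeded as one particle, so the refined configuration is never worse than
#' the grid one.
#'
#' @param logcpm gene-by-sample matrix restricted to the panel.
#' @param labels 2-level sample labels.
#' @param grid_opt result of \code{\link{gridSearchSVM}}.
#' @param box_pad half-width of the search box in powers of two.
#' @param n_particles,n_iter swarm size and iterations.
#' @param seed RNG seed.
#' @return list in the same shape as \code{\link{gridSearchSVM}} (without
#'   the grid), with the refined cost/gamma and their CV AUC.
#' @export
psoRefineSVM <- function(logcpm, labels, grid_opt, box_pad = 2,
                         n_particles = 10, n_iter = 10, seed = 1) {
  labels <- .as_group(labels)
  positive <- levels(labels)[2L]
  feat <- t(logcpm)
  fold_id <- grid_opt$fold_id
  obj <- function(par) {
    a <- .cv_auc(feat, labels, cost = 2^par[2L], gamma = 2^par[1L],
                 fold_id, positive)
    if (is.na(a)) 1 else 1 - a
  }
  center <- c(grid_opt$gamma_exp, grid_opt$cost_exp)
  res <- psoOptimize(obj, lower = center - box_pad, upper = center + box_pad,
                     n_particles = n_particles, n_iter = n_iter, seed = seed,
                     init = matrix(center, 1L))
  list(kernel = "radial", cost = 2^res$par[2L], gamma = 2^res$par[1L],
       gamma_exp = res$par[1L], cost_exp = res$par[2L],
       folds = grid_opt$folds, fold_id = fold_id, cv_auc = 1 - res$value)
}

#' Train and lock the full classifier pipeline
#'
#' Composes, on the training samples only: iterative confounder-aware
#' normalization (locked), ANOVA gene ranking, correlation filtering,
#' SVM-RFE, cost/gamma grid search with PSO refinement, and a final
#' radial-basis SVM fit (with Platt-style probability calibration on
#' training decision values). Per-panel-gene training median counts are
#' stored for low-count imputation at prediction time. The returned model is
#' frozen: no evaluation or validation information enters it.
#'
#' @param x a \linkS4class{SplicedCounts} object containing (at least) the
#'   training samples.
#' @param training training sample ids.
#' @param theta named hyperparameters: \code{libsize_threshold} (stable-gene
#'   selection), \code{fdr_threshold} (ANOVA panel), \code{corr_cutoff}
#'   (correlation filter), \code{rfe_size} (RFE panel size).
#' @param k number of RUV factors (default 3).
#' @param impute_trigger counts in [0, trigger] are imputed at prediction
#'   (12 for the matched design, 2 for the full design).
#' @param positive label of the positive (case) class; default second level.
#' @param gamma_exp,cost_exp SVM grid exponents.
#' @param refine_particles,refine_iter inner PSO size.
#' @param prior_df dispersion shrinkage prior.
#' @param seed RNG seed (folds, inner PSO, probability calibration).
#' @return a \linkS4class{ClassifierModel}.
#' @export
trainClassifier <- function(x, training = colnames(x),
                            theta = c(libsize_threshold = 0.8,
                                      fdr_threshold = 0.05,
                                      corr_cutoff = 0.9, rfe_size = 50),
                            k = 3, impute_trigger = 12, positive = NULL,
                            gamma_exp = -20:0, cost_exp = 0:20,
                            refine_particles = 10, refine_iter = 10,
                            prior_df = 10, seed = 1) {
  stopifnot(all(c("libsize_threshold", "fdr_threshold", "corr_cutoff",
                  "rfe_size") %in% names(theta)))
  xt <- x[, training]
  ann <- sampleAnnotation(xt)
  if (!"group" %in% colnames(ann)) stop("training annotation needs 'group'")
  labels <- .as_group(ann$group, positive)
  positive <- levels(labels)[2L]

  norm <- iterativeCorrection(xt, training = training,
                              libsize_threshold = theta[["libsize_threshold"]],
                              k = k)
  panel <- rankGenesANOVA(counts(xt), labels,
                          fdr_threshold = theta[["fdr_threshold"]],
                          prior_df = prior_df)
  panel <- removeCorrelatedGenes(norm$logcpm, panel,
                                 cutoff = theta[["corr_cutoff"]])
  if (length(panel@genes) == 0L) stop("panel empty after correlation filter")
  target <- min(as.integer(round(theta[["rfe_size"]])), length(panel@genes))
  if (target < 1L) stop("panel empty at RFE stage")
  panel <- svmRFE(norm$logcpm, panel, labels, target_size = target)

  lc_panel <- norm$logcpm[panel@genes, , drop = FALSE]
  grid <- gridSearchSVM(lc_panel, labels, gamma_exp = gamma_exp,
                        cost_exp = cost_exp, seed = seed)
  cfg <- psoRefineSVM(lc_panel, labels, grid,
                      n_particles = refine_particles, n_iter = refine_iter,
                      seed = seed)

  feat <- t(lc_panel)
  fit <- e1071::svm(feat, labels, kernel = "radial", cost = cfg$cost,
                    gamma = cfg$gamma, scale = FALSE)
  med <- apply(counts(xt)[panel@genes, , drop = FALSE], 1L, stats::median)
  dv <- .svm_decision(fit, feat, positive)
  calib <- .platt_fit(dv, labels == positive)
  train_scores <- .platt_apply(calib, dv)
  names(train_scores) <- training

  methods::new("ClassifierModel",
    normModel = norm$model, panel = panel,
    svmConfig = list(kernel = "radial", cost = cfg$cost, gamma = cfg$gamma,
                     folds = grid$folds, cv_auc = cfg$cv_auc),
    svmFit = fit, calibration = calib, positiveClass = positive,
    imputationMedians = med, imputeTrigger = impute_trigger,
    theta = c(libsize_threshold = unname(theta[["libsize_threshold"]]),
              fdr_threshold = unname(theta[["fdr_threshold"]]),
              corr_cutoff = unname(theta[["corr_cutoff"]]),
              rfe_size = as.numeric(target)),
    trainingSamples = training, trainingScores = train_scores)
}

#' Default hyperparameter bounds for the outer swarm
#'
#' Spans the operating points used elsewhere in the pipeline: stable-gene
#' library-size threshold 0.5-0.95, ANOVA FDR threshold 1e-4-0.2,
#' correlation cutoff 0.5-1.0, RFE panel size 10-1000.
#'
#' @return list with \code{lower} and \code{upper} named vectors.
#' @export
defaultThetaBounds <- function() {
  list(lower = c(libsize_threshold = 0.5, fdr_threshold = 1e-4,
                 corr_cutoff = 0.5, rfe_size = 10),
       upper = c(libsize_threshold = 0.95, fdr_threshold = 0.2,
                 corr_cutoff = 1.0, rfe_size = 1000))
}

#' Outer particle-swarm optimization of the pipeline hyperparameters
#'
#' Standard PSO over the four pipeline hyperparameters (stable-gene
#' library-size threshold, ANOVA FDR threshold, correlation-filter cutoff,
#' RFE panel size; the last rounded to an integer at evaluation). The
#' objective is \code{1 - AUC} of the theta-trained classifier on the
#' disjoint evaluation cohort; a failing particle (e.g. empty panel) scores
#' 1. The global-best trace is non-increasing.
#'
#' @param x a \linkS4class{SplicedCounts} with training and evaluation
#'   samples.
#' @param training,evaluation disjoint sample id sets.
#' @param n_particles,n_iter swarm size and iterations (published designs:
#'   100 x 10 matched, 200 x 7 full).
#' @param bounds list with lower/upper named vectors
#'   (default \code{\link{defaultThetaBounds}}).
#' @param seed RNG seed.
#' @param ... further arguments passed to \code{\link{trainClassifier}}
#'   (e.g. k, grid exponents, impute_trigger).
#' @return list with \code{theta}, \code{model} (trained at the best theta),
#'   \code{objective} (1 - evaluation AUC) and \code{trace}.
#' @export
outerPSO <- function(x, training, evaluation, n_particles = 100, n_iter = 10,
                     bounds = defaultThetaBounds(), seed = 1, ...) {
  if (length(intersect(training, evaluation)))
    stop("training and evaluation cohorts must be disjoint")
  ann <- sampleAnnotation(x)
  ev_group <- ann[match(evaluation, colnames(x)), "group"]
  extra <- list(...)
  evalx <- x[, evaluation]
  obj <- function(par) {
    theta <- c(libsize_threshold = par[1L], fdr_threshold = par[2L],
               corr_cutoff = par[3L], rfe_size = round(par[4L]))
    model <- tryCatch(
      do.call(trainClassifier,
              c(list(x = x[, training], training = training, theta = theta,
                     seed = seed), extra)),
      error = function(e) NULL)
    if (is.null(model)) return(1)
    pred <- tryCatch(predictSamples(model, evalx), error = function(e) NULL)
    if (is.null(pred)) return(1)
    a <- .auc_mw(pred$score, as.character(ev_group), model@positiveClass)
    if (is.na(a)) 1 else 1 - a
  }
  res <- psoOptimize(obj, lower = bounds$lower, upper = bounds$upper,
                     n_particles = n_particles, n_iter = n_iter, seed = seed)
  theta <- c(libsize_threshold = res$par[1L], fdr_threshold = res$par[2L],
             corr_cutoff = res$par[3L], rfe_size = round(res$par[4L]))
  model <- do.call(trainClassifier,
                   c(list(x = x[, training], training = training,
                          theta = theta, seed = seed), extra))
  list(theta = theta, model = model, objective = res$value,
       trace = res$trace)
}

#' Impute undetected panel genes in a validation cohort
#'
#' Undetected genes in a validation cohort can hamper normalization and
#' reduce performance: for each panel gene and sample, counts between zero
#' and the trigger (inclusive on both ends) are replaced by the stored
#' training-cohort median for that gene. Panel genes absent from the table
#' are treated as count 0 (and hence imputed) with a warning.
#'
#' @param counts gene-by-sample matrix of validation counts.
#' @param model a \linkS4class{ClassifierModel}.
#' @param trigger replacement trigger (defaults to the model's; published
#'   designs use 12 for the matched and 2 for the full cohort).
#' @return the adjusted count matrix (model gene universe rows guaranteed).
#' @export
imputeUndetectedGenes <- function(counts, model,
                                  trigger = model@imputeTrigger) {
  stopifnot(trigger >= 0)
  universe <- model@normModel@genes
  missing <- setdiff(universe, rownames(counts))
  if (length(missing)) {
    warning(length(missing), " model gene(s) absent from validation table; ",
            "treated as count 0")
    add <- matrix(0, length(missing), ncol(counts),
                  dimnames = list(missing, colnames(counts)))
    counts <- rbind(counts, add)
  }
  counts <- counts[universe, , drop = FALSE]
  pg <- model@panel@genes
  sub <- counts[pg, , drop = FALSE]
  med <- model@imputationMedians[pg]
  low <- sub >= 0 & sub <= trigger
  sub[low] <- matrix(med, nrow(sub), ncol(sub))[low]
  counts[pg, ] <- sub
  counts
}

#' Predict samples with a locked classifier
#'
#' Applies, in order, low-count imputation, the locked normalization
#' (projection onto training factor directions, training-locked correction
#' coefficients, locked TMM reference), panel restriction and the frozen
#' SVM. Decision values are mapped to a [0, 1] classification score by the
#' Platt-style sigmoid fitted on training decision values; the class call is
#' made at \code{threshold} (default 0.5).
#'
#' @param model a \linkS4class{ClassifierModel}.
#' @param x a \linkS4class{SplicedCounts} or gene-by-sample count matrix.
#' @param threshold score cutoff for the positive call.
#' @return data.frame with sample_id, score and call.
#' @export
predictSamples <- function(model, x, threshold = 0.5) {
  m <- if (methods::is(x, "SplicedCounts")) counts(x) else x
  m <- imputeUndetectedGenes(m, model)
  nm <- applyNormalization(model@normModel, m)
  feat <- t(nm$logcpm[model@panel@genes, , drop = FALSE])
  dv <- .svm_decision(model@svmFit, feat, model@positiveClass)
  score <- .platt_apply(model@calibration, dv)
  lv <- model@svmFit$levels
  negative <- setdiff(lv, model@positiveClass)
  data.frame(sample_id = colnames(m), score = score,
             call = ifelse(score >= threshold, model@positiveClass, negative),
             stringsAsFactors = FALSE)
}
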