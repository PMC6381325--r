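test_that("ANOVA ranking orders genes by LR and respects the threshold", {
  sim <- simulateCounts(n_genes = 300, n_samples = 40, frac_de = 0.05,
                        logfc = 1, n_stable = 0, batch = NULL,
                        age_effect = NULL, seed = 201)
  m <- counts(sim$data)
  g <- sampleAnnotation(sim$data)$group
  all_panel <- rankGenesANOVA(m, g, fdr_threshold = 1.0)
  expect_false(is.unsorted(rev(all_panel@scores)))
  res <- diffSplicing(m, g)
  expect_identical(all_panel@genes, res$gene_id[order(-res$LR)])
  sel <- rankGenesANOVA(m, g, fdr_threshold = 0.05)
  recall <- mean(sim$truth$de_genes %in% sel@genes)
  expect_gte(recall, 0.8)
  expect_error(rankGenesANOVA(m, g, fdr_threshold = 1e-300), "raise")
})

test_that("greedy correlation filter removes one of a duplicated pair", {
  set.seed(211)
  n <- 30
  A <- rnorm(n); C <- rnorm(n)
  lc <- rbind(A = A, B = A + rnorm(n, 0, 0.01), C = C)
  colnames(lc) <- paste0("s", 1:n)
  panel <- methods::new("GenePanel", genes = c("A", "B", "C"),
                        scores = c(3, 2, 1), provenance = list())
  out <- removeCorrelatedGenes(lc, panel, cutoff = 0.9)
  expect_true("C" %in% out@genes)
  expect_equal(sum(c("A", "B") %in% out@genes), 1)
  # cutoff 1 with no duplicates is the identity
  expect_identical(removeCorrelatedGenes(lc, panel, cutoff = 1)@genes,
                   panel@genes)
  # postcondition on random data
  lc2 <- matrix(rnorm(20 * 15), 20, 15,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:15)))
  p2 <- methods::new("GenePanel", genes = rownames(lc2),
                     scores = 20:1, provenance = list())
  out2 <- removeCorrelatedGenes(lc2, p2, cutoff = 0.6)
  cm <- abs(cor(t(lc2[out2@genes, ]))); diag(cm) <- 0
  expect_lte(max(cm), 0.6)
})

test_that("SVM-RFE retains informative genes and is path-consistent", {
  set.seed(221)
  n <- 60
  g <- factor(rep(c("a", "b"), each = n / 2))
  inf <- matrix(rnorm(5 * n, mean = rep(ifelse(g == "b", 2, 0), each = 5)),
                5, n)
  noise <- matrix(rnorm(50 * n), 50, n)
  lc <- rbind(inf, noise)
  rownames(lc) <- c(paste0("inf", 1:5), paste0("ns", 1:50))
  colnames(lc) <- paste0("s", 1:n)
  panel <- methods::new("GenePanel", genes = rownames(lc),
                        scores = rev(seq_len(55)), provenance = list())
  out <- svmRFE(lc, panel, g, target_size = 10)
  expect_length(out@genes, 10)
  expect_gte(sum(grepl("^inf", out@genes)), 4)
  # identity when target equals panel size
  same <- svmRFE(lc, panel, g, target_size = 55)
  expect_setequal(same@genes, panel@genes)
  # deterministic elimination path: 10-gene result nested in 20-gene result
  out20 <- svmRFE(lc, panel, g, target_size = 20)
  expect_true(all(out@genes %in% out20@genes))
})

test_that("grid search equals a brute-force scan and is deterministic", {
  set.seed(231)
  n <- 30
  g <- factor(rep(c("a", "b"), each = n / 2))
  lc <- matrix(rnorm(8 * n), 8, n,
               dimnames = list(paste0("g", 1:8), paste0("s", 1:n)))
  lc[1:2, g == "b"] <- lc[1:2, g == "b"] + 3
  ge <- seq(-8, 0, 2); ce <- seq(0, 8, 2)
  res <- gridSearchSVM(lc, g, gamma_exp = ge, cost_exp = ce, seed = 5)
  expect_gte(max(res$grid$cv_auc), res$cv_auc - 1e-12)
  # independent rescan with e1071 + rank AUC using the returned folds
  feat <- t(lc)
  rescan <- expand.grid(cost_exp = ce, gamma_exp = ge)
  rescan$auc <- mapply(function(cexp, gexp) {
    mean(sapply(1:2, function(f) {
      tr <- res$fold_id != f
      fit <- e1071::svm(feat[tr, ], g[tr], kernel = "radial",
                        cost = 2^cexp, gamma = 2^gexp, scale = FALSE)
      pr <- predict(fit, feat[!tr, ], decision.values = TRUE)
      d <- as.numeric(attr(pr, "decision.values")[, 1])
      first <- strsplit(colnames(attr(pr, "decision.values"))[1],
                        "/")[[1]][1]
      if (first != "b") d <- -d
      oracle_auc(d, as.character(g[!tr]), "b")
    }))
  }, rescan$cost_exp, rescan$gamma_exp)
  ord <- order(-rescan$auc, rescan$cost_exp, -rescan$gamma_exp)
  expect_equal(res$cost_exp, rescan$cost_exp[ord[1]])
  expect_equal(res$gamma_exp, rescan$gamma_exp[ord[1]])
  # linearly separable data reaches CV AUC 1 somewhere on the grid
  expect_equal(max(res$grid$cv_auc), 1)
  # seed contract
  res2 <- gridSearchSVM(lc, g, gamma_exp = ge, cost_exp = ce, seed = 5)
  expect_identical(res$grid, res2$grid)
})

test_that("PSO refinement never falls below the seeded grid optimum", {
  set.seed(241)
  n <- 24
  g <- factor(rep(c("a", "b"), each = n / 2))
  lc <- matrix(rnorm(6 * n), 6, n,
               dimnames = list(paste0("g", 1:6), paste0("s", 1:n)))
  grid <- gridSearchSVM(lc, g, gamma_exp = seq(-6, 0, 3),
                        cost_exp = seq(0, 6, 3), seed = 7)
  ref <- psoRefineSVM(lc, g, grid, n_particles = 4, n_iter = 4, seed = 7)
  expect_gte(ref$cv_auc, grid$cv_auc - 1e-12)
  expect_lte(abs(ref$gamma_exp - grid$gamma_exp), 2)
  expect_lte(abs(ref$cost_exp - grid$cost_exp), 2)
})

test_that("the swarm optimizer solves a shifted sphere", {
  target <- c(0.3, -1.2, 2.0, 0.7)
  fn <- function(x) sum((x - target)^2)
  res <- psoOptimize(fn, lower = rep(-5, 4), upper = rep(5, 4),
                     n_particles = 30, n_iter = 50, seed = 9)
  expect_lt(res$value, 1e-2)
  expect_true(all(diff(res$trace) <= 0))
  # 1 particle, 1 iteration evaluates twice (init + one move)
  calls <- 0
  res1 <- psoOptimize(function(x) { calls <<- calls + 1; sum(x^2) },
                      lower = -1, upper = 1, n_particles = 1, n_iter = 1,
                      seed = 2)
  expect_equal(calls, 2)
  expect_length(res1$trace, 2)
})

test_that("training is locked: validation content never enters the model", {
  sim <- separable_cohort(seed = 251)
  x <- sim$data
  ann <- sampleAnnotation(x)
  tr <- rownames(ann)[ann$cohort_role == "training"]
  va <- rownames(ann)[ann$cohort_role == "validation"]
  m1 <- fast_train(x, tr)
  # replace validation counts with a different cohort entirely
  x2 <- x
  alt <- simulateCounts(n_genes = 400, n_samples = length(va), seed = 999,
                        n_stable = 50)$data
  SummarizedExperiment::assay(x2, "counts")[, va] <- counts(alt)
  x2$lib_size <- colSums(counts(x2))
  m2 <- fast_train(x2, tr)
  f1 <- tempfile(); f2 <- tempfile()
  saveModel(m1, f1); saveModel(m2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("imputation replaces only counts within the trigger window", {
  sim <- separable_cohort(seed = 251)
  x <- sim$data
  ann <- sampleAnnotation(x)
  tr <- rownames(ann)[ann$cohort_role == "training"]
  model <- fast_train(x, tr)
  pg <- panelGenes(model)[1:3]
  m <- counts(x)[, 1:2]
  m[pg, 1] <- c(0, 1, 3)
  out2 <- imputeUndetectedGenes(m, model, trigger = 2)
  med <- model@imputationMedians
  expect_equal(out2[pg[1], 1], unname(med[pg[1]]))
  expect_equal(out2[pg[2], 1], unname(med[pg[2]]))
  expect_equal(out2[pg[3], 1], 3)                    # above trigger
  out0 <- imputeUndetectedGenes(m, model, trigger = 0)
  expect_equal(out0[pg[1], 1], unname(med[pg[1]]))   # zero imputed
  expect_equal(out0[pg[2], 1], 1)                    # untouched
  # absent panel gene treated as zero and imputed, with a warning
  m_missing <- m[setdiff(rownames(m), pg[1]), , drop = FALSE]
  expect_warning(out_m <- imputeUndetectedGenes(m_missing, model), "absent")
  expect_equal(out_m[pg[1], 1], unname(med[pg[1]]))
})

test_that("prediction is order-equivariant and separates the training toy", {
  sim <- separable_cohort(seed = 251)
  x <- sim$data
  ann <- sampleAnnotation(x)
  tr <- rownames(ann)[ann$cohort_role == "training"]
  va <- rownames(ann)[ann$cohort_role == "validation"]
  model <- fast_train(x, tr)
  # training samples score on the correct side of 0.5
  calls <- ifelse(model@trainingScores >= 0.5, "NSCLC", "nonCancer")
  expect_true(all(calls == ann[tr, "group"]))
  pred <- predictSamples(model, x[, va])
  perm <- rev(seq_along(va))
  pred_perm <- predictSamples(model, x[, va[perm]])
  expect_equal(pred_perm$score, pred$score[perm], tolerance = 1e-12)
  expect_identical(pred_perm$sample_id, pred$sample_id[perm])
  expect_true(all(pred$score >= 0 & pred$score <= 1))
})

test_that("outer swarm optimizes hyperparameters on the evaluation cohort", {
  sim <- separable_cohort(seed = 261)
  x <- sim$data
  ann <- sampleAnnotation(x)
  tr <- rownames(ann)[ann$cohort_role == "training"]
  ev <- rownames(ann)[ann$cohort_role == "evaluation"]
  bounds <- list(lower = c(libsize_threshold = 0.6, fdr_threshold = 0.005,
                           corr_cutoff = 0.7, rfe_size = 10),
                 upper = c(libsize_threshold = 0.9, fdr_threshold = 0.1,
                           corr_cutoff = 0.99, rfe_size = 30))
  res <- outerPSO(x, tr, ev, n_particles = 3, n_iter = 2, bounds = bounds,
                  seed = 5, gamma_exp = seq(-20, 0, 5),
                  cost_exp = seq(0, 20, 5), refine_particles = 3,
                  refine_iter = 2)
  expect_true(all(diff(res$trace) <= 0))
  expect_s4_class(res$model, "ClassifierModel")
  expect_true(res$theta[["rfe_size"]] >= 10 && res$theta[["rfe_size"]] <= 30)
  expect_error(outerPSO(x, tr, c(tr[1], ev), n_particles = 1, n_iter = 1),
               "disjoint")
})
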