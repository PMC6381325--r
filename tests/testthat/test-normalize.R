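test_that("TMM reference selection matches the q75 rule", {
  m <- rand_counts(50, 5, seed = 21)
  expect_equal(selectTMMReference(m, "s3"), "s3")
  ident <- matrix(rep(m[, 1], 4), ncol = 4,
                  dimnames = list(rownames(m), paste0("s", 1:4)))
  expect_equal(selectTMMReference(ident), "s1")  # tie-break: first
  # brute-force argmin |q75 - mean(q75)|
  q75 <- apply(m, 2, function(y) quantile(y / sum(y) * 1e6, 0.75))
  expect_equal(selectTMMReference(m),
               colnames(m)[which.min(abs(q75 - mean(q75)))])
  expect_error(selectTMMReference(m, character(0)), "empty")
})

test_that("TMM factors agree with an independent trimmed-mean oracle", {
  set.seed(31)
  for (case in 1:5) {
    m <- matrix(rpois(20 * 4, exp(runif(20 * 4, 1, 6))), 20, 4,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:4)))
    tf <- tmmFactors(m, m[, "s1"])
    raw_oracle <- vapply(1:4, function(j) oracle_tmm(m[, j], m[, "s1"]),
                         numeric(1))
    expected <- raw_oracle / exp(mean(log(raw_oracle)))
    expect_lt(max(abs(unname(tf$factors) - expected)), 1e-8)
  }
  # identical to reference -> factor 1 (before cohort rescaling)
  ident <- cbind(s1 = rpois(50, 100), s2 = NA)
  ident[, 2] <- ident[, 1]
  tf <- tmmFactors(ident, ident[, 1])
  expect_equal(unname(tf$factors), c(1, 1))
  # pure scaling is absorbed by the library size
  sc <- cbind(s1 = rpois(50, 100) + 1, s2 = NA)
  sc[, 2] <- sc[, 1] * 2
  tf2 <- tmmFactors(sc, sc[, 1])
  expect_equal(unname(tf2$factors), c(1, 1), tolerance = 1e-12)
  # geometric mean of training factors is 1
  m <- rand_counts(100, 6, seed = 32)
  tf3 <- tmmFactors(m, m[, 2], training = colnames(m)[1:4])
  expect_equal(exp(mean(log(tf3$factors[1:4]))), 1, tolerance = 1e-12)
})

test_that("logCPM follows its closed form and is monotone", {
  m <- matrix(c(0, 10), 2, 1, dimnames = list(c("a", "b"), "s"))
  lc <- logCPM(m, eff_lib = 1e6)
  expect_equal(lc["a", 1], log2(0.5 * 1e6 / (1e6 + 1)), tolerance = 1e-12)
  m2 <- m; m2["a", 1] <- 1
  expect_gt(logCPM(m2, 1e6)["a", 1], lc["a", 1])
})

test_that("stable-gene selection keeps libsize-tracking, age-independent genes", {
  set.seed(41)
  n <- 60
  lib_factor <- rlnorm(n, 0, 0.4)
  lib_size <- round(1e5 * lib_factor)
  age <- round(runif(n, 30, 80))
  prop <- round(500 * lib_factor)                 # tracks library size
  agey <- round(10 * age + rnorm(n, 0, 5))        # tracks age
  noise <- rpois(n, 50)
  m <- rbind(prop = prop, agey = agey, noise = noise)
  colnames(m) <- paste0("s", 1:n)
  sg <- stableGeneSelection(m, lib_size, age)
  expect_true("prop" %in% sg$genes)
  expect_false("agey" %in% sg$genes)
  expect_gt(sg$r_libsize["prop"], 0.9)
  expect_gt(abs(sg$r_age["agey"]), 0.9)
})

test_that("planted stable genes are recovered at thresholds (0.8, 0.2)", {
  sim <- simulateCounts(n_genes = 500, n_samples = 100, frac_de = 0.1,
                        n_stable = 50, seed = 4)
  m <- counts(sim$data)
  sg <- stableGeneSelection(m, libSize(sim$data),
                            sampleAnnotation(sim$data)$age)
  recall <- mean(sim$truth$stable_genes %in% sg$genes)
  expect_gte(recall, 0.9)
})

test_that("RUV factor estimation recovers a planted batch factor", {
  set.seed(51)
  n <- 80; p <- 60
  batch <- rnorm(n)
  base <- matrix(rpois(p * n, 100), p, n,
                 dimnames = list(paste0("g", 1:p), paste0("s", 1:n)))
  m <- round(exp(log(base + 1) + 0.5 * rep(batch, each = p)))
  est <- ruvEstimate(m, rownames(m), k = 2)
  expect_gt(abs(cor(est$W[, 1], batch)), 0.9)
  # singular values ordered
  expect_true(all(diff(est$d) <= 1e-9))
  # degenerate controls
  const <- matrix(5, 4, n, dimnames = list(paste0("c", 1:4), colnames(m)))
  expect_error(ruvEstimate(const, rownames(const), k = 2), "rank")
})

test_that("factor assignment protects group signal and matches confounders", {
  set.seed(61)
  n <- 60
  group <- rep(c("a", "b"), each = n / 2)
  lib <- rlnorm(n, 10, 0.5)
  # factor 1 = group indicator (protected), factor 2 = scaled libsize,
  # factor 3 = noise
  W <- cbind(as.numeric(group == "b") + rnorm(n, 0, 0.05),
             scale(log(lib))[, 1], rnorm(n))
  colnames(W) <- paste0("W", 1:3)
  asg <- assignFactors(W, group, list(libsize = lib))
  expect_false(1L %in% asg$removed)
  expect_true(2L %in% asg$removed)
  expect_identical(asg$matches[["W2"]], "libsize")
  expect_false(3L %in% asg$removed)
})

test_that("RUV correction removes a planted batch effect", {
  set.seed(71)
  n <- 80; p <- 200
  batch <- rnorm(n)
  mu <- exp(matrix(log(50), p, n) + 0.8 * rep(batch, each = p))
  m <- matrix(rpois(p * n, mu), p, n,
              dimnames = list(paste0("g", 1:p), paste0("s", 1:n)))
  pre_cor <- apply(log(m + 1), 1, cor, y = batch)
  expect_gt(mean(abs(pre_cor) > 0.6), 0.95)
  est <- ruvEstimate(m, rownames(m), k = 1)
  out <- ruvCorrect(m, est$W, removed = 1L)
  post_cor <- apply(log(out$corrected + 1), 1, cor, y = batch)
  expect_gte(mean(abs(post_cor) < 0.1), 0.95)
  expect_true(all(out$corrected >= 0))
  # no removed factors -> exact identity
  out0 <- ruvCorrect(m, est$W, removed = integer(0))
  expect_identical(out0$corrected, m)
})

test_that("iterative correction is locked on the training cohort", {
  sim <- simulateCounts(n_genes = 300, n_samples = 40, frac_de = 0.1,
                        n_stable = 40, seed = 81,
                        roles = c(training = 24, validation = 16))
  x <- sim$data
  ann <- sampleAnnotation(x)
  tr <- rownames(ann)[ann$cohort_role == "training"]
  ho <- setdiff(colnames(x), tr)
  fit <- iterativeCorrection(x, training = tr, k = 3)
  expect_s4_class(fit$model, "NormalizationModel")
  expect_true(methods::validObject(fit$model))
  # geometric mean of training TMM factors is 1
  expect_equal(exp(mean(log(fit$model@tmmFactors[tr]))), 1,
               tolerance = 1e-9)
  # held-out samples: shuffling their labels changes nothing (they are
  # never consulted); applying the model to held-out counts alone is
  # bit-identical to the joint fit
  app <- applyNormalization(fit$model, counts(x)[, ho])
  expect_identical(app$logcpm, fit$logcpm[, ho])
  # k = 0 degenerates to plain TMM-logCPM
  fit0 <- iterativeCorrection(x, training = tr, k = 0)
  ref <- selectTMMReference(counts(x), tr)
  tf <- tmmFactors(counts(x), counts(x)[, ref], training = tr)
  expect_equal(fit0$logcpm,
               logCPM(counts(x), colSums(counts(x)) * tf$factors))
})

test_that("RLE statistics detect removal of per-sample offsets", {
  set.seed(91)
  p <- 200; n <- 100
  base <- matrix(rnorm(p * n, 5), p, n)
  offs <- rnorm(n, 0, 1.5)
  before <- base + rep(offs, each = p)
  rs_same <- rleStats(before, before)
  expect_equal(rs_same$p_value, 1)
  expect_true(all(rs_same$stat_before == rs_same$stat_after))
  rs <- rleStats(before, base)
  expect_lt(rs$p_value, 0.01)
  expect_lt(mean(rs$stat_after), mean(rs$stat_before))
  # RLE rows are centered on their across-sample median
  rle <- before - apply(before, 1, median)
  expect_lt(max(abs(apply(rle, 1, median))), 1e-12)
})
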