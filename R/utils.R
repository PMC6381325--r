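# Internal helpers shared across modules.

.geomean <- function(x) exp(mean(log(x)))

# counts-per-million on raw counts; columns scaled to 1e6
.cpm <- function(counts, lib = colSums(counts)) {
  sweep(counts, 2L, pmax(lib, 1), "/") * 1e6
}

.rowMedians <- function(m) apply(m, 1L, stats::median, na.rm = TRUE)

# Coerce a grouping vector to a 2-level factor; the positive (case) class is
# the second level. If `positive` is given it is forced to be last.
# Character input gets levels in order of first appearance (never locale
# collation), so the implied positive class is reproducible everywhere.
.as_group <- function(group, positive = NULL) {
  f <- if (is.factor(group)) droplevels(group)
       else factor(group, levels = unique(as.character(group)))
  if (nlevels(f) != 2L)
    stop("group must have exactly 2 levels, got ", nlevels(f))
  if (!is.null(positive)) {
    if (!positive %in% levels(f))
      stop("positive class '", positive, "' not among group levels")
    f <- stats::relevel(f, ref = setdiff(levels(f), positive))
  }
  f
}

# SVM decision values oriented so that larger means "more positive class".
.svm_decision <- function(fit, newx, positive) {
  pr <- stats::predict(fit, newx, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # e1071 names the single column "A/B": decision value is positive for A
  lab <- colnames(dv)[1L]
  first <- strsplit(lab, "/", fixed = TRUE)[[1L]][1L]
  d <- as.numeric(dv[, 1L])
  if (identical(first, positive)) d else -d
}

# Platt sigmoid calibration: fit P(positive | d) = 1 / (1 + exp(A d + B))
# on decision values, with Platt's smoothed targets so perfect separation
# stays well-behaved. Returns c(A, B).
.platt_fit <- function(d, ispos) {
  np <- sum(ispos); nn <- sum(!ispos)
  t <- ifelse(ispos, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(par) {
    p <- 1 / (1 + exp(par[1L] * d + par[2L]))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(t * log(p) + (1 - t) * log(1 - p))
  }
  init <- c(-1, log((nn + 1) / (np + 1)))
  fit <- stats::optim(init, nll, method = "BFGS")
  c(A = fit$par[1L], B = fit$par[2L])
}

.platt_apply <- function(calib, d) 1 / (1 + exp(calib[1L] * d + calib[2L]))

# Stratified fold assignment; returns integer fold ids per sample.
.stratified_folds <- function(labels, nfolds, seed) {
  set.seed(seed)
  folds <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    folds[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  folds
}

.stopifnot_matrix <- function(m, what = "counts") {
  if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, " must be a matrix with gene and sample names")
  invisible(m)
}
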