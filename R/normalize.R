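#' Select and lock the TMM reference sample
#'
#' Among the candidate samples (in practice the training cohort), the sample
#' whose 75th-percentile counts-per-million value lies closest to the mean of
#' the candidates' 75th percentiles is chosen and locked; ties break to the
#' first candidate in sample order.
#'
#' @param counts gene-by-sample matrix (raw or RUV-corrected counts).
#' @param candidates sample ids eligible as reference; default all.
#' @return the reference sample id.
#' @export
selectTMMReference <- function(counts, candidates = colnames(counts)) {
  if (length(candidates) == 0L) stop("empty candidate set")
  if (!all(candidates %in% colnames(counts)))
    stop("unknown candidate sample(s)")
  sub <- counts[, candidates, drop = FALSE]
  q75 <- apply(sub, 2L, function(y) stats::quantile(y / max(sum(y), 1) * 1e6,
                                                    0.75, names = FALSE))
  candidates[which.min(abs(q75 - mean(q75)))]
}

# Raw (un-rescaled) pairwise TMM factor of column y against the reference,
# computed with edgeR's trimmed weighted mean of M-values (trim 30% by M, 5%
# by A, inverse-asymptotic-variance weights).
.tmm_raw <- function(y, ref) {
  if (sum(y) <= 0 || sum(ref) <= 0) {
    warning("zero library; TMM factor set to 1")
    return(1)
  }
  f <- suppressWarnings(edgeR::calcNormFactors(cbind(ref, y), refColumn = 1L))
  raw <- f[2L] / f[1L]
  if (!is.finite(raw) || raw <= 0) {
    warning("no genes survive TMM trimming; factor set to 1")
    return(1)
  }
  unname(raw)
}

#' TMM factors against a locked reference
#'
#' Computes each sample's trimmed-mean-of-M-values factor against the locked
#' reference column (pairwise), then rescales all factors by the geometric
#' mean over the training samples so that training factors multiply to one.
#' The rescaling constant is locked with the model, so held-out samples never
#' influence training factors.
#'
#' @param counts gene-by-sample matrix.
#' @param ref_counts reference sample count vector (same gene order).
#' @param training sample ids defining the geometric-mean rescaling.
#' @return list with \code{factors} (named) and \code{scale} (the locked
#'   geometric-mean divisor).
#' @export
tmmFactors <- function(counts, ref_counts, training = colnames(counts)) {
  raw <- vapply(seq_len(ncol(counts)),
                function(j) .tmm_raw(counts[, j], ref_counts), numeric(1))
  names(raw) <- colnames(counts)
  sc <- .geomean(raw[training])
  list(factors = raw / sc, scale = sc)
}

#' log2 counts-per-million with effective library sizes
#'
#' \code{logCPM[g,s] = log2(1e6 * (counts[g,s] + 0.5) / (eff_lib[s] + 1))},
#' where the effective library size is the corrected library size times the
#' sample's TMM factor. Monotone in counts.
#'
#' @param counts gene-by-sample matrix (raw or corrected).
#' @param eff_lib per-sample effective library sizes.
#' @return numeric matrix of the same shape.
#' @export
logCPM <- function(counts, eff_lib = colSums(counts)) {
  t(log2(1e6 * t(counts + 0.5) / (eff_lib + 1)))
}

#' Select stable (negative control) genes
#'
#' Stable genes are genes whose raw counts track the intron-spanning library
#' size (Pearson r towards 1: such genes show the least variability after
#' counts-per-million normalization) while being independent of the age of
#' the individuals (|r| at most \code{age_threshold}). Samples with missing
#' age are skipped in the age correlation only. Zero-variance genes are
#' excluded with a warning.
#'
#' @param counts gene-by-sample raw count matrix (training cohort).
#' @param lib_size per-sample library sizes.
#' @param age per-sample ages in years; NA allowed.
#' @param libsize_threshold minimum r against library size (default 0.8).
#' @param age_threshold maximum |r| against age (default 0.2).
#' @return list with \code{genes}, \code{r_libsize} and \code{r_age}.
#' @export
stableGeneSelection <- function(counts, lib_size, age = NULL,
                                libsize_threshold = 0.8, age_threshold = 0.2) {
  stopifnot(libsize_threshold > 0, libsize_threshold < 1)
  sds <- apply(counts, 1L, stats::sd)
  if (any(sds == 0))
    warning(sum(sds == 0), " zero-variance gene(s) excluded from stable set")
  r_lib <- suppressWarnings(as.numeric(stats::cor(t(counts), lib_size)))
  names(r_lib) <- rownames(counts)
  r_age <- rep(NA_real_, nrow(counts))
  names(r_age) <- rownames(counts)
  ok_age <- rep(TRUE, nrow(counts))
  if (!is.null(age) && sum(!is.na(age)) >= 3) {
    keep <- !is.na(age)
    r_age <- suppressWarnings(
      as.numeric(stats::cor(t(counts[, keep, drop = FALSE]), age[keep])))
    names(r_age) <- rownames(counts)
    ok_age <- !is.na(r_age) & abs(r_age) <= age_threshold
  }
  ok <- sds > 0 & !is.na(r_lib) & r_lib >= libsize_threshold & ok_age
  list(genes = rownames(counts)[ok], r_libsize = r_lib, r_age = r_age)
}

#' Estimate latent factors of unwanted variation (RUV)
#'
#' Singular value decomposition of the per-gene centered log(counts + 1)
#' matrix restricted to the control (stable) genes; the first k left-singular
#' directions are the sample scores W, ordered by singular value. The right
#' singular vectors, singular values and per-gene centers are retained so
#' that any new sample can be projected onto the same factors.
#'
#' @param counts gene-by-sample raw count matrix.
#' @param controls control gene ids (at least k of them).
#' @param k number of factors (>= 1).
#' @return list with \code{W} (samples x k), \code{V}, \code{d},
#'   \code{center} and \code{controls}.
#' @export
ruvEstimate <- function(counts, controls, k) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  if (length(controls) < k)
    stop("need at least k = ", k, " control genes, got ", length(controls))
  if (!all(controls %in% rownames(counts)))
    stop("control genes missing from count matrix")
  lc <- log(counts[controls, , drop = FALSE] + 1)   # controls x samples
  center <- rowMeans(lc)
  M <- t(lc - center)                                # samples x controls
  sv <- svd(M)
  if (length(sv$d) < k || sv$d[k] < 1e-10)
    stop("k = ", k, " exceeds the rank of the control matrix")
  W <- sv$u[, seq_len(k), drop = FALSE]
  rownames(W) <- colnames(counts)
  colnames(W) <- paste0("W", seq_len(k))
  list(W = W, V = sv$v[, seq_len(k), drop = FALSE], d = sv$d[seq_len(k)],
       center = center, controls = controls)
}

# Project new samples onto previously estimated factor directions.
# Returns samples x k scores on the same scale as the training W (= U).
.ruv_project <- function(counts, V, d, center, controls) {
  lc <- log(counts[controls, , drop = FALSE] + 1)
  W <- crossprod(lc - center, V) %*% diag(1 / d, length(d))
  rownames(W) <- colnames(counts)
  colnames(W) <- paste0("W", seq_along(d))
  W
}

#' Match latent factors to confounders or protected signal
#'
#' A factor is flagged for removal only when (a) it is not associated with
#' the group of interest (two-sided independent t-test p > \code{p_group},
#' protecting biological signal) and (b) it is associated with at least one
#' continuous confounder (Pearson correlation test p < \code{p_conf}). The
#' matched confounder(s) are recorded per factor.
#'
#' @param W samples x k factor score matrix.
#' @param group 2-level factor/vector over the same samples.
#' @param confounders named list of per-sample numeric vectors (e.g. library
#'   size, age); missing values handled pairwise-complete with a warning.
#' @param p_group signal-protection floor (default 1e-5).
#' @param p_conf confounder-match ceiling (default 0.01).
#' @return list with \code{removed} (integer factor indices), \code{matches}
#'   (list of matched confounder names per factor), \code{p_group} and
#'   \code{p_conf} (k x confounder matrix).
#' @export
assignFactors <- function(W, group, confounders, p_group = 1e-5,
                          p_conf = 0.01) {
  g <- .as_group(group)
  k <- ncol(W)
  pg <- vapply(seq_len(k), function(j)
    stats::t.test(W[g == levels(g)[1L], j],
                  W[g == levels(g)[2L], j])$p.value, numeric(1))
  pc <- matrix(NA_real_, k, length(confounders),
               dimnames = list(colnames(W), names(confounders)))
  for (cn in names(confounders)) {
    v <- confounders[[cn]]
    if (any(is.na(v)))
      warning("missing values in confounder '", cn,
              "'; using pairwise-complete observations")
    for (j in seq_len(k)) {
      ok <- !is.na(v)
      if (sum(ok) >= 3 && stats::sd(v[ok]) > 0 && stats::sd(W[ok, j]) > 0)
        pc[j, cn] <- stats::cor.test(W[ok, j], v[ok])$p.value
    }
  }
  removed <- integer(0)
  matches <- vector("list", k)
  names(matches) <- colnames(W)
  for (j in seq_len(k)) {
    hit <- colnames(pc)[which(pc[j, ] < p_conf)]
    matches[[j]] <- hit
    if (pg[j] > p_group && length(hit)) removed <- c(removed, j)
  }
  list(removed = as.integer(removed), matches = matches,
       p_group = pg, p_conf = pc)
}

#' Remove flagged factors from the counts
#'
#' Per gene, log(counts + 1) is regressed on the removed factor scores and
#' the fitted unwanted component subtracted; values are back-transformed
#' (exp - 1) and clipped at zero. With no removed factors the input is
#' returned unchanged. The corrected library size is the per-sample sum of
#' corrected values.
#'
#' @param counts gene-by-sample matrix.
#' @param W samples x k factor scores.
#' @param removed integer indices of factors to remove (subset of 1..k).
#' @param gene_beta optional pre-estimated gene x removed coefficient matrix
#'   (from a training fit); when supplied no regression is performed, so
#'   held-out samples are corrected with training-locked coefficients.
#' @return list with \code{corrected}, \code{corrected_lib_size} and
#'   \code{gene_beta}.
#' @export
ruvCorrect <- function(counts, W, removed, gene_beta = NULL) {
  if (length(removed) == 0L) {
    return(list(corrected = counts, corrected_lib_size = colSums(counts),
                gene_beta = matrix(0, nrow(counts), 0,
                                   dimnames = list(rownames(counts), NULL))))
  }
  Wr <- W[, removed, drop = FALSE]
  ly <- log(counts + 1)
  if (is.null(gene_beta)) {
    X <- cbind(1, Wr)
    fit <- stats::lm.fit(X, t(ly))
    gene_beta <- t(fit$coefficients[-1L, , drop = FALSE])  # genes x removed
    rownames(gene_beta) <- rownames(counts)
  }
  adj <- ly - gene_beta %*% t(Wr)
  corrected <- pmax(exp(adj) - 1, 0)
  list(corrected = corrected, corrected_lib_size = colSums(corrected),
       gene_beta = gene_beta)
}

#' Iterative confounder-aware correction module
#'
#' Composes the full normalization chain with every choice locked on the
#' training cohort: stable-gene selection (training counts, library sizes and
#' ages) -> latent-factor estimation on the controls -> factor-to-confounder
#' assignment (training group labels, library size and age) -> per-gene
#' correction coefficients -> locked TMM reference selection among training
#' candidates -> TMM factors -> logCPM. Non-training samples are scored by
#' projection onto the training factor directions, so the module is agnostic
#' to their group labels. With \code{k = 0} the module degenerates to plain
#' TMM-logCPM.
#'
#' @param x a \linkS4class{SplicedCounts} object.
#' @param training training-cohort sample ids (subset of samples of x).
#' @param libsize_threshold stable-gene library-size correlation threshold
#'   (default 0.8).
#' @param age_threshold stable-gene age correlation threshold (default 0.2).
#' @param k number of latent factors (default 3).
#' @return list with \code{model} (a \linkS4class{NormalizationModel}),
#'   \code{logcpm}, \code{corrected} and \code{corrected_lib_size} for all
#'   samples of \code{x}.
#' @export
iterativeCorrection <- function(x, training = colnames(x),
                                libsize_threshold = 0.8, age_threshold = 0.2,
                                k = 3) {
  k <- as.integer(k)
  m <- counts(x)
  if (!all(training %in% colnames(m))) stop("training ids not in cohort")
  ann <- sampleAnnotation(x)
  tr_idx <- match(training, colnames(m))
  m_tr <- m[, tr_idx, drop = FALSE]
  lib_tr <- libSize(x)[tr_idx]
  age_tr <- if ("age" %in% colnames(ann)) ann$age[tr_idx] else NULL

  stable <- character(0); W <- matrix(0, ncol(m), 0)
  removed <- integer(0); matches <- list()
  V <- matrix(0, 0, 0); d <- numeric(0); center <- numeric(0)
  gene_beta <- matrix(0, nrow(m), 0, dimnames = list(rownames(m), NULL))
  corrected <- m; corrected_lib <- colSums(m)

  if (k > 0L) {
    sg <- stableGeneSelection(m_tr, lib_tr, age_tr,
                              libsize_threshold, age_threshold)
    stable <- sg$genes
    if (length(stable) < k)
      stop("only ", length(stable), " stable genes at threshold ",
           libsize_threshold, "; need at least k = ", k)
    est <- ruvEstimate(m_tr, stable, k)
    V <- est$V; d <- est$d; center <- est$center
    group_tr <- if ("group" %in% colnames(ann)) ann$group[tr_idx] else NULL
    conf <- list(libsize = as.numeric(lib_tr))
    if (!is.null(age_tr)) conf$age <- as.numeric(age_tr)
    if (is.null(group_tr)) stop("training samples need group labels")
    asg <- assignFactors(est$W, group_tr, conf)
    removed <- asg$removed; matches <- asg$matches
    # training-locked per-gene coefficients
    cor_tr <- ruvCorrect(m_tr, est$W, removed)
    gene_beta <- cor_tr$gene_beta
    # score all samples by projection (training rows reproduce est$W)
    W <- .ruv_project(m, V, d, center, stable)
    cor_all <- ruvCorrect(m, W, removed, gene_beta = gene_beta)
    corrected <- cor_all$corrected
    corrected_lib <- cor_all$corrected_lib_size
  }

  ref <- selectTMMReference(corrected, candidates = training)
  tf <- tmmFactors(corrected, corrected[, ref], training = training)
  eff <- corrected_lib * tf$factors
  lc <- logCPM(corrected, eff)

  model <- methods::new("NormalizationModel",
    genes = rownames(m), refSample = ref, refCounts = corrected[, ref],
    tmmFactors = tf$factors, tmmScale = tf$scale,
    stableGenes = stable, k = k, W = W,
    svdV = V, svdD = d, controlCenter = center,
    removedFactors = removed, factorMatches = matches,
    geneBeta = gene_beta, correctedLibSize = corrected_lib,
    thresholds = list(libsize_corr_threshold = libsize_threshold,
                      age_corr_threshold = age_threshold,
                      p_group_floor = 1e-5, p_confounder_ceiling = 0.01),
    trainingSamples = training)
  list(model = model, logcpm = lc, corrected = corrected,
       corrected_lib_size = corrected_lib)
}

#' Apply a locked normalization model to new samples
#'
#' Uses only training-derived parameters: factor directions (projection),
#' per-gene correction coefficients, locked TMM reference and geometric-mean
#' rescaling constant. Shuffling the labels of the new samples cannot change
#' the result.
#'
#' @param model a \linkS4class{NormalizationModel}.
#' @param counts gene-by-sample matrix over the model's gene universe.
#' @return list with \code{logcpm}, \code{corrected},
#'   \code{corrected_lib_size}, \code{tmm_factors} and \code{W}.
#' @export
applyNormalization <- function(model, counts) {
  .stopifnot_matrix(counts)
  if (!identical(rownames(counts), model@genes))
    stop("count matrix does not match the model's gene universe")
  if (model@k > 0L) {
    W <- .ruv_project(counts, model@svdV, model@svdD, model@controlCenter,
                      model@stableGenes)
    cr <- ruvCorrect(counts, W, model@removedFactors,
                     gene_beta = model@geneBeta)
  } else {
    W <- matrix(0, ncol(counts), 0)
    cr <- list(corrected = counts, corrected_lib_size = colSums(counts))
  }
  raw <- vapply(seq_len(ncol(counts)),
                function(j) .tmm_raw(cr$corrected[, j], model@refCounts),
                numeric(1))
  tf <- raw / model@tmmScale
  names(tf) <- colnames(counts)
  eff <- cr$corrected_lib_size * tf
  list(logcpm = logCPM(cr$corrected, eff), corrected = cr$corrected,
       corrected_lib_size = cr$corrected_lib_size, tmm_factors = tf, W = W)
}

#' Relative log expression diagnostics
#'
#' RLE is each gene's logCPM deviation from its across-sample median; the
#' per-sample statistic is the absolute difference of the sample's median RLE
#' from the overall median. Reduction of inter-sample variability by the
#' correction is assessed by a two-sided paired t-test of the statistic
#' before vs after.
#'
#' @param before,after logCPM matrices of identical shape.
#' @return list with \code{stat_before}, \code{stat_after} (per sample) and
#'   \code{p_value}.
#' @export
rleStats <- function(before, after) {
  stopifnot(identical(dim(before), dim(after)))
  stat <- function(lc) {
    rle <- lc - .rowMedians(lc)
    med <- apply(rle, 2L, stats::median)
    abs(med - stats::median(med))
  }
  sb <- stat(before); sa <- stat(after)
  p <- if (isTRUE(all.equal(sb, sa))) 1
       else stats::t.test(sb, sa, paired = TRUE)$p.value
  list(stat_before = sb, stat_after = sa, p_value = p)
}
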