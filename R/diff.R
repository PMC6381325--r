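#' Estimate negative-binomial dispersions
#'
#' Common, trended and tagwise dispersion estimates for a count matrix under
#' a design, via adjusted profile likelihood with empirical-Bayes shrinkage
#' of per-gene estimates toward the abundance trend (fixed prior weight,
#' default 10 prior degrees of freedom). Offsets are log effective library
#' sizes from the normalization module; all-zero genes are excluded from
#' estimation.
#'
#' @param counts gene-by-sample matrix of (raw or corrected) counts.
#' @param design model matrix (full rank).
#' @param offset optional per-sample log effective library sizes; default
#'   log of TMM-scaled column totals.
#' @param prior_df prior degrees of freedom for tagwise shrinkage.
#' @return list with \code{common}, \code{trended}, \code{tagwise},
#'   \code{ave_logcpm} and the fitted \code{dge} object.
#' @export
estimateDispersions <- function(counts, design, offset = NULL,
                                prior_df = 10) {
  keep <- rowSums(counts) > 0
  if (!all(keep)) counts <- counts[keep, , drop = FALSE]
  y <- edgeR::DGEList(counts = counts)
  if (is.null(offset)) {
    y <- edgeR::calcNormFactors(y)
  } else {
    y$offset <- matrix(offset, nrow(counts), ncol(counts), byrow = TRUE)
  }
  y <- edgeR::estimateDisp(y, design, prior.df = prior_df)
  list(common = y$common.dispersion, trended = y$trended.dispersion,
       tagwise = y$tagwise.dispersion, ave_logcpm = y$AveLogCPM, dge = y)
}

#' Negative-binomial GLM likelihood-ratio test
#'
#' Per gene, a negative-binomial GLM (log link, offsets) is fitted under the
#' full and the reduced design (differing only in the 2-level group column);
#' the likelihood-ratio statistic is referred to chi-squared with 1 degree of
#' freedom. Benjamini-Hochberg FDR is computed across the tested genes.
#'
#' @param disp result of \code{\link{estimateDispersions}} (fitted on the
#'   full design).
#' @param design the full model matrix.
#' @param coef column of \code{design} to drop for the reduced model
#'   (default: last column, the group coefficient).
#' @return data.frame with gene_id, logFC (log2, group2 vs group1), logCPM,
#'   LR, PValue and FDR, in input gene order.
#' @export
glmLRT <- function(disp, design, coef = ncol(design)) {
  fit <- edgeR::glmFit(disp$dge, design,
                       dispersion = disp$tagwise)
  lrt <- edgeR::glmLRT(fit, coef = coef)
  tab <- lrt$table
  data.frame(gene_id = rownames(tab), logFC = tab$logFC, logCPM = tab$logCPM,
             LR = tab$LR, PValue = tab$PValue,
             FDR = bhAdjust(tab$PValue), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Differential splicing analysis between two groups
#'
#' Convenience wrapper running dispersion estimation and the NB GLM
#' likelihood-ratio test for a two-group comparison (design: intercept +
#' group). For signal exploration use the RUV-corrected counts
#' (\code{use_corrected = TRUE} with a fitted normalization result); for
#' classifier training the non-corrected raw read counts are used.
#'
#' @param x a \linkS4class{SplicedCounts} object or count matrix.
#' @param group 2-level group labels per sample.
#' @param norm optional result of \code{\link{iterativeCorrection}}.
#' @param use_corrected use RUV-corrected counts and effective library sizes
#'   from \code{norm}.
#' @param prior_df tagwise shrinkage prior degrees of freedom.
#' @return a DiffResult data.frame (see \code{\link{glmLRT}}).
#' @export
diffSplicing <- function(x, group, norm = NULL, use_corrected = FALSE,
                         prior_df = 10) {
  m <- if (methods::is(x, "SplicedCounts")) counts(x) else x
  g <- .as_group(group)
  design <- stats::model.matrix(~g)
  offset <- NULL
  if (use_corrected) {
    if (is.null(norm)) stop("use_corrected = TRUE needs a normalization result")
    m <- round(norm$corrected)
    offset <- log(norm$corrected_lib_size *
                    norm$model@tmmFactors[colnames(m)])
  }
  disp <- estimateDispersions(m, design, offset = offset, prior_df = prior_df)
  glmLRT(disp, design)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values: \code{adj_(i) = min_(j>=i) min(1, p_(j)*n/j)}
#' in sorted order, mapped back to the input order.
#'
#' @param p vector of p values in [0, 1].
#' @return adjusted p values (FDR), same order.
#' @export
bhAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Post-hoc filtering of differential results
#'
#' Keeps genes at or above the logCPM abundance floor and strictly below the
#' FDR cutoff, and reports up/down counts by sign of logFC.
#'
#' @param res DiffResult data.frame.
#' @param min_logcpm abundance floor (default 3, genes below removed).
#' @param max_fdr FDR cutoff (default 0.01, strict <).
#' @return list with \code{table} (filtered), \code{n_up}, \code{n_down}.
#' @export
filterResults <- function(res, min_logcpm = 3, max_fdr = 0.01) {
  keep <- !is.na(res$FDR) & res$logCPM >= min_logcpm & res$FDR < max_fdr
  tab <- res[keep, , drop = FALSE]
  list(table = tab, n_up = sum(tab$logFC > 0), n_down = sum(tab$logFC < 0))
}

#' Unsupervised clustering with a partition test
#'
#' Hierarchical clustering of samples on 1 - Pearson correlation distances
#' with Ward linkage; the dendrogram is cut into \code{n_clusters} and
#' non-random partitioning by group is assessed with a two-sided Fisher's
#' exact test on the cluster-by-group contingency table.
#'
#' @param logcpm gene-by-sample matrix (selected genes).
#' @param group 2-level group labels.
#' @param n_clusters number of clusters to cut (default 2).
#' @return list with \code{hclust}, \code{clusters}, \code{table} and
#'   \code{p_value}.
#' @export
clusterAndPartitionTest <- function(logcpm, group, n_clusters = 2) {
  g <- .as_group(group)
  if (min(table(g)) < 2) stop("need >= 2 samples per group")
  d <- stats::as.dist(1 - stats::cor(logcpm))
  h <- stats::hclust(d, method = "ward.D2")
  cl <- stats::cutree(h, k = n_clusters)
  tab <- table(cluster = cl, group = g)
  if (any(rowSums(tab) == 0)) {
    warning("degenerate clustering (empty cluster); p set to 1")
    p <- 1
  } else {
    p <- stats::fisher.test(tab)$p.value
  }
  list(hclust = h, clusters = cl, table = tab, p_value = p)
}
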