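#' Filter low-coverage RNA isoforms
#'
#' An isoform is excluded when it has fewer than \code{min_reads} assigned
#' reads in more than \code{frac} of the cohort (defaults: <10 reads in >90%
#' of samples), mirroring the gene-level abundance rule.
#'
#' @param counts isoform-by-sample assigned-read count matrix.
#' @param min_reads,frac rule parameters.
#' @return the filtered matrix.
#' @export
filterIsoforms <- function(counts, min_reads = 10, frac = 0.9) {
  stopifnot(frac > 0, frac < 1)
  keep <- rowSums(counts < min_reads) <= frac * ncol(counts)
  counts[keep, , drop = FALSE]
}

#' Differential isoform analysis
#'
#' TMM + counts-per-million normalized negative-binomial GLM
#' likelihood-ratio test per isoform, selecting the most significant hits
#' (FDR < 0.01, logCPM > 1 by default).
#'
#' @param counts isoform-by-sample assigned-read counts (post filter).
#' @param group 2-level labels.
#' @param max_fdr,min_logcpm selection thresholds (strict < and > resp.).
#' @param prior_df dispersion shrinkage prior.
#' @return list with \code{table} (all tested), \code{selected},
#'   \code{n_up}, \code{n_down}.
#' @export
diffIsoforms <- function(counts, group, max_fdr = 0.01, min_logcpm = 1,
                         prior_df = 10) {
  res <- diffSplicing(counts, group, prior_df = prior_df)
  sel <- res[!is.na(res$FDR) & res$FDR < max_fdr & res$logCPM > min_logcpm, ,
             drop = FALSE]
  list(table = res, selected = sel,
       n_up = sum(sel$logFC > 0), n_down = sum(sel$logFC < 0))
}

#' Classify per-locus isoform concordance
#'
#' For each parent gene with selected isoforms, the per-group median
#' expression difference of every isoform is reduced to its sign: genes
#' whose isoforms all move the same way are concordant (up or down), genes
#' with isoforms moving in opposite directions are alternatively spliced.
#' A zero median difference is treated as concordant with either sign;
#' single-isoform genes are labeled by their sign.
#'
#' @param counts isoform-by-sample expression (normalized or raw).
#' @param isoforms character vector of selected isoform ids (rows of
#'   \code{counts}).
#' @param parent_gene named vector mapping isoform id to parent gene id.
#' @param group 2-level labels (difference is group2 - group1).
#' @return data.frame gene_id, n_isoforms, label in
#'   \{concordant_up, concordant_down, alternative\}.
#' @export
classifyLocusPatterns <- function(counts, isoforms, parent_gene, group) {
  g <- .as_group(group)
  stopifnot(all(isoforms %in% rownames(counts)),
            all(isoforms %in% names(parent_gene)))
  med_diff <- apply(counts[isoforms, , drop = FALSE], 1L, function(v)
    stats::median(v[g == levels(g)[2L]]) -
      stats::median(v[g == levels(g)[1L]]))
  genes <- split(med_diff, parent_gene[isoforms])
  lab <- vapply(genes, function(d) {
    s <- sign(d)
    if (any(s > 0) && any(s < 0)) "alternative"
    else if (any(s < 0)) "concordant_down"
    else "concordant_up"
  }, character(1))
  data.frame(gene_id = names(genes),
             n_isoforms = lengths(genes), label = unname(lab),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Coverage gate for exon-skipping events
#'
#' Keeps events for which, in more than \code{frac} of the samples (strict
#' >), the assigned reads exceed \code{min_reads} (strict >) and both
#' inclusion-supporting and exclusion-supporting reads are nonzero.
#' Defaults: >10 reads in >60\% of samples.
#'
#' @param inc,exc event-by-sample inclusion and exclusion assigned-read
#'   matrices (same shape).
#' @param min_reads,frac rule parameters.
#' @return logical vector of retained events (named by event).
#' @export
exonCoverageFilter <- function(inc, exc, min_reads = 10, frac = 0.6) {
  stopifnot(identical(dim(inc), dim(exc)))
  ok <- (inc + exc > min_reads) & inc > 0 & exc > 0
  keep <- rowSums(ok) > frac * ncol(inc)
  names(keep) <- rownames(inc)
  keep
}

#' Differential exon skipping on PSI values
#'
#' Per event, a two-sided Welch t-test of PSI between groups with
#' Benjamini-Hochberg correction; delta-PSI is the group2 median minus the
#' group1 median. Missing PSI values are excluded pairwise; events with too
#' few observations are skipped with a warning.
#'
#' @param psi event-by-sample PSI matrix in [0, 1] (NA allowed).
#' @param group 2-level labels.
#' @param max_fdr significance threshold for the up/down report.
#' @param pooled use the pooled-variance t-test instead of Welch.
#' @return list with \code{table} (event_id, t, p, FDR, delta_psi),
#'   \code{n_up}, \code{n_down} among FDR < \code{max_fdr}.
#' @export
exonSkippingTest <- function(psi, group, max_fdr = 0.01, pooled = FALSE) {
  g <- .as_group(group)
  g1 <- g == levels(g)[1L]; g2 <- g == levels(g)[2L]
  rows <- lapply(seq_len(nrow(psi)), function(i) {
    a <- psi[i, g1]; b <- psi[i, g2]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      warning("event ", rownames(psi)[i], " has <2 observations per group; ",
              "skipped")
      return(NULL)
    }
    tt <- tryCatch(stats::t.test(b, a, var.equal = pooled),
                   error = function(e) NULL)
    if (is.null(tt)) return(NULL)
    data.frame(event_id = rownames(psi)[i], t = unname(tt$statistic),
               p = tt$p.value,
               delta_psi = stats::median(b) - stats::median(a),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab))
    return(list(table = data.frame(), n_up = 0L, n_down = 0L))
  tab$FDR <- bhAdjust(tab$p)
  sig <- tab[tab$FDR < max_fdr, , drop = FALSE]
  list(table = tab[, c("event_id", "t", "p", "FDR", "delta_psi")],
       n_up = sum(sig$delta_psi > 0), n_down = sum(sig$delta_psi < 0))
}

#' Correlation signature around a target gene
#'
#' Pearson correlation of every gene's logCPM profile with the target
#' gene's (e.g. P-selectin/SELP); the signature is the set of positively
#' (r > 0) and significantly (FDR < 0.01) correlated genes. When an
#' up-regulated differential gene set is supplied, the overlap counts are
#' reported Venn-style.
#'
#' @param logcpm gene-by-sample matrix.
#' @param target target gene id (must have nonzero variance).
#' @param up_set optional character vector of up-regulated genes.
#' @param max_fdr signature FDR cutoff.
#' @return list with \code{table} (gene_id, r, p, FDR), \code{signature},
#'   and (if \code{up_set} given) \code{overlap} counts.
#' @export
targetGeneSignature <- function(logcpm, target, up_set = NULL,
                                max_fdr = 0.01) {
  if (!target %in% rownames(logcpm)) stop("target gene not in matrix")
  y <- logcpm[target, ]
  if (stats::sd(y) == 0) stop("target gene has zero variance")
  n <- ncol(logcpm)
  r <- suppressWarnings(as.numeric(stats::cor(t(logcpm), y)))
  # two-sided p from the t transform of r
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  tab <- data.frame(gene_id = rownames(logcpm), r = r, p = p,
                    FDR = bhAdjust(p), stringsAsFactors = FALSE)
  sig <- tab$gene_id[!is.na(tab$r) & tab$r > 0 & tab$FDR < max_fdr]
  out <- list(table = tab, signature = sig)
  if (!is.null(up_set)) {
    out$overlap <- c(signature = length(sig), up = length(up_set),
                     both = length(intersect(sig, up_set)))
  }
  out
}
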