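#' Filter genes with low intron-spanning coverage
#'
#' A gene is removed when it yields fewer than \code{min_count} reads in more
#' than \code{frac} of the cohort (defaults: fewer than 30 reads in more than
#' 90\% of samples). The comparison is strict on both sides, so at n = 10 a
#' gene below threshold in exactly 9 samples (9 > 0.9 * 10 is false) is
#' retained. Gene order is preserved.
#'
#' @param x a \linkS4class{SplicedCounts} object.
#' @param min_count minimum read count a sample must reach (default 30).
#' @param frac fraction of the cohort allowed below \code{min_count}
#'   (default 0.9), strictly exceeded for removal.
#' @return filtered \linkS4class{SplicedCounts}.
#' @export
filterLowAbundanceGenes <- function(x, min_count = 30, frac = 0.9) {
  stopifnot(frac > 0, frac < 1, min_count >= 0)
  m <- counts(x)
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty count matrix")
  n_below <- rowSums(m < min_count)
  keep <- n_below <= frac * ncol(m)
  x[keep, ]
}

#' Number of detected genes in one sample
#'
#' A gene counts as detected when at least one intron-spanning read maps to
#' it.
#'
#' @param x a \linkS4class{SplicedCounts} object.
#' @param sample sample identifier.
#' @return integer count of genes with count >= 1.
#' @export
countDetectedGenes <- function(x, sample) {
  if (!sample %in% colnames(x)) stop("unknown sample: ", sample)
  sum(counts(x)[, sample] >= 1)
}

#' Filter samples by number of detected genes
#'
#' Samples with fewer than \code{min_genes} detected genes (strict <) are
#' removed; default 750.
#'
#' @param x a \linkS4class{SplicedCounts} object.
#' @param min_genes detection threshold.
#' @return list with \code{data} (filtered \linkS4class{SplicedCounts}) and
#'   \code{removed} (data.frame of excluded samples and their detected-gene
#'   counts).
#' @export
filterSamplesByDetectedGenes <- function(x, min_genes = 750) {
  stopifnot(min_genes >= 0)
  detected <- colSums(counts(x) >= 1)
  drop <- detected < min_genes
  if (all(drop)) stop("all samples fall below the detected-gene threshold")
  list(data = x[, !drop],
       removed = data.frame(sample_id = colnames(x)[drop],
                            detected_genes = unname(detected[drop]),
                            stringsAsFactors = FALSE))
}

#' Leave-one-sample-out cross-correlation filter
#'
#' For each sample the reference profile is the per-gene median
#' counts-per-million over all other samples; the sample's Pearson
#' correlation to that reference measures its comparability to the cohort.
#' Samples with r below \code{threshold} are removed in a single pass (the
#' references are not recomputed after removals). Plain CPM on raw counts is
#' used, keeping the filter label-agnostic and free of any training-cohort
#' choices. No log transform is applied unless \code{log} is set.
#'
#' @param x a \linkS4class{SplicedCounts} object with at least 3 samples.
#' @param threshold correlation cutoff (default 0.5, strict <).
#' @param log correlate log2(CPM + 1) instead of CPM.
#' @return list with \code{data} (filtered), \code{r} (named per-sample
#'   correlations) and \code{removed} (character vector).
#' @export
losoCrossCorrelation <- function(x, threshold = 0.5, log = FALSE) {
  m <- counts(x)
  if (ncol(m) < 3L) stop("leave-one-sample-out filter needs >= 3 samples")
  cpm <- .cpm(m, libSize(x))
  if (log) cpm <- log2(cpm + 1)
  r <- vapply(seq_len(ncol(cpm)), function(j) {
    ref <- .rowMedians(cpm[, -j, drop = FALSE])
    if (stats::sd(cpm[, j]) == 0 || stats::sd(ref) == 0) return(NA_real_)
    stats::cor(cpm[, j], ref)
  }, numeric(1))
  names(r) <- colnames(m)
  undef <- is.na(r)
  if (any(undef))
    warning("zero-variance profile for: ",
            paste(names(r)[undef], collapse = ", "),
            "; treated as failing the filter")
  fail <- undef | r < threshold
  list(data = x[, !fail], r = r, removed = colnames(m)[fail])
}

#' Run the full cohort QC chain
#'
#' Applies, in the published order, the low-abundance gene filter, the
#' detected-genes sample filter and the leave-one-sample-out
#' cross-correlation filter, and records for audit what each ordering of the
#' first two filters would have removed.
#'
#' @param x a \linkS4class{SplicedCounts} object.
#' @param min_count,frac gene-filter parameters (see
#'   \code{\link{filterLowAbundanceGenes}}).
#' @param min_genes sample detection threshold.
#' @param loso_threshold cross-correlation cutoff.
#' @return list with \code{data} and a \code{report} list (genes/samples
#'   retained at each stage, removed sample ids, per-sample r, and the
#'   genes-first vs samples-first audit).
#' @export
runQC <- function(x, min_count = 30, frac = 0.9, min_genes = 750,
                  loso_threshold = 0.5) {
  n0 <- c(genes = nrow(x), samples = ncol(x))
  gf <- filterLowAbundanceGenes(x, min_count, frac)
  sf <- filterSamplesByDetectedGenes(gf, min_genes)
  lf <- losoCrossCorrelation(sf$data, loso_threshold)
  # audit: alternative order (samples first, then genes)
  alt_sf <- filterSamplesByDetectedGenes(x, min_genes)
  alt_gf <- filterLowAbundanceGenes(alt_sf$data, min_count, frac)
  list(data = lf$data,
       report = list(
         input = n0,
         genes_retained = nrow(gf),
         samples_removed_detection = sf$removed,
         samples_removed_loso = lf$removed,
         loso_r = lf$r,
         final = c(genes = nrow(lf$data), samples = ncol(lf$data)),
         audit_samples_first = c(genes = nrow(alt_gf),
                                 samples = ncol(alt_gf))))
}
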