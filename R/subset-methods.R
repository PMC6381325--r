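#' Subsetting keeps library sizes consistent
#'
#' Subsetting a \linkS4class{SplicedCounts} by genes recomputes
#' \code{lib_size} as the column sums of the remaining counts, so the
#' object's invariant (lib_size equals column totals) always holds.
#'
#' @param x a \linkS4class{SplicedCounts}.
#' @param i,j gene and sample indices.
#' @param ... ignored.
#' @param drop ignored (always FALSE).
#' @return a \linkS4class{SplicedCounts}.
#' @export
setMethod("[", "SplicedCounts",
          function(x, i, j, ..., drop = FALSE) {
  out <- methods::callNextMethod()
  out$lib_size <- colSums(SummarizedExperiment::assay(out, "counts"))
  out
})
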