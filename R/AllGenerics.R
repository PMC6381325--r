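#' Per-sample library sizes
#'
#' Total intron-spanning read count per sample (column sums of the counts
#' assay).
#'
#' @param x a \linkS4class{SplicedCounts} object.
#' @return named numeric vector.
#' @export
setGeneric("libSize", function(x) standardGeneric("libSize"))

#' @rdname libSize
#' @export
setMethod("libSize", "SplicedCounts", function(x) {
  ls <- as.numeric(x$lib_size)
  names(ls) <- colnames(x)
  ls
})

#' Extract the raw count matrix
#'
#' @param object a \linkS4class{SplicedCounts} object.
#' @return integer matrix, genes as rows.
#' @importFrom BiocGenerics counts
#' @export counts
#' @aliases counts,SplicedCounts-method
#' @export
setMethod("counts", "SplicedCounts", function(object) {
  SummarizedExperiment::assay(object, "counts")
})

#' Sample annotation accessor
#'
#' @param x a \linkS4class{SplicedCounts} object.
#' @return a data.frame with one row per sample.
#' @export
setGeneric("sampleAnnotation", function(x) standardGeneric("sampleAnnotation"))

#' @rdname sampleAnnotation
#' @export
setMethod("sampleAnnotation", "SplicedCounts", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
})

#' Panel gene accessor
#' @param x a \linkS4class{GenePanel} or \linkS4class{ClassifierModel}.
#' @return character vector of gene ids in rank order.
#' @export
setGeneric("panelGenes", function(x) standardGeneric("panelGenes"))

#' @rdname panelGenes
#' @export
setMethod("panelGenes", "GenePanel", function(x) x@genes)

#' @rdname panelGenes
#' @export
setMethod("panelGenes", "ClassifierModel", function(x) x@panel@genes)

#' Stable (negative control) gene accessor
#' @param x a \linkS4class{NormalizationModel} or \linkS4class{ClassifierModel}.
#' @return character vector of stable gene ids.
#' @export
setGeneric("stableGenes", function(x) standardGeneric("stableGenes"))

#' @rdname stableGenes
#' @export
setMethod("stableGenes", "NormalizationModel", function(x) x@stableGenes)

#' @rdname stableGenes
#' @export
setMethod("stableGenes", "ClassifierModel", function(x) x@normModel@stableGenes)
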