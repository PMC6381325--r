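#' Construct a SplicedCounts object
#'
#' Joins a gene-by-sample integer count matrix of intron-spanning reads with
#' its sample annotation. Samples without an annotation record are rejected;
#' gene and sample order is preserved exactly as supplied (no implicit
#' sorting), so downstream tie-breaking is reproducible.
#'
#' @param counts integer matrix, genes as rows, samples as columns; dimnames
#'   required, no duplicates, all cells non-negative integers.
#' @param annotation data.frame with a \code{sample_id} column plus any of
#'   group, age, storage, gender, smoking, cohort_role, site. May be NULL.
#' @return a \linkS4class{SplicedCounts} object with \code{lib_size} in
#'   \code{colData}.
#' @examples
#' m <- matrix(0:3, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' ann <- data.frame(sample_id = c("s1", "s2"), group = c("a", "b"))
#' SplicedCounts(m, ann)
#' @export
SplicedCounts <- function(counts, annotation = NULL) {
  .stopifnot_matrix(counts)
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop("invalid count for gene '", rownames(counts)[bad[1, 1]],
         "', sample '", colnames(counts)[bad[1, 2]],
         "': counts must be non-negative integers")
  }
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene identifiers in count table")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers in count table")
  storage.mode(counts) <- "double"
  cd <- S4Vectors::DataFrame(lib_size = colSums(counts),
                             row.names = colnames(counts))
  if (!is.null(annotation)) {
    annotation <- as.data.frame(annotation)
    if (!"sample_id" %in% colnames(annotation))
      stop("annotation must have a sample_id column")
    if (anyDuplicated(annotation$sample_id))
      stop("duplicate sample_id in annotation")
    missing <- setdiff(colnames(counts), annotation$sample_id)
    if (length(missing))
      stop("samples without annotation: ", paste(missing, collapse = ", "))
    ann <- annotation[match(colnames(counts), annotation$sample_id), ,
                      drop = FALSE]
    for (col in setdiff(colnames(ann), "sample_id")) cd[[col]] <- ann[[col]]
  }
  methods::new("SplicedCounts",
               SummarizedExperiment::SummarizedExperiment(
                 assays = list(counts = counts), colData = cd))
}

#' Read a count table and annotation from disk
#'
#' The count table is a UTF-8 TSV with gene ids in the first column and
#' sample ids in the header; the annotation is a CSV with at least a
#' \code{sample_id} column.
#'
#' @param counts_path path to the TSV count table.
#' @param annotation_path optional path to the annotation CSV.
#' @return a \linkS4class{SplicedCounts} object.
#' @export
readSplicedCounts <- function(counts_path, annotation_path = NULL) {
  tab <- utils::read.delim(counts_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop("count table contains non-numeric cells")
  rownames(m) <- genes
  ann <- NULL
  if (!is.null(annotation_path))
    ann <- utils::read.csv(annotation_path, stringsAsFactors = FALSE)
  SplicedCounts(m, ann)
}

#' Write a SplicedCounts object to disk
#'
#' Writes the count table as TSV (first column \code{gene_id}) and,
#' optionally, the annotation as CSV. The written files round-trip exactly
#' through \code{\link{readSplicedCounts}}.
#'
#' @param x a \linkS4class{SplicedCounts} object.
#' @param counts_path output TSV path.
#' @param annotation_path optional output CSV path.
#' @return invisibly, the paths written.
#' @export
writeSplicedCounts <- function(x, counts_path, annotation_path = NULL) {
  m <- counts(x)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(annotation_path)) {
    ann <- sampleAnnotation(x)
    ann <- data.frame(sample_id = rownames(ann),
                      ann[, setdiff(colnames(ann), "lib_size"), drop = FALSE],
                      row.names = NULL, check.names = FALSE)
    utils::write.csv(ann, annotation_path, row.names = FALSE, quote = FALSE)
  }
  invisible(c(counts_path, annotation_path))
}

#' Merge technical replicate columns
#'
#' Re-sequenced libraries of the same sample (run when the first sequencing
#' yielded too few intron-spanning reads) are merged by per-gene summation of
#' the two count vectors; library size is recomputed. Merging happens before
#' any filtering. The operation is commutative and associative.
#'
#' @param a,b numeric count vectors named by gene, for the same sample and
#'   the same gene universe.
#' @return merged named count vector.
#' @export
mergeTechnicalReplicates <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b)) || !identical(names(a), names(b)))
    stop("replicates must cover the same genes in the same order")
  a + b
}

#' Serialize a model object to a single archive
#'
#' Models are written as a one-object archive with a format-version field so
#' that future readers can refuse incompatible files.
#'
#' @param model a \linkS4class{NormalizationModel} or
#'   \linkS4class{ClassifierModel}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(format_version = 1L, class = class(model)[1L], model = model),
          path)
  invisible(path)
}

#' @rdname saveModel
#' @export
readModel <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$format_version))
    stop("not a swarmSeq model archive: ", path)
  if (obj$format_version != 1L)
    stop("unsupported model format version: ", obj$format_version)
  obj$model
}
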