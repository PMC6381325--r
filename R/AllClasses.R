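#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Spliced read counts with sample annotation
#'
#' \code{SplicedCounts} is the central container of the package: a
#' \linkS4class{SummarizedExperiment} holding one \code{"counts"} assay of
#' non-negative integer intron-spanning read counts (genes as rows, samples
#' as columns).  Sample annotation (group, age, blood-storage stratum,
#' smoking, gender, cohort role, site) lives in \code{colData}, alongside the
#' per-sample total count \code{lib_size}, which is kept consistent with the
#' column sums of the assay.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @seealso \code{\link{SplicedCounts}} (constructor),
#'   \code{\link{readSplicedCounts}}, \code{\link{libSize}}
#' @export
setClass("SplicedCounts", contains = "SummarizedExperiment")

setValidity("SplicedCounts", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is missing")
  m <- SummarizedExperiment::assay(object, "counts")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "counts must have gene and sample names")
  if (anyDuplicated(rownames(m)))
    msg <- c(msg, "duplicate gene identifiers")
  if (anyDuplicated(colnames(m)))
    msg <- c(msg, "duplicate sample identifiers")
  if (any(is.na(m)))
    msg <- c(msg, "counts contain missing values")
  else {
    if (any(m < 0)) msg <- c(msg, "counts contain negative values")
    if (any(m != round(m))) msg <- c(msg, "counts contain non-integer values")
  }
  if (!"lib_size" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData lacks lib_size")
  else if (!any(is.na(m)) &&
           !isTRUE(all.equal(unname(colSums(m)),
                             as.numeric(object$lib_size))))
    msg <- c(msg, "lib_size does not equal column sums of counts")
  if (length(msg)) msg else TRUE
})

#' Locked normalization model (TMM reference + RUV factors)
#'
#' Frozen state of the iterative correction module: the stable (negative
#' control) gene set, the SVD factorization used to score latent factors on
#' any sample, per-gene regression coefficients for the factors flagged as
#' unwanted variation, the locked TMM reference sample and the training
#' geometric-mean rescaling constant.  All fields are derived from the
#' training cohort only, so applying the model to held-out samples uses no
#' information from their labels.
#'
#' @slot genes gene universe (order preserved from the fitted matrix).
#' @slot refSample sample id locked as TMM reference.
#' @slot refCounts corrected counts of the reference sample.
#' @slot tmmFactors named per-sample TMM factors for the fitted samples.
#' @slot tmmScale training geometric-mean divisor applied to raw pairwise
#'   factors so that training factors have geometric mean 1.
#' @slot stableGenes negative-control genes used for factor estimation.
#' @slot k number of latent factors estimated.
#' @slot W sample-by-k latent factor scores for the fitted samples.
#' @slot svdV,svdD,controlCenter right singular vectors, singular values and
#'   per-control-gene centers used to project new samples onto the factors.
#' @slot removedFactors indices (in 1..k) flagged as unwanted variation.
#' @slot factorMatches per-factor record of the matched confounder(s) and
#'   the group/confounder p values.
#' @slot geneBeta gene-by-removed-factor regression coefficients on the log
#'   scale, used to subtract the unwanted component.
#' @slot correctedLibSize per-sample totals of the corrected counts.
#' @slot thresholds list with libsize_corr_threshold, age_corr_threshold,
#'   p_group_floor (1e-5) and p_confounder_ceiling (0.01).
#' @slot trainingSamples ids of the samples the model was locked on.
#' @export
setClass("NormalizationModel",
  representation(
    genes = "character",
    refSample = "character",
    refCounts = "numeric",
    tmmFactors = "numeric",
    tmmScale = "numeric",
    stableGenes = "character",
    k = "integer",
    W = "matrix",
    svdV = "matrix",
    svdD = "numeric",
    controlCenter = "numeric",
    removedFactors = "integer",
    factorMatches = "list",
    geneBeta = "matrix",
    correctedLibSize = "numeric",
    thresholds = "list",
    trainingSamples = "character"
  )
)

setValidity("NormalizationModel", function(object) {
  msg <- character()
  if (any(object@tmmFactors <= 0))
    msg <- c(msg, "TMM factors must be positive")
  tr <- intersect(object@trainingSamples, names(object@tmmFactors))
  if (length(tr)) {
    gm <- exp(mean(log(object@tmmFactors[tr])))
    if (abs(gm - 1) > 1e-9)
      msg <- c(msg, "training TMM factors must have geometric mean 1")
  }
  if (!all(object@stableGenes %in% object@genes))
    msg <- c(msg, "stable genes outside gene universe")
  if (length(object@removedFactors) &&
      (any(object@removedFactors < 1L) || any(object@removedFactors > object@k)))
    msg <- c(msg, "removedFactors outside 1..k")
  if (length(msg)) msg else TRUE
})

#' Ranked gene panel
#'
#' Ordered gene identifiers with their ranking scores (ANOVA likelihood-ratio
#' statistics) and a provenance record of the thresholds that produced them.
#'
#' @slot genes ordered gene ids (no duplicates).
#' @slot scores ranking score per gene, same order.
#' @slot provenance named list of the thresholds/stages applied.
#' @export
setClass("GenePanel",
  representation(genes = "character", scores = "numeric", provenance = "list"))

setValidity("GenePanel", function(object) {
  msg <- character()
  if (anyDuplicated(object@genes)) msg <- c(msg, "duplicate panel genes")
  if (length(object@scores) && length(object@scores) != length(object@genes))
    msg <- c(msg, "scores length must match genes")
  if (length(msg)) msg else TRUE
})

#' Locked classifier model
#'
#' Frozen end-to-end pipeline state: the training-locked
#' \linkS4class{NormalizationModel}, the final \linkS4class{GenePanel}, the
#' tuned radial-basis SVM (with its Platt-style probability calibration
#' fitted on training decision values), per-gene training median counts for
#' low-count imputation, and the hyperparameter vector the panel was built
#' under.  Prediction of any sample uses only the fields of this object.
#'
#' @slot normModel locked normalization model.
#' @slot panel final gene panel.
#' @slot svmConfig list with kernel, cost, gamma, cv folds.
#' @slot svmFit fitted \code{e1071::svm} object.
#' @slot calibration Platt sigmoid coefficients (A, B) fitted on training
#'   decision values; scores are 1 / (1 + exp(A d + B)).
#' @slot positiveClass label treated as the positive (case) class.
#' @slot imputationMedians named per-panel-gene training median raw counts.
#' @slot imputeTrigger counts in [0, trigger] are replaced by the median.
#' @slot theta hyperparameters (libsize threshold, ANOVA FDR threshold,
#'   correlation cutoff, RFE panel size) used to build the panel.
#' @slot trainingSamples training cohort sample ids.
#' @slot trainingScores calibrated training scores (for reference).
#' @export
setClass("ClassifierModel",
  representation(
    normModel = "NormalizationModel",
    panel = "GenePanel",
    svmConfig = "list",
    svmFit = "ANY",
    calibration = "numeric",
    positiveClass = "character",
    imputationMedians = "numeric",
    imputeTrigger = "numeric",
    theta = "numeric",
    trainingSamples = "character",
    trainingScores = "numeric"
  )
)

setValidity("ClassifierModel", function(object) {
  msg <- character()
  if (!all(object@panel@genes %in% object@normModel@genes))
    msg <- c(msg, "panel genes outside normalization gene universe")
  if (!setequal(names(object@imputationMedians), object@panel@genes))
    msg <- c(msg, "imputation medians must cover exactly the panel genes")
  if (object@imputeTrigger < 0) msg <- c(msg, "imputeTrigger must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SplicedCounts", function(object) {
  cat("SplicedCounts:", nrow(object), "genes x", ncol(object), "samples\n")
  cd <- SummarizedExperiment::colData(object)
  if ("group" %in% colnames(cd)) {
    tab <- table(cd$group)
    cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  if ("cohort_role" %in% colnames(cd)) {
    tab <- table(cd$cohort_role)
    cat("  roles: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  cat("  total intron-spanning reads:", sum(object$lib_size), "\n")
})

setMethod("show", "NormalizationModel", function(object) {
  cat("NormalizationModel\n")
  cat("  gene universe:", length(object@genes), "genes\n")
  cat("  stable (control) genes:", length(object@stableGenes), "\n")
  cat("  latent factors k =", object@k,
      "| removed:", if (length(object@removedFactors))
        paste(object@removedFactors, collapse = ",") else "none", "\n")
  cat("  TMM reference:", object@refSample, "\n")
})

setMethod("show", "GenePanel", function(object) {
  cat("GenePanel of", length(object@genes), "genes\n")
  n <- min(5L, length(object@genes))
  if (n > 0)
    cat("  top:", paste(utils::head(object@genes, n), collapse = ", "), "\n")
})

setMethod("show", "ClassifierModel", function(object) {
  cat("ClassifierModel (RBF SVM)\n")
  cat("  panel size:", length(object@panel@genes), "genes\n")
  cat("  cost:", object@svmConfig$cost, " gamma:", object@svmConfig$gamma, "\n")
  cat("  positive class:", object@positiveClass, "\n")
  cat("  imputation trigger:", object@imputeTrigger, "\n")
  cat("  training samples:", length(object@trainingSamples), "\n")
})
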