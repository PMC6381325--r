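#' Default pipeline configuration
#'
#' All thresholds of the pipeline as one nested list; any subset can be
#' overridden in \code{\link{runPipeline}}.
#'
#' @return nested configuration list.
#' @export
defaultConfig <- function() {
  list(
    seed = 1,
    qc = list(min_count = 30, frac = 0.9, min_genes = 750,
              loso_threshold = 0.5),
    normalize = list(k = 3, libsize_threshold = 0.8, age_threshold = 0.2),
    diff = list(min_logcpm = 3, fdr = 0.01, use_corrected = TRUE),
    classifier = list(theta = c(libsize_threshold = 0.8,
                                fdr_threshold = 0.05,
                                corr_cutoff = 0.9, rfe_size = 50),
                      optimize = FALSE, particles = 100, iters = 10,
                      impute_trigger = 12,
                      gamma_exp = -20:0, cost_exp = 0:20),
    evaluate = list(permutations = 1000))
}

.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Executes qc -> normalize -> differential splicing -> classifier training
#' -> validation evaluation in order. Every stage writes a versioned
#' artifact into \code{out_dir} plus a JSON log of parameters, seeds and
#' exclusion lists; any stage error aborts with a stage-labeled message
#' (partial artifacts are retained). Reruns with the same configuration and
#' seed reproduce identical artifacts. Cohort roles are taken from the
#' \code{cohort_role} annotation column (training / evaluation /
#' validation).
#'
#' @param counts a \linkS4class{SplicedCounts}, or path to a count TSV.
#' @param annotation annotation CSV path (when \code{counts} is a path).
#' @param out_dir output directory.
#' @param config configuration overrides (see \code{\link{defaultConfig}}),
#'   or a YAML file path.
#' @return list with the QC report, normalization model, differential
#'   table, classifier model, evaluation report and artifact paths.
#' @export
runPipeline <- function(counts, annotation = NULL, out_dir = tempfile("run"),
                        config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  cfg <- .merge_config(defaultConfig(), config)
  if (is.character(counts)) {
    if (!file.exists(counts)) stop("count table not found: ", counts)
    if (!is.null(annotation) && !file.exists(annotation))
      stop("annotation file not found: ", annotation)
    counts <- readSplicedCounts(counts, annotation)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(cfg)
  logf <- file.path(out_dir, "pipeline.log.jsonl")
  log_event <- function(stage, ...) {
    rec <- list(stage = stage, config_hash = hash, seed = cfg$seed, ...)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", file = logf,
        append = TRUE)
    message("[", stage, "] done")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }

  qc <- stage("qc", runQC(counts, cfg$qc$min_count, cfg$qc$frac,
                          cfg$qc$min_genes, cfg$qc$loso_threshold))
  x <- qc$data
  jsonlite::write_json(
    list(config_hash = hash,
         genes_retained = qc$report$genes_retained,
         samples_removed = list(
           detection = qc$report$samples_removed_detection$sample_id,
           loso = qc$report$samples_removed_loso),
         final = as.list(qc$report$final)),
    file.path(out_dir, "qc.json"), auto_unbox = TRUE)
  log_event("qc", final = as.list(qc$report$final))

  ann <- sampleAnnotation(x)
  training <- rownames(ann)[ann$cohort_role == "training"]
  evaluation <- rownames(ann)[ann$cohort_role == "evaluation"]
  validation <- rownames(ann)[ann$cohort_role == "validation"]
  if (length(training) < 4) stop("stage roles: too few training samples")

  norm <- stage("normalize",
                iterativeCorrection(x, training = training,
                                    libsize_threshold =
                                      cfg$normalize$libsize_threshold,
                                    age_threshold =
                                      cfg$normalize$age_threshold,
                                    k = cfg$normalize$k))
  saveModel(norm$model, file.path(out_dir, "normalization_model.rds"))
  log_event("normalize", k = cfg$normalize$k,
            stable_genes = length(norm$model@stableGenes),
            removed_factors = norm$model@removedFactors)

  de <- stage("diff", {
    res <- diffSplicing(x, ann$group, norm = norm,
                        use_corrected = cfg$diff$use_corrected)
    filterResults(res, cfg$diff$min_logcpm, cfg$diff$fdr)
  })
  utils::write.table(de$table, file.path(out_dir, "differential.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_event("diff", n_significant = nrow(de$table), n_up = de$n_up,
            n_down = de$n_down)

  cls <- cfg$classifier
  fit <- stage("train", {
    if (isTRUE(cls$optimize)) {
      outerPSO(x, training, evaluation, n_particles = cls$particles,
               n_iter = cls$iters, seed = cfg$seed,
               k = cfg$normalize$k, impute_trigger = cls$impute_trigger,
               gamma_exp = cls$gamma_exp, cost_exp = cls$cost_exp)
    } else {
      list(model = trainClassifier(x, training, theta = cls$theta,
                                   k = cfg$normalize$k,
                                   impute_trigger = cls$impute_trigger,
                                   gamma_exp = cls$gamma_exp,
                                   cost_exp = cls$cost_exp,
                                   seed = cfg$seed),
           theta = cls$theta)
    }
  })
  model <- fit$model
  saveModel(model, file.path(out_dir, "classifier_model.rds"))
  log_event("train", panel_size = length(model@panel@genes),
            theta = as.list(fit$theta))

  report <- stage("evaluate", {
    if (length(validation) >= 4) {
      pred <- predictSamples(model, x[, validation])
      lab <- ann[validation, "group"]
      perf <- rocAUC(pred$score, lab, model@positiveClass)
      ci <- delongCI(pred$score, lab, positive = model@positiveClass)
      acc <- bestAccuracy(pred$score, lab, model@positiveClass)
      lc_tr <- applyNormalization(model@normModel,
                                  counts(x)[, model@trainingSamples])$logcpm
      lc_va <- applyNormalization(model@normModel,
                                  counts(x)[, validation])$logcpm
      pn <- permutationNull(
        t(lc_tr[model@panel@genes, , drop = FALSE]),
        ann[model@trainingSamples, "group"],
        t(lc_va[model@panel@genes, , drop = FALSE]), lab,
        model@svmConfig$cost, model@svmConfig$gamma,
        observed_auc = perf$auc, n_perm = cfg$evaluate$permutations,
        positive = model@positiveClass, seed = cfg$seed)
      list(auc = perf$auc, ci = as.numeric(ci), accuracy = acc$accuracy,
           threshold = acc$threshold, p_permutation = pn$p_value,
           predictions = pred)
    } else list(note = "validation cohort too small; evaluation skipped")
  })
  jsonlite::write_json(c(list(config_hash = hash),
                         report[setdiff(names(report), "predictions")]),
                       file.path(out_dir, "report.json"), auto_unbox = TRUE,
                       digits = NA)
  log_event("evaluate", auc = report$auc)

  list(qc = qc$report, norm_model = norm$model, differential = de,
       model = model, report = report, out_dir = out_dir,
       config_hash = hash)
}
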