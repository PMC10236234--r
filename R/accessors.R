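#' Extract the subjects-by-ROI volume matrix
#'
#' @param x a [RoiCohort-class].
#' @param ... unused.
#' @return numeric matrix, subjects in rows and ROIs in columns (the
#'   transpose of the stored assay, matching the CSV layout).
#' @export
setMethod("roiVolumes", "RoiCohort", function(x, ...) {
  t(SummarizedExperiment::assay(x, "volumes"))
})

#' Scanner (batch) labels
#' @param x a [RoiCohort-class].
#' @return character vector, one scanner label per subject.
#' @export
setMethod("scannerIds", "RoiCohort", function(x) {
  as.character(SummarizedExperiment::colData(x)$scanner)
})

#' Study labels
#' @param x a [RoiCohort-class].
#' @return character vector with values in `study`, `control`,
#'   `reference_control`, `reference_ad`.
#' @export
setMethod("studyLabels", "RoiCohort", function(x) {
  as.character(SummarizedExperiment::colData(x)$study_label)
})

#' Per-subject covariate table
#' @param x a [RoiCohort-class].
#' @return a base data.frame of the colData, one row per subject.
#' @export
setMethod("subjectData", "RoiCohort", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
})

#' Longitudinal risk-factor visit records
#' @param x a [RoiCohort-class].
#' @return long-format data.frame (`subject_id`, `covariate`, `time`,
#'   `value`) or `NULL` if none attached.
#' @export
setMethod("riskHistories", "RoiCohort", function(x) {
  metadata(x)$riskHistories
})

#' @export
setMethod("show", "RoiCohort", function(object) {
  lab <- table(studyLabels(object))
  cat("RoiCohort:", ncol(object), "subjects x", nrow(object), "ROIs\n")
  cat("  scanners:", length(unique(scannerIds(object))), "\n")
  cat("  labels:", paste(sprintf("%s=%d", names(lab), lab), collapse = ", "),
      "\n")
  if (!is.null(riskHistories(object)))
    cat("  risk histories:", nrow(riskHistories(object)), "visit records\n")
})

#' @export
setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat(sprintf("  cohorts: study=%d control=%d reference=%d ad=%d\n",
              object@nStudy, object@nControl, object@nReference,
              object@nAdCases))
  cat(sprintf("  %d ROIs on %d scanners; ages %g-%g\n", object@nRois,
              object@nScanners, object@ageRange[1], object@ageRange[2]))
  cat(sprintf(
    "  site shift SD %g mm3, log-scale SD %g, noise SD %g mm3\n",
    object@siteShiftSd, object@siteScaleSd, object@noiseSd))
  cat(sprintf("  aging offset %g y; AD effect %g SD; seed %d\n",
              object@agingOffsetYears, object@adEffectSd, object@seed))
})

#' @export
setMethod("show", "CombatModel", function(object) {
  cat("CombatModel:", length(object@alpha), "ROIs,",
      length(object@batches), "batches\n")
  cat("  covariates:", if (length(object@covariates))
    paste(object@covariates, collapse = ", ") else "(none)", "\n")
  if (length(object@referenceBatch))
    cat("  reference batch:", object@referenceBatch, "\n")
})

#' @export
setMethod("show", "SpareModel", function(object) {
  cat(sprintf("SpareModel (SPARE-%s): %d ROI features\n", object@kind,
              length(object@weights)))
  tm <- object@trainingMeta
  if (!is.null(tm$n)) cat("  trained on n =", tm$n, "\n")
  cat("  cost =", object@hyperparameters$cost, "\n")
  if (!is.null(tm$cv)) {
    if (object@kind == "BA")
      cat(sprintf("  held-out MAE %.2f y, cor(age, pred) %.3f\n",
                  tm$cv$mae, tm$cv$cor))
    else
      cat(sprintf("  held-out balanced accuracy %.3f\n",
                  tm$cv$balanced_accuracy))
  }
})

#' Years-equivalent point estimate
#' @param x a [GapEstimate-class].
#' @return numeric scalar, years.
#' @export
setMethod("gapYears", "GapEstimate", function(x) x@years)

#' @export
setMethod("show", "GapEstimate", function(object) {
  cat(sprintf(
    "Years-equivalent brain aging: %.2f y (SE %.2f)\n", object@years,
    object@seYears))
  cat(sprintf("  beta_group = %.3f (SE %.3f), beta_age = %.3f (SE %.3f), n = %d\n",
              object@betaGroup, object@seGroup, object@betaAge, object@seAge,
              object@n))
})
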