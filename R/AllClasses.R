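#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Simulation configuration for synthetic multi-scanner cohorts
#'
#' Holds every tunable of the synthetic-data generator: cohort sizes, ROI
#' count, scanner count, age range, scanner location/scale effect magnitudes,
#' the group-wise accelerated-aging offset (in years), the AD-signature
#' atrophy effect (in standardized units), residual noise, and the seed.
#' Defaults emulate the study design this package targets: a study arm of 416
#' adults with type 1 diabetes aged 44-74 imaged on 24 scanners, 99 matched
#' controls, a reference pool of 2764 healthy adults, 221 amyloid-positive AD
#' cases for signature training, and 145 anatomical ROIs.
#'
#' @slot nStudy,nControl,nReference,nAdCases cohort sizes (subjects).
#' @slot nRois number of ROI volume columns.
#' @slot nScanners number of scanners in the study arm.
#' @slot ageRange numeric length-2, min and max age in years.
#' @slot siteShiftSd SD of per-scanner per-ROI additive shifts, mm3.
#' @slot siteScaleSd SD (log scale) of per-scanner per-ROI multiplicative
#'   noise-scale effects.
#' @slot agingOffsetYears years added to the effective age of study-group
#'   subjects on age-sensitive ROIs only.
#' @slot adEffectSd AD-case atrophy on signature ROIs, in units of the
#'   marginal generating SD of those ROIs.
#' @slot noiseSd residual noise SD, mm3.
#' @slot affectedRoiFraction fraction of ROIs with an age trend.
#' @slot studyShift global study-space offset versus the reference space, mm3.
#' @slot seed integer seed; identical config + seed is bit-reproducible.
#'
#' @seealso [generateCohort()], [generateReferenceCohort()]
#' @export
setClass("SimConfig",
  representation(
    nStudy = "integer", nControl = "integer", nReference = "integer",
    nAdCases = "integer", nRois = "integer", nScanners = "integer",
    ageRange = "numeric", siteShiftSd = "numeric", siteScaleSd = "numeric",
    agingOffsetYears = "numeric", adEffectSd = "numeric", noiseSd = "numeric",
    affectedRoiFraction = "numeric", studyShift = "numeric", seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  for (f in c("nStudy", "nControl", "nReference", "nAdCases", "nRois",
              "nScanners")) {
    v <- slot(object, f)
    if (length(v) != 1L || is.na(v) || (v <= 0L && f != "nAdCases") || v < 0L)
      msg <- c(msg, sprintf("'%s' must be a single positive integer", f))
  }
  if (length(object@ageRange) != 2L || object@ageRange[1] >= object@ageRange[2])
    msg <- c(msg, "'ageRange' must be (min, max) with min < max")
  if (object@affectedRoiFraction < 0 || object@affectedRoiFraction > 1)
    msg <- c(msg, "'affectedRoiFraction' must lie in [0, 1]")
  for (f in c("siteShiftSd", "siteScaleSd", "noiseSd")) {
    if (slot(object, f) < 0) msg <- c(msg, sprintf("'%s' must be >= 0", f))
  }
  if (length(msg)) msg else TRUE
})

#' @param nStudy,nControl,nReference,nAdCases,nRois,nScanners,ageRange,siteShiftSd,siteScaleSd,agingOffsetYears,adEffectSd,noiseSd,affectedRoiFraction,studyShift,seed
#'   see the corresponding slots.
#' @return `SimConfig()` returns a validated `SimConfig` object.
#' @rdname SimConfig-class
#' @examples
#' cfg <- SimConfig(nStudy = 40, nControl = 10, nReference = 60,
#'                  nRois = 20, nScanners = 4, seed = 7)
#' cfg
#' @export
SimConfig <- function(nStudy = 416L, nControl = 99L, nReference = 2764L,
                      nAdCases = 221L, nRois = 145L, nScanners = 24L,
                      ageRange = c(44, 74), siteShiftSd = 100,
                      siteScaleSd = 0.15, agingOffsetYears = 0,
                      adEffectSd = 0, noiseSd = 120,
                      affectedRoiFraction = 0.5, studyShift = 0, seed = 1L) {
  new("SimConfig",
      nStudy = as.integer(nStudy), nControl = as.integer(nControl),
      nReference = as.integer(nReference), nAdCases = as.integer(nAdCases),
      nRois = as.integer(nRois), nScanners = as.integer(nScanners),
      ageRange = as.numeric(ageRange), siteShiftSd = as.numeric(siteShiftSd),
      siteScaleSd = as.numeric(siteScaleSd),
      agingOffsetYears = as.numeric(agingOffsetYears),
      adEffectSd = as.numeric(adEffectSd), noiseSd = as.numeric(noiseSd),
      affectedRoiFraction = as.numeric(affectedRoiFraction),
      studyShift = as.numeric(studyShift), seed = as.integer(seed))
}

#' Subjects-by-ROI volume cohort
#'
#' A `RoiCohort` is a [SummarizedExperiment::SummarizedExperiment] whose
#' single assay `"volumes"` holds gray-matter ROI volumes (mm3) with ROIs as
#' rows and subjects as columns. `colData` carries the per-subject
#' covariates: `subject_id`, `age` (years), `sex` (`"male"`/`"female"`),
#' `icv` (mm3), `education` (years), `scanner` (batch label), `group`
#' (`"study"`/`"control"`), `study_label` (one of `study`, `control`,
#' `reference_control`, `reference_ad`) and `diagnosis`. Visit-level
#' longitudinal risk-factor records live in
#' `metadata(x)$riskHistories` as a long-format data.frame.
#'
#' @seealso [generateCohort()], [roiVolumes()]
#' @export
setClass("RoiCohort", contains = "SummarizedExperiment")

.required_coldata <- c("subject_id", "age", "sex", "icv", "scanner",
                       "group", "study_label", "diagnosis")

setValidity("RoiCohort", function(object) {
  msg <- character()
  if (!"volumes" %in% SummarizedExperiment::assayNames(object))
    return("assay 'volumes' is required")
  v <- SummarizedExperiment::assay(object, "volumes")
  if (anyNA(v)) msg <- c(msg, "ROI volumes contain missing values")
  else if (any(v <= 0)) msg <- c(msg, "all ROI volumes must be > 0")
  cd <- SummarizedExperiment::colData(object)
  missing_cols <- setdiff(.required_coldata, colnames(cd))
  if (length(missing_cols))
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(missing_cols, collapse = ", ")))
  if ("sex" %in% colnames(cd) &&
      !all(cd$sex %in% c("male", "female")))
    msg <- c(msg, "sex must be 'male' or 'female'")
  if ("scanner" %in% colnames(cd) && anyNA(cd$scanner))
    msg <- c(msg, "every subject needs exactly one scanner label")
  if (length(msg)) msg else TRUE
})

#' Construct a RoiCohort
#'
#' @param volumes numeric matrix of ROI volumes, subjects in rows and ROIs in
#'   columns (the CSV layout); stored transposed as the SE assay.
#' @param covariates data.frame of per-subject covariates, one row per
#'   subject in the same order as `volumes`; must contain the columns listed
#'   in [RoiCohort-class].
#' @param riskHistories optional long-format data.frame
#'   (`subject_id`, `covariate`, `time`, `value`) of visit-level records.
#' @param truth optional list of generator ground truth (kept in metadata).
#' @return a `RoiCohort`.
#' @rdname RoiCohort-class
#' @export
RoiCohort <- function(volumes, covariates, riskHistories = NULL,
                      truth = NULL) {
  volumes <- as.matrix(volumes)
  if (nrow(volumes) != nrow(covariates))
    stop("volumes and covariates describe different numbers of subjects")
  if (is.null(rownames(volumes)))
    rownames(volumes) <- as.character(covariates$subject_id)
  if (is.null(colnames(volumes)))
    colnames(volumes) <- sprintf("ROI_%03d", seq_len(ncol(volumes)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(volumes = t(volumes)),
    colData = S4Vectors::DataFrame(covariates,
                                   row.names = rownames(volumes)))
  md <- list()
  if (!is.null(riskHistories)) md$riskHistories <- riskHistories
  if (!is.null(truth)) md$truth <- truth
  metadata(se) <- md
  new("RoiCohort", se)
}

#' Fitted ComBat-GAM harmonization model
#'
#' Stores, per ROI, the pooled covariate model (intercept, penalized-spline
#' age trend, linear covariate coefficients) and, per batch, the
#' empirical-Bayes shrunk location (`gammaStar`, standardized units) and
#' scale (`deltaStar`, multiplicative on the residual SD) effects, together
#' with the pooled residual SD used for standardization.
#'
#' @slot alpha named numeric, per-ROI grand intercept (mm3).
#' @slot coefC matrix (covariate-design columns x ROIs) of covariate
#'   coefficients, age-spline block included.
#' @slot sigma named numeric, per-ROI pooled residual SD (mm3).
#' @slot gammaStar,deltaStar matrices (batches x ROIs); `deltaStar` is on the
#'   SD scale and strictly positive.
#' @slot smooth the `mgcv` smooth construction object for the age basis
#'   (`NULL` when age is not in the roster).
#' @slot covariates character, the fitted covariate roster.
#' @slot factorLevels named list of factor levels for categorical covariates.
#' @slot batches character batch roster; @slot nPerBatch integer batch sizes.
#' @slot referenceBatch optional batch label mapped to itself unchanged.
#' @slot ageRange numeric, age range seen in fitting (extrapolation warns).
#' @slot batchKey the colData column used as batch label.
#' @export
setClass("CombatModel",
  representation(
    alpha = "numeric", coefC = "matrix", sigma = "numeric",
    gammaStar = "matrix", deltaStar = "matrix",
    smooth = "ANY", covariates = "character", factorLevels = "list",
    batches = "character", nPerBatch = "integer",
    referenceBatch = "character", ageRange = "numeric", batchKey = "character"
  )
)

setValidity("CombatModel", function(object) {
  msg <- character()
  if (any(object@deltaStar <= 0))
    msg <- c(msg, "all scale effects deltaStar must be > 0")
  if (any(object@sigma <= 0))
    msg <- c(msg, "pooled residual SDs must be > 0")
  if (!identical(rownames(object@gammaStar), object@batches))
    msg <- c(msg, "gammaStar rows must match the batch roster")
  if (length(msg)) msg else TRUE
})

#' Trained SPARE index model
#'
#' A linear model over standardized ROI volumes: either a brain-age
#' support-vector regression (`kind = "BA"`, predictions in years) or an
#' AD-signature linear SVM (`kind = "AD"`, scores are signed decision values,
#' positive = more AD-like atrophy).
#'
#' @slot kind `"BA"` or `"AD"`.
#' @slot weights named per-ROI coefficients in standardized-feature space.
#' @slot intercept scalar offset.
#' @slot featureMeans,featureSds training-set standardization constants,
#'   frozen into the model.
#' @slot hyperparameters list: selected cost, grid, epsilon (BA), folds.
#' @slot trainingMeta list: training counts, seed, cross-validation summary.
#' @export
setClass("SpareModel",
  representation(
    kind = "character", weights = "numeric", intercept = "numeric",
    featureMeans = "numeric", featureSds = "numeric",
    hyperparameters = "list", trainingMeta = "list"
  )
)

setValidity("SpareModel", function(object) {
  msg <- character()
  if (!object@kind %in% c("BA", "AD"))
    msg <- c(msg, "kind must be 'BA' or 'AD'")
  if (length(object@weights) != length(object@featureMeans) ||
      length(object@weights) != length(object@featureSds))
    msg <- c(msg, "weights and standardization constants disagree in length")
  if (any(object@featureSds <= 0))
    msg <- c(msg, "feature SDs must be > 0")
  if (length(msg)) msg else TRUE
})

#' Years-equivalent brain-aging estimate
#'
#' The group difference in a brain-age index expressed as additional years of
#' aging: the ratio of the group coefficient to the age coefficient from a
#' mixed model of the index on group, age and ICV with a per-scanner random
#' intercept, with a delta-method standard error.
#'
#' @slot years point estimate, years; equals `betaGroup / betaAge` exactly.
#' @slot seYears delta-method SE, years.
#' @slot betaGroup,seGroup,betaAge,seAge the underlying coefficients.
#' @slot n number of subjects in the model.
#' @export
setClass("GapEstimate",
  representation(
    years = "numeric", seYears = "numeric",
    betaGroup = "numeric", seGroup = "numeric",
    betaAge = "numeric", seAge = "numeric", n = "integer"
  )
)

setValidity("GapEstimate", function(object) {
  if (abs(object@years - object@betaGroup / object@betaAge) >
      1e-8 * max(1, abs(object@years)))
    "years must equal betaGroup / betaAge" else TRUE
})
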