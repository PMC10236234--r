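#' Run the full brain-aging analysis pipeline
#'
#' Orchestrates every stage on a synthetic cohort: simulate study and
#' reference cohorts, two-step harmonization into the reference space, train
#' the brain-age index on reference controls and the AD-signature index on a
#' reference subset (by default 256 controls plus the AD cases), score the
#' study sample, then run the association stages — group differences in both
#' indices, the years-equivalent brain-aging statistic, a risk-factor
#' covariate scan with backward elimination among study subjects, the
#' region-wise group scan with FDR control, and cognition-domain
#' associations on simulated cognition.
#'
#' @param config a [SimConfig-class] describing the cohorts.
#' @param outDir optional directory; when given, stage outputs are written as
#'   CSV (with provenance headers) plus a `summary.json` of headline numbers.
#' @param seed integer master seed; stage sub-seeds derive from it
#'   deterministically. Defaults to the config's seed.
#' @param nAdTrainControls reference controls used for signature training.
#' @param computeMetrics forward to the SPARE trainers (cross-validated
#'   accuracy summaries).
#' @return a list with the harmonized cohorts, fitted models, score tables,
#'   association records and a `summary` list (gap years and SE, group
#'   differences, FDR-significant ROI count, retained covariates).
#' @examples
#' \donttest{
#' res <- runPipeline(SimConfig(nStudy = 80, nControl = 30, nReference = 120,
#'                              nAdCases = 40, nRois = 24, nScanners = 4,
#'                              agingOffsetYears = 6, adEffectSd = 1.5,
#'                              seed = 7))
#' res$summary$gap_years
#' }
#' @export
runPipeline <- function(config, outDir = NULL, seed = config@seed,
                        nAdTrainControls = 256L, computeMetrics = TRUE) {
  stopifnot(is(config, "SimConfig"))
  if (!identical(as.integer(seed), config@seed)) {
    cfg <- config
    cfg@seed <- as.integer(seed)
    config <- cfg
  }
  study <- generateCohort(config)
  study <- generateRiskHistories(study, seed = .sub_seed(config@seed, 21L))
  reference <- generateReferenceCohort(config)

  harm <- twoStepHarmonize(study, reference)
  studyH <- harm$study

  refData <- subjectData(reference)
  isRefCtl <- refData$study_label == "reference_control"
  refCtl <- reference[, isRefCtl]
  baModel <- trainSpareBA(refCtl,
                          seed = .sub_seed(config@seed, 22L),
                          computeMetrics = computeMetrics)
  adModel <- NULL
  if (config@nAdCases >= 20L) {
    pick <- which(isRefCtl)[seq_len(min(nAdTrainControls, sum(isRefCtl)))]
    adTrain <- reference[, c(pick, which(!isRefCtl))]
    adModel <- trainSpareAD(adTrain,
                            seed = .sub_seed(config@seed, 23L),
                            computeMetrics = computeMetrics)
  }

  baScores <- scoreSpare(baModel, studyH)
  adScores <- if (!is.null(adModel)) scoreSpare(adModel, studyH) else NULL

  baDiff <- fitGroupDifference(baScores, studyH, outcome = "spare_ba")
  adDiff <- if (!is.null(adScores))
    fitGroupDifference(adScores, studyH, outcome = "spare_ad") else NULL
  gap <- brainAgeGapYears(baScores, studyH)

  sd_ <- subjectData(studyH)
  isStudy <- sd_$group == "study"
  studyOnly <- studyH[, isStudy]
  panel <- summarizeRiskHistories(riskHistories(studyH))
  baStudy <- baScores[match(sd_$subject_id[isStudy], baScores$subject_id), ]
  scanCovs <- c("education", "hba1c_twm", "bmi_twm", "severe_hypo_ever")
  scan <- covariateScan(baStudy, studyOnly, scanCovs, panel = panel,
                        outcome = "spare_ba")
  multi <- backwardEliminate(baStudy, studyOnly,
                             candidates = c("hba1c_twm", "bmi_twm",
                                            "severe_hypo_ever"),
                             panel = panel, outcome = "spare_ba")
  roiScan <- roiGroupScan(studyH)

  cogIdx <- data.frame(subject_id = baScores$subject_id,
                       spare_ba = baScores$score)
  if (!is.null(adScores)) cogIdx$spare_ad <- adScores$score
  else cogIdx$spare_ad <- 0
  cognition <- generateCognition(cogIdx,
                                 seed = .sub_seed(config@seed, 24L))
  cogRecords <- do.call(rbind, lapply(
    setdiff(colnames(cognition), "subject_id"), function(dom)
      cognitionAssociation(cognition, baScores, studyH, dom,
                           indexName = "spare_ba")))

  summary <- list(
    seed = config@seed,
    gap_years = gap@years,
    gap_years_se = gap@seYears,
    spare_ba_group_beta = baDiff$beta,
    spare_ad_group_beta = if (!is.null(adDiff)) adDiff$beta else NA,
    n_fdr_significant_rois = sum(roiScan$q < 0.05),
    retained_covariates = multi$retained)

  res <- list(config = config, study = studyH, reference = reference,
              harmonization = harm[c("step1", "step2")],
              spareBA = baModel, spareAD = adModel,
              baScores = baScores, adScores = adScores,
              groupDifference = rbind(baDiff, adDiff),
              gap = gap, covariateScan = scan, multivariable = multi,
              roiScan = roiScan, cognition = cogRecords,
              summary = summary)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeRoiCohort(studyH, outDir, "study_harmonized", seed = config@seed)
    .write_csv_prov(baScores, file.path(outDir, "spare_ba_scores.csv"),
                    config@seed)
    if (!is.null(adScores))
      .write_csv_prov(adScores, file.path(outDir, "spare_ad_scores.csv"),
                      config@seed)
    .write_csv_prov(rbind(baDiff, adDiff, scan, multi$records, cogRecords),
                    file.path(outDir, "association_records.csv"),
                    config@seed)
    .write_csv_prov(roiScan, file.path(outDir, "roi_group_scan.csv"),
                    config@seed)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
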