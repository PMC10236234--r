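# Small shared fixtures, built once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

quick_config <- function(...) {
  args <- list(...)
  defaults <- list(nStudy = 120L, nControl = 40L, nReference = 200L,
                   nAdCases = 50L, nRois = 30L, nScanners = 4L, seed = 42L)
  do.call(SimConfig, utils::modifyList(defaults, args))
}

# One small accelerated-aging pipeline shared across SPARE tests.
aging_pipeline <- function() {
  fixture("aging_pipeline", function() {
    cfg <- quick_config(nStudy = 150L, nControl = 60L, nReference = 250L,
                        nAdCases = 60L, nRois = 40L,
                        agingOffsetYears = 6, adEffectSd = 1.5, seed = 9L)
    study <- generateCohort(cfg)
    reference <- generateReferenceCohort(cfg)
    harm <- twoStepHarmonize(study, reference)
    refCtl <- reference[, studyLabels(reference) == "reference_control"]
    ba <- trainSpareBA(refCtl, seed = 1L, computeMetrics = FALSE)
    ad <- trainSpareAD(reference, seed = 1L, computeMetrics = FALSE)
    baScores <- scoreSpare(ba, harm$study)
    adScores <- scoreSpare(ad, harm$study)
    list(cfg = cfg, study = harm$study, reference = reference,
         ba = ba, ad = ad, baScores = baScores, adScores = adScores)
  })
}

# Hand-built cohort with exactly linear age trends and near-zero noise.
linear_cohort <- function(n = 200L, nRois = 20L, seed = 5L, label = "reference_control") {
  set.seed(seed)
  age <- runif(n, 44, 74)
  sex <- ifelse(rbinom(n, 1, 0.5) == 1, "male", "female")
  slopes <- seq(-40, -10, length.out = nRois)
  vol <- outer(rep(1, n), seq(8000, 15000, length.out = nRois)) +
    outer(age, slopes) + matrix(rnorm(n * nRois, 0, 1e-6), n, nRois)
  covs <- data.frame(subject_id = sprintf("L%03d", seq_len(n)), age = age,
                     sex = sex, icv = rnorm(n, 1.45e6, 1e5),
                     education = rep(16, n), scanner = "SC01",
                     group = "control", study_label = label,
                     diagnosis = "control")
  RoiCohort(vol, covs)
}
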