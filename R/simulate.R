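#' @importFrom stats rnorm runif rbinom rpois var sd
NULL

# ROI-level generating parameters are drawn once under a fixed internal seed
# so that the deterministic components (baselines, age-trend slopes,
# covariate coefficients, ROI roles) are a function of the ROI count and
# affected fraction only: different user seeds change the stochastic draws
# (subjects, noise, site effects) but not the underlying curves.
.ROI_PARAM_SEED <- 20230601L
.AGE_FLOOR <- 20
.AGE_PLATEAU <- 95
.ICV_MEAN <- 1.45e6
.ICV_SD <- 1.1e5
.ICV_SEX_GAP <- 1.2e5

# Monotone-increasing quadratic ramp with zero slope at the plateau age;
# ROI volume trend is -rate * .age_ramp(age): decline that levels off.
.age_ramp <- function(age) {
  a <- pmin(pmax(age, .AGE_FLOOR), .AGE_PLATEAU) - .AGE_FLOOR
  span <- .AGE_PLATEAU - .AGE_FLOOR
  a - a^2 / (2 * span)
}

.roi_params <- function(nRois, affectedFraction) {
  .with_seed(.ROI_PARAM_SEED, {
    nAff <- round(affectedFraction * nRois)
    ageSensitive <- seq_len(nAff)
    rest <- setdiff(seq_len(nRois), ageSensitive)
    nSig <- max(min(length(rest), 3L), round(0.15 * nRois))
    adSignature <- if (length(rest) >= nSig) rev(rest)[seq_len(nSig)]
      else rest
    if (!length(adSignature))  # degenerate: every ROI age-sensitive
      adSignature <- seq(nRois, by = -1L, length.out = min(3L, nRois))
    rate <- numeric(nRois)
    rate[ageSensitive] <- runif(length(ageSensitive), 20, 80)
    list(
      baseline = runif(nRois, 6000, 20000),
      rate = rate,
      bSex = runif(nRois, 0, 150),
      bIcv = runif(nRois, 5e-4, 3e-3),
      ageSensitive = ageSensitive,
      adSignature = sort(adSignature)
    )
  })
}

# Marginal generating SD of each ROI (noise + covariate + age-trend
# components), used to express the AD-signature effect in SD units.
.roi_marginal_sd <- function(p, config) {
  icvVar <- .ICV_SD^2 + 0.25 * .ICV_SEX_GAP^2
  grid <- seq(config@ageRange[1], config@ageRange[2], length.out = 2001)
  rampVar <- var(.age_ramp(grid))
  sqrt(config@noiseSd^2 + p$bIcv^2 * icvVar + p$bSex^2 * 0.25 +
         p$rate^2 * rampVar)
}

.draw_subjects <- function(n, config, prefix) {
  age <- runif(n, config@ageRange[1], config@ageRange[2])
  sex <- ifelse(rbinom(n, 1L, 0.5) == 1L, "male", "female")
  icv <- rnorm(n, .ICV_MEAN, .ICV_SD) + ifelse(sex == "male", .ICV_SEX_GAP, 0)
  education <- round(rnorm(n, 16, 1.8), 1)
  data.frame(
    subject_id = sprintf("%s%04d", prefix, seq_len(n)),
    age = age, sex = sex, icv = icv, education = education,
    stringsAsFactors = FALSE)
}

# Deterministic part of the volume matrix for a subject table.
.mean_volumes <- function(subj, p, config, offsetOnAffected = FALSE) {
  nRois <- length(p$baseline)
  effAge <- matrix(subj$age, nrow(subj), nRois)
  if (offsetOnAffected && config@agingOffsetYears != 0) {
    isStudy <- subj$group == "study"
    effAge[isStudy, p$ageSensitive] <-
      effAge[isStudy, p$ageSensitive] + config@agingOffsetYears
  }
  trend <- -.age_ramp(effAge) * rep(p$rate, each = nrow(subj))
  male <- as.numeric(subj$sex == "male")
  base <- matrix(p$baseline, nrow(subj), nRois, byrow = TRUE)
  base + trend +
    outer(male - 0.5, p$bSex) +
    outer(subj$icv - .ICV_MEAN, p$bIcv)
}

#' Generate a synthetic multi-scanner study cohort
#'
#' Simulates the study arm plus its demographically similar control arm:
#' subjects-by-ROI gray-matter volumes with nonlinear (quadratic-with-plateau,
#' monotone-decreasing) age trends on age-sensitive ROIs, linear sex and ICV
#' effects, per-scanner additive location shifts and multiplicative noise
#' scale effects, and Gaussian residual noise. Accelerated brain aging in the
#' study group is injected as an *age shift* of `agingOffsetYears` on the
#' age-sensitive ROIs only, so the years-equivalent statistic has a known
#' ground truth in years. Both groups are spread over every scanner
#' (balanced random assignment), keeping group and scanner effects separable.
#'
#' @param config a [SimConfig-class]; identical config yields bit-identical
#'   output.
#' @return a [RoiCohort-class] of `nStudy + nControl` subjects with the
#'   generator ground truth in `metadata(x)$truth`.
#' @examples
#' cohort <- generateCohort(SimConfig(nStudy = 30, nControl = 10,
#'                                    nRois = 12, nScanners = 3))
#' cohort
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  p <- .roi_params(config@nRois, config@affectedRoiFraction)
  .with_seed(.sub_seed(config@seed, 1L), {
    siteShift <- matrix(rnorm(config@nScanners * config@nRois,
                              0, config@siteShiftSd),
                        config@nScanners, config@nRois)
    siteScale <- matrix(exp(rnorm(config@nScanners * config@nRois,
                                  0, config@siteScaleSd)),
                        config@nScanners, config@nRois)
    subj <- rbind(
      cbind(.draw_subjects(config@nStudy, config, "S"), group = "study"),
      cbind(.draw_subjects(config@nControl, config, "C"), group = "control"))
    n <- nrow(subj)
    # balanced random scanner assignment within each group
    scannerPool <- sprintf("SC%02d", seq_len(config@nScanners))
    subj$scanner <- NA_character_
    for (g in c("study", "control")) {
      idx <- which(subj$group == g)
      subj$scanner[idx] <- sample(rep_len(scannerPool, length(idx)))
    }
    mu <- .mean_volumes(subj, p, config, offsetOnAffected = TRUE)
    sc <- match(subj$scanner, scannerPool)
    noise <- matrix(rnorm(n * config@nRois, 0, config@noiseSd),
                    n, config@nRois)
    vol <- mu + siteShift[sc, , drop = FALSE] +
      siteScale[sc, , drop = FALSE] * noise + config@studyShift
    subj$study_label <- subj$group
    subj$diagnosis <- ifelse(subj$group == "study", "T1D", "control")
    RoiCohort(vol, subj,
              truth = list(roiParams = p, siteShift = siteShift,
                           siteScale = siteScale, scannerPool = scannerPool,
                           config = config))
  })
}

#' Generate a synthetic reference cohort for index training
#'
#' Simulates the large pooled reference sample used to train the atrophy
#' indices: `nReference` healthy controls plus `nAdCases` AD-pattern cases
#' carrying `adEffectSd` standard deviations of additional atrophy on a
#' designated AD-signature ROI subset (emulating temporal-lobe regions,
#' disjoint from the age-sensitive set whenever the affected fraction leaves
#' room). The reference cohort lives on a single pooled batch label `"REF"`
#' with no site effects: it defines the harmonization target space.
#'
#' @param config a [SimConfig-class]; ROI-level generating parameters are
#'   shared with [generateCohort()] so study and reference cohorts describe
#'   the same anatomy.
#' @return a [RoiCohort-class] with `study_label` in
#'   `reference_control` / `reference_ad`.
#' @export
generateReferenceCohort <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  p <- .roi_params(config@nRois, config@affectedRoiFraction)
  .with_seed(.sub_seed(config@seed, 2L), {
    subj <- rbind(
      cbind(.draw_subjects(config@nReference, config, "R"),
            study_label = "reference_control", diagnosis = "control"),
      if (config@nAdCases > 0L)
        cbind(.draw_subjects(config@nAdCases, config, "A"),
              study_label = "reference_ad", diagnosis = "AD"))
    subj$group <- "control"
    subj$scanner <- "REF"
    n <- nrow(subj)
    mu <- .mean_volumes(subj, p, config)
    vol <- mu + matrix(rnorm(n * config@nRois, 0, config@noiseSd),
                       n, config@nRois)
    if (config@nAdCases > 0L && config@adEffectSd != 0) {
      sdMarg <- .roi_marginal_sd(p, config)
      isAd <- subj$study_label == "reference_ad"
      for (v in p$adSignature)
        vol[isAd, v] <- vol[isAd, v] - config@adEffectSd * sdMarg[v]
    }
    RoiCohort(vol, subj, truth = list(roiParams = p, config = config))
  })
}

#' Attach longitudinal risk-factor histories to a cohort
#'
#' Gives each subject irregularly spaced visit-level series for quantitative
#' risk factors (random walk anchored at a subject-level mean) and
#' event-count indicators, emulating quarterly-to-annual follow-up records.
#' These are the inputs of [timeWeightedMean()] and friends.
#'
#' @param cohort a [RoiCohort-class].
#' @param seed integer seed for the visit draws.
#' @param quantitative named list; each element a list with fields
#'   `mean_study`, `mean_control`, `sd_between` (subject-level spread) and
#'   `walk_sd` (per-visit random-walk step SD).
#' @param events named list; each element a list with per-visit Poisson rates
#'   `rate_study` and `rate_control`.
#' @param visitsMean mean number of visits per subject (Poisson, min 1).
#' @param followUpYears length of the follow-up window, years.
#' @return the cohort with `metadata(x)$riskHistories` set to a long-format
#'   data.frame (`subject_id`, `covariate`, `time`, `value`), visit times
#'   strictly increasing within subject.
#' @export
generateRiskHistories <- function(cohort, seed = 1L,
    quantitative = list(
      hba1c = list(mean_study = 8, mean_control = 5.4,
                   sd_between = 0.7, walk_sd = 0.3),
      bmi = list(mean_study = 26.6, mean_control = 26.6,
                 sd_between = 3.5, walk_sd = 0.4)),
    events = list(
      severe_hypo = list(rate_study = 0.08, rate_control = 0)),
    visitsMean = 12, followUpYears = 32) {
  stopifnot(is(cohort, "RoiCohort"))
  subj <- subjectData(cohort)
  .with_seed(.sub_seed(seed, 3L), {
    rows <- vector("list", nrow(subj) * (length(quantitative) +
                                           length(events)))
    k <- 0L
    for (i in seq_len(nrow(subj))) {
      nv <- max(1L, rpois(1L, visitsMean))
      times <- sort(runif(nv, 0.25, followUpYears))
      while (anyDuplicated(times))
        times <- sort(times + runif(nv, 0, 1e-6))
      isStudy <- subj$group[i] == "study"
      for (nm in names(quantitative)) {
        q <- quantitative[[nm]]
        m <- rnorm(1L, if (isStudy) q$mean_study else q$mean_control,
                   q$sd_between)
        vals <- m + cumsum(rnorm(nv, 0, q$walk_sd))
        k <- k + 1L
        rows[[k]] <- data.frame(subject_id = subj$subject_id[i],
                                covariate = nm, time = times, value = vals)
      }
      for (nm in names(events)) {
        e <- events[[nm]]
        rate <- if (isStudy) e$rate_study else e$rate_control
        k <- k + 1L
        rows[[k]] <- data.frame(subject_id = subj$subject_id[i],
                                covariate = nm, time = times,
                                value = rpois(nv, rate))
      }
    }
    metadata(cohort)$riskHistories <- do.call(rbind, rows[seq_len(k)])
  })
  cohort
}

#' Simulate cognitive-domain summary scores from atrophy indices
#'
#' Generates per-subject domain z-scores as linear functions of the supplied
#' index scores plus Gaussian noise, emulating cognition correlated with
#' atrophy (worse cognition with higher index values under negative slopes).
#'
#' @param indices data.frame with `subject_id` and one column per index
#'   (e.g. `spare_ba`, `spare_ad`).
#' @param slopes named list: one numeric vector per domain, named by index
#'   column, giving the slope of the domain score on that index.
#' @param noiseSd residual SD of each domain score.
#' @param seed integer seed.
#' @return data.frame with `subject_id` and one column per domain.
#' @export
generateCognition <- function(indices,
    slopes = list(
      psychomotor = c(spare_ba = -0.04, spare_ad = -0.17),
      immediate_memory = c(spare_ad = -0.13),
      delayed_recall = c(spare_ad = -0.11)),
    noiseSd = 0.8, seed = 1L) {
  out <- data.frame(subject_id = indices$subject_id)
  .with_seed(.sub_seed(seed, 4L), {
    for (dom in names(slopes)) {
      s <- slopes[[dom]]
      mu <- rep(0, nrow(indices))
      for (nm in names(s)) {
        if (!nm %in% colnames(indices))
          .stopf("index column '%s' not found for domain '%s'", nm, dom)
        mu <- mu + s[[nm]] * indices[[nm]]
      }
      out[[dom]] <- mu + rnorm(nrow(indices), 0, noiseSd)
    }
  })
  out
}
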