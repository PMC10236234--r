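# gamma-hat oracle: per-batch means of the model-standardized residuals,
# recomputed from the stored model components.
gamma_hat_oracle <- function(model, cohort) {
  cd <- subjectData(cohort)
  Y <- roiVolumes(cohort)
  des <- BrainSpare:::.covariate_design(cd, model@covariates,
                                        smooth = model@smooth,
                                        factorLevels = model@factorLevels)
  sm <- matrix(model@alpha, nrow(Y), ncol(Y), byrow = TRUE) + des$C %*% model@coefC
  s <- (Y - sm) / matrix(model@sigma, nrow(Y), ncol(Y), byrow = TRUE)
  t(vapply(model@batches, function(b)
    colMeans(s[cd[[model@batchKey]] == b, , drop = FALSE]),
    numeric(ncol(Y))))
}

test_that("a single-batch fit is an identity transform", {
  cfg <- quick_config(nStudy = 60L, nControl = 20L, nRois = 10L,
                      nScanners = 1L, seed = 31L)
  co <- generateCohort(cfg)
  m <- fitCombatGam(co)
  h <- applyCombatGam(m, co)
  expect_equal(roiVolumes(h), roiVolumes(co), tolerance = 1e-6)
  expect_true(all(m@gammaStar == 0))
  expect_true(all(m@deltaStar == 1))
})

test_that("null site effects give small location effects and near-identity output", {
  cfg <- quick_config(nStudy = 300L, nControl = 100L, nRois = 30L,
                      nScanners = 2L, siteShiftSd = 0, siteScaleSd = 0,
                      seed = 32L)
  co <- generateCohort(cfg)
  m <- fitCombatGam(co)
  h <- applyCombatGam(m, co)
  expect_lt(max(abs(m@gammaStar)), 0.3)
  relRms <- sqrt(mean((roiVolumes(h) - roiVolumes(co))^2)) /
    sqrt(mean(roiVolumes(co)^2))
  expect_lt(relRms, 0.02)
  # batch-size-weighted mean of location effects is ~0 without a reference
  wmean <- colSums(m@gammaStar * as.numeric(m@nPerBatch)) / sum(m@nPerBatch)
  expect_lt(max(abs(wmean)), 0.05)
})

test_that("injected location and scale effects are removed, matching the oracle", {
  cfg <- quick_config(nStudy = 300L, nControl = 100L, nRois = 20L,
                      nScanners = 2L, siteShiftSd = 0, siteScaleSd = 0,
                      seed = 33L)
  co <- generateCohort(cfg)
  truth <- metadata(co)$truth
  cd <- subjectData(co)
  mu <- BrainSpare:::.mean_volumes(cd, truth$roiParams, cfg)
  vol <- roiVolumes(co)
  onB <- cd$scanner == "SC02"
  vol[onB, ] <- mu[onB, ] + 100 + 2 * (vol[onB, ] - mu[onB, ])
  shifted <- RoiCohort(vol, cd)
  h <- applyCombatGam(fitCombatGam(shifted), shifted)
  res <- adjusted_residuals(h)
  gapAfter <- colMeans(res[onB, ]) - colMeans(res[!onB, ])
  # the injected common +100 mm3 location effect is gone
  expect_lt(abs(mean(gapAfter)), 5)
  sdRatio <- apply(res[onB, ], 2, sd) / apply(res[!onB, ], 2, sd)
  expect_true(all(sdRatio > 0.9 & sdRatio < 1.1))
  # the direct per-batch standardization oracle meets the same bounds, and
  # both remove the same common shift
  oracle <- RoiCohort(standardize_oracle(shifted), cd)
  resO <- adjusted_residuals(oracle)
  gapOracle <- colMeans(resO[onB, ]) - colMeans(resO[!onB, ])
  expect_lt(abs(mean(gapOracle)), 5)
  expect_lt(abs(mean(gapAfter) - mean(gapOracle)), 5)
})

test_that("harmonization is idempotent", {
  cfg <- quick_config(nStudy = 150L, nControl = 50L, nRois = 15L, seed = 34L)
  co <- generateCohort(cfg)
  h1 <- applyCombatGam(fitCombatGam(co), co)
  m2 <- fitCombatGam(h1)
  h2 <- applyCombatGam(m2, h1)
  rel <- (roiVolumes(h2) - roiVolumes(h1)) / roiVolumes(h1)
  expect_lt(sqrt(mean(rel^2)), 1e-3)
})

test_that("identity parameters return the input exactly and batch labels matter", {
  cfg <- quick_config(nStudy = 80L, nControl = 30L, nRois = 8L,
                      nScanners = 2L, seed = 35L)
  co <- generateCohort(cfg)
  m <- fitCombatGam(co)
  mId <- m
  mId@gammaStar[] <- 0
  mId@deltaStar[] <- 1
  h <- applyCombatGam(mId, co)
  expect_equal(roiVolumes(h), roiVolumes(co), tolerance = 1e-12)
  # same raw values under a different batch label harmonize differently
  cd2 <- subjectData(co)
  cd2$scanner <- ifelse(cd2$scanner == "SC01", "SC02", "SC01")
  relabeled <- RoiCohort(roiVolumes(co), cd2)
  hA <- applyCombatGam(m, co)
  hB <- applyCombatGam(m, relabeled)
  expect_gt(max(abs(roiVolumes(hA) - roiVolumes(hB))), 1e-6)
})

test_that("empirical-Bayes shrinkage vanishes as batches grow", {
  gaps <- vapply(c(10L, 100L, 1000L), function(n) {
    cfg <- quick_config(nStudy = as.integer(0.75 * n),
                        nControl = as.integer(0.25 * n),
                        nRois = 20L, nScanners = 2L,
                        seed = 36L)
    co <- generateCohort(cfg)
    # classical location/scale model: the shrinkage property is about the
    # EB step, and tiny batches cannot support the full covariate design
    m <- fitCombatGam(co, covariates = character())
    ghat <- gamma_hat_oracle(m, co)
    mean(abs(m@gammaStar - ghat))
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 0.02)
})

test_that("fit and apply reject malformed inputs informatively", {
  cfg <- quick_config(nStudy = 40L, nControl = 15L, nRois = 8L,
                      nScanners = 2L, seed = 37L)
  co <- generateCohort(cfg)
  # batch with < 3 subjects
  cd <- subjectData(co)
  cd$scanner[1] <- "TINY"
  expect_error(fitCombatGam(RoiCohort(roiVolumes(co), cd)), "TINY")
  # rank-deficient design names the collinear column
  cd2 <- subjectData(co)
  cd2$icv2 <- 2 * cd2$icv
  expect_error(
    fitCombatGam(RoiCohort(roiVolumes(co), cd2),
                 covariates = c("age", "sex", "icv", "icv2")),
    "collinear")
  m <- fitCombatGam(co)
  # unknown batch at apply time
  cd3 <- subjectData(co)
  cd3$scanner[] <- "NEW"
  expect_error(applyCombatGam(m, RoiCohort(roiVolumes(co), cd3)), "NEW")
  # covariate roster mismatch
  cd4 <- subjectData(co)
  cd4$icv <- NULL
  vol4 <- roiVolumes(co)
  expect_error(applyCombatGam(m, RoiCohort(vol4, cd4)), "icv")
})

test_that("two-step harmonization maps study data into the reference space", {
  cfg <- quick_config(nStudy = 250L, nControl = 80L, nReference = 300L,
                      nAdCases = 0L, nRois = 20L, nScanners = 3L,
                      studyShift = 150, seed = 38L)
  study <- generateCohort(cfg)
  reference <- generateReferenceCohort(cfg)
  out <- twoStepHarmonize(study, reference)
  # reference rows pass through bit-identical
  expect_identical(roiVolumes(out$reference), roiVolumes(reference))
  # adjusted study means align with adjusted reference means per ROI
  combined <- BrainSpare:::.combine_cohorts(out$study, reference)
  res <- adjusted_residuals(combined, extra = "")
  isStudy <- subjectData(combined)$cohort_batch == "study"
  ok <- vapply(seq_len(ncol(res)), function(v) {
    d <- mean(res[isStudy, v]) - mean(res[!isStudy, v])
    se <- sqrt(stats::var(res[isStudy, v]) / sum(isStudy) +
                 stats::var(res[!isStudy, v]) / sum(!isStudy))
    abs(d) <= 3 * se
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("two-step harmonization is a near-identity under the null", {
  cfg <- quick_config(nStudy = 200L, nControl = 60L, nReference = 250L,
                      nAdCases = 0L, nRois = 15L, nScanners = 3L,
                      siteShiftSd = 0, siteScaleSd = 0, studyShift = 0,
                      seed = 39L)
  study <- generateCohort(cfg)
  reference <- generateReferenceCohort(cfg)
  out <- twoStepHarmonize(study, reference)
  relRms <- sqrt(mean((roiVolumes(out$study) - roiVolumes(study))^2)) /
    sqrt(mean(roiVolumes(study)^2))
  expect_lt(relRms, 0.02)
})

test_that("harmonization neither misses nor invents scanner effects", {
  cfg <- quick_config(nStudy = 300L, nControl = 100L, nRois = 60L,
                      nScanners = 4L, siteShiftSd = 0, siteScaleSd = 0,
                      seed = 40L)
  co <- generateCohort(cfg)
  scn <- factor(scannerIds(co))
  # generator null really is null: scanner ANOVA p-values uniform pre-harmonization
  pvRaw <- apply(adjusted_residuals(co), 2, function(y)
    summary(stats::aov(y ~ scn))[[1]][["Pr(>F)"]][1])
  expect_gt(stats::ks.test(pvRaw, "punif")$p.value, 0.01)
  h0 <- applyCombatGam(fitCombatGam(co), co)
  pv0 <- apply(adjusted_residuals(h0), 2, function(y)
    summary(stats::aov(y ~ scn))[[1]][["Pr(>F)"]][1])
  expect_lte(mean(pv0 < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / length(pv0)))
  # with real site effects, harmonization removes them
  cfg2 <- quick_config(nStudy = 300L, nControl = 100L, nRois = 60L,
                       nScanners = 4L, seed = 41L)
  co2 <- generateCohort(cfg2)
  scn2 <- factor(scannerIds(co2))
  h2 <- applyCombatGam(fitCombatGam(co2), co2)
  pv2 <- apply(adjusted_residuals(h2), 2, function(y)
    summary(stats::aov(y ~ scn2))[[1]][["Pr(>F)"]][1])
  expect_lte(mean(pv2 < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / length(pv2)))
})

test_that("the fitted age trend survives harmonization", {
  cfg <- quick_config(nStudy = 400L, nControl = 150L, nRois = 20L,
                      nScanners = 4L, seed = 42L)
  co <- generateCohort(cfg)
  h <- applyCombatGam(fitCombatGam(co), co)
  p <- metadata(co)$truth$roiParams
  cd <- subjectData(co)
  # linear probe: slope of volume on age, harmonized vs batch-effect-free
  agev <- cd$age - mean(cd$age)
  for (v in p$ageSensitive[1:5]) {
    free <- p$baseline[v] - p$rate[v] * BrainSpare:::.age_ramp(cd$age)
    slopeFree <- sum(agev * free) / sum(agev^2)
    slopeHarm <- stats::coef(stats::lm(roiVolumes(h)[, v] ~ cd$age +
                                         cd$icv + cd$sex))[2]
    expect_equal(unname(slopeHarm), slopeFree, tolerance = 0.05 * abs(slopeFree) +
                   0.02 * p$rate[v])
  }
  # pooled residual variance close to the generating noise variance
  res <- adjusted_residuals(h)
  expect_equal(mean(apply(res, 2, stats::var)),
               mean(cfg@noiseSd^2 * colMeans(metadata(co)$truth$siteScale^2)),
               tolerance = 0.12)
})

test_that("classical ComBat limit agrees with the sva reference implementation", {
  skip_if_not_installed("sva")
  cfg <- quick_config(nStudy = 120L, nControl = 60L, nRois = 12L,
                      nScanners = 3L, seed = 43L)
  co <- generateCohort(cfg)
  # empty covariate roster reduces the model to classical location/scale ComBat
  m <- fitCombatGam(co, covariates = character())
  h <- applyCombatGam(m, co)
  ref <- t(sva::ComBat(dat = t(roiVolumes(co)),
                       batch = factor(scannerIds(co))))
  expect_equal(unname(roiVolumes(h)), unname(ref), tolerance = 1e-3)
})
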