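# Build a minimal scored cohort without running the imaging stages: a dummy
# 3-ROI volume table carries the covariates; scores are supplied directly.
synthetic_scored_cohort <- function(n = 500L, nScanners = 4L, seed = 61L,
                                    groupEffect = 0, scannerSd = 1,
                                    noiseSd = 3) {
  set.seed(seed)
  grp <- rep(c("study", "control"), times = c(round(0.8 * n), n - round(0.8 * n)))
  cd <- data.frame(
    subject_id = sprintf("P%04d", seq_len(n)),
    age = runif(n, 44, 74),
    sex = sample(c("male", "female"), n, replace = TRUE),
    icv = rnorm(n, 1.45e6, 1.1e5),
    education = round(rnorm(n, 16, 1.8), 1),
    scanner = sample(sprintf("SC%02d", seq_len(nScanners)), n, replace = TRUE),
    group = grp, study_label = grp,
    diagnosis = ifelse(grp == "study", "T1D", "control"))
  scEff <- rnorm(nScanners, 0, scannerSd)
  score <- cd$age + groupEffect * (grp == "study") +
    scEff[match(cd$scanner, sprintf("SC%02d", seq_len(nScanners)))] +
    rnorm(n, 0, noiseSd)
  vol <- matrix(rnorm(n * 3, 8000, 100), n, 3)
  list(cohort = RoiCohort(vol, cd),
       scores = data.frame(subject_id = cd$subject_id, score = score))
}

test_that("BH adjustment matches hand computations and closed forms", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bhFdr(0.2), 0.2)
  expect_equal(bhFdr(rep(0.03, 7)), rep(0.03, 7))
  expect_error(bhFdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bhFdr(c(0.5, 1.2)), "\\(0, 1\\]")
  set.seed(62)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))
    expect_equal(bhFdr(p), stats::p.adjust(p, method = "BH"),
                 tolerance = 1e-14)
  }
})

test_that("group difference recovers an injected additive offset", {
  sim <- synthetic_scored_cohort(n = 500L, groupEffect = 6, seed = 63L)
  rec <- fitGroupDifference(sim$scores, sim$cohort, outcome = "spare_ba")
  expect_lt(abs(rec$beta - 6), 3 * rec$se)
  expect_gt(rec$t, 1.96)
  expect_equal(rec$t, rec$beta / rec$se, tolerance = 1e-8)
  expect_equal(rec$n, 500L)
})

test_that("single-scanner cohorts fall back to fixed effects with a warning", {
  sim <- synthetic_scored_cohort(n = 200L, nScanners = 1L, groupEffect = 6,
                                 seed = 64L)
  expect_warning(rec <- fitGroupDifference(sim$scores, sim$cohort),
                 "single scanner")
  expect_lt(abs(rec$beta - 6), 3 * rec$se)
})

test_that("permuting group labels centers the group effect at zero", {
  sim <- synthetic_scored_cohort(n = 300L, nScanners = 1L, groupEffect = 6,
                                 seed = 65L)
  cd <- subjectData(sim$cohort)
  set.seed(66)
  betas <- replicate(300, {
    cd2 <- cd
    cd2$group <- sample(cd2$group)
    perm <- RoiCohort(roiVolumes(sim$cohort), cd2)
    suppressWarnings(fitGroupDifference(sim$scores, perm)$beta)
  })
  expect_lt(abs(mean(betas)), 3 * sd(betas) / sqrt(length(betas)))
})

test_that("the worked years-equivalent ratio and its delta SE are exact", {
  g <- gapYearsFromCoefficients(6.16, 1.04, seGroup = 0.71, seAge = 0.04)
  expect_equal(gapYears(g), 6.16 / 1.04)
  expect_equal(g@seYears,
               sqrt(0.71^2 / 1.04^2 + 6.16^2 * 0.04^2 / 1.04^4),
               tolerance = 1e-12)
  expect_error(gapYearsFromCoefficients(6.16, -0.2), "positive")
})

test_that("gap estimation recovers a known years offset and ignores ICV units", {
  # score built as slope * (age + offset * study): ratio ground truth = 6
  sim <- synthetic_scored_cohort(n = 500L, groupEffect = 0, seed = 67L)
  cd <- subjectData(sim$cohort)
  sc <- sim$scores
  set.seed(68)
  sc$score <- 0.8 * (cd$age + 6 * (cd$group == "study")) + rnorm(500, 0, 2)
  g <- brainAgeGapYears(sc, sim$cohort)
  expect_lt(abs(gapYears(g) - 6), 3 * g@seYears)
  expect_equal(g@years, g@betaGroup / g@betaAge)
  # affine ICV rescaling leaves the estimate unchanged
  cd2 <- cd
  cd2$icv <- cd2$icv / 1000 + 5
  g2 <- brainAgeGapYears(sc, RoiCohort(roiVolumes(sim$cohort), cd2))
  expect_equal(gapYears(g2), gapYears(g), tolerance = 1e-8)
  # a null group effect stays near zero
  sc0 <- sim$scores
  g0 <- brainAgeGapYears(sc0, sim$cohort)
  expect_lt(abs(gapYears(g0)), 0.5)
})

test_that("covariate scans recover injected slopes and keep input order", {
  sim <- synthetic_scored_cohort(n = 400L, seed = 69L)
  cd <- subjectData(sim$cohort)
  set.seed(70)
  panel <- data.frame(subject_id = cd$subject_id,
                      exposure = rnorm(400, 8, 2),
                      noisevar = rnorm(400),
                      flat = rep(1, 400))
  sc <- sim$scores
  sc$score <- sc$score - 0.25 * panel$exposure
  recs <- covariateScan(sc, sim$cohort, c("exposure", "noisevar", "flat"),
                        panel = panel)
  expect_equal(recs$covariate[1:2], c("exposure", "noisevar"))
  expect_equal(nrow(recs), 3L)
  expect_lt(abs(recs$beta[1] + 0.25), 3 * recs$se[1])
  expect_gt(recs$p[2], 0.001)
  expect_match(recs$note[3], "constant")
  expect_true(is.na(recs$beta[3]))
  # categorical covariates are labelled level vs reference
  panel$cat <- sample(c("0", "1-5", ">5"), 400, replace = TRUE)
  recsCat <- covariateScan(sc, sim$cohort, "cat", panel = panel)
  expect_equal(nrow(recsCat), 2L)
  expect_match(recsCat$covariate[1], "vs 0")
})

test_that("null covariate scans produce uniform p-values", {
  sim <- synthetic_scored_cohort(n = 150L, nScanners = 3L, seed = 71L)
  cd <- subjectData(sim$cohort)
  set.seed(72)
  pvals <- replicate(200, {
    panel <- data.frame(subject_id = cd$subject_id, x = rnorm(150))
    covariateScan(sim$scores, sim$cohort, "x", panel = panel)$p
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("backward elimination keeps forced terms and prunes candidates", {
  sim <- synthetic_scored_cohort(n = 500L, seed = 73L)
  cd <- subjectData(sim$cohort)
  set.seed(74)
  panel <- data.frame(subject_id = cd$subject_id,
                      strong = rnorm(500), null1 = rnorm(500),
                      null2 = rnorm(500), null3 = rnorm(500))
  sc <- sim$scores
  sdScore <- sd(sc$score)
  sc$score <- sc$score + 0.5 * sdScore * panel$strong
  out <- backwardEliminate(sc, sim$cohort,
                           candidates = c("strong", "null1", "null2", "null3"),
                           panel = panel)
  expect_true("strong" %in% out$retained)
  expect_true(all(c("age", "sex") %in% rownames(summary(out$model)$coefficients) |
                    c("age", "sexmale") %in% rownames(summary(out$model)$coefficients)))
  # no candidates: the model is forced covariates only
  out0 <- backwardEliminate(sc, sim$cohort, candidates = character(),
                            panel = panel)
  expect_identical(out0$retained, character(0))
  expect_equal(nrow(out0$records), 0L)
  # collinear candidates are refused by name
  panel$dup <- 2 * panel$strong
  expect_error(backwardEliminate(sc, sim$cohort,
                                 candidates = c("strong", "dup"),
                                 panel = panel),
               "collinear")
})

test_that("all-null candidate sets are usually emptied", {
  sim <- synthetic_scored_cohort(n = 300L, seed = 75L)
  cd <- subjectData(sim$cohort)
  set.seed(76)
  emptied <- replicate(100, {
    panel <- data.frame(subject_id = cd$subject_id,
                        a = rnorm(300), b = rnorm(300), c = rnorm(300))
    out <- backwardEliminate(sim$scores, sim$cohort,
                             candidates = c("a", "b", "c"), panel = panel)
    length(out$retained) == 0
  })
  expect_gte(mean(emptied), 0.85)
})

test_that("the ROI group scan flags affected regions and controls FDR", {
  set.seed(77)
  n <- 500L; nRois <- 100L
  cd <- data.frame(
    subject_id = sprintf("P%04d", 1:n),
    age = runif(n, 44, 74),
    sex = sample(c("male", "female"), n, TRUE),
    icv = rnorm(n, 1.45e6, 1.1e5),
    education = 16,
    scanner = sample(sprintf("SC%02d", 1:4), n, TRUE),
    group = rep(c("study", "control"), each = n / 2))
  cd$study_label <- cd$group
  cd$diagnosis <- ifelse(cd$group == "study", "T1D", "control")
  noise <- 100
  vol <- matrix(rnorm(n * nRois, 8000, noise), n, nRois)
  affected <- 1:10
  d <- 0.5
  vol[cd$group == "study", affected] <-
    vol[cd$group == "study", affected] - d * noise
  co <- RoiCohort(vol, cd)
  recs <- roiGroupScan(co)
  expect_equal(nrow(recs), nRois)
  expect_true(all(recs$q[affected] < 0.05))
  # BH controls the false discovery proportion, not the count exactly
  expect_lte(sum(recs$q[-affected] < 0.05), 2L)
  expect_equal(mean(recs$effect_size[affected]), -d, tolerance = 0.2)
  # q-values equal the package BH rule applied to the scan's p-vector
  expect_equal(recs$q, bhFdr(recs$p), tolerance = 1e-14)
  # null scan: no discoveries
  vol0 <- matrix(rnorm(n * nRois, 8000, noise), n, nRois)
  recs0 <- roiGroupScan(RoiCohort(vol0, cd))
  expect_equal(sum(recs0$q < 0.05), 0L)
})

test_that("domain z-scores standardize, flip and average as specified", {
  tests <- data.frame(subject_id = c("a", "b", "c"),
                      fluency = c(50, 60, NA),
                      pegboard = c(100, 80, 90),
                      recall = c(10, 12, NA))
  refStats <- data.frame(test = c("fluency", "pegboard", "recall"),
                         mean = c(50, 100, 10), sd = c(10, 20, 2))
  domains <- list(efficiency = c("fluency", "pegboard"),
                  memory = "recall")
  expect_message(
    z <- cognitionDomainScores(tests, refStats, domains,
                               higherIsWorse = "pegboard"),
    "partial")
  # subject a: fluency z = 0, pegboard z = 0 (flipped), mean 0
  expect_equal(z$efficiency[1], 0)
  # subject b: fluency z = 1, pegboard z = -(-1) = 1, mean 1
  expect_equal(z$efficiency[2], 1)
  # subject c: fluency missing -> mean of available = pegboard z = 0.5
  expect_equal(z$efficiency[3], 0.5)
  # all tests of a domain missing -> NA
  expect_true(is.na(z$memory[3]))
  expect_equal(z$memory[2], 1)
  expect_error(cognitionDomainScores(tests,
                                     transform(refStats, sd = c(10, 0, 2)),
                                     domains), "> 0")
})

test_that("cognition associations recover the generating slope", {
  sim <- synthetic_scored_cohort(n = 400L, seed = 78L)
  idx <- data.frame(subject_id = sim$scores$subject_id,
                    spare_ba = sim$scores$score)
  cog <- generateCognition(idx,
                           slopes = list(psychomotor = c(spare_ba = -0.04)),
                           noiseSd = 0.5, seed = 3L)
  rec <- cognitionAssociation(cog, sim$scores, sim$cohort, "psychomotor",
                              indexName = "spare_ba")
  expect_lt(abs(rec$beta + 0.04), 3 * rec$se)
  rec2 <- cognitionAssociation(cog, sim$scores, sim$cohort, "psychomotor",
                               indexName = "spare_ba")
  expect_identical(rec, rec2)
})
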