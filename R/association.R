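#' @importFrom stats lm model.matrix pt coef vcov complete.cases nobs
NULL

# One tidy association record; q is filled only by FDR scans.
.record <- function(outcome, covariate, beta, se, t, p, n, note = NA_character_) {
  data.frame(outcome = outcome, covariate = covariate, beta = beta, se = se,
             t = t, p = p, q = NA_real_, n = n, note = note,
             stringsAsFactors = FALSE)
}

# Pulls one coefficient row out of an lm / lmerTest fit.
.coef_record <- function(fit, term, outcome, covariate) {
  sm <- summary(fit)$coefficients
  if (!term %in% rownames(sm))
    .stopf("term '%s' absent from the fitted model", term)
  est <- sm[term, "Estimate"]
  se <- sm[term, "Std. Error"]
  tv <- sm[term, grep("^t value$", colnames(sm))]
  pv <- sm[term, grep("^Pr", colnames(sm))]
  .record(outcome, covariate, est, se, tv, pv, nobs(fit))
}

.score_frame <- function(scores, cohort) {
  cd <- subjectData(cohort)
  m <- match(cd$subject_id, scores$subject_id)
  if (anyNA(m)) .stopf("scores missing for %d subject(s)", sum(is.na(m)))
  # ICV is standardized internally for numerical stability of the mixed
  # models; the years-equivalent ratio is invariant to this affine rescaling.
  df <- data.frame(
    score = scores$score[m],
    group = factor(cd$group, levels = c("control", "study")),
    age = cd$age,
    sex = factor(cd$sex, levels = c("female", "male")),
    icv = as.numeric(scale(cd$icv)),
    education = cd$education,
    scanner = factor(cd$scanner),
    subject_id = cd$subject_id,
    stringsAsFactors = FALSE)
  df
}

#' Group difference in an atrophy index
#'
#' Estimates the study-vs-control mean difference in an index with a linear
#' mixed model `score ~ group + age + sex + (1 | scanner)`. With a single
#' scanner the model falls back to fixed effects with a warning.
#'
#' @param scores data.frame (`subject_id`, `score`), e.g. from
#'   [scoreSpare()].
#' @param cohort a [RoiCohort-class] containing both groups.
#' @param outcome label used in the returned record.
#' @return a one-row association record (data.frame with `beta`, `se`, `t`,
#'   `p`, `n`) for the group term (study minus control).
#' @export
fitGroupDifference <- function(scores, cohort, outcome = "score") {
  df <- .score_frame(scores, cohort)
  if (nlevels(droplevels(df$group)) < 2L)
    .stopf("both study and control subjects are required")
  if (nlevels(droplevels(df$scanner)) > 1L) {
    fit <- lmerTest::lmer(score ~ group + age + sex + (1 | scanner),
                          data = df)
  } else {
    .warnf("single scanner: falling back to a fixed-effects model")
    fit <- lm(score ~ group + age + sex, data = df)
  }
  .coef_record(fit, "groupstudy", outcome, "group (study vs control)")
}

#' Years-equivalent brain aging from model coefficients
#'
#' Expresses a group difference in a brain-age index as additional years of
#' aging by taking the ratio of the group coefficient to the age coefficient,
#' with a delta-method standard error when the coefficient SEs are supplied.
#'
#' @param betaGroup,betaAge model coefficients (index units; index units per
#'   year).
#' @param seGroup,seAge their standard errors (optional).
#' @param covGroupAge sampling covariance of the two coefficients.
#' @param n number of subjects behind the coefficients (optional).
#' @return a [GapEstimate-class].
#' @examples
#' gapYearsFromCoefficients(6.16, 1.04)  # about 6 years
#' @export
gapYearsFromCoefficients <- function(betaGroup, betaAge,
                                     seGroup = NA_real_, seAge = NA_real_,
                                     covGroupAge = 0, n = NA_integer_) {
  if (betaAge <= 0)
    .stopf("age coefficient must be positive; years-equivalent undefined")
  years <- betaGroup / betaAge
  seYears <- if (is.na(seGroup) || is.na(seAge)) NA_real_ else
    sqrt(seGroup^2 / betaAge^2 + betaGroup^2 * seAge^2 / betaAge^4 -
           2 * betaGroup * covGroupAge / betaAge^3)
  new("GapEstimate", years = years, seYears = seYears,
      betaGroup = betaGroup, seGroup = seGroup,
      betaAge = betaAge, seAge = seAge, n = as.integer(n))
}

#' Years-equivalent brain aging of a cohort
#'
#' Fits the mixed model `score ~ group + age + icv + (1 | scanner)` to
#' brain-age index scores and returns the group coefficient divided by the
#' age coefficient: the additional years of age that would produce the same
#' index difference as study-group membership. Invariant to affine rescaling
#' of the ICV units.
#'
#' @inheritParams fitGroupDifference
#' @return a [GapEstimate-class].
#' @export
brainAgeGapYears <- function(scores, cohort) {
  df <- .score_frame(scores, cohort)
  if (nlevels(droplevels(df$group)) < 2L)
    .stopf("both study and control subjects are required")
  if (nlevels(droplevels(df$scanner)) > 1L) {
    fit <- lmerTest::lmer(score ~ group + age + icv + (1 | scanner),
                          data = df)
    fe <- lme4::fixef(fit)
    Vf <- as.matrix(vcov(fit))
  } else {
    .warnf("single scanner: falling back to a fixed-effects model")
    fit <- lm(score ~ group + age + icv, data = df)
    fe <- coef(fit)
    Vf <- vcov(fit)
  }
  g <- fe[["groupstudy"]]; a <- fe[["age"]]
  if (a <= 0)
    .stopf("estimated age coefficient is <= 0 (%.3g); degenerate brain-age model",
           a)
  gapYearsFromCoefficients(
    g, a,
    seGroup = sqrt(Vf["groupstudy", "groupstudy"]),
    seAge = sqrt(Vf["age", "age"]),
    covGroupAge = Vf["groupstudy", "age"],
    n = nobs(fit))
}

.panel_frame <- function(scores, cohort, panel = NULL) {
  df <- .score_frame(scores, cohort)
  if (!is.null(panel)) {
    m <- match(df$subject_id, panel$subject_id)
    for (nm in setdiff(colnames(panel), "subject_id"))
      df[[nm]] <- panel[[nm]][m]
  }
  df
}

#' Per-covariate association scan
#'
#' Fits one linear model per covariate of interest,
#' `score ~ covariate + age + sex + scanner` (scanner as fixed effects), and
#' returns the covariate term of each: the single-covariate scan behind
#' risk-factor tables. Categorical covariates contribute one record per
#' non-reference level. Constant covariates are flagged, not fitted.
#'
#' @inheritParams fitGroupDifference
#' @param covariates character vector of covariate names to scan.
#' @param panel optional wide per-subject data.frame (`subject_id` + summary
#'   columns, e.g. from [summarizeRiskHistories()]) providing covariates not
#'   in the cohort's colData.
#' @return data.frame of association records, in input covariate order.
#' @export
covariateScan <- function(scores, cohort, covariates, panel = NULL,
                          outcome = "score") {
  df <- .panel_frame(scores, cohort, panel)
  useScanner <- nlevels(droplevels(df$scanner)) > 1L
  out <- list()
  for (nm in covariates) {
    if (!nm %in% colnames(df))
      .stopf("covariate '%s' not found in cohort or panel", nm)
    x <- df[[nm]]
    if (length(unique(x[!is.na(x)])) < 2L) {
      out[[nm]] <- .record(outcome, nm, NA_real_, NA_real_, NA_real_,
                           NA_real_, sum(!is.na(x)),
                           note = "constant covariate; not fitted")
      next
    }
    if (is.character(x)) df[[nm]] <- factor(x)
    fml <- stats::as.formula(paste("score ~", nm, "+ age + sex",
                                   if (useScanner) "+ scanner" else ""))
    fit <- lm(fml, data = df)
    sm <- summary(fit)$coefficients
    terms_nm <- grep(paste0("^", nm), rownames(sm), value = TRUE)
    recs <- lapply(terms_nm, function(tt) {
      lev <- sub(paste0("^", nm), "", tt)
      label <- if (nzchar(lev)) sprintf("%s (%s vs %s)", nm, lev,
                                        levels(df[[nm]])[1]) else nm
      .coef_record(fit, tt, outcome, label)
    })
    out[[nm]] <- do.call(rbind, recs)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Backward elimination for a multivariable model
#'
#' Starting from a joint model of all candidate covariates plus the forced
#' adjustment set (age, sex, scanner), iteratively removes the least
#' significant candidate with `p >= pRemove` (refit after every removal)
#' until all candidates pass, then drops candidates with `p >= pFinal` and
#' refits once. Forced covariates are never removed.
#'
#' @inheritParams covariateScan
#' @param candidates character vector of candidate covariate names
#'   (numeric or 2-level).
#' @param pRemove stepwise retention threshold (default 0.10).
#' @param pFinal final retention threshold (default 0.05).
#' @return list with `records` (association records of retained candidates
#'   from the final fit), `retained`, `eliminated`, and the final `model`.
#' @export
backwardEliminate <- function(scores, cohort, candidates, panel = NULL,
                              pRemove = 0.10, pFinal = 0.05,
                              outcome = "score") {
  df <- .panel_frame(scores, cohort, panel)
  for (nm in candidates) {
    if (!nm %in% colnames(df))
      .stopf("candidate '%s' not found in cohort or panel", nm)
    if (is.character(df[[nm]]) || is.factor(df[[nm]])) {
      f <- factor(df[[nm]])
      if (nlevels(f) != 2L)
        .stopf("candidate '%s' must be numeric or 2-level", nm)
      df[[nm]] <- as.numeric(f) - 1
    }
  }
  keep <- complete.cases(df[, c("score", "age", "sex", candidates),
                            drop = FALSE])
  df <- df[keep, , drop = FALSE]
  cmat <- as.matrix(df[, candidates, drop = FALSE])
  qrc <- qr(cbind(1, scale(cmat, scale = FALSE)))
  if (qrc$rank < ncol(cmat) + 1L) {
    bad <- candidates[qrc$pivot[seq(qrc$rank + 1L, ncol(cmat) + 1L)] - 1L]
    .stopf("collinear candidate set: %s", paste(bad, collapse = ", "))
  }
  useScanner <- nlevels(droplevels(df$scanner)) > 1L
  forced <- paste("age + sex", if (useScanner) "+ scanner" else "")
  fit_with <- function(cands) {
    rhs <- paste(c(cands, forced), collapse = " + ")
    lm(stats::as.formula(paste("score ~", rhs)), data = df)
  }
  cand_p <- function(fit, cands) {
    sm <- summary(fit)$coefficients
    vapply(cands, function(nm) sm[nm, "Pr(>|t|)"], numeric(1))
  }
  current <- candidates
  eliminated <- character()
  while (length(current)) {
    fit <- fit_with(current)
    p <- cand_p(fit, current)
    if (all(p < pRemove)) break
    worst <- max(p)
    # ties: drop the lexicographically first among the worst
    drop_nm <- sort(names(p)[p == worst])[1L]
    eliminated <- c(eliminated, drop_nm)
    current <- setdiff(current, drop_nm)
  }
  if (length(current)) {
    fit <- fit_with(current)
    p <- cand_p(fit, current)
    late <- names(p)[p >= pFinal]
    if (length(late)) {
      eliminated <- c(eliminated, late)
      current <- setdiff(current, late)
    }
  }
  fit <- fit_with(current)
  records <- if (length(current))
    do.call(rbind, lapply(current, function(nm)
      .coef_record(fit, nm, outcome, nm)))
  else
    .record("x", "x", NA_real_, NA_real_, NA_real_, NA_real_, 0L)[0, ]
  list(records = records, retained = current, eliminated = eliminated,
       model = fit)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' `q_i = min over {j : p_j >= p_i} of m * p_j / rank_j`, with monotone
#' enforcement from the largest p down; ties share ranks by stable sort
#' order.
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @return numeric vector of q-values, same length and order.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bhFdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1))
    .stopf("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p)
  qs <- m * p[o] / seq_len(m)
  qs <- rev(cummin(rev(qs)))
  q <- numeric(m)
  q[o] <- qs
  q
}

#' Region-wise group scan with FDR control
#'
#' Fits, per ROI, the linear model
#' `volume ~ group + age + sex + icv + scanner` on harmonized volumes and
#' returns the group term with a standardized effect size (beta divided by
#' the ROI residual SD) and Benjamini-Hochberg q-values across ROIs.
#'
#' @param cohort a harmonized [RoiCohort-class] with both groups.
#' @param useIcv include ICV in the adjustment set.
#' @return data.frame of per-ROI association records with columns `beta`,
#'   `se`, `t`, `p`, `q` and `effect_size`, one row per ROI in table order.
#' @export
roiGroupScan <- function(cohort, useIcv = TRUE) {
  cd <- subjectData(cohort)
  Y <- roiVolumes(cohort)
  df <- data.frame(
    group = factor(cd$group, levels = c("control", "study")),
    age = cd$age, sex = factor(cd$sex, levels = c("female", "male")),
    icv = cd$icv, scanner = factor(cd$scanner))
  if (nlevels(droplevels(df$group)) < 2L)
    .stopf("both study and control subjects are required")
  fml <- ~ group + age + sex + scanner
  if (useIcv) fml <- ~ group + age + sex + icv + scanner
  if (nlevels(droplevels(df$scanner)) < 2L)
    fml <- stats::update.formula(fml, . ~ . - scanner)
  X <- model.matrix(fml, df)
  qx <- qr(X)
  if (qx$rank < ncol(X)) .stopf("rank-deficient scan design")
  coefs <- qr.coef(qx, Y)
  resid <- qr.resid(qx, Y)
  dfres <- nrow(X) - qx$rank
  sigma2 <- colSums(resid^2) / dfres
  XtXinv <- chol2inv(chol(crossprod(X)))
  gi <- which(colnames(X) == "groupstudy")
  XtXinv_g <- XtXinv[gi, gi]
  beta <- coefs["groupstudy", ]
  se <- sqrt(sigma2 * XtXinv_g)
  tv <- beta / se
  pv <- 2 * pt(-abs(tv), dfres)
  rec <- .record("roi_volume", colnames(Y), beta, se, tv, pv, nrow(X))
  rec$q <- bhFdr(pv)
  rec$effect_size <- beta / sqrt(sigma2)
  rec
}

#' Cognitive domain z-scores
#'
#' Standardizes each raw test score against reference statistics
#' (`z = (score - ref_mean) / ref_sd`, sign-flipped for tests where a higher
#' raw score means worse performance, e.g. timed tests) and averages the
#' z-scores within each domain with equal weights. Subjects missing some
#' tests of a domain get the mean of the available ones (flagged via a
#' message); subjects missing all tests get `NA`.
#'
#' @param tests data.frame: `subject_id` plus one column per raw test score.
#' @param referenceStats data.frame with columns `test`, `mean`, `sd`
#'   (all `sd > 0`).
#' @param domains named list mapping each domain to its test columns.
#' @param higherIsWorse character vector of tests whose z-scores are
#'   sign-flipped.
#' @return data.frame: `subject_id` plus one z-score column per domain.
#' @export
cognitionDomainScores <- function(tests, referenceStats, domains,
                                  higherIsWorse = character()) {
  stopifnot(all(c("test", "mean", "sd") %in% colnames(referenceStats)))
  if (any(referenceStats$sd <= 0)) .stopf("reference SDs must be > 0")
  z <- data.frame(subject_id = tests$subject_id)
  for (tn in referenceStats$test) {
    if (!tn %in% colnames(tests))
      .stopf("test '%s' missing from the score table", tn)
    i <- match(tn, referenceStats$test)
    zi <- (tests[[tn]] - referenceStats$mean[i]) / referenceStats$sd[i]
    if (tn %in% higherIsWorse) zi <- -zi
    z[[tn]] <- zi
  }
  out <- data.frame(subject_id = tests$subject_id)
  for (dom in names(domains)) {
    cols <- domains[[dom]]
    missing_tests <- setdiff(cols, colnames(z))
    if (length(missing_tests))
      .stopf("domain '%s' refers to unknown test(s): %s", dom,
             paste(missing_tests, collapse = ", "))
    zm <- as.matrix(z[, cols, drop = FALSE])
    nAvail <- rowSums(!is.na(zm))
    partial <- nAvail > 0 & nAvail < length(cols)
    if (any(partial))
      message(sum(partial), " subject(s) scored domain '", dom,
              "' from a partial test set")
    val <- rowMeans(zm, na.rm = TRUE)
    val[nAvail == 0] <- NA_real_
    out[[dom]] <- val
  }
  out
}

#' Association of an atrophy index with a cognitive domain
#'
#' Fits `domain ~ index + age + sex + education + scanner` and returns the
#' index term: the change in domain z-score per unit of the index.
#'
#' @param domainScores data.frame (`subject_id` + domain columns), e.g. from
#'   [cognitionDomainScores()] or [generateCognition()].
#' @param indexScores data.frame (`subject_id`, `score`).
#' @param cohort a [RoiCohort-class] providing age, sex, education, scanner.
#' @param domain which domain column to model.
#' @param indexName label for the returned record.
#' @return a one-row association record for the index term.
#' @export
cognitionAssociation <- function(domainScores, indexScores, cohort,
                                 domain, indexName = "index") {
  df <- .score_frame(indexScores, cohort)
  names(df)[names(df) == "score"] <- "index"
  m <- match(df$subject_id, domainScores$subject_id)
  df$domain <- domainScores[[domain]][m]
  if (anyNA(df$education)) .stopf("education missing for some subjects")
  df <- df[!is.na(df$domain), , drop = FALSE]
  useScanner <- nlevels(droplevels(df$scanner)) > 1L
  fml <- stats::as.formula(paste("domain ~ index + age + sex + education",
                                 if (useScanner) "+ scanner" else ""))
  fit <- lm(fml, data = df)
  .coef_record(fit, "index", domain, indexName)
}
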