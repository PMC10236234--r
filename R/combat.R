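#' @importFrom stats var
NULL

# ---- covariate design -------------------------------------------------------

# Reference levels a practitioner expects: effects are expressed against
# female sex and control diagnosis, matching "male vs female" rows in
# covariate tables.
.relevel_covariate <- function(x, name) {
  x <- as.character(x)
  lev <- sort(unique(x))
  pref <- switch(name, sex = "female", diagnosis = "control", group = "control",
                 NULL)
  if (!is.null(pref) && pref %in% lev) lev <- c(pref, setdiff(lev, pref))
  factor(x, levels = lev)
}

# Builds the covariate block of the design matrix (no intercept): the
# penalized age spline basis plus linear/one-hot terms for the rest.
.covariate_design <- function(data, covariates, smooth = NULL,
                              factorLevels = NULL, splineK = 10) {
  cols <- list()
  penalty_idx <- integer()
  newSmooth <- smooth
  newLevels <- if (is.null(factorLevels)) list() else factorLevels
  for (nm in covariates) {
    if (!nm %in% colnames(data))
      .stopf("covariate '%s' is missing from the covariate table", nm)
    x <- data[[nm]]
    if (nm == "age") {
      if (is.null(smooth)) {
        kUse <- max(4L, min(splineK, length(unique(as.numeric(x))) - 1L))
        newSmooth <- mgcv::smoothCon(
          mgcv::s(age, k = kUse, bs = "cr"),
          data = data.frame(age = as.numeric(x)), absorb.cons = TRUE)[[1]]
        B <- newSmooth$X
      } else {
        B <- mgcv::PredictMat(smooth, data.frame(age = as.numeric(x)))
      }
      colnames(B) <- sprintf("age.s%02d", seq_len(ncol(B)))
      cols[[nm]] <- B
    } else if (is.numeric(x)) {
      cols[[nm]] <- matrix(as.numeric(x), ncol = 1,
                           dimnames = list(NULL, nm))
    } else {
      if (!is.null(factorLevels) && nm %in% names(factorLevels)) {
        bad <- setdiff(unique(as.character(x)), factorLevels[[nm]])
        if (length(bad))
          .stopf("covariate '%s' has level(s) unseen at fit time: %s",
                 nm, paste(bad, collapse = ", "))
        f <- factor(as.character(x), levels = factorLevels[[nm]])
      } else {
        f <- .relevel_covariate(x, nm)
        newLevels[[nm]] <- levels(f)
      }
      if (nlevels(f) > 1L) {
        mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(nm, substring(colnames(mm), 2))
        cols[[nm]] <- mm
      }
    }
  }
  C <- if (length(cols)) do.call(cbind, cols) else
    matrix(0, nrow(data), 0)
  splineCols <- if ("age" %in% names(cols)) {
    before <- if (which(names(cols) == "age") > 1)
      sum(vapply(cols[seq_len(which(names(cols) == "age") - 1)], ncol, 1L))
    else 0L
    before + seq_len(ncol(cols[["age"]]))
  } else integer()
  list(C = C, smooth = newSmooth, factorLevels = newLevels,
       splineCols = splineCols)
}

# ---- penalized pooled fit ---------------------------------------------------

# Per-ROI penalized least squares with the smoothing parameter chosen by
# generalized cross-validation on a log grid; only the spline block is
# penalized, so batch dummies and linear covariates stay unbiased and the
# residuals are exactly orthogonal to the batch indicators.
.penalized_fit <- function(X, Y, splineCols, S0,
                           lambdaGrid = 10^seq(-4, 8, length.out = 40)) {
  n <- nrow(X); p <- ncol(X); V <- ncol(Y)
  XtX <- crossprod(X)
  XtY <- crossprod(X, Y)
  if (!length(splineCols)) lambdaGrid <- 0
  S <- matrix(0, p, p)
  if (length(splineCols)) S[splineCols, splineCols] <- S0
  bestGcv <- rep(Inf, V)
  bestIdx <- rep(1L, V)
  coefs <- vector("list", length(lambdaGrid))
  yty <- colSums(Y^2)
  for (j in seq_along(lambdaGrid)) {
    A <- XtX + lambdaGrid[j] * S
    R <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(R)) { coefs[[j]] <- NULL; next }
    coef <- backsolve(R, forwardsolve(t(R), XtY))
    coefs[[j]] <- coef
    edf <- sum(diag(backsolve(R, forwardsolve(t(R), XtX))))
    rss <- pmax(yty - 2 * colSums(coef * XtY) +
                  colSums(coef * (XtX %*% coef)), 0)
    gcv <- n * rss / (n - edf)^2
    upd <- gcv < bestGcv
    bestGcv[upd] <- gcv[upd]
    bestIdx[upd] <- j
  }
  coef <- matrix(0, p, V, dimnames = list(colnames(X), colnames(Y)))
  for (j in unique(bestIdx)) {
    sel <- bestIdx == j
    coef[, sel] <- coefs[[j]][, sel, drop = FALSE]
  }
  list(coef = coef, lambda = lambdaGrid[bestIdx])
}

# ---- empirical Bayes --------------------------------------------------------

.aprior <- function(d2) { m <- mean(d2); s2 <- var(d2); (2 * s2 + m^2) / s2 }
.bprior <- function(d2) { m <- mean(d2); s2 <- var(d2); (m * s2 + m^3) / s2 }

# Parametric empirical-Bayes shrinkage of per-batch location/scale effects:
# normal prior on gamma, inverse-gamma prior on delta^2, prior moments from
# the spread across ROIs within the batch, iterated to convergence.
.eb_shrink <- function(sdat, batchIdx, gammaHat, delta2Hat,
                       tol = 1e-4, maxIter = 100L) {
  B <- nrow(gammaHat); V <- ncol(gammaHat)
  gammaStar <- gammaHat
  delta2Star <- delta2Hat
  for (b in seq_len(B)) {
    rows <- batchIdx[[b]]
    nb <- length(rows)
    ghat <- gammaHat[b, ]
    d2hat <- delta2Hat[b, ]
    gbar <- mean(ghat)
    t2 <- var(ghat)
    a <- .aprior(d2hat); bp <- .bprior(d2hat)
    g <- ghat; d2 <- d2hat
    change <- Inf
    it <- 0L
    sb <- sdat[rows, , drop = FALSE]
    while (change > tol) {
      it <- it + 1L
      if (it > maxIter)
        .stopf(paste0("empirical-Bayes shrinkage did not converge in %d ",
                      "iterations (last relative change %.3g)"),
               maxIter, change)
      gNew <- (nb * t2 * ghat + d2 * gbar) / (nb * t2 + d2)
      ss <- colSums((sb - matrix(gNew, nb, V, byrow = TRUE))^2)
      d2New <- (bp + 0.5 * ss) / (nb / 2 + a - 1)
      change <- max(abs(gNew - g) / (abs(g) + tol),
                    abs(d2New - d2) / (abs(d2) + tol))
      g <- gNew; d2 <- d2New
    }
    gammaStar[b, ] <- g
    delta2Star[b, ] <- d2
  }
  list(gammaStar = gammaStar, deltaStar = sqrt(delta2Star))
}

# ---- fit / apply ------------------------------------------------------------

#' Fit a ComBat-GAM harmonization model
#'
#' Pools ROI volumes across batches to fit, per ROI, a covariate model with a
#' penalized cubic-regression-spline age trend (smoothness by generalized
#' cross-validation) plus linear terms for the remaining covariates, then
#' estimates per-batch location and scale effects on the standardized
#' residuals and shrinks them by parametric empirical Bayes (normal prior on
#' location, inverse-gamma on scale, prior moments across ROIs within batch,
#' iterated to convergence). With a `referenceBatch`, standardization is
#' anchored at that batch and its effects are fixed at location 0 / scale 1,
#' so applying the model leaves the reference batch unchanged and maps every
#' other batch into its space.
#'
#' @param cohort a [RoiCohort-class] with volumes and covariates.
#' @param batchKey name of the colData column holding the batch label.
#' @param covariates character roster of covariates whose effects must be
#'   preserved (an `"age"` entry gets the spline; factors are one-hot with
#'   control-type reference levels). May be empty, giving classical ComBat
#'   location/scale adjustment with no covariate model.
#' @param referenceBatch optional batch label to harmonize towards.
#' @param splineK number of spline basis functions for the age trend.
#' @param lambdaGrid smoothing-parameter grid searched by GCV.
#' @param ebTol,ebMaxIter empirical-Bayes convergence tolerance (relative
#'   change in the shrunk effects) and iteration cap.
#' @return a [CombatModel-class].
#' @examples
#' cfg <- SimConfig(nStudy = 60, nControl = 20, nRois = 10, nScanners = 3,
#'                  seed = 2)
#' cohort <- generateCohort(cfg)
#' fit <- fitCombatGam(cohort)
#' fit
#' @export
fitCombatGam <- function(cohort, batchKey = "scanner",
                         covariates = c("age", "sex", "icv", "diagnosis"),
                         referenceBatch = NULL, splineK = 10,
                         lambdaGrid = 10^seq(-4, 8, length.out = 40),
                         ebTol = 1e-4, ebMaxIter = 100L) {
  stopifnot(is(cohort, "RoiCohort"))
  cd <- subjectData(cohort)
  if (!batchKey %in% colnames(cd))
    .stopf("batch column '%s' not found", batchKey)
  Y <- roiVolumes(cohort)
  # complete-case handling for missing covariates
  if (length(covariates)) {
    cc <- stats::complete.cases(cd[, covariates, drop = FALSE])
    if (!all(cc)) {
      message(sum(!cc), " subject(s) dropped for missing covariates")
      cd <- cd[cc, , drop = FALSE]
      Y <- Y[cc, , drop = FALSE]
    }
  }
  batch <- factor(as.character(cd[[batchKey]]))
  nPerBatch <- as.integer(table(batch))
  names(nPerBatch) <- levels(batch)
  if (any(nPerBatch < 3L))
    .stopf("each batch needs >= 3 subjects; too small: %s",
           paste(levels(batch)[nPerBatch < 3L], collapse = ", "))
  if (!is.null(referenceBatch) && !referenceBatch %in% levels(batch))
    .stopf("reference batch '%s' not present in the data", referenceBatch)

  des <- .covariate_design(cd, covariates, splineK = splineK)
  Zb <- vapply(levels(batch), function(b) as.numeric(batch == b),
               numeric(length(batch)))
  X <- cbind(Zb, des$C)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    .stopf("design is rank deficient; collinear column(s): %s",
           paste(bad, collapse = ", "))
  }
  splineCols <- if (length(des$splineCols)) ncol(Zb) + des$splineCols
    else integer()
  S0 <- if (length(splineCols)) des$smooth$S[[1]] else NULL
  fit <- .penalized_fit(X, Y, splineCols, S0, lambdaGrid)
  coefB <- fit$coef[seq_len(ncol(Zb)), , drop = FALSE]
  coefC <- fit$coef[-seq_len(ncol(Zb)), , drop = FALSE]
  resid <- Y - X %*% fit$coef

  if (is.null(referenceBatch)) {
    alpha <- drop(crossprod(coefB, nPerBatch / sum(nPerBatch)))
    varPooled <- colMeans(resid^2)
  } else {
    alpha <- coefB[referenceBatch, ]
    refRows <- batch == referenceBatch
    varPooled <- colMeans(resid[refRows, , drop = FALSE]^2)
  }
  sigma <- sqrt(pmax(varPooled, 1e-12))
  standMean <- matrix(alpha, nrow(Y), ncol(Y), byrow = TRUE) +
    des$C %*% coefC
  sdat <- (Y - standMean) / matrix(sigma, nrow(Y), ncol(Y), byrow = TRUE)
  batchIdx <- lapply(levels(batch), function(b) which(batch == b))
  gammaHat <- do.call(rbind, lapply(batchIdx, function(ix)
    colMeans(sdat[ix, , drop = FALSE])))
  delta2Hat <- do.call(rbind, lapply(batchIdx, function(ix)
    apply(sdat[ix, , drop = FALSE], 2, var)))
  dimnames(gammaHat) <- dimnames(delta2Hat) <-
    list(levels(batch), colnames(Y))
  if (nlevels(batch) == 1L) {
    # single batch: identity model
    eb <- list(gammaStar = gammaHat * 0,
               deltaStar = delta2Hat * 0 + 1)
  } else if (ncol(Y) < 4L) {
    # too few ROIs to estimate cross-ROI prior moments: no shrinkage
    eb <- list(gammaStar = gammaHat, deltaStar = sqrt(delta2Hat))
  } else {
    eb <- .eb_shrink(sdat, batchIdx, gammaHat, delta2Hat,
                     tol = ebTol, maxIter = ebMaxIter)
  }
  gammaStar <- eb$gammaStar
  deltaStar <- eb$deltaStar
  if (!is.null(referenceBatch)) {
    gammaStar <- sweep(gammaStar, 2, gammaStar[referenceBatch, ], "-")
    deltaStar <- sweep(deltaStar, 2, deltaStar[referenceBatch, ], "/")
  }
  sm <- des$smooth
  if (!is.null(sm)) sm$X <- NULL  # drop the training basis, keep the spec
  new("CombatModel",
      alpha = alpha, coefC = coefC, sigma = sigma,
      gammaStar = gammaStar, deltaStar = deltaStar,
      smooth = sm, covariates = as.character(covariates),
      factorLevels = des$factorLevels,
      batches = levels(batch), nPerBatch = nPerBatch,
      referenceBatch = if (is.null(referenceBatch)) character()
        else referenceBatch,
      ageRange = if ("age" %in% covariates)
        range(as.numeric(cd$age)) else numeric(),
      batchKey = batchKey)
}

#' Apply a fitted ComBat-GAM model
#'
#' Removes the model's batch location/scale effects from a cohort:
#' `((y - fit)/sigma - gamma*) / delta* * sigma + fit`, where `fit` is the
#' covariate model prediction (intercept + spline age trend + linear terms).
#' Rows belonging to the model's reference batch are returned bit-identical.
#'
#' @param model a [CombatModel-class].
#' @param cohort a [RoiCohort-class]; every batch label must be known to the
#'   model and the covariate roster must match the one it was fitted with.
#' @return a [RoiCohort-class] with harmonized volumes (same shape and keys).
#' @export
applyCombatGam <- function(model, cohort) {
  stopifnot(is(model, "CombatModel"), is(cohort, "RoiCohort"))
  cd <- subjectData(cohort)
  Y <- roiVolumes(cohort)
  if (!identical(colnames(Y), names(model@alpha)))
    .stopf("ROI roster mismatch between model and cohort")
  if (!model@batchKey %in% colnames(cd))
    .stopf("batch column '%s' not found", model@batchKey)
  batch <- as.character(cd[[model@batchKey]])
  unknown <- setdiff(unique(batch), model@batches)
  if (length(unknown))
    .stopf("batch label(s) unknown to the model: %s",
           paste(unknown, collapse = ", "))
  missing_cov <- setdiff(model@covariates, colnames(cd))
  if (length(missing_cov))
    .stopf("covariate(s) required by the model are missing: %s",
           paste(missing_cov, collapse = ", "))
  if (length(model@ageRange)) {
    out_of_range <- cd$age < model@ageRange[1] | cd$age > model@ageRange[2]
    if (any(out_of_range))
      .warnf(paste0("%d subject(s) outside the fitted age range ",
                    "[%.1f, %.1f]; age trend extrapolated linearly"),
             sum(out_of_range), model@ageRange[1], model@ageRange[2])
  }
  des <- .covariate_design(cd, model@covariates, smooth = model@smooth,
                           factorLevels = model@factorLevels)
  standMean <- matrix(model@alpha, nrow(Y), ncol(Y), byrow = TRUE) +
    des$C %*% model@coefC
  sig <- matrix(model@sigma, nrow(Y), ncol(Y), byrow = TRUE)
  z <- (Y - standMean) / sig
  bIdx <- match(batch, model@batches)
  adj <- (z - model@gammaStar[bIdx, , drop = FALSE]) /
    model@deltaStar[bIdx, , drop = FALSE]
  out <- adj * sig + standMean
  if (length(model@referenceBatch)) {
    refRows <- batch == model@referenceBatch
    out[refRows, ] <- Y[refRows, ]
  }
  RoiCohort(out, cd, riskHistories = riskHistories(cohort),
            truth = metadata(cohort)$truth)
}

# Stack two cohorts on their shared covariate columns, tagging provenance.
.combine_cohorts <- function(study, reference) {
  sv <- roiVolumes(study); rv <- roiVolumes(reference)
  if (!identical(colnames(sv), colnames(rv)))
    .stopf("study and reference cohorts have different ROI rosters")
  sd_ <- subjectData(study); rd <- subjectData(reference)
  shared <- intersect(colnames(sd_), colnames(rd))
  cd <- rbind(cbind(sd_[, shared, drop = FALSE], cohort_batch = "study"),
              cbind(rd[, shared, drop = FALSE], cohort_batch = "reference"))
  RoiCohort(rbind(sv, rv), cd)
}

#' Two-step harmonization: within study, then study to reference
#'
#' Step 1 removes scanner effects inside the study sample (covariates age,
#' sex, ICV, diagnosis). Step 2 treats the whole study as one batch against
#' the pooled reference cohort (covariates age, sex, diagnosis), with the
#' reference as the fixed target space, so the study data are mapped into the
#' reference space and the reference rows are returned unchanged. This makes
#' index models trained in the reference space applicable to the study data.
#'
#' @param study a [RoiCohort-class] with per-subject scanner labels.
#' @param reference a [RoiCohort-class] on a single pooled batch.
#' @param step1Covariates,step2Covariates covariate rosters for the two fits.
#' @param ... passed to [fitCombatGam()] (spline size, EB controls).
#' @return a list with elements `study` (harmonized study cohort),
#'   `reference` (identical to the input), and the two fitted
#'   [CombatModel-class] objects `step1` and `step2`.
#' @export
twoStepHarmonize <- function(study, reference,
                             step1Covariates = c("age", "sex", "icv",
                                                 "diagnosis"),
                             step2Covariates = c("age", "sex", "diagnosis"),
                             ...) {
  m1 <- fitCombatGam(study, batchKey = "scanner",
                     covariates = step1Covariates, ...)
  studyH <- applyCombatGam(m1, study)
  combined <- .combine_cohorts(studyH, reference)
  m2 <- fitCombatGam(combined, batchKey = "cohort_batch",
                     covariates = step2Covariates,
                     referenceBatch = "reference", ...)
  combinedH <- applyCombatGam(m2, combined)
  cdAll <- subjectData(combinedH)
  isStudy <- cdAll$cohort_batch == "study"
  volAll <- roiVolumes(combinedH)
  studyOut <- RoiCohort(volAll[isStudy, , drop = FALSE],
                        subjectData(studyH),
                        riskHistories = riskHistories(study),
                        truth = metadata(study)$truth)
  list(study = studyOut, reference = reference, step1 = m1, step2 = m2)
}
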