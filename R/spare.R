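#' @importFrom stats predict cor
NULL

.standardize <- function(X, means, sds) {
  sweep(sweep(X, 2, means, "-"), 2, sds, "/")
}

.fold_ids <- function(n, k) sample(rep_len(seq_len(k), n))

# Extract the primal weight vector of a linear-kernel libsvm model fitted on
# already-standardized features (internal scaling disabled).
.linear_svm_weights <- function(fit) {
  w <- drop(crossprod(fit$coefs, fit$SV))
  list(weights = w, intercept = -fit$rho)
}

.svr_cv_mae <- function(X, y, cost, epsilon, folds) {
  err <- numeric(max(folds))
  for (f in seq_len(max(folds))) {
    tr <- folds != f
    fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], type = "eps-regression",
                      kernel = "linear", cost = cost, epsilon = epsilon,
                      scale = FALSE, tolerance = 0.05)
    err[f] <- mean(abs(predict(fit, X[!tr, , drop = FALSE]) - y[!tr]))
  }
  mean(err)
}

# Walk the cost grid in increasing order and stop once the cross-validated
# criterion has plateaued (two consecutive steps without a >0.5% relative
# improvement): the regularization path of a linear SVM/SVR flattens beyond
# the optimum, so the expensive high-cost fits are skipped when they cannot
# win.
.path_search <- function(grid, evalFn, maximize = FALSE) {
  grid <- sort(grid)
  best <- if (maximize) -Inf else Inf
  bestCost <- grid[1]
  stall <- 0L
  for (cc in grid) {
    val <- evalFn(cc)
    improved <- if (maximize) val > best * (1 + 5e-3) + 1e-12
      else val < best * (1 - 5e-3)
    if (improved) {
      best <- val
      bestCost <- cc
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= 2L) break
    }
  }
  bestCost
}

.svc_cv_balacc <- function(X, y, cost, folds) {
  acc <- numeric(max(folds))
  for (f in seq_len(max(folds))) {
    tr <- folds != f
    fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], type = "C-classification",
                      kernel = "linear", cost = cost, scale = FALSE,
                      tolerance = 0.05)
    pred <- predict(fit, X[!tr, , drop = FALSE])
    truth <- y[!tr]
    sens <- mean(pred[truth == "AD"] == "AD")
    spec <- mean(pred[truth == "control"] == "control")
    acc[f] <- (sens + spec) / 2
  }
  mean(acc)
}

#' Train the brain-age index (SPARE-BA)
#'
#' Fits a linear epsilon-insensitive support vector regression predicting
#' chronological age from standardized ROI volumes of control subjects. The
#' regularization constant is selected by inner 5-fold cross-validation over
#' a logarithmic grid; held-out accuracy (MAE and age-prediction correlation)
#' is estimated by an outer 5-fold loop with the selection repeated inside
#' each outer fold. Standardization constants come from the training data
#' only and are frozen into the model. Higher predicted age relative to
#' chronological age indicates more age-related atrophy.
#'
#' @param cohort a [RoiCohort-class]; all subjects must be controls
#'   (`study_label` `control` or `reference_control`), n >= 50.
#' @param costGrid candidate regularization constants.
#' @param epsilon SVR epsilon-tube half width, years.
#' @param folds number of cross-validation folds.
#' @param seed integer seed for fold assignment.
#' @param computeMetrics if `FALSE`, skip the outer cross-validation loop
#'   (the model itself is unchanged; only `trainingMeta$cv` is omitted).
#' @return a [SpareModel-class] with `kind = "BA"`; predictions in years.
#' @export
trainSpareBA <- function(cohort, costGrid = 10^(-3:3), epsilon = 0.1,
                         folds = 5L, seed = 1L, computeMetrics = TRUE) {
  stopifnot(is(cohort, "RoiCohort"))
  lab <- studyLabels(cohort)
  if (!all(lab %in% c("control", "reference_control")))
    .stopf("brain-age training requires controls only; found label(s): %s",
           paste(setdiff(unique(lab), c("control", "reference_control")),
                 collapse = ", "))
  X <- roiVolumes(cohort)
  y <- subjectData(cohort)$age
  if (anyNA(y)) .stopf("age missing for some training subjects")
  n <- nrow(X)
  if (n < 50L) .stopf("need >= 50 training subjects, got %d", n)
  mu <- colMeans(X)
  sds <- apply(X, 2, sd)
  if (any(sds <= 0)) .stopf("constant ROI feature(s) in training data")
  Xs <- .standardize(X, mu, sds)
  .with_seed(.sub_seed(seed, 11L), {
    pick_cost <- function(Xtr, ytr) {
      if (length(costGrid) == 1L) return(costGrid)
      fid <- .fold_ids(nrow(Xtr), folds)
      .path_search(costGrid, function(cc)
        .svr_cv_mae(Xtr, ytr, cc, epsilon, fid))
    }
    cv <- NULL
    if (computeMetrics) {
      outer <- .fold_ids(n, folds)
      pred <- numeric(n)
      for (f in seq_len(folds)) {
        tr <- outer != f
        cc <- pick_cost(Xs[tr, , drop = FALSE], y[tr])
        fit <- e1071::svm(Xs[tr, , drop = FALSE], y[tr],
                          type = "eps-regression", kernel = "linear",
                          cost = cc, epsilon = epsilon, scale = FALSE)
        pred[!tr] <- predict(fit, Xs[!tr, , drop = FALSE])
      }
      cv <- list(mae = mean(abs(pred - y)), cor = cor(y, pred))
    }
    cost <- pick_cost(Xs, y)
    fit <- e1071::svm(Xs, y, type = "eps-regression", kernel = "linear",
                      cost = cost, epsilon = epsilon, scale = FALSE)
    wb <- .linear_svm_weights(fit)
    new("SpareModel", kind = "BA", weights = wb$weights,
        intercept = wb$intercept, featureMeans = mu, featureSds = sds,
        hyperparameters = list(cost = cost, grid = costGrid,
                               epsilon = epsilon, folds = folds),
        trainingMeta = list(n = n, seed = seed, cv = cv))
  })
}

#' Train the AD-signature index (SPARE-AD)
#'
#' Fits a linear soft-margin support vector machine separating AD-pattern
#' reference cases (`study_label == "reference_ad"`, coded +1) from reference
#' controls (coded -1). The score is the signed decision value: positive and
#' higher values point to more AD-like atrophy. Regularization is chosen by
#' inner 5-fold cross-validation on balanced accuracy.
#'
#' @inheritParams trainSpareBA
#' @param cohort a [RoiCohort-class] containing both `reference_ad` and
#'   `reference_control` subjects, each class n >= 20.
#' @return a [SpareModel-class] with `kind = "AD"`; scores are unitless
#'   signed distances.
#' @export
trainSpareAD <- function(cohort, costGrid = 10^(-3:3), folds = 5L,
                         seed = 1L, computeMetrics = TRUE) {
  stopifnot(is(cohort, "RoiCohort"))
  lab <- studyLabels(cohort)
  cls <- ifelse(lab == "reference_ad", "AD",
                ifelse(lab %in% c("reference_control", "control"),
                       "control", NA))
  if (anyNA(cls))
    .stopf("unexpected study label(s) in AD training data: %s",
           paste(unique(lab[is.na(cls)]), collapse = ", "))
  if (!all(c("AD", "control") %in% cls))
    .stopf("both AD cases and controls are required for signature training")
  if (any(table(cls) < 20L))
    .stopf("each class needs >= 20 subjects")
  y <- factor(cls, levels = c("AD", "control"))
  X <- roiVolumes(cohort)
  mu <- colMeans(X)
  sds <- apply(X, 2, sd)
  if (any(sds <= 0)) .stopf("constant ROI feature(s) in training data")
  Xs <- .standardize(X, mu, sds)
  n <- nrow(Xs)
  .with_seed(.sub_seed(seed, 12L), {
    pick_cost <- function(Xtr, ytr) {
      if (length(costGrid) == 1L) return(costGrid)
      fid <- .fold_ids(nrow(Xtr), folds)
      .path_search(costGrid, function(cc)
        .svc_cv_balacc(Xtr, ytr, cc, fid), maximize = TRUE)
    }
    cv <- NULL
    if (computeMetrics) {
      outer <- .fold_ids(n, folds)
      pred <- character(n)
      for (f in seq_len(folds)) {
        tr <- outer != f
        cc <- pick_cost(Xs[tr, , drop = FALSE], y[tr])
        fit <- e1071::svm(Xs[tr, , drop = FALSE], y[tr],
                          type = "C-classification", kernel = "linear",
                          cost = cc, scale = FALSE)
        pred[!tr] <- as.character(predict(fit, Xs[!tr, , drop = FALSE]))
      }
      sens <- mean(pred[y == "AD"] == "AD")
      spec <- mean(pred[y == "control"] == "control")
      cv <- list(balanced_accuracy = (sens + spec) / 2)
    }
    cost <- pick_cost(Xs, y)
    fit <- e1071::svm(Xs, y, type = "C-classification", kernel = "linear",
                      cost = cost, scale = FALSE)
    wb <- .linear_svm_weights(fit)
    score <- drop(Xs %*% wb$weights) + wb$intercept
    # enforce the sign convention: AD class scores positive
    if (mean(score[y == "AD"]) < mean(score[y == "control"])) {
      wb$weights <- -wb$weights
      wb$intercept <- -wb$intercept
    }
    new("SpareModel", kind = "AD", weights = wb$weights,
        intercept = wb$intercept, featureMeans = mu, featureSds = sds,
        hyperparameters = list(cost = cost, grid = costGrid, folds = folds),
        trainingMeta = list(n = n, nAd = sum(y == "AD"),
                            nControl = sum(y == "control"),
                            seed = seed, cv = cv))
  })
}

#' Score a cohort with a trained SPARE model
#'
#' Deterministic linear scoring of standardized ROI volumes. Brain-age
#' (`kind = "BA"`) scores are predicted ages in years; AD-signature
#' (`kind = "AD"`) scores are signed decision values.
#'
#' @param model a [SpareModel-class].
#' @param x a [RoiCohort-class] whose ROI roster matches the model's exactly.
#' @param ... unused.
#' @return data.frame with columns `subject_id` and `score`.
#' @export
setMethod("scoreSpare", "SpareModel", function(model, x, ...) {
  stopifnot(is(x, "RoiCohort"))
  X <- roiVolumes(x)
  want <- names(model@weights)
  have <- colnames(X)
  if (!identical(have, want)) {
    miss <- setdiff(want, have)
    extra <- setdiff(have, want)
    .stopf("ROI roster mismatch; missing: %s; extra: %s",
           if (length(miss)) paste(miss, collapse = ", ") else "(none)",
           if (length(extra)) paste(extra, collapse = ", ") else "(none)")
  }
  Xs <- .standardize(X, model@featureMeans, model@featureSds)
  data.frame(subject_id = subjectData(x)$subject_id,
             score = drop(Xs %*% model@weights) + model@intercept)
})
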