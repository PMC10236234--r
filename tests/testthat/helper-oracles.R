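# Brute-force Benjamini-Hochberg: for each p_i take the minimum of
# m * p_j / rank_j over all p_j >= p_i, straight from the definition.
bh_brute_force <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    min((m * p / r)[p >= p[i]])
  }, numeric(1))
}

# Direct per-batch standardization oracle: residualize on the covariates,
# then map each batch's residuals to the pooled location/scale.
standardize_oracle <- function(cohort) {
  cd <- subjectData(cohort)
  Y <- roiVolumes(cohort)
  X <- stats::model.matrix(~ age + I(age^2) + sex + icv + group, cd)
  fit <- stats::lm.fit(X, Y)
  res <- fit$residuals
  fitted <- Y - res
  batch <- factor(cd$scanner)
  pooled_sd <- apply(res, 2, stats::sd)
  out <- Y
  for (b in levels(batch)) {
    ix <- batch == b
    mu_b <- colMeans(res[ix, , drop = FALSE])
    sd_b <- apply(res[ix, , drop = FALSE], 2, stats::sd)
    out[ix, ] <- fitted[ix, ] +
      sweep(sweep(res[ix, , drop = FALSE], 2, mu_b, "-"), 2,
            sd_b / pooled_sd, "/")
  }
  out
}

# Covariate-adjusted per-group/batch residuals (no batch terms in the model).
adjusted_residuals <- function(cohort, extra = "+ group") {
  cd <- subjectData(cohort)
  Y <- roiVolumes(cohort)
  fml <- stats::as.formula(paste("~ age + I(age^2) + sex + icv", extra))
  X <- stats::model.matrix(fml, cd)
  stats::lm.fit(X, Y)$residuals
}
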