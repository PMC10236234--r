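#' @importFrom utils write.csv read.csv packageVersion
NULL

.provenance <- function(seed = NA) {
  sprintf("# BrainSpare %s | seed %s | written %s",
          as.character(packageVersion("BrainSpare")),
          as.character(seed), format(Sys.time(), "%Y-%m-%d"))
}

.write_csv_prov <- function(df, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance(seed), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write a cohort to CSV files
#'
#' Writes the subjects-by-ROI volume table (`<prefix>_roi.csv`, subject_id
#' key column first), the covariate table (`<prefix>_covariates.csv`) and,
#' when present, the long-format risk histories
#' (`<prefix>_risk_histories.csv`). Each file starts with a provenance
#' comment line.
#'
#' @param cohort a [RoiCohort-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param seed seed recorded in the provenance header.
#' @return invisibly, the written paths.
#' @export
writeRoiCohort <- function(cohort, dir, prefix = "cohort", seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  roi <- data.frame(subject_id = subjectData(cohort)$subject_id,
                    roiVolumes(cohort), check.names = FALSE)
  paths <- c(
    .write_csv_prov(roi, file.path(dir, paste0(prefix, "_roi.csv")), seed),
    .write_csv_prov(subjectData(cohort),
                    file.path(dir, paste0(prefix, "_covariates.csv")), seed))
  if (!is.null(riskHistories(cohort)))
    paths <- c(paths, .write_csv_prov(
      riskHistories(cohort),
      file.path(dir, paste0(prefix, "_risk_histories.csv")), seed))
  invisible(paths)
}

#' Read a cohort back from CSV files
#'
#' Counterpart of [writeRoiCohort()].
#'
#' @param dir directory holding the files.
#' @param prefix file-name prefix used when writing.
#' @return a [RoiCohort-class].
#' @export
readRoiCohort <- function(dir, prefix = "cohort") {
  roi <- read.csv(file.path(dir, paste0(prefix, "_roi.csv")),
                  comment.char = "#", check.names = FALSE)
  cov <- read.csv(file.path(dir, paste0(prefix, "_covariates.csv")),
                  comment.char = "#")
  vol <- as.matrix(roi[, -1, drop = FALSE])
  rownames(vol) <- roi$subject_id
  rh_path <- file.path(dir, paste0(prefix, "_risk_histories.csv"))
  rh <- if (file.exists(rh_path))
    read.csv(rh_path, comment.char = "#") else NULL
  RoiCohort(vol, cov, riskHistories = rh)
}
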