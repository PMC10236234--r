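#' Time-weighted mean of a longitudinal visit series
#'
#' Summarizes an irregularly sampled follow-up series into a single exposure
#' value, weighting each visit's value by the time elapsed since the previous
#' measurement: `sum(w_i v_i) / sum(w_i)` with `w_i = t_i - t_{i-1}` and
#' `t_0 = 0` (baseline). A visit exactly at baseline receives zero weight
#' unless it is the only visit, in which case its value is returned. Time
#' beyond the last visit is not carried forward: only elapsed intervals
#' between measurements contribute weight.
#'
#' @param times numeric, visit times in years since baseline, strictly
#'   increasing, all `>= 0`.
#' @param values numeric, one measurement per visit.
#' @param endTime end of the observation window, years; must be at or after
#'   the last visit.
#' @return numeric scalar; with equal visit spacing this equals the
#'   arithmetic mean of the values.
#' @examples
#' timeWeightedMean(c(1, 2, 3), c(1, 2, 3))      # 2: equal spacing
#' timeWeightedMean(c(1, 3), c(8, 9))            # (8*1 + 9*2) / 3
#' @export
timeWeightedMean <- function(times, values, endTime = max(times)) {
  if (length(times) == 0L) .stopf("empty visit series")
  if (length(times) != length(values))
    .stopf("times and values differ in length")
  if (anyNA(times) || anyNA(values)) .stopf("missing times or values")
  if (any(diff(times) <= 0)) .stopf("visit times must be strictly increasing")
  if (any(times < 0)) .stopf("visit times must be >= 0")
  if (endTime < times[length(times)])
    .stopf("endTime precedes the last visit")
  w <- diff(c(0, times))
  if (sum(w) == 0) return(values[1L])  # single visit at baseline
  sum(w * values) / sum(w)
}

#' Any event reported within the observation window
#'
#' @param times numeric visit times (years since baseline).
#' @param values event reports per visit: logical, or counts (any value
#'   `> 0` counts as an event).
#' @param endTime end of the window; reports after it are ignored.
#' @return `TRUE` iff any event was reported at or before `endTime`.
#' @export
everEvent <- function(times, values, endTime = Inf) {
  if (length(times) == 0L) return(FALSE)
  if (length(times) != length(values))
    .stopf("times and values differ in length")
  any(as.numeric(values)[times <= endTime] > 0, na.rm = TRUE)
}

#' Categorize cumulative severe-hypoglycemia events
#'
#' Bins the cumulative event count of a visit-level count series into the
#' three categories used for covariate scans: `"0"`, `"1-5"`, `">5"`.
#'
#' @param counts numeric vector of per-visit event counts (all `>= 0`).
#' @return factor with levels `"0"`, `"1-5"`, `">5"` (reference `"0"`).
#' @export
categorizeHypoglycemia <- function(counts) {
  if (anyNA(counts)) .stopf("missing event counts")
  if (any(counts < 0)) .stopf("event counts must be >= 0")
  total <- sum(counts)
  lab <- if (total == 0) "0" else if (total <= 5) "1-5" else ">5"
  factor(lab, levels = c("0", "1-5", ">5"))
}

#' Summarize longitudinal risk histories per subject
#'
#' Collapses a long-format visit table into one row per subject: a
#' time-weighted mean for each quantitative covariate, an ever-event flag and
#' a cumulative-count category for each event covariate.
#'
#' @param histories long-format data.frame (`subject_id`, `covariate`,
#'   `time`, `value`), e.g. from [riskHistories()].
#' @param quantitative,events character vectors naming which covariates are
#'   quantitative series and which are event-count series.
#' @param endTime end of the observation window, years.
#' @return wide data.frame, one row per subject: `<name>_twm` columns for
#'   quantitative covariates, `<name>_ever` (0/1) and `<name>_cat` for event
#'   covariates.
#' @export
summarizeRiskHistories <- function(histories,
                                   quantitative = c("hba1c", "bmi"),
                                   events = "severe_hypo",
                                   endTime = NULL) {
  stopifnot(all(c("subject_id", "covariate", "time", "value") %in%
                  colnames(histories)))
  ids <- unique(histories$subject_id)
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (nm in quantitative) {
    sub <- histories[histories$covariate == nm, , drop = FALSE]
    out[[paste0(nm, "_twm")]] <- vapply(ids, function(id) {
      s <- sub[sub$subject_id == id, , drop = FALSE]
      if (!nrow(s)) return(NA_real_)
      s <- s[order(s$time), , drop = FALSE]
      timeWeightedMean(s$time, s$value,
                       endTime = if (is.null(endTime)) max(s$time)
                       else endTime)
    }, numeric(1))
  }
  for (nm in events) {
    sub <- histories[histories$covariate == nm, , drop = FALSE]
    ever <- vapply(ids, function(id) {
      s <- sub[sub$subject_id == id, , drop = FALSE]
      everEvent(s$time, s$value,
                endTime = if (is.null(endTime)) Inf else endTime)
    }, logical(1))
    out[[paste0(nm, "_ever")]] <- as.numeric(ever)
    out[[paste0(nm, "_cat")]] <- vapply(ids, function(id) {
      s <- sub[sub$subject_id == id, , drop = FALSE]
      if (is.null(endTime)) keep <- rep(TRUE, nrow(s))
      else keep <- s$time <= endTime
      as.character(categorizeHypoglycemia(s$value[keep]))
    }, character(1))
  }
  out
}
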