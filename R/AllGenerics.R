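#' @rdname roiVolumes
#' @export
setGeneric("roiVolumes", function(x, ...) standardGeneric("roiVolumes"))

#' @rdname scannerIds
#' @export
setGeneric("scannerIds", function(x) standardGeneric("scannerIds"))

#' @rdname studyLabels
#' @export
setGeneric("studyLabels", function(x) standardGeneric("studyLabels"))

#' @rdname subjectData
#' @export
setGeneric("subjectData", function(x) standardGeneric("subjectData"))

#' @rdname riskHistories
#' @export
setGeneric("riskHistories", function(x) standardGeneric("riskHistories"))

#' @rdname scoreSpare
#' @export
setGeneric("scoreSpare", function(model, x, ...) standardGeneric("scoreSpare"))

#' @rdname gapYears
#' @export
setGeneric("gapYears", function(x) standardGeneric("gapYears"))
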