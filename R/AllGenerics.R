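#' @export
setGeneric("cohortKind", function(x) standardGeneric("cohortKind"))

#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @export
setGeneric("visitTimes", function(x) standardGeneric("visitTimes"))

#' @export
setGeneric("ages", function(x) standardGeneric("ages"))

#' @export
setGeneric("diagnoses", function(x) standardGeneric("diagnoses"))

#' @export
setGeneric("outcomes", function(x) standardGeneric("outcomes"))

#' @export
setGeneric("thicknessMatrix", function(x) standardGeneric("thicknessMatrix"))

#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @export
setGeneric("inertia", function(x) standardGeneric("inertia"))

#' @export
setGeneric("atlasEntries", function(x) standardGeneric("atlasEntries"))

#' @export
setGeneric("auc", function(x) standardGeneric("auc"))
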