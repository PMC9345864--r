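#' @title Accessor generics
#' @description Accessors for the S4 containers used across the package:
#' recording sessions, per-session feature vectors, index results, and
#' ROC summaries. Slots are never reached into directly by user code.
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @return `subjectId()`: the subject identifier, a character scalar.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @return `sessionFrames()`: the long-format landmark frame table.
#' @export
setGeneric("sessionFrames", function(x) standardGeneric("sessionFrames"))

#' @rdname accessors
#' @return `sessionWindows()`: the protocol window table.
#' @export
setGeneric("sessionWindows", function(x) standardGeneric("sessionWindows"))

#' @rdname accessors
#' @return `featureValues()`: named numeric vector of the six features.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname accessors
#' @return `frameCounts()`: named integer vector of frames used per feature.
#' @export
setGeneric("frameCounts", function(x) standardGeneric("frameCounts"))

#' @rdname accessors
#' @return `ipaScore()`: numeric vector of index scores.
#' @export
setGeneric("ipaScore", function(x) standardGeneric("ipaScore"))

#' @rdname accessors
#' @return `isPDLike()`: logical vector, score at or above the lower cut-off.
#' @export
setGeneric("isPDLike", function(x) standardGeneric("isPDLike"))

#' @rdname accessors
#' @return `isPALike()`: logical vector, score at or above the upper cut-off.
#' @export
setGeneric("isPALike", function(x) standardGeneric("isPALike"))

#' @rdname accessors
#' @return `aucValue()`: the area under the ROC curve, a numeric scalar.
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))

#' @rdname accessors
#' @return `optimalCutoff()`: the Youden-optimal threshold, a numeric scalar.
#' @export
setGeneric("optimalCutoff", function(x) standardGeneric("optimalCutoff"))

#' @rdname accessors
#' @return `bandLabel()`: the qualitative interpretation band, a character scalar.
#' @export
setGeneric("bandLabel", function(x) standardGeneric("bandLabel"))
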