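#' Accessors for the stereoKi67 classes
#'
#' Small accessor generics: \code{marks}, \code{spotId}, \code{role} and
#' \code{nMarks} for \code{\linkS4class{MarkSet}}; \code{frames} and
#' \code{nFrames} for \code{\linkS4class{FrameGrid}}; \code{tallies},
#' \code{edits}, \code{nEdits} and \code{ki67Values} for
#' \code{\linkS4class{SpotAudit}}; \code{truthMarks} and \code{eventLog}
#' for \code{\linkS4class{SyntheticSpot}}.
#'
#' @param object an object of the documented class.
#' @return the slot content; \code{ki67Values} returns a named numeric
#'   vector \code{c(dD = ..., cD = ...)}.
#' @name accessors
#' @aliases marks spotId role nMarks frames nFrames tallies edits nEdits
#'   ki67Values truthMarks eventLog
NULL

#' @rdname accessors
#' @export
setGeneric("marks", function(object) standardGeneric("marks"))
#' @rdname accessors
#' @export
setGeneric("spotId", function(object) standardGeneric("spotId"))
#' @rdname accessors
#' @export
setGeneric("role", function(object) standardGeneric("role"))
#' @rdname accessors
#' @export
setGeneric("nMarks", function(object) standardGeneric("nMarks"))
#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("tallies", function(object) standardGeneric("tallies"))
#' @rdname accessors
#' @export
setGeneric("edits", function(object) standardGeneric("edits"))
#' @rdname accessors
#' @export
setGeneric("nEdits", function(object) standardGeneric("nEdits"))
#' @rdname accessors
#' @export
setGeneric("ki67Values", function(object) standardGeneric("ki67Values"))
#' @rdname accessors
#' @export
setGeneric("truthMarks", function(object) standardGeneric("truthMarks"))
#' @rdname accessors
#' @export
setGeneric("eventLog", function(object) standardGeneric("eventLog"))
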