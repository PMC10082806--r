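#' @title Accessors for nanodmr classes
#'
#' @description Slot accessors for \linkS4class{DeltaBetaTrack},
#' \linkS4class{SLMParams} and \linkS4class{Segmentation}.
#' \code{cpgDistances} returns the start-to-start distances
#' \eqn{d_i = start_i - start_{i-1}} between consecutive CpG groups (length
#' one less than the track).
#'
#' @param x An object of the documented classes.
#' @return The slot contents; for \code{cpgDistances} a numeric vector of
#'   positive distances in bp.
#' @name nanodmr-accessors
#' @aliases chrom cpgStarts cpgEnds nMotifs betaTest betaControl deltaBeta
#'   cpgDistances nSegments segmentTable
#' @examples
#' trk <- exampleDeltaTrack(n = 5)
#' cpgDistances(trk)
NULL

#' @rdname nanodmr-accessors
#' @export
setGeneric("chrom", function(x) standardGeneric("chrom"))
#' @rdname nanodmr-accessors
#' @export
setGeneric("cpgStarts", function(x) standardGeneric("cpgStarts"))
#' @rdname nanodmr-accessors
#' @export
setGeneric("cpgEnds", function(x) standardGeneric("cpgEnds"))
#' @rdname nanodmr-accessors
#' @export
setGeneric("nMotifs", function(x) standardGeneric("nMotifs"))
#' @rdname nanodmr-accessors
#' @export
setGeneric("betaTest", function(x) standardGeneric("betaTest"))
#' @rdname nanodmr-accessors
#' @export
setGeneric("betaControl", function(x) standardGeneric("betaControl"))
#' @rdname nanodmr-accessors
#' @export
setGeneric("deltaBeta", function(x) standardGeneric("deltaBeta"))
#' @rdname nanodmr-accessors
#' @export
setGeneric("cpgDistances", function(x) standardGeneric("cpgDistances"))
#' @rdname nanodmr-accessors
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))
#' @rdname nanodmr-accessors
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))

#' @rdname nanodmr-accessors
#' @export
setGeneric("stateGrid", function(x) standardGeneric("stateGrid"))
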