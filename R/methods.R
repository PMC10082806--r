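#' Construct a DeltaBetaTrack
#'
#' Low-level constructor; most users will obtain tracks from
#' \code{\link{buildDeltaTrack}}.
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open CpG group spans, strictly increasing
#'   starts.
#' @param betaTest,betaControl Per-group methylation frequencies.
#' @param nMotifs CpG motifs per group (default 1).
#' @param calledTest,calledControl Motif-weighted call support per group.
#' @return A \linkS4class{DeltaBetaTrack}.
#' @examples
#' DeltaBetaTrack("chr1", start = c(100, 250, 1000), end = c(102, 252, 1002),
#'                betaTest = c(0.9, 0.8, 0.1), betaControl = c(0.1, 0.2, 0.1))
#' @export
DeltaBetaTrack <- function(chrom, start, end = start + 2, betaTest,
                           betaControl, nMotifs = rep(1L, length(start)),
                           calledTest = rep(10L, length(start)),
                           calledControl = rep(10L, length(start))) {
    new("DeltaBetaTrack", chrom = as.character(chrom),
        start = as.numeric(start), end = as.numeric(end),
        nMotifs = as.integer(nMotifs),
        betaTest = as.numeric(betaTest),
        betaControl = as.numeric(betaControl),
        deltaBeta = as.numeric(betaTest) - as.numeric(betaControl),
        calledTest = as.integer(calledTest),
        calledControl = as.integer(calledControl))
}

#' @rdname nanodmr-accessors
#' @export
setMethod("chrom", "DeltaBetaTrack", function(x) x@chrom)
#' @rdname nanodmr-accessors
#' @export
setMethod("cpgStarts", "DeltaBetaTrack", function(x) x@start)
#' @rdname nanodmr-accessors
#' @export
setMethod("cpgEnds", "DeltaBetaTrack", function(x) x@end)
#' @rdname nanodmr-accessors
#' @export
setMethod("nMotifs", "DeltaBetaTrack", function(x) x@nMotifs)
#' @rdname nanodmr-accessors
#' @export
setMethod("betaTest", "DeltaBetaTrack", function(x) x@betaTest)
#' @rdname nanodmr-accessors
#' @export
setMethod("betaControl", "DeltaBetaTrack", function(x) x@betaControl)
#' @rdname nanodmr-accessors
#' @export
setMethod("deltaBeta", "DeltaBetaTrack", function(x) x@deltaBeta)
#' @rdname nanodmr-accessors
#' @export
setMethod("cpgDistances", "DeltaBetaTrack", function(x) diff(x@start))

#' @describeIn DeltaBetaTrack Number of CpG groups in the track.
#' @param x A \code{DeltaBetaTrack}.
#' @export
setMethod("length", "DeltaBetaTrack", function(x) length(x@start))

setMethod("show", "DeltaBetaTrack", function(object) {
    n <- length(object)
    cat("DeltaBetaTrack on ", object@chrom, ": ", n, " CpG groups", sep = "")
    if (n) {
        cat(sprintf(" [%d-%d]", as.integer(object@start[1L]),
                    as.integer(object@end[n])))
        cat(sprintf("\n  mean delta-beta %.3f; range [%.3f, %.3f]\n",
                    mean(object@deltaBeta), min(object@deltaBeta),
                    max(object@deltaBeta)))
    } else cat("\n")
    invisible(object)
})

#' @rdname nanodmr-accessors
#' @export
setMethod("stateGrid", "SLMParams", function(x)
    seq(-1, 1, length.out = x@nStates))

setMethod("show", "SLMParams", function(object) {
    cat(sprintf(paste0("SLMParams: theta=%.3g dNorm=%g sigmaEps=%.4g ",
                       "sigmaMu=%.4g nStates=%d\n"),
                object@theta, object@dNorm, object@sigmaEps, object@sigmaMu,
                object@nStates))
    invisible(object)
})

#' @rdname nanodmr-accessors
#' @export
setMethod("chrom", "Segmentation", function(x) x@chrom)
#' @rdname nanodmr-accessors
#' @export
setMethod("nSegments", "Segmentation", function(x) length(x@firstIndex))

#' @rdname nanodmr-accessors
#' @export
setMethod("segmentTable", "Segmentation", function(x)
    data.frame(chrom = rep(x@chrom, length(x@firstIndex)),
               first_index = x@firstIndex, last_index = x@lastIndex,
               n_cpg_groups = x@lastIndex - x@firstIndex + 1L,
               level = x@level, mean_delta_beta = x@meanDeltaBeta))

setMethod("show", "Segmentation", function(object) {
    cat("Segmentation of ", object@nSites, " CpG groups on ", object@chrom,
        " into ", nSegments(object), " segments\n", sep = "")
    invisible(object)
})

#' Small synthetic track for examples
#'
#' @param n Number of CpG groups.
#' @param seed Random seed.
#' @return A \linkS4class{DeltaBetaTrack} with evenly spaced groups and
#'   Gaussian noise around zero.
#' @examples
#' exampleDeltaTrack(10)
#' @export
exampleDeltaTrack <- function(n = 100, seed = 1L) {
    set.seed(seed)
    start <- cumsum(c(100, rep(100, n - 1L)))
    bc <- rep(0.5, n)
    bt <- pmin(1, pmax(0, bc + rnorm(n, 0, 0.05)))
    DeltaBetaTrack("chrS", start = start, end = start + 2,
                   betaTest = bt, betaControl = bc)
}
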