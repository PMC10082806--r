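#' @title Per-chromosome differential methylation track
#'
#' @description A \code{DeltaBetaTrack} holds the ordered CpG groups of one
#' chromosome that are covered in both samples of a pair, together with their
#' methylation frequencies (beta), the per-group difference
#' \eqn{\Delta\beta = \beta_{test} - \beta_{control}} and enough bookkeeping
#' (group spans, motif counts, coverage) to call, size and classify DMRs.
#' Coordinates are 0-based half-open, as in the nanopore methylation TSVs the
#' track is built from.
#'
#' @slot chrom Chromosome name (single string).
#' @slot start Integer-valued group start (anchor) coordinates, strictly
#'   increasing.
#' @slot end Group end coordinates, \code{end >= start} element-wise.
#' @slot nMotifs Number of CpG motifs per group.
#' @slot betaTest,betaControl Methylation frequencies in [0, 1].
#' @slot deltaBeta \code{betaTest - betaControl}, in [-1, 1].
#' @slot calledTest,calledControl Number of called CpG sites (motif-weighted
#'   read support) per group in each sample.
#'
#' @seealso \code{\link{buildDeltaTrack}}, \code{\link{viterbiSegment}}
#' @export
setClass("DeltaBetaTrack",
    representation(
        chrom         = "character",
        start         = "numeric",
        end           = "numeric",
        nMotifs       = "integer",
        betaTest      = "numeric",
        betaControl   = "numeric",
        deltaBeta     = "numeric",
        calledTest    = "integer",
        calledControl = "integer"
    )
)

setValidity("DeltaBetaTrack", function(object) {
    msg <- character()
    n <- length(object@start)
    lens <- c(length(object@end), length(object@nMotifs),
              length(object@betaTest), length(object@betaControl),
              length(object@deltaBeta), length(object@calledTest),
              length(object@calledControl))
    if (length(object@chrom) != 1L)
        msg <- c(msg, "'chrom' must be a single string")
    if (any(lens != n))
        msg <- c(msg, "all per-group slots must have equal length")
    else if (n > 0L) {
        if (any(diff(object@start) <= 0))
            msg <- c(msg, "'start' must be strictly increasing")
        if (any(object@end < object@start))
            msg <- c(msg, "'end' must be >= 'start'")
        if (any(object@nMotifs < 1L))
            msg <- c(msg, "'nMotifs' must be >= 1")
        if (any(object@betaTest < 0 | object@betaTest > 1) ||
            any(object@betaControl < 0 | object@betaControl > 1))
            msg <- c(msg, "beta values must lie in [0, 1]")
        if (any(abs(object@deltaBeta -
                    (object@betaTest - object@betaControl)) > 1e-12))
            msg <- c(msg, "'deltaBeta' must equal betaTest - betaControl")
    }
    if (length(msg)) msg else TRUE
})

#' @title Parameters of the heterogeneous shifting-level model
#'
#' @description Bundles the parameters of the segmentation model: the baseline
#' jump parameter \code{theta} and distance scale \code{dNorm} of the
#' distance-dependent jump probability \eqn{\eta(d)}, the truncated-Gaussian
#' emission noise s.d. \code{sigmaEps}, the s.d. \code{sigmaMu} of the Gaussian
#' increments of the latent mean level, and the size of the symmetric grid of
#' candidate mean levels on [-1, 1] used by the Viterbi decoder.
#'
#' @slot theta Baseline jump parameter, in (0, 0.5).
#' @slot dNorm Distance normalisation in bp, > 0.
#' @slot sigmaEps Emission (white noise) standard deviation, > 0.
#' @slot sigmaMu Level-jump standard deviation, > 0.
#' @slot nStates Odd integer >= 3; number of candidate mean levels.
#'
#' @seealso \code{\link{estimateSLMParams}}, \code{\link{stateGrid}}
#' @export
setClass("SLMParams",
    representation(
        theta    = "numeric",
        dNorm    = "numeric",
        sigmaEps = "numeric",
        sigmaMu  = "numeric",
        nStates  = "integer"
    )
)

setValidity("SLMParams", function(object) {
    msg <- character()
    if (length(object@theta) != 1L || object@theta <= 0 || object@theta >= 0.5)
        msg <- c(msg, "'theta' must lie strictly in (0, 0.5)")
    if (length(object@dNorm) != 1L || object@dNorm <= 0)
        msg <- c(msg, "'dNorm' must be > 0")
    if (length(object@sigmaEps) != 1L || object@sigmaEps <= 0)
        msg <- c(msg, "'sigmaEps' must be > 0")
    if (length(object@sigmaMu) != 1L || object@sigmaMu <= 0)
        msg <- c(msg, "'sigmaMu' must be > 0")
    if (length(object@nStates) != 1L || object@nStates < 3L ||
        object@nStates %% 2L == 0L)
        msg <- c(msg, "'nStates' must be an odd integer >= 3")
    if (length(msg)) msg else TRUE
})

#' Constructor for \linkS4class{SLMParams}
#'
#' @param theta Baseline jump parameter in (0, 0.5).
#' @param dNorm Distance normalisation in bp.
#' @param sigmaEps Emission noise standard deviation.
#' @param sigmaMu Level-jump standard deviation.
#' @param nStates Odd number of candidate mean levels on [-1, 1].
#' @return An \linkS4class{SLMParams} object.
#' @examples
#' SLMParams(sigmaEps = 0.1, sigmaMu = 0.3)
#' @export
SLMParams <- function(theta = 0.1, dNorm = 1000, sigmaEps = 0.1,
                      sigmaMu = 0.3, nStates = 41L) {
    new("SLMParams", theta = as.numeric(theta), dNorm = as.numeric(dNorm),
        sigmaEps = as.numeric(sigmaEps), sigmaMu = as.numeric(sigmaMu),
        nStates = as.integer(nStates))
}

#' @title Segmentation of a delta-beta track
#'
#' @description The result of Viterbi decoding one \linkS4class{DeltaBetaTrack}:
#' maximal runs of a constant latent mean level.  Segments partition the index
#' range of the track and consecutive segments carry different levels.
#'
#' @slot chrom Chromosome name.
#' @slot firstIndex,lastIndex 1-based index range of each segment into the
#'   track the segmentation was computed from.
#' @slot level Grid mean level assigned by the decoder.
#' @slot meanDeltaBeta Arithmetic mean of the member delta-beta values.
#' @slot nSites Number of CpG groups in the decoded track.
#'
#' @seealso \code{\link{viterbiSegment}}, \code{\link{callDMRs}}
#' @export
setClass("Segmentation",
    representation(
        chrom         = "character",
        firstIndex    = "integer",
        lastIndex     = "integer",
        level         = "numeric",
        meanDeltaBeta = "numeric",
        nSites        = "integer"
    )
)

setValidity("Segmentation", function(object) {
    msg <- character()
    k <- length(object@firstIndex)
    if (length(object@lastIndex) != k || length(object@level) != k ||
        length(object@meanDeltaBeta) != k)
        msg <- c(msg, "per-segment slots must have equal length")
    else if (k > 0L) {
        if (object@firstIndex[1L] != 1L ||
            object@lastIndex[k] != object@nSites ||
            (k > 1L && any(object@firstIndex[-1L] != object@lastIndex[-k] + 1L)))
            msg <- c(msg, "segments must partition 1..nSites")
        if (k > 1L && any(object@level[-1L] == object@level[-k]))
            msg <- c(msg, "consecutive segments must have different levels")
    }
    if (length(msg)) msg else TRUE
})
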