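## Heterogeneous truncated-Gaussian shifting-level model (HTGSLM).
##
## The observed delta-beta value at CpG group i is modelled as
## x_i = m_i + eps_i, where m_i is an unobserved piecewise-constant mean
## level and eps_i is truncated-Gaussian white noise on [-1, 1].  The mean
## level persists for geometric durations and, when it jumps, is incremented
## by a N(0, sigmaMu^2) draw.  The jump probability between consecutive CpG
## groups depends on their genomic distance d through eta(d), so widely
## separated CpGs are a priori more likely to sit on different levels.
## Decoding discretises m onto a symmetric grid and runs Viterbi.

#' Distance-dependent jump probability
#'
#' Probability that the latent mean level changes between two consecutive CpG
#' groups separated by \code{d} bp:
#' \deqn{\eta(d) = \frac{\theta}{2} +
#'   \left(\frac{1}{2}-\theta\right)\exp\!\left[\frac{\log\theta}{d/d_{Norm}}\right]}
#' \eqn{\eta} increases monotonically from \eqn{\theta/2} (as \eqn{d \to 0})
#' to \eqn{(1-\theta)/2} (as \eqn{d \to \infty}) and equals
#' \eqn{\theta - \theta^2} at \eqn{d = d_{Norm}}.
#'
#' @param d Positive distance(s) in bp (vectorised).
#' @param theta Baseline jump parameter, strictly in (0, 0.5); outside this
#'   range the formula's limits invert and an error is raised.
#' @param dNorm Positive distance normalisation in bp.
#' @return Jump probabilities in (theta/2, (1-theta)/2).
#' @examples
#' etaJump(1000, theta = 0.1, dNorm = 1000)  # theta - theta^2 = 0.09
#' @export
etaJump <- function(d, theta = 0.1, dNorm = 1000) {
    if (length(theta) != 1L || !is.finite(theta) || theta <= 0 || theta >= 0.5)
        stop("'theta' must lie strictly in (0, 0.5)", call. = FALSE)
    if (length(dNorm) != 1L || !is.finite(dNorm) || dNorm <= 0)
        stop("'dNorm' must be > 0", call. = FALSE)
    if (any(d <= 0))
        stop("distances must be > 0", call. = FALSE)
    0.5 * theta + (0.5 - theta) * exp(log(theta) / (d / dNorm))
}

#' Truncated-Gaussian density on [-1, 1]
#'
#' Density of a Gaussian with mean \code{mean} and s.d. \code{sd} truncated to
#' the delta-beta range [-1, 1]; used as the emission distribution of the
#' shifting-level model.
#'
#' @param x Quantiles in [-1, 1] (values outside are an error).
#' @param mean Mean of the untruncated Gaussian.
#' @param sd Positive standard deviation.
#' @param log If \code{TRUE}, return the log density.
#' @return Density values; the density integrates to 1 over [-1, 1].
#' @examples
#' integrate(dtruncGauss, -1, 1, mean = 0.3, sd = 0.2)
#' @export
dtruncGauss <- function(x, mean = 0, sd = 1, log = FALSE) {
    if (any(x < -1 | x > 1))
        stop("'x' must lie in [-1, 1]", call. = FALSE)
    if (any(sd <= 0))
        stop("'sd' must be > 0", call. = FALSE)
    logZ <- base::log(stats::pnorm(1, mean, sd) - stats::pnorm(-1, mean, sd))
    out <- stats::dnorm(x, mean, sd, log = TRUE) - logZ
    if (log) out else exp(out)
}

#' Estimate shifting-level model parameters from a track
#'
#' Two-step estimation, step one: the noise s.d. \code{sigmaEps} is estimated
#' robustly from lag-1 differences of the delta-beta profile,
#' \eqn{\hat\sigma_\epsilon = \mathrm{MAD}(\Delta\beta_i - \Delta\beta_{i-1}) / \sqrt{2}}
#' (MAD with the usual 1.4826 consistency constant; successive differences of
#' white noise have variance \eqn{2\sigma_\epsilon^2}, and the median makes
#' the estimate insensitive to the sparse level jumps).  The level-jump s.d.
#' is then tied to it through the signal fraction \code{omega}:
#' \eqn{\sigma_\mu^2 = \frac{\omega}{1-\omega}\sigma_\epsilon^2}.
#' \code{theta} and \code{dNorm} are configuration, not estimated.
#'
#' @param track A \linkS4class{DeltaBetaTrack} (>= 10 CpG groups), or a list
#'   of tracks, in which case lag-1 differences are pooled across
#'   chromosomes.
#' @param omega Signal fraction in (0, 1) linking \code{sigmaMu} to
#'   \code{sigmaEps} (default 0.9, i.e. \code{sigmaMu = 3 sigmaEps}).
#' @param theta,dNorm,nStates Passed through to \code{\link{SLMParams}}.
#' @return An \linkS4class{SLMParams} object.
#' @examples
#' estimateSLMParams(exampleDeltaTrack(200))
#' @export
estimateSLMParams <- function(track, omega = 0.9, theta = 0.1, dNorm = 1000,
                              nStates = 41L) {
    if (length(omega) != 1L || omega <= 0 || omega >= 1)
        stop("'omega' must lie strictly in (0, 1)", call. = FALSE)
    if (is(track, "DeltaBetaTrack")) track <- list(track)
    n <- sum(vapply(track, length, 1L))
    if (n < 10L)
        stop("need at least 10 CpG groups to estimate parameters, got ", n,
             call. = FALSE)
    diffs <- unlist(lapply(track, function(t) diff(deltaBeta(t))),
                    use.names = FALSE)
    sigmaEps <- stats::mad(diffs) / sqrt(2)
    if (sigmaEps < 1e-3) {
        warning("estimated noise s.d. below 1e-3 (near-constant track); ",
                "flooring sigmaEps at 1e-3", call. = FALSE)
        sigmaEps <- 1e-3
    }
    sigmaMu <- sqrt(omega / (1 - omega)) * sigmaEps
    SLMParams(theta = theta, dNorm = dNorm, sigmaEps = sigmaEps,
              sigmaMu = sigmaMu, nStates = nStates)
}

#' Viterbi decoding of a delta-beta profile
#'
#' \code{viterbiPath} computes the maximum a posteriori sequence of grid
#' levels for raw vectors; \code{viterbiSegment} wraps it for a
#' \linkS4class{DeltaBetaTrack} and merges consecutive equal states into
#' segments.
#'
#' The chain over the level grid uses the stationary weights
#' \eqn{w_k \propto N(level_k; 0, \sigma_\mu^2)} as the initial distribution;
#' at step \eqn{i} the level is kept with probability \eqn{1 - \eta(d_i)} and
#' otherwise jumps to a different level \eqn{k} with probability proportional
#' to the Gaussian increment density \eqn{N(level_k - level_j; 0,
#' \sigma_\mu^2)}, renormalised over \eqn{k \neq j}.  Emissions are truncated
#' Gaussians centred on the level.  All arithmetic is in log space; ties in
#' the backtracking are broken toward the lower state index, so the output is
#' deterministic.
#'
#' @param x Numeric vector of delta-beta values in [-1, 1].
#' @param d Positive inter-CpG distances, \code{length(x) - 1}.
#' @param params An \linkS4class{SLMParams} object.
#' @param track A \linkS4class{DeltaBetaTrack}.
#' @return \code{viterbiPath}: integer vector of 1-based state indices into
#'   \code{stateGrid(params)}.  \code{viterbiSegment}: a
#'   \linkS4class{Segmentation}.
#' @examples
#' trk <- exampleDeltaTrack(50)
#' p <- estimateSLMParams(trk)
#' viterbiSegment(trk, p)
#' @export
viterbiPath <- function(x, d, params) {
    stopifnot(is(params, "SLMParams"))
    if (!length(x)) stop("empty profile", call. = FALSE)
    if (length(d) != length(x) - 1L)
        stop("'d' must have length(x) - 1 elements", call. = FALSE)
    if (length(d) && any(d <= 0))
        stop("distances must be > 0", call. = FALSE)
    if (any(x < -1 | x > 1))
        stop("delta-beta values must lie in [-1, 1]", call. = FALSE)
    viterbi_path_cpp(as.numeric(x), as.numeric(d), stateGrid(params),
                     params@sigmaEps, params@sigmaMu, params@theta,
                     params@dNorm)
}

#' @rdname viterbiPath
#' @export
viterbiSegment <- function(track, params) {
    stopifnot(is(track, "DeltaBetaTrack"))
    path <- viterbiPath(deltaBeta(track), cpgDistances(track), params)
    r <- rle(path)
    last <- cumsum(r$lengths)
    first <- last - r$lengths + 1L
    levels <- stateGrid(params)[r$values]
    meanDb <- vapply(seq_along(first), function(i)
        mean(deltaBeta(track)[first[i]:last[i]]), 1.0)
    new("Segmentation", chrom = chrom(track),
        firstIndex = as.integer(first), lastIndex = as.integer(last),
        level = levels, meanDeltaBeta = meanDb,
        nSites = length(track))
}

#' Export a segmentation as a BED-like TSV
#'
#' One row per segment: \code{chrom}, \code{start}, \code{end} (0-based
#' half-open span from first to last member group), \code{segment_id},
#' \code{mean_delta_beta}, \code{strand} ("."), \code{n_cpgs},
#' \code{assigned_level}.
#'
#' @param segs Named list of \linkS4class{Segmentation} objects (as from
#'   mapping \code{\link{viterbiSegment}} over tracks).
#' @param tracks Matching named list of \linkS4class{DeltaBetaTrack}s.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
exportSegments <- function(segs, tracks, path) {
    rows <- lapply(names(segs), function(ch) {
        s <- segs[[ch]]
        trk <- tracks[[ch]]
        data.frame(chrom = rep(chrom(s), nSegments(s)),
                   start = format(cpgStarts(trk)[s@firstIndex],
                                  scientific = FALSE, trim = TRUE),
                   end = format(cpgEnds(trk)[s@lastIndex],
                                scientific = FALSE, trim = TRUE),
                   segment_id = paste0(ch, "_seg", seq_len(nSegments(s))),
                   mean_delta_beta = formatC(s@meanDeltaBeta, format = "g",
                                             digits = 17),
                   strand = ".",
                   n_cpgs = s@lastIndex - s@firstIndex + 1L,
                   assigned_level = formatC(s@level, format = "g",
                                            digits = 17),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    names(out)[1L] <- "#chrom"
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
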