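## Segment testing and DMR classification.
##
## A decoded segment becomes a DMR when (i) the absolute unweighted mean of
## its member delta-beta values exceeds the cutoff (default 0.3), (ii) the
## two-sided Wilcoxon rank-sum test comparing the member beta values of the
## two samples is significant (default p < 0.05, uncorrected), and (iii) the
## segment has at least minCpgs member CpG groups.

#' Wilcoxon rank-sum test for one segment
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum test comparing the per-group
#' beta values of the two samples inside one segment.  The exact null
#' distribution is used for small tie-free samples; otherwise the normal
#' approximation with midranks, tie-corrected variance and continuity
#' correction (the \code{\link[stats]{wilcox.test}} machinery).
#'
#' @param betaTest,betaControl Per-CpG-group beta values of the segment
#'   (equal length).
#' @return Two-sided p-value.  Segments with fewer than 2 groups are
#'   untestable and return \code{p = 1} with a warning.
#' @examples
#' segmentWilcoxon(c(0.9, 0.8, 0.95, 0.85), c(0.1, 0.2, 0.15, 0.05))  # 2/70
#' @export
segmentWilcoxon <- function(betaTest, betaControl) {
    if (length(betaTest) != length(betaControl))
        stop("beta vectors must have equal length", call. = FALSE)
    if (length(betaTest) < 2L) {
        warning("segment with fewer than 2 CpG groups is untestable; p = 1",
                call. = FALSE)
        return(1)
    }
    suppressWarnings(
        stats::wilcox.test(betaTest, betaControl,
                           alternative = "two.sided")$p.value)
}

.densityClass <- function(density) {
    ifelse(density <= 2, "<=2", ifelse(density <= 3, "<=3", ">3"))
}

#' Call DMRs from a segmentation
#'
#' Applies the DMR definition to every segment of one chromosome: absolute
#' unweighted mean delta-beta above \code{cutoff}, rank-sum
#' \code{p < alpha}, and at least \code{minCpgs} member CpG groups.  The DMR
#' interval runs from the start of the first member group to the end of the
#' last.  CpG density is \code{100 * (total CpG motifs in member groups) /
#' (end - start)} (CpGs per 100 bp) and is binned into the resolution classes
#' \code{"<=2"}, \code{"<=3"} (boundaries inclusive) and \code{">3"}.
#'
#' @param seg A \linkS4class{Segmentation}.
#' @param track The \linkS4class{DeltaBetaTrack} it was computed from.
#' @param cutoff Absolute mean delta-beta cutoff (default 0.3); positive
#'   means are hyper-, negative hypo-methylated.
#' @param alpha Significance level for the rank-sum test (default 0.05,
#'   uncorrected as is conventional for this caller).
#' @param minCpgs Minimum member CpG groups (default 5; the rank-sum test has
#'   essentially no power below 4).
#' @param bhCorrect If \code{TRUE}, apply Benjamini-Hochberg correction across
#'   the segments of this call before thresholding (off by default).
#' @return A \link[GenomicRanges]{GRanges} (1-based, closed) with metadata
#'   columns \code{n_cpg_groups}, \code{mean_delta_beta}, \code{p_value},
#'   \code{direction}, \code{cpg_density}, \code{resolution_class}.
#' @examples
#' trk <- exampleDeltaTrack(60)
#' p <- estimateSLMParams(trk)
#' callDMRs(viterbiSegment(trk, p), trk)
#' @export
callDMRs <- function(seg, track, cutoff = 0.3, alpha = 0.05, minCpgs = 5L,
                     bhCorrect = FALSE) {
    stopifnot(is(seg, "Segmentation"), is(track, "DeltaBetaTrack"),
              seg@nSites == length(track))
    k <- nSegments(seg)
    if (!k) return(.emptyDMRs())
    pvals <- rep(1, k)
    cand <- which(abs(seg@meanDeltaBeta) > cutoff &
                  (seg@lastIndex - seg@firstIndex + 1L) >= minCpgs)
    for (i in cand) {
        idx <- seg@firstIndex[i]:seg@lastIndex[i]
        pvals[i] <- segmentWilcoxon(betaTest(track)[idx],
                                    betaControl(track)[idx])
    }
    padj <- if (bhCorrect) stats::p.adjust(pvals, "BH") else pvals
    keep <- intersect(cand, which(padj < alpha))
    if (!length(keep)) return(.emptyDMRs())
    keep <- keep[order(seg@firstIndex[keep])]
    start0 <- cpgStarts(track)[seg@firstIndex[keep]]
    end0 <- cpgEnds(track)[seg@lastIndex[keep]]
    nMot <- vapply(keep, function(i)
        sum(nMotifs(track)[seg@firstIndex[i]:seg@lastIndex[i]]), 1L)
    widths <- end0 - start0
    if (any(widths <= 0))
        stop("zero-length DMR interval; cannot compute CpG density",
             call. = FALSE)
    dens <- 100 * nMot / widths
    gr <- GenomicRanges::GRanges(
        seqnames = chrom(track),
        ranges = IRanges::IRanges(start = start0 + 1, end = end0))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        n_cpg_groups = seg@lastIndex[keep] - seg@firstIndex[keep] + 1L,
        mean_delta_beta = seg@meanDeltaBeta[keep],
        p_value = padj[keep],
        direction = ifelse(seg@meanDeltaBeta[keep] > 0, "hyper", "hypo"),
        cpg_density = dens,
        resolution_class = .densityClass(dens))
    gr
}

.emptyDMRs <- function() {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        n_cpg_groups = integer(), mean_delta_beta = numeric(),
        p_value = numeric(), direction = character(),
        cpg_density = numeric(), resolution_class = character())
    gr
}

#' End-to-end DMR calling for a sample pair
#'
#' Convenience pipeline: join two frequency tables into per-chromosome
#' delta-beta tracks, estimate the shifting-level-model parameters once from
#' the pooled lag-1 differences, Viterbi-segment each chromosome and call
#' DMRs.  Chromosomes with fewer than 10 joined CpG groups are skipped with a
#' warning (too short to segment).
#'
#' @param test,control Frequency \code{data.frame}s (canonical form, see
#'   \code{\link{readMethFreq}}) or paths to frequency TSV files.
#' @param minCalledSites Coverage filter for the join (default 5).
#' @param omega,theta,dNorm,nStates Model parameters, see
#'   \code{\link{estimateSLMParams}}.
#' @param cutoff,alpha,minCpgs,bhCorrect DMR thresholds, see
#'   \code{\link{callDMRs}}.
#' @return A list with components \code{tracks} (per-chromosome
#'   \linkS4class{DeltaBetaTrack}s), \code{params}
#'   (\linkS4class{SLMParams}), \code{segments} (per-chromosome
#'   \linkS4class{Segmentation}s) and \code{dmrs} (one merged, sorted
#'   \link[GenomicRanges]{GRanges}).
#' @examples
#' sim <- simulateMethPair(simConfig(chromLength = 2e5, nDmrs = 3))
#' res <- dmrPipeline(sim$testFreq, sim$controlFreq)
#' res$dmrs
#' @export
dmrPipeline <- function(test, control, minCalledSites = 5L, omega = 0.9,
                        theta = 0.1, dNorm = 1000, nStates = 41L,
                        cutoff = 0.3, alpha = 0.05, minCpgs = 5L,
                        bhCorrect = FALSE) {
    if (is.character(test)) test <- readMethFreq(test)
    if (is.character(control)) control <- readMethFreq(control)
    tracks <- buildDeltaTrack(test, control, minCalledSites = minCalledSites)
    short <- vapply(tracks, length, 1L) < 10L
    if (any(short)) {
        warning("skipping chromosome(s) with < 10 joined CpG groups: ",
                paste(names(tracks)[short], collapse = ", "), call. = FALSE)
        tracks <- tracks[!short]
    }
    if (!length(tracks))
        stop("no chromosome has enough joined CpG groups to segment",
             call. = FALSE)
    params <- estimateSLMParams(tracks, omega = omega, theta = theta,
                                dNorm = dNorm, nStates = nStates)
    segments <- lapply(tracks, viterbiSegment, params = params)
    dmrList <- mapply(callDMRs, segments, tracks,
                      MoreArgs = list(cutoff = cutoff, alpha = alpha,
                                      minCpgs = minCpgs,
                                      bhCorrect = bhCorrect),
                      SIMPLIFY = FALSE)
    dmrs <- suppressWarnings(do.call(c, unname(dmrList)))
    dmrs <- GenomicRanges::sort(dmrs)
    if (length(dmrs))
        dmrs$dmr_id <- paste0("dmr", seq_along(dmrs))
    list(tracks = tracks, params = params, segments = segments, dmrs = dmrs)
}

#' Export DMRs as a BED-like TSV
#'
#' Columns: \code{chrom}, \code{start}, \code{end} (0-based half-open),
#' \code{dmr_id}, \code{mean_delta_beta}, \code{strand} ("."),
#' \code{n_cpg_groups}, \code{p_value}, \code{direction},
#' \code{cpg_density}, \code{resolution_class}; rows sorted by coordinate.
#'
#' @param dmrs DMR \link[GenomicRanges]{GRanges} from \code{\link{callDMRs}}
#'   or \code{\link{dmrPipeline}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
exportDMRs <- function(dmrs, path) {
    dmrs <- GenomicRanges::sort(dmrs)
    ids <- if (!is.null(dmrs$dmr_id)) dmrs$dmr_id
           else paste0("dmr", seq_along(dmrs))
    out <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(dmrs)),
        start = format(GenomicRanges::start(dmrs) - 1, scientific = FALSE,
                       trim = TRUE),
        end = format(GenomicRanges::end(dmrs), scientific = FALSE,
                     trim = TRUE),
        dmr_id = ids,
        mean_delta_beta = formatC(dmrs$mean_delta_beta, format = "g",
                                  digits = 17),
        strand = rep(".", length(dmrs)),
        n_cpg_groups = dmrs$n_cpg_groups,
        p_value = formatC(dmrs$p_value, format = "g", digits = 17),
        direction = dmrs$direction,
        cpg_density = formatC(dmrs$cpg_density, format = "g", digits = 17),
        resolution_class = dmrs$resolution_class,
        stringsAsFactors = FALSE)
    names(out)[1L] <- "#chrom"
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a DMR TSV written by \code{\link{exportDMRs}}
#'
#' @param path Path to the TSV.
#' @return A DMR \link[GenomicRanges]{GRanges}.
#' @export
readDMRs <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    names(df)[1L] <- sub("^#", "", names(df)[1L])
    gr <- GenomicRanges::GRanges(
        seqnames = df$chrom,
        ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        df[, setdiff(names(df), c("chrom", "start", "end", "strand")),
           drop = FALSE])
    gr
}

#' Run summary of a DMR set
#'
#' Counts and total genomic extent (kb) of hyper- and hypo-methylated DMRs,
#' plus the share of DMRs below the common short-read resolution limits
#' (2 and 3 CpG per 100 bp).
#'
#' @param dmrs DMR \link[GenomicRanges]{GRanges}.
#' @param path Optional path; if given the summary is also written as JSON.
#' @return A list with elements \code{n_total}, \code{n_hyper},
#'   \code{n_hypo}, \code{kb_hyper}, \code{kb_hypo}, \code{frac_le2},
#'   \code{frac_le3}.
#' @export
dmrSummary <- function(dmrs, path = NULL) {
    hyper <- dmrs$direction == "hyper"
    s <- list(
        n_total = length(dmrs),
        n_hyper = sum(hyper),
        n_hypo = sum(!hyper),
        kb_hyper = sum(GenomicRanges::width(dmrs)[hyper]) / 1000,
        kb_hypo = sum(GenomicRanges::width(dmrs)[!hyper]) / 1000,
        frac_le2 = if (length(dmrs))
            mean(dmrs$resolution_class == "<=2") else NA_real_,
        frac_le3 = if (length(dmrs))
            mean(dmrs$resolution_class %in% c("<=2", "<=3")) else NA_real_)
    if (!is.null(path))
        jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA)
    s
}
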