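## Observed-vs-expected enrichment of DMRs in genomic features with a
## Monte Carlo null.
##
## The statistic is log2((Size_GF^DMR / Size_Total^DMR) /
## (Size_GF^Genome / Size_Total^Genome)): the fraction of total DMR base
## pairs belonging to DMRs that overlap the feature, relative to the
## feature's fraction of the genome.  Significance is the relative ranking of
## the observed statistic among statistics recomputed on randomly placed
## segment sets with the same size multiset as the real DMRs.

#' Observed-vs-expected log2 ratio
#'
#' @param overlapBp Total size (bp) of DMRs overlapping the feature.
#' @param totalDmrBp Total size (bp) of all DMRs.
#' @param featureBp Total size (bp) of the feature in the genome.
#' @param genomeBp Total genome size (bp).
#' @return \code{log2((overlapBp/totalDmrBp)/(featureBp/genomeBp))}.  A zero
#'   overlap returns \code{-Inf} (depleted below the resolution of the
#'   inputs); \code{featureBp = 0} is an error.
#' @examples
#' log2ObsExp(2e5, 1e6, 3e7, 3e8)  # = 1: twofold over-representation
#' @export
log2ObsExp <- function(overlapBp, totalDmrBp, featureBp, genomeBp) {
    if (any(featureBp <= 0))
        stop("'featureBp' must be > 0", call. = FALSE)
    if (any(totalDmrBp <= 0) || any(genomeBp <= 0))
        stop("'totalDmrBp' and 'genomeBp' must be > 0", call. = FALSE)
    if (any(overlapBp < 0))
        stop("'overlapBp' must be >= 0", call. = FALSE)
    log2((overlapBp / totalDmrBp) / (featureBp / genomeBp))
}

#' Read a UCSC-style chromosome sizes table
#'
#' @param path Two-column TSV (chromosome name, length in bp), no header.
#' @return A named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
    df <- utils::read.delim(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    stats::setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}

## Per-chromosome step function of cumulative feature coverage; returns, for
## 0-based positions x, the feature bp in [0, x).  Used to decide overlap of
## many random segments quickly.
.coverageLookup <- function(features) {
    red <- GenomicRanges::reduce(features, ignore.strand = TRUE)
    split(data.frame(start = GenomicRanges::start(red) - 1,
                     end = GenomicRanges::end(red)),
          as.character(GenomicRanges::seqnames(red)))
}

.coveredBp <- function(lookup, chromName, s, e) {
    ## vectorised over s, e (0-based half-open query intervals)
    iv <- lookup[[chromName]]
    if (is.null(iv)) return(numeric(length(s)))
    cum <- c(0, cumsum(iv$end - iv$start))
    F <- function(x) {
        i <- findInterval(x, iv$start)
        j <- pmax(i, 1L)
        out <- cum[j] + pmin(x, iv$end[j]) - iv$start[j]
        out[i == 0L] <- 0
        out
    }
    F(e) - F(s)
}

## Returns a closure that draws one random placement of segments with the
## given size multiset: chromosome proportional to length among chromosomes
## long enough to hold the segment, start uniform within bounds.  Segments
## sharing a fit pattern are drawn together for speed.
.randomPlacement <- function(sizes, chromSizes) {
    n <- length(sizes)
    chromNames <- names(chromSizes)
    fits <- outer(sizes, chromSizes, `<=`)
    pat <- apply(fits, 1L, paste, collapse = "")
    patRows <- split(seq_len(n), match(pat, unique(pat)))
    patProb <- lapply(patRows, function(r) chromSizes * fits[r[1L], ])
    function() {
        ci <- integer(n)
        for (g in seq_along(patRows))
            ci[patRows[[g]]] <- sample.int(length(chromSizes),
                                           length(patRows[[g]]),
                                           replace = TRUE,
                                           prob = patProb[[g]])
        starts <- floor(stats::runif(n) * (chromSizes[ci] - sizes + 1))
        list(chrom = chromNames[ci], start = unname(starts),
             end = unname(starts + sizes))
    }
}

## Size_GF^DMR: total bp of DMRs overlapping the feature (>= 1 bp).
.overlapDmrBp <- function(dmrs, features) {
    hits <- GenomicRanges::findOverlaps(dmrs, features, minoverlap = 1L,
                                        ignore.strand = TRUE)
    idx <- unique(S4Vectors::queryHits(hits))
    sum(GenomicRanges::width(dmrs)[idx])
}

#' Monte Carlo enrichment test of DMRs in a genomic feature
#'
#' Computes the observed \code{\link{log2ObsExp}} statistic and its empirical
#' two-sided p-value: in each of \code{nSims} simulations, \code{n} segments
#' (\code{n} = number of DMRs) with exactly the same size multiset as the
#' real DMRs are placed uniformly at random on the genome (chromosome drawn
#' with probability proportional to its length among chromosomes long enough
#' to hold the segment, start uniform so the segment stays within bounds) and
#' the statistic is recomputed.  Extremeness is measured two-sided as the
#' absolute deviation of the observed/expected ratio from the median
#' simulated ratio (on the linear scale, so that zero-overlap simulations
#' rank as depletion rather than dominating every comparison), and
#' \code{p = (1 + #\{simulations at least as extreme\}) / (nSims + 1)}, so p
#' is never 0 and its minimum halves when \code{nSims} doubles.
#'
#' @param dmrs DMR \link[GenomicRanges]{GRanges}.
#' @param features Feature \link[GenomicRanges]{GRanges} (one category).
#' @param chromSizes Named vector of chromosome lengths (bp), e.g. from
#'   \code{\link{readChromSizes}}.
#' @param nSims Number of simulations (>= 100; default 10000.  Large-scale
#'   analyses typically use many more; the default keeps a single feature
#'   test interactive).
#' @param seed Integer seed; fixed seed + fixed inputs give bit-identical
#'   results.
#' @param featureCategory Label copied to the output row.
#' @return One-row \code{data.frame}: \code{feature_category},
#'   \code{log2_oe}, \code{observed_overlap_bp}, \code{total_dmr_bp},
#'   \code{feature_bp}, \code{genome_bp}, \code{p_value}, \code{n_sims},
#'   \code{seed}.
#' @examples
#' dmrs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:5 * 1e4, width = 500))
#' cgi <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2e4, width = 1e4))
#' enrichmentTest(dmrs, cgi, c(chr1 = 1e6), nSims = 200, seed = 1)
#' @export
enrichmentTest <- function(dmrs, features, chromSizes, nSims = 10000L,
                           seed = 1L, featureCategory = NA_character_) {
    if (nSims < 100L) stop("'nSims' must be >= 100", call. = FALSE)
    if (!length(dmrs)) stop("no DMRs to test", call. = FALSE)
    sizes <- GenomicRanges::width(dmrs)
    if (max(sizes) > max(chromSizes))
        stop("a DMR is longer than every chromosome", call. = FALSE)
    genomeBp <- sum(chromSizes)
    lookup <- .coverageLookup(features)
    featureBp <- sum(vapply(lookup, function(iv) sum(iv$end - iv$start), 1.0))
    if (featureBp <= 0) stop("'features' cover no base pairs", call. = FALSE)
    totalDmrBp <- sum(sizes)
    obs <- log2ObsExp(.overlapDmrBp(dmrs, features), totalDmrBp, featureBp,
                      genomeBp)

    place <- .randomPlacement(sizes, chromSizes)
    set.seed(seed)
    sims <- vapply(seq_len(nSims), function(s) {
        seg <- place()
        hit <- logical(length(sizes))
        for (ch in unique(seg$chrom)) {
            j <- seg$chrom == ch
            hit[j] <- .coveredBp(lookup, ch, seg$start[j], seg$end[j]) > 0
        }
        log2ObsExp(sum(sizes[hit]), totalDmrBp, featureBp, genomeBp)
    }, 1.0)

    ## two-sided extremeness as absolute deviation from the median simulated
    ## observed/expected ratio; the linear-ratio scale keeps zero-overlap
    ## simulations (log2 = -Inf) finite and comparable
    simRatio <- 2^sims
    obsRatio <- 2^obs
    med <- stats::median(simRatio)
    extreme <- abs(simRatio - med) >= abs(obsRatio - med)
    p <- (1 + sum(extreme)) / (nSims + 1)
    data.frame(feature_category = featureCategory, log2_oe = obs,
               observed_overlap_bp = .overlapDmrBp(dmrs, features),
               total_dmr_bp = totalDmrBp, feature_bp = featureBp,
               genome_bp = genomeBp, p_value = p, n_sims = nSims,
               seed = seed, stringsAsFactors = FALSE)
}

#' Enrichment tests across feature categories
#'
#' Runs \code{\link{enrichmentTest}} once per feature category present in
#' \code{features}, optionally split by DMR direction as in the standard
#' hyper/hypo-stratified analysis.
#'
#' @inheritParams enrichmentTest
#' @param byDirection If \code{TRUE}, test hyper- and hypo-methylated DMRs
#'   separately (requires a \code{direction} metadata column).
#' @return A \code{data.frame} with one row per (category, direction) pair.
#' @export
enrichmentByCategory <- function(dmrs, features, chromSizes, nSims = 10000L,
                                 seed = 1L, byDirection = FALSE) {
    cats <- unique(as.character(features$category))
    sets <- if (byDirection)
        split(dmrs, dmrs$direction)
    else list(all = dmrs)
    rows <- list()
    for (dir in names(sets)) {
        if (!length(sets[[dir]])) next
        for (ct in cats) {
            r <- enrichmentTest(sets[[dir]], features[features$category == ct],
                                chromSizes, nSims = nSims, seed = seed,
                                featureCategory = ct)
            r$direction <- dir
            rows[[length(rows) + 1L]] <- r
        }
    }
    do.call(rbind, rows)
}
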