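## Synthetic methylome pair generator and benchmark scorer.
##
## The generator emulates the structure the caller assumes: long stretches of
## sparse background CpGs alternating with short dense CpG islands (two-rate
## spacing process), a bimodal baseline methylation level (islands
## unmethylated, background methylated), planted DMRs that shift beta in the
## test sample only, Poisson-like read coverage, and beta-binomial counting
## noise with within-read correlation through a shared read-level draw.

#' Configuration for the synthetic methylome generator
#'
#' Defaults describe a desk-scale in-silico validation world: one 1 Mb
#' chromosome whose CpG spacing alternates between dense islands (mean 20 bp
#' between CpGs, ~25 CpGs per island) and sparse background (mean 150 bp,
#' ~75 CpGs between islands), unmethylated islands (beta 0.1) in a methylated
#' background (beta 0.9), 20x mean coverage, and 20 planted DMRs of 20 CpG
#' groups shifting beta by 0.5.  Hyper-methylated DMRs are planted inside
#' islands and hypo-methylated ones in the background, so the shifted beta
#' stays inside [0, 1] at full effect.
#'
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @param nChroms,chromLength Number and length (bp) of simulated
#'   chromosomes.
#' @param islandSpacing,backgroundSpacing Mean inter-CpG distance (bp) inside
#'   and outside islands.
#' @param islandCpgs Mean CpGs per island.
#' @param islandEvery Mean background CpGs between consecutive islands.
#' @param coverage Mean reads per CpG site.
#' @param betaIsland,betaBackground Baseline methylation levels.
#' @param nDmrs,dmrLengthCpgs,effect,fracHyper Planted DMRs per chromosome,
#'   their length in CpG groups, the absolute beta shift, and the fraction
#'   that is hyper-methylated (placed in islands; the rest is hypo-methylated
#'   background).
#' @param readLengthCpgs CpG sites covered by one read (long-read regime).
#' @param precision Beta-binomial precision of the counting noise (larger is
#'   closer to binomial).
#' @param noiseModel \code{"betabinom"} (default) or \code{"binom"}
#'   (pure binomial sampling, no biological overdispersion).
#' @param pAmbiguous Fraction of per-read calls with |LLR| below the calling
#'   threshold (emitted but excluded from counting).
#' @return A list of class \code{"simConfig"}.
#' @examples
#' simConfig(chromLength = 2e5, nDmrs = 3)
#' @export
simConfig <- function(seed = 1L, nChroms = 1L, chromLength = 1e6,
                      islandSpacing = 20, backgroundSpacing = 150,
                      islandCpgs = 25, islandEvery = 75, coverage = 20,
                      betaIsland = 0.1, betaBackground = 0.9, nDmrs = 20L,
                      dmrLengthCpgs = 20L, effect = 0.5, fracHyper = 0.5,
                      readLengthCpgs = 20L, precision = 20,
                      noiseModel = c("betabinom", "binom"),
                      pAmbiguous = 0.05) {
    noiseModel <- match.arg(noiseModel)
    cfg <- list(seed = as.integer(seed), nChroms = as.integer(nChroms),
                chromLength = chromLength, islandSpacing = islandSpacing,
                backgroundSpacing = backgroundSpacing,
                islandCpgs = islandCpgs, islandEvery = islandEvery,
                coverage = coverage, betaIsland = betaIsland,
                betaBackground = betaBackground, nDmrs = as.integer(nDmrs),
                dmrLengthCpgs = as.integer(dmrLengthCpgs), effect = effect,
                fracHyper = fracHyper,
                readLengthCpgs = as.integer(readLengthCpgs),
                precision = precision, noiseModel = noiseModel,
                pAmbiguous = pAmbiguous)
    stopifnot(cfg$chromLength > 0, cfg$islandSpacing > 0,
              cfg$backgroundSpacing > 0, cfg$coverage > 0,
              cfg$effect >= 0, cfg$effect <= 1,
              cfg$fracHyper >= 0, cfg$fracHyper <= 1,
              cfg$betaIsland >= 0, cfg$betaIsland <= 1,
              cfg$betaBackground >= 0, cfg$betaBackground <= 1,
              cfg$precision > 0, cfg$pAmbiguous >= 0, cfg$pAmbiguous < 1)
    class(cfg) <- "simConfig"
    cfg
}

## CpG positions for one chromosome: alternate background runs and islands.
.simPositions <- function(cfg) {
    pos <- numeric(0)
    isIsland <- logical(0)
    islandStart <- numeric(0)
    islandEnd <- numeric(0)
    cur <- 10
    while (cur < cfg$chromLength) {
        nB <- stats::rgeom(1L, 1 / cfg$islandEvery) + 1L
        gaps <- pmax(2, round(stats::rexp(nB, 1 / cfg$backgroundSpacing)))
        p <- cur + cumsum(gaps)
        p <- p[p < cfg$chromLength]
        pos <- c(pos, p)
        isIsland <- c(isIsland, rep(FALSE, length(p)))
        if (length(p)) cur <- p[length(p)]
        if (cur >= cfg$chromLength) break
        nI <- max(5L, stats::rpois(1L, cfg$islandCpgs))
        gaps <- pmax(2, round(stats::rexp(nI, 1 / cfg$islandSpacing)))
        p <- cur + 200 + cumsum(gaps)  # short buffer before the island
        p <- p[p < cfg$chromLength]
        if (length(p)) {
            pos <- c(pos, p)
            isIsland <- c(isIsland, rep(TRUE, length(p)))
            islandStart <- c(islandStart, p[1L])
            islandEnd <- c(islandEnd, p[length(p)] + 2)
            cur <- p[length(p)] + 200
        } else cur <- cfg$chromLength
    }
    list(pos = pos, isIsland = isIsland,
         islands = cbind(start = islandStart, end = islandEnd))
}

## Choose non-overlapping planted runs of dmrLengthCpgs consecutive CpGs.
.plantDmrs <- function(isIsland, cfg) {
    L <- cfg$dmrLengthCpgs
    nHyper <- round(cfg$nDmrs * cfg$fracHyper)
    nHypo <- cfg$nDmrs - nHyper
    runs <- rle(isIsland)
    runEnd <- cumsum(runs$lengths)
    runStart <- runEnd - runs$lengths + 1L
    pickRuns <- function(inIsland, howMany) {
        ok <- which(runs$values == inIsland & runs$lengths >= L)
        if (length(ok) < howMany)
            stop("DMR placement impossible: only ", length(ok),
                 if (inIsland) " island" else " background",
                 " runs of >= ", L, " CpGs for ", howMany, " DMRs",
                 call. = FALSE)
        ok <- sample(ok, howMany)
        vapply(ok, function(r)
            runStart[r] + sample.int(runs$lengths[r] - L + 1L, 1L) - 1L, 1L)
    }
    starts <- c(if (nHyper) pickRuns(TRUE, nHyper) else integer(),
                if (nHypo) pickRuns(FALSE, nHypo) else integer())
    data.frame(first = starts,
               last = starts + L - 1L,
               direction = c(rep("hyper", nHyper), rep("hypo", nHypo)),
               stringsAsFactors = FALSE)
}

## Simulate per-read calls for one sample over one chromosome.
.simReads <- function(pos, beta, cfg, prefix) {
    S <- length(pos)
    readLen <- min(cfg$readLengthCpgs, S)
    nReads <- ceiling(S * cfg$coverage / readLen)
    firstSite <- sample.int(S, nReads, replace = TRUE)
    lens <- pmin(readLen, S - firstSite + 1L)
    readIdx <- rep.int(seq_len(nReads), lens)
    siteIdx <- unlist(lapply(seq_len(nReads), function(r)
        firstSite[r]:(firstSite[r] + lens[r] - 1L)), use.names = FALSE)
    b <- beta[siteIdx]
    if (cfg$noiseModel == "betabinom") {
        u <- stats::runif(nReads)[readIdx]  # shared read-level draw
        bc <- pmin(1 - 1e-4, pmax(1e-4, b))
        p <- stats::qbeta(u, bc * cfg$precision, (1 - bc) * cfg$precision)
    } else {
        p <- b
    }
    meth <- stats::rbinom(length(p), 1L, p)
    nEv <- length(meth)
    amb <- stats::runif(nEv) < cfg$pAmbiguous
    llr <- ifelse(meth == 1L, 1, -1) * stats::runif(nEv, 3, 15)
    llr[amb] <- stats::runif(sum(amb), -2.4, 2.4)
    label <- rep("ambiguous", nEv)
    label[!amb & meth == 1L] <- "methylated"
    label[!amb & meth == 0L] <- "unmethylated"
    ord <- order(siteIdx, readIdx)
    data.frame(strand = "+",
               start = pos[siteIdx[ord]], end = pos[siteIdx[ord]] + 2,
               read_id = sprintf("%s%06d", prefix, readIdx[ord]),
               log_lik_ratio = llr[ord], num_motifs = 1L,
               label = label[ord], stringsAsFactors = FALSE)
}

#' Simulate a test/control methylome pair with planted DMRs
#'
#' Generates CpG positions from the two-rate island/background spacing
#' process, assigns the bimodal baseline beta, plants DMRs (beta shifted by
#' \code{+effect} for hyper- and \code{-effect} for hypo-methylated regions,
#' clipped to [0, 1]) in the test sample only, simulates reads for both
#' samples, and aggregates the resulting per-read calls into frequency
#' tables with \code{\link{callsToFrequency}}.  Deterministic given
#' \code{config$seed}.
#'
#' @param config A \code{\link{simConfig}}.
#' @return A list: \code{testCalls}, \code{controlCalls} (labelled call
#'   \code{data.frame}s), \code{testFreq}, \code{controlFreq} (frequency
#'   \code{data.frame}s), \code{truth} (planted DMRs as a 1-based
#'   \link[GenomicRanges]{GRanges} with \code{direction} and \code{n_cpgs}),
#'   \code{islands} (island spans as \link[GenomicRanges]{GRanges}) and
#'   \code{config}.
#' @examples
#' sim <- simulateMethPair(simConfig(chromLength = 2e5, nDmrs = 3))
#' sim$truth
#' @export
simulateMethPair <- function(config) {
    stopifnot(inherits(config, "simConfig"))
    set.seed(config$seed)
    testCalls <- controlCalls <- list()
    truth <- list()
    islands <- list()
    for (ci in seq_len(config$nChroms)) {
        chromName <- paste0("chrS", ci)
        geo <- .simPositions(config)
        pos <- geo$pos
        beta0 <- ifelse(geo$isIsland, config$betaIsland,
                        config$betaBackground)
        betaTest <- beta0
        if (config$nDmrs > 0L) {
            plants <- .plantDmrs(geo$isIsland, config)
            for (k in seq_len(nrow(plants))) {
                idx <- plants$first[k]:plants$last[k]
                shift <- if (plants$direction[k] == "hyper") config$effect
                         else -config$effect
                betaTest[idx] <- pmin(1, pmax(0, beta0[idx] + shift))
            }
            truth[[ci]] <- data.frame(
                chrom = chromName, start = pos[plants$first],
                end = pos[plants$last] + 2, direction = plants$direction,
                n_cpgs = plants$last - plants$first + 1L,
                stringsAsFactors = FALSE)
        }
        tc <- .simReads(pos, betaTest, config, "t")
        cc <- .simReads(pos, beta0, config, "c")
        tc <- cbind(chrom = chromName, tc, stringsAsFactors = FALSE)
        cc <- cbind(chrom = chromName, cc, stringsAsFactors = FALSE)
        testCalls[[ci]] <- tc
        controlCalls[[ci]] <- cc
        if (nrow(geo$islands))
            islands[[ci]] <- data.frame(chrom = chromName,
                                        start = geo$islands[, "start"],
                                        end = geo$islands[, "end"],
                                        stringsAsFactors = FALSE)
    }
    testCalls <- do.call(rbind, testCalls)
    controlCalls <- do.call(rbind, controlCalls)
    truthDf <- if (length(truth)) do.call(rbind, truth) else
        data.frame(chrom = character(), start = numeric(), end = numeric(),
                   direction = character(), n_cpgs = integer())
    truthGr <- GenomicRanges::GRanges(
        seqnames = truthDf$chrom,
        ranges = IRanges::IRanges(start = truthDf$start + 1,
                                  end = truthDf$end))
    truthGr$direction <- truthDf$direction
    truthGr$n_cpgs <- truthDf$n_cpgs
    islandsDf <- if (length(islands)) do.call(rbind, islands) else
        data.frame(chrom = character(), start = numeric(), end = numeric())
    islandsGr <- GenomicRanges::GRanges(
        seqnames = islandsDf$chrom,
        ranges = IRanges::IRanges(start = islandsDf$start + 1,
                                  end = islandsDf$end))
    list(testCalls = testCalls, controlCalls = controlCalls,
         testFreq = callsToFrequency(testCalls),
         controlFreq = callsToFrequency(controlCalls),
         truth = GenomicRanges::sort(truthGr),
         islands = islandsGr, config = config)
}

.labelByOverlap <- function(points, regions) {
    lab <- rep("null", length(points))
    if (!length(regions)) return(lab)
    hits <- GenomicRanges::findOverlaps(points, regions, minoverlap = 1L,
                                        ignore.strand = TRUE)
    lab[S4Vectors::queryHits(hits)] <-
        regions$direction[S4Vectors::subjectHits(hits)]
    lab
}

.prf <- function(tp, fp, fn) {
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
        2 * precision * recall / (precision + recall) else NA_real_
    c(precision = precision, recall = recall, f1 = f1)
}

#' Score called DMRs against the planted truth
#'
#' CpG-level scoring labels every CpG group of the track(s) \code{hyper},
#' \code{hypo} or \code{null} once by the truth intervals and once by the
#' called intervals; a true positive is a group with matching non-null
#' labels, and a direction mismatch counts as both a false positive and a
#' false negative.  DMR-level scoring matches called to truth DMRs of the
#' same direction at >= \code{reciprocal} reciprocal overlap.
#'
#' @param called Called DMR \link[GenomicRanges]{GRanges} (with
#'   \code{direction}).
#' @param truth Truth \link[GenomicRanges]{GRanges} (with \code{direction};
#'   from \code{\link{simulateMethPair}}).
#' @param tracks A \linkS4class{DeltaBetaTrack} or list of them, defining the
#'   CpG coordinate system.  Called DMRs on chromosomes absent from the
#'   tracks are a coordinate-system mismatch and raise an error.
#' @param reciprocal Reciprocal-overlap fraction for DMR-level matching
#'   (default 0.5).
#' @return A list: \code{cpg} (pooled precision/recall/F1 plus per-direction
#'   rows), \code{dmr} (TP/FP/FN counts at DMR level) and \code{strata}
#'   (per truth-DMR CpG-density class recall).
#' @examples
#' sim <- simulateMethPair(simConfig(chromLength = 3e5, nDmrs = 4))
#' res <- dmrPipeline(sim$testFreq, sim$controlFreq)
#' scoreDMRCalls(res$dmrs, sim$truth, res$tracks)$cpg
#' @export
scoreDMRCalls <- function(called, truth, tracks, reciprocal = 0.5) {
    if (is(tracks, "DeltaBetaTrack")) tracks <- list(tracks)
    trackChroms <- vapply(tracks, chrom, "")
    badChrom <- setdiff(as.character(GenomicRanges::seqnames(called)),
                        trackChroms)
    if (length(badChrom))
        stop("called DMRs on chromosome(s) absent from the track: ",
             paste(badChrom, collapse = ", "), call. = FALSE)
    pts <- do.call(c, unname(lapply(tracks, function(trk)
        GenomicRanges::GRanges(chrom(trk),
                               IRanges::IRanges(cpgStarts(trk) + 1,
                                                width = 1L)))))
    truthLab <- .labelByOverlap(pts, truth)
    callLab <- .labelByOverlap(pts, called)
    tp <- sum(callLab != "null" & callLab == truthLab)
    fp <- sum(callLab != "null" & callLab != truthLab)
    fn <- sum(truthLab != "null" & callLab != truthLab)
    pooled <- .prf(tp, fp, fn)
    perDir <- lapply(c("hyper", "hypo"), function(d)
        .prf(sum(callLab == d & truthLab == d),
             sum(callLab == d & truthLab != d),
             sum(truthLab == d & callLab != d)))
    cpg <- data.frame(direction = c("pooled", "hyper", "hypo"),
                      rbind(pooled, perDir[[1L]], perDir[[2L]]),
                      row.names = NULL)

    matched <- .matchReciprocal(called, truth, reciprocal)
    dmr <- list(tp = sum(matched$calledMatched),
                fp = sum(!matched$calledMatched),
                fn = sum(!matched$truthMatched))

    strata <- NULL
    if (length(truth)) {
        dens <- 100 * truth$n_cpgs / GenomicRanges::width(truth)
        cls <- .densityClass(dens)
        strata <- do.call(rbind, lapply(unique(cls), function(cl) {
            i <- cls == cl
            data.frame(density_class = cl, n_truth = sum(i),
                       n_matched = sum(matched$truthMatched[i]),
                       recall = mean(matched$truthMatched[i]),
                       stringsAsFactors = FALSE)
        }))
    }
    list(cpg = cpg, dmr = dmr, strata = strata)
}

.matchReciprocal <- function(called, truth, reciprocal) {
    calledMatched <- logical(length(called))
    truthMatched <- logical(length(truth))
    if (length(called) && length(truth)) {
        hits <- GenomicRanges::findOverlaps(called, truth,
                                            ignore.strand = TRUE)
        for (h in seq_len(length(hits))) {
            i <- S4Vectors::queryHits(hits)[h]
            j <- S4Vectors::subjectHits(hits)[h]
            if (called$direction[i] != truth$direction[j]) next
            ow <- GenomicRanges::width(GenomicRanges::pintersect(
                called[i], truth[j]))
            if (ow >= reciprocal * GenomicRanges::width(called[i]) &&
                ow >= reciprocal * GenomicRanges::width(truth[j])) {
                calledMatched[i] <- TRUE
                truthMatched[j] <- TRUE
            }
        }
    }
    list(calledMatched = calledMatched, truthMatched = truthMatched)
}

#' Run the simulate-call-score benchmark
#'
#' For each replicate, simulates a methylome pair, runs
#' \code{\link{dmrPipeline}} with the given caller settings and scores the
#' calls against the planted truth.  Replicate \code{r} uses seed
#' \code{seed + r - 1}.
#'
#' @param config A \code{\link{simConfig}} (its \code{seed} is overridden per
#'   replicate).
#' @param replicates Number of replicates.
#' @param seed Base seed.
#' @param ... Passed to \code{\link{dmrPipeline}}.
#' @return A \code{data.frame} with one row per replicate: seed, CpG-level
#'   pooled precision/recall/F1, DMR-level TP/FP/FN and the number of called
#'   DMRs.
#' @examples
#' runBenchmark(simConfig(chromLength = 2e5, nDmrs = 3), replicates = 2)
#' @export
runBenchmark <- function(config, replicates = 10L, seed = 1L, ...) {
    rows <- lapply(seq_len(replicates), function(r) {
        cfg <- config
        cfg$seed <- as.integer(seed + r - 1L)
        sim <- simulateMethPair(cfg)
        res <- dmrPipeline(sim$testFreq, sim$controlFreq, ...)
        sc <- scoreDMRCalls(res$dmrs, sim$truth, res$tracks)
        pooled <- sc$cpg[sc$cpg$direction == "pooled", ]
        data.frame(seed = cfg$seed, cpg_precision = pooled$precision,
                   cpg_recall = pooled$recall, cpg_f1 = pooled$f1,
                   dmr_tp = sc$dmr$tp, dmr_fp = sc$dmr$fp,
                   dmr_fn = sc$dmr$fn, n_called = length(res$dmrs))
    })
    do.call(rbind, rows)
}
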