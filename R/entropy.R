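## Read-level methylation entropy.
##
## Over a window of b consecutive CpG sites, each read covering all b sites
## contributes one binary methylation pattern; the methylation entropy is the
## Shannon entropy of the pattern distribution, normalised per site:
## ME = (1/b) * sum_i -(n_i/N) log2(n_i/N).  ME is 0 when every read shows
## the same pattern and 1 when all 2^b patterns are equally frequent.

#' Methylation entropy of one pattern multiset
#'
#' @param patterns Character vector of binary pattern strings (e.g.
#'   \code{"101"}), one per read, all the same length \code{b}; or a 0/1
#'   matrix with one row per read and \code{b} columns.
#' @return Methylation entropy in [0, 1].
#' @examples
#' patternEntropy(c("000", "001", "010", "011", "100", "101", "110", "111"))
#' patternEntropy(c("00", "00", "11", "11"))  # b = 2, two patterns -> 0.5
#' @export
patternEntropy <- function(patterns) {
    if (is.matrix(patterns))
        patterns <- apply(patterns, 1L, paste, collapse = "")
    if (!length(patterns)) stop("no patterns", call. = FALSE)
    b <- unique(nchar(patterns))
    if (length(b) != 1L || b < 1L)
        stop("patterns must all have the same positive length", call. = FALSE)
    p <- table(patterns) / length(patterns)
    sum(-p * log2(p)) / b
}

## Pivot per-read calls over a site set into a read x site matrix of 0/1/NA.
.patternMatrix <- function(calls, sites) {
    calls <- calls[calls$start %in% sites & calls$label != "ambiguous", ,
                   drop = FALSE]
    reads <- unique(calls$read_id)
    m <- matrix(NA_integer_, nrow = length(reads), ncol = length(sites),
                dimnames = list(reads, as.character(sites)))
    m[cbind(match(calls$read_id, reads), match(calls$start, sites))] <-
        as.integer(calls$label == "methylated")
    m
}

#' Methylation entropy of a genomic feature
#'
#' Slides a window of \code{b} consecutive CpG sites (step one site) across
#' the feature's ordered CpG sites.  In each window, reads with an
#' unambiguous call at all \code{b} sites contribute a pattern; windows with
#' fewer than \code{minReads} such reads are skipped.  The feature entropy is
#' the unweighted mean over eligible windows.
#'
#' @param calls Labelled per-read call \code{data.frame}
#'   (\code{\link{readMethCalls}} form) for the feature's chromosome.
#' @param feature Either a numeric \code{c(start, end)} 0-based half-open
#'   interval or a length-1 \link[GenomicRanges]{GRanges}.
#' @param b Window size in CpG sites (default 3; must be >= 2).
#' @param minReads Minimum informative reads per window (default 5).
#' @return A list: \code{mean_entropy} (NA if no window was eligible),
#'   \code{n_windows} (eligible), \code{n_skipped} (below coverage).
#' @examples
#' sim <- simulateMethPair(simConfig(chromLength = 5e4, nDmrs = 0))
#' featureEntropy(sim$testCalls, c(0, 5e4))
#' @export
featureEntropy <- function(calls, feature, b = 3L, minReads = 5L) {
    if (b < 2L) stop("'b' must be >= 2", call. = FALSE)
    if (is(feature, "GRanges")) {
        stopifnot(length(feature) == 1L)
        chromName <- as.character(GenomicRanges::seqnames(feature))
        calls <- calls[calls$chrom == chromName, , drop = FALSE]
        feature <- c(GenomicRanges::start(feature) - 1,
                     GenomicRanges::end(feature))
    }
    calls <- calls[calls$start >= feature[1L] & calls$start < feature[2L], ,
                   drop = FALSE]
    sites <- sort(unique(calls$start))
    if (length(sites) < b)
        return(list(mean_entropy = NA_real_, n_windows = 0L, n_skipped = 0L))
    m <- .patternMatrix(calls, sites)
    me <- numeric()
    skipped <- 0L
    for (j in seq_len(length(sites) - b + 1L)) {
        w <- m[, j:(j + b - 1L), drop = FALSE]
        full <- rowSums(is.na(w)) == 0L
        if (sum(full) < minReads) {
            skipped <- skipped + 1L
            next
        }
        me <- c(me, patternEntropy(w[full, , drop = FALSE]))
    }
    list(mean_entropy = if (length(me)) mean(me) else NA_real_,
         n_windows = length(me), n_skipped = skipped)
}

#' Methylation entropy per feature, as a table
#'
#' @param calls Labelled per-read call \code{data.frame}.
#' @param features Feature \link[GenomicRanges]{GRanges}.
#' @param b,minReads See \code{\link{featureEntropy}}.
#' @return A \code{data.frame} with one row per feature: \code{chrom},
#'   \code{start}, \code{end} (0-based), \code{name}, \code{n_windows},
#'   \code{mean_entropy}.
#' @export
featureEntropyTable <- function(calls, features, b = 3L, minReads = 5L) {
    rows <- lapply(seq_along(features), function(i) {
        fe <- featureEntropy(calls, features[i], b = b, minReads = minReads)
        data.frame(
            chrom = as.character(GenomicRanges::seqnames(features[i])),
            start = GenomicRanges::start(features[i]) - 1,
            end = GenomicRanges::end(features[i]),
            name = if (!is.null(features$name)) features$name[i]
                   else paste0("feature", i),
            n_windows = fe$n_windows,
            mean_entropy = fe$mean_entropy,
            stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
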