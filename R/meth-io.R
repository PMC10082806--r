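## Readers and writers for the two nanopore methylation TSV dialects
## (per-read calls and per-CpG-group frequencies), plus the two-sample join
## that produces the DeltaBetaTrack segmentation substrate.
##
## All coordinates are kept 0-based half-open internally; files are read and
## written as-is (both dialects are 0-based).

.CALL_COLS <- c("chromosome", "strand", "start", "end", "read_name",
                "log_lik_ratio", "num_motifs")
.FREQ_COLS <- c("chromosome", "start", "end", "num_motifs_in_group",
                "called_sites", "called_sites_methylated")

.checkColumns <- function(df, required, path) {
    missing <- setdiff(required, names(df))
    if (length(missing))
        stop("format error in '", path, "': missing mandatory column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
}

#' Read per-read methylation calls
#'
#' Reads a tab-separated per-read methylation call table (the
#' "call-methylation" dialect: one row per read per CpG group, with the
#' log-likelihood ratio of the methylated versus unmethylated signal model)
#' and labels each call.  A call is \code{methylated} when
#' \code{log_lik_ratio > minAbsLLR}, \code{unmethylated} when
#' \code{log_lik_ratio < -minAbsLLR} and \code{ambiguous} otherwise
#' (strict inequalities; values at exactly \code{+/-minAbsLLR} are ambiguous).
#' Ambiguous calls are retained in the returned table but are excluded from
#' all downstream counting.
#'
#' @param path Path to the TSV file (header required; columns are located by
#'   name, not position).
#' @param minAbsLLR Absolute log-likelihood-ratio threshold (default 2.5).
#' @return A \code{data.frame} with columns \code{chrom}, \code{strand},
#'   \code{start}, \code{end}, \code{read_id}, \code{log_lik_ratio},
#'   \code{num_motifs} and \code{label} (factor-free character:
#'   \code{"methylated"}, \code{"unmethylated"} or \code{"ambiguous"}).
#' @examples
#' calls <- data.frame(chromosome = "chr1", strand = "+", start = 100,
#'                     end = 102, read_name = "r1", log_lik_ratio = 3.1,
#'                     log_lik_methylated = 0, log_lik_unmethylated = 0,
#'                     num_calling_strands = 1, num_motifs = 1,
#'                     sequence = ".")
#' tf <- tempfile(fileext = ".tsv")
#' write.table(calls, tf, sep = "\t", quote = FALSE, row.names = FALSE)
#' readMethCalls(tf)$label
#' @export
readMethCalls <- function(path, minAbsLLR = 2.5) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE,
                            colClasses = "character",
                            check.names = FALSE)
    .checkColumns(df, .CALL_COLS, path)
    llr <- suppressWarnings(as.numeric(df$log_lik_ratio))
    bad <- which(is.na(llr) & !is.na(df$log_lik_ratio) &
                 nzchar(df$log_lik_ratio))
    if (length(bad))
        stop("parse error in '", path, "': non-numeric log_lik_ratio at ",
             "line ", bad[1L] + 1L, " ('", df$log_lik_ratio[bad[1L]], "')",
             call. = FALSE)
    label <- rep("ambiguous", nrow(df))
    label[llr > minAbsLLR] <- "methylated"
    label[llr < -minAbsLLR] <- "unmethylated"
    data.frame(chrom = df$chromosome, strand = df$strand,
               start = as.numeric(df$start), end = as.numeric(df$end),
               read_id = df$read_name, log_lik_ratio = llr,
               num_motifs = as.integer(df$num_motifs), label = label,
               stringsAsFactors = FALSE)
}

#' Write per-read methylation calls
#'
#' Writes labelled calls (as returned by \code{\link{readMethCalls}} or
#' \code{\link{simulateMethPair}}) back to the per-read call TSV dialect.
#' The redundant likelihood columns are filled deterministically from the
#' ratio so that round-trips preserve the ratio exactly.
#'
#' @param calls Call \code{data.frame} in the canonical internal form.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeMethCalls <- function(calls, path) {
    out <- data.frame(chromosome = calls$chrom, strand = calls$strand,
                      start = format(calls$start, scientific = FALSE,
                                     trim = TRUE),
                      end = format(calls$end, scientific = FALSE, trim = TRUE),
                      read_name = calls$read_id,
                      log_lik_ratio = formatC(calls$log_lik_ratio,
                                              format = "g", digits = 17),
                      log_lik_methylated = formatC(pmax(calls$log_lik_ratio, 0),
                                                   format = "g", digits = 17),
                      log_lik_unmethylated = formatC(pmax(-calls$log_lik_ratio,
                                                          0),
                                                     format = "g", digits = 17),
                      num_calling_strands = 1L,
                      num_motifs = calls$num_motifs,
                      sequence = ".",
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Aggregate per-read calls into per-group methylation frequencies
#'
#' Clusters unambiguous calls by CpG group (\code{chrom}, \code{start},
#' \code{end}) and computes motif-weighted counts: \code{called_sites} is the
#' sum of \code{num_motifs} over unambiguous reads covering the group,
#' \code{called_sites_methylated} the same sum over reads labelled
#' methylated, and \code{beta} their ratio.  Groups with no unambiguous call
#' are dropped (the frequency is undefined).
#'
#' @param calls Labelled call \code{data.frame} from
#'   \code{\link{readMethCalls}}.
#' @return A frequency \code{data.frame} sorted by (\code{chrom},
#'   \code{start}) with columns \code{chrom}, \code{start}, \code{end},
#'   \code{num_motifs}, \code{called_sites}, \code{called_sites_methylated},
#'   \code{beta}.
#' @examples
#' calls <- simulateMethPair(simConfig(chromLength = 5e4, nDmrs = 0))$testCalls
#' head(callsToFrequency(calls))
#' @export
callsToFrequency <- function(calls) {
    empty <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), num_motifs = integer(),
                        called_sites = integer(),
                        called_sites_methylated = integer(),
                        beta = numeric(), stringsAsFactors = FALSE)
    if (!nrow(calls)) return(empty)
    keep <- calls$label != "ambiguous"
    if (!any(keep)) return(empty)
    calls <- calls[keep, , drop = FALSE]
    key <- paste(calls$chrom, calls$start, calls$end, sep = "\r")
    grp <- factor(key, levels = unique(key))
    called <- as.integer(rowsum(as.numeric(calls$num_motifs), grp,
                                reorder = FALSE))
    meth <- as.integer(rowsum(as.numeric(calls$num_motifs) *
                              (calls$label == "methylated"), grp,
                              reorder = FALSE))
    first <- !duplicated(grp)
    out <- data.frame(chrom = calls$chrom[first], start = calls$start[first],
                      end = calls$end[first],
                      num_motifs = calls$num_motifs[first],
                      called_sites = called,
                      called_sites_methylated = meth,
                      beta = meth / called, stringsAsFactors = FALSE)
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Read a methylation frequency table
#'
#' Reads the per-CpG-group "methylation frequency" TSV dialect (columns
#' \code{chromosome}, \code{start}, \code{end}, \code{num_motifs_in_group},
#' \code{called_sites}, \code{called_sites_methylated},
#' \code{methylated_frequency}, \code{group_sequence}; located by name).
#' \code{beta} is recomputed as the exact ratio
#' \code{called_sites_methylated / called_sites}, so that round-trips through
#' \code{\link{writeMethFreq}} reproduce it bit-exactly regardless of how the
#' frequency was printed.
#'
#' @param path Path to the TSV file.
#' @return A frequency \code{data.frame} in the canonical form of
#'   \code{\link{callsToFrequency}}.
#' @export
readMethFreq <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    .checkColumns(df, .FREQ_COLS, path)
    cs <- as.integer(df$called_sites)
    cm <- as.integer(df$called_sites_methylated)
    if (any(cm > cs))
        stop("format error in '", path,
             "': called_sites_methylated > called_sites", call. = FALSE)
    data.frame(chrom = as.character(df$chromosome),
               start = as.numeric(df$start), end = as.numeric(df$end),
               num_motifs = as.integer(df$num_motifs_in_group),
               called_sites = cs, called_sites_methylated = cm,
               beta = cm / cs, stringsAsFactors = FALSE)
}

#' Write a methylation frequency table
#'
#' @param freq Frequency \code{data.frame} in canonical form.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeMethFreq <- function(freq, path) {
    out <- data.frame(chromosome = freq$chrom,
                      start = format(freq$start, scientific = FALSE,
                                     trim = TRUE),
                      end = format(freq$end, scientific = FALSE, trim = TRUE),
                      num_motifs_in_group = freq$num_motifs,
                      called_sites = freq$called_sites,
                      called_sites_methylated = freq$called_sites_methylated,
                      methylated_frequency = formatC(freq$beta, format = "f",
                                                     digits = 3),
                      group_sequence = ".",
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

.assertSortedUnique <- function(freq, what) {
    o <- order(freq$chrom, freq$start)
    if (any(o != seq_len(nrow(freq))))
        stop(what, " frequency table is not sorted by (chrom, start)",
             call. = FALSE)
    dup <- duplicated(paste(freq$chrom, freq$start, sep = "\r"))
    if (any(dup)) {
        d <- freq[which(dup)[1L], ]
        stop(what, " frequency table has a duplicated CpG group at ",
             d$chrom, ":", format(d$start, scientific = FALSE), call. = FALSE)
    }
}

#' Join two samples into per-chromosome delta-beta tracks
#'
#' Intersects the CpG groups of a test and a control frequency table and
#' computes \eqn{\Delta\beta = \beta_{test} - \beta_{control}} at each shared
#' group.  Only groups present in both samples with
#' \code{called_sites >= minCalledSites} on each side are joined; groups
#' covered in a single sample are dropped.  Groups are matched on
#' (\code{chrom}, \code{start}).
#'
#' @param test,control Frequency \code{data.frame}s (canonical form, sorted by
#'   chromosome and start; an unsorted or duplicated table is an error).
#' @param minCalledSites Minimum motif-weighted call support per sample
#'   (default 5); below this a beta estimate has granularity coarser than
#'   +/-0.2 and is excluded.
#' @return A named list of \linkS4class{DeltaBetaTrack} objects, one per
#'   chromosome with at least one shared group.
#' @examples
#' sim <- simulateMethPair(simConfig(chromLength = 1e5, nDmrs = 2))
#' tracks <- buildDeltaTrack(sim$testFreq, sim$controlFreq)
#' tracks[[1]]
#' @export
buildDeltaTrack <- function(test, control, minCalledSites = 5L) {
    .assertSortedUnique(test, "test")
    .assertSortedUnique(control, "control")
    test <- test[test$called_sites >= minCalledSites, , drop = FALSE]
    control <- control[control$called_sites >= minCalledSites, , drop = FALSE]
    keyT <- paste(test$chrom, test$start, sep = "\r")
    keyC <- paste(control$chrom, control$start, sep = "\r")
    idx <- match(keyT, keyC)
    sel <- !is.na(idx)
    tt <- test[sel, , drop = FALSE]
    cc <- control[idx[sel], , drop = FALSE]
    tracks <- list()
    for (ch in unique(tt$chrom)) {
        i <- tt$chrom == ch
        tracks[[ch]] <- DeltaBetaTrack(
            chrom = ch, start = tt$start[i], end = tt$end[i],
            betaTest = tt$beta[i], betaControl = cc$beta[i],
            nMotifs = tt$num_motifs[i],
            calledTest = tt$called_sites[i],
            calledControl = cc$called_sites[i])
    }
    tracks
}

#' Export delta-beta tracks as a BED-like TSV
#'
#' Writes one row per joined CpG group: \code{chrom}, \code{start},
#' \code{end} (0-based half-open), \code{delta_beta}, \code{beta_test},
#' \code{beta_control}, \code{called_sites_test},
#' \code{called_sites_control}.
#'
#' @param tracks List of \linkS4class{DeltaBetaTrack} objects.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
exportDeltaTrack <- function(tracks, path) {
    rows <- lapply(tracks, function(trk)
        data.frame(chrom = rep(chrom(trk), length(trk)),
                   start = format(cpgStarts(trk), scientific = FALSE,
                                  trim = TRUE),
                   end = format(cpgEnds(trk), scientific = FALSE, trim = TRUE),
                   delta_beta = formatC(deltaBeta(trk), format = "g",
                                        digits = 17),
                   beta_test = formatC(betaTest(trk), format = "g",
                                       digits = 17),
                   beta_control = formatC(betaControl(trk), format = "g",
                                          digits = 17),
                   called_sites_test = trk@calledTest,
                   called_sites_control = trk@calledControl,
                   stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    names(out)[1L] <- "#chrom"
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
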