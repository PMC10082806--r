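## DMR annotation: CpG-island context and genic/regulatory elements.
##
## Element vocabulary (closed): 1to5Kb, promoter, 5UTR, first_exon, exon,
## intron, 3UTR, intergenic, CGI, DHS, TFBS, enhancer.  "Reg" groups the 5'
## regulatory elements (1to5Kb, promoter, 5UTR, first exon); "GB" groups the
## gene body (internal exons and introns).

.FEATURE_CATEGORIES <- c("1to5Kb", "promoter", "5UTR", "first_exon", "exon",
                         "intron", "3UTR", "intergenic", "CGI", "DHS",
                         "TFBS", "enhancer")
.REG_CATEGORIES <- c("1to5Kb", "promoter", "5UTR", "first_exon")
.GB_CATEGORIES <- c("exon", "intron")

#' Read genomic features from a BED file
#'
#' Reads BED3/4/6 (0-based half-open; no header, or a single leading
#' \code{#}-comment line) into a 1-based \link[GenomicRanges]{GRanges} with
#' metadata columns \code{name}, \code{category} and \code{gene}.
#'
#' @param path Path to the BED file.
#' @param category Feature category assigned to every interval (one of the
#'   closed vocabulary, e.g. \code{"CGI"}, \code{"enhancer"}); if \code{NULL}
#'   the BED name column is used and must be valid categories.
#' @param gene Optional gene symbol vector or single value; for two-column
#'   enhancer-target tables use \code{\link{readEnhancerTargets}}.
#' @return A \link[GenomicRanges]{GRanges}.
#' @export
readFeatureBed <- function(path, category = NULL, gene = NA_character_) {
    df <- utils::read.delim(path, header = FALSE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
    if (ncol(df) < 3L)
        stop("BED file '", path, "' needs at least 3 columns", call. = FALSE)
    name <- if (ncol(df) >= 4L) as.character(df[[4L]]) else NA_character_
    cat <- if (!is.null(category)) category else name
    bad <- setdiff(unique(cat), .FEATURE_CATEGORIES)
    if (length(bad))
        stop("unknown feature category: ", paste(bad, collapse = ", "),
             call. = FALSE)
    gr <- GenomicRanges::GRanges(
        seqnames = df[[1L]],
        ranges = IRanges::IRanges(start = df[[2L]] + 1, end = df[[3L]]))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        name = name, category = cat, gene = gene)
    gr
}

#' Read an enhancer-to-target-gene table
#'
#' Consumes a pre-computed enhancer/target mapping (e.g. from bidirectional
#' CAGE evidence) as a TSV with columns \code{chrom}, \code{start},
#' \code{end} (0-based half-open) and \code{gene}; no target prediction is
#' performed.
#'
#' @param path Path to the TSV (header required).
#' @return A \link[GenomicRanges]{GRanges} with \code{category = "enhancer"}
#'   and the target \code{gene}.
#' @export
readEnhancerTargets <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    names(df)[1L] <- sub("^#", "", names(df)[1L])
    .checkColumns(df, c("chrom", "start", "end", "gene"), path)
    gr <- GenomicRanges::GRanges(
        seqnames = df$chrom,
        ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        name = df$gene, category = "enhancer", gene = df$gene)
    gr
}

#' Read a simple gene model table
#'
#' Parses a TSV gene model with columns \code{gene}, \code{transcript},
#' \code{chrom}, \code{strand}, \code{tss}, \code{exon_blocks} and optional
#' \code{cds_start}, \code{cds_end}.  \code{exon_blocks} is a comma-separated
#' list of \code{start-end} spans (0-based half-open); \code{tss} is the
#' 0-based transcription start coordinate.
#'
#' @param path Path to the TSV (header required).
#' @return A \code{data.frame} suitable for \code{\link{deriveGeneElements}}.
#' @export
readGeneModel <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    names(df)[1L] <- sub("^#", "", names(df)[1L])
    .checkColumns(df, c("gene", "transcript", "chrom", "strand", "tss",
                        "exon_blocks"), path)
    df
}

.parseBlocks <- function(blocks) {
    if (is.na(blocks) || !nzchar(blocks)) return(NULL)
    parts <- strsplit(strsplit(blocks, ",", fixed = TRUE)[[1L]], "-",
                      fixed = TRUE)
    starts <- as.numeric(vapply(parts, `[`, "", 1L))
    ends <- as.numeric(vapply(parts, `[`, "", 2L))
    o <- order(starts)
    cbind(start = starts[o], end = ends[o])
}

## intersect one interval [s, e) with a set of intervals (matrix cols start/end)
.clipIntervals <- function(blocks, s, e) {
    keep <- blocks[, "start"] < e & blocks[, "end"] > s
    if (!any(keep)) return(NULL)
    b <- blocks[keep, , drop = FALSE]
    b[, "start"] <- pmax(b[, "start"], s)
    b[, "end"] <- pmin(b[, "end"], e)
    b
}

## remove a set of intervals from [s, e); returns remaining pieces
.subtractIntervals <- function(s, e, sub) {
    if (is.null(sub)) return(cbind(start = s, end = e))
    sub <- sub[order(sub[, "start"]), , drop = FALSE]
    pieces <- NULL
    cur <- s
    for (i in seq_len(nrow(sub))) {
        if (sub[i, "end"] <= cur || sub[i, "start"] >= e) next
        if (sub[i, "start"] > cur)
            pieces <- rbind(pieces, c(cur, sub[i, "start"]))
        cur <- max(cur, sub[i, "end"])
    }
    if (cur < e) pieces <- rbind(pieces, c(cur, e))
    if (is.null(pieces)) return(NULL)
    colnames(pieces) <- c("start", "end")
    pieces
}

#' Derive genic elements from a gene model
#'
#' Emits, per transcript and strand-aware: the distal upstream window
#' \code{1to5Kb} (5 kb to 1 kb upstream of the TSS), the \code{promoter}
#' (1 kb immediately upstream of the TSS), the \code{first_exon}, internal
#' \code{exon}s, \code{intron}s, and, when the CDS is annotated, the
#' \code{5UTR} (exonic sequence upstream of the CDS) and \code{3UTR} (exonic
#' sequence downstream of it).  Upstream coordinates are clipped at 0.
#' Elements of all transcripts are emitted; overlap resolution is left to the
#' annotation step.
#'
#' @param geneModel \code{data.frame} from \code{\link{readGeneModel}} (or of
#'   the same shape).
#' @return A \link[GenomicRanges]{GRanges} with \code{category} and
#'   \code{gene} metadata.
#' @examples
#' gm <- data.frame(gene = "G1", transcript = "T1", chrom = "chr1",
#'                  strand = "+", tss = 10000,
#'                  exon_blocks = "10000-10200,10500-10800,11000-11500")
#' deriveGeneElements(gm)
#' @export
deriveGeneElements <- function(geneModel) {
    out <- list()
    for (i in seq_len(nrow(geneModel))) {
        tx <- geneModel[i, ]
        blocks <- .parseBlocks(tx$exon_blocks)
        if (is.null(blocks)) {
            warning("transcript ", tx$transcript, " has no exons; skipped",
                    call. = FALSE)
            next
        }
        minus <- identical(tx$strand, "-")
        tss <- as.numeric(tx$tss)
        nEx <- nrow(blocks)
        add <- function(s, e, category) {
            s <- max(0, s)
            if (e > s)
                out[[length(out) + 1L]] <<- data.frame(
                    chrom = tx$chrom, start = s, end = e,
                    category = category, gene = tx$gene,
                    strand = tx$strand, stringsAsFactors = FALSE)
        }
        if (!minus) {
            add(tss - 5000, tss - 1000, "1to5Kb")
            add(tss - 1000, tss, "promoter")
        } else {
            add(tss + 1000, tss + 5000, "1to5Kb")
            add(tss, tss + 1000, "promoter")
        }
        cdsS <- suppressWarnings(as.numeric(tx$cds_start))
        cdsE <- suppressWarnings(as.numeric(tx$cds_end))
        utr5 <- utr3 <- NULL
        if (length(cdsS) && length(cdsE) && !is.na(cdsS) && !is.na(cdsE)) {
            txS <- blocks[1L, "start"]
            txE <- blocks[nEx, "end"]
            utr5 <- if (!minus) .clipIntervals(blocks, txS, cdsS)
                    else .clipIntervals(blocks, cdsE, txE)
            utr3 <- if (!minus) .clipIntervals(blocks, cdsE, txE)
                    else .clipIntervals(blocks, txS, cdsS)
        }
        firstIdx <- if (minus) nEx else 1L
        # first exon is emitted whole: 5'UTR/first-exon containment is the
        # one documented overlap; other exons are trimmed of UTR sequence
        add(blocks[firstIdx, "start"], blocks[firstIdx, "end"], "first_exon")
        utrs <- rbind(utr5, utr3)
        for (j in setdiff(seq_len(nEx), firstIdx)) {
            pieces <- .subtractIntervals(blocks[j, "start"], blocks[j, "end"],
                                         utrs)
            if (!is.null(pieces))
                for (q in seq_len(nrow(pieces)))
                    add(pieces[q, "start"], pieces[q, "end"], "exon")
        }
        if (nEx > 1L)
            for (j in seq_len(nEx - 1L))
                add(blocks[j, "end"], blocks[j + 1L, "start"], "intron")
        if (!is.null(utr5))
            for (j in seq_len(nrow(utr5)))
                add(utr5[j, "start"], utr5[j, "end"], "5UTR")
        if (!is.null(utr3))
            for (j in seq_len(nrow(utr3)))
                add(utr3[j, "start"], utr3[j, "end"], "3UTR")
    }
    if (!length(out)) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            name = character(), category = character(), gene = character())
        return(gr)
    }
    df <- do.call(rbind, out)
    gr <- GenomicRanges::GRanges(
        seqnames = df$chrom,
        ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
        strand = df$strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        name = paste0(df$gene, ":", df$category), category = df$category,
        gene = df$gene)
    gr
}

.regionGroups <- function(categories) {
    groups <- character()
    if (any(categories %in% .REG_CATEGORIES)) groups <- c(groups, "Reg")
    if (any(categories %in% .GB_CATEGORIES)) groups <- c(groups, "GB")
    if (any(categories == "3UTR")) groups <- c(groups, "3UTR")
    if (any(categories == "enhancer")) groups <- c(groups, "enhancer")
    if (!length(groups)) groups <- "intergenic"
    groups
}

#' Annotate DMRs with CpG-island context and genic elements
#'
#' Overlap is any-basepair (1 bp suffices).  A DMR overlapping at least one
#' \code{CGI} feature gets \code{cgi_context = "CGI"}, otherwise
#' \code{"NoCGI"} (sparse CpG).  All overlapping non-CGI elements are
#' recorded (multi-assignment allowed) and summarised into region groups:
#' \code{Reg} (1to5Kb / promoter / 5UTR / first exon), \code{GB} (internal
#' exons / introns), \code{3UTR}, \code{enhancer}; a DMR overlapping no
#' element is \code{intergenic}.  Genes are deduplicated by symbol.
#'
#' @param dmrs DMR \link[GenomicRanges]{GRanges}.
#' @param features Feature \link[GenomicRanges]{GRanges} with
#'   \code{category} (and optionally \code{gene}) metadata, e.g. from
#'   \code{\link{deriveGeneElements}} and \code{\link{readFeatureBed}}.
#' @param chroms Optional character vector of known chromosome names;
#'   features on other chromosomes are dropped with a warning.
#' @return \code{dmrs} with added metadata columns \code{cgi_context},
#'   \code{elements} (comma-separated \code{category:gene}),
#'   \code{region_group} (comma-separated) and \code{genes}.
#' @export
annotateDMRs <- function(dmrs, features, chroms = NULL) {
    if (!is.null(chroms)) {
        unknown <- !(as.character(GenomicRanges::seqnames(features)) %in%
                     chroms)
        if (any(unknown)) {
            warning(sum(unknown), " feature(s) on unknown chromosomes ",
                    "ignored", call. = FALSE)
            features <- features[!unknown]
        }
    }
    hits <- GenomicRanges::findOverlaps(dmrs, features, minoverlap = 1L,
                                        ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    cgi <- elements <- groups <- genes <- character(length(dmrs))
    for (i in seq_along(dmrs)) {
        f <- features[sh[qh == i]]
        cats <- as.character(f$category)
        cgi[i] <- if (any(cats == "CGI")) "CGI" else "NoCGI"
        genic <- cats != "CGI"
        elements[i] <- if (any(genic)) {
            g <- ifelse(is.na(f$gene[genic]), "", paste0(":", f$gene[genic]))
            paste(unique(paste0(cats[genic], g)), collapse = ",")
        } else ""
        groups[i] <- paste(.regionGroups(cats[genic]), collapse = ",")
        gg <- unique(f$gene[genic])
        genes[i] <- paste(gg[!is.na(gg)], collapse = ",")
    }
    dmrs$cgi_context <- cgi
    dmrs$elements <- elements
    dmrs$region_group <- groups
    dmrs$genes <- genes
    dmrs
}

#' Export annotated DMRs as a TSV
#'
#' The DMR TSV of \code{\link{exportDMRs}} plus the annotation columns
#' \code{cgi_context}, \code{elements}, \code{region_group}, \code{genes}.
#'
#' @param dmrs Annotated DMR \link[GenomicRanges]{GRanges} from
#'   \code{\link{annotateDMRs}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
exportAnnotatedDMRs <- function(dmrs, path) {
    out <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(dmrs)),
        start = format(GenomicRanges::start(dmrs) - 1, scientific = FALSE,
                       trim = TRUE),
        end = format(GenomicRanges::end(dmrs), scientific = FALSE,
                     trim = TRUE),
        as.data.frame(S4Vectors::mcols(dmrs)),
        stringsAsFactors = FALSE)
    names(out)[1L] <- "#chrom"
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
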