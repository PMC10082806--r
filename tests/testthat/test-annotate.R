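gr0 <- function(chrom, start, end, ...) {
    g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
    mc <- list(...)
    for (nm in names(mc)) S4Vectors::mcols(g)[[nm]] <- mc[[nm]]
    g
}

test_that("genic elements are derived strand-aware from the gene model", {
    gm <- data.frame(gene = "G1", transcript = "T1", chrom = "chr1",
                     strand = "+", tss = 10000,
                     exon_blocks = "10000-10200,10500-10800,11000-11500",
                     stringsAsFactors = FALSE)
    el <- deriveGeneElements(gm)
    df <- data.frame(cat = el$category,
                     start = GenomicRanges::start(el) - 1,
                     end = GenomicRanges::end(el))
    expect_equal(df[df$cat == "promoter", c("start", "end")],
                 data.frame(start = 9000, end = 10000),
                 ignore_attr = TRUE)
    expect_equal(df[df$cat == "1to5Kb", c("start", "end")],
                 data.frame(start = 5000, end = 9000), ignore_attr = TRUE)
    expect_equal(df[df$cat == "first_exon", c("start", "end")],
                 data.frame(start = 10000, end = 10200), ignore_attr = TRUE)
    expect_equal(sum(df$cat == "exon"), 2L)
    expect_equal(df[df$cat == "intron", "start"], c(10200, 10800))

    # minus strand: promoter is immediately downstream-in-coordinates of TSS
    gmM <- data.frame(gene = "G2", transcript = "T2", chrom = "chr1",
                      strand = "-", tss = 10000,
                      exon_blocks = "8000-9000,9500-10000",
                      stringsAsFactors = FALSE)
    elM <- deriveGeneElements(gmM)
    prom <- elM[elM$category == "promoter"]
    expect_equal(GenomicRanges::start(prom) - 1, 10000)
    expect_equal(GenomicRanges::end(prom), 11000)
    firstM <- elM[elM$category == "first_exon"]
    expect_equal(GenomicRanges::start(firstM) - 1, 9500)  # last genomic exon

    # single-exon transcript: first_exon only, no introns or internal exons
    gm1 <- data.frame(gene = "G3", transcript = "T3", chrom = "chr1",
                      strand = "+", tss = 500, exon_blocks = "500-900",
                      stringsAsFactors = FALSE)
    el1 <- deriveGeneElements(gm1)
    expect_false(any(el1$category %in% c("intron", "exon")))
    expect_equal(sum(el1$category == "first_exon"), 1L)
    # upstream windows clipped at zero
    expect_true(all(GenomicRanges::start(el1) >= 1))

    expect_warning(deriveGeneElements(
        data.frame(gene = "G4", transcript = "T4", chrom = "chr1",
                   strand = "+", tss = 100, exon_blocks = "",
                   stringsAsFactors = FALSE)), "no exons")
})

test_that("UTRs are cut at the CDS and element overlap is only documented", {
    gm <- data.frame(gene = "G5", transcript = "T5", chrom = "chr2",
                     strand = "+", tss = 1000,
                     exon_blocks = "1000-1400,2000-2600,3000-3800",
                     cds_start = 1200, cds_end = 3300,
                     stringsAsFactors = FALSE)
    el <- deriveGeneElements(gm)
    utr5 <- el[el$category == "5UTR"]
    expect_equal(GenomicRanges::start(utr5) - 1, 1000)
    expect_equal(GenomicRanges::end(utr5), 1200)
    utr3 <- el[el$category == "3UTR"]
    expect_equal(GenomicRanges::start(utr3) - 1, 3300)
    expect_equal(GenomicRanges::end(utr3), 3800)
    # within a transcript, elements do not overlap except 5'UTR inside the
    # first exon
    keep <- el[el$category != "5UTR"]
    ov <- GenomicRanges::findOverlaps(keep, keep, ignore.strand = TRUE)
    expect_true(all(S4Vectors::queryHits(ov) == S4Vectors::subjectHits(ov)))
    fe <- el[el$category == "first_exon"]
    expect_equal(S4Vectors::subjectHits(GenomicRanges::findOverlaps(
        utr5, fe)), 1L)
})

test_that("DMRs get CGI context, elements, region groups and genes", {
    dmrs <- gr0("chr1", c(100, 5000, 20000), c(900, 5400, 20500),
                direction = c("hyper", "hypo", "hyper"))
    feats <- c(gr0("chr1", 800, 1200, name = "cgi1", category = "CGI",
                   gene = NA_character_),
               gr0("chr1", 4900, 5600, name = "i1", category = "intron",
                   gene = "GENEA"))
    ann <- annotateDMRs(dmrs, feats)
    # 1 bp overlap suffices for CGI context
    expect_equal(ann$cgi_context, c("CGI", "NoCGI", "NoCGI"))
    expect_equal(sum(ann$cgi_context == "CGI") +
                 sum(ann$cgi_context == "NoCGI"), length(ann))
    # intron-only DMR is gene body; untouched DMR is intergenic
    expect_equal(ann$region_group, c("intergenic", "GB", "intergenic"))
    expect_equal(ann$genes[2L], "GENEA")

    # promoter/first-exon overlap maps to Reg; enhancers kept separate
    feats2 <- c(gr0("chr1", 80, 130, name = "p", category = "promoter",
                    gene = "GENEB"),
                gr0("chr1", 120, 250, name = "e", category = "enhancer",
                    gene = "GENEC"))
    ann2 <- annotateDMRs(dmrs, feats2)
    expect_equal(ann2$region_group[1L], "Reg,enhancer")
    expect_equal(sort(strsplit(ann2$genes[1L], ",")[[1]]),
                 c("GENEB", "GENEC"))

    withUnknown <- suppressWarnings(
        c(feats, gr0("chrUn", 1, 100, name = "x", category = "CGI",
                     gene = NA_character_)))
    expect_warning(annotateDMRs(dmrs, withUnknown, chroms = "chr1"),
                   "unknown")
})

test_that("interval overlap assignment matches a quadratic all-pairs scan", {
    set.seed(88)
    nQ <- 120; nS <- 400
    qs <- sample(0:50000, nQ); qe <- qs + sample(50:2000, nQ, replace = TRUE)
    ss <- sample(0:50000, nS); se <- ss + sample(20:800, nS, replace = TRUE)
    qc <- sample(c("c1", "c2"), nQ, replace = TRUE)
    sc <- sample(c("c1", "c2"), nS, replace = TRUE)
    q <- gr0(qc, qs, qe, direction = rep("hyper", nQ))
    s <- gr0(sc, ss, se, name = paste0("f", seq_len(nS)),
             category = sample(c("CGI", "intron", "promoter"), nS,
                               replace = TRUE),
             gene = paste0("g", seq_len(nS)))
    hits <- GenomicRanges::findOverlaps(q, s, minoverlap = 1L,
                                        ignore.strand = TRUE)
    got <- cbind(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
    expected <- bruteOverlapPairs(qc, qs, qe, sc, ss, se)
    o1 <- order(got[, 1], got[, 2]); o2 <- order(expected[, 1], expected[, 2])
    expect_equal(unname(got[o1, , drop = FALSE]),
                 unname(expected[o2, , drop = FALSE]))
})

test_that("feature BED and gene model readers enforce their contracts", {
    bed <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t100\t200\tCGI", "chr1\t500\t800\tCGI"), bed)
    cgi <- readFeatureBed(bed, category = "CGI")
    expect_equal(length(cgi), 2L)
    expect_equal(GenomicRanges::start(cgi), c(101, 501))
    writeLines("chr1\t100\t200\tnot_a_category", bed)
    expect_error(readFeatureBed(bed), "unknown feature category")

    gmPath <- tempfile(fileext = ".tsv")
    writeLines(c("gene\ttranscript\tchrom\tstrand\ttss\texon_blocks",
                 "G1\tT1\tchr1\t+\t1000\t1000-1500,2000-2500"), gmPath)
    gm <- readGeneModel(gmPath)
    expect_equal(gm$tss, 1000)
    el <- deriveGeneElements(gm)
    expect_true("promoter" %in% el$category)
})
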