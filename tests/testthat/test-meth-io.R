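test_that("per-read calls are labelled by the strict LLR threshold", {
    path <- writeCallFixture(c(
        callRow(read = "r1", llr = 3.1),
        callRow(read = "r2", llr = 0.0),
        callRow(read = "r3", llr = -2.5),   # boundary: strict inequality
        callRow(read = "r4", llr = 2.5),
        callRow(read = "r5", llr = -4.2)))
    calls <- readMethCalls(path)
    expect_equal(calls$label,
                 c("methylated", "ambiguous", "ambiguous", "ambiguous",
                   "unmethylated"))
})

test_that("call parsing reports missing columns and bad rows precisely", {
    bad <- tempfile(fileext = ".tsv")
    writeLines(c("chromosome\tstrand\tstart\tend\tread_name\tnum_motifs",
                 "chr1\t+\t1\t3\tr1\t1"), bad)
    expect_error(readMethCalls(bad), "log_lik_ratio")

    path <- writeCallFixture(c(callRow(llr = 3.0),
                               callRow(read = "r2", llr = "abc")))
    expect_error(readMethCalls(path), "line 3")
})

test_that("frequency aggregation counts motif-weighted unambiguous calls", {
    # 10 single-motif reads, 8 methylated -> beta 0.8
    rows <- vapply(1:10, function(i)
        callRow(read = paste0("r", i), llr = if (i <= 8) 5 else -5), "")
    # a group seen only ambiguously is dropped
    rows <- c(rows, callRow(start = 500, end = 502, read = "r11", llr = 1.0))
    # num_motifs = 2, 5 methylated + 5 unmethylated reads
    rows <- c(rows, vapply(1:10, function(i)
        callRow(start = 900, end = 905, read = paste0("q", i),
                llr = if (i <= 5) 6 else -6, nMotifs = 2), ""))
    freq <- callsToFrequency(readMethCalls(writeCallFixture(rows)))
    expect_equal(nrow(freq), 2L)
    g1 <- freq[freq$start == 100, ]
    expect_equal(g1$called_sites, 10L)
    expect_equal(g1$beta, 0.8)
    g2 <- freq[freq$start == 900, ]
    expect_equal(g2$called_sites, 20L)
    expect_equal(g2$called_sites_methylated, 10L)
    expect_equal(g2$beta, 0.5)
    # all-ambiguous input yields an empty frequency table
    onlyAmb <- callsToFrequency(readMethCalls(writeCallFixture(
        callRow(llr = 0.2))))
    expect_equal(nrow(onlyAmb), 0L)
})

test_that("frequency tables round-trip bit-exactly through the TSV dialect", {
    sim <- simulateMethPair(simConfig(chromLength = 5e4, nDmrs = 0L))
    freq <- sim$testFreq
    path <- tempfile(fileext = ".tsv")
    writeMethFreq(freq, path)
    back <- readMethFreq(path)
    expect_identical(back$chrom, freq$chrom)
    expect_identical(back$start, freq$start)
    expect_identical(back$end, freq$end)
    expect_identical(back$num_motifs, freq$num_motifs)
    expect_identical(back$called_sites, freq$called_sites)
    expect_identical(back$called_sites_methylated,
                     freq$called_sites_methylated)
    expect_identical(back$beta, freq$beta)
})

test_that("frequencies derived from calls match the reference table", {
    sim <- simulateMethPair(simConfig(chromLength = 5e4, seed = 3L,
                                      nDmrs = 1L))
    path <- tempfile(fileext = ".tsv")
    writeMethCalls(sim$testCalls, path)
    freq <- callsToFrequency(readMethCalls(path))
    expect_equal(freq$beta, sim$testFreq$beta)
    expect_equal(freq$start, sim$testFreq$start)
})

freqDf <- function(chrom, start, beta, called = 10L) {
    data.frame(chrom = chrom, start = start, end = start + 2,
               num_motifs = 1L, called_sites = as.integer(called),
               called_sites_methylated = as.integer(round(beta * called)),
               beta = round(beta * called) / called,
               stringsAsFactors = FALSE)
}

test_that("the two-sample join computes delta-beta and distances", {
    test <- freqDf("chr1", c(100, 250, 1000), c(1.0, 0.5, 0.3))
    ctrl <- freqDf("chr1", c(100, 250, 1000), c(0.0, 0.5, 0.3))
    trk <- buildDeltaTrack(test, ctrl)[["chr1"]]
    expect_equal(deltaBeta(trk), c(1, 0, 0))
    expect_equal(cpgDistances(trk), c(150, 750))

    # identity join: all delta-beta zero
    same <- buildDeltaTrack(test, test)[["chr1"]]
    expect_true(all(deltaBeta(same) == 0))
})

test_that("the join intersects positions and applies the coverage filter", {
    test <- freqDf("chr1", c(100, 200, 300, 400), c(0.9, 0.8, 0.7, 0.6),
                   called = c(10, 4, 10, 10))
    ctrl <- freqDf("chr1", c(100, 300, 400, 500), c(0.1, 0.2, 0.3, 0.4),
                   called = c(10, 10, 3, 10))
    trk <- buildDeltaTrack(test, ctrl, minCalledSites = 5)[["chr1"]]
    # 200 absent in control, 400 under-covered in control, 500 absent in test
    expect_equal(cpgStarts(trk), c(100, 300))
    expect_true(all(abs(deltaBeta(trk)) <= 1))
})

test_that("unsorted or duplicated inputs are rejected", {
    test <- freqDf("chr1", c(200, 100), c(0.5, 0.5))
    expect_error(buildDeltaTrack(test, test), "sorted")
    dup <- freqDf("chr1", c(100, 100), c(0.5, 0.5))
    expect_error(buildDeltaTrack(dup, dup), "100")
})

test_that("random joins keep |delta-beta| bounded and positions intersected", {
    set.seed(42)
    for (r in 1:20) {
        posT <- sort(sample(1:5000, 60)) * 10
        posC <- sort(sample(1:5000, 60)) * 10
        test <- freqDf("chrR", posT, runif(60), called = sample(1:30, 60,
                                                                TRUE))
        ctrl <- freqDf("chrR", posC, runif(60), called = sample(1:30, 60,
                                                                TRUE))
        tracks <- buildDeltaTrack(test, ctrl, minCalledSites = 5)
        expected <- intersect(test$start[test$called_sites >= 5],
                              ctrl$start[ctrl$called_sites >= 5])
        got <- if (length(tracks)) cpgStarts(tracks[["chrR"]]) else numeric()
        expect_equal(got, sort(expected))
        if (length(got))
            expect_true(all(abs(deltaBeta(tracks[["chrR"]])) <= 1))
    }
})
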