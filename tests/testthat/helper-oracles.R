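# Independent oracles used to validate the fast implementations.

# Exhaustive maximum-a-posteriori path search over all K^n state paths,
# scored directly from the model definition (no dynamic programming).
bruteViterbi <- function(x, d, params) {
    levels <- seq(-1, 1, length.out = params@nStates)
    K <- length(levels)
    n <- length(x)
    se <- params@sigmaEps
    sm <- params@sigmaMu
    emis <- vapply(seq_len(K), function(k)
        dnorm(x, levels[k], se, log = TRUE) -
            log(pnorm(1, levels[k], se) - pnorm(-1, levels[k], se)),
        numeric(n))
    emis <- matrix(emis, nrow = n)
    w <- dnorm(levels, 0, sm)
    logInit <- log(w / sum(w))
    trans <- lapply(seq_len(n - 1L), function(i) {
        eta <- 0.5 * params@theta +
            (0.5 - params@theta) * exp(log(params@theta) /
                                       (d[i] / params@dNorm))
        M <- outer(levels, levels, function(a, b) dnorm(b - a, 0, sm))
        diag(M) <- 0
        M <- M / rowSums(M)
        Tm <- log(eta * M)
        diag(Tm) <- log(1 - eta)
        Tm
    })
    paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
    s <- logInit[paths[, 1L]] + emis[cbind(1L, paths[, 1L])]
    for (i in seq_len(n)[-1L])
        s <- s + trans[[i - 1L]][cbind(paths[, i - 1L], paths[, i])] +
            emis[cbind(i, paths[, i])]
    unname(paths[which.max(s), ])
}

# All-pairs quadratic interval overlap scan (0-based half-open inputs).
bruteOverlapPairs <- function(qChrom, qStart, qEnd, sChrom, sStart, sEnd) {
    pairs <- list()
    for (i in seq_along(qStart))
        for (j in seq_along(sStart))
            if (qChrom[i] == sChrom[j] &&
                qStart[i] < sEnd[j] && sStart[j] < qEnd[i])
                pairs[[length(pairs) + 1L]] <- c(i, j)
    if (!length(pairs)) return(matrix(integer(), ncol = 2L))
    do.call(rbind, pairs)
}

# Exact two-sided rank-sum p-value by enumeration of all group assignments.
exactRankSumP <- function(x, y) {
    n <- length(x)
    pooled <- c(x, y)
    stopifnot(!anyDuplicated(pooled))
    r <- rank(pooled)
    wObs <- sum(r[seq_len(n)])
    sets <- combn(length(pooled), n)
    wAll <- colSums(matrix(r[sets], nrow = n))
    pLow <- mean(wAll <= wObs)
    pHigh <- mean(wAll >= wObs)
    min(1, 2 * min(pLow, pHigh))
}

# Two-level planted track: nA CpGs at level 0, nB at level `shift`, with
# Gaussian noise and uniform spacing.
plantedTwoBlockTrack <- function(nA = 20, nB = 20, shift = 0.6, sd = 0.05,
                                 spacing = 100, seed = 1L) {
    set.seed(seed)
    n <- nA + nB
    start <- seq(1000, by = spacing, length.out = n)
    mu <- c(rep(0, nA), rep(shift, nB))
    db <- pmin(1, pmax(-1, mu + rnorm(n, 0, sd)))
    bc <- rep(0.2, n)
    DeltaBetaTrack("chrT", start = start, end = start + 2,
                   betaTest = pmin(1, pmax(0, bc + db)), betaControl = bc)
}
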