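test_that("eta(d) matches its closed-form anchors and stays in bounds", {
    for (theta in c(0.01, 0.1, 0.3, 0.49)) {
        expect_equal(etaJump(1000, theta, 1000), theta - theta^2,
                     tolerance = 1e-14)
        expect_equal(etaJump(1e-9, theta, 1000), theta / 2, tolerance = 1e-14)
        expect_equal(etaJump(Inf, theta, 1000), (1 - theta) / 2,
                     tolerance = 1e-14)
        d <- 10^seq(-2, 8, length.out = 400)
        eta <- etaJump(d, theta, 1000)
        expect_true(all(diff(eta) >= 0))
        expect_true(all(eta > theta / 2 - 1e-15 &
                        eta < (1 - theta) / 2 + 1e-15))
    }
    expect_error(etaJump(100, theta = 0.6), "theta")
    expect_error(etaJump(100, theta = 0), "theta")
    expect_error(etaJump(-5, theta = 0.1), "distances")
})

test_that("eta scaling: only d / dNorm matters", {
    d <- c(10, 100, 1000, 1e5)
    expect_equal(etaJump(d, 0.2, 500), etaJump(d * 7, 0.2, 3500))
})

test_that("truncated Gaussian density is normalised and matches closed form", {
    # m = 0, sigma = 0.1 at x = 0: phi(0)/0.1 with negligible truncation
    expect_equal(dtruncGauss(0, 0, 0.1, log = TRUE), log(dnorm(0) / 0.1),
                 tolerance = 1e-9)
    expect_equal(dtruncGauss(0, 0, 0.1, log = TRUE), 1.38365,
                 tolerance = 1e-5)
    # sigma >> 1: flat on [-1, 1], density ~ 1/2
    x <- seq(-1, 1, by = 0.25)
    expect_equal(dtruncGauss(x, 0, 100), rep(0.5, length(x)),
                 tolerance = 1e-3)
    # unit mass for a representative (m, sigma)
    I <- integrate(dtruncGauss, -1, 1, mean = 0.3, sd = 0.2,
                   rel.tol = 1e-10)
    expect_equal(I$value, 1, tolerance = 1e-6)
    expect_error(dtruncGauss(1.5, 0, 1), "\\[-1, 1\\]")
})

test_that("the noise s.d. estimator recovers sigma and resists level jumps", {
    set.seed(7)
    n <- 10000
    start <- seq(100, by = 100, length.out = n)
    noise <- rnorm(n, 0, 0.1)
    trk <- DeltaBetaTrack("chrE", start, start + 2,
                          betaTest = pmin(1, pmax(0, 0.5 + noise)),
                          betaControl = rep(0.5, n))
    p <- estimateSLMParams(trk)
    expect_gt(p@sigmaEps, 0.09)
    expect_lt(p@sigmaEps, 0.11)
    expect_equal(p@sigmaMu, 3 * p@sigmaEps)  # omega = 0.9

    # piecewise track: robust estimator ignores the single jump
    trk2 <- plantedTwoBlockTrack(nA = 500, nB = 500, shift = 0.6, sd = 0.05,
                                 seed = 11)
    p2 <- estimateSLMParams(trk2)
    expect_gt(p2@sigmaEps, 0.045)
    expect_lt(p2@sigmaEps, 0.056)
    expect_gt(sd(deltaBeta(trk2)), 2 * p2@sigmaEps)  # naive s.d. inflated

    # degenerate constant track: floored with a warning
    trkC <- DeltaBetaTrack("chrC", start[1:50], start[1:50] + 2,
                           betaTest = rep(0.5, 50),
                           betaControl = rep(0.5, 50))
    expect_warning(pC <- estimateSLMParams(trkC), "flooring")
    expect_equal(pC@sigmaEps, 1e-3)

    expect_error(estimateSLMParams(exampleDeltaTrack(5)), "at least 10")
})

test_that("model transition rows are proper distributions", {
    set.seed(5)
    for (r in 1:25) {
        theta <- runif(1, 0.02, 0.45)
        sm <- runif(1, 0.05, 0.8)
        levels <- seq(-1, 1, length.out = sample(c(5L, 11L, 41L), 1L))
        eta <- etaJump(10^runif(1, 0, 6), theta, 1000)
        M <- outer(levels, levels, function(a, b) dnorm(b - a, 0, sm))
        diag(M) <- 0
        M <- M / rowSums(M)
        Tm <- eta * M
        diag(Tm) <- 1 - eta
        expect_true(all(abs(rowSums(Tm) - 1) < 1e-12))
    }
})

test_that("Viterbi matches exhaustive path enumeration on small instances", {
    set.seed(101)
    for (r in 1:50) {
        n <- sample(2:6, 1L)
        params <- SLMParams(theta = runif(1, 0.02, 0.45),
                            dNorm = runif(1, 100, 5000),
                            sigmaEps = runif(1, 0.03, 0.4),
                            sigmaMu = runif(1, 0.1, 0.8),
                            nStates = sample(c(3L, 5L), 1L))
        x <- runif(n, -1, 1)
        d <- 10^runif(n - 1, 0.5, 5)
        expect_identical(viterbiPath(x, d, params), bruteViterbi(x, d, params))
    }
})

test_that("an all-zero profile decodes to a single segment at level zero", {
    trk <- DeltaBetaTrack("chr0", seq(100, by = 100, length.out = 30),
                          betaTest = rep(0.4, 30), betaControl = rep(0.4, 30))
    seg <- viterbiSegment(trk, SLMParams(sigmaEps = 0.05, sigmaMu = 0.3))
    expect_equal(nSegments(seg), 1L)
    expect_equal(seg@level, 0)
    expect_equal(seg@meanDeltaBeta, 0)
})

test_that("a planted two-level track yields two segments with a sharp break", {
    # decode under the generative parameters of the planted track
    params <- SLMParams(theta = 0.1, dNorm = 1000, sigmaEps = 0.05,
                        sigmaMu = 0.3)
    trk <- plantedTwoBlockTrack(seed = 21)
    seg <- viterbiSegment(trk, params)
    expect_equal(nSegments(seg), 2L)
    expect_lte(abs(seg@firstIndex[2L] - 21L), 1L)
    expect_gt(seg@meanDeltaBeta[2L], 0.5)
    # with estimated parameters the breakpoint itself is still recovered
    segE <- viterbiSegment(trk, estimateSLMParams(trk))
    expect_true(any(abs(segE@firstIndex - 21L) <= 1L))
})

test_that("segmentation is invariant to joint rescaling of distances", {
    set.seed(31)
    x <- pmin(1, pmax(-1, c(rnorm(15, 0, 0.1), rnorm(15, 0.5, 0.1))))
    d <- 10^runif(29, 1, 4)
    p1 <- SLMParams(theta = 0.1, dNorm = 1000, sigmaEps = 0.1, sigmaMu = 0.3)
    p2 <- SLMParams(theta = 0.1, dNorm = 50000, sigmaEps = 0.1, sigmaMu = 0.3)
    expect_identical(viterbiPath(x, d, p1), viterbiPath(x, d * 50, p2))
})

test_that("a wide gap at a level change never suppresses the breakpoint", {
    params <- SLMParams(theta = 0.1, dNorm = 1000, sigmaEps = 0.05,
                        sigmaMu = 0.3)
    for (s in 1:20) {
        set.seed(400 + s)
        x <- pmin(1, pmax(-1, c(rnorm(15, 0, 0.05), rnorm(15, 0.55, 0.05))))
        dShort <- rep(100, 29)
        dGap <- dShort
        dGap[15] <- 1e5
        brk <- function(path) which(diff(path) != 0)
        if (15 %in% brk(viterbiPath(x, dShort, params)))
            expect_true(15 %in% brk(viterbiPath(x, dGap, params)))
    }
})

test_that("segment counts are recovered on model-generated tracks", {
    # generative model with jumps above the noise floor (|delta| >= 2
    # sigmaEps); sub-noise level changes are not resolvable by any decoder
    # and are excluded from the planted count
    theta <- 0.1; se <- 0.1; sm <- 0.3
    params <- SLMParams(theta = theta, dNorm = 1000, sigmaEps = se,
                        sigmaMu = sm)
    set.seed(77)
    planted <- recovered <- numeric(100)
    for (r in 1:100) {
        n <- 300
        d <- pmax(2, round(rexp(n - 1, 1 / 300)))
        eta <- etaJump(d, theta, 1000)
        jump <- rbinom(n - 1, 1, eta) == 1
        m <- numeric(n)
        m[1] <- max(-0.9, min(0.9, rnorm(1, 0, sm)))
        for (i in 2:n) {
            if (jump[i - 1]) {
                repeat {
                    delta <- rnorm(1, 0, sm)
                    if (abs(delta) >= 2 * se) break
                }
                m[i] <- max(-0.9, min(0.9, m[i - 1] + delta))
            } else m[i] <- m[i - 1]
        }
        x <- pmin(1, pmax(-1, m + rnorm(n, 0, se)))
        planted[r] <- 1 + sum(diff(m) != 0)
        recovered[r] <- length(rle(viterbiPath(x, d, params))$values)
    }
    ratio <- mean(recovered) / mean(planted)
    expect_gt(ratio, 0.8)
    expect_lt(ratio, 1.2)
})
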