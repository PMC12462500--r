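# STICS: exclusion, detrending by count addition, correlation surfaces,
# diffusion fits, two-color cross-correlation.

test_that("segment exclusion masks are validated and applied", {
    ky <- simulateKymograph(membraneSimConfig(
        nLines = 1000L, nPixels = 64L, particleDensityUm2 = 5, seed = 41))
    same <- excludeSegments(ky)
    expect_identical(same@keepLines, ky@keepLines)
    ex <- excludeSegments(ky, lineRanges = list(c(901, 1000)),
                          pixelRanges = list(c(1, 4)))
    expect_identical(sum(!ex@keepLines), 100L)
    expect_identical(sum(!ex@keepPixels), 4L)
    expect_error(excludeSegments(ky, lineRanges = list(c(1, 1000))),
                 "50%")
    expect_error(excludeSegments(ky, lineRanges = list(c(0, 10))),
                 "out of bounds")
})

test_that("detrending equalizes bin means by integer addition only", {
    ky <- simulateKymograph(membraneSimConfig(
        nLines = 4000L, nPixels = 64L, particleDensityUm2 = 10, seed = 42))
    m <- counts(ky)
    # impose a linear ~10% intensity decay (binomial thinning)
    set.seed(43)
    p <- rep(seq(1, 0.9, length.out = nrow(m)), ncol(m))
    decayed <- matrix(rbinom(length(m), as.vector(m), p), nrow(m))
    kyd <- rawKymograph(decayed)
    det <- detrendKymograph(kyd, binSizeLines = 500L, seed = 44)
    dm <- counts(det)
    expect_true(all(dm >= decayed))          # addition only
    expect_true(all(dm == round(dm)))        # integer counts
    bins <- split(seq_len(nrow(dm)), (seq_len(nrow(dm)) - 1L) %/% 500L)
    sums <- vapply(bins, function(b) sum(dm[b, ]), numeric(1))
    # bin totals agree within one count after mean equalization
    expect_lt(diff(range(sums)), 2)
    # a kymograph with equal bin means needs at most ~1 count per bin
    flat <- rawKymograph(matrix(5L, 2000L, 32L))
    det0 <- detrendKymograph(flat, binSizeLines = 500L, seed = 45)
    expect_lte(sum(counts(det0)) - sum(5L * 2000L * 32L), 4)
    # seed reproducibility
    expect_identical(counts(detrendKymograph(kyd, 500L, seed = 7)),
                     counts(detrendKymograph(kyd, 500L, seed = 7)))
    # fewer retained lines than two bins is an error
    expect_error(detrendKymograph(kyd, binSizeLines = 3000L),
                 "two detrend bins")
})

test_that("excluding a photobleached tail removes the mean drift", {
    ky <- simulateKymograph(membraneSimConfig(
        nLines = 6000L, nPixels = 64L, particleDensityUm2 = 10, seed = 46))
    m <- counts(ky)
    set.seed(47)
    # strong bleaching confined to the final quarter
    p <- rep(1, nrow(m)); tail_ <- 4501:6000
    p[tail_] <- seq(1, 0.4, length.out = length(tail_))
    bleached <- matrix(rbinom(length(m), as.vector(m), rep(p, ncol(m))),
                       nrow(m))
    kyb <- excludeSegments(rawKymograph(bleached),
                           lineRanges = list(c(4501, 6000)))
    det <- detrendKymograph(kyb, binSizeLines = 1500L, seed = 48)
    dm <- counts(det)[det@keepLines, ]
    bins <- split(seq_len(nrow(dm)), (seq_len(nrow(dm)) - 1L) %/% 1500L)
    means <- vapply(bins, function(b) mean(dm[b, ]), numeric(1))
    expect_lt(diff(range(means)) / mean(means), 0.01)
})

test_that("white noise decorrelates away from the origin", {
    set.seed(49)
    ky <- rawKymograph(matrix(rpois(20000 * 64, 10), 20000, 64))
    g <- computeStics(ky, "AA", maxLagLines = 200L)
    expect_true(all(abs(g@G) < 5e-3))
})

test_that("immobile emitters give a tau-flat autocorrelation at xi = 0", {
    ky <- simulateKymograph(membraneSimConfig(
        nLines = 20000L, nPixels = 64L, particleDensityUm2 = 3,
        diffusionUm2S = 0, seed = 50))
    g <- computeStics(ky, "AA", maxLagLines = 2000L)
    prof <- g@G[, g@xiPx == 0L]
    expect_gt(min(prof) / max(prof), 0.9)
    f <- fitDiffusion(g, waistNm = 250)
    expect_lt(f@D, 0.005)
})

test_that("the diffusion fit round-trips an analytic surface exactly", {
    surf <- analyticSurface(D = 0.05, G0 = 0.8)
    f <- fitDiffusion(surf, waistNm = 250)
    expect_true(isConverged(f))
    expect_equal(f@D, 0.05, tolerance = 1e-6)
    expect_equal(f@G0, 0.8, tolerance = 1e-6)
    expect_error(fitDiffusion(
        analyticSurface(D = 0.05, nTau = 5L)), "6 temporal bins")
})

test_that("D is recovered from a simulated kymograph within 15%", {
    ky <- simulateKymograph(membraneSimConfig(
        nLines = 50000L, nPixels = 256L, particleDensityUm2 = 5,
        diffusionUm2S = 0.1, seed = 51))
    ky <- detrendKymograph(ky, binSizeLines = 10000L, seed = 51)
    g <- computeStics(ky, "AA")
    f <- fitDiffusion(g, waistNm = 250)
    expect_true(isConverged(f))
    expect_equal(f@D, 0.1, tolerance = 0.15)
    # the correlation plume widens linearly in tau with slope ~4D:
    # per-bin Gaussian widths over the central lags, then the MSD slope
    early <- which(g@tauS <= 0.2)
    xiNm <- g@xiPx * g@pixelSizeNm
    cen <- abs(g@xiPx) <= 30L
    w2 <- vapply(early, function(i) {
        df <- data.frame(gg = g@G[i, cen], x2 = xiNm[cen]^2)
        cf <- coef(minpack.lm::nlsLM(gg ~ A * exp(-x2 / W), data = df,
                                     start = list(A = max(df$gg),
                                                  W = 7e4)))
        cf[["W"]]
    }, numeric(1))
    slope <- coef(lm(w2 ~ g@tauS[early]))[[2L]] / 4 * 1e-6  # nm^2/s -> um^2/s
    expect_equal(slope, 0.1, tolerance = 0.15)
})

test_that("the FFT correlation matches a brute-force oracle and channel
           exchange mirrors the lags", {
    # brute-force oracle: direct double loop over circular lags
    set.seed(52)
    nl <- 40L; np <- 9L
    a <- matrix(rpois(nl * np, 4), nl, np)
    b <- matrix(rpois(nl * np, 6), nl, np)
    ky <- new("Kymograph", channels = list(A = a, B = b),
              linePeriodS = 1 / 1800, pixelSizeNm = 50,
              keepLines = rep(TRUE, nl), keepPixels = rep(TRUE, np),
              metadata = list())
    brute <- function(x, y, tau, xi) {
        dx <- x - mean(x); dy <- y - mean(y)
        s <- 0
        for (t in seq_len(nl)) for (p in seq_len(np)) {
            s <- s + dx[t, p] *
                dy[(t - 1L + tau) %% nl + 1L, (p - 1L + xi) %% np + 1L]
        }
        s / (nl * np) / (mean(x) * mean(y))
    }
    gAB <- computeStics(ky, "AB", maxLagLines = 5L)
    for (tau in 1:5) for (xi in c(-3L, 0L, 2L)) {
        expect_equal(gAB@G[tau, gAB@xiPx == xi], brute(a, b, tau, xi),
                     tolerance = 1e-10)
    }
    # exchanging channels is the same estimator at jointly mirrored lags
    gBA <- computeStics(ky, "BA", maxLagLines = 5L)
    for (tau in 1:5) for (xi in c(-3L, 0L, 2L)) {
        expect_equal(gBA@G[tau, gBA@xiPx == xi], brute(b, a, tau, xi),
                     tolerance = 1e-10)
        expect_equal(brute(b, a, tau, xi), brute(a, b, -tau, -xi),
                     tolerance = 1e-12)
    }
    # for stationary data the mirrored surfaces agree within sampling error
    ky2 <- simulateKymograph(membraneSimConfig(
        nLines = 5000L, nPixels = 64L, particleDensityUm2 = 5,
        colabelFraction = 0.5, seed = 53))
    g2AB <- computeStics(ky2, "AB", maxLagLines = 100L)
    g2BA <- computeStics(ky2, "BA", maxLagLines = 100L)
    expect_gt(cor(as.vector(g2AB@G),
                  as.vector(g2BA@G[, rev(seq_along(g2BA@xiPx))])), 0.9)
})

test_that("co-diffusion fraction separates independent and co-labeled channels", {
    mk <- function(colabel, seed) {
        ky <- simulateKymograph(membraneSimConfig(
            nLines = 30000L, nPixels = 128L, particleDensityUm2 = 5,
            colabelFraction = colabel, nChannels = 2L, seed = seed))
        ky <- detrendKymograph(ky, binSizeLines = 10000L, seed = seed)
        crossCorrelationFraction(computeStics(ky, "AA"),
                                 computeStics(ky, "BB"),
                                 computeStics(ky, "AB"))
    }
    expect_lt(abs(mk(0, 53)), 0.1)       # independent channels
    expect_equal(mk(1, 54), 1, tolerance = 0.1)  # fully co-labeled
})
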