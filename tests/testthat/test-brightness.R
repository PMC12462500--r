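# Molecular brightness: moment and histogram estimators, monomer-referenced
# ratios, and the analytic mixture oracle.

test_that("ROI polygons are validated", {
    expect_error(roiPolygon(data.frame(row = c(0, 1), col = c(0, 1))),
                 "3 vertices")
    # bow-tie polygon self-intersects
    expect_error(roiPolygon(data.frame(row = c(0, 10, 0, 10),
                                       col = c(0, 10, 10, 0))),
                 "simple")
    st <- poissonStack(5, dims = c(64L, 64L, 2L))
    expect_error(momentBrightness(st, roiRectangle(1, 1, 5, 5)),
                 "50 pixels")
})

test_that("pure shot noise gives zero brightness, flagged below shot noise", {
    st <- poissonStack(8, dims = c(128L, 128L, 10L), seed = 2)
    b <- momentBrightness(st, roiRectangle(4, 4, 123, 123))
    expect_lt(abs(epsilon(b)), 0.02)
    # an estimate this close to zero may fall on either side; when it does
    # dip below, it must carry the flag
    if (epsilon(b) <= 0) expect_true("below_shot_noise" %in% fitFlags(b))
    expect_error(momentBrightness(poissonStack(0, dims = c(64L, 64L, 2L)),
                                  roiRectangle(2, 2, 60, 60)),
                 "zero")
})

test_that("moment brightness recovers the generator scale and stoichiometry", {
    mono <- momentBrightness(monomerStack(seed = 31), centralRoi
                             (monomerStack(seed = 31)))
    expect_equal(epsilon(mono), 1, tolerance = 0.05)
    dim2 <- simulateConfocalStack(membraneSimConfig(
        fieldSizePx = c(256L, 256L), nFrames = 20L,
        species = data.frame(stoichiometry = 2L, fraction = 1,
                             brightness = 1),
        particleDensityUm2 = 10, seed = 32))
    bd <- momentBrightness(dim2, centralRoi(dim2))
    expect_equal(epsilon(bd) / epsilon(mono), 2, tolerance = 0.08)
})

test_that("inhomogeneous ROIs are rejected", {
    set.seed(4)
    nr <- 128L
    grad <- matrix(rep(seq(2, 40, length.out = nr), each = nr), nr, nr)
    arr <- array(rpois(nr * nr * 4L, grad), dim = c(nr, nr, 4L))
    st <- new("ConfocalStack", channels = list(A = arr), pixelSizeNm = 50,
              frameIntervalS = 1, metadata = list())
    expect_error(momentBrightness(st, roiRectangle(4, 4, 123, 123)),
                 "inhomogeneous")
    # disabling the check accepts the ROI
    expect_s4_class(momentBrightness(st, roiRectangle(4, 4, 123, 123),
                                     maxBlockCV = Inf),
                    "BrightnessEstimate")
})

test_that("histogram and moment estimators agree on single populations", {
    st <- monomerStack(seed = 33, fieldPx = 256L, nFrames = 10L,
                       brightness = 0.8)
    roi <- centralRoi(st)
    bm <- momentBrightness(st, roi)
    bh <- histogramBrightness(st, roi, psfWaistNm = 250)
    expect_gt(bh@nPixels, 1e5)
    expect_equal(epsilon(bh) / epsilon(bm), 1, tolerance = 0.1)
    # constant image has a degenerate histogram
    stc <- new("ConfocalStack",
               channels = list(A = array(3L, c(64L, 64L, 1L))),
               pixelSizeNm = 50, frameIntervalS = 1, metadata = list())
    expect_error(histogramBrightness(stc, roiRectangle(2, 2, 60, 60)),
                 "degenerate")
})

test_that("brightness ratio identities and the mixture oracle hold", {
    st <- monomerStack(seed = 35, fieldPx = 128L, nFrames = 10L)
    b <- momentBrightness(st, centralRoi(st))
    expect_equal(brightnessRatio(b, b), 1)
    expect_equal(mixtureApparentBrightness(1, 1L), 1)
    expect_equal(mixtureApparentBrightness(1, 2L), 2)
    expect_equal(mixtureApparentBrightness(c(7, 6) / 13, c(2L, 1L)),
                 34 / 20)
    expect_error(mixtureApparentBrightness(numeric(0), integer(0)),
                 "empty")
    expect_error(mixtureApparentBrightness(c(0.5, 0.4), c(1L, 2L)),
                 "sum to 1")
})

test_that("per-cell pooling averages ROI estimates by pixel weight", {
    st <- monomerStack(seed = 38, fieldPx = 128L, nFrames = 8L)
    e1 <- momentBrightness(st, roiRectangle(4, 4, 60, 60))
    e2 <- momentBrightness(st, roiRectangle(64, 64, 123, 123))
    pooled <- poolBrightness(list(e1, e2))
    w <- c(e1@nPixels, e2@nPixels)
    expect_equal(epsilon(pooled),
                 sum(w * c(epsilon(e1), epsilon(e2))) / sum(w))
    expect_identical(pooled@nPixels, e1@nPixels + e2@nPixels)
})

test_that("apparent brightness increases strictly with dimer fraction", {
    fr <- seq(0, 1, by = 0.1)
    app <- vapply(fr, function(f)
        mixtureApparentBrightness(c(f, 1 - f), c(2L, 1L)), numeric(1))
    expect_true(all(diff(app) > 0))
})

test_that("uniform Poisson background biases brightness by the mean ratio", {
    st <- monomerStack(seed = 36, fieldPx = 256L, nFrames = 15L)
    roi <- centralRoi(st)
    b0 <- momentBrightness(st, roi)
    m0 <- mean(counts(st))
    bgMean <- 4
    set.seed(37)
    arr <- counts(st) + array(rpois(length(counts(st)), bgMean),
                              dim = dim(counts(st)))
    stBg <- new("ConfocalStack", channels = list(A = arr),
                pixelSizeNm = 50, frameIntervalS = 1, metadata = list())
    bBg <- momentBrightness(stBg, roi)
    # var - mean is unchanged by added Poisson background, so epsilon
    # shrinks by m0 / (m0 + bg)
    expect_equal(epsilon(bBg) / epsilon(b0), m0 / (m0 + bgMean),
                 tolerance = 0.05)
})
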