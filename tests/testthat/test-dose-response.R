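# Hill fitting and the assay normalization rules.

test_that("noiseless tables are recovered to optimizer tolerance", {
    tab <- hillTable(bottom = 5, span = 100, ec50M = 1e-8, noiseSd = 0)
    f <- fitHill3(tab)
    expect_true(isConverged(f))
    expect_equal(f@bottom, 5, tolerance = 1e-5)
    expect_equal(f@span, 100, tolerance = 1e-5)
    expect_equal(f@log10EC50, -8, tolerance = 1e-6)
    expect_equal(pEC50(f), 8, tolerance = 1e-6)
})

test_that("flat tables yield a zero span and an indeterminate EC50", {
    tab <- data.frame(concentration_M = rep(10^(-10:-6), each = 2),
                      response = 50)
    f <- fitHill3(tab)
    expect_equal(f@span, 0)
    expect_true(all(c("no_plateau", "ec50_indeterminate") %in% fitFlags(f)))
    expect_error(pEC50(f), "indeterminate")
})

test_that("fewer than four concentrations is an error", {
    tab <- data.frame(concentration_M = rep(c(1e-9, 1e-8, 1e-7), 2),
                      response = 1:6)
    expect_error(fitHill3(tab), "4 distinct")
})

test_that("pEC50 arithmetic matches its definition", {
    mkfit <- function(ec50M)
        fitHill3(hillTable(ec50M = ec50M, noiseSd = 0,
                           concs = ec50M * 10^seq(-3, 3)))
    expect_equal(pEC50(mkfit(1e-9)), 9, tolerance = 1e-6)
    expect_equal(pEC50(mkfit(4.5e-9)), -log10(4.5e-9), tolerance = 1e-6)
    expect_equal(pEC50(mkfit(1)), 0, tolerance = 1e-6)
})

test_that("Hill fit is affine-equivariant and EC50 affine-invariant", {
    tab <- hillTable(bottom = 0, span = 50, ec50M = 3e-9, noiseSd = 2,
                     seed = 11)
    f1 <- fitHill3(tab)
    tab2 <- tab
    tab2$response <- 3 * tab$response + 7
    f2 <- fitHill3(tab2)
    expect_equal(f2@log10EC50, f1@log10EC50, tolerance = 1e-6)
    expect_equal(f2@bottom, 3 * f1@bottom + 7, tolerance = 1e-5)
    expect_equal(f2@span, 3 * f1@span, tolerance = 1e-5)
})

test_that("EC50 recovery and SE calibration hold across 200 noisy tables", {
    errs <- cover <- numeric(200)
    for (i in 1:200) {
        tab <- hillTable(span = 100, noiseSd = 5, ec50M = 1e-8,
                         concs = 10^seq(-11, -6.5, length.out = 8),
                         nRep = 3L, seed = 1000 + i)
        f <- fitHill3(tab)
        errs[i] <- f@log10EC50 - (-8)
        cover[i] <- abs(errs[i]) <= f@se[["log10EC50"]]
    }
    expect_lt(median(abs(errs)), 0.1)
    expect_gt(mean(cover), 0.55)
    expect_lt(mean(cover), 0.80)
})

test_that("a threefold potency increase is recovered as a threefold EC50 ratio", {
    ref <- fitHill3(hillTable(ec50M = 3e-8, noiseSd = 2, seed = 21))
    shifted <- fitHill3(hillTable(ec50M = 1e-8, noiseSd = 2, seed = 22))
    ratio <- 10^(ref@log10EC50 - shifted@log10EC50)
    expect_equal(ratio, 3, tolerance = 0.15)
})

test_that("Epac FRET normalization anchors baseline at 0% and forskolin at 100%", {
    wells <- rbind(c(2, 2, 5, 8, 8),
                   c(1, 1, 2.5, 4, 4))
    nm <- normalizeEpacFret(wells, baselineWindow = 1:2,
                            forskolinWindow = 4:5)
    expect_equal(nm[, 1], c(0, 0))
    expect_equal(nm[, 4], c(100, 100))
    expect_equal(nm[1, 3], 50)   # midway -> 50%
    expect_error(normalizeEpacFret(rbind(c(1, 1, 1)), 1, 3), "span")
})

test_that("BRET ratio identities hold", {
    expect_equal(bretRatio(500, 1000), 0.5)
    expect_equal(bretRatio(0, 123), 0)
    expect_equal(bretRatio(7 * 500, 7 * 1000), bretRatio(500, 1000))
    expect_error(bretRatio(1, 0), "donor")
})

test_that("BRET-change normalization reproduces its printed anchors", {
    mock <- fitHill3(hillTable(bottom = 1, span = 0.5, ec50M = 6e-8,
                               noiseSd = 0))
    cond <- fitHill3(hillTable(bottom = 1.2, span = 0.5 * 0.67,
                               ec50M = 5e-8, noiseSd = 0))
    # mock at its own top asymptote -> 100%
    expect_equal(as.numeric(normalizeBretChange(1 + 0.5, mock, mock)), 100,
                 tolerance = 1e-6)
    # any condition at its own bottom asymptote -> 0%
    expect_equal(as.numeric(normalizeBretChange(1.2, cond, mock)), 0,
                 tolerance = 1e-4)
    # condition with 0.67x the mock span at its top -> 67%
    expect_equal(as.numeric(normalizeBretChange(1.2 + 0.5 * 0.67, cond,
                                                mock)),
                 67, tolerance = 0.01)
    flat <- fitHill3(data.frame(
        concentration_M = rep(10^(-10:-6), 2), response = 1))
    expect_error(normalizeBretChange(1, cond, flat), "span")
})

test_that("Emax is the span ratio and excludes basal differences", {
    mock <- fitHill3(hillTable(bottom = 0, span = 100, noiseSd = 0))
    same <- fitHill3(hillTable(bottom = 40, span = 100, noiseSd = 0))
    half <- fitHill3(hillTable(bottom = -10, span = 50, noiseSd = 0))
    expect_equal(emax(same, mock), 100, tolerance = 1e-4)
    expect_equal(emax(half, mock), 50, tolerance = 1e-4)
    expect_equal(emax(fitHill3(hillTable(span = 67, noiseSd = 0)), mock),
                 67, tolerance = 1e-4)
})

test_that("normalizing then fitting commutes with the span ratio", {
    mock <- hillTable(bottom = 1, span = 0.4, ec50M = 6e-8, noiseSd = 0,
                      condition = "mock")
    cond <- hillTable(bottom = 1.1, span = 0.26, ec50M = 5e-8, noiseSd = 0,
                      condition = "plusAccessory")
    fMock <- fitHill3(mock); fCond <- fitHill3(cond)
    rawEmax <- emax(fCond, fMock)
    norm <- cond
    norm$response <- as.numeric(
        normalizeBretChange(cond$response, fCond, fMock))
    normMock <- mock
    normMock$response <- as.numeric(
        normalizeBretChange(mock$response, fMock, fMock))
    normEmax <- emax(fitHill3(norm), fitHill3(normMock))
    expect_equal(normEmax, rawEmax, tolerance = 1e-4)
})

test_that("Epac-Venus FRET ratio and baseline correction behave", {
    expect_equal(epacVenusFret(100, 100), 0.5)
    expect_equal(epacVenusFret(0, 50), 0)
    expect_error(epacVenusFret(0, 0), "zero total")
    f <- fitHill3(hillTable(bottom = 0.35, span = 0.1, noiseSd = 0))
    # the zero-dose asymptote maps to 0 after bottom subtraction
    expect_equal(baselineCorrect(0.35, f), 0, tolerance = 1e-5)
})

test_that("NanoBiT pre-read normalization and AUC identities hold", {
    t <- seq(0, 600, by = 60)
    flat <- rep(800, length(t))
    auc <- nanobitNormalizeAUC(t, flat, preWindow = 1:3)
    expect_equal(as.numeric(auc), 600 - 180)  # post window duration
    # gain invariance
    expect_equal(as.numeric(nanobitNormalizeAUC(t, 5 * flat, 1:3)),
                 as.numeric(auc))
    # step to 2x at the stimulus -> AUC = 2 x duration
    step <- c(rep(400, 3), rep(800, length(t) - 3))
    expect_equal(as.numeric(nanobitNormalizeAUC(t, step, 1:3)),
                 2 * (600 - 180))
    expect_error(nanobitNormalizeAUC(t, flat, preWindow = 1:2), "3 pre")
    expect_error(nanobitNormalizeAUC(t, 0 * flat, preWindow = 1:3),
                 "pre-read")
})
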