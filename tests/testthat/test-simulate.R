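# Generators: statistical structure, analytic anchors, reproducibility.

test_that("confocal stacks are integer counts with the expected mean", {
    cfg <- membraneSimConfig(fieldSizePx = c(128L, 128L), nFrames = 30L,
                             species = data.frame(stoichiometry = 1L,
                                                  fraction = 1,
                                                  brightness = 1),
                             particleDensityUm2 = 10, seed = 42)
    st <- simulateConfocalStack(cfg)
    a <- counts(st)
    expect_true(all(a >= 0))
    expect_identical(storage.mode(a), "integer")
    # analytic per-pixel mean given the realized emitter number N:
    # N * (stoich * brightness / gamma) * (pi w0^2 / 2) / padded box area,
    # gamma = 1/2 for the 2D Gaussian beam
    waistPx <- cfg$psfWaistNm / cfg$pixelSizeNm
    pad <- 3 * waistPx
    nEm <- sum(groundTruth(st)$nEmitters)
    boxPx2 <- prod(cfg$fieldSizePx + 2 * pad)
    muExp <- nEm * 2 * 1 * pi * waistPx^2 / 2 / boxPx2
    frameMeans <- apply(a, 3, mean)
    se <- sd(frameMeans) / sqrt(length(frameMeans))
    expect_lt(abs(mean(frameMeans) - muExp), 3 * se + 0.01 * muExp)
})

test_that("zero density gives empty frames and undefined truth brightness", {
    st <- simulateConfocalStack(membraneSimConfig(
        fieldSizePx = c(32L, 32L), nFrames = 3L,
        particleDensityUm2 = 0, seed = 1))
    expect_true(all(counts(st) == 0))
    expect_true(is.na(groundTruth(st)$apparentBrightness))
})

test_that("pooled variance/mean of a monomer field obeys the moment identity", {
    # var/mean = 1 + epsilon for Poisson emitters with Poisson detection;
    # brute-force pooled moments over > 10^6 pixels
    st <- monomerStack(seed = 7, fieldPx = 256L, nFrames = 20L,
                       brightness = 1)
    v <- as.numeric(counts(st))
    expect_gt(length(v), 1e6)
    expect_equal(var(v) / mean(v), 2, tolerance = 0.03)
})

test_that("stack simulation is bit-reproducible under a fixed seed", {
    cfg <- membraneSimConfig(fieldSizePx = c(48L, 48L), nFrames = 4L,
                             seed = 99)
    expect_identical(counts(simulateConfocalStack(cfg)),
                     counts(simulateConfocalStack(cfg)))
    cfg2 <- membraneSimConfig(fieldSizePx = c(48L, 48L), nFrames = 4L,
                              seed = 100)
    expect_false(identical(counts(simulateConfocalStack(cfg)),
                           counts(simulateConfocalStack(cfg2))))
})

test_that("config validation rejects impossible membrane simulations", {
    expect_error(membraneSimConfig(fieldSizePx = c(0L, 32L)), "fieldSizePx")
    expect_error(membraneSimConfig(
        species = data.frame(stoichiometry = 1L, fraction = 0.7)),
        "sum to 1")
    expect_error(membraneSimConfig(
        species = data.frame(stoichiometry = 0L, fraction = 1)),
        "stoichiometry")
    expect_error(membraneSimConfig(diffusionUm2S = -1), "diffusion")
    expect_error(membraneSimConfig(colabelFraction = 0.5, nChannels = 1L),
                 "nChannels")
})

test_that("kymograph generator is reproducible and dimensioned correctly", {
    cfg <- membraneSimConfig(nLines = 300L, nPixels = 64L,
                             particleDensityUm2 = 5, seed = 3)
    ky <- simulateKymograph(cfg)
    expect_s4_class(ky, "Kymograph")
    expect_identical(dim(counts(ky)), c(300L, 64L))
    expect_identical(counts(simulateKymograph(cfg)), counts(ky))
    cfg2 <- membraneSimConfig(nLines = 300L, nPixels = 64L,
                              particleDensityUm2 = 5, colabelFraction = 0.5,
                              seed = 3)
    ky2 <- simulateKymograph(cfg2)
    expect_identical(channelNames(ky2), c("A", "B"))
})

test_that("dose-response generator hits the midpoint identity exactly", {
    tab <- hillTable(bottom = 10, span = 80, ec50M = 1e-8, noiseSd = 0,
                     concs = c(1e-10, 1e-9, 1e-8, 1e-7, 1e-6))
    atEc50 <- tab$response[tab$concentration_M == 1e-8]
    expect_equal(atEc50, rep(10 + 80 / 2, 3))
    # fixed seed reproducibility
    t1 <- hillTable(noiseSd = 5, seed = 5)
    t2 <- hillTable(noiseSd = 5, seed = 5)
    expect_identical(t1, t2)
    expect_error(simulateDoseResponse(doseResponseSimConfig(
        concentrationsM = numeric(0))), "empty")
})

test_that("endosome frames carry ground truth and respect separation", {
    sim <- simulateEndosomeFrames(0, seed = 1)
    expect_identical(nrow(sim$spots), 0L)
    sim2 <- simulateEndosomeFrames(20, spotSigmaPx = 2, seed = 2)
    d <- as.matrix(dist(sim2$spots))
    diag(d) <- Inf
    expect_gte(min(d), 8)  # 4 * sigma
    # impossible packing errors out
    expect_error(simulateEndosomeFrames(200, spotSigmaPx = 4,
                                        fieldSizePx = c(64L, 64L),
                                        seed = 3),
                 "cannot place")
    expect_identical(counts(simulateEndosomeFrames(5, seed = 9)$stack),
                     counts(simulateEndosomeFrames(5, seed = 9)$stack))
})

test_that("recruitment traces follow the kinetic model", {
    flat <- simulateRecruitmentTrace(0, plateau = 1, baseline = 2,
                                     noiseSd = 0, nFrames = 100L)
    expect_true(all(flat$intensity == 2))
    tr <- simulateRecruitmentTrace(0.01, plateau = 3, baseline = 1,
                                   noiseSd = 0, nFrames = 100L,
                                   stimulusFrame = 25L, frameIntervalS = 4)
    expect_true(all(tr$intensity[1:25] == 1))
    expect_equal(tr$intensity[26], 1 + 3 * (1 - exp(-0.01 * 4)))
    expect_equal(tr$intensity[100], 1 + 3 * (1 - exp(-0.01 * 75 * 4)))
})

test_that("binding tables obey half-saturation at L = Kd", {
    tab <- simulateSaturationBinding(bindingSimConfig(
        kdNM = 2, bmaxCounts = 1000, noiseCV = 0))
    tot <- tab[tab$well_type == "total" & tab$concentration_nM == 2, ]
    ns <- tab[tab$well_type == "nonspecific" & tab$concentration_nM == 2, ]
    expect_equal(tot$counts - ns$counts, 500)
    cfg <- bindingSimConfig(noiseCV = 0.1, seed = 4)
    expect_identical(simulateSaturationBinding(cfg),
                     simulateSaturationBinding(cfg))
})
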