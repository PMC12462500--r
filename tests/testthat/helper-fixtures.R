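# Shared fixture builders. Everything is generated in code; sizes are kept
# small enough for a routine test run while leaving enough samples for the
# statistical assertions.

# small monomer stack with unit per-protomer brightness
monomerStack <- function(seed, fieldPx = 256L, nFrames = 20L,
                         brightness = 1, density = 10) {
    simulateConfocalStack(membraneSimConfig(
        fieldSizePx = c(fieldPx, fieldPx), nFrames = nFrames,
        species = data.frame(stoichiometry = 1L, fraction = 1,
                             brightness = brightness),
        particleDensityUm2 = density, seed = seed))
}

# stack of the 7:6 dimer:monomer mixture (equal per-protomer brightness)
mixtureStack <- function(seed, fieldPx = 256L, nFrames = 20L,
                         brightness = 1, density = 10) {
    simulateConfocalStack(membraneSimConfig(
        fieldSizePx = c(fieldPx, fieldPx), nFrames = nFrames,
        species = data.frame(stoichiometry = c(2L, 1L),
                             fraction = c(7, 6) / 13,
                             brightness = brightness),
        particleDensityUm2 = density, seed = seed))
}

# central rectangle ROI leaving a small border
centralRoi <- function(stack, border = 6L) {
    d <- dim(counts(stack))
    roiRectangle(border, border, d[1L] - border - 1L, d[2L] - border - 1L)
}

# pure shot-noise stack (no emitters) around a given mean
poissonStack <- function(mean, dims = c(128L, 128L, 10L), seed = 1L) {
    set.seed(seed)
    arr <- array(rpois(prod(dims), mean), dim = dims)
    new("ConfocalStack", channels = list(A = arr),
        pixelSizeNm = 50, frameIntervalS = 1, metadata = list())
}

# kymograph built directly from a count matrix
rawKymograph <- function(m, linePeriodS = 1 / 1800, pixelSizeNm = 50) {
    new("Kymograph", channels = list(A = m),
        linePeriodS = linePeriodS, pixelSizeNm = pixelSizeNm,
        keepLines = rep(TRUE, nrow(m)), keepPixels = rep(TRUE, ncol(m)),
        metadata = list())
}

# analytic STICS surface from the 2D-diffusion Gaussian-beam model
analyticSurface <- function(D, G0 = 1, waistNm = 250, pixelSizeNm = 50,
                            nTau = 20L, linePeriodS = 1 / 1800) {
    tauEdges <- linePeriodS * 2^(0:nTau)
    tau <- sqrt(tauEdges[-1] * tauEdges[-(nTau + 1L)])
    xi <- -40:40
    xiNm <- xi * pixelSizeNm
    Dnm <- D * 1e6  # um^2/s -> nm^2/s
    tauD <- waistNm^2 / (4 * Dnm)
    G <- outer(tau, xiNm, function(t, x)
        G0 / (1 + t / tauD) * exp(-x^2 / (waistNm^2 + 4 * Dnm * t)))
    new("CorrelationSurface", G = G, xiPx = xi, tauS = tau,
        tauEdgesS = tauEdges, pair = "AA", pixelSizeNm = pixelSizeNm,
        metadata = list())
}

# noiseless three-parameter Hill table
hillTable <- function(bottom = 0, span = 100, ec50M = 1e-8, noiseSd = 0,
                      concs = 10^seq(-11, -6, length.out = 8),
                      nRep = 3L, condition = "sim", seed = NULL) {
    simulateDoseResponse(doseResponseSimConfig(
        bottom = bottom, span = span, log10EC50Molar = log10(ec50M),
        concentrationsM = concs, nReplicates = nRep, noiseSd = noiseSd,
        condition = condition, seed = seed))
}
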