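# Synthetic-data generators. Every generator embeds its ground truth and
# seed in the returned object's metadata so downstream recovery can be
# checked without external files.

#' Configuration for membrane-emitter simulations
#'
#' Defines a population of fluorescently labeled membrane proteins diffusing
#' in 2D, imaged either as a confocal frame series
#' ([simulateConfocalStack()]) or as a repeatedly scanned line
#' ([simulateKymograph()]). Species are given as number fractions of
#' particles with an oligomeric stoichiometry and a per-protomer molecular
#' brightness.
#'
#' `brightnessPerProtomer` is specified in the shot-noise-referenced
#' (moment) convention: it is the molecular brightness a single protomer
#' produces in a pooled variance/mean analysis, i.e. the emitter's peak
#' emission rate is `brightness / gamma` with the 2D Gaussian beam shape
#' factor `gamma = 1/2`. Generator parameter and [momentBrightness()]
#' estimate therefore share one scale.
#'
#' Defaults follow a typical photon-counting confocal acquisition of an
#' overexpressed receptor: 512 x 512 px frames or 256 px lines at 50 nm
#' pixels, 1800 Hz line rate, 250 nm beam waist, 10 particles/um^2,
#' 0.5 counts/protomer/dwell, D = 0.1 um^2/s.
#'
#' @param fieldSizePx integer pair, frame size in pixels (rows, cols).
#' @param nPixels pixels per scanned line (kymographs).
#' @param pixelSizeNm pixel size in nm.
#' @param psfWaistNm 1/e^2 Gaussian beam radius in nm.
#' @param particleDensityUm2 particle surface density per um^2 (all species
#'   combined). May be 0 (empty field).
#' @param species data.frame with columns `stoichiometry` (integer >= 1),
#'   `fraction` (number fractions, must sum to 1) and optionally
#'   `brightness` (counts/protomer/dwell; default `brightnessPerProtomer`).
#' @param brightnessPerProtomer default per-protomer brightness used when
#'   `species` lacks a `brightness` column.
#' @param diffusionUm2S diffusion coefficient(s) in um^2/s, recycled across
#'   species.
#' @param nFrames,frameIntervalS frame count and interval for stacks.
#' @param nLines,linePeriodS line count and period for kymographs.
#' @param colabelFraction fraction of channel-A particles that also carry
#'   the channel-B label (two-color kymographs).
#' @param nChannels 1 or 2 kymograph channels; defaults to 2 when
#'   `colabelFraction > 0`.
#' @param seed integer RNG seed or NULL.
#' @return a validated list of class `MembraneSimConfig`.
#' @examples
#' cfg <- membraneSimConfig(
#'     species = data.frame(stoichiometry = c(2, 1),
#'                          fraction = c(7, 6) / 13),
#'     seed = 1)
#' @export
membraneSimConfig <- function(fieldSizePx = c(512L, 512L),
                              nPixels = 256L,
                              pixelSizeNm = 50,
                              psfWaistNm = 250,
                              particleDensityUm2 = 10,
                              species = data.frame(stoichiometry = 1L,
                                                   fraction = 1),
                              brightnessPerProtomer = 0.5,
                              diffusionUm2S = 0.1,
                              nFrames = 200L,
                              frameIntervalS = 5.12,
                              nLines = 100000L,
                              linePeriodS = 1 / 1800,
                              colabelFraction = 0,
                              nChannels = if (colabelFraction > 0) 2L else 1L,
                              seed = NULL) {
    if (length(fieldSizePx) != 2L || any(fieldSizePx < 1))
        stop("fieldSizePx must be two positive integers")
    .checkScalar(pixelSizeNm, "pixelSizeNm")
    .checkScalar(psfWaistNm, "psfWaistNm")
    .checkScalar(particleDensityUm2, "particleDensityUm2", strict = FALSE)
    .checkScalar(nPixels, "nPixels")
    if (!is.data.frame(species) ||
        !all(c("stoichiometry", "fraction") %in% names(species)))
        stop("species must be a data.frame with stoichiometry and fraction")
    if (is.null(species$brightness))
        species$brightness <- brightnessPerProtomer
    if (abs(sum(species$fraction) - 1) > 1e-9)
        stop("species fractions must sum to 1")
    if (any(species$stoichiometry < 1) ||
        any(species$stoichiometry != round(species$stoichiometry)))
        stop("stoichiometry must be integer >= 1")
    if (any(species$brightness < 0) || any(species$fraction < 0))
        stop("fractions and brightnesses must be >= 0")
    if (any(diffusionUm2S < 0)) stop("diffusion coefficients must be >= 0")
    species$diffusionUm2S <- rep_len(diffusionUm2S, nrow(species))
    if (colabelFraction < 0 || colabelFraction > 1)
        stop("colabelFraction must be in [0, 1]")
    if (!nChannels %in% 1:2) stop("nChannels must be 1 or 2")
    if (colabelFraction > 0 && nChannels != 2L)
        stop("colabelFraction > 0 requires nChannels = 2")
    structure(list(
        fieldSizePx = as.integer(fieldSizePx), nPixels = as.integer(nPixels),
        pixelSizeNm = pixelSizeNm, psfWaistNm = psfWaistNm,
        particleDensityUm2 = particleDensityUm2, species = species,
        nFrames = as.integer(nFrames), frameIntervalS = frameIntervalS,
        nLines = as.integer(nLines), linePeriodS = linePeriodS,
        colabelFraction = colabelFraction, nChannels = as.integer(nChannels),
        seed = seed), class = "MembraneSimConfig")
}

# draw emitters of one species mixture for a padded box (pixel units)
.drawEmitters <- function(cfg, areaUm2, boxW, boxH) {
    sp <- cfg$species
    n <- rpois(nrow(sp), cfg$particleDensityUm2 * sp$fraction * areaUm2)
    idx <- rep(seq_len(nrow(sp)), n)
    ntot <- sum(n)
    # peak amplitude = stoich * brightness / gamma, gamma = 1/2 (2D Gaussian)
    list(
        x = runif(ntot, 0, boxW),
        y = runif(ntot, 0, boxH),
        amp = 2 * sp$stoichiometry[idx] * sp$brightness[idx],
        stepSd = sqrt(2 * sp$diffusionUm2S[idx]) * 1000 / cfg$pixelSizeNm,
        species = idx, n = n)
}

#' Simulate a photon-counting confocal image stack
#'
#' Emitters are placed by a 2D spatial Poisson process in a periodic box
#' padded by 3 beam waists around the imaged field, displaced each frame by
#' Brownian steps of per-axis variance `2 D dt`, and imaged through a 2D
#' Gaussian beam; observed pixel values are Poisson draws of the expected
#' counts. Ground truth (species table, density, apparent mixture
#' brightness) is embedded in the metadata.
#'
#' @param cfg a [membraneSimConfig()].
#' @return a [ConfocalStack-class] with one channel "A".
#' @examples
#' st <- simulateConfocalStack(
#'     membraneSimConfig(fieldSizePx = c(64, 64), nFrames = 5, seed = 7))
#' st
#' @export
simulateConfocalStack <- function(cfg) {
    stopifnot(inherits(cfg, "MembraneSimConfig"))
    if (!is.null(cfg$seed)) set.seed(cfg$seed)
    nr <- cfg$fieldSizePx[1L]; nc <- cfg$fieldSizePx[2L]
    waistPx <- cfg$psfWaistNm / cfg$pixelSizeNm
    pad <- 3 * waistPx
    umPerPx <- cfg$pixelSizeNm / 1000
    areaUm2 <- (nr + 2 * pad) * (nc + 2 * pad) * umPerPx^2
    em <- .drawEmitters(cfg, areaUm2, nc + 2 * pad, nr + 2 * pad)
    stepPerFrame <- em$stepSd * sqrt(cfg$frameIntervalS)
    arr <- .renderStackCpp(nr, nc, cfg$nFrames, em$x, em$y, em$amp,
                           stepPerFrame, pad, waistPx)
    sp <- cfg$species
    appBr <- if (cfg$particleDensityUm2 > 0)
        sum(sp$fraction * sp$stoichiometry^2 * sp$brightness) /
            sum(sp$fraction * sp$stoichiometry) else NA_real_
    new("ConfocalStack",
        channels = list(A = arr),
        pixelSizeNm = cfg$pixelSizeNm,
        frameIntervalS = cfg$frameIntervalS,
        metadata = list(groundTruth = list(
            species = sp, particleDensityUm2 = cfg$particleDensityUm2,
            nEmitters = em$n, apparentBrightness = appBr,
            psfWaistNm = cfg$psfWaistNm, seed = cfg$seed)))
}

#' Simulate a line-scan kymograph
#'
#' Each scan line is a 1D Gaussian-beam-weighted snapshot of emitters
#' diffusing in a 2D band around the scanned row (half-height 3 beam
#' waists, periodic boundaries; line period 0.56 ms is far below the beam
#' transit time so intra-line motion is neglected). With two channels, a
#' configurable fraction of channel-A particles carries the channel-B label
#' at identical coordinates; the remaining channel-B particles are
#' independent, keeping the two channel densities matched.
#'
#' @param cfg a [membraneSimConfig()].
#' @return a [Kymograph-class]; ground truth (diffusion coefficients,
#'   co-labeled fraction) is embedded in the metadata.
#' @examples
#' ky <- simulateKymograph(membraneSimConfig(
#'     nLines = 500L, nPixels = 64L, particleDensityUm2 = 5, seed = 2))
#' ky
#' @export
simulateKymograph <- function(cfg) {
    stopifnot(inherits(cfg, "MembraneSimConfig"))
    if (!is.null(cfg$seed)) set.seed(cfg$seed)
    if (cfg$nLines < 2L) stop("nLines must be >= 2")
    npx <- cfg$nPixels
    waistPx <- cfg$psfWaistNm / cfg$pixelSizeNm
    pad <- 3 * waistPx
    bandHalf <- 3 * waistPx
    umPerPx <- cfg$pixelSizeNm / 1000
    areaUm2 <- (npx + 2 * pad) * (2 * bandHalf) * umPerPx^2
    em <- .drawEmitters(cfg, areaUm2, npx + 2 * pad, 2 * bandHalf)
    nA <- length(em$x)
    two <- cfg$nChannels == 2L
    colab <- if (nA > 0) runif(nA) < cfg$colabelFraction else logical(0)
    if (two) {
        emB <- .drawEmitters(cfg, areaUm2 * (1 - cfg$colabelFraction),
                             npx + 2 * pad, 2 * bandHalf)
        x <- c(em$x, emB$x); y <- c(em$y, emB$y)
        amp <- c(em$amp, emB$amp)
        stepSd <- c(em$stepSd, emB$stepSd)
        colabAll <- c(colab, rep(FALSE, length(emB$x)))
        nB <- length(emB$x)
    } else {
        x <- em$x; y <- em$y; amp <- em$amp; stepSd <- em$stepSd
        colabAll <- colab; nB <- 0L
    }
    stepPerLine <- stepSd * sqrt(cfg$linePeriodS)
    mats <- .renderKymoCpp(cfg$nLines, npx, x, y, amp, colabAll, amp,
                           nA, nB, two, stepPerLine, pad, bandHalf, waistPx)
    channels <- if (two) list(A = mats$A, B = mats$B) else list(A = mats$A)
    new("Kymograph",
        channels = channels,
        linePeriodS = cfg$linePeriodS, pixelSizeNm = cfg$pixelSizeNm,
        keepLines = rep(TRUE, cfg$nLines), keepPixels = rep(TRUE, npx),
        metadata = list(groundTruth = list(
            species = cfg$species,
            particleDensityUm2 = cfg$particleDensityUm2,
            colabelFraction = cfg$colabelFraction,
            psfWaistNm = cfg$psfWaistNm, seed = cfg$seed)))
}

#' Configuration for dose-response simulations
#'
#' @param bottom,span zero-dose asymptote and amplitude (response units).
#' @param log10EC50Molar log10 of the EC50 in molar (e.g. -8 for 10 nM).
#' @param hillSlope Hill slope (default 1).
#' @param concentrationsM agonist concentrations in molar, all > 0.
#' @param nReplicates replicates per concentration.
#' @param noiseSd additive Gaussian noise SD (response units), >= 0.
#' @param condition condition label written into the table.
#' @param seed RNG seed or NULL.
#' @return a validated list of class `DoseResponseSimConfig`.
#' @export
doseResponseSimConfig <- function(bottom = 0, span = 100,
                                  log10EC50Molar = -8, hillSlope = 1,
                                  concentrationsM =
                                      10^seq(-11, -6.5, length.out = 8),
                                  nReplicates = 3L, noiseSd = 5,
                                  condition = "sim", seed = NULL) {
    if (length(concentrationsM) < 1L) stop("empty concentration list")
    if (any(concentrationsM <= 0)) stop("concentrations must be > 0")
    .checkScalar(noiseSd, "noiseSd", strict = FALSE)
    .checkScalar(nReplicates, "nReplicates")
    structure(list(bottom = bottom, span = span,
                   log10EC50Molar = log10EC50Molar, hillSlope = hillSlope,
                   concentrationsM = concentrationsM,
                   nReplicates = as.integer(nReplicates),
                   noiseSd = noiseSd, condition = condition, seed = seed),
              class = "DoseResponseSimConfig")
}

#' Simulate a concentration-response table
#'
#' Responses follow the three-parameter Hill model
#' `bottom + span / (1 + 10^((log10EC50 - log10 L) * hillSlope))` plus
#' additive Gaussian noise, in the long format consumed by [fitHill3()].
#'
#' @param cfg a [doseResponseSimConfig()].
#' @return data.frame with columns condition, concentration_M, replicate,
#'   response; the generating parameters are attached as attribute
#'   `"groundTruth"`.
#' @examples
#' tab <- simulateDoseResponse(doseResponseSimConfig(noiseSd = 0))
#' head(tab)
#' @export
simulateDoseResponse <- function(cfg) {
    stopifnot(inherits(cfg, "DoseResponseSimConfig"))
    if (!is.null(cfg$seed)) set.seed(cfg$seed)
    conc <- rep(cfg$concentrationsM, each = cfg$nReplicates)
    mu <- cfg$bottom + cfg$span /
        (1 + 10^((cfg$log10EC50Molar - log10(conc)) * cfg$hillSlope))
    out <- data.frame(
        condition = cfg$condition,
        concentration_M = conc,
        replicate = rep(seq_len(cfg$nReplicates),
                        times = length(cfg$concentrationsM)),
        response = mu + rnorm(length(mu), 0, cfg$noiseSd))
    attr(out, "groundTruth") <- cfg
    out
}

#' Simulate endosome-like spot images
#'
#' Gaussian spots on a textured cytosolic background, detected as photon
#' counts. Spots are placed with a minimum pairwise separation of
#' `4 * spotSigmaPx` (and the same margin from the field edge); if that is
#' impossible, an error is raised. Spot peak amplitude is
#' `snr * sqrt(backgroundMean)`, i.e. `snr` shot-noise standard deviations
#' above background.
#'
#' @param nSpots number of spots (>= 0).
#' @param spotSigmaPx Gaussian spot sigma in pixels.
#' @param snr spot peak amplitude in background shot-noise SD units.
#' @param fieldSizePx integer pair (rows, cols).
#' @param backgroundMean mean background counts per pixel.
#' @param textureCV coefficient of variation of the smooth background
#'   texture (0 = flat background).
#' @param nFrames number of frames (same expected image, independent noise).
#' @param seed RNG seed or NULL.
#' @return list with `stack` (a [ConfocalStack-class]) and `spots`
#'   (data.frame of true row/col centers).
#' @examples
#' sim <- simulateEndosomeFrames(5, seed = 3)
#' nrow(sim$spots)
#' @export
simulateEndosomeFrames <- function(nSpots, spotSigmaPx = 2, snr = 5,
                                   fieldSizePx = c(128L, 128L),
                                   backgroundMean = 50, textureCV = 0.08,
                                   nFrames = 1L, seed = NULL) {
    if (nSpots < 0) stop("nSpots must be >= 0")
    .checkScalar(spotSigmaPx, "spotSigmaPx")
    .checkScalar(backgroundMean, "backgroundMean")
    if (!is.null(seed)) set.seed(seed)
    nr <- fieldSizePx[1L]; nc <- fieldSizePx[2L]

    bg <- matrix(backgroundMean, nr, nc)
    if (textureCV > 0) {
        z <- matrix(rnorm(nr * nc), nr, nc)
        k <- EBImage::makeBrush(2L * 8L + 1L, shape = "Gaussian", sigma = 8)
        zs <- EBImage::filter2(z, k, boundary = "circular")
        bg <- backgroundMean * (1 + textureCV * zs / sd(zs))
        bg[bg < 0] <- 0
    }

    minSep <- 4 * spotSigmaPx
    pts <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(pts) < nSpots) {
        if (tries > 2000L * max(nSpots, 1L))
            stop("cannot place ", nSpots,
                 " spots with separation >= 4*sigma in this field")
        cand <- c(runif(1, minSep, nr - minSep),
                  runif(1, minSep, nc - minSep))
        ok <- nrow(pts) == 0L ||
            all(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)
                >= minSep)
        if (ok) pts <- rbind(pts, cand)
        tries <- tries + 1L
    }

    lam <- bg
    if (nSpots > 0) {
        amp <- snr * sqrt(backgroundMean)
        rows <- matrix(seq_len(nr), nr, nc)
        cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
        for (i in seq_len(nSpots)) {
            d2 <- (rows - pts[i, 1])^2 + (cols - pts[i, 2])^2
            lam <- lam + amp * exp(-d2 / (2 * spotSigmaPx^2))
        }
    }
    arr <- array(rpois(nr * nc * nFrames, rep(lam, nFrames)),
                 dim = c(nr, nc, nFrames))
    spots <- data.frame(row = pts[, 1], col = pts[, 2])
    stack <- new("ConfocalStack",
        channels = list(A = arr),
        pixelSizeNm = 100, frameIntervalS = 1,
        metadata = list(groundTruth = list(
            spots = spots, spotSigmaPx = spotSigmaPx, snr = snr,
            backgroundMean = backgroundMean, seed = seed)))
    list(stack = stack, spots = spots)
}

#' Simulate a membrane-recruitment intensity trace
#'
#' Flat pre-stimulus baseline followed by a mono-exponential rise
#' `baseline + plateau (1 - exp(-k_on t'))`, where `t'` is the time since
#' stimulus (frame `stimulusFrame` is the last baseline frame). Defaults
#' mirror a TIRF acquisition of 400 frames at 4 s/frame with a 25-frame
#' baseline.
#'
#' @param kOnPerS kinetic on-rate (1/s, >= 0).
#' @param plateau,baseline amplitude and pre-stimulus level.
#' @param frameIntervalS seconds per frame.
#' @param nFrames total frames.
#' @param noiseSd additive Gaussian noise SD.
#' @param stimulusFrame index of the last pre-stimulus frame.
#' @param seed RNG seed or NULL.
#' @return data.frame(frame, time_s, intensity) with attribute
#'   `"groundTruth"`.
#' @examples
#' tr <- simulateRecruitmentTrace(0.01, plateau = 1, baseline = 1,
#'                                noiseSd = 0)
#' @export
simulateRecruitmentTrace <- function(kOnPerS, plateau, baseline,
                                     frameIntervalS = 4, nFrames = 400L,
                                     noiseSd = 0, stimulusFrame = 25L,
                                     seed = NULL) {
    .checkScalar(kOnPerS, "kOnPerS", strict = FALSE)
    .checkScalar(frameIntervalS, "frameIntervalS")
    if (!is.null(seed)) set.seed(seed)
    fr <- seq_len(nFrames)
    tPost <- pmax(0, (fr - stimulusFrame)) * frameIntervalS
    y <- baseline + plateau * (1 - exp(-kOnPerS * tPost)) *
        (fr > stimulusFrame)
    out <- data.frame(frame = fr, time_s = (fr - 1) * frameIntervalS,
                      intensity = y + rnorm(nFrames, 0, noiseSd))
    attr(out, "groundTruth") <- list(
        kOnPerS = kOnPerS, plateau = plateau, baseline = baseline,
        stimulusFrame = stimulusFrame, frameIntervalS = frameIntervalS,
        seed = seed)
    out
}

#' Configuration for saturation-binding simulations
#'
#' @param kdNM equilibrium dissociation constant (nM, > 0).
#' @param bmaxCounts maximal specific binding (counts, >= 0).
#' @param nsSlopeCountsPerNM nonspecific binding slope.
#' @param backgroundCounts shared background counts.
#' @param ligandConcNM free ligand concentrations (nM).
#' @param noiseCV multiplicative noise coefficient of variation.
#' @param nReplicates replicates per well type and concentration.
#' @param seed RNG seed or NULL.
#' @return a validated list of class `BindingSimConfig`.
#' @export
bindingSimConfig <- function(kdNM = 2, bmaxCounts = 1000,
                             nsSlopeCountsPerNM = 20, backgroundCounts = 50,
                             ligandConcNM = c(0.25, 0.5, 1, 2, 4, 8, 16, 32),
                             noiseCV = 0.05, nReplicates = 1L, seed = NULL) {
    .checkScalar(kdNM, "kdNM")
    .checkScalar(bmaxCounts, "bmaxCounts", strict = FALSE)
    .checkScalar(noiseCV, "noiseCV", strict = FALSE)
    if (length(ligandConcNM) < 1L || any(ligandConcNM <= 0))
        stop("ligandConcNM must be positive")
    structure(list(kdNM = kdNM, bmaxCounts = bmaxCounts,
                   nsSlopeCountsPerNM = nsSlopeCountsPerNM,
                   backgroundCounts = backgroundCounts,
                   ligandConcNM = ligandConcNM, noiseCV = noiseCV,
                   nReplicates = as.integer(nReplicates), seed = seed),
              class = "BindingSimConfig")
}

#' Simulate a saturation radioligand binding table
#'
#' Total wells follow `Bmax L/(Kd + L) + NS L + bg`, nonspecific wells
#' `NS L + bg` (nonspecific binding defined by excess unlabeled ligand),
#' with multiplicative Gaussian noise of the configured CV.
#'
#' @param cfg a [bindingSimConfig()].
#' @return data.frame(well_type, concentration_nM, replicate, counts) with
#'   attribute `"groundTruth"`.
#' @examples
#' tab <- simulateSaturationBinding(bindingSimConfig(noiseCV = 0))
#' @export
simulateSaturationBinding <- function(cfg) {
    stopifnot(inherits(cfg, "BindingSimConfig"))
    if (!is.null(cfg$seed)) set.seed(cfg$seed)
    L <- rep(cfg$ligandConcNM, each = cfg$nReplicates)
    ns <- cfg$nsSlopeCountsPerNM * L + cfg$backgroundCounts
    tot <- cfg$bmaxCounts * L / (cfg$kdNM + L) + ns
    rep_ <- rep(seq_len(cfg$nReplicates), times = length(cfg$ligandConcNM))
    out <- data.frame(
        well_type = rep(c("total", "nonspecific"), each = length(L)),
        concentration_nM = c(L, L),
        replicate = c(rep_, rep_),
        counts = c(tot, ns))
    if (cfg$noiseCV > 0)
        out$counts <- pmax(0, out$counts *
                               (1 + rnorm(nrow(out), 0, cfg$noiseCV)))
    attr(out, "groundTruth") <- cfg
    out
}
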