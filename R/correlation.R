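# Line-scan spatiotemporal image correlation spectroscopy: segment
# exclusion, detrending by count addition, the STICS function with
# logarithmic temporal binning, the diffusion fit, and the two-color
# cross-correlation co-diffusion metric.

#' Exclude kymograph segments
#'
#' Marks line ranges (temporal segments, e.g. photobleached tails) and pixel
#' ranges (spatial segments with abrupt intensity changes) as excluded. All
#' subsequent statistics ([detrendKymograph()], [computeStics()]) skip the
#' masked regions and process the retained contiguous blocks independently,
#' averaging the results.
#'
#' @param kymo a [Kymograph-class].
#' @param lineRanges list of integer pairs `c(from, to)` (1-based,
#'   inclusive) of lines to exclude, or NULL.
#' @param pixelRanges list of integer pairs of pixel columns to exclude, or
#'   NULL.
#' @return the kymograph with updated masks.
#' @examples
#' ky <- simulateKymograph(membraneSimConfig(
#'     nLines = 1000L, nPixels = 64L, seed = 1))
#' ky2 <- excludeSegments(ky, lineRanges = list(c(901, 1000)))
#' @export
excludeSegments <- function(kymo, lineRanges = NULL, pixelRanges = NULL) {
    stopifnot(is(kymo, "Kymograph"))
    d <- dim(counts(kymo))
    keepL <- kymo@keepLines
    keepP <- kymo@keepPixels
    for (r in lineRanges %||% list()) {
        if (r[1L] < 1L || r[2L] > d[1L] || r[1L] > r[2L])
            stop("line range out of bounds")
        keepL[r[1L]:r[2L]] <- FALSE
    }
    for (r in pixelRanges %||% list()) {
        if (r[1L] < 1L || r[2L] > d[2L] || r[1L] > r[2L])
            stop("pixel range out of bounds")
        keepP[r[1L]:r[2L]] <- FALSE
    }
    if (!any(keepL) || !any(keepP) ||
        mean(keepL) <= 0.5 || mean(keepP) <= 0.5)
        stop("exclusions would mask 50% or more of the kymograph")
    initialize(kymo, keepLines = keepL, keepPixels = keepP)
}

# contiguous TRUE runs as a list of index vectors
.runs <- function(keep) {
    r <- rle(keep)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    Map(seq, starts[r$values], ends[r$values])
}

#' Detrend a kymograph by random count addition
#'
#' Equalizes the mean along the time axis: lines are grouped into temporal
#' bins (typically 10,000 lines); for every bin below the maximum bin mean,
#' integer unit counts are added at uniformly random (line, pixel) locations
#' until the bin mean matches the maximum bin mean to within one count per
#' bin. Addition (never subtraction) preserves integer photon counts; the
#' added counts are white, so they contribute only a zero-lag term to the
#' correlation, which the fits exclude. Retained line blocks are detrended
#' independently; the target mean is the global maximum across blocks and
#' the last partial bin of a block is merged into its predecessor.
#'
#' @param kymo a [Kymograph-class].
#' @param binSizeLines lines per temporal bin.
#' @param seed RNG seed for the random locations, or NULL.
#' @return the detrended kymograph (masks preserved); per-channel added
#'   counts are recorded in `metadata$detrend`.
#' @export
detrendKymograph <- function(kymo, binSizeLines = 10000L, seed = NULL) {
    stopifnot(is(kymo, "Kymograph"))
    if (!is.null(seed)) set.seed(seed)
    keepP <- which(kymo@keepPixels)
    if (!length(keepP)) stop("no pixels retained")
    blocks <- .runs(kymo@keepLines)
    if (sum(lengths(blocks)) < 2L * binSizeLines)
        stop("retained lines must cover at least two detrend bins; ",
             "reduce binSizeLines or exclude less")
    channels <- kymo@channels
    added <- setNames(numeric(length(channels)), names(channels))

    for (ch in names(channels)) {
        m <- channels[[ch]]
        # bins: split each retained block into chunks of binSizeLines,
        # merging a trailing partial chunk into the previous one
        bins <- list()
        for (bl in blocks) {
            nb <- max(1L, length(bl) %/% binSizeLines)
            cut <- pmin(length(bl), seq_len(nb) * binSizeLines)
            cut[nb] <- length(bl)
            from <- c(1L, head(cut, -1L) + 1L)
            bins <- c(bins, Map(function(f, t) bl[f:t], from, cut))
        }
        binMeans <- vapply(bins, function(b)
            mean(m[b, keepP]), numeric(1))
        target <- max(binMeans)
        for (i in seq_along(bins)) {
            b <- bins[[i]]
            nCells <- length(b) * length(keepP)
            deficit <- round((target - binMeans[i]) * nCells)
            if (deficit <= 0) next
            rows <- sample(b, deficit, replace = TRUE)
            cols <- sample(keepP, deficit, replace = TRUE)
            # accumulate duplicates
            idx <- rows + (cols - 1L) * nrow(m)
            tb <- table(idx)
            m[as.integer(names(tb))] <- m[as.integer(names(tb))] +
                as.integer(tb)
            added[ch] <- added[ch] + deficit
        }
        channels[[ch]] <- m
    }
    md <- kymo@metadata
    md$detrend <- list(binSizeLines = binSizeLines, addedCounts = added,
                       seed = seed)
    initialize(kymo, channels = channels, metadata = md)
}

# circular 2D cross-correlation of mean-subtracted blocks, rows = temporal
# lag 0..maxLag, cols = spatial lag (fft-shifted)
.blockCorr <- function(a, b, maxLag) {
    ma <- mean(a); mb <- mean(b)
    if (ma <= 0 || mb <= 0) stop("zero mean intensity")
    da <- a - ma; db <- b - mb
    Fa <- fft(da); Fb <- fft(db)
    cc <- Re(fft(Conj(Fa) * Fb, inverse = TRUE)) / length(a)^2
    G <- cc / (ma * mb)
    G[seq_len(maxLag + 1L), , drop = FALSE]
}

#' Compute the STICS function of a kymograph
#'
#' The spatiotemporal correlation
#' `G(xi, tau) = <dI_a(x, t) dI_b(x + xi, t + tau)> / (<I_a> <I_b>)`
#' is computed by FFT over both axes for each retained line/pixel block,
#' blocks are averaged weighted by their line count, and the temporal axis
#' is then binned logarithmically (geometric bin edges, ~`binsPerDecade`
#' bins per decade, equal weight per integer lag within a bin; the first bin
#' is a single line period). The zero temporal lag — and with it the
#' shot-noise spike at `xi = tau = 0` — is excluded.
#'
#' @param kymo a (typically detrended) [Kymograph-class].
#' @param pair two-letter channel pair: "AA", "BB", "AB" or "BA".
#' @param maxLagLines largest temporal lag in lines (default: a quarter of
#'   the shortest retained block).
#' @param binsPerDecade logarithmic bins per decade of temporal lag.
#' @return a [CorrelationSurface-class].
#' @examples
#' ky <- simulateKymograph(membraneSimConfig(
#'     nLines = 4000L, nPixels = 64L, particleDensityUm2 = 20, seed = 1))
#' g <- computeStics(ky, "AA", maxLagLines = 500L)
#' @export
computeStics <- function(kymo, pair = "AA", maxLagLines = NULL,
                         binsPerDecade = 16L) {
    stopifnot(is(kymo, "Kymograph"))
    chs <- strsplit(pair, "")[[1L]]
    if (length(chs) != 2L || !all(chs %in% channelNames(kymo)))
        stop("pair must name two existing channels, e.g. 'AA' or 'AB'")
    lineBlocks <- .runs(kymo@keepLines)
    pixBlocks <- .runs(kymo@keepPixels)
    minLines <- min(lengths(lineBlocks))
    if (is.null(maxLagLines)) maxLagLines <- max(1L, minLines %/% 4L)
    maxLagLines <- min(maxLagLines, minLines - 1L)
    if (maxLagLines < 1L) stop("retained blocks too short for correlation")
    npx <- min(lengths(pixBlocks))

    acc <- NULL; wsum <- 0
    for (lb in lineBlocks) {
        for (pb in pixBlocks) {
            a <- kymo@channels[[chs[1L]]][lb, pb, drop = FALSE]
            b <- kymo@channels[[chs[2L]]][lb, pb, drop = FALSE]
            G <- .blockCorr(a, b, maxLagLines)
            # crop/shift spatial lags to the common symmetric window
            nshift <- ncol(G)
            xiAll <- 0:(nshift - 1L)
            xiAll[xiAll > nshift / 2] <- xiAll[xiAll > nshift / 2] - nshift
            half <- (npx - 1L) %/% 2L
            ord <- order(xiAll)
            sel <- ord[xiAll[ord] >= -half & xiAll[ord] <= half]
            G <- G[, sel, drop = FALSE]
            w <- length(lb)
            acc <- if (is.null(acc)) G * w else acc + G * w
            wsum <- wsum + w
        }
    }
    G <- acc / wsum
    half <- (npx - 1L) %/% 2L
    xi <- -half:half

    # logarithmic temporal binning over lags 1..maxLag (lag 0 excluded)
    lags <- seq_len(maxLagLines)
    edges <- unique(c(1, ceiling(10^(seq(0, log10(maxLagLines + 1),
                                         by = 1 / binsPerDecade)))))
    edges <- edges[edges <= maxLagLines + 1L]
    if (edges[length(edges)] <= maxLagLines)
        edges <- c(edges, maxLagLines + 1L)
    binOf <- findInterval(lags, edges, rightmost.closed = FALSE)
    nbin <- max(binOf)
    Gb <- matrix(0, nbin, length(xi))
    tauC <- numeric(nbin)
    for (k in seq_len(nbin)) {
        rows <- which(binOf == k) + 1L  # +1: row 1 of G is lag 0
        Gb[k, ] <- colMeans(G[rows, , drop = FALSE])
        tauC[k] <- .gmean(lags[binOf == k]) * kymo@linePeriodS
    }
    new("CorrelationSurface",
        G = Gb, xiPx = as.integer(xi), tauS = tauC,
        tauEdgesS = edges * kymo@linePeriodS,
        pair = pair, pixelSizeNm = kymo@pixelSizeNm,
        metadata = list(lagsPerBin = tabulate(binOf, nbin),
                        maxLagLines = maxLagLines,
                        source = kymo@metadata))
}

#' Fit the 2D-diffusion model to a STICS surface
#'
#' Fits `G(xi, tau) = G0 (1 + tau/tau_d)^-1 exp(-xi^2/(w0^2 + 4 D tau))`
#' with `tau_d = w0^2 / (4 D)` — free 2D diffusion through a Gaussian beam
#' of fixed 1/e^2 waist `w0` — by least squares over all spatial lags within
#' `maxXiPx` and all temporal bins. The waist is fixed at a calibrated value
#' by default; set `fitWaist = TRUE` to fit it.
#'
#' @param surface a [CorrelationSurface-class] with >= 6 temporal bins.
#' @param waistNm fixed 1/e^2 beam waist in nm.
#' @param maxXiPx spatial-lag window half-width in pixels (default: all).
#' @param fitWaist also fit the beam waist (off by default).
#' @return a [DiffusionFit-class].
#' @export
fitDiffusion <- function(surface, waistNm = 250, maxXiPx = NULL,
                         fitWaist = FALSE) {
    stopifnot(is(surface, "CorrelationSurface"))
    if (length(surface@tauS) < 6L)
        stop("at least 6 temporal bins are required")
    xiNm <- surface@xiPx * surface@pixelSizeNm
    keep <- if (is.null(maxXiPx)) rep(TRUE, length(surface@xiPx))
            else abs(surface@xiPx) <= maxXiPx
    df <- data.frame(
        g = as.vector(surface@G[, keep]),
        tau = rep(surface@tauS, times = sum(keep)),
        xi = rep(xiNm[keep], each = length(surface@tauS)))

    g00 <- max(surface@G[1L, ], 0)
    # initial tau_d: first bin where the xi=0 profile halves
    prof <- surface@G[, surface@xiPx == 0L]
    iHalf <- which(prof <= g00 / 2)[1L]
    tauD0 <- if (is.na(iHalf)) max(surface@tauS) else surface@tauS[iHalf]
    D0 <- max(waistNm^2 / (4 * tauD0) * 1e-6, 1e-4)  # nm^2/s -> um^2/s

    model <- function(G0, D, w0, tau, xi)
        G0 / (1 + tau / (w0^2 / (4 * D * 1e6))) *
            exp(-xi^2 / (w0^2 + 4 * D * 1e6 * tau))
    fit <- tryCatch({
        if (fitWaist)
            minpack.lm::nlsLM(
                g ~ model(G0, D, w0, tau, xi), data = df,
                start = list(G0 = max(g00, 1e-6), D = D0, w0 = waistNm),
                lower = c(0, 1e-6, 50),
                control = minpack.lm::nls.lm.control(maxiter = 500))
        else
            minpack.lm::nlsLM(
                g ~ model(G0, D, waistNm, tau, xi), data = df,
                start = list(G0 = max(g00, 1e-6), D = D0),
                lower = c(0, 1e-6),
                control = minpack.lm::nls.lm.control(maxiter = 500))
    }, error = function(e) e)
    if (inherits(fit, "error"))
        return(new("DiffusionFit", D = NA_real_, G0 = NA_real_,
                   waistNm = waistNm,
                   se = c(G0 = NA_real_, D = NA_real_),
                   converged = FALSE,
                   flags = c("non_convergence", conditionMessage(fit))))
    cf <- coef(fit)
    new("DiffusionFit",
        D = unname(cf[["D"]]), G0 = unname(cf[["G0"]]),
        waistNm = if (fitWaist) unname(cf[["w0"]]) else waistNm,
        se = .nlsSE(fit), converged = fit$convInfo$isConv %||% TRUE,
        flags = character(0))
}

#' Cross-correlation (co-diffusion) fraction
#'
#' Amplitude-ratio co-diffusion metric: the cross-correlation amplitude at
#' zero spatial lag and the first temporal bin divided by the smaller of
#' the two autocorrelation amplitudes there,
#' `q = G_AB(0, tau1) / min(G_AA(0, tau1), G_BB(0, tau1))`. Independent
#' channels give q near 0; a fully co-labeled population gives q near 1.
#'
#' @param gAA,gBB autocorrelation [CorrelationSurface-class] objects.
#' @param gAB the cross-correlation surface.
#' @return unitless fraction (approximately within [0, 1]).
#' @export
crossCorrelationFraction <- function(gAA, gBB, gAB) {
    stopifnot(is(gAA, "CorrelationSurface"), is(gBB, "CorrelationSurface"),
              is(gAB, "CorrelationSurface"))
    amp <- function(s) s@G[1L, s@xiPx == 0L]
    aa <- amp(gAA); bb <- amp(gBB)
    if (aa <= 0 || bb <= 0)
        stop("non-positive autocorrelation amplitude")
    amp(gAB) / min(aa, bb)
}
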