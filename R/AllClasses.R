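#' @import methods
NULL

#' Photon-counting confocal image stack
#'
#' Container for a (possibly multi-channel) photon-counting confocal image
#' time series. Each channel is an integer array of dimension
#' `rows x cols x frames`. Pixel values are detected photon counts per pixel
#' dwell. When produced by [simulateConfocalStack()] or
#' [simulateEndosomeFrames()], the `metadata` list carries the generator
#' ground truth (species table, densities, per-protomer brightness, seed, or
#' true spot coordinates) so recovery can be checked.
#'
#' @slot channels named list of integer arrays, one per channel, identical
#'   dimensions `rows x cols x frames`.
#' @slot pixelSizeNm pixel size in nanometres.
#' @slot frameIntervalS time between frames in seconds.
#' @slot metadata list of free-form metadata; simulated data embed ground
#'   truth and the seed here.
#'
#' @seealso [Kymograph-class] for line-scan data.
#' @exportClass ConfocalStack
setClass("ConfocalStack",
    slots = c(
        channels = "list",
        pixelSizeNm = "numeric",
        frameIntervalS = "numeric",
        metadata = "list"
    )
)

setValidity("ConfocalStack", function(object) {
    ch <- object@channels
    if (length(ch) < 1L) return("at least one channel required")
    if (is.null(names(ch)) || any(!nzchar(names(ch))))
        return("channels must be named")
    dims <- lapply(ch, dim)
    if (any(vapply(dims, length, 1L) != 3L))
        return("each channel must be a rows x cols x frames array")
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
        return("all channels must share dimensions")
    for (a in ch) {
        if (anyNA(a) || any(a < 0))
            return("photon counts must be non-negative and non-missing")
        if (any(a != round(a)))
            return("photon counts must be integers")
    }
    if (length(object@pixelSizeNm) != 1L || object@pixelSizeNm <= 0)
        return("pixelSizeNm must be a single positive number")
    if (length(object@frameIntervalS) != 1L || object@frameIntervalS <= 0)
        return("frameIntervalS must be a single positive number")
    TRUE
})

#' Line-scan kymograph
#'
#' A repeatedly scanned confocal line: rows are scan lines (time), columns
#' are pixels along the line (space). One matrix per detection channel.
#' Exclusion masks (set by [excludeSegments()]) mark lines/pixels removed
#' from all downstream statistics; retained contiguous blocks are processed
#' independently and averaged.
#'
#' @slot channels named list of numeric count matrices `lines x pixels`.
#' @slot linePeriodS time per scanned line in seconds (1/1800 s for an
#'   1800 Hz acquisition).
#' @slot pixelSizeNm pixel size along the line in nanometres.
#' @slot keepLines logical vector, one per line; `FALSE` = excluded.
#' @slot keepPixels logical vector, one per pixel; `FALSE` = excluded.
#' @slot metadata list; simulated kymographs embed ground truth (diffusion
#'   coefficient, co-labeled fraction, density, seed).
#'
#' @exportClass Kymograph
setClass("Kymograph",
    slots = c(
        channels = "list",
        linePeriodS = "numeric",
        pixelSizeNm = "numeric",
        keepLines = "logical",
        keepPixels = "logical",
        metadata = "list"
    )
)

setValidity("Kymograph", function(object) {
    ch <- object@channels
    if (length(ch) < 1L) return("at least one channel required")
    if (is.null(names(ch)) || any(!nzchar(names(ch))))
        return("channels must be named")
    dims <- lapply(ch, dim)
    if (any(vapply(dims, length, 1L) != 2L))
        return("each channel must be a lines x pixels matrix")
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
        return("all channels must share dimensions")
    d <- dims[[1L]]
    if (d[1L] < 2L) return("a kymograph needs at least 2 lines")
    if (length(object@keepLines) != d[1L])
        return("keepLines length must equal the number of lines")
    if (length(object@keepPixels) != d[2L])
        return("keepPixels length must equal the number of pixels")
    if (mean(object@keepLines) <= 0.5 || mean(object@keepPixels) <= 0.5)
        return("masked fraction must stay below 50%")
    if (length(object@linePeriodS) != 1L || object@linePeriodS <= 0)
        return("linePeriodS must be a single positive number")
    if (length(object@pixelSizeNm) != 1L || object@pixelSizeNm <= 0)
        return("pixelSizeNm must be a single positive number")
    TRUE
})

#' Spatiotemporal correlation surface
#'
#' STICS correlation function G(xi, tau) over spatial lag xi (pixels along
#' the scanned line) and logarithmically binned temporal lag tau (seconds).
#' Rows are temporal bins, columns spatial lags.
#'
#' @slot G numeric matrix `length(tauS) x length(xiPx)`.
#' @slot xiPx integer spatial lags in pixels (0-centred).
#' @slot tauS temporal bin centres in seconds (geometric bin means).
#' @slot tauEdgesS temporal bin edges in seconds, strictly increasing,
#'   length `length(tauS) + 1`.
#' @slot pair channel pair id, e.g. "AA", "BB" or "AB".
#' @slot pixelSizeNm pixel size of the source kymograph.
#' @slot metadata list (lags per bin, source metadata).
#'
#' @exportClass CorrelationSurface
setClass("CorrelationSurface",
    slots = c(
        G = "matrix",
        xiPx = "integer",
        tauS = "numeric",
        tauEdgesS = "numeric",
        pair = "character",
        pixelSizeNm = "numeric",
        metadata = "list"
    )
)

setValidity("CorrelationSurface", function(object) {
    if (nrow(object@G) != length(object@tauS))
        return("nrow(G) must equal length(tauS)")
    if (ncol(object@G) != length(object@xiPx))
        return("ncol(G) must equal length(xiPx)")
    if (length(object@tauEdgesS) != length(object@tauS) + 1L)
        return("tauEdgesS must have length(tauS) + 1 entries")
    if (any(diff(object@tauEdgesS) <= 0))
        return("temporal bin edges must be strictly increasing")
    TRUE
})

#' Three-parameter Hill concentration-response fit
#'
#' Result of [fitHill3()]: `y = bottom + span / (1 + 10^(log10EC50 -
#' log10 [L]))` with the Hill slope fixed at 1. `bottom` is the zero-dose
#' asymptote in assay units; `span` is signed (negative for decreasing
#' responses, flagged `"decreasing"`); `log10EC50` is in log10 molar.
#'
#' @slot bottom,span,log10EC50 fitted parameters.
#' @slot hillSlope Hill slope used (fixed, 1 for the default model).
#' @slot se named numeric standard errors (from the Jacobian).
#' @slot converged logical convergence flag.
#' @slot flags character vector of quality flags ("no_plateau",
#'   "ec50_indeterminate", "extrapolated", "decreasing", ...).
#' @slot data the fitted records (condition, concentration_M, replicate,
#'   response).
#' @slot fit the underlying `nls` object (or NULL when degenerate).
#'
#' @exportClass HillFit
setClass("HillFit",
    slots = c(
        bottom = "numeric", span = "numeric", log10EC50 = "numeric",
        hillSlope = "numeric", se = "numeric", converged = "logical",
        flags = "character", data = "data.frame", fit = "ANY"
    )
)

#' Molecular brightness estimate
#'
#' Result of [momentBrightness()] or [histogramBrightness()]. `epsilon` is
#' the molecular brightness in detected counts per entity per pixel dwell
#' above shot noise; `numberDensity` is particles per beam area
#' (mean/epsilon). A negative epsilon is only reported together with the
#' `"below_shot_noise"` flag.
#'
#' @slot epsilon molecular brightness (counts/entity/dwell).
#' @slot numberDensity particles per beam area (NA when epsilon <= 0).
#' @slot nPixels number of ROI pixel samples used.
#' @slot method "moment" or "histogram".
#' @slot se standard error of epsilon where available (NA otherwise).
#' @slot gof goodness of fit (histogram method; NA for moment).
#' @slot flags character vector of quality flags.
#'
#' @exportClass BrightnessEstimate
setClass("BrightnessEstimate",
    slots = c(
        epsilon = "numeric", numberDensity = "numeric", nPixels = "integer",
        method = "character", se = "numeric", gof = "numeric",
        flags = "character"
    )
)

setValidity("BrightnessEstimate", function(object) {
    if (object@nPixels < 50L)
        return("a brightness estimate needs at least 50 pixels")
    if (!object@method %in% c("moment", "histogram"))
        return("method must be 'moment' or 'histogram'")
    if (object@epsilon <= 0 && !"below_shot_noise" %in% object@flags)
        return("non-positive epsilon must carry the below_shot_noise flag")
    TRUE
})

#' Diffusion fit of a STICS surface
#'
#' Result of [fitDiffusion()]: parameters of
#' `G(xi, tau) = G0 (1 + tau/tau_d)^-1 exp(-xi^2/(w0^2 + 4 D tau))`
#' with `tau_d = w0^2/(4 D)`.
#'
#' @slot D diffusion coefficient in um^2/s.
#' @slot G0 zero-lag amplitude (unitless).
#' @slot waistNm 1/e^2 beam waist used (fixed unless fitted).
#' @slot se named standard errors.
#' @slot converged logical.
#' @slot flags character quality flags.
#'
#' @exportClass DiffusionFit
setClass("DiffusionFit",
    slots = c(
        D = "numeric", G0 = "numeric", waistNm = "numeric",
        se = "numeric", converged = "logical", flags = "character"
    )
)

setValidity("DiffusionFit", function(object) {
    if (is.finite(object@D) && object@D < 0) return("D must be >= 0")
    if (is.finite(object@G0) && object@G0 < 0) return("G0 must be >= 0")
    TRUE
})

#' Recruitment kinetics fit
#'
#' Result of [fitRecruitment()]: mono-exponential approach to plateau,
#' `y(t) = baseline + A (1 - exp(-k_on (t - t_stim)))` for `t >= t_stim`.
#'
#' @slot kOn on-rate in 1/s.
#' @slot plateau amplitude A (response units).
#' @slot baseline pre-stimulus level.
#' @slot se named standard errors.
#' @slot converged logical.
#' @slot flags character quality flags ("negative_amplitude",
#'   "rate_indeterminate", ...).
#'
#' @exportClass KineticFit
setClass("KineticFit",
    slots = c(
        kOn = "numeric", plateau = "numeric", baseline = "numeric",
        se = "numeric", converged = "logical", flags = "character"
    )
)

#' One-site saturation binding fit
#'
#' Result of [fitOneSite()]: global fit of total and nonspecific wells,
#' `total(L) = Bmax L/(Kd + L) + NS L + bg`, `nonspecific(L) = NS L + bg`,
#' with NS and bg shared across well types.
#'
#' @slot kdNM equilibrium dissociation constant in nM.
#' @slot bmax maximal specific binding (counts).
#' @slot nsSlope nonspecific slope (counts per nM).
#' @slot background shared background counts.
#' @slot se named standard errors.
#' @slot converged logical.
#' @slot flags character quality flags ("extrapolated", ...).
#'
#' @exportClass BindingFit
setClass("BindingFit",
    slots = c(
        kdNM = "numeric", bmax = "numeric", nsSlope = "numeric",
        background = "numeric", se = "numeric", converged = "logical",
        flags = "character"
    )
)

setValidity("BindingFit", function(object) {
    if (is.finite(object@kdNM) && object@kdNM <= 0)
        return("Kd must be positive")
    if (is.finite(object@bmax) && object@bmax < 0)
        return("Bmax must be >= 0")
    TRUE
})
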