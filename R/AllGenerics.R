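#' Accessors for image containers and fit objects
#'
#' `counts()` returns the photon-count array/matrix of one channel;
#' `channelNames()` the channel names; `pixelSizeNm()`, `linePeriodS()` and
#' `frameIntervalS()` the acquisition metadata; `groundTruth()` the
#' generator-embedded truth (empty list for real data); `epsilon()` and
#' `numberDensity()` the brightness results; `isConverged()` and
#' `fitFlags()` the fit diagnostics.
#'
#' @param object a package object.
#' @param channel channel name or index (default: first channel).
#' @param ... unused.
#' @return the slot value documented above.
#' @name accessors
#' @examples
#' cfg <- membraneSimConfig(fieldSizePx = c(32, 32), nFrames = 2, seed = 1)
#' st <- simulateConfocalStack(cfg)
#' dim(counts(st))
#' pixelSizeNm(st)
NULL

#' @rdname accessors
#' @export
setGeneric("counts", function(object, ...) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("pixelSizeNm", function(object) standardGeneric("pixelSizeNm"))

#' @rdname accessors
#' @export
setGeneric("linePeriodS", function(object) standardGeneric("linePeriodS"))

#' @rdname accessors
#' @export
setGeneric("frameIntervalS", function(object) standardGeneric("frameIntervalS"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("epsilon", function(object) standardGeneric("epsilon"))

#' @rdname accessors
#' @export
setGeneric("numberDensity", function(object) standardGeneric("numberDensity"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setGeneric("fitFlags", function(object) standardGeneric("fitFlags"))

.getChannel <- function(channels, channel) {
    if (is.numeric(channel)) {
        stopifnot(channel >= 1, channel <= length(channels))
        channels[[channel]]
    } else {
        if (!channel %in% names(channels))
            stop("no channel '", channel, "'", call. = FALSE)
        channels[[channel]]
    }
}

#' @rdname accessors
#' @export
setMethod("counts", "ConfocalStack", function(object, channel = 1L, ...)
    .getChannel(object@channels, channel))

#' @rdname accessors
#' @export
setMethod("counts", "Kymograph", function(object, channel = 1L, ...)
    .getChannel(object@channels, channel))

#' @rdname accessors
#' @export
setMethod("channelNames", "ConfocalStack", function(object)
    names(object@channels))

#' @rdname accessors
#' @export
setMethod("channelNames", "Kymograph", function(object)
    names(object@channels))

#' @rdname accessors
#' @export
setMethod("pixelSizeNm", "ConfocalStack", function(object) object@pixelSizeNm)

#' @rdname accessors
#' @export
setMethod("pixelSizeNm", "Kymograph", function(object) object@pixelSizeNm)

#' @rdname accessors
#' @export
setMethod("linePeriodS", "Kymograph", function(object) object@linePeriodS)

#' @rdname accessors
#' @export
setMethod("frameIntervalS", "ConfocalStack", function(object)
    object@frameIntervalS)

#' @rdname accessors
#' @export
setMethod("groundTruth", "ConfocalStack", function(object)
    object@metadata$groundTruth %||% list())

#' @rdname accessors
#' @export
setMethod("groundTruth", "Kymograph", function(object)
    object@metadata$groundTruth %||% list())

#' @rdname accessors
#' @export
setMethod("epsilon", "BrightnessEstimate", function(object) object@epsilon)

#' @rdname accessors
#' @export
setMethod("numberDensity", "BrightnessEstimate", function(object)
    object@numberDensity)

#' @rdname accessors
#' @export
setMethod("isConverged", "HillFit", function(object) object@converged)

#' @rdname accessors
#' @export
setMethod("isConverged", "DiffusionFit", function(object) object@converged)

#' @rdname accessors
#' @export
setMethod("isConverged", "KineticFit", function(object) object@converged)

#' @rdname accessors
#' @export
setMethod("isConverged", "BindingFit", function(object) object@converged)

#' @rdname accessors
#' @export
setMethod("fitFlags", "HillFit", function(object) object@flags)

#' @rdname accessors
#' @export
setMethod("fitFlags", "DiffusionFit", function(object) object@flags)

#' @rdname accessors
#' @export
setMethod("fitFlags", "KineticFit", function(object) object@flags)

#' @rdname accessors
#' @export
setMethod("fitFlags", "BindingFit", function(object) object@flags)

#' @rdname accessors
#' @export
setMethod("fitFlags", "BrightnessEstimate", function(object) object@flags)

setMethod("show", "ConfocalStack", function(object) {
    d <- dim(object@channels[[1L]])
    cat("ConfocalStack:", d[1L], "x", d[2L], "px,", d[3L], "frame(s),",
        length(object@channels), "channel(s) [",
        paste(names(object@channels), collapse = ", "), "]\n")
    cat("  pixel", object@pixelSizeNm, "nm; frame interval",
        object@frameIntervalS, "s\n")
    if (!is.null(object@metadata$groundTruth))
        cat("  ground truth embedded (simulated data)\n")
})

setMethod("show", "Kymograph", function(object) {
    d <- dim(object@channels[[1L]])
    cat("Kymograph:", d[1L], "lines x", d[2L], "px,",
        length(object@channels), "channel(s) [",
        paste(names(object@channels), collapse = ", "), "]\n")
    cat("  line period", signif(object@linePeriodS, 4), "s; pixel",
        object@pixelSizeNm, "nm\n")
    nL <- sum(!object@keepLines); nP <- sum(!object@keepPixels)
    if (nL + nP > 0)
        cat("  excluded:", nL, "line(s),", nP, "pixel column(s)\n")
})

setMethod("show", "CorrelationSurface", function(object) {
    cat("CorrelationSurface (", object@pair, "): ",
        length(object@tauS), " temporal bins x ",
        length(object@xiPx), " spatial lags\n", sep = "")
    cat("  tau ", signif(min(object@tauS), 3), " - ",
        signif(max(object@tauS), 3), " s; G(0, tau1) = ",
        signif(object@G[1L, object@xiPx == 0L], 4), "\n", sep = "")
})

setMethod("show", "HillFit", function(object) {
    cat("HillFit (3-parameter):",
        if (object@converged) "converged" else "NOT converged", "\n")
    cat(sprintf("  bottom %.4g  span %.4g  log10EC50 %.4g (EC50 %.3g nM)\n",
        object@bottom, object@span, object@log10EC50,
        10^object@log10EC50 * 1e9))
    if (length(object@flags))
        cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "BrightnessEstimate", function(object) {
    cat("BrightnessEstimate (", object@method, "): epsilon = ",
        signif(object@epsilon, 4), " counts/entity/dwell over ",
        object@nPixels, " pixels\n", sep = "")
    if (is.finite(object@numberDensity))
        cat("  number density", signif(object@numberDensity, 4),
            "per beam area\n")
    if (length(object@flags))
        cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "DiffusionFit", function(object) {
    cat("DiffusionFit: D =", signif(object@D, 4), "um^2/s, G0 =",
        signif(object@G0, 4), "(waist", object@waistNm, "nm)",
        if (object@converged) "" else "[NOT converged]", "\n")
})

setMethod("show", "KineticFit", function(object) {
    cat("KineticFit: k_on =", signif(object@kOn, 4), "1/s, plateau =",
        signif(object@plateau, 4), ", baseline =",
        signif(object@baseline, 4),
        if (object@converged) "" else "[NOT converged]", "\n")
    if (length(object@flags))
        cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "BindingFit", function(object) {
    cat(sprintf(
        "BindingFit: Kd %.4g nM (pKd %.3f), Bmax %.4g, NS %.4g/nM, bg %.4g\n",
        object@kdNM, -log10(object@kdNM * 1e-9), object@bmax,
        object@nsSlope, object@background))
    if (length(object@flags))
        cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})
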