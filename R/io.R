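# File I/O: multi-page TIFF images with a structured-text (YAML) sidecar
# carrying acquisition metadata and ground truth, and schema-validated CSV
# tables. Counts are stored as 16-bit TIFF samples, so round trips are
# bit-exact for values up to 65535.

.sidecarPath <- function(path) paste0(path, ".yaml")

#' Write an image container to TIFF with a metadata sidecar
#'
#' Stacks are written one page per frame, channels concatenated in order;
#' kymographs one page per channel. A YAML sidecar (`<path>.yaml`) records
#' the kind, channel names, dimensions, pixel size, timing, seed and any
#' embedded ground truth, so [readImageStack()] can restore the typed
#' object.
#'
#' @param x a [ConfocalStack-class] or [Kymograph-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeImageStack <- function(x, path) {
    maxCount <- max(vapply(x@channels, max, numeric(1)))
    if (maxCount > 65535)
        stop("counts exceed the 16-bit TIFF range")
    if (is(x, "ConfocalStack")) {
        pages <- unlist(lapply(x@channels, function(a)
            lapply(seq_len(dim(a)[3L]), function(f) a[, , f] / 65535)),
            recursive = FALSE)
        meta <- list(kind = "ConfocalStack",
                     channels = names(x@channels),
                     dim = dim(x@channels[[1L]]),
                     pixel_size_nm = x@pixelSizeNm,
                     frame_interval_s = x@frameIntervalS)
    } else if (is(x, "Kymograph")) {
        pages <- lapply(x@channels, function(m) m / 65535)
        meta <- list(kind = "Kymograph",
                     channels = names(x@channels),
                     dim = dim(x@channels[[1L]]),
                     pixel_size_nm = x@pixelSizeNm,
                     line_period_s = x@linePeriodS,
                     keep_lines_excluded = which(!x@keepLines),
                     keep_pixels_excluded = which(!x@keepPixels))
    } else stop("x must be a ConfocalStack or Kymograph")
    meta$metadata <- rapply(x@metadata, unclass, how = "replace")
    tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                    compression = "none")
    yaml::write_yaml(meta, .sidecarPath(path), precision = 15L)
    invisible(path)
}

#' Read a TIFF image with its metadata sidecar
#'
#' Restores the typed container written by [writeImageStack()]. When the
#' sidecar is missing, the pages are interpreted per `defaultKind` with
#' default acquisition metadata and a warning.
#'
#' @param path TIFF path.
#' @param defaultKind "ConfocalStack" or "Kymograph", used only without a
#'   sidecar.
#' @return a [ConfocalStack-class] or [Kymograph-class].
#' @export
readImageStack <- function(path, defaultKind = c("ConfocalStack",
                                                 "Kymograph")) {
    defaultKind <- match.arg(defaultKind)
    pages <- tiff::readTIFF(path, all = TRUE)
    toCounts <- function(m) {
        v <- round(m * 65535)
        storage.mode(v) <- "integer"
        v
    }
    sc <- .sidecarPath(path)
    if (!file.exists(sc)) {
        warning("no metadata sidecar found for ", path,
                "; using defaults (50 nm pixels, single channel)")
        if (defaultKind == "Kymograph") {
            if (length(pages) != 1L)
                stop("cannot infer channels of a multi-page kymograph ",
                     "without a sidecar")
            m <- toCounts(pages[[1L]])
            return(new("Kymograph", channels = list(A = m),
                       linePeriodS = 1 / 1800, pixelSizeNm = 50,
                       keepLines = rep(TRUE, nrow(m)),
                       keepPixels = rep(TRUE, ncol(m)),
                       metadata = list()))
        }
        arr <- array(unlist(lapply(pages, toCounts)),
                     dim = c(dim(pages[[1L]]), length(pages)))
        return(new("ConfocalStack", channels = list(A = arr),
                   pixelSizeNm = 50, frameIntervalS = 1,
                   metadata = list()))
    }
    meta <- yaml::read_yaml(sc)
    if (identical(meta$kind, "Kymograph")) {
        if (length(pages) != length(meta$channels))
            stop("channel count mismatch between TIFF and sidecar")
        chans <- lapply(pages, toCounts)
        names(chans) <- meta$channels
        d <- dim(chans[[1L]])
        if (!identical(d, as.integer(meta$dim[1:2])))
            stop("dimension mismatch between TIFF and sidecar")
        keepL <- rep(TRUE, d[1L]); keepP <- rep(TRUE, d[2L])
        keepL[unlist(meta$keep_lines_excluded)] <- FALSE
        keepP[unlist(meta$keep_pixels_excluded)] <- FALSE
        new("Kymograph", channels = chans,
            linePeriodS = meta$line_period_s %||% (1 / 1800),
            pixelSizeNm = meta$pixel_size_nm %||% 50,
            keepLines = keepL, keepPixels = keepP,
            metadata = meta$metadata %||% list())
    } else if (identical(meta$kind, "ConfocalStack")) {
        d <- as.integer(unlist(meta$dim))
        nch <- length(meta$channels)
        if (length(pages) != nch * d[3L])
            stop("channel/frame count mismatch between TIFF and sidecar")
        chans <- lapply(seq_len(nch), function(ci) {
            arr <- array(0L, dim = d)
            for (f in seq_len(d[3L]))
                arr[, , f] <- toCounts(pages[[(ci - 1L) * d[3L] + f]])
            arr
        })
        names(chans) <- meta$channels
        new("ConfocalStack", channels = chans,
            pixelSizeNm = meta$pixel_size_nm %||% 50,
            frameIntervalS = meta$frame_interval_s %||% 1,
            metadata = meta$metadata %||% list())
    } else stop("unknown image kind in sidecar: ", meta$kind)
}

.schemas <- list(
    dose_response = c("condition", "concentration_M", "replicate",
                      "response"),
    binding = c("well_type", "concentration_nM", "counts"),
    timeseries = c("well", "time_s", "counts"),
    trace = c("frame", "time_s", "intensity")
)

#' Read a schema-validated assay table
#'
#' CSV readers for the long-format tables the analyses consume. Required
#' columns per schema: `dose_response` (condition, concentration_M,
#' replicate, response), `binding` (well_type, concentration_nM, counts),
#' `timeseries` (well, time_s, counts), `trace` (frame, time_s, intensity).
#' A `concentration_nM` column in a dose-response table is converted to
#' molar on read.
#'
#' @param path CSV path.
#' @param schema one of the schema ids above.
#' @return validated data.frame.
#' @export
readAssayTable <- function(path, schema = names(.schemas)) {
    schema <- match.arg(schema)
    tab <- read.csv(path, stringsAsFactors = FALSE)
    if (nrow(tab) == 0L) stop("empty table: ", path)
    need <- .schemas[[schema]]
    if (schema == "dose_response" && "concentration_nM" %in% names(tab) &&
        !"concentration_M" %in% names(tab)) {
        tab$concentration_M <- tab$concentration_nM * 1e-9
        tab$concentration_nM <- NULL
    }
    missing <- setdiff(need, names(tab))
    if (length(missing))
        stop("missing required column(s): ", paste(missing, collapse = ", "))
    num <- setdiff(need, c("condition", "well_type", "well"))
    for (col in num) {
        if (!is.numeric(tab[[col]]))
            stop("non-numeric values in column ", col)
    }
    tab
}

#' @rdname readAssayTable
#' @param tab data.frame to write.
#' @export
writeAssayTable <- function(tab, path) {
    write.csv(tab, path, row.names = FALSE)
    invisible(path)
}
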