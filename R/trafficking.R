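# Receptor trafficking readouts: endosome counting by blob detection,
# membrane-intensity time courses, and recruitment kinetics fits.

#' Detect endosome-like spots by Laplacian-of-Gaussian filtering
#'
#' The frame is filtered with a negative Laplacian-of-Gaussian kernel at
#' scale `sigmaPx` (matched to the expected spot size); candidate pixels are
#' kept when the filter response exceeds `median + thresholdMads * MAD` of
#' the response image (a gain-invariant, robust threshold), then reduced by
#' greedy non-maximum suppression at a minimum separation of `2 * sigmaPx`.
#'
#' @param frame 2D numeric matrix (single channel), or a
#'   [ConfocalStack-class] whose requested frame is used.
#' @param sigmaPx blob scale in pixels.
#' @param thresholdMads detection threshold in MAD units above the median
#'   response.
#' @param cellMask optional logical matrix restricting detection to a cell.
#' @param frameIndex frame to analyze when `frame` is a stack.
#' @return data.frame (class `SpotSet`) with columns row, col, radius_px,
#'   peak (filter response) and the detection parameters as attributes.
#' @examples
#' sim <- simulateEndosomeFrames(10, seed = 1)
#' nrow(detectEndosomes(sim$stack))
#' @export
detectEndosomes <- function(frame, sigmaPx = 2, thresholdMads = 4.5,
                            cellMask = NULL, frameIndex = 1L) {
    if (is(frame, "ConfocalStack")) frame <- counts(frame)[, , frameIndex]
    stopifnot(is.matrix(frame))
    .checkScalar(sigmaPx, "sigmaPx")
    empty <- data.frame(row = numeric(0), col = numeric(0),
                        radius_px = numeric(0), peak = numeric(0))
    attr(empty, "params") <- list(sigmaPx = sigmaPx,
                                  thresholdMads = thresholdMads)
    class(empty) <- c("SpotSet", "data.frame")
    if (length(frame) == 0L || all(frame == 0)) return(empty)

    # negative LoG kernel (bright blobs -> positive response)
    half <- ceiling(4 * sigmaPx)
    xs <- -half:half
    g <- exp(-outer(xs^2, xs^2, "+") / (2 * sigmaPx^2))
    r2 <- outer(xs^2, xs^2, "+")
    log_ <- (r2 / sigmaPx^2 - 2) * g
    log_ <- log_ - mean(log_)  # zero-sum: insensitive to constant offsets
    resp <- EBImage::filter2(frame, -log_, boundary = "replicate")

    sel <- if (is.null(cellMask)) rep(TRUE, length(resp)) else cellMask
    thr <- median(resp[sel]) + thresholdMads * mad(resp[sel])
    cand <- which(resp > thr & sel, arr.ind = TRUE)
    if (nrow(cand) == 0L) return(empty)
    peaks <- resp[cand]
    ord <- order(peaks, decreasing = TRUE)
    cand <- cand[ord, , drop = FALSE]
    peaks <- peaks[ord]

    minSep <- 2 * sigmaPx
    kept <- matrix(numeric(0), 0, 2)
    keptPk <- numeric(0)
    for (i in seq_len(nrow(cand))) {
        p <- cand[i, ]
        if (nrow(kept) == 0L ||
            all((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2 >= minSep^2)) {
            kept <- rbind(kept, p)
            keptPk <- c(keptPk, peaks[i])
        }
    }
    out <- data.frame(row = kept[, 1], col = kept[, 2],
                      radius_px = sqrt(2) * sigmaPx, peak = keptPk)
    attr(out, "params") <- list(sigmaPx = sigmaPx,
                                thresholdMads = thresholdMads)
    class(out) <- c("SpotSet", "data.frame")
    out
}

#' Paired pre/post endosome counts
#'
#' Convenience wrapper for the per-cell paired comparison: counts spots in a
#' pre-stimulation and a post-stimulation frame with identical detection
#' settings.
#'
#' @param stackPre,stackPost single frames or [ConfocalStack-class] objects.
#' @param ... passed to [detectEndosomes()].
#' @return data.frame with columns `pre` and `post`.
#' @export
countEndosomesPaired <- function(stackPre, stackPost, ...) {
    data.frame(pre = nrow(detectEndosomes(stackPre, ...)),
               post = nrow(detectEndosomes(stackPost, ...)))
}

#' Membrane-intensity time course
#'
#' Mean intensity of a membrane ROI per frame, normalized to the mean of the
#' pre-stimulus baseline window (1 at baseline).
#'
#' @param stack a [ConfocalStack-class].
#' @param roi a [roiPolygon()]/[roiRectangle()] selection of the membrane
#'   region.
#' @param baselineWindow integer frame indices of the pre-stimulus baseline.
#' @return data.frame(frame, time_s, intensity).
#' @export
membraneTimecourse <- function(stack, roi, baselineWindow) {
    stopifnot(is(stack, "ConfocalStack"))
    a <- counts(stack)
    mask <- .roiMask(roi, dim(a)[1:2])
    if (!any(mask)) stop("empty ROI")
    nF <- dim(a)[3L]
    if (max(baselineWindow) > nF) stop("baseline window beyond stack")
    series <- vapply(seq_len(nF), function(f) mean(a[, , f][mask]),
                     numeric(1))
    base <- mean(series[baselineWindow])
    if (!is.finite(base) || base <= 0) stop("zero baseline mean")
    data.frame(frame = seq_len(nF),
               time_s = (seq_len(nF) - 1) * frameIntervalS(stack),
               intensity = series / base)
}

#' Fit recruitment kinetics
#'
#' Least-squares fit of the mono-exponential recruitment model
#' `y(t) = baseline + A (1 - exp(-k_on (t - t_stim)))` for `t >= t_stim`,
#' with the baseline estimated jointly from the pre-stimulus frames.
#'
#' @param trace data.frame with columns `frame` (or `time_s`) and
#'   `intensity`, e.g. from [simulateRecruitmentTrace()] or
#'   [membraneTimecourse()].
#' @param stimulusFrame index of the last pre-stimulus frame.
#' @param frameIntervalS seconds per frame.
#' @return a [KineticFit-class]. A flat trace returns amplitude ~ 0 with
#'   the `"rate_indeterminate"` flag; a negative fitted amplitude is flagged
#'   `"negative_amplitude"`.
#' @examples
#' tr <- simulateRecruitmentTrace(0.01, 1, 1, noiseSd = 0)
#' fitRecruitment(tr)
#' @export
fitRecruitment <- function(trace, stimulusFrame = 25L, frameIntervalS = 4) {
    stopifnot(is.data.frame(trace), "intensity" %in% names(trace))
    y <- trace$intensity
    n <- length(y)
    if (n - stimulusFrame < 10L)
        stop("at least 10 post-stimulus frames are required")
    fr <- trace$frame %||% seq_len(n)
    tPost <- pmax(0, fr - stimulusFrame) * frameIntervalS
    post <- fr > stimulusFrame

    b0 <- mean(y[!post])
    a0 <- mean(tail(y, max(5L, n %/% 10L))) - b0
    yRange <- diff(range(y))
    if (!is.finite(yRange) || yRange <= .Machine$double.eps * 100 ||
        abs(a0) < 4 * sd(y[!post]) / sqrt(sum(!post)) + 1e-12) {
        # flat trace: amplitude indistinguishable from zero
        return(new("KineticFit", kOn = NA_real_, plateau = 0,
                   baseline = mean(y),
                   se = c(kOn = NA_real_, plateau = NA_real_,
                          baseline = sd(y) / sqrt(n)),
                   converged = TRUE, flags = "rate_indeterminate"))
    }
    tHalf <- tPost[post][which(y[post] - b0 >= a0 / 2)[1L]]
    k0 <- if (is.na(tHalf) || tHalf <= 0) 1 / max(tPost) else log(2) / tHalf

    fit <- tryCatch(
        minpack.lm::nlsLM(
            y ~ baseline + A * (1 - exp(-k * tPost)) * post,
            data = data.frame(y = y, tPost = tPost, post = as.numeric(post)),
            start = list(baseline = b0, A = a0, k = k0),
            lower = c(-Inf, -Inf, 0),
            control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) e)
    if (inherits(fit, "error"))
        return(new("KineticFit", kOn = NA_real_, plateau = NA_real_,
                   baseline = NA_real_,
                   se = c(kOn = NA_real_, plateau = NA_real_,
                          baseline = NA_real_),
                   converged = FALSE,
                   flags = c("non_convergence", conditionMessage(fit))))
    cf <- coef(fit)
    flags <- character(0)
    if (cf[["A"]] < 0) flags <- "negative_amplitude"
    new("KineticFit",
        kOn = unname(cf[["k"]]), plateau = unname(cf[["A"]]),
        baseline = unname(cf[["baseline"]]),
        se = .nlsSE(fit), converged = fit$convInfo$isConv %||% TRUE,
        flags = flags)
}

#' Match detected spots to ground truth
#'
#' Greedy nearest matching of detections to true spot positions within
#' `tolPx`; used to score detector precision and recall against the
#' synthetic ground truth.
#'
#' @param detected a `SpotSet` from [detectEndosomes()].
#' @param truth data.frame of true row/col centers.
#' @param tolPx match tolerance in pixels.
#' @return list with `nMatched`, `precision`, `recall` and the per-match
#'   distances.
#' @export
matchSpots <- function(detected, truth, tolPx = 3) {
    if (nrow(detected) == 0L || nrow(truth) == 0L)
        return(list(nMatched = 0L,
                    precision = if (nrow(detected)) 0 else NA_real_,
                    recall = if (nrow(truth)) 0 else NA_real_,
                    distances = numeric(0)))
    d <- sqrt(outer(detected$row, truth$row, "-")^2 +
              outer(detected$col, truth$col, "-")^2)
    matched <- 0L
    dist <- numeric(0)
    while (TRUE) {
        m <- which(d == min(d), arr.ind = TRUE)[1L, ]
        if (d[m[1L], m[2L]] > tolPx) break
        matched <- matched + 1L
        dist <- c(dist, d[m[1L], m[2L]])
        d[m[1L], ] <- Inf
        d[, m[2L]] <- Inf
        if (all(!is.finite(d))) break
    }
    list(nMatched = matched,
         precision = matched / nrow(detected),
         recall = matched / nrow(truth),
         distances = dist)
}
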