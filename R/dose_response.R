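# Concentration-response fitting and the assay-specific normalizations
# (Epac FRET, ebBRET, Epac-Venus FRET, NanoBiT).

#' Fit the three-parameter Hill model
#'
#' Unweighted least-squares fit of
#' `y = bottom + span / (1 + 10^(log10EC50 - log10 L))` (Hill slope fixed at
#' 1) to long-format concentration-response records. Replicates are fitted
#' jointly, not averaged first, preserving the error structure. Zero-dose
#' (basal) wells are excluded by default since the downstream normalization
#' equations exclude changes in basal; set `includeBasal` together with
#' `basalFloorM` to map them to a concentration floor.
#'
#' `bottom` is the zero-dose asymptote; `span` is signed, so a decreasing
#' raw response yields `span < 0` and the `"decreasing"` flag rather than a
#' silent reorientation. Initialization: bottom/span from the extreme
#' concentration means, log10EC50 from the geometric mean of tested
#' concentrations. Standard errors come from the Jacobian. Degenerate data
#' never error silently: flat responses return a converged zero-span fit
#' flagged `"no_plateau"` and `"ec50_indeterminate"`; an EC50 outside the
#' tested range is flagged `"extrapolated"`.
#'
#' @param table data.frame with columns `concentration_M` and `response`
#'   (optionally `condition`, `replicate`).
#' @param condition if given, fit only records of this condition.
#' @param hillSlope fixed Hill slope; 1 reproduces the three-parameter
#'   model, other values give the four-parameter shape with a fixed slope.
#' @param includeBasal include zero/NA concentrations at `basalFloorM`.
#' @param basalFloorM molar floor substituted for basal wells when
#'   `includeBasal = TRUE`.
#' @return a [HillFit-class].
#' @examples
#' tab <- simulateDoseResponse(doseResponseSimConfig(noiseSd = 0))
#' fitHill3(tab)
#' @export
fitHill3 <- function(table, condition = NULL, hillSlope = 1,
                     includeBasal = FALSE, basalFloorM = 1e-12) {
    stopifnot(is.data.frame(table),
              all(c("concentration_M", "response") %in% names(table)))
    if (!is.null(condition) && "condition" %in% names(table))
        table <- table[table$condition == condition, , drop = FALSE]
    basal <- is.na(table$concentration_M) | table$concentration_M <= 0
    if (includeBasal) {
        table$concentration_M[basal] <- basalFloorM
    } else {
        table <- table[!basal, , drop = FALSE]
    }
    conc <- table$concentration_M
    y <- table$response
    if (length(unique(conc)) < 4L)
        stop("at least 4 distinct concentrations are required")
    logL <- log10(conc)

    means <- tapply(y, logL, mean)
    ord <- order(as.numeric(names(means)))
    means <- means[ord]
    bottom0 <- means[[1L]]
    span0 <- means[[length(means)]] - means[[1L]]
    lec0 <- mean(logL)

    flags <- character(0)
    # flat data: span indistinguishable from noise -> degenerate fit
    resSd <- sd(y - means[as.character(logL)])
    if (!is.finite(resSd)) resSd <- 0
    if (abs(span0) <= max(2 * resSd / sqrt(length(y) / length(means)), 1e-12)
        && diff(range(means)) <= max(4 * resSd, 1e-12)) {
        flags <- c("no_plateau", "ec50_indeterminate")
        return(new("HillFit", bottom = mean(y), span = 0,
                   log10EC50 = NA_real_, hillSlope = hillSlope,
                   se = c(bottom = sd(y) / sqrt(length(y)), span = NA_real_,
                          log10EC50 = NA_real_),
                   converged = TRUE, flags = flags, data = table,
                   fit = NULL))
    }

    # a small multi-start ladder: rare singular-gradient failures at a
    # near-exact start are retried from perturbed initializations
    starts <- list(
        list(bottom = bottom0, span = span0, log10EC50 = lec0),
        list(bottom = min(means), span = diff(range(means)),
             log10EC50 = median(logL)),
        list(bottom = bottom0, span = span0, log10EC50 = lec0 + 0.35),
        list(bottom = bottom0 - 0.05 * span0, span = 1.1 * span0,
             log10EC50 = lec0 - 0.35))
    fit <- NULL
    for (s in starts) {
        fit <- tryCatch(
            minpack.lm::nlsLM(
                y ~ bottom + span /
                    (1 + 10^((log10EC50 - logL) * hillSlope)),
                data = data.frame(y = y, logL = logL),
                start = s,
                control = minpack.lm::nls.lm.control(maxiter = 500)),
            error = function(e) e)
        if (!inherits(fit, "error")) break
    }
    if (inherits(fit, "error")) {
        return(new("HillFit", bottom = NA_real_, span = NA_real_,
                   log10EC50 = NA_real_, hillSlope = hillSlope,
                   se = c(bottom = NA_real_, span = NA_real_,
                          log10EC50 = NA_real_),
                   converged = FALSE,
                   flags = c("non_convergence", conditionMessage(fit)),
                   data = table, fit = NULL))
    }
    cf <- coef(fit)
    se <- .nlsSE(fit)
    if (cf[["span"]] < 0) flags <- c(flags, "decreasing")
    if (cf[["log10EC50"]] < min(logL) || cf[["log10EC50"]] > max(logL))
        flags <- c(flags, "extrapolated")
    new("HillFit",
        bottom = unname(cf[["bottom"]]), span = unname(cf[["span"]]),
        log10EC50 = unname(cf[["log10EC50"]]), hillSlope = hillSlope,
        se = se, converged = fit$convInfo$isConv %||% TRUE,
        flags = flags, data = table, fit = fit)
}

#' Negative log potency from a Hill fit
#'
#' `pEC50 = -log10(EC50 in molar)`; an EC50 of 1 nM gives 9.
#'
#' @param fit a converged [HillFit-class].
#' @return unitless pEC50.
#' @examples
#' tab <- simulateDoseResponse(
#'     doseResponseSimConfig(log10EC50Molar = -9, noiseSd = 0))
#' pEC50(fitHill3(tab))
#' @export
pEC50 <- function(fit) {
    stopifnot(is(fit, "HillFit"))
    if (!fit@converged || !is.finite(fit@log10EC50) ||
        "ec50_indeterminate" %in% fit@flags)
        stop("EC50 is indeterminate; no pEC50 available")
    -fit@log10EC50
}

#' Normalize Epac FRET time courses to baseline and forskolin/IBMX
#'
#' Per well, the delta-FRET response is mapped affinely so that the mean of
#' the baseline window reads 0% and the mean of the forskolin/IBMX window
#' reads 100% (saturating adenylyl-cyclase stimulation as the assay
#' ceiling).
#'
#' @param wells numeric matrix, wells in rows and timepoints in columns (a
#'   single well may be given as a vector).
#' @param baselineWindow integer column indices of the pre-stimulation
#'   baseline reads.
#' @param forskolinWindow integer column indices of the forskolin/IBMX
#'   reads.
#' @return matrix of the same shape in percent, with attribute
#'   `"rule" = "epac_fret"`.
#' @examples
#' w <- rbind(c(1, 1, 3, 5, 5))
#' normalizeEpacFret(w, baselineWindow = 1:2, forskolinWindow = 4:5)
#' @export
normalizeEpacFret <- function(wells, baselineWindow, forskolinWindow) {
    if (is.vector(wells)) wells <- matrix(wells, nrow = 1L)
    stopifnot(is.matrix(wells),
              max(baselineWindow) <= ncol(wells),
              max(forskolinWindow) <= ncol(wells))
    base <- rowMeans(wells[, baselineWindow, drop = FALSE])
    fsk <- rowMeans(wells[, forskolinWindow, drop = FALSE])
    spanW <- fsk - base
    if (any(abs(spanW) < .Machine$double.eps * 100))
        stop("zero forskolin-baseline span in at least one well")
    out <- (wells - base) / spanW * 100
    attr(out, "rule") <- "epac_fret"
    out
}

#' BRET ratio
#'
#' Ratio of the light emitted in the acceptor channel over the light emitted
#' in the donor channel. Invariant under a common detector gain.
#'
#' @param acceptor,donor emission counts (vectorized).
#' @return acceptor/donor.
#' @examples
#' bretRatio(500, 1000)
#' @export
bretRatio <- function(acceptor, donor) {
    if (any(donor <= 0)) stop("donor counts must be > 0")
    acceptor / donor
}

#' Normalize BRET responses to the mock condition's agonist-induced change
#'
#' Implements the agonist-induced change in BRET as a percentage:
#' `(BRET_condition - bottom_condition) / span_mock * 100`, where
#' `bottom_condition` is the condition's own fitted bottom asymptote and
#' `span_mock` the mock condition's fitted span. Changes in basal never
#' enter: each condition is referenced to its own bottom asymptote.
#'
#' @param bret numeric BRET ratios of the condition.
#' @param fitCondition [HillFit-class] of the condition (supplies the
#'   bottom asymptote).
#' @param fitMock converged [HillFit-class] of the mock condition with
#'   span > 0.
#' @return percentages, with attribute `"rule" = "bret_change"`.
#' @examples
#' mock <- fitHill3(simulateDoseResponse(doseResponseSimConfig(
#'     bottom = 1, span = 0.2, noiseSd = 0)))
#' normalizeBretChange(1.2, mock, mock)  # mock at its own top: 100
#' @export
normalizeBretChange <- function(bret, fitCondition, fitMock) {
    stopifnot(is(fitCondition, "HillFit"), is(fitMock, "HillFit"))
    if (!fitMock@converged || !(fitMock@span > 0))
        stop("mock fit must be converged with span > 0")
    out <- (bret - fitCondition@bottom) / fitMock@span * 100
    attr(out, "rule") <- "bret_change"
    out
}

#' Maximal response as a span ratio over mock
#'
#' `Emax(%) = span_condition / span_mock * 100`. Basal differences are
#' excluded by construction (only spans enter).
#'
#' @param fitCondition,fitMock converged [HillFit-class] objects;
#'   `fitMock` must have span > 0.
#' @return Emax in percent.
#' @examples
#' f <- fitHill3(simulateDoseResponse(doseResponseSimConfig(noiseSd = 0)))
#' emax(f, f)  # 100
#' @export
emax <- function(fitCondition, fitMock) {
    stopifnot(is(fitCondition, "HillFit"), is(fitMock, "HillFit"))
    if (!fitCondition@converged || !fitMock@converged)
        stop("both fits must be converged")
    if (!(fitMock@span > 0)) stop("mock span must be > 0")
    fitCondition@span / fitMock@span * 100
}

#' Ratiometric Epac-Venus FRET value and baseline correction
#'
#' The FRET value is the light emitted in the 485 nm channel divided by the
#' summed light of the 485 nm and 535 nm channels. `baselineCorrect()`
#' subtracts a fitted bottom asymptote per experiment, yielding the
#' agonist-induced change in FRET.
#'
#' @param ch485,ch535 emission counts (vectorized).
#' @return FRET values in (0, 1).
#' @examples
#' epacVenusFret(100, 100)  # 0.5
#' @export
epacVenusFret <- function(ch485, ch535) {
    tot <- ch485 + ch535
    if (any(tot <= 0)) stop("zero total emission")
    ch485 / tot
}

#' @rdname epacVenusFret
#' @param fret FRET values from [epacVenusFret()].
#' @param fit a converged [HillFit-class] of the same experiment's
#'   concentration-response (supplies the bottom asymptote).
#' @export
baselineCorrect <- function(fret, fit) {
    stopifnot(is(fit, "HillFit"))
    if (!fit@converged) stop("fit must be converged")
    fret - fit@bottom
}

#' Pre-read-normalized area under the curve for NanoBiT traces
#'
#' Each luminescence reading is divided by the mean of the stable
#' pre-stimulation readings (at least 3 required), which absorbs well-to-well
#' expression and gain differences; the response metric is then the
#' trapezoidal area under the normalized post-stimulation trace. A flat
#' trace at the pre-read level yields an AUC equal to the post-window
#' duration.
#'
#' @param time_s reading times in seconds.
#' @param lum luminescence readings (same length).
#' @param preWindow indices of the pre-stimulation readings (>= 3).
#' @param postWindow indices of the post-stimulation trace; defaults to all
#'   readings after `preWindow`.
#' @return normalized AUC (seconds), with the normalized trace attached as
#'   attribute `"normalized"`.
#' @examples
#' t <- 0:10 * 60
#' nanobitNormalizeAUC(t, rep(500, 11), preWindow = 1:3)
#' @export
nanobitNormalizeAUC <- function(time_s, lum, preWindow,
                                postWindow = NULL) {
    stopifnot(length(time_s) == length(lum))
    if (length(preWindow) < 3L)
        stop("at least 3 pre-stimulation readings are required")
    pre <- mean(lum[preWindow])
    if (!is.finite(pre) || pre <= 0) stop("zero or invalid pre-read mean")
    if (is.null(postWindow))
        postWindow <- seq(max(preWindow) + 1L, length(lum))
    norm <- lum / pre
    auc <- pracma::trapz(time_s[postWindow], norm[postWindow])
    attr(auc, "normalized") <- norm
    attr(auc, "rule") <- "nanobit_auc"
    auc
}
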