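# Saturation radioligand binding: isotope decay correction and the global
# one-site total + nonspecific fit.

#' Radioisotope decay correction of ligand concentration
#'
#' Scales a nominal radioligand concentration (or activity) for isotope
#' decay between the reference date and the assay date:
#' `corrected = nominal * 2^(-days / halfLifeDays)`. The default half-life
#' is that of iodine-125 (59.39 days).
#'
#' @param nominal nominal concentration(s)/activities.
#' @param offsetDays days elapsed since the reference activity (>= 0).
#' @param halfLifeDays isotope half-life in days.
#' @return decay-corrected values.
#' @examples
#' decayCorrect(10, 59.39)  # one half-life: 5
#' @export
decayCorrect <- function(nominal, offsetDays, halfLifeDays = 59.39) {
    if (any(offsetDays < 0)) stop("offsetDays must be >= 0")
    .checkScalar(halfLifeDays, "halfLifeDays")
    nominal * 2^(-offsetDays / halfLifeDays)
}

#' One-site total and nonspecific binding fit
#'
#' Global least-squares fit of both well types of a saturation binding
#' experiment, sharing the nonspecific slope and background:
#' `total(L) = Bmax L / (Kd + L) + NS L + bg` and
#' `nonspecific(L) = NS L + bg`. Nonspecific wells are included in the fit,
#' not pre-subtracted. Free ligand is approximated by added ligand (no
#' depletion correction).
#'
#' @param table data.frame with columns `well_type` ("total" or
#'   "nonspecific"), `concentration_nM` and `counts`, e.g. from
#'   [simulateSaturationBinding()].
#' @return a [BindingFit-class]; a Kd outside the tested concentration range
#'   is flagged `"extrapolated"`.
#' @examples
#' tab <- simulateSaturationBinding(bindingSimConfig(noiseCV = 0))
#' fitOneSite(tab)
#' @export
fitOneSite <- function(table) {
    stopifnot(is.data.frame(table),
              all(c("well_type", "concentration_nM", "counts") %in%
                  names(table)))
    if (!all(c("total", "nonspecific") %in% table$well_type))
        stop("both total and nonspecific wells are required")
    concs <- sort(unique(table$concentration_nM))
    if (length(concs) < 5L)
        stop("at least 5 concentrations are required")
    byType <- split(table$concentration_nM, table$well_type)
    if (!all(concs %in% byType$total) || !all(concs %in% byType$nonspecific))
        stop("both well types must be present at every concentration")

    L <- table$concentration_nM
    isTot <- as.numeric(table$well_type == "total")
    y <- table$counts

    nsFit <- stats::lm(counts ~ concentration_nM,
                       data = table[table$well_type == "nonspecific", ])
    ns0 <- max(coef(nsFit)[[2L]], 0)
    bg0 <- max(coef(nsFit)[[1L]], 0)
    spec <- with(table[table$well_type == "total", ],
                 counts - ns0 * concentration_nM - bg0)
    bmax0 <- max(max(spec), 1e-6)
    kd0 <- median(concs)

    fit <- tryCatch(
        minpack.lm::nlsLM(
            y ~ isTot * bmax * L / (kd + L) + ns * L + bg,
            data = data.frame(y = y, L = L, isTot = isTot),
            start = list(bmax = bmax0, kd = kd0, ns = ns0, bg = bg0),
            lower = c(0, 1e-9, 0, 0),
            control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) e)
    if (inherits(fit, "error"))
        return(new("BindingFit", kdNM = NA_real_, bmax = NA_real_,
                   nsSlope = NA_real_, background = NA_real_,
                   se = c(bmax = NA_real_, kd = NA_real_, ns = NA_real_,
                          bg = NA_real_),
                   converged = FALSE,
                   flags = c("non_convergence", conditionMessage(fit))))
    cf <- coef(fit)
    flags <- character(0)
    if (cf[["kd"]] < min(concs) || cf[["kd"]] > max(concs))
        flags <- "extrapolated"
    new("BindingFit",
        kdNM = unname(cf[["kd"]]), bmax = unname(cf[["bmax"]]),
        nsSlope = unname(cf[["ns"]]), background = unname(cf[["bg"]]),
        se = .nlsSE(fit), converged = fit$convInfo$isConv %||% TRUE,
        flags = flags)
}

#' pKd of a binding fit
#'
#' `pKd = -log10(Kd in molar)`.
#'
#' @param fit a converged [BindingFit-class].
#' @return unitless pKd.
#' @export
pKd <- function(fit) {
    stopifnot(is(fit, "BindingFit"))
    if (!fit@converged || !is.finite(fit@kdNM))
        stop("Kd is not available")
    -log10(fit@kdNM * 1e-9)
}

#' Bmax normalized to the mock condition
#'
#' `Bmax_condition / Bmax_mock * 100` (percent); under the shared-background
#' global model this ratio is independent of background and detector gain.
#'
#' @param fitCondition,fitMock [BindingFit-class] objects; mock Bmax must
#'   be > 0.
#' @return normalized Bmax in percent.
#' @examples
#' f <- fitOneSite(simulateSaturationBinding(bindingSimConfig(noiseCV = 0)))
#' normalizeBmax(f, f)  # 100
#' @export
normalizeBmax <- function(fitCondition, fitMock) {
    stopifnot(is(fitCondition, "BindingFit"), is(fitMock, "BindingFit"))
    if (!(fitMock@bmax > 0)) stop("mock Bmax must be > 0")
    fitCondition@bmax / fitMock@bmax * 100
}
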