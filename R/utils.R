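#' @useDynLib receptorQuant, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef fft lm mad median nls optim quantile rnorm rpois
#'   runif sd setNames var vcov
#' @importFrom utils read.csv write.csv packageVersion head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# single positive finite scalar
.checkScalar <- function(x, name, lower = 0, strict = TRUE) {
    if (length(x) != 1L || !is.finite(x) ||
        (strict && x <= lower) || (!strict && x < lower))
        stop(name, " must be a single finite number ",
             if (strict) "> " else ">= ", lower, call. = FALSE)
    invisible(x)
}

# standard errors from an nls-like fit; NA on failure
.nlsSE <- function(fit) {
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) NULL)
    if (is.null(se)) {
        nm <- names(coef(fit))
        se <- setNames(rep(NA_real_, length(nm)), nm)
    }
    se
}

# geometric mean
.gmean <- function(x) exp(mean(log(x)))
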