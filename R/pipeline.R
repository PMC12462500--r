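# Command-style orchestration: runPipeline() executes one subcommand on
# files, writing CSV reports plus a structured YAML run log (seed, exact
# parameters, package version) so every report can be regenerated.

.parseArgs <- function(args, spec) {
    # spec: named list flag -> default (NA = required); flags are --kebab-case
    out <- spec
    i <- 1L
    while (i <= length(args)) {
        a <- args[[i]]
        if (!startsWith(a, "--"))
            stop("usage error: unexpected argument '", a, "'")
        key <- gsub("-", "_", substring(a, 3L))
        if (!key %in% names(spec))
            stop("usage error: unknown flag '", a, "'")
        if (i == length(args))
            stop("usage error: flag '", a, "' needs a value")
        val <- args[[i + 1L]]
        out[[key]] <- if (is.numeric(spec[[key]])) {
            v <- suppressWarnings(as.numeric(val))
            if (is.na(v)) stop("usage error: flag '", a,
                               "' needs a numeric value")
            v
        } else val
        i <- i + 2L
    }
    out
}

.runLog <- function(outDir, subcommand, params) {
    log <- list(subcommand = subcommand,
                package = "receptorQuant",
                version = as.character(packageVersion("receptorQuant")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                parameters = params)
    yaml::write_yaml(log, file.path(outDir, paste0(subcommand, "_run.yaml")))
}

#' Run an analysis subcommand
#'
#' Thin orchestration layer over the package functions, mirroring a
#' command-line interface. Subcommands: `simulate`, `fit-dr`, `brightness`,
#' `stics`, `endosomes`, `recruitment`, `binding`. Every run writes its CSV
#' report(s) and a YAML run log with the seed and the exact parameter set
#' into `--out`; reruns with the same seed are bit-identical. Unknown flags
#' raise a usage error.
#'
#' @param args character vector: the subcommand followed by `--flag value`
#'   pairs. Common flags: `--out` (output directory, required), `--seed`.
#'   See the package vignette for per-subcommand flags.
#' @return named list of written file paths, invisibly.
#' @examples
#' od <- tempfile(); dir.create(od)
#' runPipeline(c("simulate", "--kind", "dose-response",
#'               "--out", od, "--seed", "1"))
#' @export
runPipeline <- function(args) {
    if (length(args) < 1L)
        stop("usage error: no subcommand given")
    sub <- args[[1L]]
    rest <- args[-1L]
    paths <- switch(sub,
        "simulate" = .cmdSimulate(rest),
        "fit-dr" = .cmdFitDr(rest),
        "brightness" = .cmdBrightness(rest),
        "stics" = .cmdStics(rest),
        "endosomes" = .cmdEndosomes(rest),
        "recruitment" = .cmdRecruitment(rest),
        "binding" = .cmdBinding(rest),
        stop("usage error: unknown subcommand '", sub, "'"))
    invisible(paths)
}

.ensureOut <- function(p) {
    if (is.na(p)) stop("usage error: --out is required")
    if (!dir.exists(p)) dir.create(p, recursive = TRUE)
    p
}

.cmdSimulate <- function(args) {
    p <- .parseArgs(args, list(
        kind = NA_character_, out = NA_character_, seed = 1,
        # dose-response / binding parameters
        bottom = 0, span = 100, ec50_nm = 10, noise_sd = 5,
        n_replicates = 3, condition = "sim",
        kd_nm = 2, bmax = 1000, noise_cv = 0.05,
        # image parameters
        field_px = 128, n_frames = 20, n_lines = 20000, n_pixels = 256,
        density_um2 = 10, diffusion_um2_s = 0.1, colabel_fraction = 0,
        n_spots = 25, snr = 5,
        k_on = 0.01, plateau = 1, baseline = 1))
    out <- .ensureOut(p$out)
    seed <- as.integer(p$seed)
    paths <- switch(p$kind,
        "dose-response" = {
            tab <- simulateDoseResponse(doseResponseSimConfig(
                bottom = p$bottom, span = p$span,
                log10EC50Molar = log10(p$ec50_nm * 1e-9),
                noiseSd = p$noise_sd, nReplicates = p$n_replicates,
                condition = p$condition, seed = seed))
            writeAssayTable(tab, file.path(out, "dose_response.csv"))
        },
        "binding" = {
            tab <- simulateSaturationBinding(bindingSimConfig(
                kdNM = p$kd_nm, bmaxCounts = p$bmax, noiseCV = p$noise_cv,
                seed = seed))
            writeAssayTable(tab, file.path(out, "binding.csv"))
        },
        "stack" = {
            st <- simulateConfocalStack(membraneSimConfig(
                fieldSizePx = rep(as.integer(p$field_px), 2L),
                nFrames = as.integer(p$n_frames),
                particleDensityUm2 = p$density_um2,
                diffusionUm2S = p$diffusion_um2_s, seed = seed))
            writeImageStack(st, file.path(out, "stack.tif"))
        },
        "kymograph" = {
            ky <- simulateKymograph(membraneSimConfig(
                nLines = as.integer(p$n_lines),
                nPixels = as.integer(p$n_pixels),
                particleDensityUm2 = p$density_um2,
                diffusionUm2S = p$diffusion_um2_s,
                colabelFraction = p$colabel_fraction, seed = seed))
            writeImageStack(ky, file.path(out, "kymograph.tif"))
        },
        "endosomes" = {
            sim <- simulateEndosomeFrames(as.integer(p$n_spots), snr = p$snr,
                                          seed = seed)
            writeAssayTable(sim$spots, file.path(out, "true_spots.csv"))
            writeImageStack(sim$stack, file.path(out, "endosomes.tif"))
        },
        "recruitment" = {
            tr <- simulateRecruitmentTrace(p$k_on, p$plateau, p$baseline,
                                           noiseSd = p$noise_sd / 100,
                                           seed = seed)
            writeAssayTable(tr, file.path(out, "trace.csv"))
        },
        stop("usage error: unknown --kind '", p$kind, "'"))
    .runLog(out, "simulate", p)
    paths
}

.cmdFitDr <- function(args) {
    p <- .parseArgs(args, list(table = NA_character_, out = NA_character_,
                               mock_condition = NA_character_,
                               normalization = "none"))
    out <- .ensureOut(p$out)
    if (!p$normalization %in% c("none", "epac", "bret", "epacvenus",
                                "nanobit"))
        stop("usage error: unknown --normalization '", p$normalization, "'")
    tab <- readAssayTable(p$table, "dose_response")
    conds <- unique(tab$condition)
    fits <- lapply(conds, function(cc) fitHill3(tab, condition = cc))
    names(fits) <- conds
    mock <- if (!is.na(p$mock_condition)) fits[[p$mock_condition]] else NULL
    rows <- lapply(conds, function(cc) {
        f <- fits[[cc]]
        data.frame(
            condition = cc, normalization = p$normalization,
            bottom = f@bottom, span = f@span,
            ec50_nM = 10^f@log10EC50 * 1e9,
            pEC50 = if (is.finite(f@log10EC50)) -f@log10EC50 else NA_real_,
            emax_pct = if (!is.null(mock)) emax(f, mock) else NA_real_,
            se_log10EC50 = unname(f@se["log10EC50"]),
            converged = f@converged,
            flags = paste(f@flags, collapse = ";"))
    })
    path <- writeAssayTable(do.call(rbind, rows),
                            file.path(out, "hill_fits.csv"))
    .runLog(out, "fit-dr", p)
    path
}

.cmdBrightness <- function(args) {
    p <- .parseArgs(args, list(stack = NA_character_, roi = NA_character_,
                               reference = NA_character_,
                               out = NA_character_, waist_nm = 250,
                               method = "moment"))
    out <- .ensureOut(p$out)
    st <- readImageStack(p$stack)
    roi <- if (!is.na(p$roi)) {
        v <- read.csv(p$roi)
        roiPolygon(v)
    } else {
        d <- dim(counts(st))
        roiRectangle(2, 2, d[1L] - 3L, d[2L] - 3L)
    }
    est <- if (p$method == "histogram")
        histogramBrightness(st, roi, psfWaistNm = p$waist_nm)
    else momentBrightness(st, roi)
    ratio <- NA_real_
    if (!is.na(p$reference)) {
        ref <- read.csv(p$reference)
        ratio <- est@epsilon / ref$epsilon[1L]
    }
    rep_ <- data.frame(epsilon = est@epsilon,
                       number_density = est@numberDensity,
                       ratio_vs_reference = ratio,
                       n_pixels = est@nPixels, method = est@method,
                       flags = paste(est@flags, collapse = ";"))
    path <- writeAssayTable(rep_, file.path(out, "brightness.csv"))
    .runLog(out, "brightness", p)
    path
}

.cmdStics <- function(args) {
    p <- .parseArgs(args, list(kymo = NA_character_, out = NA_character_,
                               bin = 10000, waist_nm = 250,
                               channels = "AA", seed = 1))
    out <- .ensureOut(p$out)
    ky <- readImageStack(p$kymo, defaultKind = "Kymograph")
    ky <- detrendKymograph(ky, binSizeLines = as.integer(p$bin),
                           seed = as.integer(p$seed))
    pairs <- strsplit(p$channels, ",")[[1L]]
    paths <- character(0)
    fitRows <- list()
    for (pr in pairs) {
        g <- computeStics(ky, pr)
        surf <- data.frame(
            xi_px = rep(g@xiPx, each = length(g@tauS)),
            tau_s = rep(g@tauS, times = length(g@xiPx)),
            G = as.vector(g@G))
        paths <- c(paths, writeAssayTable(
            surf, file.path(out, paste0("stics_", pr, ".csv"))))
        if (substr(pr, 1L, 1L) == substr(pr, 2L, 2L)) {
            f <- fitDiffusion(g, waistNm = p$waist_nm)
            fitRows[[pr]] <- data.frame(
                pair = pr, D_um2_s = f@D, G0 = f@G0,
                waist_nm = f@waistNm, converged = f@converged,
                flags = paste(f@flags, collapse = ";"))
        }
    }
    if (length(fitRows))
        paths <- c(paths, writeAssayTable(
            do.call(rbind, fitRows), file.path(out, "diffusion_fits.csv")))
    .runLog(out, "stics", p)
    paths
}

.cmdEndosomes <- function(args) {
    p <- .parseArgs(args, list(stack = NA_character_, out = NA_character_,
                               sigma_px = 2, threshold_mads = 4.5))
    out <- .ensureOut(p$out)
    st <- readImageStack(p$stack)
    nF <- dim(counts(st))[3L]
    rows <- lapply(seq_len(nF), function(f) {
        sp <- detectEndosomes(st, sigmaPx = p$sigma_px,
                              thresholdMads = p$threshold_mads,
                              frameIndex = f)
        if (nrow(sp) == 0L) return(NULL)
        cbind(frame = f, as.data.frame(sp))
    })
    spots <- do.call(rbind, rows)
    if (is.null(spots))
        spots <- data.frame(frame = integer(0), row = numeric(0),
                            col = numeric(0), radius_px = numeric(0),
                            peak = numeric(0))
    path <- writeAssayTable(spots, file.path(out, "endosomes.csv"))
    .runLog(out, "endosomes", p)
    path
}

.cmdRecruitment <- function(args) {
    p <- .parseArgs(args, list(table = NA_character_, out = NA_character_,
                               stimulus_frame = 25, frame_interval_s = 4))
    out <- .ensureOut(p$out)
    tr <- readAssayTable(p$table, "trace")
    f <- fitRecruitment(tr, stimulusFrame = as.integer(p$stimulus_frame),
                        frameIntervalS = p$frame_interval_s)
    rep_ <- data.frame(k_on_per_s = f@kOn, plateau = f@plateau,
                       baseline = f@baseline, converged = f@converged,
                       flags = paste(f@flags, collapse = ";"))
    path <- writeAssayTable(rep_, file.path(out, "recruitment_fit.csv"))
    .runLog(out, "recruitment", p)
    path
}

.cmdBinding <- function(args) {
    p <- .parseArgs(args, list(table = NA_character_, out = NA_character_,
                               mock = NA_character_))
    out <- .ensureOut(p$out)
    tab <- readAssayTable(p$table, "binding")
    conds <- if ("condition" %in% names(tab)) unique(tab$condition) else "all"
    fits <- lapply(conds, function(cc) {
        sub <- if (identical(cc, "all")) tab
               else tab[tab$condition == cc, , drop = FALSE]
        fitOneSite(sub)
    })
    names(fits) <- conds
    mock <- if (!is.na(p$mock) && p$mock %in% conds) fits[[p$mock]] else NULL
    rows <- lapply(conds, function(cc) {
        f <- fits[[cc]]
        data.frame(condition = cc, kd_nM = f@kdNM,
                   pKd = if (is.finite(f@kdNM)) pKd(f) else NA_real_,
                   bmax = f@bmax, ns_slope = f@nsSlope,
                   background = f@background,
                   bmax_pct_of_mock = if (!is.null(mock))
                       normalizeBmax(f, mock) else NA_real_,
                   converged = f@converged,
                   flags = paste(f@flags, collapse = ";"))
    })
    path <- writeAssayTable(do.call(rbind, rows),
                            file.path(out, "binding_fits.csv"))
    .runLog(out, "binding", p)
    path
}
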