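#' Head-to-head comparison of isothermal and gradient designs
#'
#' Simulates both experimental designs from the same ground-truth
#' proteome and scores each against the generator's truth labels. The
#' isothermal arm (n-vs-n single temperature) is analyzed with the full
#' moderated-test pipeline at a stringent FDR; the gradient arm
#' (multi-temperature, fewer replicates) is analyzed by per-curve fitting
#' plus the replicate-concordance significance call of
#' [tppSignificance()]. Sensitivity is computed among detectable proteins
#' only (those that survive filtering / are testable in that arm), so the
#' comparison is not confounded by coverage; the detectable counts are
#' reported alongside.
#'
#' @param truth a proteome from [sampleProteome()].
#' @param config a [simConfig()] list supplying the design constants
#'   (assay temperature, replicate counts, gradient temperatures, noise).
#' @param qCutoff FDR cutoff of the isothermal arm (default 0.001).
#' @param normalize passed to [runITSA()]; disable for (near-)noiseless
#'   data, where rank-stable columns make quantile normalization
#'   collapse all within-group variance.
#' @param seed seed for the two simulated experiments (two independent
#'   draws are derived from it).
#' @return a \code{data.frame} with one row per design
#'   (\code{"isothermal"}, \code{"gradient"}): \code{n_detectable},
#'   \code{n_true_targets}, \code{n_called}, \code{n_true_positive},
#'   \code{sensitivity}, \code{realized_fdp}. The called protein ids are
#'   attached as attribute \code{"calls"}.
#' @export
compareDesigns <- function(truth, config, qCutoff = 0.001,
    normalize = TRUE, seed = config$seed) {
    targets <- truth$protein_id[truth$is_target]
    ## isothermal arm
    iso <- simulateIsothermal(truth, config = config, seed = seed)
    isoRes <- runITSA(iso, qCutoff = qCutoff, normalize = normalize)
    isoTested <- isoRes$protein_id[isoRes$tested]
    isoCalled <- isoRes$protein_id[isoRes$significant]
    isoRow <- .scoreArm("isothermal", isoTested, isoCalled, targets)
    ## gradient arm
    grad <- simulateGradient(truth, config = config, seed = seed + 1L)
    fits <- fitMeltingCurves(grad)
    calls <- tppSignificance(fits, nReps = config$gradientReplicates)
    gradTested <- calls$protein_id[calls$testable]
    gradCalled <- calls$protein_id[calls$significant]
    gradRow <- .scoreArm("gradient", gradTested, gradCalled, targets)
    out <- rbind(isoRow, gradRow)
    attr(out, "calls") <- list(isothermal = isoCalled,
        gradient = gradCalled)
    out
}

.scoreArm <- function(label, tested, called, targets) {
    detectableTargets <- intersect(targets, tested)
    tp <- intersect(called, targets)
    data.frame(design = label,
        n_detectable = length(tested),
        n_true_targets = length(detectableTargets),
        n_called = length(called),
        n_true_positive = length(tp),
        sensitivity = if (length(detectableTargets))
            length(intersect(called, detectableTargets)) /
                length(detectableTargets) else NA_real_,
        realized_fdp = if (length(called))
            length(setdiff(called, targets)) / length(called) else 0)
}

#' Assay-temperature sweep for the isothermal design
#'
#' Runs the isothermal arm at several assay temperatures on the same
#' ground truth and reports the per-temperature target sets, all
#' pairwise overlap sizes and the union count. Mirrors the observation
#' that nearby assay temperatures recover largely overlapping target
#' sets while distant ones diverge.
#'
#' @param truth a proteome from [sampleProteome()].
#' @param temperatures assay temperatures in degrees C (>= 2; default
#'   48, 52, 56).
#' @param config a [simConfig()] list.
#' @param qCutoff FDR cutoff (default 0.001).
#' @param seed base seed; temperature i uses \code{seed + i - 1} so each
#'   assay is an independent experiment on the same proteome.
#' @return a list with \code{calls} (named list of called id sets),
#'   \code{counts} (named vector), \code{overlap} (symmetric matrix of
#'   pairwise intersection sizes) and \code{union_count}.
#' @export
temperatureSweep <- function(truth, temperatures = c(48, 52, 56), config,
    qCutoff = 0.001, seed = config$seed) {
    if (length(temperatures) < 2)
        stop("temperature sweep needs >= 2 temperatures")
    calls <- lapply(seq_along(temperatures), function(i) {
        tq <- simulateIsothermal(truth, temperature = temperatures[i],
            config = config, seed = seed + i - 1L)
        res <- runITSA(tq, qCutoff = qCutoff)
        res$protein_id[res$significant]
    })
    names(calls) <- as.character(temperatures)
    m <- length(calls)
    overlap <- matrix(0L, m, m, dimnames = list(names(calls), names(calls)))
    for (i in seq_len(m)) for (j in seq_len(m))
        overlap[i, j] <- length(intersect(calls[[i]], calls[[j]]))
    list(calls = calls,
        counts = vapply(calls, length, integer(1)),
        overlap = overlap,
        union_count = length(unique(unlist(calls))))
}
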