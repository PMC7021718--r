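#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' MeltCurve: parametric protein melting curves
#'
#' A vector-like container of three-parameter sigmoid melting curves
#' describing the soluble fraction of a protein as a function of
#' temperature,
#' \deqn{f(T) = \frac{1 - plateau}{1 + e^{-(a/T - b)}} + plateau.}
#' The curve decreases monotonically in temperature (for \code{a > 0}),
#' approaches 1 at low temperature and \code{plateau} at high temperature.
#' The melting temperature Tm (where \eqn{f(T) = 0.5}) exists only when
#' \code{plateau < 0.5}.
#'
#' @slot a numeric, curve-steepness numerator on the Celsius scale
#'   (\code{a > 0}).
#' @slot b numeric, dimensionless offset (\code{b > 0}).
#' @slot plateau numeric, residual high-temperature soluble fraction in
#'   \code{[0, 1)}. Curves with \code{plateau >= 0.5} are representable
#'   (curve fitting can produce them) but have no melting temperature.
#'
#' @seealso [fractionSoluble()], [meltingTemperature()], [slopeAtTm()],
#'   [deltaY()], [deltaTm()]
#' @export
setClass("MeltCurve",
    representation(a = "numeric", b = "numeric", plateau = "numeric"))

setValidity("MeltCurve", function(object) {
    n <- length(object@a)
    if (length(object@b) != n || length(object@plateau) != n)
        return("slots 'a', 'b' and 'plateau' must have equal length")
    if (any(!is.finite(object@a)) || any(object@a <= 0))
        return("'a' must be finite and positive")
    if (any(!is.finite(object@b)) || any(object@b <= 0))
        return("'b' must be finite and positive")
    if (any(!is.finite(object@plateau)) ||
        any(object@plateau < 0) || any(object@plateau >= 1))
        return("'plateau' must lie in [0, 1)")
    TRUE
})

#' Construct a MeltCurve object
#'
#' @param a,b,plateau numeric vectors (recycled to a common length); see
#'   the class description for their meaning.
#' @return A [MeltCurve-class] object of the common length.
#' @examples
#' mc <- MeltCurve(a = 520, b = 10, plateau = 0)
#' meltingTemperature(mc)  # 52
#' @export
MeltCurve <- function(a, b, plateau = 0) {
    n <- max(length(a), length(b), length(plateau))
    new("MeltCurve",
        a = rep_len(as.numeric(a), n),
        b = rep_len(as.numeric(b), n),
        plateau = rep_len(as.numeric(plateau), n))
}

#' @describeIn MeltCurve-class number of curves in the object
#' @param x a \code{MeltCurve}
#' @export
setMethod("length", "MeltCurve", function(x) length(x@a))

#' @describeIn MeltCurve-class subset curves
#' @param i index vector
#' @export
setMethod("[", "MeltCurve", function(x, i) {
    new("MeltCurve", a = x@a[i], b = x@b[i], plateau = x@plateau[i])
})

#' @describeIn MeltCurve-class display a short summary
#' @param object a \code{MeltCurve}
#' @export
setMethod("show", "MeltCurve", function(object) {
    n <- length(object)
    cat("MeltCurve of length", n, "\n")
    k <- min(n, 5L)
    if (k > 0L) {
        df <- data.frame(a = object@a[seq_len(k)], b = object@b[seq_len(k)],
            plateau = object@plateau[seq_len(k)])
        print(df)
        if (n > k) cat("...", n - k, "more curves\n")
    }
    invisible(NULL)
})

#' @rdname MeltCurve-class
#' @export
meltA <- function(x) x@a

#' @rdname MeltCurve-class
#' @export
meltB <- function(x) x@b

#' @rdname MeltCurve-class
#' @export
meltPlateau <- function(x) x@plateau

#' ThermalQuant: a thermal-proteomics reporter-intensity experiment
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] for
#' MaxQuant-style protein-level TMT quantification. The \code{"intensity"}
#' assay holds corrected reporter-ion intensities (\code{NA} = missing;
#' serialized as 0 in the MaxQuant dialect). Row metadata carries the
#' identification evidence used for confidence filtering
#' (\code{unique_peptides}, \code{msms_count}) and optional
#' \code{reverse} / \code{contaminant} flags; column metadata carries the
#' design (\code{condition} in \code{"vehicle"}/\code{"drug"},
#' \code{replicate}, \code{temperature} in degrees Celsius).
#'
#' @seealso [simulateIsothermal()], [simulateGradient()],
#'   [readProteinGroups()], [filterHighConfidence()], [runITSA()]
#' @export
setClass("ThermalQuant", contains = "SummarizedExperiment")

setValidity("ThermalQuant", function(object) {
    if (!("intensity" %in% SummarizedExperiment::assayNames(object)))
        return("assay 'intensity' is required")
    cd <- SummarizedExperiment::colData(object)
    need <- c("condition", "replicate", "temperature")
    if (!all(need %in% colnames(cd)))
        return(paste("colData must contain:", paste(need, collapse = ", ")))
    if (!all(cd$condition %in% c("vehicle", "drug")))
        return("condition must be 'vehicle' or 'drug'")
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("unique_peptides", "msms_count") %in% colnames(rd)))
        return("rowData must contain 'unique_peptides' and 'msms_count'")
    a <- SummarizedExperiment::assay(object, "intensity")
    if (any(a < 0, na.rm = TRUE))
        return("intensities must be non-negative where present")
    TRUE
})

#' Construct a ThermalQuant object
#'
#' @param intensity numeric matrix (proteins x samples) of reporter
#'   intensities, \code{NA} for missing values; rownames are protein ids.
#' @param proteinData `DataFrame`/data.frame of per-protein metadata; must
#'   contain `unique_peptides` and `msms_count`.
#' @param sampleData `DataFrame`/data.frame of per-sample metadata; must
#'   contain `condition` ("vehicle"/"drug"), `replicate` and `temperature`.
#' @return A [ThermalQuant-class] object.
#' @export
ThermalQuant <- function(intensity, proteinData, sampleData) {
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = as.matrix(intensity)),
        rowData = S4Vectors::DataFrame(proteinData),
        colData = S4Vectors::DataFrame(sampleData))
    new("ThermalQuant", se)
}

#' @describeIn ThermalQuant-class display a short summary
#' @param object a \code{ThermalQuant}
#' @export
setMethod("show", "ThermalQuant", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat(sprintf(
        "ThermalQuant: %d proteins x %d samples (%d vehicle, %d drug)\n",
        nrow(object), ncol(object), sum(cd$condition == "vehicle"),
        sum(cd$condition == "drug")))
    temps <- sort(unique(cd$temperature))
    cat("temperatures (C):", paste(temps, collapse = ", "), "\n")
    a <- SummarizedExperiment::assay(object, "intensity")
    cat(sprintf("missing values: %.1f%%\n", 100 * mean(is.na(a))))
    invisible(NULL)
})

#' VariancePrior: empirical-Bayes variance hyperparameters
#'
#' Holds the prior degrees of freedom \code{d0} (possibly \code{Inf}) and
#' prior variance \code{s0sq} of the scaled inverse-chi-square prior on
#' per-protein variances, as estimated by [estimateVariancePrior()].
#'
#' @slot d0 numeric(1), prior degrees of freedom, \code{> 0} or \code{Inf}.
#' @slot s0sq numeric(1), prior variance, finite and \code{> 0}.
#' @export
setClass("VariancePrior", representation(d0 = "numeric", s0sq = "numeric"))

setValidity("VariancePrior", function(object) {
    if (length(object@d0) != 1L || is.na(object@d0) || object@d0 <= 0)
        return("'d0' must be a single positive number (Inf allowed)")
    if (length(object@s0sq) != 1L || !is.finite(object@s0sq) ||
        object@s0sq <= 0)
        return("'s0sq' must be a single finite positive number")
    TRUE
})

#' @rdname VariancePrior-class
#' @param d0,s0sq see slots
#' @export
VariancePrior <- function(d0, s0sq) new("VariancePrior", d0 = d0, s0sq = s0sq)

#' @rdname VariancePrior-class
#' @param x a \code{VariancePrior}
#' @export
priorDf <- function(x) x@d0

#' @rdname VariancePrior-class
#' @export
priorVar <- function(x) x@s0sq

#' @describeIn VariancePrior-class display the hyperparameters
#' @param object a \code{VariancePrior}
#' @export
setMethod("show", "VariancePrior", function(object) {
    cat(sprintf("VariancePrior: d0 = %s, s0^2 = %.6g\n",
        format(object@d0), object@s0sq))
    invisible(NULL)
})

#' SubsampleReport: replicate-subsampling power analysis results
#'
#' Produced by [runSubsampledAnalyses()]. For a replicate depth \code{k}
#' drawn from an n-vs-n isothermal design, records every paired
#' subset comparison, the fraction of comparisons in which each protein was
#' significant, the power-classified protein set (significant in more than
#' \code{powerThreshold} of comparisons) and the Type-I-flagged set
#' (significant in more than \code{type1Threshold} of comparisons but not
#' significant in the full design).
#'
#' @slot k integer(1), replicate depth per condition.
#' @slot nCombos integer(1), number of paired subset comparisons
#'   (\code{choose(n,k)^2}).
#' @slot fdr numeric(1), BH FDR threshold applied within each comparison.
#' @slot powerThreshold,type1Threshold numeric(1), tally thresholds
#'   (strict inequalities).
#' @slot tally `DataFrame` with columns `protein_id`, `n_tested`,
#'   `n_significant`, `fraction`.
#' @slot poweredSet,type1Flagged,fullSignificant character vectors of
#'   protein ids.
#' @export
setClass("SubsampleReport", representation(
    k = "integer", nCombos = "integer", fdr = "numeric",
    powerThreshold = "numeric", type1Threshold = "numeric",
    tally = "DataFrame", poweredSet = "character",
    type1Flagged = "character", fullSignificant = "character"))

#' @describeIn SubsampleReport-class display a summary
#' @param object a \code{SubsampleReport}
#' @export
setMethod("show", "SubsampleReport", function(object) {
    cat(sprintf(
        "SubsampleReport: k = %d (%d paired comparisons, FDR < %g)\n",
        object@k, object@nCombos, object@fdr))
    cat(sprintf("  powered proteins (tally > %g): %d\n",
        object@powerThreshold, length(object@poweredSet)))
    cat(sprintf("  Type-I flagged (tally > %g, not in full design): %d\n",
        object@type1Threshold, length(object@type1Flagged)))
    cat(sprintf("  full-design significant: %d\n",
        length(object@fullSignificant)))
    invisible(NULL)
})

#' @rdname SubsampleReport-class
#' @param x a \code{SubsampleReport}
#' @export
poweredSet <- function(x) x@poweredSet

#' @rdname SubsampleReport-class
#' @export
type1Flagged <- function(x) x@type1Flagged

#' @rdname SubsampleReport-class
#' @export
subsampleTally <- function(x) x@tally
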