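#' Enumerate paired replicate subsets
#'
#' All ordered pairs of k-element subsets of the vehicle and drug
#' replicate indices, in deterministic lexicographic order. With n = 5
#' replicates per condition there are 25 paired comparisons at k = 4 and
#' 100 at k = 3 or k = 2.
#'
#' @param n replicates per condition.
#' @param k subset size, \code{2 <= k <= n}.
#' @return list of length \code{choose(n, k)^2}; each element is a list
#'   with integer vectors \code{vehicle} and \code{drug}.
#' @export
enumeratePairedSubsets <- function(n, k) {
    if (k < 2 || k > n)
        stop("invalid subset size: need 2 <= k <= n")
    subsets <- combn(n, k, simplify = FALSE)
    pairs <- vector("list", length(subsets)^2)
    idx <- 0L
    for (v in subsets) for (d in subsets) {
        idx <- idx + 1L
        pairs[[idx]] <- list(vehicle = v, drug = d)
    }
    pairs
}

# analysis of one column subset, identical to a fresh experiment:
# re-filter valid values, re-normalize, re-estimate the prior, test, BH
.analyzeSubset <- function(x, cols, fdr, normalize = TRUE,
    minValidValues = 2L) {
    runITSA(x[, cols], qCutoff = fdr, fcCutoff = 0,
        normalize = normalize, minValidValues = minValidValues)
}

# matrix-level equivalent of .analyzeSubset for the enumeration loop:
# same evidence filter, per-subset valid-value rule and moderated-test
# math, but returning bare id vectors instead of a results DataFrame
.analyzeSubsetFast <- function(a, evidenceKeep, condition, cols, fdr,
    normalize = TRUE, minValidValues = 2L) {
    sub <- a[, cols, drop = FALSE]
    keep <- evidenceKeep & rowSums(!is.na(sub)) >= minValidValues
    sub <- sub[keep, , drop = FALSE]
    cond <- condition[cols]
    m <- log2(sub)
    if (normalize) m <- quantileNormalize(m)
    v <- m[, cond == "vehicle", drop = FALSE]
    d <- m[, cond == "drug", drop = FALSE]
    n1 <- rowSums(!is.na(v)); n2 <- rowSums(!is.na(d))
    testable <- n1 >= 2 & n2 >= 2
    s2 <- (rowSums((v - rowMeans(v, na.rm = TRUE))^2, na.rm = TRUE) +
        rowSums((d - rowMeans(d, na.rm = TRUE))^2, na.rm = TRUE)) /
        (n1 + n2 - 2)
    prior <- estimateVariancePrior(s2[testable], (n1 + n2 - 2)[testable])
    st <- .moderatedStats(m, cond, prior)
    q <- bhAdjust(st$p[st$tested])
    ids <- rownames(sub)
    list(tested = ids[st$tested], significant = ids[st$tested][q < fdr])
}

#' Replicate-subsampling analysis of an isothermal experiment
#'
#' Re-analyzes every paired k-replicate subset of an n-vs-n isothermal
#' design exactly as a fresh experiment (confidence filtering with the
#' valid-value rule re-applied within the subset, quantile normalization
#' and variance-prior estimation recomputed on the selected columns,
#' moderated test, BH at \code{fdr}). Each protein's significance calls
#' are tallied across comparisons; proteins significant in more than
#' \code{powerThreshold} of the comparisons form the powered set, and
#' proteins significant in more than \code{type1Threshold} of comparisons
#' but \emph{not} significant in the full n-vs-n design are flagged as
#' potential Type-I errors.
#'
#' @param x an isothermal [ThermalQuant-class] with equal numbers of
#'   vehicle and drug replicates.
#' @param k replicate depth to subsample, \code{2 <= k <= n}.
#' @param fdr BH FDR threshold within each comparison (default 0.1).
#' @param powerThreshold,type1Threshold tally thresholds, strict
#'   inequalities (defaults 0.8 and 0.1).
#' @param normalize passed to [runITSA()] for every comparison and the
#'   full design.
#' @return a [SubsampleReport-class].
#' @export
runSubsampledAnalyses <- function(x, k, fdr = 0.1, powerThreshold = 0.8,
    type1Threshold = 0.1, normalize = TRUE) {
    cd <- SummarizedExperiment::colData(x)
    vCols <- which(cd$condition == "vehicle")
    dCols <- which(cd$condition == "drug")
    n <- length(vCols)
    if (length(dCols) != n)
        stop("design error: unequal vehicle and drug replicate counts")
    if (k > n) stop("design error: k exceeds the replicate depth")
    vCols <- vCols[order(cd$replicate[vCols])]
    dCols <- dCols[order(cd$replicate[dCols])]
    pairs <- enumeratePairedSubsets(n, k)
    ids <- rownames(x)
    a <- SummarizedExperiment::assay(x, "intensity")
    rd <- SummarizedExperiment::rowData(x)
    evidenceKeep <- rd$unique_peptides >= 1L & rd$msms_count >= 2L
    if (!is.null(rd$reverse)) evidenceKeep <- evidenceKeep & !rd$reverse
    if (!is.null(rd$contaminant))
        evidenceKeep <- evidenceKeep & !rd$contaminant
    nTested <- nSig <- setNames(integer(length(ids)), ids)
    for (pr in pairs) {
        res <- .analyzeSubsetFast(a, evidenceKeep, cd$condition,
            c(vCols[pr$vehicle], dCols[pr$drug]), fdr,
            normalize = normalize)
        nTested[res$tested] <- nTested[res$tested] + 1L
        nSig[res$significant] <- nSig[res$significant] + 1L
    }
    full <- runITSA(x, qCutoff = fdr, fcCutoff = 0, normalize = normalize)
    fullSig <- full$protein_id[full$significant]
    frac <- ifelse(nTested > 0, nSig / length(pairs), NA_real_)
    tally <- S4Vectors::DataFrame(protein_id = ids,
        n_tested = unname(nTested), n_significant = unname(nSig),
        fraction = unname(frac))
    everywhere <- nTested == length(pairs)
    powered <- ids[everywhere & !is.na(frac) & frac > powerThreshold]
    flagged <- ids[!is.na(frac) & frac > type1Threshold &
        !(ids %in% fullSig)]
    new("SubsampleReport", k = as.integer(k),
        nCombos = length(pairs), fdr = fdr,
        powerThreshold = powerThreshold, type1Threshold = type1Threshold,
        tally = tally, poweredSet = powered, type1Flagged = flagged,
        fullSignificant = as.character(fullSig))
}

#' Power curve over replicate depth
#'
#' Counts the power-classified proteins at each subsampled replicate
#' depth and appends the full-design significant count.
#'
#' @param reports list of [SubsampleReport-class] objects for at least
#'   two values of k (same experiment).
#' @param fullK replicate depth of the full design (default: max k + 1
#'   if the reports come from an n = max(k)+1 design, otherwise supply
#'   explicitly).
#' @return a \code{data.frame} with columns \code{k}, \code{n_combos},
#'   \code{n_powered}; the final row is the full design (one comparison,
#'   count = full-design significant set).
#' @export
powerCurve <- function(reports, fullK = max(vapply(reports, slot,
    integer(1), "k")) + 1L) {
    if (length(reports) < 2)
        stop("need reports for >= 2 replicate depths")
    ks <- vapply(reports, slot, integer(1), "k")
    out <- data.frame(k = ks,
        n_combos = vapply(reports, slot, integer(1), "nCombos"),
        n_powered = vapply(reports, function(r)
            length(r@poweredSet), integer(1)))
    out <- out[order(out$k), ]
    full <- data.frame(k = fullK, n_combos = 1L,
        n_powered = length(reports[[1]]@fullSignificant))
    rbind(out, full)
}

#' Cross-depth Type-I error flags
#'
#' The Type-I check of the subsampling procedure asks for proteins that
#' look significant at low replication but never at high replication:
#' significant in more than the tally threshold of the 2- or 3-replicate
#' comparisons, while significant neither in the full design nor in any
#' of the 4-replicate comparisons. Per-report flags
#' ([type1Flagged()]) already exclude the full-design significant set;
#' this function additionally removes proteins that reach significance
#' in any comparison of the high-depth report.
#'
#' @param lowReports list of [SubsampleReport-class] objects at low
#'   replicate depth (typically k = 2 and k = 3).
#' @param highReport a [SubsampleReport-class] at high depth (typically
#'   k = 4) from the same experiment.
#' @return character vector of flagged protein ids.
#' @export
crossDepthTypeIFlags <- function(lowReports, highReport) {
    low <- unique(unlist(lapply(lowReports, type1Flagged)))
    tal <- subsampleTally(highReport)
    setdiff(low, tal$protein_id[tal$n_significant > 0])
}
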