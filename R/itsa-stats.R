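#' Confidence filtering of a quantification table
#'
#' Retains proteins identified with high confidence: at least
#' \code{minUniquePeptides} unique peptides, at least \code{minMSMS}
#' MS/MS spectra, and at least \code{minValidValues} valid (non-missing)
#' reporter intensities across the samples. Rows flagged as reverse-decoy
#' or potential contaminant are dropped. Row order is preserved; an empty
#' result is allowed.
#'
#' @param x a [ThermalQuant-class].
#' @param minUniquePeptides,minMSMS,minValidValues integer thresholds
#'   (defaults 1, 2, 2).
#' @return the filtered [ThermalQuant-class].
#' @export
filterHighConfidence <- function(x, minUniquePeptides = 1L, minMSMS = 2L,
    minValidValues = 2L) {
    rd <- SummarizedExperiment::rowData(x)
    valid <- rowSums(!is.na(SummarizedExperiment::assay(x, "intensity")))
    keep <- rd$unique_peptides >= minUniquePeptides &
        rd$msms_count >= minMSMS & valid >= minValidValues
    if (!is.null(rd$reverse)) keep <- keep & !rd$reverse
    if (!is.null(rd$contaminant)) keep <- keep & !rd$contaminant
    x[keep, ]
}

#' Quantile normalization with missing values
#'
#' Maps each column's values, by rank, onto the across-column mean of
#' order statistics (the reference distribution). Missing values are
#' excluded from rank computation and remain missing; columns with
#' unequal numbers of present values are aligned to the reference by
#' linear interpolation on the quantile scale. Ties receive the average
#' rank. When all columns are complete, every column afterwards carries
#' the identical multiset of values, and the map is idempotent.
#'
#' Columns with fewer than two present values cannot be rank-mapped; they
#' are excluded from the reference distribution, left unchanged, and
#' flagged with a warning.
#'
#' @param x numeric matrix (any scale; typically log2 intensities) with
#'   \code{NA} for missing entries and at least 2 columns.
#' @return the normalized matrix, same dimensions and \code{NA} pattern.
#' @export
quantileNormalize <- function(x) {
    x <- as.matrix(x)
    if (ncol(x) < 2) stop("quantile normalization needs >= 2 samples")
    nPresent <- colSums(!is.na(x))
    usable <- nPresent >= 2
    if (!all(usable))
        warning("column(s) with < 2 present values left unnormalized: ",
            paste(colnames(x)[!usable], collapse = ", "))
    n <- nrow(x)
    grid <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0.5
    quants <- vapply(which(usable), function(j) {
        s <- sort(x[, j])          # drops NA
        m <- length(s)
        if (m == n) s else approx((seq_len(m) - 1) / (m - 1), s, grid)$y
    }, numeric(n))
    ref <- rowMeans(quants)
    out <- x
    for (j in which(usable)) {
        present <- !is.na(x[, j])
        m <- sum(present)
        r <- rank(x[present, j], ties.method = "average")
        out[present, j] <- approx(grid, ref, xout = (r - 1) / (m - 1))$y
    }
    out
}

#' Log2-transform and quantile-normalize a quantification table
#'
#' @param x a [ThermalQuant-class] with positive (or missing) intensities.
#' @return numeric matrix of normalized log2 intensities.
#' @seealso [quantileNormalize()]
#' @export
normalizeLog2 <- function(x) {
    a <- SummarizedExperiment::assay(x, "intensity")
    if (any(a <= 0, na.rm = TRUE))
        stop("intensities must be positive; encode missing values as NA")
    quantileNormalize(log2(a))
}

# Newton inversion of the trigamma function (decreasing, convex on (0,Inf))
.trigammaInverse <- function(x) {
    if (x <= 0) stop("trigamma inverse requires a positive argument")
    if (x > 1e7) return(1 / sqrt(x))
    if (x < 1e-6) return(1 / x)
    y <- 0.5 + 1 / x
    for (i in 1:50) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, 2L)
        y <- y + dif
        if (abs(dif) / y < 1e-10) break
    }
    y
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits the scaled-F model for per-protein sample variances,
#' \eqn{s_i^2 \sim s_0^2 F(d_i, d_0)}, by moment-matching on the log
#' scale using digamma/trigamma closed forms: the excess dispersion of
#' \eqn{\log s_i^2} beyond what the residual degrees of freedom explain
#' determines \eqn{d_0}, and the location determines \eqn{s_0^2}. When the
#' observed log-variances are no more dispersed than sampling alone
#' predicts, \eqn{d_0 = \infty} (full shrinkage to a common variance).
#'
#' @param s2 numeric vector of per-protein sample variances.
#' @param df numeric vector of the corresponding residual degrees of
#'   freedom (recycled if length 1). At least 10 proteins with
#'   \code{df >= 1} and \code{s2 > 0} are required.
#' @return a [VariancePrior-class].
#' @export
estimateVariancePrior <- function(s2, df) {
    df <- rep_len(df, length(s2))
    ok <- is.finite(s2) & is.finite(df) & df >= 1
    if (sum(ok) && all(s2[ok] == 0))
        stop("degenerate data: all sample variances are zero")
    ok <- ok & s2 > 0
    if (sum(ok) < 10)
        stop("need >= 10 proteins with df >= 1 and positive variance")
    s2 <- s2[ok]; df <- df[ok]
    e <- log(s2) - digamma(df / 2) + log(df / 2)
    excess <- var(e) - mean(trigamma(df / 2))
    if (excess > 0) {
        d0 <- 2 * .trigammaInverse(excess)
        s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
        d0 <- Inf
        s0sq <- exp(mean(e))
    }
    VariancePrior(d0 = d0, s0sq = s0sq)
}

#' Moderated two-sample t-test
#'
#' Per protein: the log2 fold change is \code{mean(drug) - mean(vehicle)}
#' over present values; the pooled sample variance \eqn{s^2} has residual
#' degrees of freedom \eqn{d = n_1 + n_2 - 2}; the posterior variance
#' shrinks it toward the prior,
#' \eqn{\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)}; the moderated
#' statistic is \eqn{\tilde t = \Delta / (\tilde s \sqrt{1/n_1 + 1/n_2})}
#' with two-sided p-values from a t distribution on \eqn{d_0 + d} degrees
#' of freedom. With \eqn{d_0 = 0} this is the ordinary pooled t-test; with
#' \eqn{d_0 = \infty} all proteins share the prior variance.
#'
#' Proteins with fewer than two present values in either condition are
#' reported untested (\code{tested = FALSE}, statistics \code{NA}) rather
#' than imputed.
#'
#' @param x numeric matrix of normalized log2 intensities
#'   (proteins x samples), rownames = protein ids.
#' @param condition character vector over columns, values
#'   \code{"vehicle"}/\code{"drug"}; both must occur.
#' @param prior a [VariancePrior-class].
#' @return a [S4Vectors::DataFrame] with columns \code{protein_id},
#'   \code{log2_fc} (drug minus vehicle; positive = stabilized),
#'   \code{avg_log2_intensity}, \code{s_sq}, \code{df_resid},
#'   \code{t_mod}, \code{df_total}, \code{p_value}, \code{tested}.
#' @export
moderatedTTest <- function(x, condition, prior) {
    st <- .moderatedStats(x, condition, prior)
    out <- with(st, S4Vectors::DataFrame(
        protein_id = if (is.null(rownames(x)))
            sprintf("row%d", seq_len(nrow(x))) else rownames(x),
        log2_fc = unname(ifelse(tested, fc, NA_real_)),
        avg_log2_intensity = unname(rowMeans(x, na.rm = TRUE)),
        s_sq = unname(s2),
        df_resid = unname(ifelse(tested, dfRes, NA_real_)),
        t_mod = unname(ifelse(tested, tmod, NA_real_)),
        df_total = unname(ifelse(tested, dfTot, NA_real_)),
        p_value = unname(ifelse(tested, p, NA_real_)),
        tested = unname(tested)))
    rownames(out) <- out$protein_id
    out
}

# numeric core of the moderated test, shared with the subsampling fast path
.moderatedStats <- function(x, condition, prior) {
    if (length(condition) != ncol(x))
        stop("design error: 'condition' must label every column")
    if (!all(condition %in% c("vehicle", "drug")) ||
        length(unique(condition)) < 2)
        stop("design error: both 'vehicle' and 'drug' samples are required")
    v <- x[, condition == "vehicle", drop = FALSE]
    d <- x[, condition == "drug", drop = FALSE]
    n1 <- rowSums(!is.na(v)); n2 <- rowSums(!is.na(d))
    m1 <- rowMeans(v, na.rm = TRUE); m2 <- rowMeans(d, na.rm = TRUE)
    ss <- rowSums((v - m1)^2, na.rm = TRUE) +
        rowSums((d - m2)^2, na.rm = TRUE)
    dfRes <- n1 + n2 - 2
    tested <- n1 >= 2 & n2 >= 2
    s2 <- ifelse(tested, ss / dfRes, NA_real_)
    d0 <- priorDf(prior); s0 <- priorVar(prior)
    s2post <- if (is.infinite(d0)) rep(s0, nrow(x)) else
        (d0 * s0 + dfRes * s2) / (d0 + dfRes)
    fc <- m2 - m1
    tmod <- fc / sqrt(s2post * (1 / n1 + 1 / n2))
    dfTot <- d0 + dfRes
    # guard against underflow: p-values are defined on (0, 1]
    p <- pmax(2 * pt(-abs(tmod), dfTot), .Machine$double.xmin)
    list(fc = fc, s2 = s2, dfRes = dfRes, tmod = tmod, dfTot = dfTot,
        p = p, tested = tested)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: \eqn{q_i = \min_{j: rank(j) \ge rank(i)}
#' p_{(j)} m / j}, capped at 1 and order-preserving.
#'
#' @param p numeric vector of p-values in \code{(0, 1]}.
#' @return numeric vector of q-values, same order.
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p <= 0) || any(p > 1))
        stop("p-values must lie in (0, 1]")
    p.adjust(p, method = "BH")
}

#' Classify and rank moderated-test results
#'
#' Adds BH q-values (computed over the tested proteins), calls a protein
#' significant iff \code{q_value < qCutoff} (strict, matching an
#' "FDR < cutoff" rule) and \code{|log2_fc| >= fcCutoff}, and ranks by
#' q-value then absolute fold change.
#'
#' @param results output of [moderatedTTest()].
#' @param qCutoff q-value cutoff (strict \code{<}); default 0.001.
#' @param fcCutoff absolute log2-fold-change cutoff (\code{>=});
#'   default 0, i.e. classification on q alone.
#' @return \code{results} with added columns \code{q_value},
#'   \code{significant} and \code{rank}, sorted by rank (untested
#'   proteins last, \code{significant = FALSE}).
#' @export
classifyAndRank <- function(results, qCutoff = 0.001, fcCutoff = 0) {
    q <- rep(NA_real_, nrow(results))
    q[results$tested] <- bhAdjust(results$p_value[results$tested])
    results$q_value <- q
    results$significant <- !is.na(q) & q < qCutoff &
        abs(results$log2_fc) >= fcCutoff
    ord <- order(q, -abs(results$log2_fc), na.last = TRUE)
    results <- results[ord, ]
    results$rank <- seq_len(nrow(results))
    results
}

#' Volcano-plot table
#'
#' @param results output of [classifyAndRank()].
#' @return a [S4Vectors::DataFrame] with \code{protein_id},
#'   \code{log2_fc}, \code{neg_log10_q}, \code{significant}.
#' @export
volcanoTable <- function(results) {
    S4Vectors::DataFrame(protein_id = results$protein_id,
        log2_fc = results$log2_fc,
        neg_log10_q = -log10(results$q_value),
        significant = results$significant)
}

#' Run the full isothermal shift analysis
#'
#' Confidence filtering, log2 transform, quantile normalization,
#' empirical-Bayes variance-prior estimation, moderated two-sample
#' testing, BH correction and significance classification, in that order.
#'
#' @param x a [ThermalQuant-class] from a single-temperature design.
#' @param qCutoff,fcCutoff significance cutoffs, see [classifyAndRank()].
#' @param normalize logical; set \code{FALSE} to skip quantile
#'   normalization (log2 transform only), e.g. for noiseless data where
#'   exact fold-change recovery is wanted.
#' @param minUniquePeptides,minMSMS,minValidValues filter thresholds, see
#'   [filterHighConfidence()].
#' @return the classified results table (see [classifyAndRank()]).
#' @examples
#' cfg <- simConfig(nProteins = 300, seed = 11)
#' truth <- sampleProteome(cfg)
#' tq <- simulateIsothermal(truth, config = cfg)
#' res <- runITSA(tq)
#' head(res[res$significant, c("protein_id", "log2_fc", "q_value")])
#' @export
runITSA <- function(x, qCutoff = 0.001, fcCutoff = 0, normalize = TRUE,
    minUniquePeptides = 1L, minMSMS = 2L, minValidValues = 2L) {
    x <- filterHighConfidence(x, minUniquePeptides, minMSMS, minValidValues)
    .itsaCore(SummarizedExperiment::assay(x, "intensity"),
        SummarizedExperiment::colData(x)$condition,
        qCutoff = qCutoff, fcCutoff = fcCutoff, normalize = normalize)
}

# the post-filter pipeline on a raw intensity matrix; shared by runITSA
# and the subsampling fast path so both produce identical results
.itsaCore <- function(a, condition, qCutoff, fcCutoff = 0,
    normalize = TRUE) {
    if (any(a <= 0, na.rm = TRUE))
        stop("intensities must be positive; encode missing values as NA")
    m <- log2(a)
    if (normalize) m <- quantileNormalize(m)
    v <- m[, condition == "vehicle", drop = FALSE]
    d <- m[, condition == "drug", drop = FALSE]
    n1 <- rowSums(!is.na(v)); n2 <- rowSums(!is.na(d))
    testable <- n1 >= 2 & n2 >= 2
    s2 <- (rowSums((v - rowMeans(v, na.rm = TRUE))^2, na.rm = TRUE) +
        rowSums((d - rowMeans(d, na.rm = TRUE))^2, na.rm = TRUE)) /
        (n1 + n2 - 2)
    prior <- estimateVariancePrior(s2[testable], (n1 + n2 - 2)[testable])
    res <- moderatedTTest(m, condition, prior)
    classifyAndRank(res, qCutoff = qCutoff, fcCutoff = fcCutoff)
}
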