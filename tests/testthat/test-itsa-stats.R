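test_that("confidence filter applies all three evidence thresholds", {
    m <- matrix(2^rnorm(40, 20), 4, 10)
    m[3, ] <- 2^rnorm(10, 20)
    m[4, 3:10] <- NA                       # only 2 valid values -> row 4
    m[4, 1:2] <- 2^20
    tq <- makeQuant(m, uniquePeptides = c(1L, 0L, 2L, 2L),
        msms = c(5L, 9L, 1L, 3L))
    # rows: (1,5,10 keep) (0,9,10 drop) (2,1,10 drop) (2,3,2 keep: 2 valid)
    kept <- filterHighConfidence(tq)
    expect_equal(rownames(kept), c("P001", "P004"))
    m[4, ] <- 2^20
    tq2 <- makeQuant(m, uniquePeptides = c(1L, 0L, 2L, 2L),
        msms = c(5L, 9L, 1L, 3L))
    kept2 <- filterHighConfidence(tq2, minValidValues = 10)
    expect_equal(rownames(kept2), c("P001", "P004"))
    # all passing -> identity; empty result allowed
    allPass <- makeQuant(matrix(2^20, 3, 10))
    expect_equal(nrow(filterHighConfidence(allPass)), 3L)
    expect_equal(nrow(filterHighConfidence(allPass, minMSMS = 99L)), 0L)
})

test_that("reverse and contaminant rows are dropped at filtering", {
    m <- matrix(2^20, 3, 10)
    tq <- makeQuant(m)
    rd <- SummarizedExperiment::rowData(tq)
    rd$reverse <- c(TRUE, FALSE, FALSE)
    rd$contaminant <- c(FALSE, TRUE, FALSE)
    SummarizedExperiment::rowData(tq) <- rd
    expect_equal(rownames(filterHighConfidence(tq)), "P003")
})

test_that("quantile normalization maps ranks to mean order statistics", {
    # hand-computed: log2 columns (2,4,6) and (1,3,5) -> both (1.5,3.5,5.5)
    x <- cbind(c(4, 16, 64), c(2, 8, 32))
    out <- quantileNormalize(log2(x))
    expect_equal(out[, 1], c(1.5, 3.5, 5.5))
    expect_equal(out[, 2], c(1.5, 3.5, 5.5))
    # original rank order preserved under permutation
    x2 <- cbind(c(16, 4, 64), c(2, 8, 32))
    out2 <- quantileNormalize(log2(x2))
    expect_equal(out2[, 1], c(3.5, 1.5, 5.5))
    # identical columns unchanged
    same <- cbind(c(1, 5, 9), c(1, 5, 9))
    expect_equal(quantileNormalize(same), same)
    # idempotence of the rank map
    set.seed(1)
    r <- matrix(rnorm(60), 20, 3)
    once <- quantileNormalize(r)
    expect_equal(quantileNormalize(once), once)
    # missing values stay missing and are excluded from the reference
    r[3, 1] <- NA
    outNA <- quantileNormalize(r)
    expect_true(is.na(outNA[3, 1]))
    expect_equal(sum(is.na(outNA)), 1L)
    # a column with < 2 present values is flagged and left unnormalized
    r2 <- r; r2[2:20, 2] <- NA
    expect_warning(quantileNormalize(r2), "unnormalized")
})

test_that("quantile normalization matches limma on complete data", {
    set.seed(42)
    x <- matrix(rnorm(200, 20, 2), 50, 4)
    expect_equal(quantileNormalize(x),
        limma::normalizeQuantiles(x), ignore_attr = TRUE)
})

test_that("variance-prior estimation recovers known hyperparameters", {
    set.seed(77)
    d0 <- 4; s0sq <- 0.04; d <- 8; n <- 5000
    sg2 <- s0sq * d0 / rchisq(n, d0)
    s2 <- sg2 * rchisq(n, d) / d
    pr <- estimateVariancePrior(s2, d)
    expect_lt(abs(priorDf(pr) - d0) / d0, 0.2)
    expect_lt(abs(priorVar(pr) - s0sq) / s0sq, 0.1)
    # determinism
    pr2 <- estimateVariancePrior(s2, d)
    expect_identical(priorDf(pr), priorDf(pr2))
    # constant variances -> no excess dispersion -> full shrinkage
    prC <- estimateVariancePrior(rep(0.5, 100), 8)
    expect_identical(priorDf(prC), Inf)
    # location of the moment-matched log-variance model at df = 8:
    # E[log s^2] = log s0^2 + digamma(d/2) - log(d/2)
    expect_equal(priorVar(prC), 0.5 * exp(log(4) - digamma(4)),
        tolerance = 1e-12)
    expect_error(estimateVariancePrior(rep(0, 50), 8), "degenerate")
    expect_error(estimateVariancePrior(c(0.1, 0.2), c(8, 8)), ">= 10")
})

test_that("variance-prior estimation agrees with limma's fit", {
    set.seed(12)
    s2 <- 0.02 * 6 / rchisq(3000, 6) * rchisq(3000, 8) / 8
    pr <- estimateVariancePrior(s2, 8)
    sq <- limma::squeezeVar(s2, df = 8)
    expect_equal(priorDf(pr), sq$df.prior, tolerance = 1e-6)
    expect_equal(priorVar(pr), sq$var.prior, tolerance = 1e-6)
})

test_that("moderated t reduces to the pooled two-sample t at d0 = 0", {
    set.seed(3)
    x <- matrix(rnorm(80, 20), 8, 10)
    rownames(x) <- sprintf("P%03d", 1:8)
    cond <- rep(c("vehicle", "drug"), each = 5)
    res <- moderatedTTest(x, cond, VariancePrior(d0 = 1e-300, s0sq = 1))
    for (i in 1:8) {
        tt <- t.test(x[i, 6:10], x[i, 1:5], var.equal = TRUE)
        expect_equal(res$t_mod[i], unname(tt$statistic), tolerance = 1e-8)
        expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-8)
    }
})

test_that("moderated t matches an independent implementation (limma)", {
    # heterogeneous true variances so the estimated prior df is small
    # and limma's pooled-df cap on df.total never binds
    set.seed(8)
    sg <- sqrt(0.04 * 5 / rchisq(60, 5))
    x <- matrix(rnorm(600, 20, rep(sg, 10)), 60, 10)
    rownames(x) <- sprintf("P%03d", 1:60)
    cond <- rep(c("vehicle", "drug"), each = 5)
    design <- cbind(Intercept = 1, drug = as.numeric(cond == "drug"))
    fit <- limma::eBayes(limma::lmFit(x, design))
    prior <- VariancePrior(d0 = fit$df.prior, s0sq = fit$s2.prior)
    res <- moderatedTTest(x, cond, prior)
    expect_lt(fit$df.prior + 8, sum(fit$df.residual))  # cap not binding
    expect_equal(res$log2_fc, unname(fit$coefficients[, "drug"]),
        tolerance = 1e-10)
    expect_equal(res$t_mod, unname(fit$t[, "drug"]), tolerance = 1e-10)
    expect_equal(res$p_value, unname(fit$p.value[, "drug"]),
        tolerance = 1e-10)
})

test_that("moderated t handles degenerate designs and sparse proteins", {
    x <- matrix(rnorm(40, 20), 4, 10)
    expect_error(moderatedTTest(x, rep("vehicle", 10),
        VariancePrior(4, 0.02)), "design error")
    # equal group means -> t = 0, p = 1
    y <- matrix(rep(c(1, 2, 3, 4, 5), 2), 1, 10)
    rownames(y) <- "P001"
    r <- moderatedTTest(y, rep(c("vehicle", "drug"), each = 5),
        VariancePrior(4, 0.02))
    expect_equal(r$t_mod, 0)
    expect_equal(r$p_value, 1)
    # fewer than 2 present values per group -> untested, not imputed
    z <- matrix(rnorm(20, 20), 2, 10)
    z[1, 6:9] <- NA
    rownames(z) <- c("P001", "P002")
    r2 <- moderatedTTest(z, rep(c("vehicle", "drug"), each = 5),
        VariancePrior(4, 0.02))
    expect_false(r2$tested[1])
    expect_true(is.na(r2$p_value[1]))
    expect_true(r2$tested[2])
})

test_that("shrinkage interpolates between ordinary and fully shrunk t", {
    set.seed(21)
    x <- matrix(rnorm(300, 0, rep(c(0.5, 1, 2), 10)), 30, 10)
    rownames(x) <- sprintf("P%03d", 1:30)
    cond <- rep(c("vehicle", "drug"), each = 5)
    n1 <- 5; n2 <- 5
    s2 <- apply(x, 1, function(v)
        (sum((v[1:5] - mean(v[1:5]))^2) +
         sum((v[6:10] - mean(v[6:10]))^2)) / 8)
    pr <- estimateVariancePrior(s2, 8)
    tMod <- moderatedTTest(x, cond, pr)$t_mod
    tOrd <- moderatedTTest(x, cond, VariancePrior(1e-300, 1))$t_mod
    tShr <- moderatedTTest(x, cond, VariancePrior(Inf, priorVar(pr)))$t_mod
    expect_true(all(abs(tMod) <= pmax(abs(tOrd), abs(tShr)) + 1e-12))
})

test_that("BH adjustment follows the step-up definition", {
    # hand application: p = (.01,.02,.03,.04), m = 4 -> all q = 0.04
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
    expect_equal(bhAdjust(0.37), 0.37)
    expect_error(bhAdjust(c(0.5, 0)), "0, 1")
    expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
    # brute-force oracle on random vectors
    set.seed(14)
    for (i in 1:5) {
        p <- runif(40)^2
        expect_equal(bhAdjust(p), bhBruteForce(p), tolerance = 1e-12)
    }
})

test_that("significance classification uses strict q and |fc| cutoffs", {
    res <- S4Vectors::DataFrame(
        protein_id = c("A", "B", "C", "D"),
        log2_fc = c(1.2, -0.8, 0.05, 2),
        avg_log2_intensity = 20, s_sq = 0.01, df_resid = 8,
        t_mod = c(9, -7, 1, 11), df_total = 12,
        p_value = c(1e-6, 2e-6, 0.5, 4e-7), tested = TRUE)
    out <- classifyAndRank(res, qCutoff = 1e-5, fcCutoff = 0.5)
    expect_equal(sort(out$q_value), sort(bhAdjust(res$p_value)))
    # C has q far above the cutoff; A, B, D below it and |fc| >= 0.5
    expect_false(out$significant[out$protein_id == "C"])
    expect_equal(sum(out$significant), 3L)
    # q exactly equal to the cutoff is NOT significant (strict <)
    two <- S4Vectors::DataFrame(protein_id = c("X", "Y"),
        log2_fc = c(1, 1), avg_log2_intensity = 20, s_sq = 0.01,
        df_resid = 8, t_mod = c(5, 1), df_total = 12,
        p_value = c(0.001, 0.5), tested = TRUE)
    exact <- classifyAndRank(two, qCutoff = 0.002, fcCutoff = 0)
    expect_equal(exact$q_value[exact$protein_id == "X"], 0.002)
    expect_false(exact$significant[exact$protein_id == "X"])
    expect_true(classifyAndRank(two, qCutoff = 0.0021,
        fcCutoff = 0)$significant[1])
    # fcCutoff respected
    out2 <- classifyAndRank(res, qCutoff = 0.05, fcCutoff = 1.5)
    expect_equal(out2$protein_id[out2$significant], "D")
    # fcCutoff = 0: classification on q alone
    out3 <- classifyAndRank(res, qCutoff = 0.05, fcCutoff = 0)
    expect_equal(sort(out3$protein_id[out3$significant]),
        c("A", "B", "D"))
    # ranked by q then |fc|
    expect_equal(out3$rank, seq_len(4))
    expect_true(all(diff(out3$q_value) >= 0))
})

test_that("noiseless pipeline recovers the model-implied log2 ratios", {
    cfg <- quietConfig(nProteins = 60, targetFraction = 0.25, seed = 19)
    truth <- sampleProteome(cfg)
    tq <- simulateIsothermal(truth, config = cfg)
    # fully noiseless data have zero within-group variance everywhere:
    # the ensemble prior is then undefined by construction
    expect_error(runITSA(tq, normalize = FALSE), "degenerate")
    m <- log2(SummarizedExperiment::assay(filterHighConfidence(tq),
        "intensity"))
    res <- moderatedTTest(m,
        SummarizedExperiment::colData(tq)$condition,
        VariancePrior(Inf, 1))
    fV <- fractionSoluble(vehicleCurves(truth), 52)
    fD <- fractionSoluble(drugCurves(truth), 52)
    expected <- log2(fD / fV)
    keep <- truth$protein_id %in% res$protein_id   # confidence-filtered
    got <- res$log2_fc[match(truth$protein_id[keep], res$protein_id)]
    expect_equal(got, expected[keep], tolerance = 1e-10)
})

test_that("volcano table carries fold change against -log10 q", {
    cfg <- simConfig(nProteins = 200, seed = 2)
    truth <- sampleProteome(cfg)
    res <- runITSA(simulateIsothermal(truth, config = cfg), qCutoff = 0.01)
    v <- volcanoTable(res)
    expect_equal(v$neg_log10_q, -log10(res$q_value))
    expect_identical(v$significant, res$significant)
})
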