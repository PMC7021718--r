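#' Simulation configuration
#'
#' Bundles the parameters of the ground-truthed thermal-proteome
#' generator. Defaults emulate the statistical structure of a K562-lysate
#' TMT experiment: a proteome melting-temperature distribution with median
#' 52 C and interquartile range ~48-56 C, a ~1% minority of drug targets
#' with Tm shifts of +4 C on average (sd 2, so negative/destabilizing
#' shifts can occur), log-normal protein abundance, multiplicative
#' log-normal reporter-ion noise, abundance-dependent MS/MS counts, and
#' intensity-dependent (logistic in log2 intensity) dropout.
#'
#' @param nProteins number of proteins (>= 1).
#' @param targetFraction fraction of proteins that are drug targets, in
#'   \code{[0, 1]}.
#' @param tmMedian,tmIQR median and interquartile range (degrees C) of the
#'   vehicle Tm distribution, a normal truncated to \code{[37, 70]} with
#'   \code{sigma = tmIQR/1.349}.
#' @param deltaTmMean,deltaTmSd mean and sd (degrees C) of the normal
#'   distribution of true Tm shifts among targets.
#' @param assayTemperature isothermal assay temperature in degrees C.
#' @param replicatesPerCondition isothermal replicates per condition
#'   (>= 2).
#' @param gradientTemperatures temperature grid (degrees C) of the
#'   gradient design; defaults to the ten-point set
#'   37, 41.2, 44, 46.8, 50, 53.2, 56.1, 59.1, 63.2, 66.9.
#' @param gradientReplicates gradient replicates per condition.
#' @param noiseCV coefficient of variation of the multiplicative
#'   reporter-ion noise (0 = noiseless).
#' @param dropoutMidpoint,dropoutScale logistic dropout parameters on the
#'   log2-intensity scale: \code{P(missing) = plogis((dropoutMidpoint -
#'   log2 I)/dropoutScale)}. Set \code{dropoutMidpoint = -Inf} to disable
#'   missingness.
#' @param abundanceLog2Mean,abundanceLog2Sd mean and sd of log2 protein
#'   abundance (arbitrary reporter units).
#' @param bRange range of the dimensionless curve offset \code{b}
#'   (uniform); together with Tm this sets the transition steepness.
#' @param plateauRange range of the high-temperature residual soluble
#'   fraction (uniform), kept below 0.5 so every simulated curve has a Tm.
#' @param msmsRate,peptideRate Poisson-rate multipliers tying MS/MS and
#'   unique-peptide counts to log2 abundance (rate =
#'   \code{rate * pmax(log2(abundance) - 12, 0.5)}).
#' @param seed integer seed; fully determines all generator output.
#' @return a validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(nProteins = 6000L, targetFraction = 0.01,
    tmMedian = 52, tmIQR = 8, deltaTmMean = 4, deltaTmSd = 2,
    assayTemperature = 52, replicatesPerCondition = 5L,
    gradientTemperatures = c(37, 41.2, 44, 46.8, 50, 53.2, 56.1, 59.1,
        63.2, 66.9),
    gradientReplicates = 2L, noiseCV = 0.05,
    dropoutMidpoint = 14, dropoutScale = 1.5,
    abundanceLog2Mean = 20, abundanceLog2Sd = 2,
    bRange = c(12, 18), plateauRange = c(0, 0.15),
    msmsRate = 2.5, peptideRate = 0.6, seed = 1L) {
    cfg <- list(nProteins = as.integer(nProteins),
        targetFraction = targetFraction, tmMedian = tmMedian,
        tmIQR = tmIQR, deltaTmMean = deltaTmMean, deltaTmSd = deltaTmSd,
        assayTemperature = assayTemperature,
        replicatesPerCondition = as.integer(replicatesPerCondition),
        gradientTemperatures = gradientTemperatures,
        gradientReplicates = as.integer(gradientReplicates),
        noiseCV = noiseCV, dropoutMidpoint = dropoutMidpoint,
        dropoutScale = dropoutScale,
        abundanceLog2Mean = abundanceLog2Mean,
        abundanceLog2Sd = abundanceLog2Sd,
        bRange = bRange, plateauRange = plateauRange,
        msmsRate = msmsRate, peptideRate = peptideRate,
        seed = as.integer(seed))
    if (cfg$nProteins < 1L)
        stop("invalid config: 'nProteins' must be >= 1")
    if (cfg$targetFraction < 0 || cfg$targetFraction > 1)
        stop("invalid config: 'targetFraction' must be in [0, 1]")
    if (cfg$tmIQR <= 0 || cfg$tmMedian <= 0)
        stop("invalid config: Tm distribution parameters must be positive")
    if (cfg$replicatesPerCondition < 1L || cfg$gradientReplicates < 1L)
        stop("invalid config: replicate counts must be >= 1")
    if (cfg$noiseCV < 0)
        stop("invalid config: 'noiseCV' must be >= 0")
    if (cfg$plateauRange[2] >= 0.5)
        stop("invalid config: plateaus must stay below 0.5")
    if (is.na(cfg$seed))
        stop("invalid config: 'seed' must be an integer")
    structure(cfg, class = "SimConfig")
}

#' Draw a ground-truth proteome
#'
#' Samples per-protein melting-curve parameters, abundances and target
#' status. Vehicle Tm values are drawn from a normal distribution with
#' median \code{tmMedian} and IQR \code{tmIQR} truncated to
#' \code{[37, 70]} C; a fraction \code{targetFraction} of proteins are
#' targets whose drug-condition Tm is shifted by a normal
#' \code{(deltaTmMean, deltaTmSd)} amount. Drug curves share \code{b} and
#' \code{plateau} with the vehicle curve; only \code{a} is adjusted so the
#' Tm moves by exactly the drawn shift.
#'
#' @param config a [simConfig()] list; \code{config$seed} fully
#'   determines the output.
#' @return a [S4Vectors::DataFrame] with columns \code{protein_id},
#'   \code{a}, \code{b}, \code{plateau}, \code{tm_vehicle},
#'   \code{delta_tm_true}, \code{abundance}, \code{is_target}.
#' @seealso [vehicleCurves()], [drugCurves()]
#' @export
sampleProteome <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed)
    n <- config$nProteins
    sigma <- config$tmIQR / (2 * qnorm(0.75))   # IQR of a normal = 1.349 sd
    lo <- pnorm(37, config$tmMedian, sigma)
    hi <- pnorm(70, config$tmMedian, sigma)
    tm <- qnorm(runif(n, lo, hi), config$tmMedian, sigma)
    b <- runif(n, config$bRange[1], config$bRange[2])
    plateau <- runif(n, config$plateauRange[1], config$plateauRange[2])
    abundance <- 2^rnorm(n, config$abundanceLog2Mean, config$abundanceLog2Sd)
    nTargets <- round(config$targetFraction * n)
    isTarget <- rep(FALSE, n)
    if (nTargets > 0)
        isTarget[sample.int(n, nTargets)] <- TRUE
    delta <- numeric(n)
    delta[isTarget] <- rnorm(nTargets, config$deltaTmMean, config$deltaTmSd)
    # a follows from Tm: Tm = a / (b + log(1 - 2 plateau))
    a <- tm * (b + log(1 - 2 * plateau))
    S4Vectors::DataFrame(
        protein_id = sprintf("P%05d", seq_len(n)),
        a = a, b = b, plateau = plateau, tm_vehicle = tm,
        delta_tm_true = delta, abundance = abundance,
        is_target = isTarget)
}

#' Melting curves of a ground-truth proteome
#'
#' @param truth a proteome from [sampleProteome()].
#' @return a [MeltCurve-class]: vehicle-condition curves
#'   (\code{vehicleCurves}) or drug-condition curves with each target's Tm
#'   shifted by its true shift (\code{drugCurves}).
#' @export
vehicleCurves <- function(truth) {
    MeltCurve(truth$a, truth$b, truth$plateau)
}

#' @rdname vehicleCurves
#' @export
drugCurves <- function(truth) {
    tmDrug <- truth$tm_vehicle + truth$delta_tm_true
    if (any(tmDrug <= 0))
        stop("drug-condition Tm must remain positive")
    MeltCurve(tmDrug * (truth$b + log(1 - 2 * truth$plateau)),
        truth$b, truth$plateau)
}

# multiplicative log-normal noise with mean 1 and the requested CV
.reporterNoise <- function(n, cv) {
    if (cv == 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + cv^2))
    exp(rnorm(n, -sdlog^2 / 2, sdlog))
}

# evidence counts scale with log-abundance (MS/MS sampling bias)
.evidenceCounts <- function(abundance, config) {
    depth <- pmax(log2(abundance) - 12, 0.5)
    list(msms = rpois(length(abundance), config$msmsRate * depth),
        peptides = rpois(length(abundance), config$peptideRate * depth))
}

.applyDropout <- function(intensity, config) {
    if (!is.finite(config$dropoutMidpoint)) return(intensity)
    pMiss <- plogis((config$dropoutMidpoint - log2(intensity)) /
        config$dropoutScale)
    intensity[runif(length(intensity)) < pMiss] <- NA_real_
    intensity
}

#' Simulate an isothermal (iTSA) experiment
#'
#' Generates a vehicle-vs-drug reporter-intensity table at a single assay
#' temperature. Each intensity is
#' \code{abundance * fractionSoluble(condition curve, T) * noise}, with
#' multiplicative log-normal noise of coefficient of variation
#' \code{config$noiseCV}, Poisson evidence counts increasing with
#' abundance, and logistic intensity-dependent dropout.
#'
#' @param truth a proteome from [sampleProteome()].
#' @param temperature assay temperature in degrees C (default
#'   \code{config$assayTemperature}).
#' @param nReps replicates per condition (>= 2; default
#'   \code{config$replicatesPerCondition}).
#' @param config a [simConfig()] list.
#' @param seed seed for the measurement noise (defaults to
#'   \code{config$seed}); the same truth can be re-assayed under
#'   different seeds.
#' @return a [ThermalQuant-class] with \code{2 * nReps} samples.
#' @export
simulateIsothermal <- function(truth, temperature = config$assayTemperature,
    nReps = config$replicatesPerCondition, config, seed = config$seed) {
    stopifnot(inherits(config, "SimConfig"))
    if (nReps < 2)
        stop("design error: isothermal design needs >= 2 replicates per condition")
    set.seed(seed)
    n <- nrow(truth)
    fV <- fractionSoluble(vehicleCurves(truth), temperature)
    fD <- fractionSoluble(drugCurves(truth), temperature)
    cols <- 2L * nReps
    noise <- matrix(.reporterNoise(n * cols, config$noiseCV), n, cols)
    base <- truth$abundance * cbind(
        matrix(fV, n, nReps), matrix(fD, n, nReps))
    intensity <- .applyDropout(base * noise, config)
    ev <- .evidenceCounts(truth$abundance, config)
    sampleData <- S4Vectors::DataFrame(
        condition = rep(c("vehicle", "drug"), each = nReps),
        replicate = rep(seq_len(nReps), 2L),
        temperature = temperature)
    colnames(intensity) <- rownames(sampleData) <-
        paste0(sampleData$condition, "_", sampleData$replicate)
    rownames(intensity) <- truth$protein_id
    proteinData <- S4Vectors::DataFrame(
        gene_name = sub("^P", "G", truth$protein_id),
        unique_peptides = ev$peptides, msms_count = ev$msms,
        reverse = FALSE, contaminant = FALSE,
        row.names = truth$protein_id)
    ThermalQuant(intensity, proteinData, sampleData)
}

#' Simulate a thermal-gradient (TPP-style) experiment
#'
#' Generates one intensity column per (condition, replicate, temperature)
#' triple using the same noise, evidence-count and dropout mechanisms as
#' [simulateIsothermal()]. A second assay, \code{"fold_change"}, expresses
#' each (condition, replicate) series relative to its value at the lowest
#' temperature -- the scale on which melting curves are fitted.
#'
#' @param truth a proteome from [sampleProteome()].
#' @param temperatures gradient temperatures in degrees C (>= 4 points;
#'   default \code{config$gradientTemperatures}).
#' @param nReps replicates per condition (default
#'   \code{config$gradientReplicates}).
#' @inheritParams simulateIsothermal
#' @return a [ThermalQuant-class] with
#'   \code{2 * nReps * length(temperatures)} samples and assays
#'   \code{"intensity"} and \code{"fold_change"}.
#' @export
simulateGradient <- function(truth, temperatures = config$gradientTemperatures,
    nReps = config$gradientReplicates, config, seed = config$seed) {
    stopifnot(inherits(config, "SimConfig"))
    if (length(temperatures) < 4)
        stop("design error: gradient design needs >= 4 temperatures")
    set.seed(seed)
    n <- nrow(truth)
    nT <- length(temperatures)
    design <- expand.grid(temperature = temperatures,
        replicate = seq_len(nReps), condition = c("vehicle", "drug"),
        stringsAsFactors = FALSE)[, 3:1]
    fV <- vapply(temperatures, function(tt)
        fractionSoluble(vehicleCurves(truth), tt), numeric(n))
    fD <- vapply(temperatures, function(tt)
        fractionSoluble(drugCurves(truth), tt), numeric(n))
    base <- vapply(seq_len(nrow(design)), function(j) {
        f <- if (design$condition[j] == "vehicle") fV else fD
        truth$abundance * f[, match(design$temperature[j], temperatures)]
    }, numeric(n))
    noise <- matrix(.reporterNoise(length(base), config$noiseCV),
        n, nrow(design))
    intensity <- .applyDropout(base * noise, config)
    sampleData <- S4Vectors::DataFrame(design)
    colnames(intensity) <- rownames(sampleData) <- sprintf("%s_r%d_T%g",
        design$condition, design$replicate, design$temperature)
    rownames(intensity) <- truth$protein_id
    # fold change relative to the lowest temperature within each series
    tMin <- min(temperatures)
    fc <- intensity
    for (cond in c("vehicle", "drug")) for (r in seq_len(nReps)) {
        sel <- design$condition == cond & design$replicate == r
        refCol <- sel & design$temperature == tMin
        fc[, sel] <- intensity[, sel] / intensity[, refCol]
    }
    ev <- .evidenceCounts(truth$abundance, config)
    proteinData <- S4Vectors::DataFrame(
        gene_name = sub("^P", "G", truth$protein_id),
        unique_peptides = ev$peptides, msms_count = ev$msms,
        reverse = FALSE, contaminant = FALSE,
        row.names = truth$protein_id)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = intensity, fold_change = fc),
        rowData = proteinData, colData = sampleData)
    new("ThermalQuant", se)
}
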