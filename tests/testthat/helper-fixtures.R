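# small in-code fixtures shared across test files

# a ThermalQuant built directly from a matrix (isothermal single-T design)
makeQuant <- function(intensity, uniquePeptides = NULL, msms = NULL,
    temperature = 52) {
    n <- nrow(intensity)
    nv <- ncol(intensity) / 2
    if (is.null(rownames(intensity)))
        rownames(intensity) <- sprintf("P%03d", seq_len(n))
    if (is.null(uniquePeptides)) uniquePeptides <- rep(3L, n)
    if (is.null(msms)) msms <- rep(10L, n)
    ThermalQuant(intensity,
        S4Vectors::DataFrame(gene_name = rownames(intensity),
            unique_peptides = uniquePeptides, msms_count = msms,
            reverse = FALSE, contaminant = FALSE,
            row.names = rownames(intensity)),
        S4Vectors::DataFrame(
            condition = rep(c("vehicle", "drug"), each = nv),
            replicate = rep(seq_len(nv), 2),
            temperature = temperature))
}

# config for fast, noise-free simulations
quietConfig <- function(...) {
    simConfig(noiseCV = 0, dropoutMidpoint = -Inf, ...)
}

# brute-force BH step-up: q_i = min over ranks j >= rank(i) of p_(j)*m/j
bhBruteForce <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
        ri <- which(o == i)          # rank of p[i]
        cand <- vapply(ri:m, function(j) p[o[j]] * m / j, numeric(1))
        q[i] <- min(c(cand, 1))
    }
    q
}
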