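#' Write a quantification table in the MaxQuant proteinGroups dialect
#'
#' Serializes a [ThermalQuant-class] to a tab-separated file with the
#' columns \code{Protein IDs}, \code{Gene names}, \code{Unique peptides},
#' \code{MS/MS count}, \code{Reporter intensity corrected 0..N-1},
#' \code{Reverse} and \code{Potential contaminant}. Missing intensities
#' are written as 0 (the MaxQuant convention) and flags as \code{"+"} or
#' empty. A companion annotation table maps each reporter column to its
#' (condition, replicate, temperature).
#'
#' @param x a [ThermalQuant-class].
#' @param path output path for the proteinGroups TSV.
#' @param annotationPath output path for the sample-annotation TSV
#'   (columns \code{sample}, \code{condition}, \code{replicate},
#'   \code{temperature}).
#' @return invisibly, the two paths.
#' @seealso [readProteinGroups()] for the lossless round trip.
#' @export
writeProteinGroups <- function(x, path, annotationPath) {
    a <- SummarizedExperiment::assay(x, "intensity")
    rd <- SummarizedExperiment::rowData(x)
    cd <- SummarizedExperiment::colData(x)
    inten <- a
    inten[is.na(inten)] <- 0
    reporterNames <- paste("Reporter intensity corrected",
        seq_len(ncol(a)) - 1L)
    df <- data.frame(
        `Protein IDs` = rownames(x),
        `Gene names` = if (!is.null(rd$gene_name)) rd$gene_name
            else rownames(x),
        `Unique peptides` = rd$unique_peptides,
        `MS/MS count` = rd$msms_count,
        check.names = FALSE)
    df <- cbind(df, as.data.frame(inten) |>
        stats::setNames(reporterNames))
    df$Reverse <- if (!is.null(rd$reverse))
        ifelse(rd$reverse, "+", "") else ""
    df$`Potential contaminant` <- if (!is.null(rd$contaminant))
        ifelse(rd$contaminant, "+", "") else ""
    utils::write.table(df, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    ann <- data.frame(sample = reporterNames,
        condition = cd$condition, replicate = cd$replicate,
        temperature = cd$temperature)
    utils::write.table(ann, annotationPath, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(c(path, annotationPath))
}

#' Read a MaxQuant-style proteinGroups table
#'
#' Parses a proteinGroups TSV plus a sample-annotation TSV into a
#' [ThermalQuant-class]. Intensities of 0 are treated as missing
#' (the MaxQuant convention); \code{"+"} flags in \code{Reverse} /
#' \code{Potential contaminant} are carried into row metadata. Every
#' \code{Reporter intensity corrected N} column must be annotated, and
#' every annotation row must match a reporter column; mismatches raise an
#' error naming the offending columns.
#'
#' @param path proteinGroups TSV with a header row.
#' @param annotationPath annotation TSV with columns \code{sample}
#'   (the reporter column name), \code{condition}, \code{replicate},
#'   \code{temperature}.
#' @return a [ThermalQuant-class].
#' @export
readProteinGroups <- function(path, annotationPath) {
    df <- utils::read.delim(path, check.names = FALSE,
        stringsAsFactors = FALSE)
    need <- c("Protein IDs", "Unique peptides", "MS/MS count")
    missingCols <- setdiff(need, colnames(df))
    if (length(missingCols))
        stop("format error: required column(s) missing: ",
            paste(missingCols, collapse = ", "))
    ann <- utils::read.delim(annotationPath, check.names = FALSE,
        stringsAsFactors = FALSE)
    needAnn <- c("sample", "condition", "replicate", "temperature")
    if (!all(needAnn %in% colnames(ann)))
        stop("format error: annotation must have columns: ",
            paste(needAnn, collapse = ", "))
    reporter <- grep("^Reporter intensity corrected ", colnames(df),
        value = TRUE)
    if (!length(reporter))
        stop("format error: no 'Reporter intensity corrected' columns found")
    orphan <- setdiff(reporter, ann$sample)
    if (length(orphan))
        stop("annotation mismatch: unannotated reporter column(s): ",
            paste(orphan, collapse = ", "))
    unknown <- setdiff(ann$sample, reporter)
    if (length(unknown))
        stop("annotation mismatch: annotation row(s) without a matching ",
            "reporter column: ", paste(unknown, collapse = ", "))
    inten <- as.matrix(df[, ann$sample, drop = FALSE])
    if (nrow(inten) == 0) mode(inten) <- "numeric"  # header-only file
    if (!is.numeric(inten)) {
        bad <- ann$sample[!vapply(df[, ann$sample, drop = FALSE],
            is.numeric, logical(1))]
        stop("format error: non-numeric intensities in column(s): ",
            paste(bad, collapse = ", "))
    }
    inten[inten == 0] <- NA_real_
    rownames(inten) <- df$`Protein IDs`
    proteinData <- S4Vectors::DataFrame(
        gene_name = if ("Gene names" %in% colnames(df)) df$`Gene names`
            else df$`Protein IDs`,
        unique_peptides = df$`Unique peptides`,
        msms_count = df$`MS/MS count`,
        reverse = if ("Reverse" %in% colnames(df))
            !is.na(df$Reverse) & df$Reverse == "+" else FALSE,
        contaminant = if ("Potential contaminant" %in% colnames(df))
            !is.na(df$`Potential contaminant`) &
                df$`Potential contaminant` == "+" else FALSE,
        row.names = df$`Protein IDs`)
    sampleData <- S4Vectors::DataFrame(condition = ann$condition,
        replicate = ann$replicate, temperature = ann$temperature,
        row.names = paste0(ann$condition, "_", ann$replicate,
            "_", ann$temperature))
    colnames(inten) <- rownames(sampleData)
    ThermalQuant(inten, proteinData, sampleData)
}

#' Write a results table as TSV
#'
#' Full-precision tab-separated export of any results
#' \code{DataFrame}/\code{data.frame} (moderated-test results, volcano
#' tables, Tm libraries, benchmark summaries).
#'
#' @param results a \code{DataFrame} or \code{data.frame}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeResultsTable <- function(results, path) {
    utils::write.table(as.data.frame(results), path, sep = "\t",
        quote = FALSE, row.names = FALSE)
    invisible(path)
}
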