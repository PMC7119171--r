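#' @include AllClasses.R
NULL

## tab/comma auto-detection on the header line
.detectSep <- function(path) {
    header <- readLines(path, n = 1L)
    if (grepl("\t", header)) "\t" else ","
}

#' Read a per-population allele-frequency table
#'
#' Reads the delimited frequency format: a header line
#' `SNPID, Chromosome, Ref_Allele, Alt_Allele, Pop1_Freq, ..., Popk_Freq`
#' and one variant per row, where `Popj_Freq` holds the reference-allele
#' frequency in population j (population names are parsed from the `_Freq`
#' column names). Tab or comma delimiters are auto-detected. An optional
#' `Position` column (1-based base pairs, after `Chromosome`) is accepted;
#' it is needed only for distance-based thinning. Validation errors report
#' the offending file line.
#'
#' @param path path to the file.
#' @param counts optional per-population sample sizes, named by population
#'   or in column order; default equal weights (c_j = 1), under which the
#'   informativeness statistic weights all populations equally.
#' @return A [MarkerFrequencyTable-class].
#' @export
readFrequencyTable <- function(path, counts = NULL) {
    sep <- .detectSep(path)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            colClasses = "character", strip.white = TRUE)
    cols <- names(df)
    mandatory <- c("SNPID", "Chromosome", "Ref_Allele", "Alt_Allele")
    absent <- setdiff(mandatory, cols)
    if (length(absent))
        stop("frequency file is missing mandatory column(s): ",
             paste(absent, collapse = ", "))
    fcols <- grep("_Freq$", cols, value = TRUE)
    if (length(fcols) < 2L)
        stop("frequency file needs at least 2 '*_Freq' population columns")
    pops <- sub("_Freq$", "", fcols)
    if (anyDuplicated(df$SNPID))
        stop("duplicate SNPID(s): ",
             paste(unique(df$SNPID[duplicated(df$SNPID)]), collapse = ", "))
    F <- matrix(NA_real_, nrow(df), length(fcols),
                dimnames = list(df$SNPID, pops))
    for (j in seq_along(fcols)) {
        raw <- df[[fcols[j]]]
        empty <- is.na(raw) | raw == "" | toupper(raw) == "NA"
        val <- suppressWarnings(as.numeric(raw))
        bad <- !empty & (is.na(val) | val < 0 | val > 1)
        if (any(bad))
            stop("invalid frequency in column '", fcols[j], "' at file line ",
                 which(bad)[1L] + 1L, ": '", raw[which(bad)[1L]], "'")
        val[empty] <- NA_real_
        F[, j] <- val
    }
    pos <- if ("Position" %in% cols) {
        p <- suppressWarnings(as.integer(df$Position))
        bad <- !(is.na(df$Position) | df$Position == "") & is.na(p)
        if (any(bad))
            stop("non-numeric Position at file line ", which(bad)[1L] + 1L)
        p
    } else NA_integer_
    if (is.null(counts)) counts <- rep(1, length(pops))
    panel <- PopulationPanel(pops, counts = counts)
    MarkerFrequencyTable(F, panel, ids = df$SNPID,
                         chromosome = df$Chromosome, position = pos,
                         ref = df$Ref_Allele, alt = df$Alt_Allele)
}

#' Write a frequency table in the standard delimited format
#'
#' Inverse of [readFrequencyTable()]: header
#' `SNPID, Chromosome, [Position,] Ref_Allele, Alt_Allele, <Pop>_Freq...`,
#' one marker per row. The `Position` column is emitted only when at least
#' one marker has a position.
#'
#' @param table a [MarkerFrequencyTable-class].
#' @param path output path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeFrequencyTable <- function(table, path, format = c("csv", "tsv")) {
    format <- match.arg(format)
    info <- table@info
    df <- data.frame(SNPID = info$id, Chromosome = info$chromosome,
                     check.names = FALSE, stringsAsFactors = FALSE)
    if (any(!is.na(info$position))) df$Position <- info$position
    df$Ref_Allele <- info$ref
    df$Alt_Allele <- info$alt
    for (j in seq_along(table@panel@labels))
        df[[paste0(table@panel@labels[j], "_Freq")]] <- table@freqs[, j]
    utils::write.table(df, path, sep = if (format == "csv") "," else "\t",
                       row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read an individual-level genotype table
#'
#' Reads the delimited genotype format: a header line
#' `SampleID, Population, SNP1, ..., SNPk` and one sample per row, with
#' each genotype coded as the number of reference alleles (0, 1 or 2).
#' Empty cells or `NA` mark missing calls. Tab or comma delimiters are
#' auto-detected; validation errors name the offending row and column.
#'
#' @param path path to the file.
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypeTable <- function(path) {
    sep <- .detectSep(path)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            colClasses = "character", strip.white = TRUE,
                            na.strings = c("NA", ""))
    if (!all(c("SampleID", "Population") %in% names(df)))
        stop("genotype file must start with SampleID and Population columns")
    if (ncol(df) < 3L)
        stop("genotype file has no marker columns")
    if (anyDuplicated(df$SampleID))
        stop("duplicate SampleID(s): ",
             paste(unique(df$SampleID[duplicated(df$SampleID)]),
                   collapse = ", "))
    snp <- setdiff(names(df), c("SampleID", "Population"))
    g <- matrix(NA_integer_, nrow(df), length(snp),
                dimnames = list(df$SampleID, snp))
    for (j in seq_along(snp)) {
        raw <- df[[snp[j]]]
        val <- suppressWarnings(as.integer(raw))
        bad <- !is.na(raw) & (is.na(val) | !(val %in% 0:2))
        if (any(bad))
            stop("invalid genotype '", raw[which(bad)[1L]], "' for sample '",
                 df$SampleID[which(bad)[1L]], "', marker '", snp[j],
                 "' (must be 0, 1, 2 or missing)")
        g[, j] <- val
    }
    GenotypeMatrix(g, populations = df$Population, samplesInRows = TRUE)
}

#' Write a genotype table in the standard delimited format
#'
#' Inverse of [readGenotypeTable()]: header
#' `SampleID, Population, <marker ids>...`, one sample per row, missing
#' calls written as `NA`.
#'
#' @param G a [GenotypeMatrix-class].
#' @param path output path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeGenotypeTable <- function(G, path, format = c("csv", "tsv")) {
    format <- match.arg(format)
    g <- t(genotypes(G))
    df <- data.frame(SampleID = rownames(g),
                     Population = as.character(populations(G)),
                     g, check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = if (format == "csv") "," else "\t",
                       row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Per-population allele frequencies from a VCF
#'
#' Convenience bridge from the standard variant format: reads per-sample
#' GT fields, keeps biallelic records only (multi-allelic records are
#' skipped with a warning), and computes each population's reference-allele
#' frequency from the called genotypes. The VCF REF allele is taken as the
#' reference allele; half-calls and missing genotypes are excluded from the
#' denominators, and the per-population non-missing sample numbers become
#' the per-marker weights.
#'
#' @param path path to an (uncompressed or bgzipped) VCF with GT fields.
#' @param sampleMap named character vector mapping sample id to population
#'   label. VCF samples absent from the map are excluded with a warning.
#' @return A [MarkerFrequencyTable-class].
#' @export
frequenciesFromVCF <- function(path, sampleMap) {
    stopifnot(!is.null(names(sampleMap)))
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    bi <- vcfR::is.biallelic(vcf)
    if (any(!bi)) {
        warning(sum(!bi), " multi-allelic record(s) skipped")
        vcf <- vcf[bi, ]
    }
    if (nrow(vcf@fix) == 0L)
        stop("no biallelic records in VCF")
    gt <- vcfR::extract.gt(vcf, element = "GT")
    unknown <- setdiff(colnames(gt), names(sampleMap))
    if (length(unknown)) {
        warning("VCF sample(s) absent from the population map excluded: ",
                paste(unknown, collapse = ", "))
        gt <- gt[, setdiff(colnames(gt), unknown), drop = FALSE]
    }
    if (ncol(gt) == 0L)
        stop("no VCF samples remain after applying the population map")
    pop <- factor(unname(sampleMap[colnames(gt)]))
    ## count reference (0) alleles per call; half-calls/missing excluded
    alleles <- function(cell) {
        if (is.na(cell)) return(c(0L, 0L))
        parts <- strsplit(cell, "[/|]")[[1L]]
        parts <- parts[parts %in% c("0", "1")]
        if (length(parts) != 2L) return(c(0L, 0L))
        c(sum(parts == "0"), 2L)
    }
    m <- nrow(gt); labs <- levels(pop)
    F <- matrix(NA_real_, m, length(labs))
    C <- matrix(NA_real_, m, length(labs))
    for (j in seq_along(labs)) {
        sub <- gt[, pop == labs[j], drop = FALSE]
        refc <- matrix(0L, nrow(sub), ncol(sub))
        totc <- matrix(0L, nrow(sub), ncol(sub))
        for (s in seq_len(ncol(sub))) {
            a <- vapply(sub[, s], alleles, integer(2))
            refc[, s] <- a[1L, ]
            totc[, s] <- a[2L, ]
        }
        tot <- rowSums(totc)
        if (all(tot == 0L))
            stop("population '", labs[j],
                 "' has no usable genotype calls in the VCF")
        F[, j] <- ifelse(tot > 0L, rowSums(refc) / tot, NA_real_)
        C[, j] <- ifelse(tot > 0L, tot / 2, NA_real_)
    }
    ids <- vcf@fix[, "ID"]
    noid <- is.na(ids) | ids == "."
    ids[noid] <- paste0(vcf@fix[noid, "CHROM"], ":", vcf@fix[noid, "POS"])
    panel <- PopulationPanel(labs, counts = apply(C, 2L, max, na.rm = TRUE))
    for (j in seq_along(labs)) C[is.na(C[, j]), j] <- panel@counts[j]
    MarkerFrequencyTable(F, panel, ids = ids,
                         chromosome = vcf@fix[, "CHROM"],
                         position = as.integer(vcf@fix[, "POS"]),
                         ref = vcf@fix[, "REF"], alt = vcf@fix[, "ALT"],
                         countsPerMarker = C)
}

#' Write a scored marker table
#'
#' Writes the output table in the standard column order: variant ID,
#' chromosome, position (only when at least one marker has one), reference
#' allele, one frequency column per population, and the computation value
#' of the scoring method (last column, named `Score`). Rows are ordered by
#' descending score.
#'
#' @param table a [ScoredMarkerTable-class].
#' @param path output path.
#' @param format `"csv"` or `"tsv"`.
#' @param digits rounding for display-oriented output; `NA` (default)
#'   writes full precision. Use `digits = 2` for the two-decimal display
#'   convention of web-style output.
#' @return `path`, invisibly.
#' @export
writeScores <- function(table, path, format = c("csv", "tsv"), digits = NA) {
    stopifnot(is(table, "ScoredMarkerTable"))
    format <- match.arg(format)
    ord <- order(-table@score, table@info$position, table@info$id,
                 na.last = TRUE)
    tab <- table[ord]
    info <- tab@info
    df <- data.frame(SNPID = info$id, Chromosome = info$chromosome,
                     check.names = FALSE, stringsAsFactors = FALSE)
    if (any(!is.na(info$position))) df$Position <- info$position
    df$Ref_Allele <- info$ref
    fr <- tab@freqs
    sc <- tab@score
    if (!is.na(digits)) {
        fr <- round(fr, digits)
        sc <- round(sc, digits)
    }
    for (j in seq_along(tab@panel@labels))
        df[[paste0(tab@panel@labels[j], "_Freq")]] <- fr[, j]
    df$Score <- sc
    utils::write.table(df, path, sep = if (format == "csv") "," else "\t",
                       row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read back a scored marker table
#'
#' Inverse of [writeScores()] (up to the alternate-allele column, which the
#' output format does not carry): parses the frequency columns and the
#' trailing `Score` column.
#'
#' @param path path to a file written by [writeScores()].
#' @param method method tag to attach (default `"LEI"`).
#' @param counts optional per-population sample sizes.
#' @return A [ScoredMarkerTable-class].
#' @export
readScores <- function(path, method = "LEI", counts = NULL) {
    sep <- .detectSep(path)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE)
    fcols <- grep("_Freq$", names(df), value = TRUE)
    pops <- sub("_Freq$", "", fcols)
    if (is.null(counts)) counts <- rep(1, length(pops))
    F <- as.matrix(df[fcols])
    colnames(F) <- pops
    mft <- MarkerFrequencyTable(
        F, PopulationPanel(pops, counts), ids = df$SNPID,
        chromosome = df$Chromosome,
        position = if ("Position" %in% names(df)) df$Position
                   else NA_integer_,
        ref = df$Ref_Allele, alt = NA_character_)
    new("ScoredMarkerTable", mft, score = as.numeric(df$Score),
        method = method)
}
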