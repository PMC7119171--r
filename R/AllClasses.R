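#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Ordered set of ancestral populations with sample weights
#'
#' A `PopulationPanel` fixes the identity and order of the k ancestral
#' populations under comparison and carries one sample weight per population.
#' The weights are the per-population sample sizes c_j used to assemble the
#' genotype-by-population joint distribution; they may be any positive reals,
#' so equal weighting (all c_j = 1) is expressible when true panel sizes are
#' unknown. Only the relative weights matter for the informativeness
#' statistic (it is invariant to rescaling all c_j by a common factor).
#'
#' @slot labels character vector of k >= 2 distinct population names.
#' @slot counts positive numeric vector of per-population sample sizes,
#'   parallel to `labels`.
#'
#' @seealso [PopulationPanel()] for the constructor,
#'   [jointDistribution()] which consumes the weights.
#' @exportClass PopulationPanel
setClass("PopulationPanel",
    representation(labels = "character", counts = "numeric"))

setValidity("PopulationPanel", function(object) {
    msg <- character()
    if (length(object@labels) < 2L)
        msg <- c(msg, "a population panel needs at least 2 populations")
    if (anyDuplicated(object@labels))
        msg <- c(msg, "population labels must be unique")
    if (length(object@counts) != length(object@labels))
        msg <- c(msg, "'counts' and 'labels' must have the same length")
    if (any(!is.finite(object@counts)) || any(object@counts <= 0))
        msg <- c(msg, "all sample counts must be finite and > 0")
    if (length(msg)) msg else TRUE
})

#' Construct a PopulationPanel
#'
#' @param labels character vector of k >= 2 distinct population names.
#' @param counts per-population sample sizes; defaults to equal weights
#'   (c_j = 1), appropriate when a frequency table carries no sizes.
#' @return A [PopulationPanel-class] object.
#' @examples
#' PopulationPanel(c("CEU", "CHB", "YRI"))
#' PopulationPanel(c("CEU", "CHB", "YRI"), counts = c(99, 103, 108))
#' @export
PopulationPanel <- function(labels, counts = rep(1, length(labels))) {
    if (!is.null(names(counts))) {
        if (!setequal(names(counts), labels))
            stop("names of 'counts' do not match the population labels")
        counts <- counts[labels]
    }
    new("PopulationPanel", labels = as.character(labels),
        counts = unname(as.numeric(counts)))
}

#' Per-population reference-allele frequencies for a set of markers
#'
#' The central frequency container: one row per biallelic marker, one
#' frequency column per population, plus marker metadata (chromosome,
#' optional base-pair position, reference and alternate allele labels).
#' Frequencies are reference-allele frequencies f_j in [0, 1]; NA marks a
#' missing cell. The attached [PopulationPanel-class] fixes population order
#' and default sample weights; `countsPerMarker` optionally refines those
#' weights per marker (e.g. per-marker non-missing sample numbers after
#' estimating frequencies from genotypes).
#'
#' @slot info `DataFrame` with columns `id`, `chromosome`, `position`
#'   (integer, NA when unknown), `ref`, `alt`.
#' @slot freqs numeric matrix, markers x populations, entries in [0, 1] or NA.
#' @slot panel a [PopulationPanel-class].
#' @slot countsPerMarker numeric matrix, markers x populations, the
#'   per-marker sample weights; defaults to the panel counts repeated.
#'
#' @seealso [MarkerFrequencyTable()], [leiTable()], [readFrequencyTable()],
#'   [estimateFrequencies()]
#' @exportClass MarkerFrequencyTable
setClass("MarkerFrequencyTable",
    representation(info = "DataFrame", freqs = "matrix",
                   panel = "PopulationPanel", countsPerMarker = "matrix"))

setValidity("MarkerFrequencyTable", function(object) {
    msg <- character()
    need <- c("id", "chromosome", "position", "ref", "alt")
    if (!all(need %in% colnames(object@info)))
        msg <- c(msg, paste("'info' must have columns",
                            paste(need, collapse = ", ")))
    else if (anyDuplicated(object@info$id))
        msg <- c(msg, "marker ids must be unique")
    k <- length(object@panel@labels)
    if (ncol(object@freqs) != k)
        msg <- c(msg, "'freqs' must have one column per population")
    if (nrow(object@freqs) != nrow(object@info))
        msg <- c(msg, "'freqs' and 'info' row counts differ")
    bad <- object@freqs[!is.na(object@freqs)]
    if (length(bad) && (any(bad < 0) || any(bad > 1)))
        msg <- c(msg, "frequencies must lie in [0, 1] or be NA")
    if (!identical(dim(object@countsPerMarker), dim(object@freqs)))
        msg <- c(msg, "'countsPerMarker' must match the dimensions of 'freqs'")
    else if (any(!is.na(object@countsPerMarker) &
                 object@countsPerMarker <= 0))
        msg <- c(msg, "per-marker counts must be > 0")
    if (length(msg)) msg else TRUE
})

#' Construct a MarkerFrequencyTable
#'
#' @param freqs numeric matrix of reference-allele frequencies, markers in
#'   rows, populations in columns (column order follows `panel`).
#' @param panel a [PopulationPanel-class] naming the populations. May be a
#'   character vector of labels, in which case equal weights are used.
#' @param ids marker identifiers (default taken from `rownames(freqs)` or
#'   generated).
#' @param chromosome,position,ref,alt optional marker metadata, recycled to
#'   the number of markers. `position` is a 1-based physical coordinate in
#'   base pairs (NA when unknown).
#' @param countsPerMarker optional markers x populations matrix of
#'   per-marker sample weights; defaults to the panel counts.
#' @return A [MarkerFrequencyTable-class].
#' @examples
#' panel <- PopulationPanel(c("CEU", "CHB", "YRI"))
#' MarkerFrequencyTable(rbind(rs2294368 = c(0.79, 0.17, 0.99)), panel)
#' @export
MarkerFrequencyTable <- function(freqs, panel, ids = NULL,
                                 chromosome = NA_character_,
                                 position = NA_integer_,
                                 ref = NA_character_, alt = NA_character_,
                                 countsPerMarker = NULL) {
    if (is.character(panel)) panel <- PopulationPanel(panel)
    freqs <- as.matrix(freqs)
    m <- nrow(freqs)
    if (is.null(ids)) ids <- rownames(freqs)
    if (is.null(ids)) ids <- sprintf("marker%d", seq_len(m))
    dimnames(freqs) <- list(ids, panel@labels)
    if (is.null(countsPerMarker))
        countsPerMarker <- matrix(rep(panel@counts, each = m), nrow = m)
    countsPerMarker <- as.matrix(countsPerMarker)
    dimnames(countsPerMarker) <- dimnames(freqs)
    info <- DataFrame(id = as.character(ids),
                      chromosome = rep_len(as.character(chromosome), m),
                      position = rep_len(as.integer(position), m),
                      ref = rep_len(as.character(ref), m),
                      alt = rep_len(as.character(alt), m))
    new("MarkerFrequencyTable", info = info, freqs = freqs, panel = panel,
        countsPerMarker = countsPerMarker)
}

#' Estimated genotype-by-population joint distribution for one marker
#'
#' The 3 x k table of joint probabilities p_ij over genotype category
#' X in (mm, mM, MM) and population Y, reconstructed from allele frequencies
#' under Hardy-Weinberg equilibrium. Rows are genotypes ordered by
#' reference-allele count (0, 1, 2); columns follow the population panel.
#' Column marginals equal c_j / n by construction.
#'
#' @slot p 3 x k matrix of joint probabilities, summing to 1.
#' @slot rowMarginals length-3 genotype marginals p_i+.
#' @slot colMarginals length-k population marginals p_+j = c_j / n.
#'
#' @seealso [jointDistribution()], [lei()]
#' @exportClass GenotypePopulationJoint
setClass("GenotypePopulationJoint",
    representation(p = "matrix", rowMarginals = "numeric",
                   colMarginals = "numeric"))

setValidity("GenotypePopulationJoint", function(object) {
    msg <- character()
    p <- object@p
    if (nrow(p) != 3L)
        msg <- c(msg, "'p' must have 3 genotype rows")
    if (any(p < 0))
        msg <- c(msg, "joint probabilities must be >= 0")
    if (abs(sum(p) - 1) > 1e-12)
        msg <- c(msg, "joint probabilities must sum to 1")
    if (max(abs(rowSums(p) - object@rowMarginals)) > 1e-12)
        msg <- c(msg, "row marginals inconsistent with 'p'")
    if (max(abs(colSums(p) - object@colMarginals)) > 1e-12)
        msg <- c(msg, "column marginals inconsistent with 'p'")
    if (length(msg)) msg else TRUE
})

#' Individual-level genotypes with population labels
#'
#' A thin [SummarizedExperiment-class] subclass holding reference-allele
#' counts. The single assay `"genotype"` is a markers x samples integer
#' matrix with entries 0, 1, 2 (copies of the reference allele M) or NA for
#' missing calls; `colData` carries the per-sample `Population` factor and
#' `rowData` the marker metadata (`chromosome`, `position`, `ref`, `alt`).
#'
#' @seealso [GenotypeMatrix()], [readGenotypeTable()], [simulateGenotypes()]
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
    msg <- character()
    if (!"genotype" %in% SummarizedExperiment::assayNames(object))
        return("assay 'genotype' is required")
    g <- SummarizedExperiment::assay(object, "genotype")
    ok <- is.na(g) | g == 0L | g == 1L | g == 2L
    if (!all(ok))
        msg <- c(msg, "genotypes must be 0, 1, 2 or NA (reference-allele counts)")
    cd <- SummarizedExperiment::colData(object)
    if (!"Population" %in% colnames(cd))
        msg <- c(msg, "colData must contain a 'Population' column")
    else if (anyNA(cd$Population))
        msg <- c(msg, "every sample needs a population label")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be present and unique")
    if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param genotypes integer matrix of reference-allele counts (0/1/2, NA for
#'   missing), markers in rows and samples in columns. A samples x markers
#'   matrix is also accepted when `samplesInRows = TRUE`.
#' @param populations population label per sample (character or factor).
#' @param samplesInRows set `TRUE` if `genotypes` has samples in rows.
#' @param chromosome,position,ref,alt optional per-marker metadata.
#' @return A [GenotypeMatrix-class].
#' @examples
#' g <- rbind(snp1 = c(0L, 1L, 2L, 2L), snp2 = c(2L, 2L, 0L, 0L))
#' colnames(g) <- paste0("s", 1:4)
#' GenotypeMatrix(g, populations = c("A", "A", "B", "B"))
#' @export
GenotypeMatrix <- function(genotypes, populations, samplesInRows = FALSE,
                           chromosome = NA_character_, position = NA_integer_,
                           ref = NA_character_, alt = NA_character_) {
    genotypes <- as.matrix(genotypes)
    if (samplesInRows) genotypes <- t(genotypes)
    storage.mode(genotypes) <- "integer"
    if (is.null(colnames(genotypes)))
        colnames(genotypes) <- sprintf("sample%d", seq_len(ncol(genotypes)))
    if (is.null(rownames(genotypes)))
        rownames(genotypes) <- sprintf("marker%d", seq_len(nrow(genotypes)))
    m <- nrow(genotypes)
    rd <- DataFrame(chromosome = rep_len(as.character(chromosome), m),
                    position = rep_len(as.integer(position), m),
                    ref = rep_len(as.character(ref), m),
                    alt = rep_len(as.character(alt), m),
                    row.names = rownames(genotypes))
    se <- SummarizedExperiment(
        assays = list(genotype = genotypes),
        rowData = rd,
        colData = DataFrame(Population = factor(as.character(populations)),
                            row.names = colnames(genotypes)))
    new("GenotypeMatrix", se)
}

#' Per-marker informativeness scores attached to a frequency table
#'
#' Extends [MarkerFrequencyTable-class] with one score per marker and a tag
#' naming the scoring method (`"LEI"`, `"PCA"`, `"SVM"` or `"RF"`). Missing
#' scores (NA) mark markers that could not be scored, e.g. because of
#' missing frequencies; panel construction drops them.
#'
#' @slot score numeric vector, one value (or NA) per marker.
#' @slot method scalar character method tag.
#'
#' @seealso [leiTable()], [buildPanel()], [writeScores()]
#' @exportClass ScoredMarkerTable
setClass("ScoredMarkerTable", contains = "MarkerFrequencyTable",
    representation(score = "numeric", method = "character"))

setValidity("ScoredMarkerTable", function(object) {
    msg <- character()
    if (length(object@score) != nrow(object@freqs))
        msg <- c(msg, "one score per marker is required")
    if (any(is.infinite(object@score)))
        msg <- c(msg, "scores must be finite or NA")
    if (length(object@method) != 1L)
        msg <- c(msg, "'method' must be a single tag")
    if (length(msg)) msg else TRUE
})

#' Per-marker ranking produced by a genotype-based scorer
#'
#' Holds the non-negative per-marker scores of one ranking method together
#' with the marker ordering by descending score (ties broken by marker id
#' for reproducibility).
#'
#' @slot method one of `"LEI"`, `"PCA"`, `"SVM"`, `"RF"`.
#' @slot scores named numeric vector of per-marker scores (NA allowed for
#'   unscorable markers on the LEI path).
#' @slot ordering marker ids sorted by descending score.
#'
#' @seealso [leiFromGenotypes()], [pcaMarkerScores()], [svmMarkerScores()],
#'   [rfMarkerScores()]
#' @exportClass RankingResult
setClass("RankingResult",
    representation(method = "character", scores = "numeric",
                   ordering = "character"))

setValidity("RankingResult", function(object) {
    msg <- character()
    s <- object@scores
    if (is.null(names(s)))
        msg <- c(msg, "scores must be named by marker id")
    if (any(is.infinite(s)) || any(!is.na(s) & s < 0))
        msg <- c(msg, "scores must be finite and >= 0 (or NA)")
    if (!setequal(object@ordering, names(s)[!is.na(s)]))
        msg <- c(msg, "'ordering' must be a permutation of the scored marker ids")
    if (length(msg)) msg else TRUE
})

#' Per-sample ancestry proportions on the simplex
#'
#' An n x k matrix Q of ancestry proportions: row s gives the estimated (or
#' true) fraction of sample s's genome contributed by each ancestral
#' population. Rows lie on the probability simplex.
#'
#' @slot Q numeric matrix, samples x populations, rows summing to 1.
#'
#' @seealso [estimateAncestryProportions()], [rmseProportions()]
#' @exportClass AncestryProportions
setClass("AncestryProportions", representation(Q = "matrix"))

setValidity("AncestryProportions", function(object) {
    Q <- object@Q
    msg <- character()
    if (any(Q < 0) || any(Q > 1))
        msg <- c(msg, "proportions must lie in [0, 1]")
    if (nrow(Q) && max(abs(rowSums(Q) - 1)) > 1e-9)
        msg <- c(msg, "each row of Q must sum to 1")
    if (length(msg)) msg else TRUE
})

#' Simulated admixed cohort with known ancestry proportions
#'
#' Couples a simulated [GenotypeMatrix-class] of admixed individuals with
#' the true ancestry-proportion matrix used to generate it, so estimation
#' error can be measured exactly.
#'
#' @slot genotypes the admixed cohort's [GenotypeMatrix-class] (population
#'   label `"ADMIXED"` for every sample).
#' @slot Qtrue the true n x k [AncestryProportions-class].
#'
#' @seealso [simulateAdmixed()], [rmseProportions()]
#' @exportClass AdmixedCohort
setClass("AdmixedCohort",
    representation(genotypes = "GenotypeMatrix",
                   Qtrue = "AncestryProportions"))

#' Population-separation summary in principal-component space
#'
#' Summarises how well a marker panel separates known population labels:
#' the explained-variance ratios of the leading principal components of the
#' standardized genotype matrix, and the mean silhouette width of the true
#' labels in the top-2 component space (1 = perfectly separated clusters,
#' ~0 = no structure).
#'
#' @slot explainedVariance non-increasing ratios in [0, 1].
#' @slot silhouette mean silhouette width in [-1, 1].
#' @slot nComponents number of components summarised.
#'
#' @seealso [pcaSeparation()]
#' @exportClass SeparationReport
setClass("SeparationReport",
    representation(explainedVariance = "numeric", silhouette = "numeric",
                   nComponents = "integer"))

setValidity("SeparationReport", function(object) {
    ev <- object@explainedVariance
    msg <- character()
    if (any(ev < 0) || any(ev > 1) || is.unsorted(rev(ev)))
        msg <- c(msg, "explained-variance ratios must be non-increasing in [0, 1]")
    if (abs(object@silhouette) > 1)
        msg <- c(msg, "silhouette must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
})
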