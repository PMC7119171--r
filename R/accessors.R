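#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("populationLabels", "PopulationPanel", function(x) x@labels)
#' @rdname accessors
setMethod("sampleCounts", "PopulationPanel", function(x)
    structure(x@counts, names = x@labels))
#' @rdname accessors
setMethod("nPopulations", "PopulationPanel", function(x) length(x@labels))

#' @rdname accessors
setMethod("populationPanel", "MarkerFrequencyTable", function(x) x@panel)
#' @rdname accessors
setMethod("populationLabels", "MarkerFrequencyTable",
    function(x) x@panel@labels)
#' @rdname accessors
setMethod("nPopulations", "MarkerFrequencyTable",
    function(x) length(x@panel@labels))
#' @rdname accessors
setMethod("nMarkers", "MarkerFrequencyTable", function(x) nrow(x@freqs))
#' @rdname accessors
setMethod("frequencies", "MarkerFrequencyTable", function(x) x@freqs)
#' @rdname accessors
setMethod("markerInfo", "MarkerFrequencyTable", function(x) x@info)

#' @rdname accessors
setMethod("genotypes", "GenotypeMatrix", function(x)
    SummarizedExperiment::assay(x, "genotype"))
#' @rdname accessors
setMethod("populations", "GenotypeMatrix", function(x)
    droplevels(SummarizedExperiment::colData(x)$Population))
#' @rdname accessors
setMethod("populationLabels", "GenotypeMatrix", function(x)
    levels(populations(x)))
#' @rdname accessors
setMethod("nPopulations", "GenotypeMatrix", function(x)
    nlevels(populations(x)))
#' @rdname accessors
setMethod("nMarkers", "GenotypeMatrix", function(x) nrow(x))

#' @rdname accessors
setMethod("scores", "ScoredMarkerTable", function(x)
    structure(x@score, names = x@info$id))
#' @rdname accessors
setMethod("scoreMethod", "ScoredMarkerTable", function(x) x@method)
#' @rdname accessors
setMethod("scores", "RankingResult", function(x) x@scores)
#' @rdname accessors
setMethod("scoreMethod", "RankingResult", function(x) x@method)

#' @rdname accessors
setMethod("ancestryProportions", "AncestryProportions", function(x) x@Q)
#' @rdname accessors
setMethod("genotypes", "AdmixedCohort", function(x) genotypes(x@genotypes))
#' @rdname accessors
setMethod("trueProportions", "AdmixedCohort", function(x) x@Qtrue@Q)

#' Ranked marker ids of a ranking result
#' @param x a [RankingResult-class].
#' @return Character vector of marker ids, best first.
#' @export
ordering <- function(x) {
    stopifnot(is(x, "RankingResult"))
    x@ordering
}

#' Subset a frequency or scored marker table by marker
#'
#' @param x a [MarkerFrequencyTable-class] or [ScoredMarkerTable-class].
#' @param i numeric, logical or marker-id index.
#' @param j,drop,... ignored (markers are rows; populations are fixed).
#' @return An object of the same class restricted to the selected markers.
#' @export
setMethod("[", "MarkerFrequencyTable", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@info$id)
    initialize(x, info = x@info[i, , drop = FALSE],
               freqs = x@freqs[i, , drop = FALSE],
               countsPerMarker = x@countsPerMarker[i, , drop = FALSE])
})

#' @rdname sub-MarkerFrequencyTable-ANY-ANY-ANY-method
#' @export
setMethod("[", "ScoredMarkerTable", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@info$id)
    initialize(x, info = x@info[i, , drop = FALSE],
               freqs = x@freqs[i, , drop = FALSE],
               countsPerMarker = x@countsPerMarker[i, , drop = FALSE],
               score = x@score[i])
})

setMethod("show", "PopulationPanel", function(object) {
    cat("PopulationPanel with", length(object@labels), "populations\n")
    cat("  labels:", paste(object@labels, collapse = ", "), "\n")
    cat("  counts:", paste(format(object@counts), collapse = ", "), "\n")
})

setMethod("show", "MarkerFrequencyTable", function(object) {
    cat(class(object), "with", nrow(object@freqs), "markers x",
        ncol(object@freqs), "populations\n")
    cat("  populations:", paste(object@panel@labels, collapse = ", "), "\n")
    nshow <- min(5L, nrow(object@freqs))
    if (nshow > 0) {
        df <- data.frame(id = object@info$id[seq_len(nshow)],
                         round(object@freqs[seq_len(nshow), , drop = FALSE], 4))
        if (is(object, "ScoredMarkerTable"))
            df[[object@method]] <- round(object@score[seq_len(nshow)], 4)
        print(df, row.names = FALSE)
        if (nrow(object@freqs) > nshow)
            cat("  ...", nrow(object@freqs) - nshow, "more markers\n")
    }
})

setMethod("show", "GenotypePopulationJoint", function(object) {
    cat("GenotypePopulationJoint (3 x", ncol(object@p), ")\n")
    print(round(object@p, 4))
})

setMethod("show", "RankingResult", function(object) {
    cat("RankingResult [", object@method, "]:",
        length(object@scores), "markers\n")
    top <- utils::head(object@ordering, 5L)
    cat("  top:", paste(sprintf("%s (%.4g)", top, object@scores[top]),
                        collapse = ", "), "\n")
})

setMethod("show", "AncestryProportions", function(object) {
    cat("AncestryProportions:", nrow(object@Q), "samples x",
        ncol(object@Q), "ancestries\n")
    cat("  column means:", paste(round(colMeans(object@Q), 3),
                                 collapse = ", "), "\n")
})

setMethod("show", "AdmixedCohort", function(object) {
    cat("AdmixedCohort:", ncol(object@genotypes), "samples,",
        nrow(object@genotypes), "markers,",
        ncol(object@Qtrue@Q), "ancestries\n")
})

setMethod("show", "SeparationReport", function(object) {
    cat("SeparationReport\n")
    cat("  explained variance:",
        paste(sprintf("%.1f%%", 100 * object@explainedVariance),
              collapse = ", "), "\n")
    cat("  mean silhouette (top-2 PCs):",
        sprintf("%.3f", object@silhouette), "\n")
})
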