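#' @include lei.R
NULL

## samples x markers numeric matrix with per-marker mean imputation of
## missing genotypes (used by the PCA/SVM/RF paths only; the LEI path keeps
## complete-case allele counts instead).
.imputedSampleMatrix <- function(G) {
    X <- t(genotypes(G)) * 1.0
    if (anyNA(X)) {
        mu <- colMeans(X, na.rm = TRUE)
        mu[is.nan(mu)] <- 0
        idx <- which(is.na(X), arr.ind = TRUE)
        X[idx] <- mu[idx[, 2L]]
    }
    X
}

## column-standardize; zero-variance columns are dropped and reported
.standardize <- function(X) {
    sds <- apply(X, 2L, stats::sd)
    keep <- is.finite(sds) & sds > 0
    list(X = scale(X[, keep, drop = FALSE]), keep = keep)
}

.rankingResult <- function(scores, method) {
    ok <- names(scores)[!is.na(scores)]
    ord <- ok[order(-scores[ok], ok)]
    new("RankingResult", method = method, scores = scores, ordering = ord)
}

#' Estimate per-population allele frequencies from genotypes
#'
#' For each marker and population, the reference-allele frequency is
#' estimated as the sum of genotype codes over non-missing samples divided
#' by twice the number of non-missing samples. The per-marker non-missing
#' sample numbers are retained as the table's per-marker weights (so
#' downstream LEI uses exactly the data that produced each frequency); the
#' panel-level counts report the per-population maximum.
#'
#' @param G a [GenotypeMatrix-class] with at least 2 populations.
#' @return A [MarkerFrequencyTable-class] with the genotype matrix's marker
#'   metadata carried over.
#' @examples
#' g <- rbind(snp1 = c(2L, 2L, 1L, 0L))
#' colnames(g) <- paste0("s", 1:4)
#' G <- GenotypeMatrix(g, populations = c("A", "A", "B", "B"))
#' frequencies(estimateFrequencies(G))   # A: 1, B: 0.25
#' @export
estimateFrequencies <- function(G) {
    stopifnot(is(G, "GenotypeMatrix"))
    g <- genotypes(G)
    pop <- populations(G)
    labs <- levels(pop)
    m <- nrow(g)
    F <- matrix(NA_real_, m, length(labs),
                dimnames = list(rownames(g), labs))
    C <- matrix(NA_real_, m, length(labs), dimnames = dimnames(F))
    for (j in seq_along(labs)) {
        sub <- g[, pop == labs[j], drop = FALSE]
        nonmiss <- rowSums(!is.na(sub))
        F[, j] <- rowSums(sub, na.rm = TRUE) / (2 * nonmiss)
        F[nonmiss == 0L, j] <- NA_real_
        C[, j] <- ifelse(nonmiss > 0L, nonmiss, NA_real_)
    }
    if (anyNA(F))
        warning("some population/marker cells have no called genotypes; ",
                "their frequencies are missing")
    rd <- SummarizedExperiment::rowData(G)
    popSizes <- as.numeric(table(pop))
    cnt <- vapply(seq_along(labs), function(j) {
        x <- C[, j]
        if (all(is.na(x))) popSizes[j] else max(x, na.rm = TRUE)
    }, 0)
    panel <- PopulationPanel(labs, counts = cnt)
    ## populations with no calls anywhere at a marker keep NA weight; give
    ## them the panel count so the counts matrix stays positive (the NA
    ## frequency already excludes the marker from scoring)
    for (j in seq_along(labs))
        C[is.na(C[, j]), j] <- panel@counts[j]
    MarkerFrequencyTable(F, panel, ids = rownames(g),
                         chromosome = rd$chromosome, position = rd$position,
                         ref = rd$ref, alt = rd$alt, countsPerMarker = C)
}

#' LEI ranking from individual-level genotypes
#'
#' Convenience composition: estimates per-population allele frequencies
#' with [estimateFrequencies()] and scores them with [leiTable()]. On fully
#' observed data this is identical to the two-step path; markers with an
#' uncalled population receive a missing score.
#'
#' @param G a [GenotypeMatrix-class] with at least 2 populations.
#' @return A [RankingResult-class] with method `"LEI"`.
#' @export
leiFromGenotypes <- function(G) {
    if (nPopulations(G) < 2L)
        stop("LEI needs at least 2 populations; informativeness is ",
             "undefined for a single population")
    st <- leiTable(estimateFrequencies(G))
    .rankingResult(scores(st), "LEI")
}

#' PCA loading scores for markers
#'
#' Scores each marker by the explained-variance-weighted sum of its squared
#' loadings on the leading principal components of the column-standardized
#' genotype matrix. Constant (zero-variance) markers get score 0. The score
#' is invariant to component sign, hence deterministic.
#'
#' @param G a [GenotypeMatrix-class] with at least 2 samples.
#' @param nComponents number of leading components to aggregate
#'   (default 2, matching the usual two-axis ancestry plots).
#' @return A [RankingResult-class] with method `"PCA"`.
#' @export
pcaMarkerScores <- function(G, nComponents = 2L) {
    stopifnot(is(G, "GenotypeMatrix"))
    X <- .imputedSampleMatrix(G)
    if (nrow(X) < 2L)
        stop("PCA scoring needs at least 2 samples")
    std <- .standardize(X)
    nComponents <- as.integer(nComponents)
    if (nComponents < 1L || nComponents > min(dim(std$X)))
        stop("'nComponents' must be in 1..min(samples, markers)")
    pc <- stats::prcomp(std$X, center = FALSE, scale. = FALSE)
    evr <- pc$sdev^2 / sum(pc$sdev^2)
    use <- seq_len(nComponents)
    s <- drop(pc$rotation[, use, drop = FALSE]^2 %*% evr[use])
    out <- structure(numeric(ncol(X)), names = colnames(X))
    out[std$keep] <- s
    .rankingResult(out, "PCA")
}

#' Linear-SVM coefficient scores for markers
#'
#' Fits one linear support-vector classifier per population (one-vs-rest)
#' on the column-standardized genotype matrix and scores each marker by the
#' maximum absolute hyperplane coefficient across the per-population
#' classifiers. Constant markers are dropped from the fit and scored 0.
#'
#' @param G a [GenotypeMatrix-class] with >= 2 populations, each with >= 2
#'   samples.
#' @param cost regularization (cost) parameter of the soft-margin SVM;
#'   default 1.
#' @return A [RankingResult-class] with method `"SVM"`.
#' @export
svmMarkerScores <- function(G, cost = 1) {
    stopifnot(is(G, "GenotypeMatrix"))
    pop <- populations(G)
    if (nlevels(pop) < 2L)
        stop("SVM scoring needs at least 2 populations")
    if (any(table(pop) < 2L))
        stop("every population needs at least 2 samples")
    X <- .imputedSampleMatrix(G)
    std <- .standardize(X)
    w <- matrix(0, nlevels(pop), sum(std$keep))
    for (j in seq_len(nlevels(pop))) {
        y <- factor(ifelse(pop == levels(pop)[j], "in", "out"),
                    levels = c("in", "out"))
        fit <- e1071::svm(std$X, y, kernel = "linear", cost = cost,
                          scale = FALSE)
        w[j, ] <- crossprod(fit$coefs, fit$SV)
    }
    out <- structure(numeric(ncol(X)), names = colnames(X))
    out[std$keep] <- apply(abs(w), 2L, max)
    .rankingResult(out, "SVM")
}

#' Random-forest importance scores for markers
#'
#' Trains a random-forest classifier predicting population from genotypes
#' and scores each marker by its total Gini impurity decrease, normalised
#' to sum to 1 across markers (when any split occurred). Reproducible given
#' the seed.
#'
#' @param G a [GenotypeMatrix-class] with >= 2 populations.
#' @param nTrees number of trees (default 500).
#' @param seed random seed for the forest (default 1).
#' @return A [RankingResult-class] with method `"RF"`.
#' @export
rfMarkerScores <- function(G, nTrees = 500L, seed = 1L) {
    stopifnot(is(G, "GenotypeMatrix"))
    pop <- populations(G)
    if (nlevels(pop) < 2L)
        stop("random-forest scoring needs at least 2 populations")
    if (nTrees < 1L)
        stop("'nTrees' must be >= 1")
    X <- .imputedSampleMatrix(G)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    fit <- randomForest::randomForest(X, pop, ntree = as.integer(nTrees),
                                      importance = FALSE)
    imp <- fit$importance[, "MeanDecreaseGini"]
    tot <- sum(imp)
    if (tot > 0) imp <- imp / tot
    out <- structure(as.numeric(imp), names = colnames(X))
    .rankingResult(out, "RF")
}

.Random.seed_save <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv())
    else NULL
}

.Random.seed_restore <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
}

#' Attach a genotype-based ranking to a frequency table
#'
#' Combines the marker metadata/frequencies of a table with the scores of a
#' [RankingResult-class] so that panel construction and export can be used
#' with any scoring method. Markers absent from the ranking get NA scores.
#'
#' @param table a [MarkerFrequencyTable-class].
#' @param ranking a [RankingResult-class] whose marker ids match the table.
#' @return A [ScoredMarkerTable-class].
#' @export
scoreMarkers <- function(table, ranking) {
    stopifnot(is(table, "MarkerFrequencyTable"), is(ranking, "RankingResult"))
    s <- ranking@scores[match(table@info$id, names(ranking@scores))]
    new("ScoredMarkerTable", table, score = unname(s),
        method = ranking@method)
}
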