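#' @include AllClasses.R
NULL

#' Supervised ancestry-proportion estimation
#'
#' Maximum-likelihood estimation of each sample's ancestry proportions q on
#' the simplex, given known parental allele frequencies. The model is the
#' unlinked-marker frequency mixture: the genotype at marker m is
#' Binomial(2, sum_j q_j f_jm). Estimation uses the classical multiplicative
#' EM update (each allele copy's ancestry is the latent variable), started
#' from the uniform vector and iterated until the largest change in any
#' proportion falls below `tol` or `maxIter` iterations — fully
#' deterministic. Parental frequencies are clipped to [eps, 1 - eps] to
#' keep log-likelihoods finite at fixed alleles. With identical parental
#' frequencies in all populations the data carry no ancestry information
#' and the estimate stays at the uniform start, as it should.
#'
#' Missing genotypes simply drop out of a sample's likelihood.
#'
#' @param G a [GenotypeMatrix-class] restricted to the panel markers.
#' @param parental a [MarkerFrequencyTable-class] of parental reference
#'   frequencies containing every panel marker (no missing cells for those
#'   markers).
#' @param tol convergence tolerance on max |change in q|; default 1e-6.
#' @param maxIter iteration cap; default 500.
#' @param eps frequency clipping bound; default 1e-6.
#' @return An [AncestryProportions-class], samples x populations.
#' @examples
#' tab <- simulateAncestralFrequencies(2, 200, fst = 0.25, seed = 7)
#' adm <- simulateAdmixed(tab, 10, seed = 8)
#' estimateAncestryProportions(adm@genotypes, tab)
#' @export
estimateAncestryProportions <- function(G, parental, tol = 1e-6,
                                        maxIter = 500L, eps = 1e-6) {
    stopifnot(is(G, "GenotypeMatrix"), is(parental, "MarkerFrequencyTable"))
    ids <- rownames(G)
    missing <- setdiff(ids, parental@info$id)
    if (length(missing))
        stop("panel markers absent from the parental table: ",
             paste(utils::head(missing, 5L), collapse = ", "),
             if (length(missing) > 5L) ", ..." else "")
    F <- parental@freqs[match(ids, parental@info$id), , drop = FALSE]
    if (anyNA(F))
        stop("parental frequencies must be non-missing for panel markers")
    F <- pmin(pmax(F, eps), 1 - eps)             # m x k
    g <- t(genotypes(G)) * 1.0                   # n x m
    obs <- !is.na(g)
    g[!obs] <- 0
    nAllele <- 2 * rowSums(obs)                  # per-sample allele copies
    if (any(nAllele == 0))
        stop("samples with no called genotypes cannot be estimated")
    n <- nrow(g); k <- ncol(F)
    Q <- matrix(1 / k, n, k)
    for (it in seq_len(maxIter)) {
        P <- Q %*% t(F)                          # n x m mixture freqs
        W1 <- (g / P) * obs                      # reference-allele weight
        W2 <- ((2 - g) / (1 - P)) * obs          # alternate-allele weight
        Qnew <- Q * (W1 %*% F + W2 %*% (1 - F)) / nAllele
        delta <- max(abs(Qnew - Q))
        Q <- Qnew
        if (delta < tol) break
    }
    dimnames(Q) <- list(rownames(g), parental@panel@labels)
    ## guard against round-off drifting off the simplex
    Q <- pmin(pmax(Q, 0), 1)
    Q <- Q / rowSums(Q)
    new("AncestryProportions", Q = Q)
}

#' Entries-wise RMSE between proportion matrices
#'
#' The panel-quality criterion for admixture recovery: the square root of
#' the mean, over all n x k entries, of the squared difference between true
#' and estimated ancestry proportions.
#'
#' @param Qtrue,Qest matching n x k matrices (or
#'   [AncestryProportions-class] objects).
#' @return Scalar RMSE.
#' @examples
#' rmseProportions(rbind(c(1, 0)), rbind(c(0.9, 0.1)))   # 0.1
#' @export
rmseProportions <- function(Qtrue, Qest) {
    if (is(Qtrue, "AncestryProportions")) Qtrue <- Qtrue@Q
    if (is(Qest, "AncestryProportions")) Qest <- Qest@Q
    if (!identical(dim(Qtrue), dim(Qest)))
        stop("proportion matrices must have identical dimensions")
    sqrt(mean((Qtrue - Qest)^2))
}

#' Population separation of a marker panel in PC space
#'
#' Quantifies how well a panel's genotypes separate known population
#' labels: the standardized samples x markers matrix is decomposed by PCA,
#' and the report carries the explained-variance ratios of the leading
#' components together with the mean silhouette width of the true labels
#' computed on Euclidean distances in the top-2 component space. Distinct
#' clusters give silhouettes near 1; unstructured data near 0.
#'
#' @param G a [GenotypeMatrix-class] with >= 2 populations and >= 3 samples.
#' @param nComponents number of components to report (default 10, capped
#'   by the matrix rank).
#' @return A [SeparationReport-class].
#' @export
pcaSeparation <- function(G, nComponents = 10L) {
    stopifnot(is(G, "GenotypeMatrix"))
    pop <- populations(G)
    if (nlevels(pop) < 2L)
        stop("separation needs at least 2 populations")
    if (ncol(G) < 3L)
        stop("separation needs at least 3 samples")
    X <- .imputedSampleMatrix(G)
    std <- .standardize(X)
    if (!any(std$keep))
        stop("all panel markers are constant; separation is undefined")
    pc <- stats::prcomp(std$X, center = FALSE, scale. = FALSE)
    evr <- pc$sdev^2 / sum(pc$sdev^2)
    use <- seq_len(min(as.integer(nComponents), length(evr)))
    xy <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
    sil <- cluster::silhouette(as.integer(pop), stats::dist(xy))
    new("SeparationReport", explainedVariance = evr[use],
        silhouette = mean(sil[, "sil_width"]),
        nComponents = length(use))
}
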