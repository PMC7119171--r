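#' @include AllClasses.R
NULL

## Dirichlet draws via normalised gamma variates
.rdirichlet <- function(n, alpha) {
    k <- length(alpha)
    x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
    x / rowSums(x)
}

#' Simulate ancestral allele-frequency tables (Balding-Nichols)
#'
#' Draws, for each marker, an ancestral reference-allele frequency p from
#' Uniform(`baseFreqRange`) and then one frequency per population from the
#' Balding-Nichols distribution Beta(p(1-F)/F, (1-p)(1-F)/F), whose mean is
#' p and whose spread around p grows with the divergence parameter F
#' (playing the role of FST). Small F yields genetically similar
#' populations, large F strongly differentiated ones. Markers are laid out
#' on chromosome "1" at a fixed 10 kb ladder so position-based thinning is
#' exercisable; alleles are labelled A (reference) / B.
#'
#' @param k number of ancestral populations (>= 2).
#' @param nMarkers number of markers.
#' @param fst divergence parameter in (0, 1); scalar or length-k.
#' @param baseFreqRange range of the ancestral frequency law; default
#'   c(0.05, 0.95) avoids near-monomorphic markers.
#' @param labels population names; default Pop1..Popk.
#' @param seed integer random seed (the draw is fully reproducible).
#' @return A [MarkerFrequencyTable-class] with equal unit sample weights.
#' @examples
#' tab <- simulateAncestralFrequencies(3, 5, fst = 0.15, seed = 1)
#' frequencies(tab)
#' @export
simulateAncestralFrequencies <- function(k, nMarkers, fst = 0.15,
                                         baseFreqRange = c(0.05, 0.95),
                                         labels = paste0("Pop", seq_len(k)),
                                         seed = 1L) {
    stopifnot(k >= 2, nMarkers >= 1, all(fst > 0), all(fst < 1))
    fst <- rep_len(fst, k)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    p <- stats::runif(nMarkers, baseFreqRange[1], baseFreqRange[2])
    F <- vapply(seq_len(k), function(j) {
        lambda <- (1 - fst[j]) / fst[j]
        stats::rbeta(nMarkers, p * lambda, (1 - p) * lambda)
    }, numeric(nMarkers))
    F <- matrix(F, nrow = nMarkers)
    ids <- sprintf("mk%06d", seq_len(nMarkers))
    MarkerFrequencyTable(F, PopulationPanel(labels), ids = ids,
                         chromosome = "1",
                         position = as.integer(seq_len(nMarkers) * 10000L),
                         ref = "A", alt = "B")
}

#' Simulate HWE genotypes for ancestral cohorts
#'
#' Draws, independently for every sample and marker, a reference-allele
#' count from Binomial(2, f_j) where f_j is the sample's population
#' frequency — i.e. exact Hardy-Weinberg genotype proportions within each
#' population, no linkage between markers.
#'
#' @param table a [MarkerFrequencyTable-class] without missing frequencies.
#' @param samplesPerPop samples per population; scalar or length-k.
#' @param seed integer random seed.
#' @return A [GenotypeMatrix-class] carrying the table's marker metadata.
#' @export
simulateGenotypes <- function(table, samplesPerPop, seed = 1L) {
    stopifnot(is(table, "MarkerFrequencyTable"))
    if (anyNA(table@freqs))
        stop("cannot simulate genotypes from missing frequencies")
    labs <- table@panel@labels
    sizes <- rep_len(as.integer(samplesPerPop), length(labs))
    stopifnot(all(sizes >= 1))
    m <- nrow(table@freqs)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    g <- matrix(NA_integer_, m, sum(sizes))
    at <- 0L
    for (j in seq_along(labs)) {
        block <- stats::rbinom(m * sizes[j], 2L, rep(table@freqs[, j],
                                                     times = sizes[j]))
        g[, at + seq_len(sizes[j])] <- matrix(block, m, sizes[j])
        at <- at + sizes[j]
    }
    rownames(g) <- table@info$id
    colnames(g) <- sprintf("%s_%04d", rep(labs, sizes),
                           unlist(lapply(sizes, seq_len)))
    GenotypeMatrix(g, populations = rep(labs, sizes),
                   chromosome = table@info$chromosome,
                   position = table@info$position,
                   ref = table@info$ref, alt = table@info$alt)
}

#' Simulate an admixed cohort with known ancestry proportions
#'
#' Each sample receives a true ancestry-proportion vector q drawn from
#' Dirichlet(`alpha`); its genotype at each marker is then drawn
#' Binomial(2, sum_j q_j f_j) — an unlinked-marker frequency-mixture model
#' of admixture (no local-ancestry blocks or LD are simulated). The true Q
#' matrix is returned alongside the genotypes so estimation error can be
#' measured exactly.
#'
#' @param table the parental [MarkerFrequencyTable-class] (no missing
#'   frequencies).
#' @param nAdmixed number of admixed samples.
#' @param alpha length-k Dirichlet concentration; default rep(1, k), the
#'   uniform law on the simplex.
#' @param seed integer random seed.
#' @return An [AdmixedCohort-class].
#' @export
simulateAdmixed <- function(table, nAdmixed, alpha = NULL, seed = 1L) {
    stopifnot(is(table, "MarkerFrequencyTable"), nAdmixed >= 1)
    if (anyNA(table@freqs))
        stop("cannot simulate admixed genotypes from missing frequencies")
    k <- length(table@panel@labels)
    if (is.null(alpha)) alpha <- rep(1, k)
    stopifnot(length(alpha) == k, all(alpha > 0))
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    Q <- .rdirichlet(as.integer(nAdmixed), alpha)
    colnames(Q) <- table@panel@labels
    rownames(Q) <- sprintf("ADM_%04d", seq_len(nrow(Q)))
    pi <- pmin(pmax(Q %*% t(table@freqs), 0), 1)     # n x m mixture freqs
    g <- matrix(stats::rbinom(length(pi), 2L, pi), nrow(pi), ncol(pi))
    dimnames(g) <- list(rownames(Q), table@info$id)
    G <- GenotypeMatrix(t(g), populations = rep("ADMIXED", nrow(g)),
                        chromosome = table@info$chromosome,
                        position = table@info$position,
                        ref = table@info$ref, alt = table@info$alt)
    new("AdmixedCohort", genotypes = G,
        Qtrue = new("AncestryProportions", Q = Q))
}
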