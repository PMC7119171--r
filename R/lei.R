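#' @include AllGenerics.R
NULL

#' Hardy-Weinberg expected genotype counts
#'
#' Expands a reference-allele frequency f into the expected counts of the
#' three genotype categories (mm, mM, MM) among c individuals under
#' Hardy-Weinberg equilibrium: c(1-f)^2, 2cf(1-f), cf^2. This expansion is
#' what lets the informativeness statistic be computed from summary-level
#' frequencies without individual genotypes.
#'
#' @param f reference-allele frequency in [0, 1].
#' @param c number of individuals (any positive real; only relative sizes
#'   matter downstream).
#' @param what optional marker/population tag used in error messages.
#' @return Numeric vector of length 3, summing to `c`.
#' @examples
#' hweExpectedCounts(0.79, 100)   # 4.41, 33.18, 62.41
#' @export
hweExpectedCounts <- function(f, c, what = NULL) {
    tag <- if (is.null(what)) "" else paste0(" for ", what)
    if (!is.finite(f) || f < 0 || f > 1)
        stop("allele frequency must lie in [0, 1]", tag, ", got ", f)
    if (!is.finite(c) || c <= 0)
        stop("sample count must be > 0", tag, ", got ", c)
    c(c * (1 - f)^2, 2 * c * f * (1 - f), c * f^2)
}

#' Genotype-by-population joint distribution under HWE
#'
#' Builds the estimated 3 x k joint distribution p_ij of genotype category
#' X (mm, mM, MM) and population Y for a single marker, by expanding each
#' population's reference-allele frequency into HWE-expected genotype
#' counts and normalising by the total sample size n = sum(c_j). Column
#' marginals equal c_j / n by construction.
#'
#' @param freqs length-k vector of reference-allele frequencies.
#' @param panel a [PopulationPanel-class] (or character labels, taken with
#'   equal weights).
#' @param counts optional per-population counts overriding the panel's.
#' @return A [GenotypePopulationJoint-class].
#' @examples
#' jointDistribution(c(0.79, 0.17, 0.99), c("CEU", "CHB", "YRI"))
#' @export
jointDistribution <- function(freqs, panel, counts = NULL) {
    if (is.character(panel)) panel <- PopulationPanel(panel)
    cts <- if (is.null(counts)) panel@counts else as.numeric(counts)
    k <- length(panel@labels)
    if (length(freqs) != k)
        stop("expected ", k, " frequencies, got ", length(freqs))
    n <- sum(cts)
    p <- vapply(seq_len(k), function(j)
        hweExpectedCounts(freqs[j], cts[j], what = panel@labels[j]) / n,
        numeric(3))
    dimnames(p) <- list(c("mm", "mM", "MM"), panel@labels)
    new("GenotypePopulationJoint", p = p,
        rowMarginals = rowSums(p), colMarginals = cts / n)
}

## theta^2 from a 3 x k joint-probability matrix; terms with a zero genotype
## marginal contribute 0 (their cells are exactly 0). Residuals below 1e-12
## are round-off from summing the marginals and are snapped to exact 0, so
## independence (all frequencies equal) scores exactly 0.
.leiCore <- function(p, rowMarg, colMarg) {
    total <- 0
    for (i in seq_len(nrow(p))) {
        if (rowMarg[i] > 0)
            total <- total + sum(p[i, ]^2 / (rowMarg[i] * colMarg))
    }
    res <- total - 1
    if (res < 1e-12) 0 else res
}

## vectorised theta^2 over an m x k frequency matrix with an m x k count
## matrix; same arithmetic as .leiCore applied row-wise. NA rows give NA.
.leiVec <- function(F, C) {
    n <- rowSums(C)
    P1 <- C * (1 - F)^2 / n
    P2 <- C * 2 * F * (1 - F) / n
    P3 <- C * F^2 / n
    r1 <- rowSums(P1); r2 <- rowSums(P2); r3 <- rowSums(P3)
    cm <- C / n
    term <- function(P, r) {
        out <- rowSums(P^2 / cm) / r
        out[!is.na(r) & r == 0] <- 0
        out
    }
    res <- term(P1, r1) + term(P2, r2) + term(P3, r3) - 1
    res[!is.na(res) & res < 1e-12] <- 0
    res
}

#' Lancaster estimator of independence (LEI)
#'
#' The per-marker ancestry-informativeness statistic: the mean-square
#' contingency between genotype category and population membership on the
#' HWE-expected joint table,
#' \deqn{\hat\theta^2 = \sum_{ij} \hat p_{ij}^2 / (\hat p_{i+}\hat p_{+j}) - 1.}
#' It is 0 exactly when all populations share the same allele frequency and
#' is bounded above by min(3, k) - 1: at most 1 for two populations, at most
#' 2 for three or more. Larger values mean larger allele-frequency
#' differentiation, i.e. a more ancestry-informative marker.
#'
#' Methods are provided for a prebuilt [GenotypePopulationJoint-class], for
#' a single frequency vector with a panel, and for a markers x populations
#' frequency matrix (vectorised over markers; rows with NA give NA).
#'
#' @param x a joint distribution, a length-k frequency vector, or an
#'   m x k frequency matrix.
#' @param panel a [PopulationPanel-class] or character vector of labels
#'   (equal weights); required for the frequency methods.
#' @param counts optional per-population counts overriding the panel's; for
#'   the matrix method this may also be an m x k matrix of per-marker counts.
#' @param ... passed between methods.
#' @return Numeric theta-squared value(s) in [0, min(3, k) - 1].
#' @examples
#' lei(c(0.79, 0.17, 0.99), c("CEU", "CHB", "YRI"))  # 0.7772
#' lei(c(0.4, 0.4, 0.4), c("A", "B", "C"))           # 0: non-informative
#' lei(c(0, 1), c("A", "B"))                         # 1: the k = 2 maximum
#' @name lei
NULL

#' @rdname lei
setMethod("lei", "GenotypePopulationJoint", function(x, ...)
    .leiCore(x@p, x@rowMarginals, x@colMarginals))

#' @rdname lei
setMethod("lei", "numeric", function(x, panel, counts = NULL, ...)
    lei(jointDistribution(x, panel, counts)))

#' @rdname lei
setMethod("lei", "matrix", function(x, panel, counts = NULL, ...) {
    if (is.character(panel)) panel <- PopulationPanel(panel)
    k <- length(panel@labels)
    if (ncol(x) != k)
        stop("frequency matrix must have one column per population")
    if (is.null(counts)) counts <- panel@counts
    C <- if (is.matrix(counts)) counts
         else matrix(rep(as.numeric(counts), each = nrow(x)), nrow = nrow(x))
    bad <- !is.na(x) & (x < 0 | x > 1)
    if (any(bad))
        stop("allele frequencies must lie in [0, 1]")
    out <- .leiVec(x, C)
    names(out) <- rownames(x)
    out
})

#' @rdname lei
setMethod("lei", "MarkerFrequencyTable", function(x, ...)
    lei(x@freqs, x@panel, counts = x@countsPerMarker))

#' Score every marker of a frequency table with LEI
#'
#' Applies [lei()] to each marker of a [MarkerFrequencyTable-class] using
#' the table's per-marker sample weights. Markers with any missing
#' frequency receive a missing (NA) score and a warning is issued; they are
#' never silently imputed. An all-missing table yields all-NA scores with a
#' warning, not an error.
#'
#' @param table a [MarkerFrequencyTable-class].
#' @return A [ScoredMarkerTable-class] with method tag `"LEI"`, markers in
#'   input order.
#' @examples
#' tab <- MarkerFrequencyTable(
#'     rbind(rs7289657 = c(0.55, 0.55, 0.55),
#'           rs2294368 = c(0.79, 0.17, 0.99)),
#'     c("CEU", "CHB", "YRI"))
#' scores(leiTable(tab))
#' @export
leiTable <- function(table) {
    stopifnot(is(table, "MarkerFrequencyTable"))
    if (nrow(table@freqs) == 0L)
        stop("frequency table is empty")
    miss <- rowSums(is.na(table@freqs)) > 0L
    s <- rep(NA_real_, nrow(table@freqs))
    if (any(!miss))
        s[!miss] <- unname(.leiVec(
            table@freqs[!miss, , drop = FALSE],
            table@countsPerMarker[!miss, , drop = FALSE]))
    if (any(miss))
        warning(sum(miss), " marker(s) with missing frequencies received ",
                "a missing LEI score: ",
                paste(utils::head(table@info$id[miss], 5L), collapse = ", "),
                if (sum(miss) > 5L) ", ..." else "")
    new("ScoredMarkerTable", table, score = s, method = "LEI")
}
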