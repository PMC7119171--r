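# Independent oracles and small fixture builders shared across tests.
# These deliberately re-derive quantities by a different route than the
# package (brute-force loops, Pearson phi^2 on the contingency table) so
# that agreement is evidence, not tautology.

# Pearson mean-square contingency phi^2 = sum_ij (p_ij - p_i+ p_+j)^2 /
# (p_i+ p_+j), computed by explicit loops on a joint-probability matrix.
phi2Oracle <- function(p) {
    rm_ <- rowSums(p)
    cm <- colSums(p)
    total <- 0
    for (i in seq_len(nrow(p))) {
        for (j in seq_len(ncol(p))) {
            e <- rm_[i] * cm[j]
            if (e > 0) total <- total + (p[i, j] - e)^2 / e
        }
    }
    total
}

# HWE joint-probability matrix built by naive loops (independent of the
# package's construction).
hweJointOracle <- function(freqs, counts) {
    n <- sum(counts)
    p <- matrix(0, 3, length(freqs))
    for (j in seq_along(freqs)) {
        f <- freqs[j]
        p[, j] <- counts[j] * c((1 - f)^2, 2 * f * (1 - f), f^2) / n
    }
    p
}

# brute-force entries-wise RMSE by explicit double loop
rmseOracle <- function(A, B) {
    total <- 0
    for (i in seq_len(nrow(A)))
        for (j in seq_len(ncol(A)))
            total <- total + (A[i, j] - B[i, j])^2
    sqrt(total / (nrow(A) * ncol(A)))
}

# the three-population worked example: frequencies 0.79 / 0.17 / 0.99
fig4Table <- function() {
    MarkerFrequencyTable(
        rbind(rs7289657 = c(0.55, 0.55, 0.55),
              rs2294368 = c(0.79, 0.17, 0.99)),
        PopulationPanel(c("CEU", "CHB", "YRI")),
        chromosome = "22", ref = c("A", "C"), alt = c("G", "T"))
}

# scored table with explicit coordinates for thinning tests
spacedTable <- function(positions, chromosomes, scoresVec,
                        ids = sprintf("m%02d", seq_along(positions))) {
    k <- 2
    mft <- MarkerFrequencyTable(
        matrix(0.5, length(positions), k), PopulationPanel(c("A", "B")),
        ids = ids, chromosome = chromosomes,
        position = as.integer(positions), ref = "A", alt = "B")
    new("ScoredMarkerTable", mft, score = scoresVec, method = "LEI")
}

# small fully observed genotype matrix with two clearly separated and one
# uninformative marker
toyGenotypes <- function(nPerPop = 50, seed = 42) {
    set.seed(seed)
    freqs <- rbind(sep = c(0.05, 0.95), flat = c(0.5, 0.5))
    tab <- MarkerFrequencyTable(freqs, PopulationPanel(c("A", "B")))
    simulateGenotypes(tab, nPerPop, seed = seed)
}

cliPath <- function() system.file("exec", "aimselect", package = "aimselect")

rscriptBin <- function() file.path(R.home("bin"), "Rscript")
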