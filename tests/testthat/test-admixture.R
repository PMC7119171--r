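test_that("RMSE matches hand arithmetic and a brute-force loop", {
    expect_identical(rmseProportions(rbind(c(0.8, 0.2)), rbind(c(0.8, 0.2))),
                     0)
    expect_equal(rmseProportions(rbind(c(1, 0)), rbind(c(0.9, 0.1))), 0.1)
    set.seed(81)
    for (rep in 1:20) {
        n <- sample(2:30, 1); k <- sample(2:5, 1)
        A <- matrix(rgamma(n * k, 1), n, k); A <- A / rowSums(A)
        B <- matrix(rgamma(n * k, 1), n, k); B <- B / rowSums(B)
        expect_lt(abs(rmseProportions(A, B) - rmseOracle(A, B)), 1e-12)
    }
    expect_error(rmseProportions(matrix(1, 2, 2), matrix(1, 3, 2)),
                 "dimensions")
})

test_that("pure-ancestry samples are recovered almost exactly", {
    # strongly differentiated parental frequencies, sample drawn purely
    # from population 1
    set.seed(90)
    F <- cbind(P1 = rep(c(0.05, 0.95), length.out = 500),
               P2 = rep(c(0.95, 0.05), length.out = 500))
    tab <- MarkerFrequencyTable(F, c("P1", "P2"))
    g <- matrix(rbinom(500 * 10, 2, rep(F[, 1], 10)), 500, 10)
    rownames(g) <- markerInfo(tab)$id
    colnames(g) <- paste0("s", 1:10)
    G <- GenotypeMatrix(g, populations = rep("ADMIXED", 10))
    Q <- ancestryProportions(estimateAncestryProportions(G, tab))
    expect_gt(min(Q[, "P1"]), 0.95)
})

test_that("an 80/20 two-way admixture is recovered on average", {
    tab <- simulateAncestralFrequencies(2, 1000, fst = 0.15, seed = 91)
    adm <- simulateAdmixed(tab, 200, alpha = c(80, 20), seed = 92)
    Q <- ancestryProportions(estimateAncestryProportions(adm@genotypes, tab))
    expect_lt(abs(mean(Q[, 1]) - 0.8), 0.05)
})

test_that("identical parental frequencies return the uniform start point", {
    F <- matrix(0.4, 50, 3, dimnames = list(sprintf("m%02d", 1:50), NULL))
    tab <- MarkerFrequencyTable(F, c("A", "B", "C"))
    g <- matrix(rbinom(50 * 5, 2, 0.4), 50, 5,
                dimnames = list(rownames(F), paste0("s", 1:5)))
    G <- GenotypeMatrix(g, populations = rep("ADMIXED", 5))
    Q <- ancestryProportions(estimateAncestryProportions(G, tab))
    expect_equal(unname(Q), matrix(1 / 3, 5, 3), tolerance = 1e-9)
})

test_that("estimation is deterministic and validates marker overlap", {
    tab <- simulateAncestralFrequencies(3, 300, fst = 0.15, seed = 93)
    adm <- simulateAdmixed(tab, 20, seed = 94)
    q1 <- ancestryProportions(estimateAncestryProportions(adm@genotypes, tab))
    q2 <- ancestryProportions(estimateAncestryProportions(adm@genotypes, tab))
    expect_identical(q1, q2)
    expect_error(estimateAncestryProportions(adm@genotypes, tab[1:10]),
                 "absent")
})

test_that("RMSE improves with panel size along the LEI ranking", {
    tab <- simulateAncestralFrequencies(3, 2000, fst = 0.15, seed = 95)
    st <- leiTable(tab)
    adm <- simulateAdmixed(tab, 100, seed = 96)
    rmseAt <- function(size) {
        ids <- markerInfo(buildPanel(st, topK = size))$id
        G <- adm@genotypes[ids, ]
        Q <- ancestryProportions(estimateAncestryProportions(G, tab))
        rmseProportions(trueProportions(adm), Q)
    }
    errs <- vapply(c(50, 200, 1000), rmseAt, 0)
    expect_true(all(diff(errs) <= 0.005))   # weakly decreasing
    expect_lt(errs[3], errs[1])
})

test_that("top-LEI panels beat random panels of the same size", {
    wins <- 0L
    for (rep in 1:20) {
        tab <- simulateAncestralFrequencies(3, 400, fst = 0.1,
                                            seed = 100 + rep)
        st <- leiTable(tab)
        adm <- simulateAdmixed(tab, 40, seed = 200 + rep)
        topIds <- markerInfo(buildPanel(st, topK = 50))$id
        set.seed(300 + rep)
        rndIds <- sample(markerInfo(tab)$id, 50)
        err <- function(ids) rmseProportions(
            trueProportions(adm),
            ancestryProportions(estimateAncestryProportions(
                adm@genotypes[ids, ], tab)))
        if (err(topIds) < err(rndIds)) wins <- wins + 1L
    }
    # one-sided sign test against the coin-flip null
    expect_lt(binom.test(wins, 20, alternative = "greater")$p.value, 0.01)
})

test_that("PC separation distinguishes diverse from near-identical panels", {
    tab <- simulateAncestralFrequencies(3, 3000, fst = 0.15, seed = 110)
    G <- simulateGenotypes(tab, 60, seed = 111)
    top100 <- markerInfo(buildPanel(leiTable(tab), topK = 100))$id
    rep1 <- pcaSeparation(G[top100, ])
    expect_gt(rep1@silhouette, 0.6)
    ev <- rep1@explainedVariance
    expect_true(all(diff(ev) <= 1e-12) && all(ev >= 0) && all(ev <= 1))
    # near-zero divergence: no structure to find
    flat <- simulateAncestralFrequencies(3, 100, fst = 1e-6, seed = 112)
    Gflat <- simulateGenotypes(flat, 60, seed = 113)
    expect_lt(pcaSeparation(Gflat)@silhouette, 0.2)
    # degenerate all-constant panel errors out
    gconst <- matrix(1L, 5, 12, dimnames = list(paste0("m", 1:5),
                                                paste0("s", 1:12)))
    Gc <- GenotypeMatrix(gconst, populations = rep(c("A", "B"), 6))
    expect_error(pcaSeparation(Gc), "constant")
})
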