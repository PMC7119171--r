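test_that("allele frequencies are estimated by counting reference alleles", {
    g <- rbind(snp1 = c(2L, 2L, 1L, 0L))
    colnames(g) <- paste0("s", 1:4)
    G <- GenotypeMatrix(g, populations = rep(c("A", "B"), each = 2))
    F <- frequencies(estimateFrequencies(G))
    expect_equal(unname(F["snp1", "A"]), 1)      # genotypes 2,2
    expect_equal(unname(F["snp1", "B"]), 0.25)   # genotypes 1,0
    # one-population maths on a merged group: (2+2+1+0) / (2*4) = 0.625
    Gone <- GenotypeMatrix(rbind(g, snp2 = c(2L, 2L, 2L, 2L)),
                           populations = rep(c("A", "B"), each = 2))
    F2 <- frequencies(estimateFrequencies(Gone))
    expect_equal(unname(F2["snp2", ]), c(1, 1))
})

test_that("estimated frequencies recover the truth on large HWE draws", {
    tab <- MarkerFrequencyTable(rbind(m1 = c(0.3, 0.3)), c("A", "B"))
    G <- simulateGenotypes(tab, 5000, seed = 9)
    F <- frequencies(estimateFrequencies(G))
    expect_lt(max(abs(F - 0.3)), 0.01 + 1e-9)
})

test_that("missing genotypes are excluded from frequency denominators", {
    g <- rbind(snp1 = c(2L, NA, 1L, 0L, NA, 2L))
    colnames(g) <- paste0("s", 1:6)
    G <- GenotypeMatrix(g, populations = rep(c("A", "B"), each = 3))
    tab <- estimateFrequencies(G)
    expect_equal(unname(frequencies(tab)["snp1", "A"]), 3 / 4)  # 2,1 of 2 called
    expect_equal(unname(frequencies(tab)["snp1", "B"]), 2 / 4)  # 0,2 of 2 called
    expect_equal(unname(tab@countsPerMarker["snp1", ]), c(2, 2))
    # all-missing population cell -> NA frequency with warning
    g2 <- rbind(snp1 = c(NA, NA, 1L, 0L))
    colnames(g2) <- paste0("s", 1:4)
    G2 <- GenotypeMatrix(g2, populations = rep(c("A", "B"), each = 2))
    expect_warning(tab2 <- estimateFrequencies(G2), "no called")
    expect_true(is.na(frequencies(tab2)["snp1", "A"]))
})

test_that("genotype LEI equals the two-step frequency path bit for bit", {
    G <- toyGenotypes(nPerPop = 40)
    direct <- scores(leiFromGenotypes(G))
    twostep <- scores(leiTable(estimateFrequencies(G)))
    expect_identical(direct, twostep)
})

test_that("opposite fixation scores 1 and label shuffles collapse LEI", {
    # 20 markers x 200 samples: first 100 samples all 0, rest all 2
    g <- cbind(matrix(0L, 20, 100), matrix(2L, 20, 100))
    rownames(g) <- sprintf("m%02d", 1:20)
    colnames(g) <- sprintf("s%03d", 1:200)
    G <- GenotypeMatrix(g, populations = rep(c("A", "B"), each = 100))
    expect_equal(unname(scores(leiFromGenotypes(G))), rep(1, 20))
    # permuted labels: markers become uninformative
    set.seed(5)
    Gshuf <- GenotypeMatrix(genotypes(toyGenotypes(100)),
                            populations = sample(rep(c("A", "B"), 100)))
    expect_lt(median(scores(leiFromGenotypes(Gshuf))), 0.02)
})

test_that("PCA scores separate informative from flat markers", {
    G <- toyGenotypes(nPerPop = 50)
    rk <- pcaMarkerScores(G, nComponents = 2)
    s <- scores(rk)
    expect_gt(s["sep"], s["flat"])
    expect_identical(ordering(rk)[1], "sep")
    # constant marker scores 0; duplicated columns score equally
    g <- genotypes(G)
    g <- rbind(g, const = rep(1L, ncol(g)), dup = g["sep", ])
    G2 <- GenotypeMatrix(g, populations = populations(G))
    s2 <- scores(pcaMarkerScores(G2))
    expect_identical(unname(s2["const"]), 0)
    expect_lt(abs(s2["dup"] - s2["sep"]), 1e-10)
})

test_that("SVM coefficients rank the separating marker first", {
    G <- toyGenotypes(nPerPop = 50)
    rk <- svmMarkerScores(G)
    expect_identical(ordering(rk)[1], "sep")
    expect_true(all(scores(rk) >= 0))
    # constant markers are dropped from the fit and scored 0
    g <- rbind(genotypes(G), const = rep(2L, ncol(G)))
    s <- scores(svmMarkerScores(GenotypeMatrix(g, populations(G))))
    expect_identical(unname(s["const"]), 0)
    # single population rejected
    gA <- genotypes(G)[, populations(G) == "A"]
    expect_error(svmMarkerScores(GenotypeMatrix(gA, rep("A", ncol(gA)))),
                 "2 populations")
})

test_that("random-forest importances are normalised, seeded and sensible", {
    G <- toyGenotypes(nPerPop = 50)
    rk <- rfMarkerScores(G, nTrees = 200, seed = 3)
    expect_lt(abs(sum(scores(rk)) - 1), 1e-9)
    expect_identical(ordering(rk)[1], "sep")
    # same seed reproduces, different seed is a fresh forest
    rk2 <- rfMarkerScores(G, nTrees = 200, seed = 3)
    expect_identical(scores(rk), scores(rk2))
    # constant marker gets zero importance
    g <- rbind(genotypes(G), const = rep(0L, ncol(G)))
    s <- scores(rfMarkerScores(GenotypeMatrix(g, populations(G)),
                               nTrees = 100, seed = 1))
    expect_identical(unname(s["const"]), 0)
    # the separating marker wins across many seeds
    wins <- sum(vapply(1:20, function(sd)
        ordering(rfMarkerScores(G, nTrees = 100, seed = sd))[1] == "sep",
        TRUE))
    expect_gte(wins, 19)
})

test_that("all four rankings agree on frequency-difference-driven data", {
    # informativeness controlled by |delta f| between two populations
    set.seed(77)
    m <- 200
    delta <- runif(m, 0, 0.45)
    F <- cbind(A = 0.5 - delta / 2, B = 0.5 + delta / 2)
    tab <- MarkerFrequencyTable(F, c("A", "B"))
    G <- simulateGenotypes(tab, 250, seed = 78)
    sLEI <- scores(leiFromGenotypes(G))
    for (other in list(scores(pcaMarkerScores(G)),
                       scores(svmMarkerScores(G)),
                       scores(rfMarkerScores(G, nTrees = 300, seed = 1)))) {
        rho <- cor(sLEI, other[names(sLEI)], method = "spearman")
        expect_gt(rho, 0.7)
    }
})
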