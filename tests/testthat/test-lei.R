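test_that("HWE expansion reproduces expected genotype counts and sums to c", {
    expect_equal(hweExpectedCounts(0, 10), c(10, 0, 0))
    expect_equal(hweExpectedCounts(1, 10), c(0, 0, 10))
    expect_equal(hweExpectedCounts(0.79, 100), c(4.41, 33.18, 62.41))
    for (f in seq(0, 1, by = 0.1)) {
        cnt <- hweExpectedCounts(f, 37.5)
        expect_lt(abs(sum(cnt) - 37.5), 1e-12)
        expect_true(all(cnt >= 0))
    }
    expect_error(hweExpectedCounts(1.2, 10, what = "rsX/CEU"), "rsX/CEU")
    expect_error(hweExpectedCounts(0.5, 0), "count")
})

test_that("joint distribution is normalised with the right marginals", {
    j <- jointDistribution(c(0, 1), PopulationPanel(c("A", "B")))
    expect_equal(j@p, matrix(c(0.5, 0, 0, 0, 0, 0.5), 3, 2,
                             dimnames = list(c("mm", "mM", "MM"),
                                             c("A", "B"))))
    j3 <- jointDistribution(c(0.79, 0.17, 0.99),
                            PopulationPanel(c("CEU", "CHB", "YRI")))
    expect_equal(unname(j3@rowMarginals), c(0.244367, 0.211267, 0.544367),
                 tolerance = 1e-6)
    # marginals and normalisation over random inputs
    set.seed(11)
    for (rep in 1:50) {
        k <- sample(2:6, 1)
        cts <- runif(k, 0.5, 200)
        j <- jointDistribution(runif(k), PopulationPanel(letters[1:k], cts))
        expect_lt(abs(sum(j@p) - 1), 1e-12)
        expect_lt(max(abs(j@colMarginals - cts / sum(cts))), 1e-12)
        expect_lt(max(abs(rowSums(j@p) - j@rowMarginals)), 1e-12)
    }
})

test_that("LEI reproduces the worked three-population example", {
    x <- lei(c(0.79, 0.17, 0.99), c("CEU", "CHB", "YRI"))
    expect_equal(x, 0.7772058, tolerance = 1e-6)
    expect_equal(round(x, 2), 0.78)
    # true 1000G panel sizes round to the same displayed value
    x2 <- lei(c(0.79, 0.17, 0.99),
              PopulationPanel(c("CEU", "CHB", "YRI"), c(99, 103, 108)))
    expect_equal(round(x2, 2), 0.78)
})

test_that("LEI is zero iff all populations share a frequency", {
    for (f in seq(0, 1, by = 0.05))
        expect_identical(lei(rep(f, 3), letters[1:3]), 0)
    # and strictly positive off the diagonal
    for (d in c(0.01, 0.1, 0.4))
        expect_gt(lei(c(0.5, 0.5 + d), c("A", "B")), 0)
})

test_that("LEI attains the two-population bound and matches phi^2 cases", {
    expect_equal(lei(c(0, 1), c("A", "B")), 1)
    expect_equal(lei(c(1, 0), c("A", "B")), 1)
    expect_equal(lei(c(0.6, 0.4), c("A", "B")), 0.0769230769230769,
                 tolerance = 1e-12)
})

test_that("LEI equals independently computed Pearson phi^2", {
    set.seed(101)
    for (rep in 1:1000) {
        k <- sample(2:5, 1)
        f <- runif(k)
        cts <- runif(k, 0.2, 50)
        panel <- PopulationPanel(paste0("p", 1:k), cts)
        expect_lt(abs(lei(f, panel) - phi2Oracle(hweJointOracle(f, cts))),
                  1e-10)
    }
})

test_that("LEI respects the printed bounds over random inputs", {
    set.seed(202)
    for (rep in 1:1000) {
        k <- sample(2:6, 1)
        v <- lei(runif(k), PopulationPanel(paste0("p", 1:k),
                                           runif(k, 0.1, 100)))
        expect_gte(v, -1e-9)
        expect_lte(v, min(3, k) - 1 + 1e-9)
    }
})

test_that("LEI is invariant to allele relabelling, population permutation and count scaling", {
    set.seed(303)
    for (rep in 1:200) {
        k <- sample(2:5, 1)
        f <- runif(k)
        cts <- runif(k, 0.5, 60)
        panel <- PopulationPanel(paste0("p", 1:k), cts)
        base <- lei(f, panel)
        # allele swap f -> 1 - f (genotype rows 1 and 3 exchange)
        expect_lt(abs(lei(1 - f, panel) - base), 1e-9)
        # permute populations together with their counts
        perm <- sample(k)
        expect_lt(abs(lei(f[perm], PopulationPanel(paste0("p", 1:k),
                                                   cts[perm])) - base), 1e-9)
        # rescale all counts by a common factor
        expect_lt(abs(lei(f, PopulationPanel(paste0("p", 1:k), 7.3 * cts)) -
                      base), 1e-9)
    }
})

test_that("LEI grows monotonically along the symmetric two-population line", {
    ts <- seq(0.5, 1, by = 0.01)
    vals <- vapply(ts, function(t) lei(c(t, 1 - t), c("A", "B")), 0)
    expect_identical(vals[1], 0)
    expect_equal(vals[length(vals)], 1)
    expect_true(all(diff(vals) >= -1e-12))
})

test_that("matrix, vector and joint-object LEI paths agree", {
    set.seed(404)
    k <- 4
    F <- matrix(runif(60 * k), 60, k)
    cts <- runif(k, 1, 40)
    panel <- PopulationPanel(paste0("p", 1:k), cts)
    vec <- lei(F, panel)
    scal <- vapply(seq_len(nrow(F)), function(i)
        lei(jointDistribution(F[i, ], panel)), 0)
    expect_equal(unname(vec), scal, tolerance = 1e-12)
})

test_that("leiTable scores per marker, handles missing rows, ignores count scale", {
    tab <- fig4Table()
    st <- leiTable(tab)
    expect_equal(unname(scores(st)), c(0, 0.7772058), tolerance = 1e-6)
    expect_identical(scoreMethod(st), "LEI")
    # missing frequency row -> NA score + warning, others still scored
    F <- rbind(a = c(0.2, 0.9), b = c(NA, 0.5))
    tabNA <- MarkerFrequencyTable(F, c("X", "Y"))
    expect_warning(stNA <- leiTable(tabNA), "missing")
    expect_true(is.na(scores(stNA)["b"]))
    expect_false(is.na(scores(stNA)["a"]))
    # all-missing table: all-NA scores with warning, not an error
    allNA <- MarkerFrequencyTable(rbind(c(NA, NA)), c("X", "Y"))
    expect_warning(st0 <- leiTable(allNA), "missing")
    expect_true(all(is.na(scores(st0))))
    # multiplying every count by 10 leaves scores unchanged
    tab10 <- MarkerFrequencyTable(frequencies(tab),
                                  PopulationPanel(c("CEU", "CHB", "YRI"),
                                                  c(10, 10, 10)))
    expect_equal(scores(leiTable(tab10)), scores(st), tolerance = 1e-12)
})

test_that("a single population is rejected", {
    expect_error(PopulationPanel("onlyone"), "at least 2")
})
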