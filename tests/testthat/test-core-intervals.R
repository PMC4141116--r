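ivl <- POSelect:::.classInterval
geo <- POSelect:::.geneGeometry

test_that("class core intervals follow the fenced-quartile definition", {
    # constant gene: a single-point interval
    expect_equal(ivl(c(5, 5, 5, 5)),
                 c(low = 5, high = 5, q1 = 5, q3 = 5, iqr = 0))
    # 1..5 under type-7 quartiles: Q1 = 2, Q3 = 4, fences [-1, 7] clipped to
    # the observed range [1, 5]
    expect_equal(ivl(1:5), c(low = 1, high = 5, q1 = 2, q3 = 4, iqr = 2))
    # a planted extreme value is excluded by the fence: high = Q3 + 1.5 IQR
    r <- ivl(c(1, 2, 3, 4, 100))
    expect_equal(unname(r["high"]), 7)
    expect_lt(r[["high"]], 100)
    expect_equal(unname(r["low"]), 1)
})

test_that("an interval needs at least two finite values", {
    expect_error(ivl(3), "at least 2 finite values")
    expect_error(ivl(c(1, NA, Inf)), "at least 2 finite values")
})

test_that("the quartile rule is selectable and changes the interval", {
    r7 <- ivl(1:5, 7L)
    r6 <- ivl(1:5, 6L)
    expect_equal(unname(r6[c("q1", "q3")]), c(1.5, 4.5))
    expect_false(isTRUE(all.equal(r7, r6)))
})

test_that("disjoint classes give an empty overlap and full non-overlap set", {
    pe <- peFromGenes(list(g = c(1, 2, 3, 10, 11, 12)), 3, 3)
    ci <- coreIntervals(pe)
    expect_true(is.na(ci@overlapLow))
    expect_equal(ci@overlapLength, 0)
    expect_false(any(ci@overlapSet))
    expect_true(all(ci@nonoverlap))        # all six samples, no outliers
    expect_true(all(ci@nonoutlier))
})

test_that("identical class distributions overlap completely", {
    pe <- peFromGenes(list(g = c(1:6, 1:6)), 6, 6)
    ci <- coreIntervals(pe)
    expect_equal(ci@overlapLow, ci@totalLow)
    expect_equal(ci@overlapHigh, ci@totalHigh)
    expect_equal(ci@overlapLength, ci@totalLength)
    expect_false(any(ci@nonoverlap))
})

test_that("overlap and non-overlap sets partition the non-outlier set", {
    set.seed(41)
    # partially overlapping classes, 18 + 14 samples
    vals <- c(rnorm(18), rnorm(14, mean = 1.2))
    pe <- peFromGenes(list(g = vals), 18, 14)
    ci <- coreIntervals(pe)
    inS <- ci@nonoutlier[1, ]
    expect_true(all(ci@nonoverlap[1, ] | ci@overlapSet[1, ] | !inS))
    expect_false(any(ci@nonoverlap[1, ] & ci@overlapSet[1, ]))
    expect_true(all(xor(ci@nonoverlap[1, inS], ci@overlapSet[1, inS])))
})

test_that("positive affine transforms map endpoints and keep memberships", {
    set.seed(7)
    for (i in 1:10) {
        vals <- rnorm(20)
        cls <- rep(c(1L, 2L), each = 10L)
        a <- runif(1, 0.5, 3); b <- runif(1, -5, 5)
        g0 <- geo(vals, cls)
        g1 <- geo(a * vals + b, cls)
        expect_equal(g1$totalLow, a * g0$totalLow + b)
        expect_equal(g1$totalHigh, a * g0$totalHigh + b)
        expect_equal(g1$overlapLength, a * g0$overlapLength)
        expect_equal(g1$totalLength, a * g0$totalLength)
        expect_identical(g1$nonoutlier, g0$nonoutlier)
        expect_identical(g1$overlapSet, g0$overlapSet)
        expect_identical(g1$nonoverlap, g0$nonoverlap)
    }
})

test_that("membership sets are invariant to sample order", {
    set.seed(11)
    vals <- rnorm(24); cls <- rep(c(1L, 2L), each = 12L)
    perm <- sample(24)
    g0 <- geo(vals, cls)
    g1 <- geo(vals[perm], cls[perm])
    expect_identical(g1$nonoutlier, g0$nonoutlier[perm])
    expect_identical(g1$overlapSet, g0$overlapSet[perm])
    expect_equal(g1$overlapLength, g0$overlapLength)
})

test_that("dropping an outlier outside both intervals keeps memberships", {
    # order statistics at the quartile positions are locally constant, so
    # Q1 = 2 and Q3 = 3 whether or not the extreme value is present; only
    # the range clip moves, which no retained sample occupies
    c1 <- c(1, 2, 2, 2, 2, 3, 3, 3, 100)
    c2 <- c(10, 11, 12, 13)
    g0 <- geo(c(c1, c2), rep(c(1L, 2L), c(9, 4)))
    expect_false(g0$nonoutlier[9])
    g1 <- geo(c(c1[-9], c2), rep(c(1L, 2L), c(8, 4)))
    expect_identical(g1$nonoutlier, g0$nonoutlier[-9])
    expect_identical(g1$nonoverlap, g0$nonoverlap[-9])
    expect_identical(g1$overlapSet, g0$overlapSet[-9])
})

test_that("the overlap set equals its non-outlier-restricted variant", {
    # the overlap region is the intersection of the class intervals, so any
    # sample in it lies inside its own class interval; the flag is a no-op
    sim <- simulateExpression(nInformative = 3, nPartial = 3, nNoise = 10,
                              outlierRate = 0.3, seed = 5)
    ci1 <- coreIntervals(sim, overlapOnNonoutlier = FALSE)
    ci2 <- coreIntervals(sim, overlapOnNonoutlier = TRUE)
    expect_identical(ci1@overlapSet, ci2@overlapSet)
})
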