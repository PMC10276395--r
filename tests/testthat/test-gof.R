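test_that("aggregateEntries picks the nearest rates with lexicographic ties", {
    lam <- matrix(c(1, 3, 2, 4), 2, 2)  # rows (1,2), (3,4)
    x <- matrix(0L, 2, 2)
    agg <- aggregateEntries(x, lam, 2.4, 2)
    expect_setequal(agg@lambdas, c(2, 3))
    # exhaustive case
    aggAll <- aggregateEntries(x, lam, 2.4, 4)
    expect_equal(sort(aggAll@lambdas), c(1, 2, 3, 4))
    expect_error(aggregateEntries(x, lam, 2.4, 5), "exceeds")
    expect_error(aggregateEntries(x, lam, 0, 2), "positive")
    # tie at equal distance: lower (gene, cell) index wins
    lamT <- matrix(c(1, 3, 3, 1), 2, 2)
    aggT <- aggregateEntries(x, lamT, 2, 1)
    expect_equal(aggT@genes, 1L)
    expect_equal(aggT@cells, 1L)
})

test_that("KS distance handles exact and degenerate samples", {
    # counts laid on the theoretical quantile grid: tiny distance, large p
    m <- 400L
    y <- qpois((seq_len(m) - 0.5) / m, 3)
    k <- ksPoisson(mkAggregate(y, rep(3, m), 3))
    expect_lt(k$stat, 0.05)
    expect_gt(k$p, 0.5)
    # all-zero sample against lambda0 = 5
    k0 <- ksPoisson(mkAggregate(rep(0L, 100), rep(5, 100), 5))
    expect_equal(k0$stat, 1 - exp(-5), tolerance = 1e-12)
    expect_lt(k0$p, 1e-6)
})

test_that("dispersion test flags under-dispersion with one-sided p above 1/2", {
    y <- rep(2L, 100)  # constant sample, variance 0 below mean
    d <- dispersionTest(mkAggregate(y, rep(2, 100), 2))
    expect_lt(d$alphaHat, 0)
    expect_gt(d$p, 0.5)
    expect_error(dispersionTest(mkAggregate(rep(1L, 10), rep(1, 10))),
                 "at least 30")
})

test_that("pooled and per-entry dispersion modes agree on equal rates", {
    set.seed(8)
    y <- rpois(500, 2)
    a1 <- dispersionTest(mkAggregate(y, rep(2, 500), 2))
    a2 <- dispersionTest(mkAggregate(y, rep(2, 500), 2), pooled = TRUE)
    # pooled replaces lambda by the sample mean; close but not identical
    expect_equal(a1$z, a2$z, tolerance = 0.5)
})

test_that("zero-inflation test components and sign behaviour are correct", {
    y <- c(rep(0L, 30), rep(2L, 70))
    lam <- rep(1.2, 100)
    z <- zeroInflationTest(mkAggregate(y, lam, 1.2))
    expect_equal(z$pi, 0.3)
    expect_equal(z$expected, exp(-1.2))
    expect_equal(z$varPi, sum(exp(-lam) * (1 - exp(-lam))) / 100^2)
    # no observed zeros at lambda 5: deficit, not excess
    y5 <- rep(3L, 200)
    z5 <- zeroInflationTest(mkAggregate(y5, rep(5, 200), 5))
    expect_lt(z5$z, 0)
    expect_gt(z5$p, 0.5)
    # degenerate null when every rate is huge
    zd <- zeroInflationTest(mkAggregate(rep(1000L, 50), rep(1000, 50), 1000))
    expect_true(zd$degenerate)
    expect_equal(zd$p, 1)
})

test_that("Q-Q envelope contains Poisson samples and catches over-dispersion", {
    set.seed(21)
    inFrac <- replicate(20, {
        y <- rpois(200, 4)
        qqEnvelope(mkAggregate(y, rep(4, 200), 4), nSim = 200,
                   seed = sample.int(1e6, 1))$fractionInside
    })
    expect_gt(mean(inFrac >= 0.9), 0.9)
    # sample from Poisson(4 * lambda0): upper tail exits above the band
    y <- rpois(200, 16)
    env <- qqEnvelope(mkAggregate(y, rep(4, 200), 4), nSim = 200, seed = 5)
    topIdx <- 180:200
    expect_true(any(env$observed[topIdx] > env$upper[topIdx]))
    expect_false(env$inside)
    expect_error(qqEnvelope(mkAggregate(0L, 1, 1), nSim = 5), "at least 20")
})

test_that("envelope bands stabilize as simulations accumulate", {
    y <- rpois(150, 6)
    agg <- mkAggregate(y, rep(6, 150), 6)
    e500 <- qqEnvelope(agg, nSim = 500, seed = 3)
    e1000 <- qqEnvelope(agg, nSim = 1000, seed = 4)
    expect_lte(max(abs(e500$lower - e1000$lower)), 1)
    expect_lte(max(abs(e500$upper - e1000$upper)), 1)
})

test_that("poissoneityReport assembles all diagnostics", {
    set.seed(14)
    x <- matrix(rpois(400, 2), 20, 20)
    lam <- matrix(2, 20, 20)
    rep_ <- poissoneityReport(x, lam, 2, m = 200, nSim = 100, seed = 2)
    expect_s4_class(rep_, "GofReport")
    expect_true(rep_@ks$p >= 0 && rep_@ks$p <= 1)
    expect_true(rep_@dispersion$p >= 0 && rep_@dispersion$p <= 1)
    expect_true(rep_@zeroInflation$p >= 0 && rep_@zeroInflation$p <= 1)
    expect_length(rep_@envelope$observed, 200)
})
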