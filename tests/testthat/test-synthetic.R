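test_that("generation is deterministic and satisfies count invariants", {
    sp <- syntheticSpec(G = 50, C = 40, seed = 21L)
    g1 <- generateCounts(sp)
    g2 <- generateCounts(sp)
    expect_identical(counts(g1$counts), counts(g2$counts))
    x <- counts(g1$counts)
    expect_true(all(x >= 0) && all(x == round(x)))
    # effects recentred to the two-way constraints exactly
    expect_equal(sum(exp(g1$alpha)), 50, tolerance = 1e-12)
    expect_equal(sum(exp(g1$beta)), 40, tolerance = 1e-12)
})

test_that("cluster fractions must sum to one and rates are guarded", {
    expect_error(syntheticSpec(G = 10, C = 10,
        clusters = list(list(fraction = 0.4, genes = 1:2, delta = 1))),
        "sum to 1")
    expect_error(generateCounts(syntheticSpec(G = 5, C = 5, mu = 20)),
        "overflow")
})

test_that("planted offsets raise rates only in their block", {
    g <- generateCounts(syntheticSpec(
        G = 40, C = 30, mu = log(1),
        clusters = list(list(fraction = 0.5, genes = 1:10, delta = log(4)),
                        list(fraction = 0.5, genes = integer(0), delta = 0)),
        seed = 3))
    base <- exp(g$mu) * exp(g$alpha) %o% exp(g$beta)
    expect_equal(g$rates[1:10, 1:15], 4 * base[1:10, 1:15])
    expect_equal(g$rates[11:40, ], base[11:40, ])
    expect_identical(g$truth, rep(c("1", "2"), each = 15))
})

test_that("noise models change the dispersion signature as designed", {
    spNb <- syntheticSpec(G = 100, C = 100, mu = log(2), noise = "negbin",
                          noiseParam = 1, seed = 6)
    gNb <- generateCounts(spNb)
    # given the true rates, NB counts are over-dispersed
    agg <- aggregateEntries(counts(gNb$counts), gNb$rates,
                            median(gNb$rates), 200)
    expect_lt(dispersionTest(agg)$p, 0.05)
    gZip <- generateCounts(syntheticSpec(G = 100, C = 100, mu = log(2),
                                         noise = "zip", noiseParam = 0.3,
                                         seed = 6))
    aggZ <- aggregateEntries(counts(gZip$counts), gZip$rates,
                             median(gZip$rates), 200)
    expect_lt(zeroInflationTest(aggZ)$p, 0.05)
})

test_that("fixtures are deterministic with the documented shapes", {
    f1 <- syntheticFixture("three_types_136")
    f2 <- syntheticFixture("three_types_136")
    expect_identical(counts(f1$counts), counts(f2$counts))
    expect_identical(as.integer(table(f1$truth)), c(20L, 60L, 120L))
    fh <- syntheticFixture("homogeneous_small")
    expect_identical(dim(fh$counts), c(300L, 100L))
    fd <- syntheticFixture("doubletlike")
    expect_identical(dim(fd$counts), c(300L, 100L))
    expect_error(syntheticFixture("nope"))
})

test_that("homogeneous generation passes the Poissoneity battery at true rates", {
    # all three tests jointly non-significant on one aggregate: expected
    # pass rate just above (1 - 0.05)^3, helped by the conservative KS
    ok <- sapply(1:40, function(s) {
        g <- generateCounts(syntheticSpec(G = 120, C = 120, mu = log(0.5),
                                          seed = 700 + s))
        poissoneityAccept(counts(g$counts), g$rates, lambda0 = 0.5, m = 200)
    })
    expect_gte(mean(ok), 0.85)
})

test_that("doublet-style libraries depart from an under-fitted rate model", {
    # each doublet library mixes two expression profiles in proportions
    # that vary from well to well; under a null rate model with no latent
    # structure the aggregated entries are therefore a rate mixture and
    # drift towards over-dispersion, unlike true single-profile libraries
    meanZ <- function(fx) {
        m <- filterCounts(fx$counts)
        lh <- lambdaHat(fitGlmPca(m, 0L))
        zs <- sapply(c(0.5, 1, 2), function(l0) {
            nn <- sum(lh >= l0 / 1.25 & lh <= l0 * 1.25)
            if (nn < 30) return(NA_real_)
            agg <- aggregateEntries(counts(m), lh, l0, min(200L, nn))
            dispersionTest(agg)$z
        })
        mean(zs, na.rm = TRUE)
    }
    expect_gt(meanZ(syntheticFixture("doubletlike")),
              meanZ(syntheticFixture("homogeneous_small")))
})
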