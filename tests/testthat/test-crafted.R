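test_that("zero signal strength leaves both perturbations inert", {
    g <- generateCounts(syntheticSpec(G = 80, C = 60, mu = log(0.5),
                                      seed = 2))
    m <- filterCounts(g$counts)
    expect_identical(counts(magnifyLibrary(m, 0, seed = 1)), counts(m))
    pc <- plantCluster(m, 0, nGenes = 20, nCells = 25, seed = 1)
    expect_identical(counts(pc), counts(m))
    expect_identical(sort(unique(pc@truthLabels)),
                     c("perturbed", "unperturbed"))
    expect_length(pc@perturbedCells, 25)
})

test_that("library magnification pushes cell totals along the sign of beta", {
    g <- generateCounts(syntheticSpec(G = 100, C = 80, mu = log(0.5),
                                      seed = 2))
    m <- filterCounts(g$counts)
    fit <- fitTwoWay(m)
    tots <- sapply(1:25, function(s) colSums(counts(magnifyLibrary(m, 1, seed = s))))
    drift <- rowMeans(tots) - colSums(counts(m))
    agree <- sign(fit@beta) == sign(drift)
    expect_gt(mean(agree[abs(fit@beta) > 0.05]), 0.95)
    # counts stay integral and non-negative
    pd <- magnifyLibrary(m, 2, seed = 3)
    x <- counts(pd)
    expect_true(all(x >= 0) && all(x == round(x)))
})

test_that("magnification adds Poisson counts at the analytic rate", {
    # single-cell magnification: added counts follow Poisson(|e^{mu+a+2b} - lt|)
    m <- CountMatrix(matrix(c(10L, 20L, 40L, 80L), 2, 2))
    fit <- fitTwoWay(m)
    rate <- lambdaTilde(fit)[1, 2] * abs(exp(fit@beta[2]) - 1)
    draws <- sapply(1:2000, function(s) {
        counts(magnifyLibrary(m, 1, seed = s))[1, 2] - 10 * 0 - counts(m)[1, 2]
    })
    # chi-square GOF of the positive draws against the Poisson pmf
    sgn <- sign(fit@beta[2])
    added <- draws * sgn
    tab <- table(factor(pmin(added, 9), levels = 0:9))
    pr <- dpois(0:9, rate); pr[10] <- 1 - ppois(8, rate)
    expect_gt(suppressWarnings(chisq.test(tab, p = pr))$p.value, 0.001)
})

test_that("planting doubles the perturbed block at unit signal strength", {
    g <- generateCounts(syntheticSpec(G = 150, C = 100, mu = log(1),
                                      seed = 3))
    m <- filterCounts(g$counts)
    pc <- plantCluster(m, 1, nGenes = 40, nCells = 50, seed = 7)
    lt <- lambdaTilde(fitTwoWay(m))[pc@perturbedGenes, pc@perturbedCells]
    added <- counts(pc)[pc@perturbedGenes, pc@perturbedCells] -
        counts(m)[pc@perturbedGenes, pc@perturbedCells]
    expect_true(all(added >= 0))
    expect_lt(abs(mean(added) - mean(lt)),
              4 * sqrt(mean(lt) / length(lt)))
    # top-total gene selection, deterministic under the seed
    tot <- rowSums(counts(m))
    expect_true(min(tot[pc@perturbedGenes]) >=
                max(tot[-pc@perturbedGenes]) - 1e-9)
    pc2 <- plantCluster(m, 1, nGenes = 40, nCells = 50, seed = 7)
    expect_identical(counts(pc2), counts(pc))
    expect_error(plantCluster(m, 1, nCells = 1000), "exceeds")
})

test_that("agreement metrics reproduce their closed-form cases", {
    expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
    expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
    expect_equal(adjustedRandIndex(rep(1, 6), c(1, 1, 2, 2, 3, 3)), 0)
    expect_error(adjustedRandIndex(1:3, 1:4), "length")
    expect_equal(purity(c(1, 1, 1, 1), c("a", "a", "b", "b")), 0.5)
    expect_equal(purity(1:4, c("a", "a", "b", "b")), 1)  # singleton pathology
    expect_equal(purity(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
})

test_that("ARI agrees with the mclust reference implementation", {
    skip_if_not_installed("mclust")
    set.seed(13)
    for (i in 1:20) {
        a <- sample(1:4, 30, replace = TRUE)
        b <- sample(1:3, 30, replace = TRUE)
        expect_equal(adjustedRandIndex(a, b),
                     mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    }
})

test_that("perturbation sweeps are reproducible and score F = 0 honestly", {
    g <- generateCounts(syntheticSpec(G = 60, C = 50, mu = log(1), seed = 5))
    m <- filterCounts(g$counts)
    pipe <- function(cm) {
        km <- kmeans(t(departures(dipd(cm, fitTwoWay(cm)))), 2, nstart = 5)
        km$cluster
    }
    set.seed(1)
    s1 <- sweepPerturbations(m, "cluster", FGrid = c(0, 2), nRep = 3,
                             pipeline = pipe, seed = 4, nGenes = 20,
                             nCells = 20)
    set.seed(1)
    s2 <- sweepPerturbations(m, "cluster", FGrid = c(0, 2), nRep = 3,
                             pipeline = pipe, seed = 4, nGenes = 20,
                             nCells = 20)
    expect_identical(s1$results, s2$results)
    expect_identical(nrow(s1$results), 6L)
    # at F = 0 the pipeline sees unperturbed data: ARI against the planted
    # labels equals the unperturbed-data ARI by construction
    f0 <- s1$results[s1$results$F == 0, ]
    expect_true(all(abs(f0$ari) < 0.3))  # no signal to recover
    expect_error(sweepPerturbations(m, "library", FGrid = 1, nRep = 1,
                                    pipeline = pipe), "truth")
})
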