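test_that("splitOnce bisects, is permutation invariant, flags degeneracy", {
    # two cells: one each
    sp <- splitOnce(matrix(c(0, 0, 1, 1), 2, 2))
    expect_setequal(sp$labels, 1:2)
    # well separated blobs are recovered exactly
    set.seed(6)
    V <- cbind(matrix(rnorm(40 * 25), 40, 25),
               matrix(rnorm(40 * 25, 10), 40, 25))
    sp <- splitOnce(V)
    expect_true(all(sp$labels[1:25] == 1) && all(sp$labels[26:50] == 2))
    # permuting columns permutes labels up to a swap
    perm <- sample(50)
    sp2 <- splitOnce(V[, perm])
    agree <- sp2$labels == sp$labels[perm]
    expect_true(all(agree) || all(!agree))
    # identical cells: deterministic, flagged
    spd <- splitOnce(matrix(1, 5, 4))
    expect_true(spd$degenerate)
    expect_identical(spd$labels, c(1L, 2L, 2L, 2L))
})

test_that("split significance follows the Monte-Carlo p formula", {
    set.seed(4)
    V <- cbind(matrix(rnorm(50 * 50), 50, 50),
               matrix(rnorm(50 * 50), 50, 50))
    V[1, 51:100] <- V[1, 51:100] + 10
    sp <- splitOnce(V)
    # observed CI below every null CI: p = 1 / (nMc + 1)
    expect_equal(splitSignificance(V, sp$labels, nMc = 99, seed = 8), 0.01)
    expect_error(splitSignificance(V, sp$labels, nMc = 10), "resolution")
})

test_that("split significance is calibrated on a single Gaussian cluster", {
    set.seed(3)
    ps <- replicate(120, {
        V <- matrix(rnorm(50 * 40), 50, 40)
        splitSignificance(V, splitOnce(V)$labels, nMc = 39)
    })
    expect_lte(mean(ps < 0.05), 0.08)
})

test_that("recursion respects size stops and leaf bookkeeping", {
    g <- generateCounts(syntheticSpec(G = 100, C = 15, mu = log(1),
                                      seed = 8))
    m <- filterCounts(g$counts)
    tr <- hclustDeparture(m, S = 10L, seed = 1)
    expect_identical(nLeaves(tr), 1L)  # 15 < 2 * S: no split attempted
    expect_identical(tr@root$stopReason, "min_size")
    # leaves partition all cells
    fx <- plantedTwoTypes()
    mf <- filterCounts(fx$counts)
    tr2 <- hclustDeparture(mf, seed = 1)
    lab <- leafLabels(tr2)
    expect_identical(sort(names(lab)), sort(cellIds(mf)))
    expect_true(all(nchar(lab) >= 1))
    expect_lte(nLeaves(tr2), 2^tr2@J)
})

test_that("cluster trees are deterministic and serialize byte-identically", {
    fx <- syntheticFixture("homogeneous_small")
    m <- filterCounts(fx$counts)
    t1 <- hclustDeparture(m, nMc = 30, seed = 9)
    t2 <- hclustDeparture(m, nMc = 30, seed = 9)
    expect_identical(as.character(clusterTreeJSON(t1)),
                     as.character(clusterTreeJSON(t2)))
    p <- withr::local_tempfile(fileext = ".json")
    clusterTreeJSON(t1, p)
    parsed <- jsonlite::fromJSON(p)
    expect_equal(parsed$alpha, 0.05)
    expect_equal(parsed$tree$n, ncol(counts(m)))
})

test_that("marker detection takes the right test branch and flags planted genes", {
    set.seed(10)
    G <- 120
    D <- matrix(rnorm(G * 100), G, 100)
    D[1, 51:100] <- D[1, 51:100] + 8   # one strong marker
    dm <- new("DepartureMatrix",
              values = pmin(pmax(D, qlogis(1e-10)), qlogis(1 - 1e-10)),
              geneIds = sprintf("g%d", 1:G),
              cellIds = sprintf("c%d", 1:100))
    tab <- departureMarkers(dm, 1:50, 51:100)
    expect_identical(unique(tab$test), "t")
    expect_identical(tab$category[1], "red")
    expect_lt(sum(tab$category != "black"), 10)
    # small groups take the rank-sum branch
    tabW <- departureMarkers(dm, 1:10, 51:60)
    expect_identical(unique(tabW$test), "wilcoxon")
    expect_error(departureMarkers(dm, 1:10, 5:20), "disjoint")
})

test_that("null marker comparisons rarely reach the red category", {
    set.seed(11)
    reds <- replicate(10, {
        D <- matrix(rnorm(200 * 80), 200, 80)
        dm <- new("DepartureMatrix", values = D,
                  geneIds = sprintf("g%d", 1:200),
                  cellIds = sprintf("c%d", 1:80))
        sum(departureMarkers(dm, 1:40, 41:80)$category == "red")
    })
    expect_lte(mean(reds), 0.05 * 200)
})

test_that("degenerate zero-variance genes get p = 1 under the t branch", {
    D <- matrix(rnorm(5 * 80), 5, 80)
    D[3, ] <- 0.7
    dm <- new("DepartureMatrix", values = D,
              geneIds = sprintf("g%d", 1:5), cellIds = sprintf("c%d", 1:80))
    tab <- departureMarkers(dm, 1:40, 41:80)
    expect_true(tab$degenerate[3])
    expect_equal(tab$pValue[3], 1)
})
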