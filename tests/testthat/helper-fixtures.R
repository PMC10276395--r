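# shared helpers: all fixtures are generated in code, nothing on disk

.emptyDgc <- function() {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(0, 0))
}

# an EntryAggregate built directly from a sample and its rates
mkAggregate <- function(y, lam, lambda0 = mean(lam)) {
    new("EntryAggregate", targetLambda = lambda0,
        genes = seq_along(y), cells = seq_along(y),
        counts = as.numeric(y), lambdas = as.numeric(lam))
}

# small random count matrix with positive margins
randomCounts <- function(G, C, maxCount = 20, seed = 1) {
    set.seed(seed)
    repeat {
        x <- matrix(rpois(G * C, runif(1, 1, maxCount / 2)), G, C)
        if (all(rowSums(x) > 0) && all(colSums(x) > 0)) break
    }
    CountMatrix(x)
}

# brute-force constrained MLE of the two-way model: optimize over the free
# parametrization (mu, a_1..a_{G-1}, b_1..b_{C-1}) with the last effect
# forced by the sum-of-exponentials constraints; independent of the
# closed-form path
bruteForceTwoWay <- function(x) {
    G <- nrow(x); C <- ncol(x)
    nll <- function(par) {
        mu <- par[1L]
        a <- if (G > 1L) par[2:G] else numeric(0)
        b <- if (C > 1L) par[(G + 1L):(G + C - 1L)] else numeric(0)
        restA <- G - sum(exp(a)); restB <- C - sum(exp(b))
        if (restA <= 0 || restB <= 0) return(1e10)
        alpha <- c(a, log(restA)); beta <- c(b, log(restB))
        lam <- exp(mu + outer(alpha, beta, "+"))
        -sum(x * log(lam) - lam)
    }
    p0 <- c(log(mean(x)), rep(0, G - 1L), rep(0, C - 1L))
    opt <- optim(p0, nll, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-14))
    mu <- opt$par[1L]
    a <- if (G > 1L) opt$par[2:G] else numeric(0)
    b <- if (C > 1L) opt$par[(G + 1L):(G + C - 1L)] else numeric(0)
    list(mu = mu,
         alpha = c(a, log(G - sum(exp(a)))),
         beta = c(b, log(C - sum(exp(b)))),
         logLik = -opt$value)
}

# mid-CDF by direct pmf summation, the oracle for avgCdf
avgCdfBySummation <- function(x, lam) {
    Fx <- sum(dpois(0:x, lam))
    Fxm1 <- if (x >= 1) sum(dpois(0:(x - 1), lam)) else 0
    (Fx + Fxm1) / 2
}

# planted two-type matrix used by several clustering tests
plantedTwoTypes <- function(seed = 202L) {
    generateCounts(syntheticSpec(
        G = 500, C = 200, mu = log(1),
        clusters = list(list(fraction = 0.5, rankGenes = 26:75,
                             delta = log(4)),
                        list(fraction = 0.5, genes = integer(0),
                             delta = 0)),
        seed = seed))
}
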