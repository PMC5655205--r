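# Shared fixtures: all built in code, no files.

# Sample matrix whose *sample* correlation matrix equals R exactly:
# orthonormalise iid noise against the intercept, then colour by chol(R).
exactCorSample <- function(n, R, seed = 1) {
    set.seed(seed)
    p <- ncol(R)
    X <- matrix(rnorm(n * p), n, p)
    Q <- qr.Q(qr(cbind(1, X)))[, -1L, drop = FALSE]
    (Q * sqrt(n - 1)) %*% chol(R)
}

# AR(1) series with coefficient 0.5 (the generator's root dynamics).
arSeries <- function(T, seed) {
    set.seed(seed)
    as.numeric(stats::arima.sim(list(ar = 0.5), T))
}

# Regulator/target pair with a planted transcriptional shift:
# y[t] = x[t - shift] (+ noise as a fraction of the signal sd).
plantedShiftPair <- function(T, shift, noiseFrac, seed) {
    set.seed(seed)
    full <- as.numeric(stats::arima.sim(list(ar = 0.5), T + shift))
    x <- full[(shift + 1):(shift + T)]
    y <- full[1:T] + rnorm(T, 0, noiseFrac * sd(full))
    list(x = x, y = y)
}

# Reference configuration for the bundled linear-Gaussian benchmark
# (documented in the methods vignette).
benchmarkInfer <- function(expr) {
    suppressWarnings(inferGRN(expr, theta = 0.03, kMax = 5, omega = 0.09,
                              sigma = 1))
}

# One end-to-end recovery run: returns MCC, orientation accuracy on
# true-positive undirected pairs, and delay accuracy on directed TPs.
recoveryRun <- function(seed) {
    spec <- simSpec(seed = seed)
    sim <- simulateGRNData(spec)
    grn <- benchmarkInfer(sim$expression)
    met <- classificationMetrics(confusionCounts(grn, sim$network,
                                                 directed = TRUE))
    ge <- networkEdges(sim$network)
    pe <- networkEdges(grn)
    gKey <- paste(ge$regulator, ge$target)
    pKey <- paste(pe$regulator, pe$target)
    gU <- paste(pmin(ge$regulator, ge$target), pmax(ge$regulator, ge$target))
    pU <- paste(pmin(pe$regulator, pe$target), pmax(pe$regulator, pe$target))
    undirTP <- pU %in% gU
    orient <- if (any(undirTP)) mean(pKey[undirTP] %in% gKey) else NA_real_
    tpI <- pKey %in% gKey
    delayAcc <- if (any(tpI)) {
        ids <- geneIds(grn)
        ri <- match(pe$regulator[tpI], ids)
        ti <- match(pe$target[tpI], ids)
        mean(delays(grn)[cbind(ri, ti)] ==
             delays(sim$network)[cbind(ri, ti)])
    } else NA_real_
    c(mcc = met$mcc, orient = orient, delayAcc = delayAcc)
}

# Random correlation matrix over (x, y, z) for oracle tests.
randomCor3 <- function(seed) {
    set.seed(seed)
    A <- matrix(rnorm(9), 3)
    stats::cov2cor(A %*% t(A) + diag(0.3, 3))
}
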