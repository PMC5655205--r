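test_that("the LAD-lasso LP solves exact and penalty-dominated cases", {
    set.seed(30)
    x <- rnorm(20)
    fit <- ladLassoLP(2 * x, cbind(x), lam = 0)
    expect_equal(fit$beta, 2, tolerance = 1e-8)
    expect_equal(fit$objective, 0, tolerance = 1e-8)
    # a large enough penalty forces beta to zero
    y <- rnorm(20)
    lamBig <- sum(abs(x)) * max(abs(y)) + 1
    expect_equal(ladLassoLP(y, cbind(x), lam = lamBig)$beta, 0)
})

test_that("the LP objective equals the LAD-lasso objective at the optimum", {
    for (s in 1:5) {
        set.seed(s)
        m <- 25
        X <- matrix(rnorm(m * 3), m, 3)
        y <- X %*% c(1, -0.5, 0) + rnorm(m, 0, 0.3)
        lam <- 0.7
        fit <- ladLassoLP(y, X, lam)
        recomputed <- sum(abs(y - X %*% fit$beta)) + lam * sum(abs(fit$beta))
        expect_equal(fit$objective, recomputed, tolerance = 1e-6)
    }
})

test_that("the LP matches a brute-force grid search of the objective", {
    grid <- as.matrix(expand.grid(b1 = seq(-3, 3, by = 0.01),
                                  b2 = seq(-3, 3, by = 0.01)))
    for (s in 1:20) {
        set.seed(s)
        m <- 6
        X <- matrix(rnorm(m * 2), m, 2)
        y <- X %*% runif(2, -1.5, 1.5) + rnorm(m, 0, 0.3)
        lam <- 0.1
        obj <- rowSums(abs(matrix(y, nrow(grid), m, byrow = TRUE) -
                           grid %*% t(X))) + lam * rowSums(abs(grid))
        fit <- ladLassoLP(y, X, lam)
        expect_lte(fit$objective, min(obj) + 1e-8)
        # the LP must sit within one lattice step of the points the oracle
        # cannot distinguish from its optimum (flat LAD valleys make a
        # single argmin ill-posed; slack = Lipschitz bound x grid step)
        eps <- (max(colSums(abs(X))) + lam) * 0.01
        nearOpt <- grid[obj <= min(obj) + eps, , drop = FALSE]
        gap <- min(apply(abs(nearOpt - rep(fit$beta, each = nrow(nearOpt))),
                         1, max))
        expect_lte(gap, 0.02)
    }
})

test_that("recursive optimization recovers a planted sparse model", {
    set.seed(31)
    m <- 40
    x1 <- rnorm(m); x2 <- rnorm(m)
    decoys <- matrix(rnorm(m * 3), m, 3)
    y <- 1.5 * x1 - 0.8 * x2
    fit <- recursiveOptimize(y, cbind(x1, x2, decoys), lam = 0.1,
                             theta0 = 0.1)
    expect_gt(fit$beta[1], 0)
    expect_lt(fit$beta[2], 0)
    expect_identical(fit$beta[3:5], rep(0, 3))
})

test_that("recursive optimization handles all-dropped and stable fits", {
    set.seed(32)
    m <- 20
    X <- matrix(rnorm(m * 2), m, 2)
    y <- rnorm(m)
    # huge threshold: everything dropped after the first solve
    fit <- recursiveOptimize(y, X, lam = 0.1, theta0 = 100)
    expect_identical(fit$beta, c(0, 0))
    expect_identical(fit$iterations, 1L)
    # stable on the first pass: output equals the plain LP fit
    y2 <- X %*% c(2, -2) + rnorm(m, 0, 0.1)
    one <- ladLassoLP(y2, X, lam = 0.1)
    rec <- recursiveOptimize(y2, X, lam = 0.1, theta0 = 0.1)
    expect_equal(rec$beta, one$beta)
    expect_identical(rec$iterations, 1L)
    # idempotence: re-running on the survivor set changes nothing
    surv <- which(rec$beta != 0)
    again <- recursiveOptimize(y2, X[, surv, drop = FALSE], lam = 0.1,
                               theta0 = 0.1)
    expect_equal(again$beta, rec$beta[surv])
})

test_that("pruning removes the indirect edge of a chain but keeps true edges", {
    hits <- 0
    for (s in 1:20) {
        set.seed(s)
        T <- 250
        a <- rnorm(T)
        b <- 0.8 * a + rnorm(T, 0, 0.4)
        cc <- 0.8 * b + rnorm(T, 0, 0.4)
        expr <- rbind(A = a, B = b, C = cc)
        sk <- suppressWarnings(learnSkeleton(expr, theta = 0.03))
        pr <- suppressWarnings(pruneSkeleton(expr, sk, theta0 = 0.03))
        W <- skeletonWeight(pr)
        if (W["A", "C"] == 0 && W["A", "B"] > 0 && W["B", "C"] > 0)
            hits <- hits + 1
    }
    expect_gte(hits, 16)
})

test_that("pruning never adds edges and keeps strongly regulated pairs", {
    sim <- simulateGRNData(simSpec(nGenes = 8, nEdges = 8, seed = 7))
    sk <- suppressWarnings(learnSkeleton(sim$expression, theta = 0.03))
    pr <- suppressWarnings(pruneSkeleton(sim$expression, sk))
    expect_true(all(skeletonWeight(pr)[skeletonWeight(sk) == 0] == 0))
    # single-edge skeleton with a strong true regulation: edge retained
    set.seed(33)
    x <- arSeries(150, 34)
    y <- 0.9 * x + rnorm(150, 0, 0.2)
    expr <- rbind(G1 = x, G2 = y)
    sk1 <- learnSkeleton(expr, theta = 0.03)
    expect_equal(numEdges(sk1), 1L)
    pr1 <- pruneSkeleton(expr, sk1, theta0 = 0.03)
    expect_equal(numEdges(pr1), 1L)
    expect_gt(regulationStrength(pr1)["G1", "G2"], 0)
    # empty skeleton passes through empty
    emptySk <- suppressWarnings(learnSkeleton(
        matrix(rnorm(3 * 400), 3, 400,
               dimnames = list(paste0("G", 1:3), NULL)), theta = 0.1))
    expect_equal(numEdges(pruneSkeleton(
        matrix(rnorm(3 * 400), 3, 400,
               dimnames = list(paste0("G", 1:3), NULL)), emptySk)), 0L)
})
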