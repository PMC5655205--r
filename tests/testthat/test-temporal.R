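test_that("recombine aligns series and enforces the delay bounds", {
    r <- recombine(1:5, 11:15, 2)
    expect_equal(lengths(r), c(x = 3L, y = 3L))
    expect_equal(recombine(c(1, 2, 3), c(4, 5, 6), 1),
                 list(x = c(1, 2), y = c(5, 6)))
    expect_error(recombine(1:5, 1:5, 4), "aligned")
    expect_error(recombine(1:5, 1:5, 0))
    # definition identity: MI after recombination equals MI of the slices
    x <- rnorm(30); y <- rnorm(30)
    r2 <- recombine(x, y, 3)
    expect_identical(gaussianMI(r2$x, r2$y), gaussianMI(x[1:27], y[4:30]))
})

test_that("optimal delay recovers a planted shift and breaks ties low", {
    p <- plantedShiftPair(T = 50, shift = 2, noiseFrac = 0.01, seed = 40)
    expect_equal(optimalDelay(p$x, p$y, k = 5)$delay, 2L)
    # k = 1: only one candidate
    expect_equal(optimalDelay(p$x, p$y, k = 1)$delay, 1L)
    expect_error(optimalDelay(p$x, p$y, k = 49))
    expect_error(optimalDelay(rep(1, 50), rnorm(50), k = 3),
                 class = "dbncsDegenerateInput")
})

test_that("optimal delay is invariant to affine rescaling of either series", {
    for (s in 1:10) {
        p <- plantedShiftPair(T = 50, shift = sample(1:5, 1),
                              noiseFrac = 0.1, seed = s)
        d0 <- optimalDelay(p$x, p$y, k = 5)$delay
        expect_identical(optimalDelay(3 * p$x + 7, p$y, k = 5)$delay, d0)
        expect_identical(optimalDelay(p$x, -2 * p$y + 1, k = 5)$delay, d0)
    }
})

test_that("planted delays are recovered at low noise", {
    set.seed(41)
    shifts <- sample(1:5, 30, replace = TRUE)
    hits <- sum(vapply(seq_along(shifts), function(i) {
        p <- plantedShiftPair(T = 50, shift = shifts[i], noiseFrac = 0.1,
                              seed = 1000 + i)
        optimalDelay(p$x, p$y, k = 5)$delay == shifts[i]
    }, logical(1)))
    expect_gte(hits, 26)
})

test_that("the delay matrix covers both directions and can be asymmetric", {
    # empty skeleton -> all-zero matrix
    expr0 <- matrix(rnorm(3 * 400), 3, 400,
                    dimnames = list(paste0("G", 1:3), NULL))
    sk0 <- suppressWarnings(learnSkeleton(expr0, theta = 0.2))
    expect_true(all(buildDelayMatrix(expr0, sk0, k = 3) == 0L))
    # planted pair with shift 3
    p <- plantedShiftPair(T = 80, shift = 3, noiseFrac = 0.05, seed = 42)
    expr <- rbind(G1 = p$x, G2 = p$y)
    sk <- learnSkeleton(expr, theta = 0.001)
    D <- buildDelayMatrix(expr, sk, k = 5)
    expect_identical(D["G1", "G2"], 3L)
    # the reverse direction has its own optimum: generally asymmetric
    expect_false(D["G2", "G1"] == D["G1", "G2"])
})

test_that("TRS matches the hand-computed worked example and its conventions", {
    # regulator changes at t = 1, 2, 4 steps; flat step at t = 3
    x <- c(1, 2, 3, 3, 4, 5)
    y <- c(0, 1, 2, 1, 1, 3)
    # summands over t = 1..4: ind = (1,1,0,1), sign(dy[t+1]) = (1,-1,0,1),
    # N_IC = 3 -> TRS = 1 - (1 - 1 + 0 + 1)/3
    expect_equal(trs(x, y), 1 - 1 / 3)
    # constant target: degenerate
    expect_error(trs(x, rep(2, 6)), class = "dbncsDegenerateTarget")
    # constant regulator: every product term is 0 -> TRS = 1
    expect_equal(trs(rep(1, 6), y), 1)
    # multiple regulators: all must change for the indicator to fire
    expect_equal(trs(rbind(x, rep(1, 6)), y), 1)
})

test_that("TRS stays within its structural bounds", {
    set.seed(43)
    for (i in 1:25) {
        L <- sample(5:30, 1)
        val <- trs(rnorm(L), rnorm(L))
        expect_gte(val, 1 - (L - 2))
        expect_lte(val, 2)
    }
    # trsPair = recombine then trs
    x <- rnorm(20); y <- rnorm(20)
    r <- recombine(x, y, 2)
    expect_identical(trsPair(x, y, 2), trs(r$x, r$y))
})
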