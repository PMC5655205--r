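## Transcriptional-delay estimation by delay-shifted mutual information, and
## the transcriptional regulation score (TRS) computed on delay-aligned
## series.

#' Recombine a regulator/target pair at a given delay
#'
#' Aligns a candidate regulator series x with a target series y under an
#' assumed transcriptional delay of m sampling intervals:
#' `x' = x[1..T-m]`, `y' = y[m+1..T]`, so that element t of `x'` is paired
#' with the target observed m intervals later.
#'
#' @param x,y numeric series of equal length T.
#' @param m integer delay, `1 <= m <= T - 2`.
#' @return list with components `x` and `y`, both of length `T - m`.
#' @examples
#' recombine(c(1, 2, 3), c(10, 20, 30), m = 1)
#' @export
recombine <- function(x, y, m) {
    T <- length(x)
    stopifnot(length(y) == T)
    m <- as.integer(m)
    if (m < 1L || m > T - 2L)
        stop("delay m must satisfy 1 <= m <= T - 2 (at least 2 aligned points)")
    list(x = x[seq_len(T - m)], y = y[seq.int(m + 1L, T)])
}

#' Optimal transcriptional delay between two series
#'
#' Scans delays m = 1..k, computes the Gaussian mutual information of the
#' delay-recombined pair at each m, and returns the delay that maximises it
#' (ties broken to the smallest m). Because the Gaussian MI needs at least
#' 3 aligned points, the scan is capped at `m <= T - 3`.
#'
#' @param x candidate regulator series.
#' @param y target series.
#' @param k maximum delay to consider, `k <= T - 2`.
#' @return list with `delay` (m*) and `mi` (the MI at m*).
#' @examples
#' x <- rnorm(50); y <- c(0, 0, x[1:48]) + rnorm(50, sd = 0.01)
#' optimalDelay(x, y, k = 5)$delay   # recovers 2
#' @export
optimalDelay <- function(x, y, k) {
    T <- length(x)
    stopifnot(length(y) == T, k >= 1L)
    if (k > T - 2L) stop("maximum delay k must be <= T - 2")
    .checkSeries(x, "x"); .checkSeries(y, "y")
    ms <- seq_len(min(k, T - 3L))
    mis <- vapply(ms, function(m) {
        r <- recombine(x, y, m)
        gaussianMI(r$x, r$y)
    }, numeric(1))
    best <- which.max(mis)              # which.max takes the smallest tie
    list(delay = ms[best], mi = mis[best])
}

#' Transcription delay matrix over skeleton edges
#'
#' For every surviving skeleton edge (i, j), estimates the optimal delay in
#' both directions with [optimalDelay()]; the matrix is generally
#' asymmetric. Non-edges keep delay 0. Degenerate pairs are skipped with a
#' warning, leaving 0.
#'
#' @param expr numeric genes x time matrix, time-ordered columns.
#' @param skel a [GRNSkeleton-class].
#' @param k maximum delay (sampling intervals).
#' @return integer N x N delay matrix, `delays[i, j]` = delay of regulator i
#'   acting on target j.
#' @examples
#' spec <- simSpec(nGenes = 5, nEdges = 4, seed = 2)
#' sim <- simulateGRNData(spec)
#' skel <- learnSkeleton(sim$expression, theta = 0.03)
#' buildDelayMatrix(sim$expression, skel, k = 3)
#' @export
buildDelayMatrix <- function(expr, skel, k = 5L) {
    expr <- .asExprMatrix(expr)
    stopifnot(is(skel, "GRNSkeleton"),
              identical(rownames(expr), geneIds(skel)))
    n <- nrow(expr)
    D <- matrix(0L, n, n, dimnames = list(rownames(expr), rownames(expr)))
    W <- skel@weight
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
        if (W[i, j] == 0) next
        fwd <- tryCatch(optimalDelay(expr[i, ], expr[j, ], k),
                        dbncsDegenerateInput = function(e) NULL)
        rev <- tryCatch(optimalDelay(expr[j, ], expr[i, ], k),
                        dbncsDegenerateInput = function(e) NULL)
        if (is.null(fwd) || is.null(rev))
            warning(sprintf("degenerate series for pair (%s, %s); delay left 0",
                            rownames(expr)[i], rownames(expr)[j]))
        if (!is.null(fwd)) D[i, j] <- fwd$delay
        if (!is.null(rev)) D[j, i] <- rev$delay
    }
    D
}

#' Transcriptional regulation score (TRS)
#'
#' A sign-consistency statistic over change events in delay-aligned series:
#' for each time step t, the indicator that every regulator changed between
#' t and t+1 is multiplied by the sign of the target's change between t+1
#' and t+2, and TRS = 1 - (1 / N_IC) * sum of those products, where N_IC is
#' the number of steps (in the same truncated window) at which the target
#' changes. A zero target step contributes nothing and does not count
#' towards N_IC; a target that never changes raises a degenerate-target
#' error. Series should already be delay-aligned (see [recombine()]).
#'
#' @param regulators numeric vector (one regulator) or Nv x L matrix of
#'   delay-aligned regulator series.
#' @param target numeric delay-aligned target series of length L >= 3.
#' @param changeEps tolerance below which a step counts as "no change"
#'   (default 0: exact inequality, suitable for continuous simulated data).
#' @return the TRS value (lies in `[2 - .., 2]`; 1 when no complete
#'   regulator-change event exists).
#' @examples
#' trs(c(1, 2, 3, 4, 5, 6), c(0, 1, 2, 1, 1, 3))
#' @export
trs <- function(regulators, target, changeEps = 0) {
    if (is.null(dim(regulators)))
        regulators <- matrix(regulators, nrow = 1L)
    L <- length(target)
    stopifnot(L >= 3L, ncol(regulators) == L, changeEps >= 0)
    dx <- regulators[, -1L, drop = FALSE] -
          regulators[, -L, drop = FALSE]           # Nv x (L-1)
    dy <- diff(target)
    steps <- seq_len(L - 2L)
    changed <- apply(abs(dx[, steps, drop = FALSE]) > changeEps, 2L, all)
    dyNext <- dy[steps + 1L]
    sgn <- ifelse(abs(dyNext) > changeEps, sign(dyNext), 0)
    nIC <- sum(abs(dyNext) > changeEps)
    if (nIC == 0L)
        stop(errorCondition("degenerate target: expression never changes",
                            class = c("dbncsDegenerateTarget", "error")))
    1 - sum(changed * sgn) / nIC
}

#' TRS of a directed gene pair at its optimal delay
#'
#' Convenience wrapper: recombines the pair at delay `m` and evaluates
#' [trs()] with the regulator as the single regulating series.
#'
#' @param x regulator series; @param y target series.
#' @param m delay in sampling intervals.
#' @param changeEps forwarded to [trs()].
#' @return the TRS value.
#' @export
trsPair <- function(x, y, m, changeEps = 0) {
    r <- recombine(x, y, m)
    trs(r$x, r$y, changeEps = changeEps)
}
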