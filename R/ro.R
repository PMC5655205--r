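## Regulation-strength estimation: least-absolute-deviation regression with
## an L1 penalty, solved exactly as a linear program, plus the
## threshold-and-refit loop that prunes weak regulators.

#' Least-absolute-deviation lasso regression via linear programming
#'
#' Minimises `sum_i |y_i - sum_j beta_j x_ij| + lambda * sum_j |beta_j|` by
#' the exact LP reformulation: with u_i - v_i = residual_i and
#' xi_j - eta_j = beta_j (all variables non-negative), the objective is
#' `sum(u + v) + lambda * sum(xi + eta)` subject to
#' `u_i - v_i + sum_j (xi_j - eta_j) x_ij = y_i`. The problem is always
#' feasible; the simplex solver from the boot package is used.
#'
#' @param y numeric response vector (m >= 2 samples).
#' @param X numeric m x c regressor matrix (c >= 1 candidate regulators).
#' @param lam non-negative sparsity weight lambda.
#' @return list with components `beta` (signed regulation intensities),
#'   `objective` (LP optimum, equal to the LAD-lasso objective at `beta`)
#'   and `iterations` (always 1 for a single solve).
#' @examples
#' x <- rnorm(20)
#' ladLassoLP(2 * x, cbind(x), lam = 0)$beta   # exactly 2
#' @seealso [recursiveOptimize()], [pruneSkeleton()]
#' @export
ladLassoLP <- function(y, X, lam = 1) {
    X <- as.matrix(X)
    m <- length(y)
    c <- ncol(X)
    stopifnot(m >= 2L, c >= 1L, nrow(X) == m, lam >= 0)
    A3 <- cbind(diag(m), -diag(m), X, -X)
    b3 <- y
    neg <- b3 < 0                       # simplex wants non-negative rhs
    A3[neg, ] <- -A3[neg, , drop = FALSE]
    b3[neg] <- -b3[neg]
    obj <- c(rep(1, 2L * m), rep(lam, 2L * c))
    sol <- boot::simplex(a = obj, A3 = A3, b3 = b3, maxi = FALSE,
                         n.iter = 50L * (2L * m + 2L * c))
    if (sol$solved != 1L)
        stop(sprintf("LP solver failed (status %d)", sol$solved))
    beta <- unname(sol$soln[2L * m + seq_len(c)] -
                   sol$soln[2L * m + c + seq_len(c)])
    list(beta = beta, objective = unname(sol$value), iterations = 1L)
}

#' Recursive optimization of regulation intensities
#'
#' Solves the LAD-lasso LP, sets every coefficient with `|beta_j| < theta0`
#' to zero, re-solves restricted to the surviving regulators, and repeats
#' until the survivor set is stable (or `maxRefits` solves). Coefficients of
#' dropped regulators are exactly 0 in the result; an all-zero fit is a
#' valid outcome.
#'
#' @inheritParams ladLassoLP
#' @param theta0 pruning threshold on `|beta|` (>= 0).
#' @param maxRefits cap on the number of LP solves.
#' @return list with `beta` (length `ncol(X)`, zeros for dropped
#'   regulators), `objective` (of the final restricted fit; 0-regulator fits
#'   report `sum(|y|)`) and `iterations` (number of LP solves).
#' @examples
#' x1 <- rnorm(30); x2 <- rnorm(30)
#' fit <- recursiveOptimize(1.5 * x1 - 0.8 * x2, cbind(x1, x2, rnorm(30)),
#'                          lam = 0.1, theta0 = 0.1)
#' fit$beta
#' @export
recursiveOptimize <- function(y, X, lam = 1, theta0 = 0.03,
                              maxRefits = 20L) {
    X <- as.matrix(X)
    c <- ncol(X)
    stopifnot(theta0 >= 0, maxRefits >= 1L)
    active <- seq_len(c)
    beta <- numeric(c)
    objective <- sum(abs(y))
    iterations <- 0L
    while (length(active) > 0L) {
        fit <- ladLassoLP(y, X[, active, drop = FALSE], lam)
        iterations <- iterations + 1L
        surv <- active[abs(fit$beta) >= theta0]
        if (length(surv) == length(active)) {
            beta[active] <- fit$beta
            objective <- fit$objective
            break
        }
        if (iterations >= maxRefits) {
            warning("recursiveOptimize: refit cap reached before the survivor set stabilised")
            beta[] <- 0
            beta[surv] <- fit$beta[match(surv, active)]
            objective <- fit$objective
            break
        }
        active <- surv
    }
    list(beta = beta, objective = objective, iterations = max(iterations, 1L))
}

#' Prune skeleton edges by regulation strength
#'
#' For every gene g with skeleton neighbours, fits [recursiveOptimize()]
#' with g's series as response and its neighbours' series as regressors
#' (all series z-scored so that `theta0` is comparable across genes). An
#' undirected edge (g, h) survives when the fitted intensity is non-zero in
#' at least one direction; orientation is decided later by the scoring
#' stage. Never adds edges.
#'
#' @param expr numeric genes x time matrix (or SummarizedExperiment).
#' @param skel a [GRNSkeleton-class] from [learnSkeleton()].
#' @param lam sparsity weight lambda (default 1, the convention of
#'   recursive-optimization regression).
#' @param theta0 pruning threshold on `|beta|`; defaults to the skeleton
#'   independence threshold used in practice (0.03).
#' @param maxRefits refit cap per gene.
#' @return a [GRNSkeleton-class] whose `regulationStrength()` matrix holds
#'   `|beta|` per ordered (regulator, target) pair.
#' @examples
#' spec <- simSpec(nGenes = 6, nEdges = 5, seed = 1)
#' sim <- simulateGRNData(spec)
#' skel <- learnSkeleton(sim$expression, theta = 0.03)
#' pruneSkeleton(sim$expression, skel)
#' @export
pruneSkeleton <- function(expr, skel, lam = 1, theta0 = 0.03,
                          maxRefits = 20L) {
    expr <- .asExprMatrix(expr)
    stopifnot(is(skel, "GRNSkeleton"),
              identical(rownames(expr), geneIds(skel)))
    n <- nrow(expr)
    W <- skel@weight
    sds <- apply(expr, 1L, stats::sd)
    zx <- expr
    zx[sds > 0, ] <- t(scale(t(expr[sds > 0, , drop = FALSE])))
    B <- matrix(0, n, n)                # B[i, j]: strength of i -> j
    for (g in seq_len(n)) {
        nb <- which(W[g, ] > 0)
        if (length(nb) == 0L) next
        fit <- recursiveOptimize(zx[g, ], t(zx[nb, , drop = FALSE]),
                                 lam = lam, theta0 = theta0,
                                 maxRefits = maxRefits)
        B[nb, g] <- fit$beta
    }
    newW <- W
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
        if (W[i, j] > 0 && B[i, j] == 0 && B[j, i] == 0)
            newW[i, j] <- newW[j, i] <- 0
    }
    .newSkeleton(geneIds(skel), newW, beta = abs(B),
                 orderReached = skel@orderReached)
}
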