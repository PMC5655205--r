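## Path-consistency construction of the candidate skeleton: starting from
## the complete graph, edges are removed whenever their order-L conditional
## strength (CMI2, aggregated over conditioning subsets drawn from common
## neighbours) falls below the independence threshold theta.

.asExprMatrix <- function(expr) {
    if (is(expr, "SummarizedExperiment")) {
        if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
            stop("SummarizedExperiment input needs the SummarizedExperiment package")
        expr <- SummarizedExperiment::assay(expr)
    }
    expr <- as.matrix(expr)
    if (!is.numeric(expr)) stop("expression data must be numeric")
    if (anyNA(expr) || any(!is.finite(expr)))
        stop("expression data must not contain missing or non-finite values")
    if (is.null(rownames(expr)))
        rownames(expr) <- paste0("G", seq_len(nrow(expr)))
    if (anyDuplicated(rownames(expr)))
        stop("duplicate gene ids in expression matrix")
    expr
}

#' Aggregate conditional strength of a gene pair at a given order
#'
#' Evaluates CMI2(i; j | K) over all size-`L` subsets K of the candidate
#' conditioning genes and returns either the maximum or the geometric mean.
#' When the number of subsets exceeds `maxSubsets`, the candidate set is
#' restricted to the most strongly connected candidates (largest
#' `weight[i, k] + weight[j, k]`) so that the enumeration stays within
#' budget, with a warning.
#'
#' @param expr numeric genes x time matrix.
#' @param i,j gene indices (or ids) of the pair under test.
#' @param candidates indices of conditioning candidates (excluding i and j).
#' @param L conditioning order, `1 <= L <= length(candidates)`.
#' @param aggregation `"max"` or `"geomean"`.
#' @param weight optional symmetric strength matrix used to rank candidates
#'   when capping the enumeration.
#' @param maxSubsets enumeration budget (default 10000 subsets).
#' @return the aggregated conditional strength (nats).
#' @examples
#' expr <- matrix(rnorm(5 * 100), 5, 100,
#'                dimnames = list(paste0("G", 1:5), NULL))
#' aggregateConditionalStrength(expr, 1, 2, candidates = c(3, 4, 5), L = 2)
#' @export
aggregateConditionalStrength <- function(expr, i, j, candidates, L,
                                         aggregation = c("max", "geomean"),
                                         weight = NULL,
                                         maxSubsets = 10000L) {
    aggregation <- match.arg(aggregation)
    expr <- .asExprMatrix(expr)
    if (is.character(i)) i <- match(i, rownames(expr))
    if (is.character(j)) j <- match(j, rownames(expr))
    candidates <- setdiff(as.integer(candidates), c(i, j))
    stopifnot(L >= 1L, length(candidates) >= L)
    if (choose(length(candidates), L) > maxSubsets) {
        if (is.null(weight))
            weight <- matrix(1, nrow(expr), nrow(expr))
        ord <- order(weight[i, candidates] + weight[j, candidates],
                     decreasing = TRUE)
        keep <- length(candidates)
        while (keep > L && choose(keep, L) > maxSubsets) keep <- keep - 1L
        candidates <- candidates[ord[seq_len(keep)]]
        warning(sprintf(
            "conditioning enumeration for pair (%d, %d) capped at %d strongest candidates",
            i, j, keep))
    }
    ## combn(x, m) treats a scalar x as seq_len(x); guard the 1-candidate case
    subsets <- if (length(candidates) == 1L) matrix(candidates, 1L, 1L)
               else utils::combn(candidates, L)
    vals <- apply(subsets, 2L, function(K)
        gaussianCMI2(expr[i, ], expr[j, ],
                     t(expr[K, , drop = FALSE])))
    if (aggregation == "max") max(vals)
    else exp(mean(log(vals)))
}

#' Learn the candidate-edge skeleton by conditional-independence filtering
#'
#' Order-increasing path-consistency filtering of the complete graph. At
#' order 0 every gene pair whose Gaussian mutual information falls below
#' `theta` is disconnected. At order L = 1, 2, ... each surviving pair
#' (i, j) is tested conditional on size-L subsets of the genes currently
#' adjacent to both i and j; the pair is removed when the aggregated CMI2
#' falls below `theta`. Each order is swept repeatedly (lexicographic edge
#' order, neighbourhoods recomputed after every removal) until no edge is
#' removed, then the order increments; the algorithm stops when no surviving
#' pair has enough common neighbours, and records the last order at which a
#' test was evaluated. Removal is permanent; the procedure is fully
#' deterministic.
#'
#' @param expr numeric genes x time matrix (or SummarizedExperiment).
#'   Skeleton learning is order-agnostic in time.
#' @param theta independence threshold (nats), >= 0.
#' @param orderLimit optional cap on the conditioning order (default
#'   unlimited).
#' @param aggregation subset aggregation, `"max"` (default) or `"geomean"`.
#' @param maxSubsets per-pair enumeration budget forwarded to
#'   [aggregateConditionalStrength()].
#' @return a [GRNSkeleton-class]; `skeletonWeight()` holds, for every
#'   surviving edge, the last aggregated strength that kept it.
#' @examples
#' spec <- simSpec(nGenes = 6, nEdges = 5, seed = 1)
#' sim <- simulateGRNData(spec)
#' learnSkeleton(sim$expression, theta = 0.03)
#' @export
learnSkeleton <- function(expr, theta = 0.03, orderLimit = Inf,
                          aggregation = c("max", "geomean"),
                          maxSubsets = 10000L) {
    aggregation <- match.arg(aggregation)
    stopifnot(theta >= 0)
    expr <- .asExprMatrix(expr)
    n <- nrow(expr)
    if (n < 2L) stop("need at least 2 genes")
    ids <- rownames(expr)

    degenerate <- apply(expr, 1L, stats::sd) == 0
    if (any(degenerate))
        warning(sprintf("constant expression; isolating gene(s): %s",
                        paste(ids[degenerate], collapse = ", ")))

    W <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
        if (degenerate[i] || degenerate[j]) next
        mi <- gaussianMI(expr[i, ], expr[j, ])
        if (mi >= theta) W[i, j] <- W[j, i] <- mi
    }

    orderReached <- 0L
    L <- 1L
    while (L <= orderLimit) {
        testedAtL <- FALSE
        repeat {
            removed <- FALSE
            surv <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
            if (nrow(surv) == 0L) break
            surv <- surv[order(surv[, 1L], surv[, 2L]), , drop = FALSE]
            for (r in seq_len(nrow(surv))) {
                i <- surv[r, 1L]; j <- surv[r, 2L]
                if (W[i, j] == 0) next        # removed earlier in this sweep
                cand <- which(W[i, ] > 0 & W[j, ] > 0)
                cand <- setdiff(cand, c(i, j))
                if (length(cand) < L) next
                testedAtL <- TRUE
                val <- aggregateConditionalStrength(
                    expr, i, j, cand, L, aggregation = aggregation,
                    weight = W, maxSubsets = maxSubsets)
                if (val < theta) {
                    W[i, j] <- W[j, i] <- 0
                    removed <- TRUE
                } else W[i, j] <- W[j, i] <- val
            }
            if (!removed) break
        }
        if (!testedAtL) break
        orderReached <- L
        L <- L + 1L
    }
    .newSkeleton(ids, W, orderReached = orderReached)
}
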