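## Comprehensive scoring of candidate directions, clique decomposition,
## orientation, and assembly of the final time-delayed network.

#' Background standardization
#'
#' Min-max normalization of a component score over the whole candidate-edge
#' population, mapping it to `[0, 1]` so that the linear (beta), non-linear
#' (MI) and dynamic (TRS) components are comparable. An all-equal input maps
#' to 0.5 everywhere.
#'
#' @param values numeric vector with at least one finite value.
#' @return numeric vector in `[0, 1]`.
#' @examples
#' backgroundStandardize(c(0, 5, 10))
#' @export
backgroundStandardize <- function(values) {
    if (length(values) == 0L || !any(is.finite(values)))
        stop("need at least one finite value")
    rng <- range(values)
    if (diff(rng) == 0) return(rep(0.5, length(values)))
    (values - rng[1L]) / diff(rng)
}

#' Comprehensive score of a candidate directed edge
#'
#' Convex-weighted squared combination of the three background-standardized
#' evidence components:
#' `CS = sigma * (omega * |betaRO| + (1 - omega) * betaMI)^2 +
#'       (1 - sigma) * TRS^2`,
#' where `betaRO` is the regulation intensity from recursive optimization
#' (linear evidence), `betaMI` the delay-aligned mutual information
#' (non-linear evidence) and `TRS` the transcriptional regulation score
#' (dynamic evidence). All three inputs are expected on the `[0, 1]`
#' background-standardized scale; the result is in `[0, 1]`.
#'
#' @param betaRO,betaMI,trsVal normalized component values (vectorized).
#' @param sigma trade-off between the beta composite and TRS, in `[0, 1]`
#'   (default 0.6). `sigma = 1` ignores dynamics entirely.
#' @param omega weight of the linear (RO) component against the non-linear
#'   (MI) component, in `[0, 1]`.
#' @return numeric comprehensive score(s).
#' @examples
#' comprehensiveScore(0.8, 0.4, 0.5, sigma = 0.6, omega = 0.5)  # 0.316
#' @export
comprehensiveScore <- function(betaRO, betaMI, trsVal, sigma = 0.6,
                               omega = 0.5) {
    if (length(sigma) != 1L || sigma < 0 || sigma > 1)
        stop("sigma must be a single value in [0, 1]")
    if (length(omega) != 1L || omega < 0 || omega > 1)
        stop("omega must be a single value in [0, 1]")
    sigma * (omega * abs(betaRO) + (1 - omega) * betaMI)^2 +
        (1 - sigma) * trsVal^2
}

#' Decompose a skeleton into co-expressed pair cliques
#'
#' Lossless decomposition of the pruned skeleton into its undirected edges:
#' one clique per surviving gene pair, so the number of cliques equals the
#' number of candidate regulatory relations, and their union reproduces the
#' skeleton exactly.
#'
#' @param skel a [GRNSkeleton-class].
#' @return data.frame with columns `i`, `j` (gene indices, i < j), `gene1`,
#'   `gene2` (ids) and `weight`.
#' @examples
#' spec <- simSpec(nGenes = 5, nEdges = 4, seed = 3)
#' sim <- simulateGRNData(spec)
#' decomposeCliques(learnSkeleton(sim$expression))
#' @export
decomposeCliques <- function(skel) {
    stopifnot(is(skel, "GRNSkeleton"))
    W <- skel@weight
    idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    data.frame(i = idx[, 1L], j = idx[, 2L],
               gene1 = geneIds(skel)[idx[, 1L]],
               gene2 = geneIds(skel)[idx[, 2L]],
               weight = W[idx], stringsAsFactors = FALSE)
}

#' Score both candidate directions of every clique
#'
#' For each pair clique and each of its two orientations, collects the three
#' evidence components: `betaRO` = absolute recursive-optimization intensity
#' of the candidate regulator on the target; `betaMI` = Gaussian MI of the
#' pair recombined at that direction's optimal delay; `trs` = TRS on the
#' same delay-aligned series. Components are then background-standardized
#' over the whole 2D ordered-pair population and combined into the
#' comprehensive score. A degenerate (never-changing) target makes that
#' direction's TRS 0, with a warning.
#'
#' @param expr numeric genes x time matrix.
#' @param skel pruned [GRNSkeleton-class] (its `regulationStrength()`
#'   supplies betaRO).
#' @param delayMatrix integer delay matrix from [buildDelayMatrix()].
#' @param sigma,omega comprehensive-score weights, see
#'   [comprehensiveScore()].
#' @param changeEps change tolerance forwarded to [trs()].
#' @return data.frame with one row per ordered candidate pair: `regulator`,
#'   `target`, `delay`, raw and normalized components, and `cs`.
#' @export
scoreCandidates <- function(expr, skel, delayMatrix, sigma = 0.6,
                            omega = 0.5, changeEps = 0) {
    expr <- .asExprMatrix(expr)
    cliques <- decomposeCliques(skel)
    B <- skel@beta
    ids <- geneIds(skel)
    rows <- list()
    for (r in seq_len(nrow(cliques))) {
        i <- cliques$i[r]; j <- cliques$j[r]
        for (dir in list(c(i, j), c(j, i))) {
            reg <- dir[1L]; tgt <- dir[2L]
            m <- delayMatrix[reg, tgt]
            if (m < 1L) m <- 1L        # delay estimation failed; fall back
            al <- recombine(expr[reg, ], expr[tgt, ], m)
            bmi <- tryCatch(gaussianMI(al$x, al$y),
                            dbncsDegenerateInput = function(e) 0)
            tv <- tryCatch(trs(al$x, al$y, changeEps = changeEps),
                           dbncsDegenerateTarget = function(e) {
                               warning(sprintf(
                                   "target %s never changes; TRS set to 0",
                                   ids[tgt]))
                               0
                           })
            rows[[length(rows) + 1L]] <- data.frame(
                clique = r, regulator = ids[reg], target = ids[tgt],
                ri = reg, ti = tgt, delay = as.integer(m),
                betaRO = B[reg, tgt], betaMI = bmi, trs = tv,
                stringsAsFactors = FALSE)
        }
    }
    if (length(rows) == 0L)
        return(data.frame(clique = integer(0), regulator = character(0),
                          target = character(0), ri = integer(0),
                          ti = integer(0), delay = integer(0),
                          betaRO = numeric(0), betaMI = numeric(0),
                          trs = numeric(0), betaRONorm = numeric(0),
                          betaMINorm = numeric(0), trsNorm = numeric(0),
                          cs = numeric(0), stringsAsFactors = FALSE))
    tab <- do.call(rbind, rows)
    tab$betaRONorm <- backgroundStandardize(tab$betaRO)
    tab$betaMINorm <- backgroundStandardize(tab$betaMI)
    tab$trsNorm <- backgroundStandardize(tab$trs)
    tab$cs <- comprehensiveScore(tab$betaRONorm, tab$betaMINorm,
                                 tab$trsNorm, sigma = sigma, omega = omega)
    tab
}

#' Orient each clique by comparing the comprehensive scores
#'
#' For every pair clique, the direction with the larger comprehensive score
#' wins; an exact tie is broken deterministically towards the
#' lexicographically smaller regulator id and flagged. Exactly one directed
#' edge is emitted per clique.
#'
#' @param scoreTable output of [scoreCandidates()].
#' @return data.frame with one row per clique: `regulator`, `target`,
#'   `delay`, `cs`, `tieBroken`.
#' @export
orientCliques <- function(scoreTable) {
    if (nrow(scoreTable) == 0L)
        return(data.frame(regulator = character(0), target = character(0),
                          delay = integer(0), cs = numeric(0),
                          tieBroken = logical(0), stringsAsFactors = FALSE))
    out <- lapply(split(scoreTable, scoreTable$clique), function(d) {
        stopifnot(nrow(d) == 2L)
        tie <- d$cs[1L] == d$cs[2L]
        pick <- if (tie) which.min(rank(d$regulator)) else which.max(d$cs)
        data.frame(regulator = d$regulator[pick], target = d$target[pick],
                   delay = d$delay[pick], cs = d$cs[pick], tieBroken = tie,
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Assemble oriented edges into a time-delayed GRN
#'
#' Builds the final network: the prior network is the union of the oriented
#' edges, the transition structure is the delay matrix restricted to those
#' edges, and each edge carries its comprehensive score. Duplicate directed
#' edges keep the maximum-score instance with a warning.
#'
#' @param oriented data.frame from [orientCliques()].
#' @param geneIds character vector, the gene universe.
#' @param kMax maximum delay used in the run.
#' @param candidateScores optional N x N confidence matrix over all ordered
#'   pairs (for ROC ranking).
#' @param metadata optional list of run parameters.
#' @return a [TimeDelayedGRN-class].
#' @export
assembleGRN <- function(oriented, geneIds, kMax = 5L,
                        candidateScores = NULL, metadata = list()) {
    if (nrow(oriented) > 0L) {
        key <- paste(oriented$regulator, oriented$target, sep = "\r")
        if (anyDuplicated(key)) {
            warning("duplicate directed edge(s); keeping the maximum-score instance")
            oriented <- oriented[order(-oriented$cs), , drop = FALSE]
            oriented <- oriented[!duplicated(paste(oriented$regulator,
                                                   oriented$target,
                                                   sep = "\r")), ,
                                 drop = FALSE]
        }
    }
    prior <- makeNetwork(geneIds, oriented$regulator, oriented$target,
                         delay = if (nrow(oriented)) oriented$delay else NA_integer_,
                         score = if (nrow(oriented)) oriented$cs else NA_real_,
                         directed = TRUE)
    n <- length(geneIds)
    D <- matrix(0L, n, n)
    if (nrow(oriented) > 0L) {
        ri <- match(oriented$regulator, geneIds)
        ti <- match(oriented$target, geneIds)
        D[cbind(ri, ti)] <- as.integer(oriented$delay)
    }
    .newGRN(geneIds, prior, D, kMax, candidateScores, metadata)
}

#' Infer a multiple time-delayed gene regulatory network
#'
#' The full pipeline: (1) conditional-independence skeleton learning with
#' CMI2 ([learnSkeleton()]); (2) redundant-edge pruning by recursive
#' LAD-lasso optimization ([pruneSkeleton()]); (3) per-direction
#' transcriptional-delay estimation ([buildDelayMatrix()]); (4) clique
#' decomposition and orientation of every co-expressed pair by the
#' comprehensive score ([scoreCandidates()], [orientCliques()]); (5)
#' assembly into the final directed network with its delay matrix
#' ([assembleGRN()]). Fully deterministic for fixed inputs and parameters.
#'
#' @param expr numeric genes x time matrix with gene ids as rownames (or a
#'   SummarizedExperiment), columns in chronological order and equally
#'   spaced.
#' @param theta independence threshold of the skeleton stage (nats).
#' @param kMax maximum transcriptional delay considered (sampling
#'   intervals).
#' @param omega,sigma comprehensive-score weights, see
#'   [comprehensiveScore()].
#' @param lambda sparsity weight of the LAD-lasso stage.
#' @param theta0 regulation-strength pruning threshold (defaults to
#'   `theta`).
#' @param aggregation,orderLimit,maxSubsets skeleton options, see
#'   [learnSkeleton()].
#' @param changeEps TRS change tolerance, see [trs()].
#' @return a [TimeDelayedGRN-class]; `candidateScores()` holds the CS of
#'   every surviving ordered pair (0 for pairs removed earlier), and
#'   `metadata()` records the parameters and the skeleton order reached.
#' @examples
#' spec <- simSpec(nGenes = 6, nEdges = 5, seed = 4)
#' sim <- simulateGRNData(spec)
#' grn <- inferGRN(sim$expression, theta = 0.03)
#' networkEdges(grn)
#' @export
inferGRN <- function(expr, theta = 0.03, kMax = 5L, omega = 0.5,
                     sigma = 0.6, lambda = 1, theta0 = theta,
                     aggregation = c("max", "geomean"), orderLimit = Inf,
                     maxSubsets = 10000L, changeEps = 0) {
    aggregation <- match.arg(aggregation)
    expr <- .asExprMatrix(expr)
    skel <- learnSkeleton(expr, theta = theta, orderLimit = orderLimit,
                          aggregation = aggregation,
                          maxSubsets = maxSubsets)
    pruned <- pruneSkeleton(expr, skel, lam = lambda, theta0 = theta0)
    D <- buildDelayMatrix(expr, pruned, k = kMax)
    tab <- scoreCandidates(expr, pruned, D, sigma = sigma, omega = omega,
                           changeEps = changeEps)
    oriented <- orientCliques(tab)
    n <- nrow(expr)
    CS <- matrix(0, n, n)
    if (nrow(tab) > 0L) CS[cbind(tab$ri, tab$ti)] <- tab$cs
    assembleGRN(oriented, rownames(expr), kMax = kMax,
                candidateScores = CS,
                metadata = list(theta = theta, kMax = kMax, omega = omega,
                                sigma = sigma, lambda = lambda,
                                theta0 = theta0, aggregation = aggregation,
                                changeEps = changeEps,
                                orderReached = orderReached(pruned)))
}
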