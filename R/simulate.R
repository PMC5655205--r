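## Synthetic-data generator: random delayed DAGs and delayed linear-Gaussian
## time courses with known ground truth, so that every pipeline stage is
## testable without external data.

#' Specification of a synthetic delayed-network simulation
#'
#' Collects the parameters of the generator. Defaults describe the standard
#' benchmark regime used throughout the package tests: a 10-gene, 10-edge
#' DAG observed over 50 equally spaced time points with process noise 0.2
#' (root drivers have unit innovation variance, so noise is about 20% of
#' signal scale). Regulatory coefficients avoid a dead zone around zero
#' (|w| >= `coeffMin`) so planted edges are identifiable; delays are uniform
#' on `1..kMax`. The default `kMax = 1` reflects identifiability under the
#' AR(1) root dynamics (autocorrelation 0.5 per lag): the contemporaneous
#' dependence measured by the skeleton stage decays as `0.5^delay`, which at
#' T = 50 puts delays of two or more sampling intervals below the detection
#' floor of the null MI distribution regardless of coefficient size. Larger
#' `kMax` values are fully supported for delay-estimation studies.
#'
#' @param nGenes number of genes (>= 2).
#' @param nEdges number of directed edges in the planted DAG.
#' @param kMax maximum transcriptional delay (sampling intervals).
#' @param timePoints length T of the recorded series (`T >= kMax + 3`).
#' @param noiseSd process noise standard deviation for regulated genes.
#' @param coeffMin,coeffMax magnitude range of regulatory coefficients
#'   (sign random).
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @return list of class `SimSpec`.
#' @examples
#' simSpec(nGenes = 10, nEdges = 10, seed = 7)
#' @export
simSpec <- function(nGenes = 10L, nEdges = 10L, kMax = 1L,
                    timePoints = 50L, noiseSd = 0.2, coeffMin = 0.4,
                    coeffMax = 1, seed = 1L) {
    stopifnot(nGenes >= 2L, nEdges >= 0L, kMax >= 1L,
              timePoints >= kMax + 3L, noiseSd >= 0,
              coeffMin > 0, coeffMax >= coeffMin)
    if (nEdges > nGenes * (nGenes - 1L) / 2L)
        stop("nEdges exceeds the number of pairs in a DAG skeleton")
    structure(list(nGenes = as.integer(nGenes), nEdges = as.integer(nEdges),
                   kMax = as.integer(kMax),
                   timePoints = as.integer(timePoints),
                   noiseSd = noiseSd, coeffMin = coeffMin,
                   coeffMax = coeffMax, seed = as.integer(seed)),
              class = "SimSpec")
}

#' Sample a random delayed DAG
#'
#' Draws a uniformly random topological order of the genes, samples exactly
#' `nEdges` distinct pairs respecting that order, and assigns each edge a
#' delay uniform on `1..kMax` and a signed coefficient with magnitude
#' uniform on `[coeffMin, coeffMax]`. Deterministic given `spec$seed`.
#'
#' @param spec a `SimSpec` from [simSpec()].
#' @return a [TimeDelayedGRN-class]; edge scores hold the signed
#'   coefficients.
#' @examples
#' net <- sampleNetwork(simSpec(nGenes = 10, nEdges = 10, seed = 7))
#' networkEdges(net)
#' @export
sampleNetwork <- function(spec) {
    stopifnot(inherits(spec, "SimSpec"))
    set.seed(spec$seed)
    n <- spec$nGenes
    ids <- paste0("G", seq_len(n))
    topo <- sample(n)                   # topo[r] = gene at rank r
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    chosen <- pairs[sample(nrow(pairs), spec$nEdges), , drop = FALSE]
    reg <- topo[chosen[, 1L]]           # earlier rank regulates later rank
    tgt <- topo[chosen[, 2L]]
    dl <- sample(spec$kMax, spec$nEdges, replace = TRUE)
    w <- sample(c(-1, 1), spec$nEdges, replace = TRUE) *
        stats::runif(spec$nEdges, spec$coeffMin, spec$coeffMax)
    ord <- order(reg, tgt)
    prior <- makeNetwork(ids, ids[reg[ord]], ids[tgt[ord]],
                         delay = dl[ord], score = w[ord], directed = TRUE)
    D <- matrix(0L, n, n)
    D[cbind(reg, tgt)] <- as.integer(dl)
    .newGRN(ids, prior, D, spec$kMax,
            metadata = list(seed = spec$seed))
}

#' Simulate delayed linear-Gaussian expression dynamics
#'
#' Generates a time course from a delayed network:
#' `x_j[t] = sum_{i in Pa(j)} w_ij * x_i[t - delay_ij] + eps_j[t]` with
#' `eps ~ N(0, noiseSd^2)` for regulated genes; parentless (root) genes
#' evolve as AR(1) with coefficient 0.5 and unit innovation variance, so
#' they act as persistent exogenous drivers. A burn-in of `kMax + 10` steps
#' is discarded. Deterministic given the spec seed (offset from the
#' network-sampling stream).
#'
#' @param net a [TimeDelayedGRN-class] whose edge scores are the
#'   coefficients (as produced by [sampleNetwork()]).
#' @param spec the matching `SimSpec`.
#' @return numeric genes x time matrix with gene ids as rownames.
#' @examples
#' spec <- simSpec(nGenes = 5, nEdges = 4, seed = 11)
#' expr <- simulateExpression(sampleNetwork(spec), spec)
#' dim(expr)
#' @export
simulateExpression <- function(net, spec) {
    stopifnot(is(net, "TimeDelayedGRN"), inherits(spec, "SimSpec"))
    e <- networkEdges(net)
    if (nrow(e) > 0L && max(e$delay) > spec$kMax)
        stop("network delays exceed spec kMax")
    n <- length(geneIds(net))
    ids <- geneIds(net)
    burn <- spec$kMax + 10L
    total <- spec$timePoints + burn
    ri <- match(e$regulator, ids); ti <- match(e$target, ids)
    isRoot <- !(seq_len(n) %in% ti)
    set.seed(spec$seed + 100003L)
    eps <- matrix(stats::rnorm(n * total), n, total)
    eps[isRoot, ] <- eps[isRoot, , drop = FALSE] * 1
    eps[!isRoot, ] <- eps[!isRoot, , drop = FALSE] * spec$noiseSd
    x <- matrix(0, n, total)
    for (t in seq_len(total)) {
        v <- eps[, t]
        if (t > 1L) v[isRoot] <- v[isRoot] + 0.5 * x[isRoot, t - 1L]
        if (nrow(e) > 0L) {
            lagOK <- t - e$delay >= 1L
            if (any(lagOK)) {
                contrib <- e$score[lagOK] *
                    x[cbind(ri[lagOK], t - e$delay[lagOK])]
                v <- v + unname(tapply(contrib, factor(ti[lagOK],
                                                       levels = seq_len(n)),
                                       sum, default = 0))
            }
        }
        if (any(abs(v) > 1e6))
            stop("explosive dynamics; use smaller coefficients")
        x[, t] <- v
    }
    out <- x[, seq.int(burn + 1L, total), drop = FALSE]
    dimnames(out) <- list(ids, paste0("t", seq_len(spec$timePoints)))
    out
}

#' Simulate a network and its expression data in one call
#'
#' @param spec a `SimSpec`.
#' @return list with elements `network` (the planted
#'   [TimeDelayedGRN-class]) and `expression` (genes x time matrix).
#' @examples
#' sim <- simulateGRNData(simSpec(nGenes = 6, nEdges = 5, seed = 3))
#' names(sim)
#' @export
simulateGRNData <- function(spec) {
    net <- sampleNetwork(spec)
    list(network = net, expression = simulateExpression(net, spec))
}
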