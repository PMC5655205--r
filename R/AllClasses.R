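#' @import methods
NULL

.emptyEdges <- function() {
    data.frame(regulator = character(0), target = character(0),
               delay = integer(0), score = numeric(0),
               stringsAsFactors = FALSE)
}

#' Directed or undirected gene network
#'
#' A set of (regulator, target) edges over a fixed gene universe. Each edge
#' may carry an integer transcriptional delay (in sampling intervals) and a
#' numeric score. Undirected networks store each edge once, with the
#' endpoint that comes first in `geneIds` as `regulator`; membership is
#' symmetric.
#'
#' @slot geneIds character vector of unique gene identifiers (the universe).
#' @slot edges data.frame with columns `regulator`, `target`, `delay`
#'   (integer, `NA` when not applicable) and `score` (numeric, `NA` when not
#'   applicable).
#' @slot directed logical scalar.
#'
#' @seealso [readNetwork()], [writeNetwork()], [confusionCounts()]
#' @exportClass Network
setClass("Network",
    representation(geneIds = "character", edges = "data.frame",
                   directed = "logical"))

setValidity("Network", function(object) {
    msg <- character(0)
    g <- object@geneIds
    e <- object@edges
    if (anyDuplicated(g))
        msg <- c(msg, "duplicated gene ids")
    if (!all(c("regulator", "target", "delay", "score") %in% names(e)))
        msg <- c(msg, "edges must have regulator, target, delay, score columns")
    else {
        if (any(e$regulator == e$target))
            msg <- c(msg, "self-loops are not allowed")
        if (!all(e$regulator %in% g) || !all(e$target %in% g))
            msg <- c(msg, "edge endpoint not in geneIds")
        if (length(object@directed) != 1L)
            msg <- c(msg, "directed must be a logical scalar")
        else if (!object@directed && nrow(e) > 0L) {
            ri <- match(e$regulator, g); ti <- match(e$target, g)
            if (any(ri >= ti))
                msg <- c(msg, "undirected edges must be stored with regulator before target in geneIds order")
        }
        key <- paste(e$regulator, e$target, sep = "\r")
        if (anyDuplicated(key))
            msg <- c(msg, "duplicated edges")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a Network
#'
#' @param geneIds character vector of gene identifiers.
#' @param regulator,target character vectors of equal length naming edges.
#' @param delay optional integer vector of per-edge delays.
#' @param score optional numeric vector of per-edge scores.
#' @param directed logical; undirected edges are canonicalised so that the
#'   endpoint appearing first in `geneIds` is stored as `regulator`.
#' @return a [Network-class] object.
#' @examples
#' makeNetwork(c("G1", "G2", "G3"), regulator = "G1", target = "G2")
#' @export
makeNetwork <- function(geneIds, regulator = character(0),
                        target = character(0), delay = NA_integer_,
                        score = NA_real_, directed = TRUE) {
    n <- length(regulator)
    stopifnot(length(target) == n)
    e <- data.frame(regulator = as.character(regulator),
                    target = as.character(target),
                    delay = as.integer(rep_len(delay, n)),
                    score = as.numeric(rep_len(score, n)),
                    stringsAsFactors = FALSE)
    if (!directed && n > 0L) {
        ri <- match(e$regulator, geneIds); ti <- match(e$target, geneIds)
        flip <- ri > ti
        tmp <- e$regulator[flip]
        e$regulator[flip] <- e$target[flip]
        e$target[flip] <- tmp
        e <- e[!duplicated(paste(e$regulator, e$target, sep = "\r")), ,
               drop = FALSE]
        rownames(e) <- NULL
    }
    new("Network", geneIds = as.character(geneIds), edges = e,
        directed = directed)
}

#' Candidate-edge skeleton from path-consistency filtering
#'
#' The undirected search space that survives CMI2-based conditional
#' independence filtering (and, optionally, regulation-strength pruning).
#' `weight[i, j]` holds the last aggregated strength that kept edge (i, j);
#' 0 means removed. `beta[i, j]` holds the absolute regulation intensity of
#' gene i on gene j estimated by the recursive-optimization stage (all zero
#' before pruning).
#'
#' @slot geneIds character vector of gene identifiers.
#' @slot weight symmetric numeric matrix with zero diagonal.
#' @slot beta numeric matrix of absolute regulation intensities per ordered
#'   pair (regulator in rows, target in columns).
#' @slot orderReached integer; highest conditioning order at which any CMI2
#'   test was evaluated before termination.
#'
#' @seealso [learnSkeleton()], [pruneSkeleton()]
#' @exportClass GRNSkeleton
setClass("GRNSkeleton",
    representation(geneIds = "character", weight = "matrix",
                   beta = "matrix", orderReached = "integer"))

setValidity("GRNSkeleton", function(object) {
    msg <- character(0)
    n <- length(object@geneIds)
    W <- object@weight
    if (!is.numeric(W) || nrow(W) != n || ncol(W) != n)
        msg <- c(msg, "weight must be an N x N numeric matrix")
    else {
        if (any(abs(W - t(W)) > 1e-12)) msg <- c(msg, "weight must be symmetric")
        if (any(diag(W) != 0)) msg <- c(msg, "weight diagonal must be zero")
        if (any(W < 0)) msg <- c(msg, "weights must be non-negative")
    }
    if (!identical(dim(object@beta), dim(W)))
        msg <- c(msg, "beta must have the same dimensions as weight")
    if (length(object@orderReached) != 1L || object@orderReached < 0L)
        msg <- c(msg, "orderReached must be a single non-negative integer")
    if (length(msg)) msg else TRUE
})

.newSkeleton <- function(geneIds, weight, beta = NULL, orderReached = 0L) {
    n <- length(geneIds)
    dimnames(weight) <- list(geneIds, geneIds)
    if (is.null(beta)) beta <- matrix(0, n, n)
    dimnames(beta) <- list(geneIds, geneIds)
    new("GRNSkeleton", geneIds = geneIds, weight = weight, beta = beta,
        orderReached = as.integer(orderReached))
}

#' Time-delayed gene regulatory network
#'
#' The result of the full inference pipeline (or of the simulator): a
#' directed prior network over the genes paired with the transition
#' structure of a dynamic Bayesian network, encoded as an integer delay
#' matrix (`delays[i, j]` = number of sampling intervals by which target j
#' lags regulator i; 0 for non-edges). Edge scores are the per-edge
#' comprehensive scores (or, for simulated networks, the signed regulatory
#' coefficients). `candidateScores` optionally ranks every ordered gene pair
#' for ROC analysis.
#'
#' @slot geneIds character vector of gene identifiers.
#' @slot prior directed [Network-class].
#' @slot delays integer N x N matrix; entries for non-edges are 0.
#' @slot kMax integer; maximum allowed delay.
#' @slot candidateScores numeric N x N matrix of edge confidences (0 for
#'   pairs removed before scoring), or a 0 x 0 matrix when absent.
#' @slot metadata list of run parameters and diagnostics.
#'
#' @seealso [inferGRN()], [sampleNetwork()], [writeNetwork()]
#' @exportClass TimeDelayedGRN
setClass("TimeDelayedGRN",
    representation(geneIds = "character", prior = "Network",
                   delays = "matrix", kMax = "integer",
                   candidateScores = "matrix", metadata = "list"))

setValidity("TimeDelayedGRN", function(object) {
    msg <- character(0)
    g <- object@geneIds
    n <- length(g)
    if (!object@prior@directed)
        msg <- c(msg, "prior network must be directed")
    if (!identical(object@prior@geneIds, g))
        msg <- c(msg, "prior network gene universe must match geneIds")
    D <- object@delays
    if (nrow(D) != n || ncol(D) != n)
        msg <- c(msg, "delays must be an N x N matrix")
    else {
        e <- object@prior@edges
        ri <- match(e$regulator, g); ti <- match(e$target, g)
        onEdge <- matrix(FALSE, n, n)
        onEdge[cbind(ri, ti)] <- TRUE
        if (nrow(e) > 0L &&
            (any(D[cbind(ri, ti)] < 1L) || any(D[cbind(ri, ti)] > object@kMax)))
            msg <- c(msg, "every prior edge needs a delay in [1, kMax]")
        if (any(D[!onEdge] != 0L))
            msg <- c(msg, "delay entries for non-edges must be 0")
    }
    if (length(msg)) msg else TRUE
})

.newGRN <- function(geneIds, prior, delays, kMax, candidateScores = NULL,
                    metadata = list()) {
    dimnames(delays) <- list(geneIds, geneIds)
    if (is.null(candidateScores))
        candidateScores <- matrix(numeric(0), 0, 0)
    else dimnames(candidateScores) <- list(geneIds, geneIds)
    new("TimeDelayedGRN", geneIds = geneIds, prior = prior,
        delays = delays, kMax = as.integer(kMax),
        candidateScores = candidateScores, metadata = metadata)
}
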