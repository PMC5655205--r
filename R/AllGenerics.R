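#' Accessors for network objects
#'
#' `geneIds()` returns the gene universe; `networkEdges()` the edge table;
#' `delays()` the integer delay matrix; `priorNetwork()` the directed prior
#' network of a [TimeDelayedGRN-class]; `edgeScores()` the per-edge scores;
#' `candidateScores()` the full ordered-pair confidence matrix;
#' `skeletonWeight()` the symmetric strength matrix of a
#' [GRNSkeleton-class]; `regulationStrength()` its absolute regulation
#' intensity matrix; `orderReached()` the terminal conditioning order of
#' skeleton learning; `numEdges()` the edge count.
#'
#' @param object a [Network-class], [GRNSkeleton-class] or
#'   [TimeDelayedGRN-class] object.
#' @return see the individual descriptions above.
#' @examples
#' net <- makeNetwork(c("G1", "G2"), "G1", "G2", delay = 2L, score = 0.9)
#' geneIds(net)
#' networkEdges(net)
#' numEdges(net)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("delays", function(object) standardGeneric("delays"))
#' @rdname accessors
#' @export
setGeneric("priorNetwork", function(object) standardGeneric("priorNetwork"))
#' @rdname accessors
#' @export
setGeneric("edgeScores", function(object) standardGeneric("edgeScores"))
#' @rdname accessors
#' @export
setGeneric("candidateScores",
           function(object) standardGeneric("candidateScores"))
#' @rdname accessors
#' @export
setGeneric("skeletonWeight",
           function(object) standardGeneric("skeletonWeight"))
#' @rdname accessors
#' @export
setGeneric("regulationStrength",
           function(object) standardGeneric("regulationStrength"))
#' @rdname accessors
#' @export
setGeneric("orderReached", function(object) standardGeneric("orderReached"))
#' @rdname accessors
#' @export
setGeneric("numEdges", function(object) standardGeneric("numEdges"))

#' @rdname accessors
setMethod("geneIds", "Network", function(object) object@geneIds)
#' @rdname accessors
setMethod("geneIds", "GRNSkeleton", function(object) object@geneIds)
#' @rdname accessors
setMethod("geneIds", "TimeDelayedGRN", function(object) object@geneIds)

#' @rdname accessors
setMethod("networkEdges", "Network", function(object) object@edges)
#' @rdname accessors
setMethod("networkEdges", "TimeDelayedGRN",
          function(object) object@prior@edges)
#' @rdname accessors
setMethod("networkEdges", "GRNSkeleton", function(object) {
    W <- object@weight
    idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
    data.frame(regulator = object@geneIds[idx[, 1L]],
               target = object@geneIds[idx[, 2L]],
               delay = NA_integer_, score = W[idx],
               stringsAsFactors = FALSE)
})

#' @rdname accessors
setMethod("delays", "TimeDelayedGRN", function(object) object@delays)
#' @rdname accessors
setMethod("priorNetwork", "TimeDelayedGRN", function(object) object@prior)
#' @rdname accessors
setMethod("edgeScores", "Network", function(object) {
    stats::setNames(object@edges$score,
                    paste(object@edges$regulator, object@edges$target,
                          sep = "->"))
})
#' @rdname accessors
setMethod("edgeScores", "TimeDelayedGRN",
          function(object) edgeScores(object@prior))
#' @rdname accessors
setMethod("candidateScores", "TimeDelayedGRN",
          function(object) object@candidateScores)
#' @rdname accessors
setMethod("skeletonWeight", "GRNSkeleton", function(object) object@weight)
#' @rdname accessors
setMethod("regulationStrength", "GRNSkeleton", function(object) object@beta)
#' @rdname accessors
setMethod("orderReached", "GRNSkeleton",
          function(object) object@orderReached)
#' @rdname accessors
setMethod("numEdges", "Network", function(object) nrow(object@edges))
#' @rdname accessors
setMethod("numEdges", "TimeDelayedGRN",
          function(object) nrow(object@prior@edges))
#' @rdname accessors
setMethod("numEdges", "GRNSkeleton",
          function(object) sum(object@weight[upper.tri(object@weight)] > 0))

setMethod("show", "Network", function(object) {
    cat(sprintf("%s Network: %d genes, %d edges\n",
                if (object@directed) "Directed" else "Undirected",
                length(object@geneIds), nrow(object@edges)))
    if (nrow(object@edges) > 0L)
        print(utils::head(object@edges, 6L))
    invisible(NULL)
})

setMethod("show", "GRNSkeleton", function(object) {
    cat(sprintf("GRNSkeleton: %d genes, %d undirected edges, order reached %d\n",
                length(object@geneIds), numEdges(object),
                object@orderReached))
    invisible(NULL)
})

setMethod("show", "TimeDelayedGRN", function(object) {
    cat(sprintf("TimeDelayedGRN: %d genes, %d directed edges, kMax = %d\n",
                length(object@geneIds), numEdges(object), object@kMax))
    if (numEdges(object) > 0L)
        print(utils::head(object@prior@edges, 6L))
    invisible(NULL)
})
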