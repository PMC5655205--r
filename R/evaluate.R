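## Evaluation against a gold standard: confusion counts over the ordered
## (or unordered) non-self gene pairs, the standard metric suite, and AUROC
## over ranked candidate edges.

.pairKeys <- function(net, directed) {
    e <- networkEdges(net)
    if (directed) paste(e$regulator, e$target, sep = "\r")
    else {
        g <- geneIds(net)
        ri <- match(e$regulator, g); ti <- match(e$target, g)
        paste(pmin(ri, ti), pmax(ri, ti), sep = "\r")
    }
}

#' Confusion counts of a predicted network against a gold standard
#'
#' Compares the two edge sets over the full universe of non-self gene
#' pairs: `N(N-1)` ordered pairs in directed mode, `N(N-1)/2` unordered
#' pairs otherwise (both networks are collapsed to unordered pairs first).
#' The gene universes must be identical.
#'
#' @param pred predicted [Network-class] or [TimeDelayedGRN-class].
#' @param gold gold-standard [Network-class].
#' @param directed logical; compare ordered pairs (default) or unordered.
#' @return object of class `ConfusionCounts`: list with integer fields
#'   `tp`, `fp`, `tn`, `fn` summing to the universe size.
#' @examples
#' g <- makeNetwork(c("A", "B", "C"), c("A", "B"), c("B", "C"))
#' p <- makeNetwork(c("A", "B", "C"), c("A", "C"), c("B", "B"))
#' confusionCounts(p, g)
#' @export
confusionCounts <- function(pred, gold, directed = TRUE) {
    if (is(pred, "TimeDelayedGRN")) pred <- priorNetwork(pred)
    if (is(gold, "TimeDelayedGRN")) gold <- priorNetwork(gold)
    gp <- geneIds(pred); gg <- geneIds(gold)
    if (!setequal(gp, gg)) {
        missing <- c(setdiff(gg, gp), setdiff(gp, gg))
        stop(sprintf("gene universes differ; unmatched ids: %s",
                     paste(missing, collapse = ", ")))
    }
    n <- length(gp)
    total <- if (directed) n * (n - 1L) else n * (n - 1L) / 2L
    pk <- unique(.pairKeys(pred, directed))
    gk <- unique(.pairKeys(gold, directed))
    tp <- length(intersect(pk, gk))
    fp <- length(setdiff(pk, gk))
    fn <- length(setdiff(gk, pk))
    tn <- total - tp - fp - fn
    structure(list(tp = as.integer(tp), fp = as.integer(fp),
                   tn = as.integer(tn), fn = as.integer(fn)),
              class = "ConfusionCounts")
}

#' @export
print.ConfusionCounts <- function(x, ...) {
    cat(sprintf("ConfusionCounts: TP=%d FP=%d TN=%d FN=%d\n",
                x$tp, x$fp, x$tn, x$fn))
    invisible(x)
}

#' Classification metrics from confusion counts
#'
#' The standard binary-classification suite:
#' TPR = TP/(TP+FN), FPR = FP/(FP+TN), PPV = TP/(TP+FP),
#' ACC = (TP+TN)/total, and the Matthews correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' A metric whose denominator is zero is reported as `NA` (undefined), not
#' as 0.
#'
#' @param counts a `ConfusionCounts` object, or `tp` given all four counts.
#' @param tp,fp,tn,fn individual counts (used when `counts` is missing).
#' @return list of class `MetricReport` with fields `tpr`, `fpr`, `ppv`,
#'   `acc`, `mcc` and `auc` (`NA` unless filled in by the caller).
#' @examples
#' classificationMetrics(tp = 16, fp = 11, tn = 37, fn = 8)
#' @export
classificationMetrics <- function(counts, tp, fp, tn, fn) {
    if (!missing(counts) && inherits(counts, "ConfusionCounts")) {
        tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
    } else if (!missing(counts) && missing(tp)) {
        stop("supply a ConfusionCounts object or all of tp, fp, tn, fn")
    }
    safeDiv <- function(num, den) if (den == 0) NA_real_ else num / den
    total <- tp + fp + tn + fn
    mccDen <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    structure(list(
        tpr = safeDiv(tp, tp + fn),
        fpr = safeDiv(fp, fp + tn),
        ppv = safeDiv(tp, tp + fp),
        acc = safeDiv(tp + tn, total),
        mcc = if (mccDen == 0) NA_real_ else (tp * tn - fp * fn) / mccDen,
        auc = NA_real_), class = "MetricReport")
}

#' @export
print.MetricReport <- function(x, ...) {
    cat(sprintf("TPR=%.3f FPR=%.3f PPV=%.3f ACC=%.3f MCC=%.3f AUC=%s\n",
                x$tpr, x$fpr, x$ppv, x$acc, x$mcc,
                if (is.na(x$auc)) "NA" else sprintf("%.3f", x$auc)))
    invisible(x)
}

#' Area under the ROC curve for ranked candidate edges
#'
#' Rank-statistic AUROC (ties averaged) of per-pair confidence scores
#' against the gold-standard labels over all ordered non-self pairs.
#' Unscored pairs count as score 0.
#'
#' @param scores N x N numeric matrix of edge confidences with gene ids as
#'   dimnames (regulators in rows), e.g. `candidateScores()` of an inferred
#'   network.
#' @param gold gold-standard directed [Network-class].
#' @return AUC in `[0, 1]`.
#' @examples
#' g <- makeNetwork(c("A", "B"), "A", "B")
#' s <- matrix(c(0, 0.1, 0.9, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
#' rocAUC(s, g)
#' @export
rocAUC <- function(scores, gold) {
    if (is(gold, "TimeDelayedGRN")) gold <- priorNetwork(gold)
    g <- geneIds(gold)
    n <- length(g)
    stopifnot(is.matrix(scores))
    if (!is.null(rownames(scores))) {
        if (!setequal(rownames(scores), g))
            stop("score matrix gene ids do not match the gold standard")
        scores <- scores[g, g]
    } else stopifnot(nrow(scores) == n, ncol(scores) == n)
    off <- which(row(scores) != col(scores))
    s <- scores[off]
    lab <- matrix(FALSE, n, n)
    e <- networkEdges(gold)
    lab[cbind(match(e$regulator, g), match(e$target, g))] <- TRUE
    y <- lab[off]
    nPos <- sum(y); nNeg <- sum(!y)
    if (nPos == 0L || nNeg == 0L)
        stop("AUC undefined: gold standard needs both positives and negatives")
    r <- rank(s)
    (sum(r[y]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}
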