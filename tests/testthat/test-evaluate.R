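# Deterministic 9-gene, 24-edge gold standard and a 27-edge prediction with
# 16 true positives, mirroring the canonical SOS-network bookkeeping.
.goldPred99 <- function() {
    ids <- paste0("G", 1:9)
    pairs <- expand.grid(regulator = ids, target = ids,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$regulator != pairs$target, ]     # 72 ordered pairs
    pairs <- pairs[order(pairs$regulator, pairs$target), ]
    goldE <- pairs[1:24, ]
    predE <- rbind(goldE[1:16, ], pairs[25:35, ])          # 16 TP + 11 FP
    list(gold = makeNetwork(ids, goldE$regulator, goldE$target),
         pred = makeNetwork(ids, predE$regulator, predE$target))
}

test_that("confusion counts follow the ordered-pair universe", {
    gp <- .goldPred99()
    perfect <- confusionCounts(gp$gold, gp$gold, directed = TRUE)
    expect_equal(unclass(perfect)[c("tp", "fp", "tn", "fn")],
                 list(tp = 24L, fp = 0L, tn = 48L, fn = 0L))
    emptyPred <- makeNetwork(paste0("G", 1:9))
    none <- confusionCounts(emptyPred, gp$gold)
    expect_equal(unclass(none)[c("tp", "fp", "tn", "fn")],
                 list(tp = 0L, fp = 0L, tn = 48L, fn = 24L))
    # 27 predicted edges with 16 true positives over 72 ordered pairs
    cc <- confusionCounts(gp$pred, gp$gold)
    expect_equal(unclass(cc)[c("tp", "fp", "tn", "fn")],
                 list(tp = 16L, fp = 11L, tn = 37L, fn = 8L))
    expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, 9L * 8L)
    # gene-set mismatch is an error naming the offending ids
    other <- makeNetwork(c("G1", "G2", "GX"), "G1", "G2")
    expect_error(confusionCounts(other, gp$gold), "GX")
})

test_that("undirected comparison collapses both networks to unordered pairs", {
    ids <- c("A", "B", "C")
    gold <- makeNetwork(ids, "A", "B")
    predRev <- makeNetwork(ids, "B", "A")
    ccDir <- confusionCounts(predRev, gold, directed = TRUE)
    expect_equal(ccDir$tp, 0L)
    ccUndir <- confusionCounts(predRev, gold, directed = FALSE)
    expect_equal(ccUndir$tp, 1L)
    expect_equal(ccUndir$tp + ccUndir$fp + ccUndir$tn + ccUndir$fn, 3L)
})

test_that("classification metrics reproduce canonical values", {
    m <- classificationMetrics(tp = 16, fp = 11, tn = 37, fn = 8)
    expect_equal(round(m$tpr, 3), 0.667)
    expect_equal(round(m$fpr, 3), 0.229)
    expect_equal(round(m$ppv, 3), 0.593)
    expect_equal(round(m$acc, 3), 0.736)
    expect_equal(round(m$mcc, 3), 0.426)
    p <- classificationMetrics(tp = 24, fp = 0, tn = 48, fn = 0)
    expect_equal(c(p$tpr, p$ppv, p$acc, p$mcc), c(1, 1, 1, 1))
    expect_equal(round(classificationMetrics(tp = 8, fp = 1, tn = 79,
                                             fn = 2)$mcc, 3), 0.825)
    # zero denominators are reported as undefined, not 0
    z <- classificationMetrics(tp = 0, fp = 0, tn = 10, fn = 5)
    expect_true(is.na(z$ppv))
    expect_false(is.na(z$acc))
})

test_that("metric identities hold under complement and swap", {
    gp <- .goldPred99()
    cc <- confusionCounts(gp$pred, gp$gold)
    m <- classificationMetrics(cc)
    # complement prediction: predicted pairs become the unpredicted ones
    ids <- paste0("G", 1:9)
    all <- expand.grid(regulator = ids, target = ids,
                       stringsAsFactors = FALSE)
    all <- all[all$regulator != all$target, ]
    pe <- networkEdges(gp$pred)
    inPred <- paste(all$regulator, all$target) %in%
        paste(pe$regulator, pe$target)
    comp <- makeNetwork(ids, all$regulator[!inPred], all$target[!inPred])
    mc <- classificationMetrics(confusionCounts(comp, gp$gold))
    expect_equal(mc$tpr, 1 - m$tpr)
    expect_equal(mc$fpr, 1 - m$fpr)
    # MCC is symmetric under (tp <-> tn, fp <-> fn)
    a <- classificationMetrics(tp = 7, fp = 3, tn = 50, fn = 12)
    b <- classificationMetrics(tp = 50, fp = 12, tn = 7, fn = 3)
    expect_equal(a$mcc, b$mcc)
})

test_that("AUC matches a brute-force pairwise comparison and pROC", {
    set.seed(60)
    ids <- paste0("G", 1:4)
    gold <- makeNetwork(ids, c("G1", "G2", "G3"), c("G2", "G3", "G4"))
    S <- matrix(runif(16), 4, 4, dimnames = list(ids, ids))
    diag(S) <- 0
    auc <- rocAUC(S, gold)
    # oracle: count concordant pairs (ties get half credit)
    off <- which(row(S) != col(S))
    lab <- matrix(FALSE, 4, 4)
    lab[cbind(1:3, 2:4)] <- TRUE
    pos <- S[off][lab[off]]; neg <- S[off][!lab[off]]
    conc <- sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))
    expect_equal(auc, conc / (length(pos) * length(neg)))
    skip_if_not_installed("pROC")
    expect_equal(auc, as.numeric(pROC::auc(pROC::roc(
        response = lab[off], predictor = S[off], quiet = TRUE,
        direction = "<", levels = c(FALSE, TRUE)))))
})

test_that("AUC is 1 for perfect ranking, ~0.5 under permutation, monotone-invariant", {
    ids <- paste0("G", 1:5)
    gold <- makeNetwork(ids, c("G1", "G2"), c("G2", "G3"))
    S <- matrix(0, 5, 5, dimnames = list(ids, ids))
    S["G1", "G2"] <- 0.9; S["G2", "G3"] <- 0.8
    expect_equal(rocAUC(S, gold), 1)
    # strictly monotone transforms leave the AUC unchanged
    set.seed(61)
    S2 <- matrix(runif(25), 5, 5, dimnames = list(ids, ids)); diag(S2) <- 0
    expect_equal(rocAUC(S2, gold), rocAUC(exp(3 * S2), gold))
    # permutation null centred on 0.5
    off <- which(row(S2) != col(S2))
    vals <- S2[off]
    aucs <- replicate(1000, {
        P <- S2
        P[off] <- sample(vals)
        rocAUC(P, gold)
    })
    expect_lt(abs(mean(aucs) - 0.5), 0.02)
    # degenerate gold standards are rejected
    expect_error(rocAUC(S2, makeNetwork(ids)), "positives")
})
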