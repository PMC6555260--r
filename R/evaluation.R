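.withSeed <- function(seed, expr) {
    if (!exists(".Random.seed", envir = globalenv())) runif(1)
    oldSeed <- .Random.seed
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
    set.seed(seed)
    expr
}

#' Stratified five-fold split of known and unknown interactions
#'
#' Known interactions (positives) are shuffled with the given seed and
#' dealt round-robin into five folds; unknown pairs (negatives) likewise.
#' Fold sizes within each class differ by at most one.
#'
#' @param Y Binary interaction matrix.
#' @param seed Integer seed for the shuffles.
#' @param nFolds Number of folds (default 5).
#' @return A list with `positive` and `negative`: each a list of `nFolds`
#'   integer vectors of linear indices into `Y`, plus the `seed`.
#' @export
stratifiedFiveFold <- function(Y, seed = 1L, nFolds = 5L) {
    pos <- which(Y == 1)
    neg <- which(Y == 0)
    if (length(pos) < nFolds || length(neg) < nFolds) {
        stop(sprintf(
            "need at least %d known and %d unknown interactions (got %d / %d)",
            nFolds, nFolds, length(pos), length(neg)
        ))
    }
    .withSeed(seed, {
        pos <- sample(pos)
        neg <- sample(neg)
    })
    fold <- function(x) {
        split(x, rep_len(seq_len(nFolds), length(x)))
    }
    list(positive = fold(pos), negative = fold(neg), seed = as.integer(seed))
}

# Cumulative TP/FP counts at each distinct score threshold, descending.
.rocPoints <- function(scores, labels) {
    o <- order(scores, decreasing = TRUE)
    s <- scores[o]
    y <- labels[o]
    last <- cumsum(rle(s)$lengths) # end of every tie group
    data.frame(
        threshold = s[last],
        tp = cumsum(y)[last],
        fp = cumsum(1 - y)[last]
    )
}

#' Area under the ROC curve
#'
#' Sweeps all score thresholds, computes (FPR, TPR) per threshold and
#' integrates by the trapezoidal rule. Tied scores are handled as one
#' threshold group, which makes the result equal to the mid-rank
#' concordance (Mann-Whitney) statistic.
#'
#' @param scores Numeric prediction scores (higher = more likely positive).
#' @param labels 0/1 true labels; both classes must be present.
#' @return The AUC in \[0, 1\].
#' @export
rocAUC <- function(scores, labels) {
    labels <- as.numeric(labels)
    if (length(unique(labels)) < 2L) {
        stop("ROC-AUC requires both classes in the labels")
    }
    pts <- .rocPoints(scores, labels)
    P <- sum(labels == 1)
    N <- sum(labels == 0)
    tpr <- c(0, pts$tp / P)
    fpr <- c(0, pts$fp / N)
    sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' ROC curve points
#'
#' @inheritParams rocAUC
#' @return Data.frame with columns `threshold`, `fpr`, `tpr` (one row per
#'   distinct score, descending), suitable for TSV export and plotting.
#' @export
rocCurve <- function(scores, labels) {
    labels <- as.numeric(labels)
    pts <- .rocPoints(scores, labels)
    data.frame(
        threshold = pts$threshold,
        fpr = pts$fp / sum(labels == 0),
        tpr = pts$tp / sum(labels == 1)
    )
}

#' Area under the precision-recall curve
#'
#' Non-interpolated step rule: thresholds sweep the distinct scores in
#' descending order and each recall increment contributes the precision at
#' that threshold, `sum((R_t - R_{t-1}) * P_t)`. With all scores distinct
#' this is average precision; the rule is fixed so results reproduce
#' bit-for-bit.
#'
#' @inheritParams rocAUC
#' @return The AUPR in \[0, 1\].
#' @export
prAUC <- function(scores, labels) {
    labels <- as.numeric(labels)
    if (sum(labels == 1) == 0) {
        stop("PR-AUC requires at least one positive label")
    }
    pts <- .rocPoints(scores, labels)
    P <- sum(labels == 1)
    rec <- pts$tp / P
    prec <- pts$tp / (pts$tp + pts$fp)
    sum(diff(c(0, rec)) * prec)
}

#' Precision-recall curve points
#'
#' @inheritParams rocAUC
#' @return Data.frame with columns `threshold`, `recall`, `precision`.
#' @export
prCurve <- function(scores, labels) {
    labels <- as.numeric(labels)
    pts <- .rocPoints(scores, labels)
    data.frame(
        threshold = pts$threshold,
        recall = pts$tp / sum(labels == 1),
        precision = pts$tp / (pts$tp + pts$fp)
    )
}

#' Average per-drug recall within the top k candidates
#'
#' For every drug (within every fold, when a `fold` column is present)
#' with at least one positive test pair, its candidates are ranked by
#' score and the fraction of its positives retrieved within the top k is
#' computed; the mean over all such drug units is returned for each k.
#' Drugs without test positives are excluded (a message reports how many).
#'
#' @param predictions Data.frame with columns `drug`, `score`, `label`
#'   and optionally `fold`.
#' @param ks Integer vector of cutoffs, e.g. `c(50, 100, 150, 200, 250,
#'   300)`.
#' @return Named numeric vector of average recalls, one per k,
#'   non-decreasing in k.
#' @export
topkRecall <- function(predictions, ks = c(50L, 100L, 150L, 200L, 250L, 300L)) {
    stopifnot(all(c("drug", "score", "label") %in% names(predictions)))
    grp <- if ("fold" %in% names(predictions)) {
        paste(predictions$fold, predictions$drug, sep = "\r")
    } else {
        as.character(predictions$drug)
    }
    units <- split(predictions[, c("score", "label")], grp)
    hasPos <- vapply(units, function(u) any(u$label == 1), logical(1))
    if (any(!hasPos)) {
        message(sum(!hasPos), " drug unit(s) without test positives excluded from top-k recall")
    }
    units <- units[hasPos]
    if (!length(units)) {
        return(stats::setNames(rep(NA_real_, length(ks)), ks))
    }
    recalls <- vapply(units, function(u) {
        o <- order(u$score, decreasing = TRUE)
        lab <- u$label[o]
        vapply(ks, function(k) sum(lab[seq_len(min(k, length(lab)))]) / sum(lab),
            numeric(1)
        )
    }, numeric(length(ks)))
    if (length(ks) == 1L) recalls <- matrix(recalls, nrow = 1L)
    stats::setNames(rowMeans(recalls), ks)
}

#' Five-fold cross-validation of the full prediction pipeline
#'
#' Both similarity networks are diffused once by random walk with restart
#' (the diffusion depends only on the similarity matrices, not on the
#' interaction labels) and the k-nearest-neighbour tables are built from
#' the diffused weights. Per fold, the test-fold known interactions are
#' masked to 0 in the interaction layer before any feature is computed, so
#' no path can use a held-out edge; features for training and test pairs
#' are built from the masked network, the ensemble is trained on the
#' training pairs and the test pairs are scored. Metrics are reported per
#' fold and pooled over all folds.
#'
#' @param net A [DrugTargetNetwork-class].
#' @param config A [gbdtConfig()] for the per-fold ensembles.
#' @param restart Restart probability of the random walk (default 0.4).
#' @param k Number of nearest neighbours kept per node (default 30).
#' @param seed Seed for the fold assignment.
#' @param ks Top-k recall cutoffs.
#' @param tol,maxIter Random-walk convergence controls.
#' @return A list of class `dtiEvalReport`: `pooled` (auc, aupr),
#'   `perFold` data.frame, `topkRecall`, `predictions` (drug, target,
#'   fold, score, label), and `params`.
#' @export
runCrossValidation <- function(net, config = gbdtConfig(), restart = 0.4,
                               k = 30L, seed = 1L,
                               ks = c(50L, 100L, 150L, 200L, 250L, 300L),
                               tol = 1e-6, maxIter = 1000L) {
    Y <- interactions(net)
    folds <- stratifiedFiveFold(Y, seed = seed)
    WD <- randomWalkWithRestart(rowNormalize(drugSimilarity(net)),
        restart = restart, tol = tol, maxIter = maxIter
    )
    WT <- randomWalkWithRestart(rowNormalize(targetSimilarity(net)),
        restart = restart, tol = tol, maxIter = maxIter
    )
    KD <- selectKNeighbors(WD, k)
    KT <- selectKNeighbors(WT, k)
    WDs <- .symmetrize(WD)
    WTs <- .symmetrize(WT)
    m <- numDrugs(net)
    nFolds <- length(folds$positive)
    allIdx <- seq_along(Y)
    preds <- vector("list", nFolds)
    perFold <- data.frame(
        fold = seq_len(nFolds), auc = NA_real_, aupr = NA_real_
    )
    for (f in seq_len(nFolds)) {
        testIdx <- c(folds$positive[[f]], folds$negative[[f]])
        trainIdx <- setdiff(allIdx, testIdx)
        Ytrain <- Y
        Ytrain[folds$positive[[f]]] <- 0
        pairFeats <- function(idx) {
            di <- ((idx - 1L) %% m) + 1L
            tj <- ((idx - 1L) %/% m) + 1L
            feats <- matrix(0, length(idx), 18,
                dimnames = list(NULL, .featureNames())
            )
            for (r in seq_along(idx)) {
                feats[r, ] <- .pairFeatures(di[r], tj[r], Ytrain, WDs, WTs, KD, KT)
            }
            list(X = feats, drug = di, target = tj)
        }
        tr <- pairFeats(trainIdx)
        te <- pairFeats(testIdx)
        model <- trainGBDT(tr$X, Y[trainIdx], config)
        sc <- predictMargin(model, te$X)
        preds[[f]] <- data.frame(
            drug = drugIds(net)[te$drug],
            target = targetIds(net)[te$target],
            fold = f, score = sc, label = Y[testIdx],
            stringsAsFactors = FALSE
        )
        perFold$auc[f] <- rocAUC(sc, Y[testIdx])
        perFold$aupr[f] <- prAUC(sc, Y[testIdx])
    }
    predictions <- do.call(rbind, preds)
    structure(
        list(
            pooled = list(
                auc = rocAUC(predictions$score, predictions$label),
                aupr = prAUC(predictions$score, predictions$label)
            ),
            perFold = perFold,
            topkRecall = suppressMessages(topkRecall(predictions, ks)),
            predictions = predictions,
            params = list(
                restart = restart, k = as.integer(k), seed = as.integer(seed),
                tol = tol, maxIter = as.integer(maxIter),
                config = unclass(config),
                topkCandidatePool = "all test-fold pairs of each drug, per fold"
            )
        ),
        class = "dtiEvalReport"
    )
}

#' @export
print.dtiEvalReport <- function(x, ...) {
    cat("Five-fold cross-validation report\n")
    cat(sprintf(
        "  pooled ROC-AUC %.4f, AUPR %.4f\n", x$pooled$auc, x$pooled$aupr
    ))
    cat("  per fold:\n")
    for (f in seq_len(nrow(x$perFold))) {
        cat(sprintf(
            "    fold %d: AUC %.4f, AUPR %.4f\n",
            x$perFold$fold[f], x$perFold$auc[f], x$perFold$aupr[f]
        ))
    }
    cat("  top-k recall (mean over drugs):\n")
    for (k in names(x$topkRecall)) {
        cat(sprintf("    k = %s: %.4f\n", k, x$topkRecall[[k]]))
    }
    invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report A `dtiEvalReport` from [runCrossValidation()].
#' @param path Destination JSON file.
#' @return Invisibly, `path`.
#' @export
writeEvalReport <- function(report, path) {
    payload <- list(
        pooled = report$pooled,
        perFold = report$perFold,
        topkRecall = as.list(report$topkRecall),
        params = report$params
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
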