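#' Boosting configuration
#'
#' Hyperparameters of the gradient-boosted tree ensemble. Each boosting
#' round draws a random subset of `ceiling(featureFraction * p)` of the p
#' features, fits a depth-capped regression tree to the negative gradients
#' of the logistic loss `sum(log(1 + exp(-2 * y * F)))` (labels in
#' \{-1, +1\}), sets leaf values by a Newton step damped by the L2 penalty
#' `regLambda`, and updates the margin with step size `learningRate`.
#'
#' @param nTrees Number of boosting rounds z (default 300).
#' @param learningRate Shrinkage applied to every tree's contribution,
#'   in \[0, 1\] (default 0.1; 0 freezes the model at its base margin).
#' @param maxDepth Maximum tree depth (default 3).
#' @param featureFraction Fraction of features sampled per tree, in
#'   (0, 1\] (default 0.7).
#' @param minSamplesLeaf Minimum samples per leaf (default 5).
#' @param regLambda L2 penalty added to the Newton denominator of every
#'   leaf value; shrinks leaf magnitudes towards 0 (default 0.1).
#' @param seed Integer seed driving the per-round feature subsampling.
#' @return A list of class `gbdtConfig`.
#' @export
gbdtConfig <- function(nTrees = 300L, learningRate = 0.1, maxDepth = 3L,
                       featureFraction = 0.7, minSamplesLeaf = 5L,
                       regLambda = 0.1, seed = 1L) {
    stopifnot(
        nTrees >= 1, learningRate >= 0, learningRate <= 1,
        maxDepth >= 1, featureFraction > 0, featureFraction <= 1,
        minSamplesLeaf >= 1, regLambda >= 0
    )
    structure(
        list(
            nTrees = as.integer(nTrees), learningRate = learningRate,
            maxDepth = as.integer(maxDepth), featureFraction = featureFraction,
            minSamplesLeaf = as.integer(minSamplesLeaf),
            regLambda = regLambda, seed = as.integer(seed)
        ),
        class = "gbdtConfig"
    )
}

# Best squared-error split of the samples in `idx` over the columns of X.
# Returns NULL when no split satisfies the leaf-size floor. Deterministic:
# ties resolve to the lowest feature index, then the lowest threshold.
.bestSplit <- function(X, r, idx, minLeaf) {
    n <- length(idx)
    if (n < 2L * minLeaf) {
        return(NULL)
    }
    best <- NULL
    bestGain <- -Inf
    base <- sum(r[idx])^2 / n
    for (f in seq_len(ncol(X))) {
        x <- X[idx, f]
        o <- order(x)
        xs <- x[o]
        cs <- cumsum(r[idx][o])
        total <- cs[n]
        p <- seq_len(n - 1L)
        ok <- xs[p] < xs[p + 1L] & p >= minLeaf & (n - p) >= minLeaf
        if (!any(ok)) next
        p <- p[ok]
        gain <- cs[p]^2 / p + (total - cs[p])^2 / (n - p) - base
        b <- which.max(gain)
        if (gain[b] > bestGain + 1e-12) {
            bestGain <- gain[b]
            best <- list(
                feature = f,
                threshold = (xs[p[b]] + xs[p[b] + 1L]) / 2,
                gain = gain[b]
            )
        }
    }
    best
}

# Fit a depth-capped regression tree to residuals r (squared error), with
# Newton leaf values sum(r)/(sum(h) + lambda). Flat node table: leaves
# have feature = 0 and carry `value`; internal nodes route x <= threshold
# left.
.fitTree <- function(X, r, h, maxDepth, minLeaf, regLambda) {
    nodes <- list()
    grow <- function(idx, depth) {
        id <- length(nodes) + 1L
        nodes[[id]] <<- list() # reserve slot
        split <- if (depth < maxDepth) .bestSplit(X, r, idx, minLeaf) else NULL
        if (is.null(split) || split$gain <= 1e-12) {
            nodes[[id]] <<- list(
                feature = 0L, threshold = NA_real_, left = 0L, right = 0L,
                value = sum(r[idx]) / (sum(h[idx]) + regLambda)
            )
            return(id)
        }
        goLeft <- X[idx, split$feature] <= split$threshold
        left <- grow(idx[goLeft], depth + 1L)
        right <- grow(idx[!goLeft], depth + 1L)
        nodes[[id]] <<- list(
            feature = split$feature, threshold = split$threshold,
            left = left, right = right, value = NA_real_
        )
        id
    }
    grow(seq_len(nrow(X)), 0L)
    data.frame(
        feature = vapply(nodes, `[[`, integer(1), "feature"),
        threshold = vapply(nodes, `[[`, numeric(1), "threshold"),
        left = vapply(nodes, `[[`, integer(1), "left"),
        right = vapply(nodes, `[[`, integer(1), "right"),
        value = vapply(nodes, `[[`, numeric(1), "value")
    )
}

.predictTree <- function(tree, X) {
    n <- nrow(X)
    node <- rep(1L, n)
    out <- numeric(n)
    active <- seq_len(n)
    while (length(active)) {
        nd <- node[active]
        isLeaf <- tree$feature[nd] == 0L
        if (any(isLeaf)) {
            done <- active[isLeaf]
            out[done] <- tree$value[node[done]]
            active <- active[!isLeaf]
            if (!length(active)) break
            nd <- node[active]
        }
        goLeft <- X[cbind(active, tree$feature[nd])] <= tree$threshold[nd]
        node[active] <- ifelse(goLeft, tree$left[nd], tree$right[nd])
    }
    out
}

.asFeatureMatrix <- function(features) {
    if (is.data.frame(features)) {
        keep <- intersect(.featureNames(), names(features))
        if (length(keep) == 18L) {
            features <- features[, keep]
        } else {
            features <- features[, vapply(features, is.numeric, logical(1)) &
                !(names(features) %in% c("label"))]
        }
    }
    as.matrix(features)
}

#' Train the gradient-boosted tree ensemble
#'
#' Labels are mapped to \{-1, +1\} and the initial margin is the log-odds
#' `F0 = 0.5 * log(p / (1 - p))` of the positive fraction. Each round fits
#' a regression tree to the negative gradients `2 y / (1 + exp(2 y F))` of
#' the logistic loss on a seeded random feature subset, assigns Newton
#' leaf values damped by `regLambda`, and advances the margin by
#' `learningRate` times the tree output. The per-round training loss curve
#' is recorded on the model.
#'
#' @param features Numeric matrix or feature-table data.frame (the 18
#'   `v1_c1`..`v3_c6` columns are used when present).
#' @param labels Vector of 0/1 (or -1/+1) interaction labels, one per row.
#' @param config A [gbdtConfig()].
#' @return A list of class `gbdtEnsemble` with elements `trees`,
#'   `featureSubsets`, `baseScore`, `lossCurve`, `config`, `featureNames`.
#' @export
trainGBDT <- function(features, labels, config = gbdtConfig()) {
    X <- .asFeatureMatrix(features)
    if (any(!is.finite(X))) {
        bad <- which(!is.finite(X), arr.ind = TRUE)[1, ]
        col <- if (is.null(colnames(X))) bad[2] else colnames(X)[bad[2]]
        stop(sprintf(
            "non-finite feature value at row %d, column '%s'", bad[1], col
        ))
    }
    y <- as.numeric(labels)
    y[y == 0] <- -1
    if (!all(y %in% c(-1, 1))) stop("labels must be 0/1 (or -1/+1)")
    if (length(y) != nrow(X)) stop("one label per feature row required")
    if (length(unique(y)) < 2L) {
        stop("training requires both an interacting and a non-interacting class")
    }
    p <- ncol(X)
    nSub <- as.integer(ceiling(config$featureFraction * p))
    prior <- mean(y == 1)
    F0 <- 0.5 * log(prior / (1 - prior))
    Fm <- rep(F0, length(y))
    trees <- vector("list", config$nTrees)
    subsets <- vector("list", config$nTrees)
    lossCurve <- numeric(config$nTrees)
    if (!exists(".Random.seed", envir = globalenv())) runif(1)
    oldSeed <- .Random.seed
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
    set.seed(config$seed)
    for (k in seq_len(config$nTrees)) {
        sub <- sort(sample.int(p, nSub))
        r <- 2 * y / (1 + exp(2 * y * Fm))
        h <- abs(r) * (2 - abs(r))
        tree <- .fitTree(
            X[, sub, drop = FALSE], r, h,
            config$maxDepth, config$minSamplesLeaf, config$regLambda
        )
        Fm <- Fm + config$learningRate *
            .predictTree(tree, X[, sub, drop = FALSE])
        trees[[k]] <- tree
        subsets[[k]] <- sub
        lossCurve[k] <- sum(log1p(exp(-2 * y * Fm)))
    }
    structure(
        list(
            trees = trees, featureSubsets = subsets, baseScore = F0,
            lossCurve = lossCurve, config = config,
            featureNames = colnames(X), nFeatures = p
        ),
        class = "gbdtEnsemble"
    )
}

#' @export
print.gbdtEnsemble <- function(x, ...) {
    cat(sprintf(
        "gbdtEnsemble: %d trees, depth <= %d, learning rate %.3g, %d features\n",
        length(x$trees), x$config$maxDepth, x$config$learningRate, x$nFeatures
    ))
    cat(sprintf(
        "  base score %.4f; final training loss %.4f\n",
        x$baseScore, utils::tail(x$lossCurve, 1)
    ))
    invisible(x)
}

#' Predict interaction scores from a trained ensemble
#'
#' Returns `F0 + sum_k(learningRate * T_k(x)) / z`: the base margin plus
#' the shrinkage-weighted tree outputs averaged over the z rounds. The
#' 1/z averaging is a positive monotone rescaling of the boosted margin,
#' so every ranking metric is unchanged by it.
#'
#' @param model A trained `gbdtEnsemble`.
#' @param features Feature matrix/table with the same width the model was
#'   trained on.
#' @return Numeric vector of scores, one per row; higher means more
#'   likely to interact.
#' @export
predictMargin <- function(model, features) {
    X <- .asFeatureMatrix(features)
    if (ncol(X) != model$nFeatures) {
        stop(sprintf(
            "feature width mismatch: model expects %d, got %d",
            model$nFeatures, ncol(X)
        ))
    }
    z <- length(model$trees)
    acc <- numeric(nrow(X))
    for (k in seq_len(z)) {
        acc <- acc + model$config$learningRate *
            .predictTree(model$trees[[k]], X[, model$featureSubsets[[k]], drop = FALSE])
    }
    model$baseScore + acc / z
}

#' Score every drug-target pair of a network
#'
#' @param model A trained `gbdtEnsemble`.
#' @param net The [DrugTargetNetwork-class] the feature table was built on.
#' @param featureTable Output of [buildFeatureTable()] covering the pairs
#'   to score (default expectation: all m x n pairs).
#' @return An m x n numeric matrix of scores with drug/target identifiers
#'   as dimnames; pairs absent from `featureTable` are `NA`.
#' @export
scoreAllPairs <- function(model, net, featureTable) {
    s <- predictMargin(model, featureTable)
    out <- matrix(NA_real_, numDrugs(net), numTargets(net),
        dimnames = list(drugIds(net), targetIds(net))
    )
    out[cbind(
        match(featureTable$drug, drugIds(net)),
        match(featureTable$target, targetIds(net))
    )] <- s
    out
}

#' Save a trained ensemble as JSON
#'
#' The file stores the tree tables (split feature within the round's
#' subset, threshold, children, leaf values), the per-round feature
#' subsets, the base score and the full configuration including the seed,
#' so a model round-trips exactly.
#'
#' @param model A `gbdtEnsemble`.
#' @param path Destination JSON file.
#' @return Invisibly, `path`.
#' @export
saveGBDT <- function(model, path) {
    payload <- list(
        format = "pathDTI-gbdt-1",
        baseScore = model$baseScore,
        config = unclass(model$config),
        featureNames = model$featureNames,
        nFeatures = model$nFeatures,
        lossCurve = model$lossCurve,
        featureSubsets = model$featureSubsets,
        trees = model$trees
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Load an ensemble saved by [saveGBDT()]
#'
#' @param path JSON file written by [saveGBDT()].
#' @return A `gbdtEnsemble`.
#' @export
loadGBDT <- function(path) {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(payload$format, "pathDTI-gbdt-1")) {
        stop("not a pathDTI GBDT model file: ", path)
    }
    cfg <- do.call(gbdtConfig, payload$config)
    trees <- lapply(payload$trees, function(tr) {
        tr <- as.data.frame(tr)
        tr$feature <- as.integer(tr$feature)
        tr$left <- as.integer(tr$left)
        tr$right <- as.integer(tr$right)
        tr
    })
    fs <- payload$featureSubsets
    if (is.matrix(fs)) {
        fs <- lapply(seq_len(nrow(fs)), function(i) as.integer(fs[i, ]))
    } else {
        fs <- lapply(fs, as.integer)
    }
    structure(
        list(
            trees = trees,
            featureSubsets = fs,
            baseScore = payload$baseScore,
            lossCurve = payload$lossCurve,
            config = cfg,
            featureNames = payload$featureNames,
            nFeatures = as.integer(payload$nFeatures)
        ),
        class = "gbdtEnsemble"
    )
}
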