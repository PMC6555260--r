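#' The six drug-to-target path categories
#'
#' Paths from a drug to a target of length 2 or 3 edges fall into six
#' node-type categories: C1 (D-D-T), C2 (D-T-T), C3 (D-T-T-T),
#' C4 (D-D-T-T), C5 (D-D-D-T) and C6 (D-T-D-T). Longer paths are not
#' considered (combinatorial cost grows quickly and the added topological
#' signal is weak).
#'
#' @return Named list of node-type sequences, one per category.
#' @export
pathCategories <- function() {
    list(
        C1 = c("D", "D", "T"),
        C2 = c("D", "T", "T"),
        C3 = c("D", "T", "T", "T"),
        C4 = c("D", "D", "T", "T"),
        C5 = c("D", "D", "D", "T"),
        C6 = c("D", "T", "D", "T")
    )
}

.featureNames <- function() {
    paste0(rep(c("v1", "v2", "v3"), each = 6), "_c", rep(1:6, 3))
}

.resolveDrug <- function(net, drug) {
    if (is.character(drug)) {
        i <- match(drug, drugIds(net))
        if (is.na(i)) stop("unknown drug identifier: ", drug)
        return(i)
    }
    i <- as.integer(drug)
    if (i < 1L || i > numDrugs(net)) stop("drug index out of range: ", drug)
    i
}

.resolveTarget <- function(net, target) {
    if (is.character(target)) {
        j <- match(target, targetIds(net))
        if (is.na(j)) stop("unknown target identifier: ", target)
        return(j)
    }
    j <- as.integer(target)
    if (j < 1L || j > numTargets(net)) stop("target index out of range: ", target)
    j
}

# Path weights for pair (i, j) under one category, using symmetrized
# drug-drug / target-target weights (WDs, WTs; zero diagonal) and the 0/1
# interaction matrix Y. dN = drug neighbours of i, tN = target neighbours
# of j. Intermediate drugs must come from dN, intermediate targets from
# tN; paths are simple (neighbour tables already exclude the endpoints);
# drug-target edges are interactions of weight 1; similarity edges exist
# iff their symmetrized weight is strictly positive. The direct edge
# (i, j) can never occur inside any category's path, so no special-casing
# is needed beyond endpoint exclusion.
.categoryWeights <- function(i, j, h, Y, WDs, WTs, dN, tN) {
    switch(h,
        { # C1: d_i - d_a - t_j
            a <- dN[WDs[i, dN] > 0 & Y[dN, j] == 1]
            WDs[i, a]
        },
        { # C2: d_i - t_b - t_j
            b <- tN[Y[i, tN] == 1 & WTs[tN, j] > 0]
            WTs[b, j]
        },
        { # C3: d_i - t_b - t_c - t_j
            b <- tN[Y[i, tN] == 1]
            if (!length(b)) return(numeric(0))
            M <- WTs[b, tN, drop = FALSE] *
                rep(WTs[tN, j], each = length(b))
            M[outer(b, tN, "==")] <- 0
            M[M > 0]
        },
        { # C4: d_i - d_a - t_b - t_j
            a <- dN[WDs[i, dN] > 0]
            b <- tN[WTs[tN, j] > 0]
            if (!length(a) || !length(b)) return(numeric(0))
            M <- Y[a, b, drop = FALSE] * outer(WDs[i, a], WTs[b, j])
            M[M > 0]
        },
        { # C5: d_i - d_a - d_b - t_j
            a <- dN[WDs[i, dN] > 0]
            b <- dN[Y[dN, j] == 1]
            if (!length(a) || !length(b)) return(numeric(0))
            M <- WDs[a, b, drop = FALSE] * WDs[i, a]
            M[outer(a, b, "==")] <- 0
            M[M > 0]
        },
        { # C6: d_i - t_b - d_a - t_j; all three edges are interactions
            b <- tN[Y[i, tN] == 1]
            a <- dN[Y[dN, j] == 1]
            if (!length(a) || !length(b)) return(numeric(0))
            rep(1, sum(Y[a, b, drop = FALSE]))
        }
    )
}

#' Enumerate the admissible paths of one category for a drug-target pair
#'
#' Returns every simple path from drug `drug` to target `target` whose
#' node-type sequence matches the requested category, whose intermediate
#' drug nodes lie among the drug's k nearest neighbours and intermediate
#' target nodes among the target's k nearest neighbours, whose
#' drug-drug/target-target edges have strictly positive symmetrized
#' diffused weight, and whose drug-target edges are known interactions
#' (weight 1). The direct edge between the pair itself is never part of a
#' path. An empty result is valid.
#'
#' @param net A [DrugTargetNetwork-class].
#' @param WD,WT Diffused (or raw) drug and target similarity matrices;
#'   they are symmetrized internally.
#' @param KD,KT Neighbour tables from [selectKNeighbors()] for drugs and
#'   targets respectively.
#' @param drug,target Identifier or index of the pair.
#' @param category Category code `"C1"`..`"C6"` or integer 1..6.
#' @return A data.frame with columns `path` (node identifiers joined by
#'   `-`) and `weight` (product of similarity-edge weights; interaction
#'   edges contribute factor 1).
#' @export
enumeratePaths <- function(net, WD, WT, KD, KT, drug, target, category) {
    i <- .resolveDrug(net, drug)
    j <- .resolveTarget(net, target)
    if (is.character(category)) {
        h <- match(category, names(pathCategories()))
        if (is.na(h)) stop("unknown path category: ", category)
    } else {
        h <- as.integer(category)
        if (h < 1L || h > 6L) stop("path category must be 1..6")
    }
    Y <- interactions(net)
    WDs <- .symmetrize(WD)
    WTs <- .symmetrize(WT)
    dN <- KD[i, ]
    tN <- KT[j, ]
    dn <- drugIds(net)
    tn <- targetIds(net)
    paths <- character(0)
    weights <- numeric(0)
    add <- function(nodes, w) {
        paths[[length(paths) + 1L]] <<- paste(nodes, collapse = "-")
        weights[[length(weights) + 1L]] <<- w
    }
    if (h == 1L) {
        for (a in dN) {
            if (WDs[i, a] > 0 && Y[a, j] == 1) {
                add(c(dn[i], dn[a], tn[j]), WDs[i, a])
            }
        }
    } else if (h == 2L) {
        for (b in tN) {
            if (Y[i, b] == 1 && WTs[b, j] > 0) {
                add(c(dn[i], tn[b], tn[j]), WTs[b, j])
            }
        }
    } else if (h == 3L) {
        for (b in tN)

            for (c in tN) {
                if (b != c && Y[i, b] == 1 && WTs[b, c] > 0 && WTs[c, j] > 0) {
                    add(c(dn[i], tn[b], tn[c], tn[j]), WTs[b, c] * WTs[c, j])
                }
            }
    } else if (h == 4L) {
        for (a in dN)

            for (b in tN) {
                if (WDs[i, a] > 0 && Y[a, b] == 1 && WTs[b, j] > 0) {
                    add(c(dn[i], dn[a], tn[b], tn[j]), WDs[i, a] * WTs[b, j])
                }
            }
    } else if (h == 5L) {
        for (a in dN)

            for (b in dN) {
                if (a != b && WDs[i, a] > 0 && WDs[a, b] > 0 && Y[b, j] == 1) {
                    add(c(dn[i], dn[a], dn[b], tn[j]), WDs[i, a] * WDs[a, b])
                }
            }
    } else {
        for (b in tN)

            for (a in dN) {
                if (Y[i, b] == 1 && Y[a, b] == 1 && Y[a, j] == 1) {
                    add(c(dn[i], tn[b], dn[a], tn[j]), 1)
                }
            }
    }
    data.frame(path = paths, weight = weights, stringsAsFactors = FALSE)
}

#' Aggregate a set of path weights into the (sum, max, count) triple
#'
#' @param weights Numeric vector of path weights (possibly empty).
#' @return Named numeric vector `c(v1, v2, v3)`: sum of weights, maximum
#'   weight (0 for an empty set), and path count.
#' @export
aggregateCategory <- function(weights) {
    c(
        v1 = sum(weights),
        v2 = if (length(weights)) max(weights) else 0,
        v3 = length(weights)
    )
}

#' Build the 18-dimensional path-category feature vector of one pair
#'
#' For each of the six categories the admissible paths are aggregated into
#' sum (V1), maximum (V2) and count (V3) of path weights; the three
#' 6-vectors are concatenated in block order V1(C1..C6), V2(C1..C6),
#' V3(C1..C6).
#'
#' @inheritParams enumeratePaths
#' @return Named numeric vector of length 18 (`v1_c1` .. `v3_c6`).
#' @export
buildPairFeatures <- function(net, WD, WT, KD, KT, drug, target) {
    i <- .resolveDrug(net, drug)
    j <- .resolveTarget(net, target)
    Y <- interactions(net)
    WDs <- .symmetrize(WD)
    WTs <- .symmetrize(WT)
    .pairFeatures(i, j, Y, WDs, WTs, KD, KT)
}

.pairFeatures <- function(i, j, Y, WDs, WTs, KD, KT) {
    dN <- KD[i, ]
    tN <- KT[j, ]
    v <- vapply(
        1:6,
        function(h) aggregateCategory(.categoryWeights(i, j, h, Y, WDs, WTs, dN, tN)),
        numeric(3)
    )
    out <- c(v[1, ], v[2, ], v[3, ])
    names(out) <- .featureNames()
    out
}

#' Build the feature table for a set of drug-target pairs
#'
#' One row per pair in input order, with the 18 path-category features and
#' the interaction label `Y[i, j]`.
#'
#' @inheritParams enumeratePaths
#' @param pairs A data.frame (or 2-column matrix) of drug and target
#'   identifiers or indices; `NULL` means all m x n combinations (drugs
#'   varying slowest).
#' @return A data.frame with columns `drug`, `target`, `v1_c1` .. `v3_c6`,
#'   `label`.
#' @export
buildFeatureTable <- function(net, WD, WT, KD, KT, pairs = NULL) {
    Y <- interactions(net)
    WDs <- .symmetrize(WD)
    WTs <- .symmetrize(WT)
    if (is.null(pairs)) {
        pairs <- expand.grid(
            target = seq_len(numTargets(net)),
            drug = seq_len(numDrugs(net)),
            KEEP.OUT.ATTRS = FALSE
        )[, c("drug", "target")]
    }
    pairs <- as.data.frame(pairs)
    di <- vapply(pairs[[1]], function(d) .resolveDrug(net, d), integer(1))
    tj <- vapply(pairs[[2]], function(t) .resolveTarget(net, t), integer(1))
    feats <- matrix(0, length(di), 18,
        dimnames = list(NULL, .featureNames())
    )
    for (r in seq_along(di)) {
        feats[r, ] <- .pairFeatures(di[r], tj[r], Y, WDs, WTs, KD, KT)
    }
    data.frame(
        drug = drugIds(net)[di],
        target = targetIds(net)[tj],
        feats,
        label = Y[cbind(di, tj)],
        stringsAsFactors = FALSE
    )
}

#' Write a feature table to TSV
#'
#' @param table Output of [buildFeatureTable()].
#' @param path Destination file.
#' @return Invisibly, `path`.
#' @export
writeFeatureTable <- function(table, path) {
    utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
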