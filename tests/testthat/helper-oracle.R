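# Test helpers: random network fixtures and independent brute-force
# oracles. The oracles deliberately share no code with the package's
# optimized implementations: paths are found by looping over all node
# tuples and filtering; AUC is the pairwise concordance statistic.

randomNetworkFixture <- function(m, n, seed, simDensity = 0.6,
                                 interDensity = 0.3) {
    set.seed(seed)
    randSim <- function(p) {
        S <- matrix(0, p, p)
        up <- upper.tri(S)
        vals <- runif(sum(up))
        vals[runif(sum(up)) > simDensity] <- 0
        S[up] <- vals
        S <- S + t(S)
        diag(S) <- 1
        S
    }
    dn <- paste0("d", seq_len(m))
    tn <- paste0("t", seq_len(n))
    SD <- randSim(m)
    ST <- randSim(n)
    dimnames(SD) <- list(dn, dn)
    dimnames(ST) <- list(tn, tn)
    Y <- matrix(rbinom(m * n, 1, interDensity), m, n,
        dimnames = list(dn, tn)
    )
    DrugTargetNetwork(SD, ST, Y)
}

# All admissible path weights of category h for pair (i, j), by exhaustive
# enumeration over node tuples. Returns the sorted weight vector.
brutePathWeights <- function(Y, WDs, WTs, KD, KT, i, j, h) {
    typeSeqs <- list(
        c("D", "D", "T"), c("D", "T", "T"), c("D", "T", "T", "T"),
        c("D", "D", "T", "T"), c("D", "D", "D", "T"), c("D", "T", "D", "T")
    )
    ty <- typeSeqs[[h]]
    L <- length(ty)
    interPos <- 2:(L - 1)
    cand <- lapply(interPos, function(p) {
        if (ty[p] == "D") seq_len(nrow(Y)) else seq_len(ncol(Y))
    })
    grid <- as.matrix(expand.grid(cand))
    weights <- numeric(0)
    for (r in seq_len(nrow(grid))) {
        nodes <- c(i, grid[r, ], j)
        dnodes <- nodes[ty == "D"]
        tnodes <- nodes[ty == "T"]
        if (anyDuplicated(dnodes) || anyDuplicated(tnodes)) next
        ok <- TRUE
        for (p in seq_along(interPos)) {
            v <- grid[r, p]
            if (ty[interPos[p]] == "D" && !(v %in% KD[i, ])) ok <- FALSE
            if (ty[interPos[p]] == "T" && !(v %in% KT[j, ])) ok <- FALSE
        }
        if (!ok) next
        w <- 1
        for (e in seq_len(L - 1)) {
            a <- nodes[e]
            b <- nodes[e + 1]
            if (ty[e] == "D" && ty[e + 1] == "D") {
                ew <- WDs[a, b]
            } else if (ty[e] == "T" && ty[e + 1] == "T") {
                ew <- WTs[a, b]
            } else {
                dd <- if (ty[e] == "D") a else b
                tt <- if (ty[e] == "D") b else a
                if (dd == i && tt == j) { # direct edge is off limits
                    ew <- 0
                } else {
                    ew <- as.numeric(Y[dd, tt] == 1)
                }
            }
            if (ew <= 0) {
                w <- 0
                break
            }
            w <- w * ew
        }
        if (w > 0) weights <- c(weights, w)
    }
    sort(weights)
}

symRaw <- function(S) {
    out <- (S + t(S)) / 2
    diag(out) <- 0
    out
}

# Mid-rank pairwise concordance (Mann-Whitney) AUC.
bruteConcordanceAUC <- function(scores, labels) {
    ps <- scores[labels == 1]
    ns <- scores[labels == 0]
    mean(outer(ps, ns, ">") + 0.5 * outer(ps, ns, "=="))
}

# Diffuse + select neighbours for a network at given settings.
diffuseFixture <- function(net, restart = 0.4, k = 5) {
    WD <- randomWalkWithRestart(rowNormalize(drugSimilarity(net)), restart)
    WT <- randomWalkWithRestart(rowNormalize(targetSimilarity(net)), restart)
    list(
        WD = WD, WT = WT,
        KD = selectKNeighbors(WD, min(k, numDrugs(net) - 1)),
        KT = selectKNeighbors(WT, min(k, numTargets(net) - 1))
    )
}
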