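#' Worked-example micro-network fixture
#'
#' A 7-drug / 5-target heterogeneous network whose raw edge weights are
#' chosen so that the pair (d7, t3) has exactly the following admissible
#' paths when every node keeps all other nodes as neighbours:
#' \itemize{
#'   \item C1: d7-d6-t3 (s = 0.16)
#'   \item C2: d7-t5-t3 (s = 0.16)
#'   \item C3: d7-t5-t2-t3 (s = 0.03) and d7-t5-t4-t3 (s = 0.05)
#'   \item C4: d7-d1-t2-t3 (s = 0.03) and d7-d4-t4-t3 (s = 0.05)
#'   \item C5: d7-d3-d2-t3 (s = 0.02)
#'   \item C6: d7-t5-d5-t3 (s = 1)
#' }
#' so the three feature blocks of (d7, t3) are
#' V1 = (0.16, 0.16, 0.08, 0.08, 0.02, 1),
#' V2 = (0.16, 0.16, 0.05, 0.05, 0.02, 1) and
#' V3 = (1, 1, 2, 2, 1, 1).
#'
#' The fixture is meant to be used with the raw similarity weights (no
#' diffusion): path weights multiply the drawn edge weights directly, with
#' interaction edges contributing factor 1.
#'
#' @return A list with `network` (a [DrugTargetNetwork-class]), `pair`
#'   (`c("d7", "t3")`), `k` (neighbour count making the neighbour
#'   constraint vacuous), and `expected` (`v1`, `v2`, `v3` blocks).
#' @export
workedExampleFixture <- function() {
    dn <- paste0("d", 1:7)
    tn <- paste0("t", 1:5)
    SD <- matrix(0, 7, 7, dimnames = list(dn, dn))
    diag(SD) <- 1
    SD["d7", "d6"] <- 0.16
    SD["d7", "d1"] <- 0.1
    SD["d7", "d4"] <- 0.1
    SD["d7", "d3"] <- 0.1
    SD["d3", "d2"] <- 0.2
    SD <- pmax(SD, t(SD))
    ST <- matrix(0, 5, 5, dimnames = list(tn, tn))
    diag(ST) <- 1
    ST["t5", "t3"] <- 0.16
    ST["t5", "t2"] <- 0.1
    ST["t2", "t3"] <- 0.3
    ST["t5", "t4"] <- 0.1
    ST["t4", "t3"] <- 0.5
    ST <- pmax(ST, t(ST))
    Y <- matrix(0, 7, 5, dimnames = list(dn, tn))
    Y["d7", "t5"] <- 1
    Y["d6", "t3"] <- 1
    Y["d1", "t2"] <- 1
    Y["d4", "t4"] <- 1
    Y["d2", "t3"] <- 1
    Y["d5", "t5"] <- 1
    Y["d5", "t3"] <- 1
    list(
        network = DrugTargetNetwork(SD, ST, Y),
        pair = c(drug = "d7", target = "t3"),
        k = 6L,
        expected = list(
            v1 = c(0.16, 0.16, 0.08, 0.08, 0.02, 1),
            v2 = c(0.16, 0.16, 0.05, 0.05, 0.02, 1),
            v3 = c(1, 1, 2, 2, 1, 1)
        )
    )
}

#' Specification of a planted-signal synthetic network
#'
#' Drugs and targets are assigned to latent clusters; similarities are
#' high inside a cluster and low between clusters, and each drug cluster
#' is wired to the matching target cluster: interactions are sampled
#' densely inside matched cluster pairs and at a small noise rate outside.
#' This embodies the guilt-by-association assumption that similar drugs
#' tend to share targets, giving a known recoverable signal.
#'
#' @param nDrugs,nTargets Node counts (default 40 each).
#' @param nClusters Number of drug clusters = number of target clusters
#'   (default 4).
#' @param withinSim Similarity level inside a cluster, jittered by
#'   +-0.05 (default 0.8).
#' @param betweenSim Similarity level between clusters (default 0.1).
#' @param density Interaction probability inside matched cluster pairs
#'   (default 0.3).
#' @param noiseRate Interaction probability outside matched pairs
#'   (default 0.02).
#' @param seed Integer seed.
#' @return A list of class `syntheticSpec`.
#' @export
syntheticSpec <- function(nDrugs = 40L, nTargets = 40L, nClusters = 4L,
                          withinSim = 0.8, betweenSim = 0.1, density = 0.3,
                          noiseRate = 0.02, seed = 1L) {
    stopifnot(
        nDrugs >= 2, nTargets >= 2, nClusters >= 1,
        nClusters <= min(nDrugs, nTargets),
        withinSim >= 0, withinSim <= 1, betweenSim >= 0, betweenSim <= 1,
        density >= 0, density <= 1, noiseRate >= 0, noiseRate <= 1
    )
    structure(
        list(
            nDrugs = as.integer(nDrugs), nTargets = as.integer(nTargets),
            nClusters = as.integer(nClusters), withinSim = withinSim,
            betweenSim = betweenSim, density = density,
            noiseRate = noiseRate, seed = as.integer(seed)
        ),
        class = "syntheticSpec"
    )
}

.clusterSim <- function(labels, within, between, jitter = 0.05) {
    n <- length(labels)
    same <- outer(labels, labels, "==")
    S <- matrix(between, n, n)
    S[same] <- within + stats::runif(sum(same), -jitter, jitter)
    S[lower.tri(S)] <- t(S)[lower.tri(S)]
    S <- pmin(pmax(S, 0), 1)
    diag(S) <- 1
    S
}

#' Generate a planted-signal heterogeneous network
#'
#' @param spec A [syntheticSpec()].
#' @return A list with `network` (a validated [DrugTargetNetwork-class]),
#'   `drugClusters` and `targetClusters` (integer ground-truth labels).
#' @export
generateNetwork <- function(spec = syntheticSpec()) {
    stopifnot(inherits(spec, "syntheticSpec"))
    .withSeed(spec$seed, {
        dcl <- sample(rep_len(seq_len(spec$nClusters), spec$nDrugs))
        tcl <- sample(rep_len(seq_len(spec$nClusters), spec$nTargets))
        SD <- .clusterSim(dcl, spec$withinSim, spec$betweenSim)
        ST <- .clusterSim(tcl, spec$withinSim, spec$betweenSim)
        matched <- outer(dcl, tcl, "==")
        prob <- ifelse(matched, spec$density, spec$noiseRate)
        Y <- matrix(
            stats::rbinom(length(prob), 1, prob),
            spec$nDrugs, spec$nTargets
        )
    })
    dn <- paste0("d", seq_len(spec$nDrugs))
    tn <- paste0("t", seq_len(spec$nTargets))
    dimnames(SD) <- list(dn, dn)
    dimnames(ST) <- list(tn, tn)
    dimnames(Y) <- list(dn, tn)
    list(
        network = DrugTargetNetwork(SD, ST, Y),
        drugClusters = dcl,
        targetClusters = tcl
    )
}

#' Randomly permute the interaction labels of a network
#'
#' Shuffles the entries of the interaction matrix over all drug-target
#' pairs, severing any relation between the similarity structure and the
#' labels while keeping the number of known interactions. Used as a null
#' model: cross-validation on a permuted network should score near
#' chance.
#'
#' @param net A [DrugTargetNetwork-class].
#' @param seed Integer seed.
#' @return A [DrugTargetNetwork-class] with permuted interactions.
#' @export
permuteInteractions <- function(net, seed = 1L) {
    Y <- interactions(net)
    .withSeed(seed, {
        Yp <- matrix(sample(as.vector(Y)), nrow(Y), ncol(Y),
            dimnames = dimnames(Y)
        )
    })
    DrugTargetNetwork(drugSimilarity(net), targetSimilarity(net), Yp)
}
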