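writeSimFile <- function(S, path, sep = "\t") {
    utils::write.table(
        data.frame(id = rownames(S), S, check.names = FALSE),
        path,
        sep = sep, quote = FALSE, row.names = FALSE
    )
    path
}

toySimFiles <- function(dir) {
    dn <- paste0("d", 1:3)
    tn <- paste0("t", 1:2)
    SD <- matrix(c(1, .5, .2, .5, 1, 0, .2, 0, 1), 3, 3,
        dimnames = list(dn, dn)
    )
    ST <- matrix(c(1, .7, .7, 1), 2, 2, dimnames = list(tn, tn))
    list(
        drug = writeSimFile(SD, file.path(dir, "d.tsv")),
        target = writeSimFile(ST, file.path(dir, "t.tsv")),
        SD = SD, ST = ST
    )
}

test_that("readNetwork builds the interaction matrix from an edge list", {
    dir <- withr::local_tempdir()
    fx <- toySimFiles(dir)
    writeLines("d1\tt1", file.path(dir, "y.tsv"))
    net <- readNetwork(fx$drug, fx$target, file.path(dir, "y.tsv"))
    expect_s4_class(net, "DrugTargetNetwork")
    expect_equal(unname(interactions(net)), rbind(c(1, 0), c(0, 0), c(0, 0)))
    expect_equal(drugIds(net), paste0("d", 1:3))
    # optional header accepted
    writeLines(c("drug\ttarget", "d2\tt2"), file.path(dir, "yh.tsv"))
    net2 <- readNetwork(fx$drug, fx$target, file.path(dir, "yh.tsv"))
    expect_equal(interactions(net2)["d2", "t2"], 1)
})

test_that("malformed inputs raise distinct, described errors", {
    dir <- withr::local_tempdir()
    fx <- toySimFiles(dir)
    writeLines("dX\tt1", file.path(dir, "y.tsv"))
    expect_error(
        readNetwork(fx$drug, fx$target, file.path(dir, "y.tsv")),
        "unknown identifier.*dX"
    )
    asym <- fx$SD
    asym[1, 2] <- 0.3
    asym[2, 1] <- 0.4
    writeSimFile(asym, file.path(dir, "asym.tsv"))
    expect_error(
        readSimilarityMatrix(file.path(dir, "asym.tsv")),
        "asymmetric"
    )
    bad <- fx$SD
    bad[1, 2] <- bad[2, 1] <- 1.7
    writeSimFile(bad, file.path(dir, "range.tsv"))
    expect_error(
        readSimilarityMatrix(file.path(dir, "range.tsv")),
        "out of range"
    )
    nad <- fx$SD
    nad[1, 2] <- nad[2, 1] <- NA
    writeSimFile(nad, file.path(dir, "na.tsv"))
    expect_error(
        readSimilarityMatrix(file.path(dir, "na.tsv")),
        "NaN or blank"
    )
    # dimension mismatch between layers
    y <- matrix(0, 2, 2, dimnames = list(paste0("d", 1:2), paste0("t", 1:2)))
    expect_error(
        DrugTargetNetwork(fx$SD, fx$ST, y),
        "dimension mismatch"
    )
})

test_that("rowNormalize excludes the diagonal and handles zero rows", {
    S <- matrix(c(1, 1, 1, 1, 1, 0, 1, 0, 1), 3, 3)
    N <- rowNormalize(S)
    expect_equal(N[1, ], c(0, 0.5, 0.5))
    expect_equal(rowSums(N), rep(1, 3))
    # already-normalized off-diagonal row passes through
    S2 <- rbind(
        c(1, 0.2, 0.3, 0.5),
        c(0.2, 1, 0, 0),
        c(0.3, 0, 1, 0),
        c(0.5, 0, 0, 1)
    )
    expect_equal(rowNormalize(S2)[1, ], c(0, 0.2, 0.3, 0.5))
    # isolated node becomes self-absorbing
    S3 <- diag(3)
    N3 <- rowNormalize(S3)
    expect_equal(N3, diag(3))
})

test_that("random walk matches the closed form and keeps rows stochastic", {
    # 2x2 swap chain has a hand-derivable fixed point
    N <- matrix(c(0, 1, 1, 0), 2, 2)
    W <- randomWalkWithRestart(N, restart = 0.4)
    expect_equal(unname(W[1, ]), c(0.625, 0.375), tolerance = 1e-5)
    # identity transition is a fixed point for any restart
    expect_equal(randomWalkWithRestart(diag(4), 0.7), diag(4),
        ignore_attr = TRUE
    )
    # closed form a * (I - (1-a)N)^-1 on random row-stochastic matrices
    for (seed in 1:5) {
        set.seed(seed)
        m <- sample(5:20, 1)
        N <- matrix(runif(m * m), m, m)
        N <- N / rowSums(N)
        a <- runif(1, 0.2, 0.8)
        W <- randomWalkWithRestart(N, a)
        closed <- a * solve(diag(m) - (1 - a) * N)
        expect_lt(max(abs(W - closed)), 1e-5)
        expect_lt(max(abs(rowSums(W) - 1)), 1e-6)
    }
})

test_that("row sums of every iterate stay 1 and restart pulls W to identity", {
    set.seed(42)
    N <- matrix(runif(100), 10, 10)
    N <- N / rowSums(N)
    # manually replay iterates to check row-stochasticity along the way
    W <- diag(10)
    for (t in 1:25) {
        W <- 0.6 * N %*% W + 0.4 * diag(10)
        expect_lt(max(abs(rowSums(W) - 1)), 1e-9)
    }
    dist <- vapply(
        c(0.2, 0.4, 0.6, 0.8, 0.95),
        function(a) max(abs(randomWalkWithRestart(N, a) - diag(10))),
        numeric(1)
    )
    expect_true(all(diff(dist) < 0))
})

test_that("non-convergence within the cap reports the last norm", {
    N <- matrix(c(0, 1, 1, 0), 2, 2)
    expect_error(
        randomWalkWithRestart(N, restart = 0.01, maxIter = 2L),
        "did not converge in 2 iterations.*norm"
    )
})

test_that("neighbour selection orders by symmetrized similarity with index tie-break", {
    W <- rbind(
        c(0.9, 0.5, 0.3, 0.2),
        c(0.5, 0.9, 0.1, 0.1),
        c(0.3, 0.1, 0.9, 0.1),
        c(0.2, 0.1, 0.1, 0.9)
    )
    K <- selectKNeighbors(W, 2)
    expect_equal(K[1, ], c(2L, 3L))
    # a node never lists itself
    expect_true(all(K != row(K)[, 1:2]))
    # equal scores resolve to the lower index
    W2 <- rbind(
        c(1, 0.3, 0.3, 0.1),
        c(0.3, 1, 0.2, 0.2),
        c(0.3, 0.2, 1, 0.2),
        c(0.1, 0.2, 0.2, 1)
    )
    expect_equal(selectKNeighbors(W2, 1)[1, ], 2L)
    # k = m - 1 keeps everything; larger k degrades with a warning
    expect_equal(ncol(selectKNeighbors(W, 3)), 3)
    expect_warning(K4 <- selectKNeighbors(W, 10), "using all 3 other nodes")
    expect_equal(ncol(K4), 3)
    # determinism
    expect_identical(selectKNeighbors(W, 2), selectKNeighbors(W, 2))
})

test_that("network files round-trip through write and read", {
    net <- randomNetworkFixture(6, 5, seed = 11)
    dir <- withr::local_tempdir()
    paths <- writeNetworkFiles(net, dir)
    back <- readNetwork(paths["drug_sim"], paths["target_sim"], paths["interactions"])
    expect_equal(drugSimilarity(back), drugSimilarity(net), tolerance = 1e-12)
    expect_equal(interactions(back), interactions(net))
})
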