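fixtureState <- function() {
    fx <- workedExampleFixture()
    net <- fx$network
    list(
        fx = fx, net = net,
        WD = drugSimilarity(net), WT = targetSimilarity(net),
        KD = selectKNeighbors(drugSimilarity(net), fx$k),
        KT = selectKNeighbors(targetSimilarity(net), numTargets(net) - 1)
    )
}

test_that("worked-example path sets are enumerated exactly", {
    st <- fixtureState()
    p3 <- enumeratePaths(st$net, st$WD, st$WT, st$KD, st$KT, "d7", "t3", "C3")
    expect_equal(nrow(p3), 2)
    expect_setequal(p3$path, c("d7-t5-t2-t3", "d7-t5-t4-t3"))
    expect_equal(sort(p3$weight), c(0.03, 0.05), tolerance = 1e-12)
    p5 <- enumeratePaths(st$net, st$WD, st$WT, st$KD, st$KT, "d7", "t3", "C5")
    expect_equal(p5$path, "d7-d3-d2-t3")
    expect_equal(p5$weight, 0.02, tolerance = 1e-12)
})

test_that("aggregation is sum, max and count with an all-zero empty-set convention", {
    expect_equal(
        aggregateCategory(c(0.03, 0.05)),
        c(v1 = 0.08, v2 = 0.05, v3 = 2)
    )
    expect_equal(aggregateCategory(0.02), c(v1 = 0.02, v2 = 0.02, v3 = 1))
    expect_equal(aggregateCategory(numeric(0)), c(v1 = 0, v2 = 0, v3 = 0))
})

test_that("the fixture pair yields the printed 18-dimensional feature vector", {
    st <- fixtureState()
    v <- buildPairFeatures(st$net, st$WD, st$WT, st$KD, st$KT, "d7", "t3")
    expect_length(v, 18)
    expect_equal(unname(v[1:6]), st$fx$expected$v1, tolerance = 1e-12)
    expect_equal(unname(v[7:12]), st$fx$expected$v2, tolerance = 1e-12)
    expect_equal(unname(v[13:18]), st$fx$expected$v3, tolerance = 1e-12)
})

test_that("a drug with no edges yields an empty path set for every category", {
    dn <- paste0("d", 1:3)
    tn <- paste0("t", 1:3)
    SD <- diag(3)
    dimnames(SD) <- list(dn, dn)
    ST <- diag(3)
    dimnames(ST) <- list(tn, tn)
    Y <- matrix(0, 3, 3, dimnames = list(dn, tn))
    Y["d2", "t2"] <- 1
    net <- DrugTargetNetwork(SD, ST, Y)
    KD <- selectKNeighbors(SD, 2)
    KT <- selectKNeighbors(ST, 2)
    for (h in 1:6) {
        expect_equal(nrow(enumeratePaths(net, SD, ST, KD, KT, "d1", "t1", h)), 0)
    }
    v <- buildPairFeatures(net, SD, ST, KD, KT, "d1", "t1")
    expect_equal(unname(v), rep(0, 18))
})

test_that("optimized features equal exhaustive brute force on random networks", {
    for (seed in 1:6) {
        m <- 4 + (seed %% 4)
        n <- 4 + ((seed + 2) %% 4)
        net <- randomNetworkFixture(m, n, seed = 100 + seed)
        df <- diffuseFixture(net, k = 3)
        WDs <- symRaw(df$WD)
        WTs <- symRaw(df$WT)
        Y <- interactions(net)
        for (i in seq_len(m)) {
            for (j in seq_len(n)) {
                v <- buildPairFeatures(net, df$WD, df$WT, df$KD, df$KT, i, j)
                for (h in 1:6) {
                    w <- brutePathWeights(Y, WDs, WTs, df$KD, df$KT, i, j, h)
                    expect_equal(unname(v[h]), sum(w), tolerance = 1e-12)
                    expect_equal(unname(v[6 + h]),
                        if (length(w)) max(w) else 0,
                        tolerance = 1e-12
                    )
                    expect_equal(unname(v[12 + h]), length(w))
                    # member paths agree too, not just the aggregates
                    ep <- enumeratePaths(net, df$WD, df$WT, df$KD, df$KT, i, j, h)
                    expect_equal(sort(ep$weight), w, tolerance = 1e-12)
                }
            }
        }
    }
})

test_that("feature vectors satisfy the v2 <= v1 <= v3*v2 bound chain", {
    for (seed in 1:5) {
        net <- randomNetworkFixture(7, 7, seed = 200 + seed)
        df <- diffuseFixture(net, k = 4)
        tbl <- buildFeatureTable(net, df$WD, df$WT, df$KD, df$KT)
        v1 <- as.matrix(tbl[, paste0("v1_c", 1:6)])
        v2 <- as.matrix(tbl[, paste0("v2_c", 1:6)])
        v3 <- as.matrix(tbl[, paste0("v3_c", 1:6)])
        expect_true(all(v2 >= 0))
        expect_true(all(v1 - v2 >= -1e-12))
        expect_true(all(v3 * v2 - v1 >= -1e-12))
        expect_true(all((v3 == 0) == (v1 == 0 & v2 == 0)))
        expect_true(all(abs(v1[v3 <= 1] - v2[v3 <= 1]) < 1e-12))
    }
})

test_that("raising a drug-drug edge weight never lowers sum or max features", {
    net <- randomNetworkFixture(6, 6, seed = 321)
    df <- diffuseFixture(net, k = 5)
    WDs <- symRaw(df$WD)
    base <- buildPairFeatures(net, df$WD, df$WT, df$KD, df$KT, 1, 1)
    WDup <- df$WD
    # strengthen every drug-drug edge out of d1
    WDup[1, ] <- pmin(WDup[1, ] * 1.5, 1)
    WDup[, 1] <- pmin(WDup[, 1] * 1.5, 1)
    up <- buildPairFeatures(net, WDup, df$WT, df$KD, df$KT, 1, 1)
    ddCats <- c(1, 4, 5) # categories with a drug-drug edge
    expect_true(all(up[ddCats] >= base[ddCats] - 1e-12))
    expect_true(all(up[6 + ddCats] >= base[6 + ddCats] - 1e-12))
})

test_that("features of a pair never depend on its own interaction label", {
    net <- randomNetworkFixture(6, 6, seed = 77)
    df <- diffuseFixture(net, k = 4)
    Y <- interactions(net)
    for (pair in list(c(1, 1), c(2, 5), c(6, 3))) {
        Yflip <- Y
        Yflip[pair[1], pair[2]] <- 1 - Yflip[pair[1], pair[2]]
        netFlip <- DrugTargetNetwork(
            drugSimilarity(net), targetSimilarity(net), Yflip
        )
        expect_equal(
            buildPairFeatures(net, df$WD, df$WT, df$KD, df$KT, pair[1], pair[2]),
            buildPairFeatures(netFlip, df$WD, df$WT, df$KD, df$KT, pair[1], pair[2])
        )
    }
})

test_that("feature tables have the contracted shape, labels and determinism", {
    net <- randomNetworkFixture(3, 2, seed = 5)
    df <- diffuseFixture(net, k = 2)
    tbl <- buildFeatureTable(net, df$WD, df$WT, df$KD, df$KT)
    expect_equal(nrow(tbl), 6)
    expect_equal(ncol(tbl), 2 + 18 + 1)
    expect_equal(tbl$label, interactions(net)[cbind(
        match(tbl$drug, drugIds(net)), match(tbl$target, targetIds(net))
    )])
    # permuting the requested pairs permutes the rows identically
    pairs <- tbl[, c("drug", "target")]
    perm <- c(4, 1, 6, 3, 2, 5)
    tblPerm <- buildFeatureTable(net, df$WD, df$WT, df$KD, df$KT, pairs[perm, ])
    expect_equal(tblPerm, tbl[perm, ], ignore_attr = TRUE)
})
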