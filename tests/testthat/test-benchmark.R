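test_that("decoy sampling is reproducible and well-formed", {
    universe <- sprintf("g%03d", 1:120)
    sets <- sampleDecoys(universe, "g001", size = 50, nReplicates = 30,
                         seed = 99)
    expect_length(sets, 30)
    for (s in sets) {
        expect_length(s, 51)
        expect_true("g001" %in% s)
        expect_false(anyDuplicated(s) > 0)
    }
    expect_identical(sets, sampleDecoys(universe, "g001", 50, 30, seed = 99))
    # exhaustive sample: every replicate is the whole universe
    all <- sampleDecoys(universe, "g001", size = 119, nReplicates = 3,
                        seed = 1)
    for (s in all) expect_setequal(s, universe)
    expect_error(sampleDecoys(universe, "g001", size = 120, seed = 1),
                 "too small")
})

test_that("ROC endpoints: perfect and chance-level ranking", {
    perfect <- benchmarkRun("g", decoySize = 50, ranks = rep(1L, 30))
    expect_identical(auc(rocFromRanks(perfect)), 1)
    # one decoy above, one below -> half the pairs correct
    mid <- benchmarkRun("g", decoySize = 2, ranks = rep(2L, 12))
    expect_equal(auc(rocFromRanks(mid)), 0.5)
    # uniform ranks approach 0.5 with many replicates
    set.seed(5)
    unif <- benchmarkRun("g", decoySize = 100,
                         ranks = sample(1:101, 2000, replace = TRUE))
    expect_equal(auc(rocFromRanks(unif)), 0.5, tolerance = 0.03)
    expect_error(rocFromRanks(list()), "no benchmark runs")
    expect_error(rocFromRanks(list(perfect, mid)), "decoy size")
})

test_that("ROC curves are valid and trapezoid AUC equals Mann-Whitney", {
    set.seed(17)
    for (rep in 1:30) {
        n <- sample(c(5L, 20L, 50L), 1)
        ranks <- sample(seq_len(n + 1L), sample(1:20, 1), replace = TRUE)
        roc <- rocFromRanks(benchmarkRun("g", n, ranks))
        pts <- rocPoints(roc)
        expect_false(is.unsorted(pts$fpr))
        expect_false(is.unsorted(pts$tpr))
        expect_equal(pts$fpr[c(1, nrow(pts))], c(0, 1))
        expect_equal(auc(roc), mwAuc(ranks, n), tolerance = 1e-12)
    }
})

test_that("per-replicate AUC averaging agrees with the closed form", {
    ranks <- c(1L, 5L, 11L)
    run <- benchmarkRun("g", decoySize = 10, ranks = ranks)
    expect_equal(meanReplicateAuc(run), mean((11 - ranks) / 10))
})

test_that("rank statistics: mean, sample SD, reciprocal rank", {
    st <- rankStats(benchmarkRun("g", 10, c(1L, 1L, 1L)))
    expect_equal(st[c("meanRank", "sdRank", "mrr")],
                 list(meanRank = 1, sdRank = 0, mrr = 1))
    st <- rankStats(benchmarkRun("g", 10, c(1L, 2L, 3L)))
    expect_equal(st$meanRank, 2)
    expect_equal(st$sdRank, 1)
    expect_equal(st$mrr, 11 / 18)
    st <- rankStats(benchmarkRun("g", 10, 5L))
    expect_equal(st$meanRank, 5)
    expect_false(st$sdDefined)
    expect_equal(st$sdRank, 0)
    expect_equal(st$mrr, 0.2)
})

test_that("one-sided KS statistic matches the direct CDF comparison", {
    # identical affected and unaffected pools: no separation
    m <- matrix(c(1, 2, 1, 2), 2, 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("t1", "t2")))
    m <- cbind(m, t3 = c(1, 1), t4 = c(2, 2))
    prof <- makeProfiles(m)
    assoc <- data.frame(gene = c("a", "b"), tissues = "t1;t2",
                        stringsAsFactors = FALSE)
    ks <- ksAffectedVsUnaffected(prof, assoc)
    expect_equal(ks@d, 0)

    # complete separation: affected {3,4} vs unaffected {1,2}
    m2 <- matrix(c(3, 4, 1, 2), 1, 4,
                 dimnames = list("a", c("t1", "t2", "t3", "t4")))
    ks2 <- ksAffectedVsUnaffected(makeProfiles(m2),
                                  data.frame(gene = "a", tissues = "t1;t2"))
    expect_equal(ks2@d, 1)
    expect_identical(ks2@nAffected, 2L)

    # random pools agree with the CDF-difference oracle
    set.seed(29)
    for (rep in 1:10) {
        z <- matrix(rnorm(80), 8, 10,
                    dimnames = list(paste0("g", 1:8), paste0("t", 1:10)))
        prof <- makeProfiles(z)
        assoc <- data.frame(gene = paste0("g", 1:8),
                            tissues = paste0("t", sample(1:10, 8, TRUE)),
                            stringsAsFactors = FALSE)
        ks <- ksAffectedVsUnaffected(prof, assoc)
        A <- unlist(lapply(1:8, function(i) z[i, assoc$tissues[i]]))
        B <- unlist(lapply(1:8, function(i)
            z[i, setdiff(colnames(z), assoc$tissues[i])]))
        expect_equal(ks@d, bruteKsD(A, B), tolerance = 1e-12)
        expect_equal(ks@pValue,
                     exp(-2 * ks@d^2 * length(A) * length(B) /
                         (length(A) + length(B))),
                     tolerance = 1e-6)
    }
    expect_error(
        ksAffectedVsUnaffected(makeProfiles(m2),
                               data.frame(gene = "zz", tissues = "t1")),
        "at least 2")
})

test_that("planted elevation is detected by the KS test", {
    # 200 genes each elevated in one tissue: pooled affected sample n = 200
    set.seed(41)
    planted <- data.frame(gene = sprintf("G%04d", 1:200),
                          tissues = sample(testTissues, 200, replace = TRUE),
                          effect = 1.5, stringsAsFactors = FALSE)
    spec <- syntheticSpec(nGenes = 250, planted = planted,
                          experimentsPerTissue = c(human_rnaseq = 2L),
                          seed = 41)
    db <- generateDatabase(spec)
    prof <- profilesBySource(db$datasets)$human_rnaseq
    ks <- ksAffectedVsUnaffected(prof, planted[, c("gene", "tissues")])
    expect_gt(ks@d, 0.3)
    expect_lt(ks@pValue, 1e-6)
    # the opposite direction shows no signal
    ksRev <- ksAffectedVsUnaffected(prof, planted[, c("gene", "tissues")],
                                    direction = "affected_less")
    expect_gt(ksRev@pValue, 0.5)
})

test_that("expected AUC never decreases along an effect-size ladder", {
    meanAuc <- vapply(c(0, 1, 2, 3), function(eff) {
        aucs <- vapply(1:6, function(s) {
            spec <- syntheticSpec(nGenes = 80, effect = eff, seed = s,
                                  experimentsPerTissue = c(human_rnaseq = 2L))
            db <- generateDatabase(spec)
            profs <- profilesBySource(db$datasets)
            run <- benchmarkGene("G0001", db$truth$tissue[1], profs,
                                 size = 30, nReplicates = 5, seed = s + 500)
            auc(rocFromRanks(run))
        }, numeric(1))
        mean(aucs)
    }, numeric(1))
    expect_true(all(diff(meanAuc) >= -0.05))  # monotone up to MC noise
    expect_gt(meanAuc[4], 0.95)
})
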