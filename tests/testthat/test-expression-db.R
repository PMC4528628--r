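test_that("ambiguous probes are discarded, order preserved", {
    maps <- list(pA = "G1", pB = c("G1", "G2"), pC = "G3")
    expect_identical(filterAmbiguousProbes(maps), maps[c("pA", "pC")])
    expect_identical(filterAmbiguousProbes(list()), list())
    expect_identical(filterAmbiguousProbes(list(pC = "G3")), list(pC = "G3"))
    expect_error(filterAmbiguousProbes(list(p = character())), "non-empty|target")
})

test_that("modified z-scores match hand evaluation", {
    d <- ExperimentDataset("e1", "human", "rnaseq", "liver",
                           c(g1 = 2, g2 = 4, g3 = 6, g4 = 8, g5 = 10))
    z <- modifiedZScores(d, center = "mean")
    expect_equal(z[["g3"]], 0)                       # equals the center
    expect_equal(z[["g5"]], 0.6745 * (10 - 6) / 2)   # = 1.349, MAD = 2
    expect_equal(z[["g1"]], -1.349)
})

test_that("zero-dispersion and degenerate experiments are handled", {
    flat <- ExperimentDataset("e1", "human", "rnaseq", "liver",
                              c(g1 = 5, g2 = 5, g3 = 5, g4 = 5))
    expect_equal(unname(modifiedZScores(flat)), rep(0, 4))
    # MAD 0 but values not identical: mean-absolute-deviation fallback
    d <- ExperimentDataset("e2", "human", "rnaseq", "liver",
                           c(g1 = 5, g2 = 5, g3 = 5, g4 = 9))
    z <- modifiedZScores(d)
    expect_true(all(is.finite(z)))
    expect_gt(z[["g4"]], 0)
    expect_error(
        ExperimentDataset("e3", "human", "rnaseq", "liver", c(g1 = 1, g2 = 2)),
        "at least 3")
})

test_that("z-scores are affine invariant and order preserving", {
    set.seed(42)
    for (i in 1:25) {
        n <- sample(3:40, 1)
        e <- setNames(rexp(n, 1 / 50), paste0("g", seq_len(n)))
        a <- runif(1, 0.1, 10)
        b <- runif(1, 0, 100)
        for (ctr in c("mean", "median")) {
            d1 <- ExperimentDataset("e", "human", "microarray", "lung", e)
            d2 <- ExperimentDataset("e", "human", "microarray", "lung",
                                    a * e + b)
            z1 <- modifiedZScores(d1, ctr)
            z2 <- modifiedZScores(d2, ctr)
            expect_equal(z1, z2, tolerance = 1e-10)
            ord <- order(e)
            expect_false(is.unsorted(z1[ord]))
        }
    }
})

test_that("mean and median centers agree on symmetric data", {
    e <- setNames(c(1, 2, 3, 4, 5, 6, 7), paste0("g", 1:7))
    d <- ExperimentDataset("e", "mouse", "rnaseq", "brain", e)
    expect_equal(modifiedZScores(d, "mean"), modifiedZScores(d, "median"))
})

test_that("tissue profiles equal the brute-force group-mean oracle", {
    set.seed(7)
    for (rep in 1:8) {
        nG <- sample(5:20, 1)
        genes <- paste0("g", seq_len(nG))
        tissues <- paste0("t", seq_len(sample(2:5, 1)))
        datasets <- list()
        for (t in tissues) for (k in seq_len(sample(1:3, 1))) {
            present <- sort(sample(genes, max(3L, rbinom(1, nG, 0.8))))
            datasets[[length(datasets) + 1L]] <- ExperimentDataset(
                paste0(t, "_", k), "human", "rnaseq", t,
                setNames(rlnorm(length(present), 2, 1), present))
        }
        prof <- buildTissueProfiles(datasets, "human_rnaseq")
        oracle <- bruteProfiles(datasets)
        expect_equal(meanZ(prof)[rownames(oracle$meanZ), colnames(oracle$meanZ)],
                     oracle$meanZ, tolerance = 1e-12)
        expect_equal(medianZ(prof)[names(oracle$medianZ)], oracle$medianZ,
                     tolerance = 1e-12)
    }
})

test_that("profile construction validates inputs", {
    d <- ExperimentDataset("e", "mouse", "rnaseq", "brain",
                           c(g1 = 1, g2 = 2, g3 = 3))
    expect_error(buildTissueProfiles(list(d), "human_rnaseq"),
                 "does not belong")
    voc <- TissueVocabulary(c("liver", "lung"))
    expect_error(buildTissueProfiles(list(d), "mouse_rnaseq",
                                     vocabulary = voc), "brain")
    empty <- buildTissueProfiles(list(), "human_rnaseq")
    expect_length(profileGenes(empty), 0)
})

test_that("two experiments of one tissue average; medians recompute", {
    # constructed so gene gA has z = 1.349 and 0 in the two liver runs
    e1 <- ExperimentDataset("l1", "human", "rnaseq", "liver",
                            c(gA = 10, gB = 2, gC = 4, gD = 6, gE = 8))
    e2 <- ExperimentDataset("l2", "human", "rnaseq", "liver",
                            c(gA = 6, gB = 2, gC = 4, gD = 8, gE = 10))
    prof <- buildTissueProfiles(list(e1, e2), "human_rnaseq")
    expect_equal(meanZ(prof)["gA", "liver"], (1.349 + 0) / 2)
    expect_equal(medianZ(prof),
                 apply(meanZ(prof), 1, median, na.rm = TRUE))
})

test_that("expression tables round-trip and reject bad rows", {
    d1 <- ExperimentDataset("e1", "human", "microarray", "liver",
                            c(g1 = 1.25, g2 = 2.5, g3 = 10.125))
    d2 <- ExperimentDataset("e2", "mouse", "rnaseq", "brain",
                            c(g1 = 0.1, g2 = 7.77, g4 = 123.456))
    path <- withr::local_tempfile(fileext = ".tsv")
    writeExpressionTable(list(d1, d2), path)
    back <- readExpressionTable(path)
    expect_length(back, 2)
    expect_equal(exprValues(back[[1]]), exprValues(d1))
    expect_identical(species(back[[2]]), "mouse")
    expect_identical(tissue(back[[2]]), "brain")
    # write(read(file)) is byte-identical
    path2 <- withr::local_tempfile(fileext = ".tsv")
    writeExpressionTable(back, path2)
    expect_identical(readLines(path), readLines(path2))

    lines <- readLines(path)
    bad <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c(lines, "e1\thuman\tmicroarray\tliver\tg9\t-1"), bad)
    expect_error(readExpressionTable(bad), "negative.*line 8")
    writeLines(c(lines, lines[2]), bad)
    expect_error(readExpressionTable(bad), "duplicate")
    writeLines(c(lines[1], "e1\tmartian\tmicroarray\tliver\tg1\t1"), bad)
    expect_error(readExpressionTable(bad), "species")
    writeLines(c(lines[1], "e1\thuman\tmicroarray"), bad)
    expect_error(readExpressionTable(bad), "line 2")
})

test_that("comment lines are ignored when reading", {
    d <- ExperimentDataset("e1", "human", "rnaseq", "liver",
                           c(g1 = 1, g2 = 2, g3 = 3))
    path <- withr::local_tempfile(fileext = ".tsv")
    writeExpressionTable(list(d), path)
    withComments <- c("# database export", readLines(path))
    writeLines(withComments, path)
    expect_equal(exprValues(readExpressionTable(path)[[1]]), exprValues(d))
})
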