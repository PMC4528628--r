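test_that("base score matches hand-evaluated cases", {
    m <- matrix(c(2, 2, 0.5), 1, 3,
                dimnames = list("g", c("t1", "t2", "t3")))
    p <- new("TissueProfiles", source = "human_rnaseq", meanZ = m,
             medianZ = c(g = 2))
    # ratio-one collapse: ln(1) = 0
    expect_equal(baseScore(p, "g", c("t1", "t2")), 4, tolerance = 1e-12,
                 ignore_attr = TRUE)
    # single tissue at e with baseline 1: e * (1 + 1)
    m2 <- matrix(c(exp(1), 1, 1), 1, 3,
                 dimnames = list("g", c("t1", "t2", "t3")))
    p2 <- makeProfiles(m2)
    expect_equal(baseScore(p2, "g", "t1"), 2 * exp(1), tolerance = 1e-12,
                 ignore_attr = TRUE)
    # negative mean z falls back to the plain value
    m3 <- matrix(c(-0.5, 1, 1.5), 1, 3,
                 dimnames = list("g", c("t1", "t2", "t3")))
    p3 <- makeProfiles(m3)
    expect_equal(baseScore(p3, "g", "t1"), -0.5, ignore_attr = TRUE)
})

test_that("affected tissues missing from the profile contribute zero", {
    p <- makeProfiles(matrix(c(2, 1, 1), 1, 3,
                             dimnames = list("g", c("t1", "t2", "t3"))))
    s <- baseScore(p, "g", c("t1", "nowhere"))
    expect_equal(as.numeric(s), 2 * (1 + log(2)))
    expect_identical(attr(s, "missingTissues"), "nowhere")
    expect_error(baseScore(p, "g", c("x", "y")), "affected")
})

test_that("base score is monotone in the affected-tissue mean z", {
    grid <- seq(1, 6, by = 0.05)   # z̄_t >= z̃ = 1 > 0
    scores <- vapply(grid, function(z) {
        m <- matrix(c(z, 1, 1), 1, 3,
                    dimnames = list("g", c("t1", "t2", "t3")))
        as.numeric(baseScore(makeProfiles(m), "g", "t1"))
    }, numeric(1))
    expect_true(all(diff(scores) > 0))
})

test_that("a below-baseline affected tissue never raises the score", {
    # adding a negative-z tissue to the affected set lowers S_g
    m <- matrix(c(2, -1, 1, 1), 1, 4,
                dimnames = list("g", c("t1", "t2", "t3", "t4")))
    p <- makeProfiles(m)
    s1 <- as.numeric(baseScore(p, "g", "t1"))
    s2 <- as.numeric(baseScore(p, "g", c("t1", "t2")))
    expect_lt(s2, s1)
    expect_equal(s2, s1 - 1)
})

test_that("variance adjustment damps flat housekeeping profiles", {
    cfg <- scoringConfig(varianceAdjust = TRUE, tau = 1, c = 1)
    flat <- makeProfiles(matrix(3, 1, 4,
                                dimnames = list("g", paste0("t", 1:4))))
    expect_equal(varianceAdjust(10, flat, "g", cfg), 0)  # sigma = 0
    low <- makeProfiles(matrix(c(0.2, 3, 3), 1, 3,
                               dimnames = list("g", paste0("t", 1:3))))
    expect_equal(varianceAdjust(10, low, "g", cfg), 10)  # gate not triggered
    spread <- makeProfiles(matrix(c(2, 3, 4), 1, 3,
                                  dimnames = list("g", paste0("t", 1:3))))
    expect_equal(varianceAdjust(4, spread, "g", cfg), 2)  # sigma = 1, c = 1
})

test_that("source combination is a weighted mean with mouse weight", {
    expect_equal(combineSources(c(human_microarray = 4, mouse_microarray = 2),
                                scoringConfig(mouseWeight = 0.5)),
                 5 / 1.5)
    expect_equal(combineSources(c(human_microarray = 4), scoringConfig()), 4)
    expect_equal(combineSources(c(human_microarray = 4, mouse_rnaseq = 2),
                                scoringConfig(mouseWeight = 0)), 4)
    expect_true(is.na(combineSources(c(mouse_rnaseq = 2),
                                     scoringConfig(mouseWeight = 0))))
    expect_error(combineSources(c(weird_source = 1)), "unknown")
    expect_error(combineSources(numeric(0)), "non-empty")
})

test_that("prioritize uses competition ranking and flags no-data genes", {
    m <- matrix(c(5, 2, 2,
                  0, 0, 0,
                  0, 0, 0), 3, 3, byrow = FALSE,
                dimnames = list(c("a", "b", "c"), c("t1", "t2", "t3")))
    m["b", ] <- c(2, 0, 0)
    m["c", ] <- c(2, 0, 0)
    m["a", ] <- c(5, 0, 0)
    p <- makeProfiles(m)
    res <- prioritize(c("a", "b", "c", "zz"), list(human_rnaseq = p), "t1")
    expect_identical(res$gene_id, c("a", "b", "c", "zz"))
    expect_identical(res$rank, c(1L, 2L, 2L, NA_integer_))
    expect_identical(res$no_data, c(FALSE, FALSE, FALSE, TRUE))
    expect_error(prioritize("zz", list(human_rnaseq = p), "t1"),
                 "no candidate could be scored")
})

test_that("prioritize matches a brute-force reimplementation", {
    set.seed(23)
    for (rep in 1:6) {
        nG <- sample(20:100, 1)
        genes <- sprintf("g%03d", seq_len(nG))
        tissues <- paste0("t", 1:6)
        mkMat <- function(ids) {
            m <- matrix(rnorm(length(ids) * 6), length(ids), 6,
                        dimnames = list(ids, tissues))
            m[sample(length(m), length(m) %/% 10)] <- NA  # spotty coverage
            bad <- rowSums(!is.na(m)) == 0
            m[bad, 1] <- rnorm(sum(bad))
            m
        }
        humanGenes <- sample(genes, nG - 5)
        orth <- data.frame(human_canonical_id = sample(genes, nG %/% 2),
                           stringsAsFactors = FALSE)
        orth$mouse_canonical_id <- paste0("m", orth$human_canonical_id)
        mouseGenes <- paste0("m", sample(orth$human_canonical_id,
                                         nrow(orth) - 3))
        profs <- list(human_rnaseq = makeProfiles(mkMat(humanGenes)),
                      mouse_microarray = makeProfiles(mkMat(mouseGenes),
                                                      "mouse_microarray"))
        mw <- runif(1)
        affected <- sample(tissues, 2)
        cfg <- scoringConfig(mouseWeight = mw)
        res <- prioritize(genes, profs, affected, config = cfg,
                          orthologs = orth)

        # oracle: direct formula evaluation gene by gene, then full sort
        comb <- setNames(rep(NA_real_, nG), genes)
        for (g in genes) {
            ss <- c()
            ww <- c()
            if (g %in% rownames(meanZ(profs$human_rnaseq))) {
                ss <- c(ss, bruteBaseScore(meanZ(profs$human_rnaseq)[g, ],
                                           medianZ(profs$human_rnaseq)[[g]],
                                           affected))
                ww <- c(ww, 1)
            }
            mg <- orth$mouse_canonical_id[match(g, orth$human_canonical_id)]
            if (!is.na(mg) && mg %in% rownames(meanZ(profs$mouse_microarray))) {
                ss <- c(ss, bruteBaseScore(
                    meanZ(profs$mouse_microarray)[mg, ],
                    medianZ(profs$mouse_microarray)[[mg]], affected))
                ww <- c(ww, mw)
            }
            if (length(ss) && sum(ww) > 0)
                comb[g] <- sum(ss * ww) / sum(ww)
        }
        expect_equal(setNames(res$combined_score, res$gene_id)[genes], comb,
                     tolerance = 1e-10)
        scored <- comb[!is.na(comb)]
        wantRank <- setNames(as.integer(rank(-scored, ties.method = "min")),
                             names(scored))
        gotRank <- setNames(res$rank, res$gene_id)[names(scored)]
        expect_identical(gotRank, wantRank)
        expect_true(all(res$no_data[is.na(res$rank)]))
    }
})

test_that("mouse weight zero reproduces human-only rankings exactly", {
    set.seed(31)
    genes <- sprintf("g%02d", 1:40)
    tissues <- paste0("t", 1:5)
    hm <- matrix(rnorm(200), 40, 5, dimnames = list(genes, tissues))
    mm <- matrix(rnorm(200), 40, 5,
                 dimnames = list(paste0("m", genes), tissues))
    orth <- data.frame(human_canonical_id = genes,
                       mouse_canonical_id = paste0("m", genes),
                       stringsAsFactors = FALSE)
    both <- list(human_microarray = makeProfiles(hm, "human_microarray"),
                 mouse_rnaseq = makeProfiles(mm, "mouse_rnaseq"))
    humanOnly <- both["human_microarray"]
    r1 <- prioritize(genes, both, c("t1", "t3"),
                     config = scoringConfig(mouseWeight = 0),
                     orthologs = orth)
    r2 <- prioritize(genes, humanOnly, c("t1", "t3"))
    expect_identical(r1$gene_id, r2$gene_id)
    expect_identical(r1$rank, r2$rank)
    expect_equal(r1$combined_score, r2$combined_score)
    # and the mouse sources are reported unused
    expect_false(any(grepl("mouse", r1$sources_used)))
})

test_that("results table writes as TSV", {
    p <- makeProfiles(matrix(c(2, 1, 1), 1, 3,
                             dimnames = list("g", c("t1", "t2", "t3"))))
    res <- prioritize("g", list(human_rnaseq = p), "t1")
    path <- withr::local_tempfile(fileext = ".tsv")
    writeScores(res, path)
    back <- read.delim(path)
    expect_equal(back$gene_id, "g")
    expect_equal(back$rank, 1L)
})
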