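# RNG hygiene: run code under a seed without disturbing the caller's stream
.withSeed <- function(seed, code) {
    if (!is.null(seed) && !is.na(seed)) {
        old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
            get(".Random.seed", globalenv()) else NULL
        on.exit(if (is.null(old))
            rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, envir = globalenv()))
        set.seed(seed)
    }
    force(code)
}

#' Sample random decoy candidate sets around a disease gene
#'
#' Each replicate is a uniform sample of `size` genes, drawn without
#' replacement from the universe with the disease gene excluded, plus the
#' disease gene itself — the random candidate lists the ranking is
#' benchmarked against.
#'
#' @param universe character vector of all gene ids available for
#'   sampling.
#' @param diseaseGene the positive instance, added to every replicate.
#' @param size number of decoys per replicate (commonly 50, 100, 200 or
#'   500).
#' @param nReplicates number of replicates (default 30).
#' @param seed RNG seed; identical seeds give identical sets.
#' @return List of `nReplicates` character vectors of `size + 1` genes.
#' @export
sampleDecoys <- function(universe, diseaseGene, size, nReplicates = 30L,
                         seed = NULL) {
    pool <- setdiff(unique(universe), diseaseGene)
    if (length(pool) < size)
        stop("universe too small: ", length(pool),
             " genes available, need ", size)
    .withSeed(seed, replicate(nReplicates,
                              c(diseaseGene, sample(pool, size)),
                              simplify = FALSE))
}

#' Rank-cutoff ROC curve from replicate disease-gene ranks
#'
#' Treats each replicate's disease gene as the single positive and its
#' decoys (occupying the remaining ranks) as negatives. A confusion matrix
#' is formed at every integer rank cutoff, pooled over all replicates, and
#' the curve of sensitivity against 1 - specificity is integrated by the
#' trapezoidal rule. The resulting AUC is identical to the Mann-Whitney
#' statistic on the pooled data: the fraction of (positive, negative)
#' pairs ranked in the correct order, ties counted half.
#'
#' @param runs a [BenchmarkRun-class] or list of them, all with the same
#'   decoy size.
#' @return A [RocResult-class].
#' @examples
#' r <- benchmarkRun("g", decoySize = 50, ranks = rep(1L, 30))
#' auc(rocFromRanks(r))
#' @export
rocFromRanks <- function(runs) {
    if (is(runs, "BenchmarkRun")) runs <- list(runs)
    if (length(runs) == 0L) stop("no benchmark runs supplied")
    stopifnot(all(vapply(runs, is, logical(1), "BenchmarkRun")))
    n <- unique(vapply(runs, decoySize, integer(1)))
    if (length(n) != 1L)
        stop("all runs must share one decoy size; got: ",
             paste(n, collapse = ", "))
    ranks <- unlist(lapply(runs, replicateRanks), use.names = FALSE)
    R <- length(ranks)
    cutoffs <- 0:(n + 1L)
    tp <- vapply(cutoffs, function(k) sum(ranks <= k), numeric(1))
    fp <- vapply(cutoffs, function(k) k * R, numeric(1)) - tp
    tpr <- tp / R
    fpr <- fp / (R * n)
    # the cutoff n+1 classifies everything positive; clamp numeric noise
    pts <- data.frame(cutoff = cutoffs, fpr = fpr, tpr = tpr)
    a <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                              utils::tail(pts$tpr, -1)) / 2)
    new("RocResult", points = pts, auc = a)
}

#' Mean per-replicate AUC
#'
#' Alternative to the pooled curve of [rocFromRanks()]: the single-positive
#' AUC `(n + 1 - r) / n` of each replicate, averaged.
#'
#' @param runs a [BenchmarkRun-class] or list of them.
#' @return Mean AUC across all replicates.
#' @export
meanReplicateAuc <- function(runs) {
    if (is(runs, "BenchmarkRun")) runs <- list(runs)
    n <- unique(vapply(runs, decoySize, integer(1)))
    if (length(n) != 1L) stop("all runs must share one decoy size")
    ranks <- unlist(lapply(runs, replicateRanks), use.names = FALSE)
    mean((n + 1 - ranks) / n)
}

#' Rank summary statistics of a benchmark run
#'
#' @param run a [BenchmarkRun-class].
#' @return List with `meanRank`, `sdRank` (sample standard deviation,
#'   n - 1 denominator; 0 with `sdDefined = FALSE` for a single
#'   replicate), `mrr` (mean reciprocal rank) and `nReplicates`.
#' @examples
#' rankStats(benchmarkRun("g", decoySize = 10, ranks = c(1L, 2L, 3L)))
#' @export
rankStats <- function(run) {
    stopifnot(is(run, "BenchmarkRun"))
    r <- replicateRanks(run)
    sdDefined <- length(r) >= 2L
    list(meanRank = mean(r),
         sdRank = if (sdDefined) stats::sd(r) else 0,
         mrr = mean(1 / r),
         nReplicates = length(r),
         sdDefined = sdDefined)
}

#' One-sided KS test: affected versus unaffected tissue expression
#'
#' Tests the core modeling assumption that disease genes are more highly
#' expressed in their affected tissues. For every (gene, affected tissues)
#' association, the gene's per-tissue mean modified z-scores are pooled
#' into an affected sample (its affected tissues) and an unaffected sample
#' (all its other tissues); the two pooled samples are compared with a
#' one-sided two-sample Kolmogorov-Smirnov test with asymptotic p-value.
#'
#' The default direction, `"affected_greater"`, takes the alternative
#' that the affected-tissue scores are stochastically greater (their
#' cumulative distribution lies below the unaffected one), matching the
#' elevated-expression hypothesis; `"affected_less"` tests the reverse.
#'
#' @param profiles a [TissueProfiles-class] for one evidence source.
#' @param associations data.frame with columns `gene` and `tissues`
#'   (affected tissue labels, `';'`-separated).
#' @param direction `"affected_greater"` (default) or `"affected_less"`.
#' @return A [KSResult-class].
#' @export
ksAffectedVsUnaffected <- function(profiles, associations,
                                   direction = c("affected_greater",
                                                 "affected_less")) {
    direction <- match.arg(direction)
    stopifnot(is(profiles, "TissueProfiles"),
              all(c("gene", "tissues") %in% colnames(associations)))
    m <- meanZ(profiles)
    A <- numeric()
    B <- numeric()
    for (i in seq_len(nrow(associations))) {
        g <- associations$gene[i]
        if (!(g %in% rownames(m))) next
        aff <- strsplit(associations$tissues[i], ";", fixed = TRUE)[[1L]]
        aff <- trimws(aff)
        z <- m[g, ]
        A <- c(A, z[intersect(aff, colnames(m))])
        B <- c(B, z[setdiff(colnames(m), aff)])
    }
    A <- A[!is.na(A)]
    B <- B[!is.na(B)]
    if (length(A) < 2L || length(B) < 2L)
        stop("need at least 2 pooled values per sample (affected: ",
             length(A), ", unaffected: ", length(B), ")")
    # one-sided two-sample KS: D+ = sup_x [F_unaffected(x) - F_affected(x)]
    # when the alternative is "affected stochastically greater"
    # ties only make the (already asymptotic) p-value approximate
    kt <- suppressWarnings(if (direction == "affected_greater")
        stats::ks.test(B, A, alternative = "greater", exact = FALSE)
    else
        stats::ks.test(B, A, alternative = "less", exact = FALSE))
    new("KSResult", d = unname(kt$statistic), pValue = kt$p.value,
        direction = direction, nAffected = length(A),
        nUnaffected = length(B))
}

#' Benchmark the prioritization of one disease gene
#'
#' Repeatedly ranks a disease gene against random decoy sets drawn from
#' the profiled gene universe and records its rank per replicate.
#' Candidates that cannot be scored (no expression data) are placed after
#' all scored genes, so an unscorable disease gene receives the worst rank
#' `size + 1`.
#'
#' @param diseaseGene the positive gene id.
#' @param affected affected tissue labels for scoring.
#' @param profiles named list of [TissueProfiles-class] (see
#'   [prioritize()]).
#' @param size decoy-set size.
#' @param nReplicates replicates (default 30).
#' @param seed RNG seed.
#' @param universe optional sampling universe; defaults to all genes with
#'   a profile in any supplied source.
#' @param config,orthologs passed to [prioritize()].
#' @return A [BenchmarkRun-class].
#' @export
benchmarkGene <- function(diseaseGene, affected, profiles, size,
                          nReplicates = 30L, seed = NULL, universe = NULL,
                          config = scoringConfig(), orthologs = NULL) {
    if (is.null(universe))
        universe <- unique(unlist(lapply(profiles, profileGenes)))
    sets <- sampleDecoys(universe, diseaseGene, size, nReplicates, seed)
    ranks <- vapply(sets, function(cand) {
        res <- prioritize(cand, profiles, affected, config = config,
                          orthologs = orthologs)
        i <- match(diseaseGene, res$gene_id)
        if (is.na(res$rank[i])) size + 1L else res$rank[i]
    }, integer(1))
    benchmarkRun(diseaseGene, size, ranks, tissues = affected,
                 seed = if (is.null(seed)) NA_integer_ else seed)
}
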