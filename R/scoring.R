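#' Base prioritization score of one gene in one evidence source
#'
#' Sums, over the affected tissues `T`, the gene's per-tissue mean
#' modified z-score modified by the log-ratio against the gene's own
#' cross-tissue baseline:
#' \deqn{S_g = \sum_{t \in T} \bar z_t \cdot (1 + \ln(\bar z_t / \tilde z))}
#' when both \eqn{\bar z_t > 0} and the cross-tissue median \eqn{\tilde z >
#' 0}; otherwise the tissue contributes its plain \eqn{\bar z_t} (the
#' logarithm needs a positive ratio, and a negative \eqn{\bar z_t} must
#' never raise the score). The modifier rewards expression elevated above
#' the gene's baseline even when the absolute level is modest, and
#' penalizes tissues expressed below baseline.
#'
#' Affected tissues in which the gene was never observed contribute 0 and
#' are reported in the `"missingTissues"` attribute of the result.
#'
#' @param profiles a [TissueProfiles-class] for one evidence source.
#' @param geneId gene to score; must be present in the profiles.
#' @param affected character vector of affected tissue labels; must share
#'   at least one label with the source's tissue set.
#'
#' @return The base score, a single numeric (possibly negative), with
#'   attribute `missingTissues`.
#' @export
baseScore <- function(profiles, geneId, affected) {
    stopifnot(is(profiles, "TissueProfiles"))
    .checkAffected(affected, profileTissues(profiles))
    if (!(geneId %in% profileGenes(profiles)))
        stop("gene '", geneId, "' absent from ", evidenceSource(profiles),
             " profiles")
    zbar <- meanZ(profiles)[geneId, ]
    ztilde <- medianZ(profiles)[[geneId]]
    s <- .scoreVector(zbar, ztilde, affected)
    missing <- affected[!(affected %in% names(zbar)) |
                        is.na(zbar[affected])]
    attr(s, "missingTissues") <- unname(missing)
    s
}

.checkAffected <- function(affected, tissues) {
    if (length(affected) == 0L)
        stop("the affected tissue set must be non-empty")
    if (!any(affected %in% tissues))
        stop("none of the affected tissues (",
             paste(affected, collapse = ", "),
             ") are present in the tissue vocabulary of this data")
    invisible(TRUE)
}

# score one gene from its per-tissue means and cross-tissue median
.scoreVector <- function(zbar, ztilde, affected) {
    z <- zbar[affected[affected %in% names(zbar)]]
    z <- z[!is.na(z)]
    if (length(z) == 0L) return(0)
    mod <- z
    useLog <- z > 0 & ztilde > 0
    mod[useLog] <- z[useLog] * (1 + log(z[useLog] / ztilde))
    sum(mod)
}

# vectorized base scores for every gene of one source
.baseScoreAll <- function(profiles, affected) {
    m <- meanZ(profiles)
    med <- medianZ(profiles)
    aff <- intersect(affected, colnames(m))
    if (length(aff) == 0L)
        return(stats::setNames(rep(0, nrow(m)), rownames(m)))
    sub <- m[, aff, drop = FALSE]
    medm <- matrix(med, nrow(sub), ncol(sub))
    useLog <- !is.na(sub) & sub > 0 & medm > 0
    contrib <- sub
    contrib[useLog] <- sub[useLog] * (1 + log(sub[useLog] / medm[useLog]))
    rowSums(contrib, na.rm = TRUE)
}

#' Damp ubiquitously highly expressed (housekeeping-like) genes
#'
#' Genes expressed highly in every tissue match any affected-tissue query
#' and crowd out genuinely tissue-specific candidates. When a gene's
#' minimum per-tissue mean z across all tissues is at least `tau`, its
#' score is multiplied by `sigma / (sigma + c)`, where `sigma` is the
#' standard deviation of its per-tissue means: a perfectly flat
#' high-expression profile (`sigma = 0`) is fully suppressed, and the
#' penalty fades as cross-tissue variance grows. Genes below the gate are
#' returned unchanged.
#'
#' @param score base score to adjust.
#' @param profiles a [TissueProfiles-class].
#' @param geneId the scored gene.
#' @param config a [ScoringConfig-class] supplying `tau` and `c`.
#' @return The adjusted score.
#' @export
varianceAdjust <- function(score, profiles, geneId, config = scoringConfig()) {
    stopifnot(is(profiles, "TissueProfiles"), is(config, "ScoringConfig"))
    zbar <- meanZ(profiles)[geneId, ]
    zbar <- zbar[!is.na(zbar)]
    if (min(zbar) < config@tau) return(score)
    sigma <- if (length(zbar) > 1L) stats::sd(zbar) else 0
    score * sigma / (sigma + config@c)
}

.varianceAdjustAll <- function(scores, profiles, config) {
    m <- meanZ(profiles)
    minz <- apply(m, 1L, min, na.rm = TRUE)
    sigma <- apply(m, 1L, stats::sd, na.rm = TRUE)
    sigma[is.na(sigma)] <- 0
    gate <- minz >= config@tau
    scores[gate] <- scores[gate] * sigma[gate] / (sigma[gate] + config@c)
    scores
}

#' Combine per-source scores into the final ranking score
#'
#' Weighted mean over the evidence sources in which the gene was scored:
#' human sources have weight 1, mouse sources the configurable
#' `mouseWeight`. A gene measured in only some sources is combined over
#' those — incomplete evidence narrows, it does not invalidate.
#'
#' @param perSource named numeric of per-source scores; names from
#'   [evidenceSources()]. `NA` entries are treated as missing sources.
#' @param config a [ScoringConfig-class].
#' @return The combined score, or `NA_real_` when the total weight is zero
#'   (mouse-only evidence with `mouseWeight = 0`), in which case the gene
#'   is unrankable.
#' @examples
#' combineSources(c(human_microarray = 4, mouse_microarray = 2),
#'                scoringConfig(mouseWeight = 0.5))
#' @export
combineSources <- function(perSource, config = scoringConfig()) {
    stopifnot(is(config, "ScoringConfig"))
    if (length(perSource) == 0L) stop("perSource must be non-empty")
    bad <- setdiff(names(perSource), evidenceSources())
    if (length(bad)) stop("unknown evidence source: ", bad[1L])
    keep <- !is.na(perSource)
    perSource <- perSource[keep]
    if (length(perSource) == 0L) return(NA_real_)
    w <- ifelse(sourceSpecies(names(perSource)) == "mouse",
                config@mouseWeight, 1)
    if (sum(w) == 0) return(NA_real_)
    sum(w * perSource) / sum(w)
}

#' Prioritize candidate disease genes by tissue-specific expression
#'
#' The full scoring pipeline: each candidate is scored in every evidence
#' source where it has a profile (mouse sources through its one-to-one
#' ortholog when an ortholog table is supplied), optionally
#' variance-adjusted, and the per-source scores are combined into the
#' final ranking score. Genes are ranked by descending combined score with
#' competition ranking (ties share the smaller rank; display order breaks
#' ties by gene id). Candidates absent from every source are appended
#' after all scored genes, flagged `no_data` and unranked.
#'
#' @param candidateSet a [CandidateSet-class], or a character vector of
#'   canonical gene ids.
#' @param profiles named list of [TissueProfiles-class], one per available
#'   evidence source (names from [evidenceSources()]).
#' @param affected character vector of affected tissue labels.
#' @param config a [ScoringConfig-class].
#' @param orthologs optional one-to-one ortholog data.frame (see
#'   [readOrthologTable()]); used to look candidates up in mouse sources.
#'   Without it, mouse profiles are assumed to be keyed by the same ids as
#'   the candidates.
#' @param model optional [GeneModel-class] used to attach approved
#'   symbols to the result.
#'
#' @return data.frame with one row per candidate: `rank`, `gene_id`,
#'   `approved_symbol`, `combined_score`, one `score_<source>` column per
#'   supplied source, `sources_used`, `no_data`, `provenance`,
#'   `source_detail`.
#' @export
prioritize <- function(candidateSet, profiles, affected,
                       config = scoringConfig(), orthologs = NULL,
                       model = NULL) {
    stopifnot(is(config, "ScoringConfig"))
    if (is.character(candidateSet))
        candidateSet <- CandidateSet(data.frame(
            canonical_id = candidateSet,
            provenance = rep("list_token", length(candidateSet)),
            source_detail = candidateSet, stringsAsFactors = FALSE))
    stopifnot(is(candidateSet, "CandidateSet"))
    genes <- candidateIds(candidateSet)
    if (length(genes) == 0L) stop("no candidates to prioritize")
    if (length(profiles) == 0L || is.null(names(profiles)))
        stop("profiles must be a non-empty named list of TissueProfiles")
    badsrc <- setdiff(names(profiles), evidenceSources())
    if (length(badsrc)) stop("unknown evidence source: ", badsrc[1L])
    allTissues <- unique(unlist(lapply(profiles, profileTissues)))
    .checkAffected(affected, allTissues)

    scoreCols <- matrix(NA_real_, length(genes), length(profiles),
                        dimnames = list(genes, names(profiles)))
    for (src in names(profiles)) {
        prof <- profiles[[src]]
        lookup <- genes
        if (sourceSpecies(src) == "mouse" && !is.null(orthologs))
            lookup <- mapOrtholog(genes, "human_to_mouse", orthologs)
        s <- .baseScoreAll(prof, affected)
        if (config@varianceAdjust)
            s <- .varianceAdjustAll(s, prof, config)
        hit <- !is.na(lookup) & lookup %in% names(s)
        scoreCols[hit, src] <- s[lookup[hit]]
    }
    w <- ifelse(sourceSpecies(colnames(scoreCols)) == "mouse",
                config@mouseWeight, 1)
    wm <- matrix(rep(w, each = nrow(scoreCols)), nrow(scoreCols))
    wm[is.na(scoreCols)] <- 0
    totw <- rowSums(wm)
    combined <- ifelse(totw > 0,
                       rowSums(scoreCols * wm, na.rm = TRUE) / totw,
                       NA_real_)
    sourcesUsed <- apply(!is.na(scoreCols) & wm > 0, 1L, function(u)
        paste(colnames(scoreCols)[u], collapse = ","))
    noData <- is.na(combined)
    if (all(noData))
        stop("no candidate could be scored: check that the expression ",
             "database covers the candidate genes and affected tissues")

    res <- data.frame(gene_id = genes,
                      combined_score = combined,
                      stringsAsFactors = FALSE)
    for (src in colnames(scoreCols))
        res[[paste0("score_", src)]] <- scoreCols[, src]
    res$sources_used <- sourcesUsed
    res$no_data <- noData
    cand <- candidates(candidateSet)
    res$provenance <- cand$provenance[match(genes, cand$canonical_id)]
    res$source_detail <- cand$source_detail[match(genes, cand$canonical_id)]
    res$approved_symbol <- if (!is.null(model))
        geneTable(model)$approved_symbol[match(genes,
                                               geneTable(model)$canonical_id)]
    else NA_character_

    scored <- res[!res$no_data, , drop = FALSE]
    scored$rank <- as.integer(rank(-scored$combined_score,
                                   ties.method = "min"))
    scored <- scored[order(-scored$combined_score, scored$gene_id), ,
                     drop = FALSE]
    nodata <- res[res$no_data, , drop = FALSE]
    if (nrow(nodata)) {
        nodata$rank <- NA_integer_
        nodata <- nodata[order(nodata$gene_id), , drop = FALSE]
    } else nodata$rank <- integer(0)
    out <- rbind(scored, nodata)
    rownames(out) <- NULL
    front <- c("rank", "gene_id", "approved_symbol", "combined_score")
    out[, c(front, setdiff(colnames(out), front))]
}

#' Write prioritization results as TSV
#'
#' @param results data.frame from [prioritize()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
writeScores <- function(results, path) {
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    invisible(path)
}
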