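#' Discard microarray probes that hybridize to more than one gene
#'
#' Probe-to-gene mappings are ambiguous when one probe hybridizes to
#' several distinct genes; such probes carry no gene-level signal and are
#' discarded before the database is built. Input order is preserved.
#'
#' @param mappings named list: probe id -> character vector of gene ids the
#'   probe hybridizes to. Every element must be non-empty.
#'
#' @return The sub-list of mappings with exactly one target gene.
#' @examples
#' filterAmbiguousProbes(list(pA = "G1", pB = c("G1", "G2")))
#' @export
filterAmbiguousProbes <- function(mappings) {
    if (length(mappings) == 0L) return(mappings)
    n <- lengths(mappings)
    if (any(n == 0L))
        stop("probe mappings must have at least one target gene")
    mappings[vapply(mappings, function(g) length(unique(g)) == 1L, logical(1))]
}

#' Modified z-scores of one experiment
#'
#' Robustly standardizes the normalized expression values of one experiment
#' across its genes: `z_e = 0.6745 * (e - center) / MAD`, where `MAD =
#' median(|e - median(E)|)`. With `center = "mean"` (the default) the
#' numerator is centered on the experiment mean; `center = "median"` gives
#' the standard Iglewicz-Hoaglin form centered on the median. The MAD
#' denominator makes the score resistant to the handful of very highly
#' expressed genes typical of expression data.
#'
#' Zero dispersion is handled without division by zero: when the MAD is 0
#' the mean absolute deviation about the median is substituted; if that is
#' also 0 (all values identical) every z is 0.
#'
#' @param dataset an [ExperimentDataset-class].
#' @param center `"mean"` or `"median"`.
#'
#' @return Named numeric vector of modified z-scores, one per gene in the
#'   experiment.
#' @examples
#' d <- ExperimentDataset("e1", "human", "rnaseq", "liver",
#'                        c(g1 = 2, g2 = 4, g3 = 6, g4 = 8, g5 = 10))
#' modifiedZScores(d)
#' @export
modifiedZScores <- function(dataset, center = c("mean", "median")) {
    center <- match.arg(center)
    stopifnot(is(dataset, "ExperimentDataset"))
    validObject(dataset)
    e <- dataset@values
    if (length(e) < 3L)
        stop("degenerate experiment: fewer than 3 genes in '",
             dataset@experimentId, "'")
    med <- stats::median(e)
    ctr <- if (center == "mean") mean(e) else med
    mad0 <- stats::median(abs(e - med))
    if (mad0 == 0) mad0 <- mean(abs(e - med))
    if (mad0 == 0) {
        z <- rep(0, length(e))
        names(z) <- names(e)
        return(z)
    }
    0.6745 * (e - ctr) / mad0
}

#' Build per-gene tissue z-profiles for one evidence source
#'
#' Transforms every experiment of one evidence source (species x platform
#' stratum) to modified z-scores, then averages each gene's z-scores over
#' all experiments of the same tissue. The result is, per gene, the vector
#' of per-tissue mean modified z-scores together with the median of those
#' means across the tissues in which the gene was observed — the gene's
#' cross-tissue baseline used by the prioritization score. Genes absent
#' from an experiment simply do not contribute to it (absence is not
#' treated as zero expression).
#'
#' @param datasets list of [ExperimentDataset-class], all of the requested
#'   source's species and platform.
#' @param source one of [evidenceSources()].
#' @param center centering convention passed to [modifiedZScores()].
#' @param vocabulary optional [TissueVocabulary-class]; when given, every
#'   experiment's tissue label must be in it.
#'
#' @return A [TissueProfiles-class]; an empty one if `datasets` is empty.
#' @export
buildTissueProfiles <- function(datasets, source, center = c("mean", "median"),
                                vocabulary = NULL) {
    center <- match.arg(center)
    if (!(source %in% evidenceSources()))
        stop("unknown evidence source: ", source)
    if (length(datasets) == 0L) {
        m <- matrix(numeric(), 0L, 0L, dimnames = list(character(), character()))
        return(new("TissueProfiles", source = source, meanZ = m,
                   medianZ = stats::setNames(numeric(), character())))
    }
    for (d in datasets) {
        if (d@species != sourceSpecies(source) ||
            d@platform != sourcePlatform(source))
            stop("experiment '", d@experimentId, "' (", d@species, " ",
                 d@platform, ") does not belong to source '", source, "'")
        if (!is.null(vocabulary) && !(d@tissue %in% labels(vocabulary)))
            stop("tissue label not in vocabulary: '", d@tissue, "'")
    }
    genes <- unique(unlist(lapply(datasets, function(d) names(d@values)),
                           use.names = FALSE))
    tissues <- unique(vapply(datasets, tissue, character(1)))
    zsum <- matrix(0, length(genes), length(tissues),
                   dimnames = list(genes, tissues))
    zcnt <- matrix(0L, length(genes), length(tissues),
                   dimnames = list(genes, tissues))
    for (d in datasets) {
        z <- modifiedZScores(d, center = center)
        gi <- names(z)
        zsum[gi, d@tissue] <- zsum[gi, d@tissue] + z
        zcnt[gi, d@tissue] <- zcnt[gi, d@tissue] + 1L
    }
    m <- zsum / zcnt            # 0/0 -> NaN where never observed
    m[zcnt == 0L] <- NA_real_
    med <- apply(m, 1L, stats::median, na.rm = TRUE)
    new("TissueProfiles", source = source, meanZ = m, medianZ = med)
}

.EXPR_COLUMNS <- c("experiment_id", "species", "platform", "tissue",
                   "gene_id", "value")

#' Read a tissue-specific expression database table
#'
#' The database interchange format is a UTF-8 TSV with a header line and
#' columns exactly `experiment_id`, `species` (human|mouse), `platform`
#' (microarray|rnaseq), `tissue`, `gene_id`, `value` — one row per
#' (experiment, gene). Lines starting with `#` are comments. Every
#' experiment's metadata must be consistent across its rows.
#'
#' @param path file to read.
#' @return List of [ExperimentDataset-class], in order of first appearance.
#' @seealso [writeExpressionTable()] for the inverse; the pair round-trips
#'   values exactly (full-precision decimal text).
#' @export
readExpressionTable <- function(path) {
    raw <- readLines(path, encoding = "UTF-8")
    keep <- !startsWith(raw, "#")
    lineno <- seq_along(raw)[keep]
    raw <- raw[keep]
    if (length(raw) == 0L) stop("empty expression table: ", path)
    header <- strsplit(raw[1L], "\t", fixed = TRUE)[[1L]]
    if (!identical(header, .EXPR_COLUMNS))
        stop("bad expression table header; expected columns: ",
             paste(.EXPR_COLUMNS, collapse = ", "))
    body <- raw[-1L]
    lineno <- lineno[-1L]
    if (length(body) == 0L) stop("expression table has no data rows: ", path)
    fields <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != length(.EXPR_COLUMNS))
    if (length(bad))
        stop("malformed row at line ", lineno[bad[1L]], ": expected ",
             length(.EXPR_COLUMNS), " tab-separated fields")
    tab <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
    colnames(tab) <- .EXPR_COLUMNS
    badsp <- which(!(tab$species %in% .SPECIES))
    if (length(badsp))
        stop("unknown species token '", tab$species[badsp[1L]],
             "' at line ", lineno[badsp[1L]])
    badpl <- which(!(tab$platform %in% .PLATFORMS))
    if (length(badpl))
        stop("unknown platform token '", tab$platform[badpl[1L]],
             "' at line ", lineno[badpl[1L]])
    val <- suppressWarnings(as.numeric(tab$value))
    badv <- which(!is.finite(val))
    if (length(badv))
        stop("non-numeric or non-finite expression value at line ",
             lineno[badv[1L]])
    badneg <- which(val < 0)
    if (length(badneg))
        stop("negative expression value at line ", lineno[badneg[1L]])
    dupkey <- paste(tab$experiment_id, tab$gene_id, sep = "\r")
    dup <- which(duplicated(dupkey))
    if (length(dup))
        stop("duplicate (experiment, gene) row at line ", lineno[dup[1L]],
             ": ", tab$experiment_id[dup[1L]], " / ", tab$gene_id[dup[1L]])
    ids <- unique(tab$experiment_id)
    lapply(ids, function(id) {
        rows <- tab[tab$experiment_id == id, , drop = FALSE]
        meta <- unique(rows[, c("species", "platform", "tissue")])
        if (nrow(meta) != 1L)
            stop("inconsistent species/platform/tissue for experiment '",
                 id, "'")
        ExperimentDataset(id, meta$species, meta$platform, meta$tissue,
                          stats::setNames(as.numeric(rows$value), rows$gene_id))
    })
}

#' Write a tissue-specific expression database table
#'
#' @param datasets list of [ExperimentDataset-class].
#' @param path file to write.
#' @return `path`, invisibly.
#' @seealso [readExpressionTable()] for the format.
#' @export
writeExpressionTable <- function(datasets, path) {
    rows <- unlist(lapply(datasets, function(d) {
        validObject(d)
        sprintf("%s\t%s\t%s\t%s\t%s\t%s", d@experimentId, d@species,
                d@platform, d@tissue, names(d@values),
                formatC(d@values, format = "g", digits = 17))
    }), use.names = FALSE)
    writeLines(c(paste(.EXPR_COLUMNS, collapse = "\t"), rows), path,
               useBytes = TRUE)
    invisible(path)
}
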