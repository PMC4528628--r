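#' SyntheticSpec: parameters of the synthetic database generator
#'
#' Describes a synthetic tissue-specific expression database with planted
#' signal: background values are drawn i.i.d. log-normal per (gene,
#' experiment), and each planted (gene, tissue) pair has its effect added
#' on the log scale in every experiment of that tissue, i.e. the signal is
#' multiplicative on the raw expression scale and passes through the full
#' standardization pipeline.
#'
#' @slot nGenes number of genes.
#' @slot tissues tissue labels.
#' @slot experimentsPerTissue named integer: experiments per tissue for
#'   each evidence source to simulate.
#' @slot planted data.frame with columns `gene`, `tissues`
#'   (`';'`-separated) and `effect` (additive shift in log-expression
#'   units, >= 0).
#' @slot meanlog,sdlog location and scale of the log-normal background.
#' @slot noiseSd extra per-value log-scale noise (default 0; the
#'   background scale already carries the measurement noise).
#' @slot orthologFraction fraction of genes given a one-to-one mouse
#'   ortholog in the generated identifier tables.
#' @slot ambiguousAliasCount number of deliberately ambiguous aliases
#'   (each shared by two genes) in the generated gene model.
#' @slot seed RNG seed; everything the generator emits is a pure function
#'   of the spec including this seed.
#'
#' @aliases SyntheticSpec-class
#' @export
setClass("SyntheticSpec", slots = c(
    nGenes = "integer",
    tissues = "character",
    experimentsPerTissue = "integer",
    planted = "data.frame",
    meanlog = "numeric",
    sdlog = "numeric",
    noiseSd = "numeric",
    orthologFraction = "numeric",
    ambiguousAliasCount = "integer",
    seed = "integer"
))

setValidity("SyntheticSpec", function(object) {
    msg <- character()
    if (object@nGenes < 3L)
        msg <- c(msg, "need at least 3 genes")
    if (length(object@tissues) < 1L || anyDuplicated(object@tissues))
        msg <- c(msg, "tissues must be unique and non-empty")
    if (is.null(names(object@experimentsPerTissue)) ||
        !all(names(object@experimentsPerTissue) %in% evidenceSources()))
        msg <- c(msg, "experimentsPerTissue must be named by evidence source")
    p <- object@planted
    if (nrow(p)) {
        if (!all(c("gene", "tissues", "effect") %in% colnames(p)))
            msg <- c(msg, "planted needs columns gene, tissues, effect")
        else {
            if (any(p$effect < 0))
                msg <- c(msg, "planted effects must be >= 0")
            if (!all(p$gene %in% .syntheticGeneIds(object@nGenes)))
                msg <- c(msg, "planted genes must exist in the spec")
            pt <- unlist(strsplit(p$tissues, ";", fixed = TRUE))
            if (!all(trimws(pt) %in% object@tissues))
                msg <- c(msg, "planted tissues must exist in the spec")
        }
    }
    if (object@sdlog <= 0) msg <- c(msg, "sdlog must be positive")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@orthologFraction < 0 || object@orthologFraction > 1)
        msg <- c(msg, "orthologFraction must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

.syntheticGeneIds <- function(n) sprintf("G%04d", seq_len(n))

.DEFAULT_TISSUES <- c("brain", "liver", "kidney", "heart", "lung",
                      "muscle", "skin", "spleen", "testis", "retina")

#' Construct a SyntheticSpec
#'
#' The defaults describe the standard validation condition: 500 genes, 10
#' tissues, two human evidence sources with 3 experiments per tissue each,
#' log-normal background (meanlog 2, sdlog 1), and one gene planted with a
#' 3 log-unit elevation in one tissue.
#'
#' @param nGenes number of genes (default 500).
#' @param tissues tissue labels (default 10 named tissues).
#' @param experimentsPerTissue named integer per source (default 3 for
#'   each of `human_microarray` and `human_rnaseq`).
#' @param planted data.frame (`gene`, `tissues`, `effect`); default plants
#'   gene `G0001` in the first tissue at effect 3. Pass a zero-row frame
#'   for a pure-null database.
#' @param effect convenience override of the default planted effect.
#' @param meanlog,sdlog,noiseSd background distribution parameters.
#' @param orthologFraction,ambiguousAliasCount identifier-table knobs.
#' @param seed RNG seed (default 1).
#' @return A [SyntheticSpec-class].
#' @examples
#' syntheticSpec(nGenes = 50, effect = 3, seed = 7)
#' @export
syntheticSpec <- function(nGenes = 500L,
                          tissues = .DEFAULT_TISSUES,
                          experimentsPerTissue = c(human_microarray = 3L,
                                                   human_rnaseq = 3L),
                          planted = NULL,
                          effect = 3,
                          meanlog = 2,
                          sdlog = 1,
                          noiseSd = 0,
                          orthologFraction = 0.5,
                          ambiguousAliasCount = 2L,
                          seed = 1L) {
    if (is.null(planted))
        planted <- data.frame(gene = .syntheticGeneIds(nGenes)[1L],
                              tissues = tissues[1L], effect = effect,
                              stringsAsFactors = FALSE)
    epr <- as.integer(experimentsPerTissue)
    names(epr) <- names(experimentsPerTissue)
    new("SyntheticSpec", nGenes = as.integer(nGenes), tissues = tissues,
        experimentsPerTissue = epr, planted = planted,
        meanlog = meanlog, sdlog = sdlog, noiseSd = noiseSd,
        orthologFraction = orthologFraction,
        ambiguousAliasCount = as.integer(ambiguousAliasCount),
        seed = as.integer(seed))
}

setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf(paste0("SyntheticSpec: %d genes x %d tissues, sources: %s;",
                       " %d planted signal(s); seed %d\n"),
                object@nGenes, length(object@tissues),
                paste(names(object@experimentsPerTissue), collapse = ", "),
                nrow(object@planted), object@seed))
})

.mouseId <- function(g) paste0("m", g)

#' Generate a synthetic expression database with planted signal
#'
#' Draws one log-normal value per (gene, experiment) and multiplies
#' planted (gene, tissue) pairs by `exp(effect)` in every experiment of
#' that tissue (for mouse sources, under the gene's synthetic ortholog
#' id). Identical specs — including the seed — give identical databases.
#'
#' @param spec a [SyntheticSpec-class].
#' @return List with `datasets` (list of [ExperimentDataset-class]) and
#'   `truth` (data.frame `gene`, `tissue`, `effect` of every planted
#'   pair).
#' @export
generateDatabase <- function(spec) {
    stopifnot(is(spec, "SyntheticSpec"))
    validObject(spec)
    genes <- .syntheticGeneIds(spec@nGenes)
    truth <- if (nrow(spec@planted)) do.call(rbind, lapply(
        seq_len(nrow(spec@planted)), function(i) {
            ts <- trimws(strsplit(spec@planted$tissues[i], ";",
                                  fixed = TRUE)[[1L]])
            data.frame(gene = spec@planted$gene[i], tissue = ts,
                       effect = spec@planted$effect[i],
                       stringsAsFactors = FALSE)
        }))
    else data.frame(gene = character(), tissue = character(),
                    effect = numeric(), stringsAsFactors = FALSE)
    datasets <- .withSeed(spec@seed, {
        out <- list()
        for (src in names(spec@experimentsPerTissue)) {
            sp <- sourceSpecies(src)
            ids <- if (sp == "mouse") .mouseId(genes) else genes
            for (t in spec@tissues) {
                shift <- rep(0, spec@nGenes)
                hit <- truth[truth$tissue == t, , drop = FALSE]
                if (nrow(hit))
                    shift[match(hit$gene, genes)] <- hit$effect
                for (r in seq_len(spec@experimentsPerTissue[[src]])) {
                    lg <- stats::rnorm(spec@nGenes, spec@meanlog, spec@sdlog)
                    if (spec@noiseSd > 0)
                        lg <- lg + stats::rnorm(spec@nGenes, 0, spec@noiseSd)
                    v <- exp(lg + shift)
                    names(v) <- ids
                    out[[length(out) + 1L]] <- ExperimentDataset(
                        sprintf("%s_%s_%02d", src, t, r),
                        sp, sourcePlatform(src), t, v)
                }
            }
        }
        out
    })
    list(datasets = datasets, truth = truth)
}

#' Generate a synthetic gene model
#'
#' Places the spec's genes on synthetic chromosomes (50 genes per
#' chromosome) with sorted, non-overlapping spans, 2-5 exons inside each
#' span, an approved symbol, one private alias and synthetic
#' Ensembl/Entrez/RefSeq accessions per gene, plus
#' `ambiguousAliasCount` aliases each deliberately shared by two genes to
#' exercise the resolver.
#'
#' @param spec a [SyntheticSpec-class].
#' @return A [GeneModel-class] of human records.
#' @export
generateGeneModel <- function(spec) {
    stopifnot(is(spec, "SyntheticSpec"))
    n <- spec@nGenes
    ids <- .syntheticGeneIds(n)
    perChrom <- 50L
    chrom <- sprintf("chr%d", (seq_len(n) - 1L) %/% perChrom + 1L)
    .withSeed(spec@seed + 1L, {
        widths <- round(stats::runif(n, 5e3, 2e4))
        gaps <- round(stats::runif(n, 1e3, 1e4))
        start <- numeric(n)
        end <- numeric(n)
        pos <- 1
        for (i in seq_len(n)) {
            if (i > 1L && chrom[i] != chrom[i - 1L]) pos <- 1
            start[i] <- pos + gaps[i]
            end[i] <- start[i] + widths[i] - 1
            pos <- end[i]
        }
        exons <- vapply(seq_len(n), function(i) {
            k <- sample(2:5, 1L)
            cuts <- sort(sample(seq(start[i], end[i]), 2L * k))
            paste(sprintf("%d-%d", cuts[seq(1L, 2L * k, 2L)],
                          cuts[seq(2L, 2L * k, 2L)]), collapse = ",")
        }, character(1))
        sym <- sprintf("GENE%d", seq_len(n))
        aliases <- sprintf("AL%d", seq_len(n))
        k <- spec@ambiguousAliasCount
        if (k > 0L) {
            if (2L * k > n) stop("too many ambiguous aliases for nGenes")
            amb <- sprintf("AMB%d", seq_len(k))
            for (j in seq_len(k)) {
                i1 <- 2L * j - 1L
                i2 <- 2L * j
                aliases[i1] <- paste(aliases[i1], amb[j], sep = "|")
                aliases[i2] <- paste(aliases[i2], amb[j], sep = "|")
            }
        }
        GeneModel(data.frame(
            canonical_id = ids,
            species = "human",
            approved_symbol = sym,
            aliases = aliases,
            ensembl_id = sprintf("ENSG%011d", seq_len(n)),
            entrez_id = as.character(seq_len(n) + 1000L),
            refseq_id = sprintf("NM_%06d", seq_len(n)),
            chromosome = chrom,
            span_start = start,
            span_end = end,
            exons = exons,
            stringsAsFactors = FALSE))
    })
}

#' Generate synthetic identifier and ortholog tables on disk
#'
#' Writes the gene model of [generateGeneModel()] and a one-to-one
#' human-mouse ortholog table covering `orthologFraction` of the genes
#' (mouse ids are the human ids prefixed with `m`, matching the ids used
#' by mouse sources of [generateDatabase()]).
#'
#' @param spec a [SyntheticSpec-class].
#' @param dir output directory (created if needed).
#' @return List with paths `geneModel` and `orthologs`.
#' @export
generateIdentifierTables <- function(spec, dir) {
    stopifnot(is(spec, "SyntheticSpec"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    model <- generateGeneModel(spec)
    gmPath <- file.path(dir, "gene_model.tsv")
    writeGeneModel(model, gmPath)
    ids <- .syntheticGeneIds(spec@nGenes)
    nOrth <- round(spec@orthologFraction * spec@nGenes)
    orth <- .withSeed(spec@seed + 2L, {
        chosen <- sort(sample(ids, nOrth))
        data.frame(human_canonical_id = chosen,
                   mouse_canonical_id = .mouseId(chosen),
                   stringsAsFactors = FALSE)
    })
    orthPath <- file.path(dir, "orthologs.tsv")
    writeLines(c("human_canonical_id\tmouse_canonical_id",
                 sprintf("%s\t%s", orth$human_canonical_id,
                         orth$mouse_canonical_id)), orthPath)
    list(geneModel = gmPath, orthologs = orthPath)
}
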