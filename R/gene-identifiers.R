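#' GeneModel: gene records, identifiers and coordinates
#'
#' The reference table behind identifier resolution and coordinate-based
#' candidate extraction: one record per gene with its approved symbol,
#' aliases, Ensembl/Entrez/RefSeq accessions, species, and 1-based
#' inclusive genomic span and exon coordinates.
#'
#' @slot table data.frame with columns `canonical_id`, `species`,
#'   `approved_symbol`, `aliases` (`'|'`-separated, possibly empty),
#'   `ensembl_id`, `entrez_id`, `refseq_id`, `chromosome`, `span_start`,
#'   `span_end`, `exons` (comma-separated `"start-end"` pairs).
#'
#' @aliases GeneModel-class
#' @export
setClass("GeneModel", slots = c(table = "data.frame"))

.GENEMODEL_COLUMNS <- c("canonical_id", "species", "approved_symbol",
                        "aliases", "ensembl_id", "entrez_id", "refseq_id",
                        "chromosome", "span_start", "span_end", "exons")

.parseExons <- function(s) {
    if (!nzchar(s)) return(matrix(numeric(), 0L, 2L))
    parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1L]], "-", fixed = TRUE)
    if (any(lengths(parts) != 2L)) stop("malformed exon field: '", s, "'")
    m <- matrix(as.numeric(unlist(parts)), ncol = 2L, byrow = TRUE)
    if (any(!is.finite(m))) stop("malformed exon field: '", s, "'")
    m
}

setValidity("GeneModel", function(object) {
    t <- object@table
    msg <- character()
    if (!all(.GENEMODEL_COLUMNS %in% colnames(t)))
        return(sprintf("gene model table needs columns: %s",
                       paste(.GENEMODEL_COLUMNS, collapse = ", ")))
    if (nrow(t) == 0L) return(TRUE)
    if (!all(t$species %in% .SPECIES))
        msg <- c(msg, "species must be human or mouse")
    if (any(t$span_start > t$span_end))
        msg <- c(msg, "span_start must be <= span_end")
    for (sp in unique(t$species)) {
        sub <- t[t$species == sp, ]
        if (anyDuplicated(sub$canonical_id))
            msg <- c(msg, sprintf("duplicate canonical_id within species %s", sp))
        if (anyDuplicated(sub$approved_symbol))
            msg <- c(msg, sprintf("duplicate approved_symbol within species %s", sp))
    }
    for (i in seq_len(nrow(t))) {
        ex <- .parseExons(t$exons[i])
        if (nrow(ex) && (any(ex[, 1L] > ex[, 2L]) ||
                         any(ex[, 1L] < t$span_start[i]) ||
                         any(ex[, 2L] > t$span_end[i]))) {
            msg <- c(msg, sprintf("exon outside gene span for %s",
                                  t$canonical_id[i]))
            break
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GeneModel from a record table
#'
#' @param table data.frame with the columns listed under
#'   [GeneModel-class].
#' @return A [GeneModel-class].
#' @export
GeneModel <- function(table) {
    table$span_start <- as.numeric(table$span_start)
    table$span_end <- as.numeric(table$span_end)
    rownames(table) <- NULL
    new("GeneModel", table = table)
}

#' @describeIn GeneModel-class number of gene records.
#' @param x,object a `GeneModel`.
#' @export
setMethod("length", "GeneModel", function(x) nrow(x@table))

setMethod("show", "GeneModel", function(object) {
    cat(sprintf("GeneModel: %d genes (%s)\n", nrow(object@table),
                paste(unique(object@table$species), collapse = ", ")))
})

#' @rdname geneModelAccessors
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))
#' @rdname geneModelAccessors
#' @export
setGeneric("geneRanges", function(x, ...) standardGeneric("geneRanges"))

#' Accessors for GeneModel
#'
#' @param x a [GeneModel-class].
#' @param ... for `geneRanges`: `exons = TRUE` returns exon-level ranges
#'   instead of full gene spans.
#' @return `geneTable`: the record data.frame; `geneRanges`: a
#'   [GenomicRanges::GRanges] of the gene spans (or exons), 1-based
#'   inclusive, with a `canonical_id` metadata column.
#' @name geneModelAccessors
NULL

#' @rdname geneModelAccessors
#' @export
setMethod("geneTable", "GeneModel", function(x) x@table)

#' @rdname geneModelAccessors
#' @export
setMethod("geneRanges", "GeneModel", function(x, exons = FALSE) {
    t <- x@table
    if (!exons) {
        gr <- GenomicRanges::GRanges(
            seqnames = t$chromosome,
            ranges = IRanges::IRanges(start = t$span_start, end = t$span_end))
        S4Vectors::mcols(gr)$canonical_id <- t$canonical_id
        return(gr)
    }
    exs <- lapply(seq_len(nrow(t)), function(i) .parseExons(t$exons[i]))
    n <- vapply(exs, nrow, integer(1))
    ex <- do.call(rbind, exs)
    gr <- GenomicRanges::GRanges(
        seqnames = rep(t$chromosome, n),
        ranges = IRanges::IRanges(start = ex[, 1L], end = ex[, 2L]))
    S4Vectors::mcols(gr)$canonical_id <- rep(t$canonical_id, n)
    gr
})

.stripVersion <- function(x) sub("\\.[0-9]+$", "", x)

#' Resolve one gene identifier token to a canonical gene record
#'
#' Matching follows a fixed precedence ladder: exact approved symbol,
#' then Ensembl, Entrez and RefSeq accessions, then aliases. Symbol and
#' alias matching is case-insensitive; accession matching is
#' case-sensitive after stripping a trailing `.N` version suffix. When a
#' token still matches several genes and `resolveAmbiguous` is set, the
#' unique match with expression data (membership in `expressionGeneIds`)
#' is chosen; with several equally supported matches the token stays
#' ambiguous — the resolver never guesses.
#'
#' @param token the input identifier (symbol, alias or accession).
#' @param model a [GeneModel-class]; must be non-empty.
#' @param resolveAmbiguous attempt the expression-presence tie-break.
#' @param expressionGeneIds canonical ids with expression data, used only
#'   by the tie-break.
#'
#' @return A [Resolution-class]; failures are encoded in its status, never
#'   as errors.
#' @export
resolveIdentifier <- function(token, model, resolveAmbiguous = FALSE,
                              expressionGeneIds = character()) {
    stopifnot(is(model, "GeneModel"))
    t <- geneTable(model)
    if (nrow(t) == 0L) stop("empty gene registry")
    tok <- trimws(token)
    ladder <- list(
        approved_symbol = which(tolower(t$approved_symbol) == tolower(tok)),
        ensembl = which(nzchar(t$ensembl_id) &
                        .stripVersion(t$ensembl_id) == .stripVersion(tok)),
        entrez = which(nzchar(t$entrez_id) & t$entrez_id == tok),
        refseq = which(nzchar(t$refseq_id) &
                       .stripVersion(t$refseq_id) == .stripVersion(tok)),
        alias = which(vapply(strsplit(t$aliases, "|", fixed = TRUE),
                             function(a) any(tolower(a) == tolower(tok)),
                             logical(1)))
    )
    for (rule in names(ladder)) {
        hit <- ladder[[rule]]
        if (length(hit) == 0L) next
        ids <- t$canonical_id[hit]
        if (length(ids) == 1L)
            return(new("Resolution", inputToken = token, status = "resolved",
                       matches = ids, chosen = ids, ruleApplied = rule))
        if (resolveAmbiguous) {
            withExpr <- ids[ids %in% expressionGeneIds]
            if (length(withExpr) == 1L)
                return(new("Resolution", inputToken = token,
                           status = "resolved", matches = ids,
                           chosen = withExpr,
                           ruleApplied = paste0(rule, "+expression_presence")))
        }
        return(new("Resolution", inputToken = token, status = "ambiguous",
                   matches = ids, chosen = character(), ruleApplied = rule))
    }
    new("Resolution", inputToken = token, status = "unresolved",
        matches = character(), chosen = character(), ruleApplied = "none")
}

#' Map a gene to its one-to-one ortholog in the other species
#'
#' @param canonicalId gene to map.
#' @param direction `"human_to_mouse"` or `"mouse_to_human"`.
#' @param pairs data.frame with columns `human_canonical_id`,
#'   `mouse_canonical_id`, already reduced to one-to-one pairs (see
#'   [readOrthologTable()]).
#'
#' @return The partner canonical id, or `NA_character_` when the gene has
#'   no stored ortholog. Round-trip mapping returns the original id
#'   whenever both calls succeed.
#' @export
mapOrtholog <- function(canonicalId,
                        direction = c("human_to_mouse", "mouse_to_human"),
                        pairs) {
    direction <- match.arg(direction)
    from <- if (direction == "human_to_mouse") "human_canonical_id" else "mouse_canonical_id"
    to <- if (direction == "human_to_mouse") "mouse_canonical_id" else "human_canonical_id"
    hit <- match(canonicalId, pairs[[from]])
    ifelse(is.na(hit), NA_character_, pairs[[to]][hit])
}

#' Read a gene model table
#'
#' TSV with header and the columns listed under [GeneModel-class];
#' coordinates 1-based inclusive; `#` lines are comments. Malformed
#' coordinates (start > end) and exons outside the gene span are rejected
#' with the offending line number; duplicate approved symbols within a
#' species are an error.
#'
#' @param path file to read.
#' @return A [GeneModel-class].
#' @export
readGeneModel <- function(path) {
    raw <- readLines(path, encoding = "UTF-8")
    keep <- !startsWith(raw, "#")
    lineno <- seq_along(raw)[keep]
    raw <- raw[keep]
    if (length(raw) == 0L) stop("empty gene model table: ", path)
    header <- strsplit(raw[1L], "\t", fixed = TRUE)[[1L]]
    if (!identical(header, .GENEMODEL_COLUMNS))
        stop("bad gene model header; expected columns: ",
             paste(.GENEMODEL_COLUMNS, collapse = ", "))
    body <- raw[-1L]
    lineno <- lineno[-1L]
    fields <- strsplit(body, "\t", fixed = TRUE)
    # a trailing empty exons field drops the last element of strsplit
    fields <- lapply(fields, function(f)
        if (length(f) == length(.GENEMODEL_COLUMNS) - 1L) c(f, "") else f)
    bad <- which(lengths(fields) != length(.GENEMODEL_COLUMNS))
    if (length(bad))
        stop("malformed row at line ", lineno[bad[1L]])
    t <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
    colnames(t) <- .GENEMODEL_COLUMNS
    start <- suppressWarnings(as.numeric(t$span_start))
    end <- suppressWarnings(as.numeric(t$span_end))
    badc <- which(!is.finite(start) | !is.finite(end) | start > end)
    if (length(badc))
        stop("malformed coordinates at line ", lineno[badc[1L]],
             " (start > end or non-numeric)")
    t$span_start <- start
    t$span_end <- end
    for (i in seq_len(nrow(t))) {
        ex <- tryCatch(.parseExons(t$exons[i]),
                       error = function(e) stop("malformed exons at line ",
                                                lineno[i]))
        if (nrow(ex) && (any(ex[, 1L] > ex[, 2L]) ||
                         any(ex[, 1L] < t$span_start[i]) ||
                         any(ex[, 2L] > t$span_end[i])))
            stop("exon outside gene span at line ", lineno[i])
    }
    GeneModel(t)
}

#' Write a gene model table
#'
#' @param model a [GeneModel-class].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
writeGeneModel <- function(model, path) {
    t <- geneTable(model)
    rows <- sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
                    t$canonical_id, t$species, t$approved_symbol, t$aliases,
                    t$ensembl_id, t$entrez_id, t$refseq_id, t$chromosome,
                    format(t$span_start, scientific = FALSE, trim = TRUE),
                    format(t$span_end, scientific = FALSE, trim = TRUE),
                    t$exons)
    writeLines(c(paste(.GENEMODEL_COLUMNS, collapse = "\t"), rows), path,
               useBytes = TRUE)
    invisible(path)
}

#' Read a human-mouse ortholog table
#'
#' TSV with header columns `human_canonical_id`, `mouse_canonical_id`.
#' Only one-to-one pairs are kept: every pair whose human or mouse gene
#' appears in more than one row is dropped, with a warning naming how many
#' rows were removed — the scorer needs an unambiguous expression profile
#' per candidate.
#'
#' @param path file to read.
#' @return data.frame with columns `human_canonical_id`,
#'   `mouse_canonical_id`, one-to-one.
#' @export
readOrthologTable <- function(path) {
    raw <- readLines(path, encoding = "UTF-8")
    raw <- raw[!startsWith(raw, "#")]
    if (length(raw) == 0L) stop("empty ortholog table: ", path)
    header <- strsplit(raw[1L], "\t", fixed = TRUE)[[1L]]
    if (!identical(header, c("human_canonical_id", "mouse_canonical_id")))
        stop("bad ortholog table header")
    if (length(raw) == 1L)
        return(data.frame(human_canonical_id = character(),
                          mouse_canonical_id = character(),
                          stringsAsFactors = FALSE))
    fields <- strsplit(raw[-1L], "\t", fixed = TRUE)
    if (any(lengths(fields) != 2L)) stop("malformed ortholog row")
    p <- data.frame(human_canonical_id = vapply(fields, `[`, character(1), 1L),
                    mouse_canonical_id = vapply(fields, `[`, character(1), 2L),
                    stringsAsFactors = FALSE)
    p <- unique(p)
    multi <- p$human_canonical_id %in%
        p$human_canonical_id[duplicated(p$human_canonical_id)] |
        p$mouse_canonical_id %in%
        p$mouse_canonical_id[duplicated(p$mouse_canonical_id)]
    if (any(multi)) {
        warning(sum(multi), " ortholog rows dropped (not one-to-one)")
        p <- p[!multi, , drop = FALSE]
    }
    rownames(p) <- NULL
    p
}
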