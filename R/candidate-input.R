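#' Tokenize a delimited candidate gene list
#'
#' Accepts the delimiter styles gene lists are commonly pasted in: commas,
#' semicolons, tabs, spaces and newlines, in any mixture. Tokens are
#' trimmed, empties dropped, first-seen order preserved, and duplicates
#' removed case-insensitively (the first spelling is kept).
#'
#' @param text the raw list, a single string (possibly multi-line) or a
#'   character vector of lines.
#' @return Character vector of tokens.
#' @examples
#' parseGeneList("BRCA1, TP53;EGFR\nMYC")
#' @export
parseGeneList <- function(text) {
    tokens <- unlist(strsplit(paste(text, collapse = "\n"), "[,;\t[:space:]\n]+"),
                     use.names = FALSE)
    tokens <- trimws(tokens)
    tokens <- tokens[nzchar(tokens)]
    tokens[!duplicated(tolower(tokens))]
}

#' Parse "chr:start-end" region strings
#'
#' @param x character vector of `"chr:start-end"` strings (1-based
#'   inclusive, the genome-browser convention). Commas in numbers are
#'   tolerated.
#' @return A [GenomicRanges::GRanges].
#' @export
parseRegions <- function(x) {
    x <- gsub(",", "", trimws(x))
    m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))
    bad <- which(lengths(m) != 4L)
    if (length(bad))
        stop("malformed region string: '", x[bad[1L]],
             "' (expected chr:start-end)")
    chr <- vapply(m, `[`, character(1), 2L)
    start <- as.numeric(vapply(m, `[`, character(1), 3L))
    end <- as.numeric(vapply(m, `[`, character(1), 4L))
    if (any(start > end))
        stop("region start exceeds end: '", x[which(start > end)[1L]], "'")
    GenomicRanges::GRanges(chr, IRanges::IRanges(start = start, end = end))
}

.sortCandidates <- function(cs, model) {
    t <- geneTable(model)
    idx <- match(cs@candidates$canonical_id, t$canonical_id)
    ord <- order(t$chromosome[idx], t$span_start[idx],
                 cs@candidates$canonical_id)
    cs@candidates <- cs@candidates[ord, , drop = FALSE]
    rownames(cs@candidates) <- NULL
    cs
}

#' Extract candidate genes overlapping genomic regions
#'
#' A gene is a candidate iff its full span overlaps any query region by at
#' least one base (closed-interval overlap, 1-based inclusive). Output
#' order is deterministic: chromosome, span start, canonical id.
#'
#' @param regions a [GenomicRanges::GRanges] or character vector of
#'   `"chr:start-end"` strings.
#' @param model a [GeneModel-class].
#' @return A [CandidateSet-class] with provenance `"region"`. Regions on
#'   chromosomes absent from the gene model are skipped with a warning.
#' @export
genesFromRegions <- function(regions, model) {
    if (is.character(regions)) regions <- parseRegions(regions)
    stopifnot(is(regions, "GRanges"), is(model, "GeneModel"))
    gr <- geneRanges(model)
    known <- as.character(GenomicRanges::seqnames(regions)) %in%
        unique(geneTable(model)$chromosome)
    if (any(!known)) {
        warning("skipping region(s) on chromosome(s) absent from gene model: ",
                paste(unique(as.character(
                    GenomicRanges::seqnames(regions))[!known]), collapse = ", "))
        regions <- regions[known]
    }
    if (length(regions) == 0L) return(CandidateSet())
    hits <- GenomicRanges::findOverlaps(regions, gr, minoverlap = 1L)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    detail <- sprintf("%s:%d-%d",
                      as.character(GenomicRanges::seqnames(regions))[qi],
                      GenomicRanges::start(regions)[qi],
                      GenomicRanges::end(regions)[qi])
    cs <- CandidateSet(data.frame(
        canonical_id = S4Vectors::mcols(gr)$canonical_id[si],
        provenance = rep("region", length(si)),
        source_detail = detail,
        stringsAsFactors = FALSE))
    .sortCandidates(cs, model)
}

#' Extract candidate genes from a pre-filtered VCF
#'
#' Maps each variant's footprint (`POS` through `POS + nchar(REF) - 1`, so
#' deletions cover their deleted bases) onto gene coordinates and returns
#' the union of hit genes. Variants are expected to be pre-filtered for
#' potential deleteriousness upstream; no consequence filtering happens
#' here. By default the full gene span is used (introns included);
#' `exonsOnly = TRUE` restricts to exon overlap.
#'
#' @param path an uncompressed or bgzipped VCF v4.x file; only CHROM, POS
#'   and REF are used.
#' @param model a [GeneModel-class].
#' @param maxRecords refuse files with more records than this (default
#'   10000), the batch-size guard for interactive use.
#' @param exonsOnly restrict overlap to exons.
#' @return A [CandidateSet-class] with provenance `"variant"` and
#'   `"chrom:pos"` source details; genes hit by several variants appear
#'   once with concatenated details.
#' @export
genesFromVcf <- function(path, model, maxRecords = 10000L, exonsOnly = FALSE) {
    stopifnot(is(model, "GeneModel"))
    vcf <- tryCatch(
        suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE)),
        error = function(e) stop("failed to parse VCF '", path, "': ",
                                 conditionMessage(e)))
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix)))   # single record collapses to a named vector
        fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
    if (is.null(fix) || nrow(fix) == 0L)
        return(CandidateSet())
    if (nrow(fix) > maxRecords)
        stop("VCF has ", nrow(fix), " records, more than the cap of ",
             maxRecords)
    pos <- as.numeric(fix[, "POS"])
    ref <- fix[, "REF"]
    ref[is.na(ref)] <- "N"
    vr <- GenomicRanges::GRanges(
        fix[, "CHROM"],
        IRanges::IRanges(start = pos, end = pos + nchar(ref) - 1L))
    gr <- geneRanges(model, exons = exonsOnly)
    hits <- GenomicRanges::findOverlaps(vr, gr, minoverlap = 1L)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    df <- unique(data.frame(
        canonical_id = S4Vectors::mcols(gr)$canonical_id[si],
        provenance = rep("variant", length(si)),
        source_detail = sprintf("%s:%d", fix[qi, "CHROM"], as.integer(pos[qi])),
        stringsAsFactors = FALSE))
    .sortCandidates(CandidateSet(df), model)
}

#' Resolve a delimited gene list into a CandidateSet
#'
#' Tokenizes the list with [parseGeneList()] and resolves every token with
#' [resolveIdentifier()]. Resolved tokens become candidates with
#' provenance `"list_token"`; ambiguous and unresolved tokens are kept in
#' the candidate set's `ambiguities` for reporting.
#'
#' @param text raw gene list text (or a pre-tokenized character vector of
#'   length > 1 is also accepted).
#' @param model a [GeneModel-class].
#' @param resolveAmbiguous,expressionGeneIds passed to
#'   [resolveIdentifier()].
#' @return A [CandidateSet-class].
#' @export
genesFromList <- function(text, model, resolveAmbiguous = FALSE,
                          expressionGeneIds = character()) {
    tokens <- parseGeneList(text)
    res <- lapply(tokens, resolveIdentifier, model = model,
                  resolveAmbiguous = resolveAmbiguous,
                  expressionGeneIds = expressionGeneIds)
    ok <- vapply(res, function(r) r@status == "resolved", logical(1))
    df <- data.frame(
        canonical_id = vapply(res[ok], function(r) r@chosen, character(1)),
        provenance = rep("list_token", sum(ok)),
        source_detail = vapply(res[ok], function(r) r@inputToken, character(1)),
        stringsAsFactors = FALSE)
    CandidateSet(df, ambiguities = res[!ok])
}
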