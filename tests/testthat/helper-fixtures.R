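# Shared fixture builders and independent brute-force oracles.

# default tissue labels of the synthetic generator
testTissues <- c("brain", "liver", "kidney", "heart", "lung",
                 "muscle", "skin", "spleen", "testis", "retina")

# TissueProfiles straight from a meanZ matrix (median recomputed)
makeProfiles <- function(meanZ, source = "human_rnaseq") {
    med <- apply(meanZ, 1L, median, na.rm = TRUE)
    new("TissueProfiles", source = source, meanZ = meanZ, medianZ = med)
}

# group datasets by evidence source and build profiles for each
profilesBySource <- function(datasets, center = "mean") {
    key <- vapply(datasets, function(d)
        paste(species(d), platform(d), sep = "_"), character(1))
    lapply(split(datasets, key), function(ds)
        buildTissueProfiles(ds, paste(species(ds[[1L]]),
                                      platform(ds[[1L]]), sep = "_"),
                            center = center))
}

# brute-force modified z-score: direct arithmetic on the value vector
bruteModifiedZ <- function(e, center = "mean") {
    med <- median(e)
    ctr <- if (center == "mean") mean(e) else med
    mad0 <- median(abs(e - med))
    if (mad0 == 0) mad0 <- mean(abs(e - med))
    if (mad0 == 0) return(setNames(rep(0, length(e)), names(e)))
    0.6745 * (e - ctr) / mad0
}

# brute-force per-gene per-tissue group means + cross-tissue medians
bruteProfiles <- function(datasets, center = "mean") {
    zs <- lapply(datasets, function(d) bruteModifiedZ(exprValues(d), center))
    genes <- unique(unlist(lapply(zs, names)))
    tissues <- unique(vapply(datasets, tissue, character(1)))
    meanZ <- matrix(NA_real_, length(genes), length(tissues),
                    dimnames = list(genes, tissues))
    for (g in genes) for (t in tissues) {
        vals <- unlist(lapply(seq_along(datasets), function(i)
            if (tissue(datasets[[i]]) == t && g %in% names(zs[[i]]))
                zs[[i]][[g]] else NULL))
        if (length(vals)) meanZ[g, t] <- mean(vals)
    }
    list(meanZ = meanZ, medianZ = apply(meanZ, 1L, median, na.rm = TRUE))
}

# brute-force base score by direct formula evaluation
bruteBaseScore <- function(zbar, ztilde, affected) {
    s <- 0
    for (t in affected) {
        if (!(t %in% names(zbar)) || is.na(zbar[[t]])) next
        z <- zbar[[t]]
        s <- s + if (z > 0 && ztilde > 0) z * (1 + log(z / ztilde)) else z
    }
    s
}

# pooled Mann-Whitney AUC oracle: fraction of (positive, negative) pairs
# correctly ordered (lower rank = better), ties counted half
mwAuc <- function(ranks, n) {
    pos <- ranks
    neg <- unlist(lapply(ranks, function(r) setdiff(seq_len(n + 1L), r)))
    tot <- 0
    for (p in pos) tot <- tot + sum(neg > p) + 0.5 * sum(neg == p)
    tot / (length(pos) * length(neg))
}

# one-sided KS D oracle by direct CDF comparison: sup_x [F_B(x) - F_A(x)]
bruteKsD <- function(A, B) {
    xs <- sort(unique(c(A, B)))
    max(vapply(xs, function(x) mean(B <= x) - mean(A <= x), numeric(1)))
}

# small hand-built gene model: genes on two chromosomes
handGeneModel <- function() {
    GeneModel(data.frame(
        canonical_id = c("G1", "G2", "G3", "G4"),
        species = "human",
        approved_symbol = c("ALPHA", "BETA", "ZETA", "DELTA"),
        aliases = c("A1|X1", "B1|X1", "D0", "zeta|D4"),
        ensembl_id = sprintf("ENSG%011d", 1:4),
        entrez_id = as.character(101:104),
        refseq_id = sprintf("NM_%06d", 1:4),
        chromosome = c("chr1", "chr1", "chr2", "chr2"),
        span_start = c(100, 300, 100, 500),
        span_end = c(200, 400, 250, 800),
        exons = c("100-150,180-200", "300-350", "120-240", "500-600,700-800"),
        stringsAsFactors = FALSE))
}

writeMiniVcf <- function(path, rows) {
    writeLines(c("##fileformat=VCFv4.2",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                 rows), path)
    path
}
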