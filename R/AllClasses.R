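#' @import methods
NULL

.SPECIES <- c("human", "mouse")
.PLATFORMS <- c("microarray", "rnaseq")

#' Evidence sources
#'
#' The four (species x platform) strata scored separately before combination.
#'
#' @return Character vector of the four source names.
#' @export
evidenceSources <- function() {
    as.vector(outer(.SPECIES, .PLATFORMS, paste, sep = "_"))
}

sourceSpecies <- function(source) sub("_.*$", "", source)
sourcePlatform <- function(source) sub("^.*_", "", source)

#' ExperimentDataset: one experiment's normalized expression vector
#'
#' Holds the set of normalized expression values measured in a single
#' experiment: one value per gene, tagged with species, platform and the
#' tissue the sample came from. Values must be finite, non-negative and
#' cover at least 3 genes (the median and MAD used by the modified z-score
#' are degenerate below that).
#'
#' @slot experimentId opaque experiment identifier.
#' @slot species `"human"` or `"mouse"`.
#' @slot platform `"microarray"` or `"rnaseq"`.
#' @slot tissue tissue label.
#' @slot values named numeric vector, names are gene identifiers.
#'
#' @aliases ExperimentDataset-class
#' @export
setClass("ExperimentDataset", slots = c(
    experimentId = "character",
    species = "character",
    platform = "character",
    tissue = "character",
    values = "numeric"
))

setValidity("ExperimentDataset", function(object) {
    msg <- character()
    v <- object@values
    if (length(object@experimentId) != 1L || !nzchar(object@experimentId))
        msg <- c(msg, "experimentId must be a single non-empty string")
    if (length(object@species) != 1L || !(object@species %in% .SPECIES))
        msg <- c(msg, sprintf("species must be one of: %s",
                              paste(.SPECIES, collapse = ", ")))
    if (length(object@platform) != 1L || !(object@platform %in% .PLATFORMS))
        msg <- c(msg, sprintf("platform must be one of: %s",
                              paste(.PLATFORMS, collapse = ", ")))
    if (length(object@tissue) != 1L || !nzchar(object@tissue))
        msg <- c(msg, "tissue must be a single non-empty label")
    if (is.null(names(v)) || any(!nzchar(names(v))))
        msg <- c(msg, "values must be named by gene identifier")
    if (anyDuplicated(names(v)))
        msg <- c(msg, "duplicate gene identifiers within one experiment")
    if (length(v) < 3L)
        msg <- c(msg, "an experiment needs at least 3 genes")
    if (any(!is.finite(v)))
        msg <- c(msg, "expression values must be finite")
    else if (any(v < 0))
        msg <- c(msg, "expression values must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Construct an ExperimentDataset
#'
#' @param experimentId opaque experiment identifier.
#' @param species `"human"` or `"mouse"`.
#' @param platform `"microarray"` or `"rnaseq"`.
#' @param tissue tissue label.
#' @param values named numeric vector of normalized expression values
#'   (names are gene identifiers).
#'
#' @return An [ExperimentDataset-class] object.
#' @examples
#' ExperimentDataset("e1", "human", "rnaseq", "liver",
#'                   c(g1 = 2, g2 = 4, g3 = 6))
#' @export
ExperimentDataset <- function(experimentId, species, platform, tissue, values) {
    new("ExperimentDataset", experimentId = as.character(experimentId),
        species = as.character(species), platform = as.character(platform),
        tissue = as.character(tissue), values = values)
}

#' @describeIn ExperimentDataset-class number of genes measured.
#' @param x,object an `ExperimentDataset`.
#' @export
setMethod("length", "ExperimentDataset", function(x) length(x@values))

setMethod("show", "ExperimentDataset", function(object) {
    cat(sprintf("ExperimentDataset %s: %s %s, tissue '%s', %d genes\n",
                object@experimentId, object@species, object@platform,
                object@tissue, length(object@values)))
})

#' @rdname experimentAccessors
#' @export
setGeneric("experimentId", function(x) standardGeneric("experimentId"))
#' @rdname experimentAccessors
#' @export
setGeneric("species", function(x) standardGeneric("species"))
#' @rdname experimentAccessors
#' @export
setGeneric("platform", function(x) standardGeneric("platform"))
#' @rdname experimentAccessors
#' @export
setGeneric("tissue", function(x) standardGeneric("tissue"))
#' @rdname experimentAccessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' Accessors for ExperimentDataset slots
#'
#' @param x an [ExperimentDataset-class].
#' @return The corresponding slot value.
#' @name experimentAccessors
NULL

#' @rdname experimentAccessors
#' @export
setMethod("experimentId", "ExperimentDataset", function(x) x@experimentId)
#' @rdname experimentAccessors
#' @export
setMethod("species", "ExperimentDataset", function(x) x@species)
#' @rdname experimentAccessors
#' @export
setMethod("platform", "ExperimentDataset", function(x) x@platform)
#' @rdname experimentAccessors
#' @export
setMethod("tissue", "ExperimentDataset", function(x) x@tissue)
#' @rdname experimentAccessors
#' @export
setMethod("exprValues", "ExperimentDataset", function(x) x@values)

#' TissueVocabulary: the controlled set of tissue labels
#'
#' @slot labels unique, non-empty tissue labels.
#' @slot speciesAvailability named list mapping a label to the character
#'   vector of species with data for it (may be empty, meaning unknown).
#'
#' @aliases TissueVocabulary-class
#' @export
setClass("TissueVocabulary", slots = c(
    labels = "character",
    speciesAvailability = "list"
))

setValidity("TissueVocabulary", function(object) {
    msg <- character()
    if (any(!nzchar(object@labels)))
        msg <- c(msg, "tissue labels must be non-empty")
    if (anyDuplicated(object@labels))
        msg <- c(msg, "tissue labels must be unique")
    extra <- setdiff(names(object@speciesAvailability), object@labels)
    if (length(extra))
        msg <- c(msg, "speciesAvailability refers to unknown labels")
    if (length(msg)) msg else TRUE
})

#' Construct a TissueVocabulary
#'
#' @param labels character vector of tissue labels.
#' @param speciesAvailability optional named list label -> species vector.
#' @return A [TissueVocabulary-class] object.
#' @export
TissueVocabulary <- function(labels, speciesAvailability = list()) {
    new("TissueVocabulary", labels = unique(as.character(labels)),
        speciesAvailability = speciesAvailability)
}

#' @describeIn TissueVocabulary-class tissue labels in the vocabulary.
#' @param x,object a `TissueVocabulary`.
#' @export
setMethod("labels", "TissueVocabulary", function(object) object@labels)

setMethod("show", "TissueVocabulary", function(object) {
    cat(sprintf("TissueVocabulary with %d labels\n", length(object@labels)))
})

#' TissueProfiles: per-gene tissue z-score profiles for one evidence source
#'
#' Summarizes modified z-scores across all experiments of one evidence
#' source into a genes x tissues matrix of per-tissue means, plus each
#' gene's cross-tissue median. Unobserved (gene, tissue) pairs are `NA`;
#' the cross-tissue median is taken over observed tissues only.
#'
#' @slot source one of [evidenceSources()].
#' @slot meanZ numeric matrix, rows genes, columns tissues; per-tissue mean
#'   modified z-scores, `NA` where the gene was never measured in that tissue.
#' @slot medianZ named numeric, per-gene median of its observed per-tissue
#'   means.
#'
#' @aliases TissueProfiles-class
#' @export
setClass("TissueProfiles", slots = c(
    source = "character",
    meanZ = "matrix",
    medianZ = "numeric"
))

setValidity("TissueProfiles", function(object) {
    msg <- character()
    m <- object@meanZ
    if (length(object@source) != 1L || !(object@source %in% evidenceSources()))
        msg <- c(msg, sprintf("source must be one of: %s",
                              paste(evidenceSources(), collapse = ", ")))
    if (nrow(m) > 0L && (is.null(rownames(m)) || is.null(colnames(m))))
        msg <- c(msg, "meanZ must have gene rownames and tissue colnames")
    if (any(is.infinite(m)))
        msg <- c(msg, "per-tissue mean z-scores must be finite")
    if (nrow(m) > 0L && any(rowSums(!is.na(m)) == 0L))
        msg <- c(msg, "every gene must be observed in at least one tissue")
    if (!identical(as.character(names(object@medianZ)),
                   as.character(rownames(m))))
        msg <- c(msg, "medianZ names must match meanZ rownames")
    if (nrow(m) > 0L) {
        expect <- apply(m, 1L, stats::median, na.rm = TRUE)
        if (any(abs(expect - object@medianZ) > 1e-8, na.rm = TRUE))
            msg <- c(msg, "medianZ must equal the median of per-tissue means")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "TissueProfiles", function(object) {
    cat(sprintf("TissueProfiles [%s]: %d genes x %d tissues\n",
                object@source, nrow(object@meanZ), ncol(object@meanZ)))
})

#' @rdname profileAccessors
#' @export
setGeneric("meanZ", function(x) standardGeneric("meanZ"))
#' @rdname profileAccessors
#' @export
setGeneric("medianZ", function(x) standardGeneric("medianZ"))
#' @rdname profileAccessors
#' @export
setGeneric("profileGenes", function(x) standardGeneric("profileGenes"))
#' @rdname profileAccessors
#' @export
setGeneric("profileTissues", function(x) standardGeneric("profileTissues"))
#' @rdname profileAccessors
#' @export
setGeneric("evidenceSource", function(x) standardGeneric("evidenceSource"))

#' Accessors for TissueProfiles
#'
#' @param x a [TissueProfiles-class].
#' @return `meanZ`: the genes x tissues matrix of per-tissue mean modified
#'   z-scores; `medianZ`: the per-gene cross-tissue medians; `profileGenes`
#'   and `profileTissues`: the row/column names; `evidenceSource`: the
#'   source label.
#' @name profileAccessors
NULL

#' @rdname profileAccessors
#' @export
setMethod("meanZ", "TissueProfiles", function(x) x@meanZ)
#' @rdname profileAccessors
#' @export
setMethod("medianZ", "TissueProfiles", function(x) x@medianZ)
#' @rdname profileAccessors
#' @export
setMethod("profileGenes", "TissueProfiles", function(x) rownames(x@meanZ))
#' @rdname profileAccessors
#' @export
setMethod("profileTissues", "TissueProfiles", function(x) colnames(x@meanZ))
#' @rdname profileAccessors
#' @export
setMethod("evidenceSource", "TissueProfiles", function(x) x@source)

#' Resolution: outcome of resolving one input gene token
#'
#' @slot inputToken the token as supplied.
#' @slot status `"resolved"`, `"ambiguous"` or `"unresolved"`.
#' @slot matches canonical ids of all matching gene records.
#' @slot chosen the chosen canonical id (length 0 unless resolved).
#' @slot ruleApplied the matching rule that produced the outcome.
#'
#' @aliases Resolution-class
#' @export
setClass("Resolution", slots = c(
    inputToken = "character",
    status = "character",
    matches = "character",
    chosen = "character",
    ruleApplied = "character"
))

setValidity("Resolution", function(object) {
    msg <- character()
    if (!(object@status %in% c("resolved", "ambiguous", "unresolved")))
        msg <- c(msg, "invalid status")
    if (object@status == "resolved" && length(object@chosen) != 1L)
        msg <- c(msg, "resolved implies exactly one chosen id")
    if (object@status != "resolved" && length(object@chosen) != 0L)
        msg <- c(msg, "only resolved tokens may have a chosen id")
    if (object@status == "unresolved" && length(object@matches) != 0L)
        msg <- c(msg, "unresolved implies no matches")
    if (length(msg)) msg else TRUE
})

setMethod("show", "Resolution", function(object) {
    cat(sprintf("Resolution '%s': %s [%s]%s\n", object@inputToken,
                object@status, object@ruleApplied,
                if (length(object@chosen)) paste0(" -> ", object@chosen) else ""))
})

#' CandidateSet: resolved candidate genes with provenance
#'
#' @slot candidates data.frame with columns `canonical_id`, `provenance`
#'   (`list_token`, `region` or `variant`; comma-joined when a gene was
#'   reached through several routes) and `source_detail`.
#' @slot ambiguities list of [Resolution-class] objects with status other
#'   than resolved.
#'
#' @aliases CandidateSet-class
#' @export
setClass("CandidateSet", slots = c(
    candidates = "data.frame",
    ambiguities = "list"
))

setValidity("CandidateSet", function(object) {
    msg <- character()
    need <- c("canonical_id", "provenance", "source_detail")
    if (!all(need %in% colnames(object@candidates)))
        msg <- c(msg, sprintf("candidates must have columns: %s",
                              paste(need, collapse = ", ")))
    else if (anyDuplicated(object@candidates$canonical_id))
        msg <- c(msg, "candidate canonical ids must be unique")
    if (length(object@ambiguities) &&
        !all(vapply(object@ambiguities, is, logical(1), "Resolution")))
        msg <- c(msg, "ambiguities must be Resolution objects")
    if (length(msg)) msg else TRUE
})

#' Construct a CandidateSet
#'
#' Duplicate canonical ids are merged; their provenance and source details
#' are concatenated in first-seen order.
#'
#' @param candidates data.frame with columns `canonical_id`, `provenance`,
#'   `source_detail`.
#' @param ambiguities list of unresolved/ambiguous [Resolution-class]s.
#' @return A [CandidateSet-class].
#' @export
CandidateSet <- function(candidates = data.frame(canonical_id = character(),
                                                 provenance = character(),
                                                 source_detail = character(),
                                                 stringsAsFactors = FALSE),
                         ambiguities = list()) {
    if (nrow(candidates) && anyDuplicated(candidates$canonical_id)) {
        merged <- lapply(split(candidates,
                               factor(candidates$canonical_id,
                                      levels = unique(candidates$canonical_id))),
                         function(d) data.frame(
                             canonical_id = d$canonical_id[1L],
                             provenance = paste(unique(d$provenance), collapse = ","),
                             source_detail = paste(d$source_detail, collapse = ","),
                             stringsAsFactors = FALSE))
        candidates <- do.call(rbind, merged)
        rownames(candidates) <- NULL
    }
    new("CandidateSet", candidates = candidates, ambiguities = ambiguities)
}

#' @describeIn CandidateSet-class number of distinct candidate genes.
#' @param x,object a `CandidateSet`.
#' @export
setMethod("length", "CandidateSet", function(x) nrow(x@candidates))

#' @rdname candidateAccessors
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))
#' @rdname candidateAccessors
#' @export
setGeneric("candidateIds", function(x) standardGeneric("candidateIds"))
#' @rdname candidateAccessors
#' @export
setGeneric("ambiguities", function(x) standardGeneric("ambiguities"))

#' Accessors for CandidateSet
#'
#' @param x a [CandidateSet-class].
#' @return `candidates`: the provenance data.frame; `candidateIds`: the
#'   canonical ids; `ambiguities`: the list of non-resolved [Resolution-class]s.
#' @name candidateAccessors
NULL

#' @rdname candidateAccessors
#' @export
setMethod("candidates", "CandidateSet", function(x) x@candidates)
#' @rdname candidateAccessors
#' @export
setMethod("candidateIds", "CandidateSet", function(x) x@candidates$canonical_id)
#' @rdname candidateAccessors
#' @export
setMethod("ambiguities", "CandidateSet", function(x) x@ambiguities)

setMethod("show", "CandidateSet", function(object) {
    cat(sprintf("CandidateSet: %d candidates, %d unresolved/ambiguous tokens\n",
                nrow(object@candidates), length(object@ambiguities)))
})

#' ScoringConfig: tunable parameters of the prioritization
#'
#' @slot mouseWeight weight of mouse evidence sources relative to human
#'   (human weight is fixed at 1); in `[0, 1]`.
#' @slot varianceAdjust whether to damp ubiquitously high (housekeeping-like)
#'   genes by their cross-tissue variance.
#' @slot tau gate for the variance adjustment: applied only when the gene's
#'   minimum per-tissue mean z is at least `tau`.
#' @slot c softening constant of the damping factor `sigma / (sigma + c)`.
#' @slot center centering convention of the modified z-score: `"mean"`
#'   (numerator uses the experiment mean) or `"median"` (standard
#'   Iglewicz-Hoaglin form).
#'
#' @aliases ScoringConfig-class
#' @export
setClass("ScoringConfig", slots = c(
    mouseWeight = "numeric",
    varianceAdjust = "logical",
    tau = "numeric",
    c = "numeric",
    center = "character"
))

setValidity("ScoringConfig", function(object) {
    msg <- character()
    if (length(object@mouseWeight) != 1L || is.na(object@mouseWeight) ||
        object@mouseWeight < 0 || object@mouseWeight > 1)
        msg <- c(msg, "mouseWeight must be in [0, 1]")
    if (length(object@c) != 1L || !is.finite(object@c) || object@c <= 0)
        msg <- c(msg, "c must be > 0")
    if (length(object@tau) != 1L || !is.finite(object@tau))
        msg <- c(msg, "tau must be finite")
    if (!(object@center %in% c("mean", "median")))
        msg <- c(msg, "center must be 'mean' or 'median'")
    if (length(msg)) msg else TRUE
})

#' Construct a ScoringConfig
#'
#' @param mouseWeight mouse-source weight in `[0, 1]` (default 1: mouse and
#'   human evidence contribute equally).
#' @param varianceAdjust enable the housekeeping variance adjustment
#'   (default `FALSE`; the unadjusted base score is canonical).
#' @param tau high-expression gate on the minimum per-tissue mean z
#'   (default 1).
#' @param c softening constant, must be positive (default 1).
#' @param center z-score centering convention, `"mean"` (default) or
#'   `"median"`.
#' @return A [ScoringConfig-class].
#' @examples
#' scoringConfig(mouseWeight = 0.5)
#' @export
scoringConfig <- function(mouseWeight = 1, varianceAdjust = FALSE,
                          tau = 1, c = 1, center = c("mean", "median")) {
    center <- match.arg(center)
    new("ScoringConfig", mouseWeight = mouseWeight,
        varianceAdjust = varianceAdjust, tau = tau, c = c, center = center)
}

setMethod("show", "ScoringConfig", function(object) {
    cat(sprintf(paste0("ScoringConfig: mouseWeight=%g, varianceAdjust=%s",
                       " (tau=%g, c=%g), center=%s\n"),
                object@mouseWeight, object@varianceAdjust, object@tau,
                object@c, object@center))
})

#' BenchmarkRun: replicate ranks of one disease gene
#'
#' One benchmarking condition: a disease gene repeatedly ranked against
#' random decoy sets of fixed size; the per-replicate rank of the disease
#' gene among the `decoySize + 1` candidates is recorded.
#'
#' @slot diseaseGene gene identifier of the positive instance.
#' @slot tissues affected tissue labels used for scoring.
#' @slot decoySize number of random decoy genes per replicate.
#' @slot ranks integer vector, the disease gene's rank per replicate, each
#'   in `[1, decoySize + 1]`.
#' @slot seed RNG seed of the run.
#'
#' @aliases BenchmarkRun-class
#' @export
setClass("BenchmarkRun", slots = c(
    diseaseGene = "character",
    tissues = "character",
    decoySize = "integer",
    ranks = "integer",
    seed = "integer"
))

setValidity("BenchmarkRun", function(object) {
    msg <- character()
    if (length(object@ranks) < 1L)
        msg <- c(msg, "at least one replicate rank is required")
    if (length(object@decoySize) != 1L || object@decoySize < 1L)
        msg <- c(msg, "decoySize must be a positive integer")
    else if (any(object@ranks < 1L | object@ranks > object@decoySize + 1L))
        msg <- c(msg, "ranks must lie in [1, decoySize + 1]")
    if (length(msg)) msg else TRUE
})

#' Construct a BenchmarkRun
#'
#' @param diseaseGene gene identifier of the positive instance.
#' @param decoySize number of decoys per replicate.
#' @param ranks integer replicate ranks of the disease gene.
#' @param tissues affected tissue labels (optional bookkeeping).
#' @param seed RNG seed used (optional bookkeeping).
#' @return A [BenchmarkRun-class].
#' @export
benchmarkRun <- function(diseaseGene, decoySize, ranks,
                         tissues = character(), seed = NA_integer_) {
    new("BenchmarkRun", diseaseGene = as.character(diseaseGene),
        tissues = as.character(tissues), decoySize = as.integer(decoySize),
        ranks = as.integer(ranks), seed = as.integer(seed))
}

#' @rdname benchmarkAccessors
#' @export
setGeneric("replicateRanks", function(x) standardGeneric("replicateRanks"))
#' @rdname benchmarkAccessors
#' @export
setGeneric("decoySize", function(x) standardGeneric("decoySize"))

#' Accessors for BenchmarkRun
#'
#' @param x a [BenchmarkRun-class].
#' @return `replicateRanks`: the per-replicate ranks; `decoySize`: the
#'   decoy-set size.
#' @name benchmarkAccessors
NULL

#' @rdname benchmarkAccessors
#' @export
setMethod("replicateRanks", "BenchmarkRun", function(x) x@ranks)
#' @rdname benchmarkAccessors
#' @export
setMethod("decoySize", "BenchmarkRun", function(x) x@decoySize)

setMethod("show", "BenchmarkRun", function(object) {
    cat(sprintf("BenchmarkRun '%s': %d replicates vs %d decoys, mean rank %.2f\n",
                object@diseaseGene, length(object@ranks), object@decoySize,
                mean(object@ranks)))
})

#' RocResult: rank-cutoff ROC curve and its AUC
#'
#' @slot points data.frame with columns `cutoff`, `fpr` (1 - specificity)
#'   and `tpr` (sensitivity), one row per integer rank cutoff from 0 to
#'   `decoySize + 1`, running monotonically from (0, 0) to (1, 1).
#' @slot auc trapezoidal area under the curve, in `[0, 1]`.
#'
#' @aliases RocResult-class
#' @export
setClass("RocResult", slots = c(
    points = "data.frame",
    auc = "numeric"
))

setValidity("RocResult", function(object) {
    msg <- character()
    p <- object@points
    if (!all(c("cutoff", "fpr", "tpr") %in% colnames(p)))
        msg <- c(msg, "points must have columns cutoff, fpr, tpr")
    else {
        if (nrow(p) < 2L || p$fpr[1L] != 0 || p$tpr[1L] != 0 ||
            p$fpr[nrow(p)] != 1 || p$tpr[nrow(p)] != 1)
            msg <- c(msg, "curve must run from (0,0) to (1,1)")
        if (is.unsorted(p$fpr) || is.unsorted(p$tpr))
            msg <- c(msg, "curve must be monotone non-decreasing")
        area <- sum(diff(p$fpr) * (utils::head(p$tpr, -1) + utils::tail(p$tpr, -1)) / 2)
        if (abs(area - object@auc) > 1e-10)
            msg <- c(msg, "auc must equal the trapezoidal area of points")
    }
    if (length(object@auc) != 1L || is.na(object@auc) ||
        object@auc < 0 || object@auc > 1)
        msg <- c(msg, "auc must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' @rdname rocAccessors
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))
#' @rdname rocAccessors
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' Accessors for RocResult
#'
#' @param x a [RocResult-class].
#' @return `auc`: the area under the curve; `rocPoints`: the per-cutoff
#'   (fpr, tpr) data.frame.
#' @name rocAccessors
NULL

#' @rdname rocAccessors
#' @export
setMethod("auc", "RocResult", function(x) x@auc)
#' @rdname rocAccessors
#' @export
setMethod("rocPoints", "RocResult", function(x) x@points)

setMethod("show", "RocResult", function(object) {
    cat(sprintf("RocResult: AUC = %.4f over %d cutoffs\n",
                object@auc, nrow(object@points)))
})

#' KSResult: one-sided two-sample Kolmogorov-Smirnov comparison
#'
#' @slot d one-sided D statistic, in `[0, 1]`.
#' @slot pValue asymptotic one-sided p-value.
#' @slot direction `"affected_greater"` or `"affected_less"`.
#' @slot nAffected,nUnaffected pooled sample sizes.
#'
#' @aliases KSResult-class
#' @export
setClass("KSResult", slots = c(
    d = "numeric",
    pValue = "numeric",
    direction = "character",
    nAffected = "integer",
    nUnaffected = "integer"
))

setValidity("KSResult", function(object) {
    msg <- character()
    if (object@d < 0 || object@d > 1)
        msg <- c(msg, "D must be in [0, 1]")
    if (!(object@direction %in% c("affected_greater", "affected_less")))
        msg <- c(msg, "invalid direction")
    if (length(msg)) msg else TRUE
})

setMethod("show", "KSResult", function(object) {
    cat(sprintf("KSResult (%s): D = %.4f, p = %.4g (n = %d vs %d)\n",
                object@direction, object@d, object@pValue,
                object@nAffected, object@nUnaffected))
})
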