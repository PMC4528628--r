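# TissueRank

Candidate disease gene prioritization from tissue-specific gene expression.

## The problem

Linkage intervals and exome filtering routinely leave a researcher with tens
to hundreds of candidate disease genes, far more than can be verified
experimentally. Most prioritization tools rank candidates by
guilt-by-association with already characterized genes, which biases them
against poorly annotated genes and diseases. TissueRank instead uses only
experimental baseline expression data, on the hypothesis that a gene causing
a tissue-restricted phenotype tends to be more highly expressed in the
affected tissue(s) than elsewhere. It is aimed at geneticists triaging
candidate lists for diseases where the affected tissues can be named but
little else is known.

## The method

Each expression experiment (one tissue sample, human or mouse, microarray or
RNA-seq, values already normalized) is standardized across its genes with a
robust modified z-score,

    z_e = 0.6745 * (e - Ē) / median(|e - Ẽ|),

where `E` is the experiment's value set, `Ē` its mean and `Ẽ` its median —
the median-absolute-deviation denominator keeps the handful of very highly
expressed genes from dominating the scale. (A median-centered variant is
available via `center = "median"`.) Per evidence source (species × platform
stratum), the scores are averaged into per-gene per-tissue means `z̄_t` and
each gene's cross-tissue median baseline `z̃`. Given the affected tissue set
`T`, the source-level base score of gene *g* is

    S_g = Σ_{t ∈ T}  z̄_t · (1 + ln(z̄_t / z̃))   if z̄_t > 0 and z̃ > 0
                      z̄_t                        otherwise,

so expression elevated above the gene's own baseline is rewarded even when
its absolute level is modest, and below-baseline expression is penalized. An
optional variance adjustment damps ubiquitously high (housekeeping-like)
profiles by the factor `σ/(σ + c)`. Source scores are combined by a weighted
mean with human weight 1 and a user-adjustable mouse weight, and candidates
are ranked by descending combined score (competition ranking).

Candidates may be supplied as a delimited gene list (HGNC symbols, aliases,
Ensembl/Entrez/RefSeq accessions, mixed), as genomic regions
(`chr:start-end`, 1-based inclusive), or as a pre-filtered VCF; identifiers
are resolved through a fixed precedence ladder with an optional
expression-presence tie-break, and human–mouse ortholog tables map
candidates into mouse evidence sources.

The package also ships the evaluation machinery: random decoy-set sampling,
pooled rank-cutoff ROC curves whose trapezoidal AUC equals the Mann–Whitney
pair-ordering statistic, mean rank / mean reciprocal rank summaries, a
one-sided two-sample Kolmogorov–Smirnov test of the elevated-expression
hypothesis, and a synthetic-database generator with planted tissue-specific
signal for end-to-end validation.

## Worked example

```r
library(TissueRank)

# synthetic database: 100 genes, 10 tissues, two human sources,
# gene G0001 planted 3 log-units high in brain
spec <- syntheticSpec(nGenes = 100, effect = 3, seed = 42)
db   <- generateDatabase(spec)
key  <- vapply(db$datasets, function(d) paste(species(d), platform(d), sep = "_"), "")
profiles <- lapply(split(db$datasets, key), function(ds)
    buildTissueProfiles(ds, paste(species(ds[[1]]), platform(ds[[1]]), sep = "_")))

model <- generateGeneModel(spec)
cand  <- genesFromList("GENE1, GENE7; GENE20 GENE33\nGENE40", model)
res   <- prioritize(cand, profiles, affected = "brain", model = model)
res[, c("rank", "gene_id", "approved_symbol", "combined_score")]
#>   rank gene_id approved_symbol combined_score
#> 1    1   G0001           GENE1      211.65038
#> 2    2   G0020          GENE20        0.11042
#> 3    3   G0007           GENE7        0.07375
#> 4    4   G0040          GENE40       -1.21410
#> 5    5   G0033          GENE33       -1.41015
```

The planted gene tops the list with a combined score orders of magnitude
above the background candidates, whose scores scatter around zero (their
brain expression is at their own cross-tissue baseline). Benchmarking the
planted gene against 50 random decoys, 30 replicates:

```r
run <- benchmarkGene("G0001", "brain", profiles, size = 50,
                     nReplicates = 30, seed = 7)
auc(rocFromRanks(run))        #> 1
rankStats(run)$meanRank       #> 1
```

The same workflow is available from a shell through the thin wrapper in
`exec/tissuerank` (`tissuerank simulate | prioritize | benchmark`); every
run writes a JSON manifest with config values and input digests alongside
its output.

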