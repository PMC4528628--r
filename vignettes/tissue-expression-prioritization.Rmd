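---
title: "Prioritizing candidate disease genes by tissue-specific expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing candidate disease genes by tissue-specific expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TissueRank)
```

## The model and its assumptions

TissueRank ranks candidate disease genes on a single biological hypothesis:
a gene whose dysfunction produces a tissue-restricted phenotype tends to be
expressed more highly in the affected tissue(s) than in unaffected ones.
Nothing else about the disease or the genes — annotations, interactions,
literature — enters the score, which makes the method equally applicable to
well-studied and completely uncharacterized genes, and equally *inapplicable*
to diseases whose causal genes are ubiquitously or conditionally expressed
(see Limitations).

The data model is a collection of expression experiments. Each experiment
contributes one normalized expression value per gene and is tagged with a
species (human or mouse), a platform (microarray or RNA-seq) and a tissue
label. The four species × platform strata are treated as independent
*evidence sources*: platforms are never mixed on the raw scale, and mouse
evidence reaches a human candidate only through a one-to-one ortholog.

### Robust standardization

Within each experiment the values are transformed to modified z-scores
across genes:

$$z_e = \frac{0.6745\,(e - \bar E)}{\mathrm{median}(|e - \tilde E|)}$$

with $\bar E$ the experiment mean and the denominator the median absolute
deviation about the experiment median $\tilde E$. Expression values are
strongly right-skewed, so an SD-based z-score would be dominated by the few
most expressed genes; the MAD denominator is insensitive to them. The
0.6745 factor scales the MAD to the standard deviation under normality, so
the scores read on a familiar scale.

Standardization is applied per experiment across genes (not per gene across
experiments): each experiment is its own reference population, which makes
values comparable across laboratories and platforms without any joint
renormalization. The default centers the numerator on the experiment
*mean*; `center = "median"` gives the textbook median-centered form. The two
agree exactly on symmetric data and differ by a constant shift otherwise —
within one experiment the shift is shared by all genes, so candidate
*ordering* inside a tissue is unaffected; only the split into positive and
negative scores moves.

### From experiments to profiles and scores

Per evidence source, a gene's modified z-scores are averaged over all
experiments of the same tissue into $\bar z_t$, and the gene's cross-tissue
baseline $\tilde z$ is the median of its observed $\bar z_t$. Given the
affected tissue set $T$, the source-level base score is

$$S_g = \sum_{t \in T} \begin{cases}
  \bar z_t\,(1 + \ln(\bar z_t / \tilde z)) & \bar z_t > 0 \text{ and } \tilde z > 0\\
  \bar z_t & \text{otherwise.}
\end{cases}$$

The log-ratio modifier is the heart of the method: among genes with equal
affected-tissue expression, the one whose expression elsewhere is *low*
(small $\tilde z$) scores higher, because its expression is specifically
elevated where the disease manifests. The piecewise condition is a design
decision of this package: the logarithm needs a strictly positive ratio, so
the modifier applies only when both $\bar z_t$ and $\tilde z$ are positive,
and every other case contributes the plain $\bar z_t$ — in particular a
below-average affected-tissue expression always counts against the gene and
can never be inflated by the modifier. On the region $\bar z_t \ge \tilde z
> 0$ the contribution is strictly increasing in $\bar z_t$ (derivative
$2 + \ln(\bar z_t/\tilde z) > 0$), and at ratio one it collapses exactly to
$\sum_t \bar z_t$; both properties are enforced by tests.

## Tunable parameters

* `mouseWeight` (default 1, range [0, 1]) — relative weight of mouse
  evidence sources in the combined score; human sources are fixed at 1.
  Setting it to 0 reproduces human-only ranking exactly.
* `varianceAdjust` (default off), with `tau` (default 1) and `c` (default
  1) — a gene whose *minimum* per-tissue mean z is at least `tau` is
  expressed high everywhere; its score is multiplied by
  $\sigma/(\sigma + c)$, $\sigma$ the SD of its per-tissue means, in units
  of modified z-scores. A perfectly flat housekeeping profile is fully
  suppressed; the penalty fades as the profile becomes tissue-specific.
  The gated multiplicative form is this package's concrete realization of a
  cross-tissue-variance adjustment; it is off by default so the unadjusted
  base score remains the canonical behaviour.
* `center` (default `"mean"`) — z-score centering convention, above.
* Combination is a weighted *mean* rather than a sum so that a gene
  measured in three sources is comparable with one measured in one; sources
  where a gene has no data simply drop out (absence of a measurement is not
  evidence of absence of expression), and a gene absent everywhere is
  flagged `no_data` and listed after all scored genes, unranked.
* Ties share the smaller (competition) rank; display order breaks ties by
  gene id so output is byte-reproducible.

## Candidate input and identifier resolution

Gene lists accept commas, semicolons, tabs, spaces and newlines, with
case-insensitive de-duplication. Tokens are resolved through a fixed
precedence ladder — approved symbol, Ensembl, Entrez, RefSeq, alias —
case-insensitive for symbols and aliases, case-sensitive (version suffix
stripped) for accessions. When several genes match, the only tie-break
offered is expression presence: if exactly one match has expression data it
is chosen (and the applied rule recorded); otherwise the token is reported
ambiguous rather than guessed. Ortholog tables are reduced to strictly
one-to-one pairs, dropping any many-to-many rows with a warning, because a
candidate must map to exactly one mouse expression profile to be scored.

Genomic regions use 1-based inclusive coordinates and closed-interval
overlap with the full gene span; a single shared base suffices. VCF
variants (only CHROM/POS/REF are read) use the footprint `POS .. POS +
nchar(REF) - 1`, so deletions reach the bases they remove. Variants are
expected to be pre-filtered for deleteriousness upstream. Whether overlap
should count introns is genuinely open; the package defaults to the full
span (permissive and reproducible) and offers `exonsOnly = TRUE`.

## Benchmarking machinery

A benchmark run ranks a disease gene against `size` random decoys sampled
uniformly without replacement, over `nReplicates` replicates (default 30;
sizes 50/100/200/500 in the command-line driver). Replicates are pooled
into a single rank-cutoff ROC curve: at every integer cutoff *k* the
replicate's positive is predicted positive iff its rank ≤ *k*, decoys
occupy the remaining ranks, and sensitivity / 1-specificity are pooled over
replicates. The trapezoidal area of this curve is provably the
Mann–Whitney pair statistic (fraction of positive–decoy pairs correctly
ordered, ties half), and the test suite asserts exact equality against an
independent pair-counting oracle; per-replicate averaging is available as
`meanReplicateAuc()`. Mean rank uses the sample SD (n − 1); a
single-replicate run reports SD 0 with `sdDefined = FALSE`.

The elevated-expression hypothesis itself is tested by pooling, per disease
gene, its per-tissue mean z-scores over affected tissues versus all its
other tissues, and comparing the pools with a one-sided two-sample
Kolmogorov–Smirnov test (asymptotic p-value; exact small-sample p-values
are out of scope). The direction is an explicit parameter defaulting to
"affected stochastically greater", i.e. the affected-tissue CDF lying
*below* the unaffected one — stated explicitly because prose descriptions
of one-sided KS directions are notoriously easy to invert.

## The synthetic generator

Real tissue expression databases are large, heterogeneous and encumbered;
the generator provides a fully specified stand-in so that every pipeline
stage is testable end to end. Background values are i.i.d. log-normal per
(gene, experiment) — positive and right-skewed like normalized intensities —
with `meanlog = 2`, `sdlog = 1` by default. Planted (gene, tissue) signals
add their effect on the log scale in every experiment of that tissue, i.e.
multiplicatively on the raw scale, so the signal must survive the entire
standardization pipeline rather than being injected as a z-score. The
standard validation condition is 500 genes, 10 tissues, two human sources
with 3 experiments per tissue each, one gene planted at 3 log-units
(about 20-fold).

What the generator deliberately does *not* emulate: gene-specific baseline
levels (values are i.i.d. across genes, so there are no natural
housekeeping genes), platform artifacts such as probe saturation or RNA-seq
count overdispersion, correlated tissues, and batch effects. Passing the
planted-signal tests therefore demonstrates that the pipeline recovers a
clean multiplicative signal of stated size from skewed noise — not that it
is robust to every pathology of real data. The null condition (effect 0)
makes all candidates exchangeable, so the planted gene's rank among 51
candidates must be uniform; the suite checks this with a chi-square
goodness-of-fit test over 1,000 seeds, alongside recovery (rank 1 in at
least 95% of 100 seeds) under effect 3. Problem sizes throughout the test
suite (500 genes, up to 1,000 seeds, decoy sets of tens) were chosen as the
smallest at which these distributional checks are statistically meaningful.

## Numerical choices and degenerate inputs

* A MAD of exactly 0 (more than half the experiment at one value) falls
  back to the mean absolute deviation about the median; if that is also 0,
  every score is 0 — "no signal" rather than an error or a division by
  zero.
* Experiments with fewer than 3 genes are rejected: median and MAD are
  degenerate below that.
* Genes missing from an experiment contribute nothing to it — no zero
  imputation anywhere.
* Affected tissues absent from a gene's profile contribute 0 to its score
  and are reported in the `missingTissues` attribute; an affected set with
  *no* overlap with the data's vocabulary is an error.
* All table formats are plain TSV with full-precision decimal values;
  write-then-read is an exact round trip, and reread-then-rewrite is
  byte-identical.

## Limitations

The method inherits the limits of its hypothesis. It cannot find disease
genes that are ubiquitously expressed, repressed in disease, expressed only
under stimulation or in narrow developmental windows, or expressed in
tissues absent from the database; diseases whose visible phenotype and site
of expression diverge (circulating factors, autoimmune mechanisms) require
the user to select the tissue of *synthesis*, not of manifestation. Ranks
should be read as an ordering for follow-up, not as evidence that the top
gene is causal. Differential case-control expression is intentionally out
of scope: the database holds baseline, non-diseased tissue only.
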