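---
title: "Methods: weighted feature scoring, weight learning and ontological expansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted feature scoring, weight learning and ontological expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Statistical association alone rarely identifies which single nucleotide
polymorphisms (SNPs) around a disease gene are biologically consequential:
the causal variants are dispersed among many co-inherited, statistically
indistinguishable ones. `snpprio` re-scores SNPs using *a priori*
biomolecular knowledge: each SNP is annotated with a set of features —
its localization class (frame shift, missense, UTR, intron, ...),
membership in regulatory tracks (DNase clusters, CpG islands, enhancers,
transcription-factor binding sites), conservation, protein-level evidence —
and the features are combined into one prioritization score.

# The scoring model

Every feature value is first normalized to a score $f_i \in [0,1]$:

* **binary** features (track membership) pass through as 0/1;
* **categorical** features use an editable label-to-score map; the shipped
  localization map ranks coding-disruptive classes highest (frame shift 1.0,
  missense 0.9, start codon 0.85, UTRs 0.6, near-gene 0.4, intron 0.2,
  intergenic/unknown 0.1) — the ordering is the biologically motivated part,
  the numeric values are config, not code;
* **continuous** features are min–max scaled to a declared range and clipped
  (minor allele frequency uses $[0, 0.5]$, its mathematical range);
* **contextual** features (per tissue or cell line) contribute the mean of
  their context scores unless the user selects one context, in which case
  that context's score is used alone;
* **missing** annotations score 0: in a sum-based score, absence of evidence
  contributes no score mass. The annotation store nevertheless keeps missing
  distinct from zero until normalization, so the raw matrix stays auditable.

The SNP score is the weighted linear combination
$$\sigma_i(w) = \sum_{j \in \text{selected}} w_j f_{ij}, \qquad w_j \in [0,1],$$
so $0 \le \sigma_i \le \sum_j w_j$ with equality at $f \equiv 1$. Linearity
keeps every weight interpretable as the user-visible relevance of one
biomolecular aspect and makes the score monotone in every feature. Ranking
is by $\sigma$ descending with ties broken by rsid (C-locale), so results
are reproducible regardless of input order; percentile truncation keeps the
top $\lceil p/100 \cdot n \rceil$ entries.

SNPs are associated to genes through a symmetric, strand-blind flanking
region (default 100,000 bp — the scale at which regulatory elements
plausibly act on a gene, and adjustable per run). A SNP inside two genes'
flanks keeps both associations; gene-level outputs list it under each.

# Learning the default weights

Useful default weights are learned from disease benchmarks. A benchmark is a
disease's gene set, the candidate universe $S$ of all SNPs within the flank
of those genes, and the certified subset $A \subseteq S$ of variants known
to be involved. Given weights $w$, scores are filtered at the relative
threshold
$$T_\varepsilon = \varepsilon \cdot \sigma_{\max}, \qquad
  \sigma_{\max} = \sum_j w_j,$$
and $Y = \{ s_i : \sigma_i(w) > T_\varepsilon \}$ (strict inequality, so
$\varepsilon = 1$ empties $Y$). Sensitivity is $|A \cap Y| / |A|$; the
fitness to minimize is $1 - $ mean sensitivity across training diseases.
Configurations that fail to filter — $|Y|/|S| \ge T_r$ for any training
disease — receive the sentinel fitness 2.0, strictly worse than any
feasible value in $[0,1]$, which preserves the ordering the genetic
algorithm relies on without distorting feasible comparisons.

**Why the attainable maximum as the threshold reference.** Two relative
references are defensible: the best *observed* score $\max_{S} \sigma_i(w)$
or the maximum *attainable* score $\sum_j w_j$. Both are invariant to
rescaling $w$ (an absolute constant is not, and could not work across weight
scales). We use the attainable maximum in the optimizer for two reasons.
First, the observed maximum is an extreme order statistic: it is noisy, and
it couples the threshold to the single best-annotated SNP of each disease.
Second, and decisively, with dense background annotation the typical score
of *any* generic weight vector sits near half the observed maximum, so
$|Y|/|S|$ exceeds any practical $T_r$ for essentially every random
individual, the penalty is flat across the whole population, and the
genetic algorithm has no gradient to start from. Against the attainable
maximum, random-weight individuals are almost always feasible and the
search is well-posed. `score_threshold()` still defaults to the observed
maximum for interactive filtering of an existing score list; the optimizer
passes `sigma_max = sum(w)` explicitly.

The genetic algorithm follows a fixed schedule: 100 generations of 120
individuals; coefficients initialized i.i.d. uniform on $[0,1]$; each new
generation keeps the 10 best individuals unmodified (elitism — which makes
the best-fitness trajectory non-increasing), adds 10 fresh random
individuals (immigration against premature convergence) and fills the
remaining 100 slots by recombining parents drawn uniformly from the top 50.
The recombination operator is uniform crossover per coefficient followed by
per-coefficient Gaussian mutation (probability 0.05, sd 0.1, clipped to
$[0,1]$); the schedule, not the operator, is the load-bearing part, and all
of it is configurable through `ga_config()`. `ga_config_scaled()` shrinks
the population while preserving the random/elite/recombinant proportions
for reduced experiments.

Generalization is assessed by leave-one-out cross-validation: each disease
serves once as validation per grid cell, over $\varepsilon \in \{0.1,
\ldots, 1.0\}$ (step 0.1) and $T_r \in \{0.25, 0.5, 0.75, 1.0\}$ — with a
16-disease panel, 640 training runs. The grid report carries per-cell mean
sensitivity, specificity and accuracy; raising $\varepsilon$ trades
sensitivity for specificity, and tighter $T_r$ forces sparser, more
selective weightings. Every run's RNG seed derives deterministically from
the master seed, the held-out disease and the cell, so the whole grid is
reproducible from one integer and runs can be re-executed independently.

The shipped 31-feature default registry carries the weights produced by
this optimization. Their pattern is instructive: sparse, specific tracks
(DNase clusters 0.9558, enhancers 0.9571, CpG-island promoter regions
0.9665) earn high weights, while dense or weakly specific annotations
(open chromatin 0.1596, lamina-associated domains 0.2444, MAF 0.3133) are
down-weighted — under a sum score with a relative threshold, dense features
raise everyone's score and dilute the filter, so the optimizer learns to
suppress them.

# Ontological expansion

An input gene list $g_1$ can be enlarged to $g_2 \supseteq g_1$ with genes
whose ontology annotations resemble a seed gene's. Two term-level measures
are provided:

* **Wang**: semantic contributions ($S$-values) propagate from a term to its
  ancestors, starting at 1 and multiplying by an edge-type factor per step
  (defaults 0.8 for `is_a`, 0.6 for `part_of`, configurable), keeping the
  maximum over paths; the similarity of two terms is the sum of both
  $S$-values over shared ancestors divided by the sum of all $S$-values.
* **Rel** (relevance): with $c^\ast$ the common ancestor of maximal
  information content (IC estimated from the annotation corpus itself with
  ancestor propagation — no external IC tables), the similarity is
  $\frac{2\,\mathrm{ic}(c^\ast)}{\mathrm{ic}(t_1) + \mathrm{ic}(t_2)}
  (1 - p(c^\ast))$; the rarity factor $1 - p$ zeroes similarities whose only
  shared ancestor is the root.

Gene-level similarity aggregates term similarities by best-match average
(each term matched to its best counterpart, the two directional means
averaged), the aggregation published with the Wang measure's reference
implementation; whether the original relevance-measure deployments averaged
or took the maximum is not recoverable, so BMA is used for both, and the
expansion additionally exposes an optional top-$k$ cap. Expansion keeps
every candidate whose best similarity against any seed reaches the
threshold, so it is monotone: a higher threshold can only shrink $g_2$.

# Enrichment

After ranking, the *genes* carrying the SNPs that survive the percentile
cut (a gene with many top SNPs counts once) are tested for
over-representation in pathway, ontology-term or disorder categories:
upper-tail hypergeometric tests with the whole category map as background
universe, Benjamini–Hochberg correction applied per category source
(pathway / ontology / disorder families mirror separate questions, so each
family is its own testing batch). Categories without any top gene are
skipped by default — they cannot be enriched, and skipping them keeps the
correction's $m$ focused on categories actually at play — with a flag to
include them at $k = 0$. Only over-representation is tested; depletion is
out of scope.

# The synthetic data generator

`simulation_spec()` / `simulate_store()` build a self-contained annotation
warehouse: genes tiled on one chromosome with spacing larger than twice the
flank (so per-disease candidate sets are disjoint and cross-validation is
honest; an overlap fraction can relax this), SNP positions uniform within
gene ± flank, and a feature registry whose first $k$ features are
*informative*: certified SNPs carry them at rate $p_1 = 0.8$, everything
else at $p_0 = 0.2$. This two-rate binary model is the simplest signal a
linear score can exploit; a flag switches to continuous tracks (shifted
Gaussians through min–max normalization). Benchmarks draw disjoint gene
blocks per disease with 10 certified SNPs each (certified fractions are
small, as in curated disease databases); 4 genes per disease and 40 SNPs
per gene reflect the scale of curated disease panels. The toy ontology is a
balanced DAG (depth 3, branching 3 by default, mostly `is_a` with a
sprinkling of `part_of`) in which each disease's genes cluster around an
anchor leaf, so within-disease gene similarity exceeds between-disease
similarity in expectation.

What the generator does **not** emulate: linkage disequilibrium and
haplotype structure, realistic allele frequencies, per-track genomic
footprints, chromosome-level coordinate conventions of any particular
genome build, or correlated features. Passing tests therefore demonstrate
that the machinery — mapping, scoring, optimization, validation bookkeeping
— behaves correctly and that planted signal of realistic strength is
recovered; they do not certify performance on real annotation warehouses.

# Numerical and design details

* Internal coordinates are 0-based half-open; BED enters natively, VCF and
  1-based-inclusive TSVs are converted on read. Converting out and back is
  the identity.
* Identifier resolution priority is gene ID, then symbol, then alias,
  case-insensitive; unmatched tokens are reported, never dropped.
* Row rejections (SNPs without an identifier, certified SNPs outside their
  disease's candidate universe) are counted and surfaced as warnings.
* Ties: ranking breaks score ties by rsid; elite selection breaks fitness
  ties by population index. Both are arbitrary but deterministic.
* Degenerate inputs: all-zero scores yield threshold 0 with a warning;
  benchmarks with no certified SNPs are rejected (sensitivity undefined);
  an empty expansion seed set after annotation filtering is an error.
* The hypergeometric tail and BH correction are computed with R's `phyper`
  and `p.adjust` and are cross-checked in the test suite against exhaustive
  draw enumeration (universes up to 12) and a hand-rolled step-up
  implementation.
* Problem sizes in the test and acceptance suites (16-disease grid with
  reduced per-gene SNP counts, ten 8-disease recovery panels with a
  30-generation, 40-individual GA) were chosen so the full suite
  demonstrates every claim at desk scale; all of them are spec parameters,
  not constants.

# Known limitations

* The attainable-maximum threshold makes $Y$ empty whenever no SNP reaches
  $\varepsilon \sum w_j$; with very sparse annotation and large
  $\varepsilon$ entire diseases can report zero sensitivity. The grid
  report makes this visible rather than masking it.
* Weight learning assumes certified SNPs are representative positives;
  curation bias in the benchmark source propagates into the weights.
* The expansion threshold is an absolute similarity value; its practical
  range depends on the measure (Wang values run higher than Rel on shallow
  ontologies), so thresholds are not transferable between measures.
* Enrichment treats genes as exchangeable; gene length and SNP density are
  not modeled in the null, a standard caveat for hypergeometric gene-set
  tests.
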