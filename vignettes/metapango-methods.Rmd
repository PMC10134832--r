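---
title: "MetaPanGO: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MetaPanGO: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MetaPanGO)
```

# The problem

Shotgun metagenomics routinely assembles millions of microbial genes whose
functions are unknown. Two complementary annotation strategies exist:
orthology transfer (eggNOG-mapper style), which is precise but covers only
genes with characterized homologs, and structure/deep-learning prediction
(DeepFRI style), which scores a Gene Ontology (GO) term for essentially
every protein but at lower average specificity. MetaPanGO implements the
downstream computations needed to integrate and compare such annotations
over a nonredundant gene catalogue, to attach them to metagenome-assembled
genomes (MAGs), to quantify them in copies per million (CPM), and to build
reference-free pangenomes per species. Every upstream tool (assembler, gene
caller, clusterer, aligner, binner, the annotators themselves) is out of
scope: only their *output dialects* are parsed, and a seeded synthetic
generator emulates all of them with planted ground truth.

# The GO DAG, information content, and informative terms

GO terms form a directed acyclic graph. MetaPanGO reads OBO `[Term]`
stanzas and keeps only `is_a` edges — the simplest defensible reading of
"child–parent relationships", and the relation the cited
information-content corpus uses; `part_of` and other relations are
ignored. Obsolete terms and, when a namespace filter is given,
foreign-branch terms are dropped at parse time; dangling parent references
are pruned with a warning; a cyclic `is_a` relation is a validation error
naming one cycle member.

**Upward propagation.** `propagateUp()` closes a term set under the
ancestor relation. Annotations from methods of different specificity are
always propagated before comparison so that a child annotation in one
method can meet its parent annotation in the other.

**Information content.** For term $i$ with $n_i$ annotated proteins in a
reference corpus of $n$ annotated proteins (counts upward-propagated),

$$\mathrm{IC}(i) = -\log_2 \frac{n_i}{n} \quad \text{bits.}$$

IC 0 means the term annotates the whole corpus; rare terms carry many
bits. The table may be computed from a counts corpus or loaded
precomputed (two-column TSV); both pathways are supported because
published workflows often reuse an external IC list. Terms absent from
the table are never silently dropped: histogram and concordance code
routes them to an explicit "unbinned" bucket.

**Informative terms.** With threshold $k$ (default 2000), a term is
*informative* iff it annotates **more than** $k$ proteins and every proper
descendant annotates **fewer than** $k$. The published wording leaves a
count of exactly $k$ unclassified; MetaPanGO reads both inequalities
strictly, so a term with count $k$ is not informative itself and also does
not disqualify its ancestor. The result is provably an antichain: no
informative term is an ancestor of another. Counts are validated to be
propagation-consistent (no child exceeding a parent) before the rule is
applied.

# Annotation ingestion and projection

The structure-based reader accepts comma- or tab-delimited tables (header
optional, auto-detected) of gene, term, score, and keeps rows with
`score >= threshold`; the reference thresholds are 0.2 (standard quality)
and 0.5 (high quality). Because the rule is a simple cut, the 0.5-gene set
is always nested in the 0.2-gene set. Orthology tables are
eggNOG-mapper-style TSVs: `#`-prefixed comment lines (the last one may be
the header), a comma-separated GO column exploded to one record per term
at score 1.0, and a free-text description column; `-` means absent, and a
gene with only a description is retained as description-annotated.
Duplicate (gene, term, method) records collapse keeping the maximum score.

`filterInformative()` projects a gene's propagated term set onto the
informative antichain and **replaces** the specific terms by the
informative ancestors reached. The alternative reading — keep the original
terms and merely require an informative ancestor — was rejected because
downstream abundance is summed per informative term, which requires the
projection. Genes whose closure misses the informative set are dropped.

# Gene catalogue and cluster propagation

The catalogue models CD-HIT output: `.clstr` stanzas with exactly one `*`
representative per cluster (the centroid), members at the identity
threshold (carried as metadata only — clustering itself is upstream). Gene
ids are Prodigal-style `<contig>_<ordinal>`; the contig is recovered by
splitting on the *last* underscore, since contig names may contain
underscores. Ids are stored truncated exactly as the tool truncates them
(before the first `...`), and the FASTA reader truncates at whitespace,
so joins never fail.

Annotation methods run on centroids only; `propagateClusterAnnotations()`
copies the centroid's records to every member, so member term sets equal
the centroid's bit for bit, and the annotated-gene count equals the summed
size of clusters with annotated centroids.

# MAG integration

MAG quality uses the CheckM convention: *nearly complete* means
completeness $\ge 90\%$ (inclusive) **and** contamination $< 5\%$
(exclusive) — read literally from the symbols. Taxonomy strings follow the
GTDB prefix convention (`d__` … `s__`), parsed and stripped into seven
ranks with empty strings for unassigned ranks.

Two different filters are deliberately used downstream: the
multi-taxonomy gene-family analysis (`clusterTaxonomySharing()`) applies
*only* the contamination filter (< 5%), exactly as described for that
analysis, whereas pangenome construction requires the full 90/5 rule.
Sharing counts are distinct non-empty labels at the requested rank over
all qualifying MAGs touching the cluster; an unbinned cluster counts 0.
The convention of counting over *all* qualifying MAGs (not one per
sample-species pair) is fixed and tested.

# Abundance

Two CPM modes exist because the reference description is internally
inconsistent (a raw-count formula next to a length-weighting sentence):

* `paper_raw`: $\mathrm{cpm}_g = c_g \times 10^6 / N$ with $N$ the
  sample's total read count — the literal printed formula. Row sums equal
  $10^6 \times$ (mapped fraction).
* `length_rescaled` (default): $\mathrm{cpm}_g = (c_g/L_g) \times 10^6 /
  \sum_h (c_h/L_h)$ — counts become copies via the template length, then
  rescale to a million per sample. This matches the length-weighting
  sentence and standard practice, is scale-invariant in the counts, and
  row sums are exactly $10^6$.

When the sample's total read count is unknown, the mapped sum stands in
with a message. Per-term abundance sums the full CPM of every gene
carrying the term — a multi-term gene contributes to each of its terms
without fractional splitting (the simplest reading of "summed CPM"), so
term totals can exceed the annotated-gene CPM total. `annotatedFraction()`
reports the percent of a sample's CPM carried by an annotated gene set;
zero-abundance samples report NA.

# Concordance

"Information content level" is not defined by the reference; MetaPanGO
bins terms by $\lfloor \mathrm{IC} \rfloor$, matching the integer axis of
the published figures. For each gene and occupied bin, with $A_L$/$B_L$
the two methods' propagated term sets restricted to the bin:
both non-empty and intersecting → *concordant*; both non-empty and
disjoint → *discordant*; one side only → *unique*. The shared-term rule is
the strictest reading of "agree at the same level"; a looser
`both_present` mode (any two non-empty sets agree) is available for
sensitivity analysis. The four categories partition the genes annotated in
the bin by either method, swapping the inputs swaps the unique counts and
fixes the rest, and a set compared against itself is 100% concordant —
all asserted as properties. Because the figure's unit (genes vs gene-term
pairs) is unstated, `icHistogram()` emits both tallies, column-labelled.
Venn comparisons (2- or 3-way, including the description channel as a
plain gene set) return exact disjoint region counts satisfying
inclusion–exclusion.

# Pangenomes

Species with at least 10 nearly complete MAGs (90/5) qualify; species
identity is the GTDB species string, and unassigned MAGs never enter. The
presence matrix is boolean over (cluster, MAG); a cluster is **core** when
present in $\ge 90\%$ of the species' qualifying MAGs (inclusive, so 9 of
10 is core — the denominator is the matrix's column count), otherwise
**accessory**; core plus accessory is the pangenome. An accessory cluster
is *shared* when observed in another species' entire pangenome (a gene
core in A and accessory in B makes B's copy shared) — the defensible
reading of "observed in more than one species"; a strict
accessory-vs-accessory mode is flagged. All qualifying MAGs are kept even
when one sample contributes several ("independent" is read as distinct
MAGs). `pangenomeSummary()` adds per-method known-function splits
(clusters with an informative-annotated member) and the Pearson
correlation between pangenome size and MAG count, undefined (NA, with a
message) below 3 pangenomes or at zero variance.

# The synthetic generator: what it emulates, and what it does not

`simulateCommunity()` plants a community and emits every input dialect the
package parses, deterministically under its seed (same seed, byte-identical
files). The stated world behind the defaults:

* **Ontology**: a fixed 21-term molecular-function DAG (root, 5 mid-level
  terms, 15 leaves) with planted corpus counts ($n = 10^4$) such that at
  $k = 2000$ exactly the four well-populated mids are informative, and
  leaves sit in IC bins 3, 5 and 7 while mids occupy bins 1–2 — so
  leaf-level agreement is cleanly separable from ancestor agreement.
* **Genomes**: per species, a core pool (every MAG) and an accessory pool
  (each cluster in at most 89% of MAGs, so planted accessory can never
  classify core); per-gene-per-MAG dropout $d = 0.05$ models MAG
  incompleteness, making core recovery follow the binomial tail
  $P(\mathrm{Bin}(n, 1-d) \ge \lceil 0.9n \rceil)$ — a parameter-recovery
  test asserts this across 50 replicate seeds. Contamination is injected
  as foreign-species clusters at rate 0.02 per gene, which is what
  CheckM-style contamination percentages stand for downstream. Reported
  completeness is $100(1-d)$ (the estimator's expectation), so the
  qualifying-MAG count stays fixed and the binomial law exact.
* **Annotations**: the structure-based channel annotates 99% of clusters
  at the 0.2 threshold (uniform scores in [0.2, 1], plus sub-threshold
  noise rows), a quarter of them at mid-level only (less specific); the
  orthology channel annotates 12% with GO and 72% with descriptions; when
  both annotate, the orthology term equals the structure-based leaf with
  probability 0.7, else a different leaf of the same IC bin. The 99%/12%,
  72% and 0.7 rates are the reference dataset's printed coverages and
  mean concordance; community sizes (3 species, 10–14 MAGs each, 60-core
  and 80-accessory pools, 4 samples) are desk-scale choices made once.
* **Counts**: negative-binomial reads per centroid with mean proportional
  to gene length (no read-level simulation — alignment is out of scope),
  80% of a sample's total reads mapping.

What the generator does **not** emulate: real sequence homology (sequences
are decorative random nucleotides), phylogenetically realistic taxonomies,
read-level error models, and database-driven annotation biases. A green
test therefore establishes the correctness of the downstream computations
on inputs with the stated statistical structure — not the accuracy of any
upstream tool.

# Numerical choices and degenerate inputs

* Strict inequalities at every printed boundary (90.0 kept / 89.9
  dropped; 4.9 kept / 5.0 dropped; score 0.2 kept / 0.19 dropped; count
  2001 informative / 2000 not).
* Zero denominators are domain errors (all-zero counts, zero total
  reads), not NaNs; zero-abundance samples in `annotatedFraction()`
  report NA.
* Unknown GO ids in propagation: strict error by default, drop-with-
  warning behind a flag. Terms without IC: explicit "unbinned" bucket.
* Ties in Pearson correlation inputs (zero variance) report NA rather
  than an error, since the summary table remains useful.
* All readers are plain-text, header-driven where headers exist, with
  configurable column names for the count tables.

# Known limitations

* Semantic-similarity measures (Resnik/Lin), GO-slim mapping, and EC/KEGG
  ontologies are out of scope, as are the longitudinal mixed-effect models
  and rank tests on the emitted per-term CPM tables (standard fits users
  can run themselves on `functionAbundance()` output).
* The package has no opinion on which GO release to use; the toy ontology
  is versioned in code and any OBO file can be supplied.
* `informativeTerms()` recomputes descendant closures per candidate; fine
  for ontologies up to tens of thousands of terms, not optimized beyond
  that.
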