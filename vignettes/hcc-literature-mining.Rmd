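---
title: "Mining the HCC-metastasis literature: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining the HCC-metastasis literature: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hccmine)
```

`hccmine` quantifies what the hepatocellular carcinoma (HCC) metastasis
literature says about genes: how often each is discussed, how the HBV- and
HCV-driven literatures differ, which pathways the mined genes
over-represent, which proteins are interaction hubs, and which genes
co-occur in sentences with the classical steps of the metastatic cascade.
This vignette explains the model behind each stage, the parameters that
matter, and the design decisions taken where more than one reading was
defensible.

## The counting model

The unit of evidence is the **sentence**. Abstracts (MEDLINE flat file,
fields `PMID`, `TI`, `AB`) are segmented by a rule-based splitter:
a boundary is a run of `.?!` followed by whitespace and an uppercase letter
or digit, with an editable abbreviation list ("et al.", "Fig.", "e.g.",
"i.e.", "vs.", ...) suppressing false boundaries. A rule-based splitter was
chosen over a trained model because it is deterministic, auditable and
sufficient for abstract prose; the abbreviation list is a parameter
(`default_abbreviations()`), not a constant. The title is carried as one
additional sentence preceding the abstract: gene mentions in titles are
plainly part of the record, and nothing in the mined statistics
distinguishes them. This is an assumption — whether titles should be mined
at all is a judgement call, and excluding them only requires dropping
sentence index 0.

Every count in the pipeline follows one rule: **a gene contributes at most
once per sentence**, regardless of how many times its aliases occur there.
Gene frequency is therefore sentence incidence, and a gene–phenotype
co-occurrence is a sentence containing both tokens, counted once per pair
per sentence. The alternative — mention-level counting for frequencies and
sentence-level only for co-occurrence — would leave the pipeline with two
incompatible semantics for the same word "count"; we adopt the
once-per-sentence rule globally and state it prominently wherever counts
are reported.

## Dictionary gene recognition

Statistical taggers for gene names are not reproducible without their
training artifacts, and a mining study whose vocabulary is ultimately
normalized to official symbols is, in effect, operating over a closed
dictionary. Recognition is therefore dictionary matching against a lexicon
(`symbol`, `gene_id`, `description`, pipe-separated `aliases`):

* every canonical symbol is an alias of itself;
* aliases ambiguous across genes (after case folding) fail the lexicon
  load with line numbers — disambiguation is out of scope, so ambiguity is
  an input error, not a runtime guess;
* matches must start and end at word boundaries, where the hyphen counts
  as a word character: `E-cadherin` matches as a unit, and neither
  `proMMP2` nor `anti-E-cadherin` produces a match;
* overlapping candidates resolve leftmost-longest;
* aliases shorter than 4 characters match case-sensitively, longer ones
  case-insensitively. The cut at 4 is the standard precision guard for
  gene NER: it keeps `MET`, `AR`, `APP` from firing on common words while
  letting `e-cadherin` or `vegf-a` match in any case. It is a heuristic;
  a lexicon wanting different behaviour for a specific alias can encode
  the variants explicitly.

An illustrative lexicon for the HCC-metastasis gene space (37 genes with
the aliases one meets in that literature, e.g. E-cadherin/CDH1, FAK/PTK2,
CD147/BSG, p53/TP53) ships in `inst/extdata/hcc_lexicon.tsv`. It is a
demonstration vocabulary, not an authoritative one.

## Phenotype co-occurrence

The phenotype lexicon defaults to the five cascade keywords — metastasis,
adhesion, migration, invasion, angiogenesis. Matching is case-insensitive,
whole-word, on exact surface forms: "invasion" does not match "invasive".
Morphological expansion is deliberately not automatic — pure co-occurrence
mining has no negation or syntax handling, so widening the net silently
changes what a count means; users extend the `surface_forms` column
instead (the shipped list adds only the plural "metastases"). The
four-phenotype analyses (bipartite graph, clustering) exclude the generic
"metastasis" column by default: it anchors the corpus query rather than a
distinct cascade step.

`multi_phenotype_genes()` retains a gene when its co-occurrence count
reaches `min_freq` (default 7) on at least `min_phenotypes` (default 2)
distinct phenotypes. A phenotype only qualifies with a nonzero count, so
`min_freq = 0` degenerates to "any nonzero co-occurrence" rather than
"every gene".

## Frequencies, etiology arms, normalization

Rankings (`top_n()`, `degree_ranking()`) sort descending with
lexicographic tie-breaks — every ordering in the pipeline is
deterministic. The etiology comparison partitions the HBV- and HCV-mined
gene sets into shared and arm-specific sets, drops genes below
`min_freq = 5`, and rescales the smaller arm by the ratio of paper counts,
`normalization_factor()`, reported rounded to 3 decimals (262 vs 136
papers gives ×1.926). Rounding applies to the reported factor only;
callers needing full precision compute the raw ratio.

## Over-representation analysis

Pathway enrichment uses the classical one-sided hypergeometric test: for a
universe of $N$ symbols containing a set of size $K$, and a query of size
$n$ overlapping it in $k$, $p = P[X \ge k]$, $X \sim
\mathrm{Hypergeom}(N, K, n)$ (`stats::phyper`). Results are filtered on
**raw** $p \le 0.05$, matching common practice for this kind of screening
analysis; because no multiple-testing correction is applied at the filter,
Benjamini–Hochberg adjusted values are always computed and reported
alongside, so readers can judge the difference. The universe defaults to
the lexicon genes present in the collection: over-representation is
relative to the minable vocabulary, not to the whole genome.

A discreteness note that shaped the validation design: the hypergeometric
p-value is discrete, so under a null query $P(p \le 0.05)$ sits at the
largest achievable tail value below 0.05, not at 0.05 itself. With small
sets the gap is large and no calibration statement is meaningful. The
calibration-mode synthetic collection therefore uses large sizes (universe
5,000; 20 sets of 800–1,200; queries of 500) where the null distribution
of $p$ is fine-grained and the achieved level approaches the nominal one.
This choice follows from the granularity argument, not from any property
of the implementation.

## PPI network

Interaction data enter as a pre-exported TSV (`interactorA`,
`interactorB`, `source`, `evidence`); rows not marked experimental are
dropped, multiple sources supporting one pair collapse to a single
undirected edge. The network is **induced**: only edges with both
endpoints in the mined gene list survive, then self-loops and isolated
nodes are removed. Only degree centrality is computed — the hub analysis
this pipeline supports is degree-based, and degree is the number of
distinct partners, which the edge dedup makes well defined. The graph
machinery is igraph; the degree ranking is cross-checked in the tests
against a brute-force adjacency scan.

## Clustering

The heatmap stage normalizes each selected gene's co-occurrence row by
min–max to $[0,1]$ ("linear normalization"); constant rows map to zeros.
Per-row scaling is the default because it makes genes of very different
overall frequency comparable within a row — the question is the *profile*
across phenotypes, not the magnitude; a global min–max mode is available
(`linear_normalize(mode = "global")`) for magnitude-preserving displays.

Rows are clustered by complete ("maximum") linkage on Euclidean distance.
The agglomeration is implemented directly (naive $O(n^3)$, fine for the
tens-to-hundreds of genes this stage sees) because the dendrogram shape
under ties must be pinned down: among equally close cluster pairs the pair
whose lowest original row indices are lexicographically smallest merges
first, and within a merge the subtree holding the lower original index is
placed left. The result is a valid `hclust` object, and on tie-free random
matrices the tests verify cophenetic equivalence with
`stats::hclust(method = "complete")`. Columns (the four phenotypes) are
never clustered. Complete linkage is monotone, so merge heights are
non-decreasing — asserted in the property tests.

## Synthetic corpora and what the tests mean

No public corpus accompanies the pipeline, so the generators define the
study conditions. `generate_corpus()` embeds sampled gene aliases and
phenotype words into neutral template prose, one token per present entity
per sentence; sentence counts per abstract are uniform on 3–6; the demo
scale is 200 abstracts over a 20-gene vocabulary, which runs the full
pipeline in seconds. Ground truth (sentence incidence per gene, sentence
co-occurrence per pair, the designated multi-phenotype genes) is recorded
from the realized token placements during generation — not re-derived by
mining — so recovery tests are genuinely two-route. Planted pair rates in
the validation runs are 0.06 per sentence (expected counts ≈ 50 against a
threshold of 7) with a background mention rate of 0.01 (expected chance
co-occurrence below 1), so the selection margin is wide by design.
Templates avoid abbreviations, internal punctuation and any token that
collides with an alias or phenotype word, making ground-truth sentence
counts unambiguous.

What passing these tests shows: the mining arithmetic — segmentation,
matching, normalization, once-per-sentence counting, selection, ranking,
clustering — is exact on text whose structure is known. What it does not
show: performance on real abstracts, where alias ambiguity, unusual
punctuation, morphological variants and negation all occur. The generator
emulates none of those; conclusions about real-corpus recall or precision
require a curated benchmark, not this package's synthetic fixtures.

## Numerical and degenerate-input choices

* Empty corpora flow through: empty frequency tables, zero matrices,
  empty rankings, a pipeline manifest with explicit zeros.
* `hierarchical_cluster()` refuses fewer than 2 rows, naming the minimum;
  the pipeline skips clustering (and says so in the manifest) when fewer
  than 2 multi-phenotype genes survive selection.
* An all-zero phenotype column has no top gene rather than an arbitrary
  one.
* Lexicon ambiguity, duplicate GMT set names, and edge rows with fewer
  than two columns are load-time errors with line numbers; missing `AB`
  fields and out-of-universe symbols are warnings, not errors.
* GEXF output is version 1.2 with explicit edge weights, the dialect the
  common network visualization tools consume; exports are re-parsed in the
  tests to confirm lossless round-trips.
* All generators and the pipeline are pure functions of inputs + seed;
  rerun identity is asserted byte-for-byte.

## Validation scale

The test suite runs entirely on synthetic fixtures built in code: oracle
equivalence suites use ≥ 100 seeded instances per operation (sentences
≤ 200 characters, universes ≤ 12 for exhaustive hypergeometric
enumeration, matrices ≤ 12 rows, graphs ≤ 30 nodes); planted-signal
recovery uses 20 corpora of 200 abstracts; enrichment calibration uses
1,000 null replicates. These sizes were chosen to exercise every code path
at full statistical strength while keeping the default suite fast enough
to run on every change. The same computations, re-run from scratch, back
`scripts/acceptance.R`.

## Known limitations

* Dictionary NER cannot find genes absent from the lexicon, by design;
  recall is bounded by lexicon coverage.
* Co-occurrence is not relation extraction: "X did not affect invasion"
  counts. This matches the counting model's definition, and is the main
  reason counts should be read as attention, not as causal claims.
* Aliases shared by multiple genes are rejected rather than disambiguated.
* Only degree centrality is offered; betweenness/closeness hubs need a
  different tool.
* The corpus-size normalization is a single global ratio; it corrects for
  arm size, not for topical drift between arms.
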