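---
title: "Matching biomedical ontologies with multi-dimensional clues and reduction anchors"
author: "ontoMatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching biomedical ontologies with multi-dimensional clues and reduction anchors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoMatch)
```

## The matching model

An ontology is a triple set over concepts `C`, properties `R`, and
individuals `I`; `ontoMatch` parses RDF/XML and Turtle files into an
`OntologyGraph` holding these sets together with labels, synonyms,
comments, and the directed child-to-parent hierarchy (subclass edges,
plus any part-of style predicates the caller lists in
`hierarchyPredicates` — anatomy ontologies frequently encode the
salient structure in a part-of property rather than in subclass
axioms). An alignment is a set of correspondences `<e_i, e_j, r, s>`;
this package is restricted to one-to-one equivalence (`r` is always
`"="`), with `s` the similarity of the selected pair.

Matching proceeds in three steps: build per-concept *virtual documents*
in up to four clue dimensions, score concept pairs with a similarity
derived from those documents (optionally under a reduction driver that
skips pairs predicted ignorable), and extract a one-to-one alignment
from the combined similarity matrix by greedy descending-similarity
selection above a threshold.

### Clue dimensions and matcher presets

* **Terminological** — token bags of the local name (unless it is an
  opaque ID like `MA_0000216`; a name counts as ID-form when at least
  half its non-separator characters are digits, which covers the usual
  `PREFIX_digits` patterns without catching word names), labels,
  synonyms, and comments. Tokenization splits on non-alphanumerics and
  camelCase, lowercases, and drops a fixed 25-word closed-class stop
  list; no stemming is applied, because the intended lexica are noun
  phrases whose inflection is rare and meaningful ("bone" vs "bones"
  is noise, but "ossa" vs "osseous" is not a stemming problem).
* **Structural** — the terminological documents of the concept's
  context, always merged with its own document so that structure
  refines rather than replaces the lexical signal. Four modes:
  property attributes, direct neighbors (parents, children, siblings,
  disjoint concepts), the local *semantic subgraph* (radius-2 ball plus
  siblings — a configurable stand-in, since the extraction algorithm
  the idea originates from is not reproduced here), and the global
  transitive hierarchy with per-level decay `decay^depth` (default 0.5,
  capped at depth 5; deeper ancestors describe the concept less).
* **External** — expansion of the terminological document through a
  local synonym lexicon (TSV), the offline stand-in for WordNet /
  UBERON / UMLS services. The lexicon is reverse-closed at load time so
  lookups work in both directions; phrases are looked up whole first,
  then per token.
* **Representation learning** — a unit vector per concept, the mean of
  token embeddings over its labels and synonyms, compared by cosine.
  Providers are deterministic lookups: a plain-text word2vec file, or
  the seeded toy provider used in tests. Training or fine-tuning
  language models is out of scope; embedding similarity is always
  combined at the matrix level, never merged into token bags, because a
  dense vector has no meaningful union with a weighted bag.

Thirteen presets `M1`–`M13` (see `matcherPreset()`) fix the clue
selection: `M1` name-only; `M2`/`M3` label (+ synonym); `M4`–`M8`
label + synonym with the four structural modes (and their property +
direct combination); `M9`/`M10` with a general or domain lexicon;
`M11`–`M13` with an embedding provider. Document matchers score pairs
by cosine over TF-IDF vectors with `TF = w/W` and
`IDF = (1/2)(1 + log2(N/n))`, where the corpus `N` spans *both*
ontologies' documents of that dimension so that discriminativeness is
cross-ontology; the formula floors the weight of ubiquitous terms at
0.5 instead of zeroing them. The per-term TF-IDF products are
aggregated by cosine (the standard vector-space choice; the formula
itself does not dictate an aggregation). The name matcher uses the
normalized edit similarity `1 − DE/(DE + SE)`: read literally, the
printed normalized edit *distance* `DE/(DE+SE)` would assign identical
strings a score of 0, so the complement is used throughout, making 1
mean identity.

### Alignment extraction and evaluation

Greedy extraction scans pairs in descending similarity (ties broken
lexicographically by source then target identifier), keeping a pair
when both endpoints are unused and the similarity is at or above the
threshold. An exhaustive optimal-assignment mode exists behind
`method = "optimal"` for cross-checking on small matrices; on matrices
whose row/column maxima are unique the two coincide, and greedy
matches the "select the maximum similarity pairs" semantics the
matcher design implies. Evaluation is standard `p`, `r`, `F1` over
correspondence triples; confidences never affect the measures.
References loaded from cross-reference tables keep many-to-many
entries, since reference alignments are ground truth, not extractions.

## Reduction anchors

Exhaustive matching computes `n1 × n2` similarities. Two observations
prune this:

* **Hierarchy coherence (positive anchors).** If `S(a, b) > ptValue`,
  then descendants of `a` will not match ancestors of `b` and vice
  versa: the pairs `sub(a)×sup(b) ∪ sup(a)×sub(b)` are skipped. With
  `topK > 1` anchors per concept the skip set is the intersection of
  the per-anchor sets — the lattice least-upper/greatest-lower-bound
  construction collapses to exactly this intersection on a hierarchy —
  so keeping fewer anchors can only enlarge the reduction set.
* **Matching locality (negative anchors).** If `S(a, b) < ntValue`,
  the neighbors of `a` within graph distance `nScale` are predicted
  not to match `b` either. Three constraints temper this: anchors must
  come from *freshly computed* similarities (enforced structurally:
  skipped or extended entries never spawn anchors), propagation is
  limited to the concept's semantic subgraph (SSG), and a concept
  whose document has at most `tItems` distinct tokens propagates
  nothing (SDD) — sparse documents make unreliable witnesses.

Both anchor kinds are extended through intra-ontology *equivalent
concepts*: explicit equivalence axioms, plus concepts whose name
similarity reaches `eqValue`. The membership of this set is not
crisply defined in the matching literature; explicit-axiom ∪
name-similarity is this package's operationalization, and `eqValue`
above 1 disables it.

Three drivers accumulate the skips in one status mask per pair
(`computed`, `skipped_positive`, `skipped_negative`):

* `lomPE()` walks the source hierarchy in preorder. Each concept is
  probed first against the *promising* targets suggested by its
  parents' anchors (those targets and their children; target roots for
  source roots); only if no anchor emerges there is the full remaining
  row computed. A final sweep computes every pair still neither
  computed nor skipped, so the run is exhaustive-equivalent outside
  the reduction sets. On two isomorphic single-path taxonomies with
  exact labels this computes `3n − 2` similarities (each row costs one
  probe; the sweep adds the off-by-one diagonal pairs no anchor can
  cover) against the idealized `2n` of a pure anchor count — the
  difference is the price of guaranteeing every pair a status.
* `lomNE()` processes source concepts by descending degree (ties by
  identifier): high-degree concepts sit in the middle of the hierarchy
  and their rows seed the most propagation.
* `lomHybrid()` is the NE driver with PE bookkeeping embedded: every
  computed row contributes both anchor kinds.

The benefit rate `G = N/(n1·n2)` (skipped over total) measures the
saved work. Skipped pairs read as similarity 0 in the final matrix —
both skip kinds predict non-correspondence — and every pair the driver
*did* compute carries bitwise the exhaustive value: pair scores are
per-column dot products (`colSums`), so computing a row over a column
subset is numerically identical to computing it exhaustively (a plain
matrix product is not: BLAS blocking perturbs the last ulp when the
output shape changes).

### Choosing the matcher under reduction

Negative anchors assume locality: *if a neighbor of `a` scores low
against `b`, then `a` will too*. For bare label documents this is
false — a parent's label usually shares little with the child's match —
and negative propagation then suppresses true pairs. With
structure-enriched documents (`M5` and up), neighboring concepts share
context tokens with each other's matches and the assumption holds.
The pipeline therefore defaults to `M5` for reduced runs; reduction
over `M1`–`M3` is supported but will trade recall for speed. This
mirrors how anchor-based reduction is sensibly deployed: embedded in a
composite matcher, not a bare string comparison.

## Parameters at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` | 0.8 | extraction cut-off on combined similarity |
| `ptValue` | 0.8 | positive anchor threshold (strict `>`) |
| `ntValue` | 0.15 | negative anchor threshold (strict `<`) |
| `topK` | 2 | P-AnchorsE kept per concept (1–4) |
| `nScale` | 3 | negative propagation radius (graph distance) |
| `tItems` | 4 | SDD: document must exceed this many tokens |
| `eqValue` | 0.95 | intra-ontology equivalence name similarity |
| `decay` | 0.5 | global-hierarchy per-level weight decay |

`ptValue`/`ntValue`/`nScale` defaults are the recommended operating
point of the anchor design; sweeping `ntValue` upward raises `G` at a
gradual cost in F1, raising `nScale` does the same more aggressively,
and enabling SSG + SDD recovers quality for a modest `G` cost — the
trend checks in `tests/testthat/test-acceptance.R` verify these
directions on the synthetic suite (five seeds, 120-concept pairs; the
`nScale` sweep is run with SSG off, since SSG caps the effective
radius at the subgraph radius 2 and would flatten it).

## The synthetic study pairs

`generateOntologyPair()` builds a source taxonomy (chain, tree, or
DAG) over a compositional vocabulary of anatomical-flavored modifiers
and head nouns; subtrees inherit their head noun with high probability,
so structural neighbors are lexically related the way "hindlimb bone"
and "foot bone" are. Concepts carry up to two internal synonyms
(anatomical thesauri list several name variants per concept), drawn by
substituting a token with its lexicon alias. The target is derived by
label perturbation (alias substitution, token reorder, case change),
ID-ification of a fraction of local names, and structural edits (node
deletion with re-parenting, same-depth parent swaps). The reference
alignment is the identity on surviving concepts; the emitted lexicon
doubles as the external-matcher resource and as cross-references.

Default rates — 200 concepts, branching 3, synonym rate 0.6, label
perturbation 0.25, structural perturbation 0.05, ID fraction 0.5 —
emulate a mid-sized anatomy-style task: ID local names with rich
labels and synonyms, moderate lexical divergence, light structural
divergence. What the generator does **not** emulate: the extreme label
multiplicity and cross-domain vocabulary clashes of clinical-scale
terminologies, non-taxonomic axioms, and real synonym distributions.
Passing the suite therefore demonstrates the mechanics (soundness of
skipping, trend directions, formula correctness) at desk scale, not
benchmark-level quality on public evaluation tracks, whose inputs are
external downloads and out of scope here. The acceptance script runs
ten 200-concept pairs, a 50-concept chain, and a 60-concept identity
pair — sizes chosen so a full from-scratch run stays comfortably under
a minute on one CPU while keeping the reduction statistics stable
across seeds.

## Numerical and degenerate-input choices

* Two empty strings have edit similarity 1; empty documents have
  cosine 0 against everything; a fully out-of-vocabulary concept gets
  the zero embedding vector and similarity 0.
* Similarity matrices are dense (values + integer status); the package
  targets desk-scale ontologies where `n1·n2` doubles fit trivially in
  memory and the status mask needs that footprint anyway.
* Greedy ties break lexicographically by (source, target) identifier;
  driver orders break degree ties by identifier — all orderings are
  total, making every run byte-deterministic for a fixed configuration.
* Subclass cycles are rejected at graph construction (the hierarchy
  must be a DAG); blank-node parents are resolved by recursive
  traversal to the nearest named class, keeping a restriction edge only
  when its property is configured as hierarchical.
* The equivalence-set detection pools all labels and word-form local
  names and computes one vectorized cross-similarity per ontology —
  quadratic in the label count, which is fine at the intended scale.

## Known limitations

* OWL reasoning, OBO flat files, instance matching, and n:m
  correspondences are out of scope.
* The Turtle reader covers the dialect OWL tools emit (prefixes,
  `a`, `;`/`,` lists, quoted literals, anonymous restriction nodes) —
  not the full Turtle grammar (no multiline literals, collections, or
  bare decimal terms).
* The optimal extraction mode is exhaustive and guarded to matrices
  with a side of at most 8; it exists for verification, not production.
* Hybrid combination weights are user-supplied (default equal); no
  weight learning is attempted.
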