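---
title: "Measuring what formal axioms contribute: methods and design"
author: "ontoablate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring what formal axioms contribute: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoablate)
```

## The question this package answers

Biomedical ontologies are no longer bare term hierarchies: they carry
formal axioms — existential restrictions, equivalence definitions,
disjointness constraints — that link classes within and across
ontologies, and they carry meta-data (labels, synonyms, definitions)
written for humans.  The Gene Ontology's axiom-enriched edition, for
example, contains tens of thousands of axioms pointing into chemical,
phenotype, anatomy and cell ontologies.  Two biological-process classes
can be unrelated in the subclass hierarchy yet both restricted onto the
same chemical class (the classic example: two histidine/formamide
metabolism processes that meet only at the chemical entity *formamide*).

`ontoablate` measures whether that formal content earns its keep in a
concrete prediction task.  The design is a controlled ablation: the
biological data — entity annotations, positive interaction pairs, the
train/test split — are held byte-identical while only the background
ontology changes (base hierarchy; base plus inter-ontology axioms; plus
the external ontologies' own axioms; plus meta-data).  Any change in
test AUC is then attributable to the ontology content alone.

## Pipeline

Each variant runs the same five stages:

1. **Assemble** the ontology (`parse_ontology()`,
   `restrict_to_namespace_links()`, `merge_or_substitute()`).
2. **Saturate** (`saturate()`): an EL-style structural closure adds
   inferred axioms — equivalences expand into subclass conjuncts, the
   named-class hierarchy closes under transitivity, and existential
   fillers are lifted along that closed hierarchy
   (`A SubClassOf R some B` and `B SubClassOf C` yield
   `A SubClassOf R some C`).  The rule set deliberately stays inside a
   fragment that terminates without deepening expressions; it captures
   the hierarchy-completion effect that matters for co-occurrence
   statistics, and does not claim equivalence with any complete
   description-logic reasoner.  Disjointness axioms pass through
   untouched: downstream stages only consume co-occurrence structure,
   so unsatisfiability propagation would add nothing.
3. **Encode** as sentences: one sentence per axiom (its token
   serialization) and one `(entity, hasAssociation, class)` sentence
   per annotation; optionally one sentence per meta-data assertion
   (subject, property keyword, tokenized text); or, alternatively,
   biased random walks over the relational-pattern graph.
4. **Embed** with skip-gram and negative sampling
   (`train_embeddings()`).
5. **Score and evaluate**: cosine similarity between entity vectors, or
   a feed-forward network on concatenated pair vectors; rank-based
   ROC/AUC with a Mann–Whitney or bootstrap comparison between
   variants.

```{r tiny-example}
f <- tempfile()
writeLines(c("GO:0019556 SubClassOf has_participant some CHEBI:16397",
             "GO:0043606 SubClassOf has_participant some CHEBI:16397"), f)
o <- saturate(parse_ontology(f, format = "axiom-lines"))
ann <- data.frame(entity = c("P1", "P2"),
                  class = c("GO:0019556", "GO:0043606"),
                  evidence = NA_character_)
str(unclass(build_logical_corpus(o, ann)))
```

## Representation choices

**Tokens.** Classes are CURIEs everywhere — corpus token, graph node and
embedding row are the same string — and relations may be bare
identifiers.  Entity identifiers must not contain `:` (the `ENT:`
prefix is reserved) so entity and class tokens can never collide.

**Canonical form.** Axioms are identified by (subject, kind, canonical
object serialization); conjuncts are sorted lexicographically and `some`
binds tighter than `and`.  Sets of axioms are stored sorted and
deduplicated, which makes parsing order-independent, makes corpora
bit-identical across runs, and gives merge/union idempotence for free.
When an asserted and an inferred copy of the same axiom meet, the
asserted provenance wins.

**Referencing an external ontology** is decided purely by CURIE prefix:
`restrict_to_namespace_links()` keeps an axiom iff the prefixes of all
classes it mentions lie in `{base, external}`.  Identifier spaces are
how biomedical ontologies are in fact distinguished.

**Graph compilation** follows the relational-pattern reading: only
axioms mentioning exactly two named classes produce edges
(`X SubClassOf Y`, `X SubClassOf R some Y`, equivalences in both
directions, disjointness, plus one edge per annotation).  Walks ignore
edge direction: pure forward traversal dead-ends at ontology roots and
would starve leaf classes of context.  Edge labels are stored and
exported but do not enter walk sentences — the corpus is a
node-sequence corpus.  Parallel edges collapse to one adjacency entry
so duplicated axioms cannot silently reweight a class.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `skipgram_params(dimension)` | 200 | vector width for realistic corpora |
| `window` | 5 | corpus sentences are short; 5 spans them |
| `min_count` | 1 | every entity/class must receive a vector; missing tokens error downstream |
| `negative_samples` | 5 | standard skip-gram negative sampling |
| `epochs` | 10 | passes over the corpus |
| `sample` | 1e-3 | frequent-word subsampling; see below |
| `walk_params(p, q)` | 1, 1 | second-order walk biases; unbiased by default |
| `walk_length`, `walks_per_node` | 20, 10 | standard walk corpus size |
| `nn_config(hidden)` | 800, 200 | the evaluated two-hidden-layer architecture |
| `learning_rate`, `batch_size`, `epochs` | 1e-3, 64, 20 | fixed defaults for reproducibility (ReLU, Adam, binary cross-entropy) |
| `build_pair_dataset(negative_ratio)` | 1 | one uniform non-edge negative per positive |
| `split_fraction` | 0.7 | pair-level 70/30 split, no cross-validation |

Frequent-word subsampling deserves a note: axiom sentences repeat the
keywords `SubClassOf`, `some`, `and` and the annotation-relation token
in almost every sentence (roughly a third of all corpus tokens).
Without word2vec's standard subsampling these tokens dominate both the
positive updates and the negative-sampling table, and the informative
class–class co-occurrences are barely learnable.  An occurrence of a
token with corpus share `f` is kept with probability
`(sqrt(f/s) + 1) * s / f` (`s = sample`).

For study-scale corpora (around 10^4 tokens, as produced by the
synthetic generator) the realistic-corpus defaults are mis-sized:
`study_embedding_params()` uses dimension 50, 150 epochs and 10
negative samples, reflecting that small corpora need smaller models and
many more passes.  All of the package's own synthetic experiments use
these settings.

## Decisions where the design was genuinely open

* **Annotation linking token**: the corpus needs a consistent
  vocabulary item, nothing more; it defaults to `hasAssociation`.
* **Meta-data properties**: labels, synonyms and definitions are
  encoded by default; comments are opt-in.  Meta-data text is
  lowercased and split only on whitespace and `.,;()[]{}"`, keeping
  colons so CURIEs and chemistry-style tokens survive intact —
  aggressive splitting would worsen exactly the symbol-heavy-label
  noise that chemical ontologies are known for.
* **Background text**: supported as a user-supplied plain-text file,
  either appended as extra sentences (default) or used for two-phase
  training via the `init` warm-start of `train_embeddings()`.
  Literature-scale pre-training is out of scope.
* **Pair symmetry in the network**: interactions are unordered, so
  every training pair is presented in both orders and inference
  averages the two order scores; scores are then order-invariant to
  numerical precision.
* **Negatives**: sampled uniformly from unordered non-edges at ratio 1
  by default — the standard protocol for interaction link prediction;
  the ratio is configurable for sensitivity checks.
* **Split**: at pair level, so an entity may occur in both splits;
  this mirrors the evaluation procedure the package implements.  An
  entity-disjoint mode exists for stricter generalization estimates.
* **What the significance test compares**: both readings are
  implemented — a Mann–Whitney U test between the two models' scores
  on the positive pairs, and a paired bootstrap over pairs for the AUC
  difference — and every report names the method used.  Raw p-values
  are reported by default, with an opt-in Benjamini–Hochberg
  adjustment across ablation rows.
* **Per-variant retraining**: embeddings are always retrained from
  scratch per ontology variant (the corpus changes with the ontology),
  and the network is refit per variant with fresh initialization.

## Numerical choices

* AUC uses the rank statistic with half-credit ties,
  `(#{s+ > s-} + 0.5 #{s+ = s-}) / (n+ n-)`; the Mann–Whitney U shares
  the same tie convention, so `U/(n_a n_b)` is exactly the AUC of the
  merged labeled sample.
* The U test switches from the exact null distribution (used when
  `n_a * n_b <= 400` and no ties are present) to a normal approximation
  with tie and continuity correction.
* Embedding training is single-threaded with an internal deterministic
  RNG: fixed seed implies bit-identical vectors.  Walks, negative
  sampling, splits and network fits restore the R RNG state and are
  likewise bit-identical per seed.  Corpus construction is
  deterministic unconditionally.
* Vectors persist in the word2vec text format with 17 significant
  digits, so a save/load round trip is exact to float precision.
* Degenerate inputs fail loudly: empty corpora, single-class label
  vectors, missing or zero embedding vectors, and malformed files all
  raise errors naming the offending token, row or line.

## The synthetic generator

`generate_study()` builds a self-contained study with the causal
structure that makes inter-ontology axioms valuable:

* a primary ontology (random rooted tree, 120 classes by default) and a
  small external ontology (8 classes);
* `n_modules = 8` functional modules of `module_size = 6` leaves each,
  deliberately dealt round-robin across different root branches, so
  module-mates are *distant* in the primary hierarchy;
* bridge axioms `leaf SubClassOf related_to some EXT:k` emitted with
  probability `rho = 0.9` per module member — the only place module
  membership is visible;
* 300 entities, each annotated with one leaf of its home module plus
  two noise leaves drawn from the module-free leaf pool;
* unordered entity pairs interact with probability `pi1 = 0.35` when
  their annotations reach a common external class through bridges, and
  `pi0 = 0.03` otherwise.  `pi0 > 0` keeps the task noisy and AUC
  meaningfully below 1.

Two generator choices matter and were fixed at design time.  First,
modules occupy a *subset* of the leaves and each entity carries exactly
one module leaf: if every leaf were a module member and entities drew
all three annotations from their module, same-module entities would
almost always share an identical annotation leaf, and the base
ontology would already expose the module signal that the bridge axioms
are supposed to carry.  Second, interaction labels are generated from
the bridge structure recorded in `truth.json`, never from the files a
pipeline later chooses to read — withholding `bridge.axioms` from a run
cannot change the positive-pair file, which is precisely the
fixed-data/varying-background contract.

`plant_metadata()` adds the meta-data analogue: with the signal on,
module members' labels share a module-specific marker word among noise
words from a common vocabulary; with the signal off, all label words
are noise and no word is module-predictive.

What the generator does **not** emulate: realistic ontology topology
or annotation-depth distributions, interaction-score semantics of real
protein networks, evidence-code biases, or the scale of real corpora.
A passing ablation here demonstrates that the pipeline recovers a
planted axiom-mediated signal through the intended mechanism — it does
not predict effect sizes on real ontologies.

## Problem sizes used in the shipped experiments

The test suite and the acceptance script run the synthetic study at its
default configuration (300 entities, ~45 000 candidate pairs, ~2 800
positives) over 8–10 seeds per experiment, with
`study_embedding_params()` for the embedding stage; oracle equivalence
checks use 100–200 random instances of up to 500 scores or 30 classes /
60 axioms; the network benchmark uses 80 entities in 50 dimensions.

## Known limitations

* The saturation fragment omits disjointness reasoning, cardinality,
  unions and property chains; unsupported OWL constructs are skipped
  with a warning and counted in the parse report.
* OBO writing is restricted to the fragment the package models;
  inexpressible axioms are skipped with a warning (the axiom-lines
  format is lossless for logical content but carries no metadata).
* Embedding quality on very small corpora is noisy; sentence-order
  permutation changes individual vectors (only the downstream AUC is
  stable, and only within a tolerance).
* The network's leakage canary has irreducible seed-to-seed variance:
  with permuted train labels an overparameterized net can ride chance
  correlations between label noise and the (real) cluster feature, so
  the canary is assessed as a mean over seeds on a benchmark sized to
  keep that variance small.
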