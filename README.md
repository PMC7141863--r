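# ontoablate

Quantifying what the formal axioms and meta-data of biomedical
ontologies contribute to prediction tasks.

## The problem

Ontologies such as the Gene Ontology carry, beyond their subclass
hierarchy, formal axioms — existential restrictions
(`X SubClassOf: R some Y`), equivalence definitions, disjointness —
that link classes within and across ontologies, plus human-readable
meta-data (labels, synonyms, definitions).  Inter-ontology axioms can
relate classes that are distant in the hierarchy: two metabolic-process
classes may meet only at a shared chemical class in a chemistry
ontology.  Do those axioms actually improve ontology-based analysis,
for example predicting protein–protein interactions from functional
annotations, or gene–disease associations from phenotypes?

`ontoablate` answers this with a controlled ablation.  Entities (e.g.
proteins) are embedded by training skip-gram on a corpus built from the
ontology's axioms (asserted plus inferred) and the entity–class
annotations — optionally extended with meta-data sentences, or replaced
by Node2Vec-style biased random walks over the relational-pattern
graph.  Entity pairs are scored by cosine similarity or by a
feed-forward network (two hidden layers of 800 and 200 units, sigmoid
output, binary cross-entropy, 70/30 pair split).  Performance is the
rank-based AUC, `(#{s⁺ > s⁻} + ½#{s⁺ = s⁻}) / (n⁺ n⁻)`, with
Mann–Whitney-U or paired-bootstrap comparisons between variants.
Across variants, the annotations, positive pairs and train/test split
stay byte-identical; only the background ontology changes — so AUC
differences measure exactly the contribution of the added axioms or
meta-data.

Because real ontology/interaction snapshots are large and
version-dependent, the package also ships a synthetic-study generator
that plants an interaction signal reachable *only* through
inter-ontology bridge axioms, making every pipeline stage — and the
qualitative headline claim — testable offline.

## Worked example

```r
library(ontoablate)

# a synthetic study: primary ontology, external ontology, bridge
# axioms, annotations, positive pairs, generator truth
cfg <- synth_config(seed = 1)
st <- generate_study(cfg, "study")

base <- parse_ontology(st$paths$primary, format = "obo")
plus <- merge_or_substitute(base,
          parse_ontology(st$paths$bridge, format = "axiom-lines"))
plus <- merge_or_substitute(plus,
          parse_ontology(st$paths$external, format = "obo"))
base
#> <OntologySet> 119 axioms (0 inferred), 120 metadata assertions, prefixes: PRI
saturate(plus)
#> <OntologySet> 507 axioms (336 inferred), 120 metadata assertions, prefixes: EXT, PRI

ann <- read_annotations(st$paths$annotations, dialect = "tsv")
pos <- read_positive_pairs(st$paths$positives)
d <- build_pair_dataset(pos, unique(ann$entity), seed = 1001)
nrow(d); sum(d$split == "test")
#> [1] 5944
#> [1] 1784

for (v in c("base", "plus")) {
  o <- if (v == "base") base else plus
  r <- evaluate_variant(o, ann, d, encoder = "axiom-corpus",
                        scorer = "cosine",
                        embedding = study_embedding_params(501))
  cat(v, "AUC:", round(r$auc, 4), "\n")
}
#> base AUC: 0.5381
#> plus AUC: 0.6117
```

The base hierarchy alone barely beats chance — the interacting modules
are scattered across its branches by construction.  Adding the ~100
bridge axioms (and the 7-axiom external hierarchy) lifts the test AUC
by about 0.07: the embedding now places entities annotated to classes
that share an external bridge target near each other, which is the
mechanism by which inter-ontology axioms carry background knowledge.
`run_experiment()` wraps this loop (variants `base`, `plus`,
`plus-ns:<PREFIX>`, `plus-external`, `plus-metadata`,
`substitute:<PREFIX>`) and emits a TSV report with per-variant AUC and
delta/p-value against base.  A thin CLI over the same functions lives
at `inst/cli/ontoablate.R` (subcommands `parse`, `saturate`, `corpus`,
`graph`, `walks`, `embed`, `pairs`, `score`, `eval`, `ablate`,
`simulate`).

See the vignette `vignettes/axiom-ablation.Rmd` for the model,
parameter and design rationale.

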