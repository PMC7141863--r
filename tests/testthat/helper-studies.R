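# Shared pipeline shortcuts for tests that run the synthetic study.

load_study <- function(cfg) {
  st <- generate_study(cfg)
  base <- parse_ontology(st$paths$primary, format = "obo")
  plus <- merge_or_substitute(
    base, parse_ontology(st$paths$bridge, format = "axiom-lines"))
  plus <- merge_or_substitute(
    plus, parse_ontology(st$paths$external, format = "obo"))
  ann <- read_annotations(st$paths$annotations, dialect = "tsv")
  pos <- read_positive_pairs(st$paths$positives)
  dataset <- build_pair_dataset(pos, unique(ann$entity),
                                seed = cfg$seed + 1000L)
  list(study = st, base = base, plus = plus, ann = ann, dataset = dataset)
}

study_auc <- function(sl, which = c("base", "plus"), encoder = "axiom-corpus",
                      emb_seed = 1L) {
  which <- match.arg(which)
  evaluate_variant(sl[[which]], sl$ann, sl$dataset, encoder = encoder,
                   scorer = "cosine",
                   embedding = study_embedding_params(emb_seed))$auc
}

# small ready-made ontology used across tests
tiny_ontology <- function() {
  ontology_set(list(
    axiom("SubClassOf", "GO:0019556", ce_some("has_participant", "CHEBI:16397")),
    axiom("SubClassOf", "GO:0043606", ce_some("has_participant", "CHEBI:16397")),
    axiom("SubClassOf", "GO:0019556", "GO:0006547"),
    axiom("SubClassOf", "GO:0043606", "GO:0043603"),
    axiom("SubClassOf", "GO:0006547", "GO:0008150"),
    axiom("SubClassOf", "GO:0043603", "GO:0008150")))
}
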