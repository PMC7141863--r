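# Annotation reading with evidence filtering, and the two sentence
# corpora (logical axioms + annotations; class meta-data).

test_that("evidence-code filtering drops excluded assertions", {
  f <- tempfile()
  writeLines(c("P1\tGO:1\tIEA", "P2\tGO:2\tEXP", "P3\tGO:3"), f)
  ann <- read_annotations(f, dialect = "tsv", excluded_evidence = "IEA")
  expect_equal(nrow(ann), 2L)
  expect_setequal(ann$entity, c("P2", "P3"))
  # vacuous filter keeps everything
  expect_equal(nrow(read_annotations(f, dialect = "tsv")), 3L)
})

test_that("GAF dialect reads columns 2/5/7 and skips comments", {
  gaf_row <- function(e, cls, ev) {
    paste(c("DB", e, "SYM", "", cls, "REF", ev, "", "P", "", "", "protein",
            "taxon:9606", "20240101", "DB"), collapse = "\t")
  }
  f <- tempfile()
  writeLines(c("!gaf-version: 2.1",
               gaf_row("P1", "GO:0019556", "IEA"),
               gaf_row("P2", "GO:0043606", "EXP")), f)
  ann <- read_annotations(f, dialect = "gaf", excluded_evidence = "IEA")
  expect_equal(ann$entity, "P2")
  expect_equal(ann$class, "GO:0043606")
  expect_equal(ann$evidence, "EXP")
})

test_that("annotation row counts match a brute-force scan on random input", {
  withr::with_seed(11, {
    ev_pool <- c("IEA", "EXP", "IDA", "")
    rows <- replicate(50, sprintf("P%d\tGO:%d\t%s", sample(20, 1),
                                  sample(30, 1), sample(ev_pool, 1)))
    f <- tempfile()
    writeLines(rows, f)
    ann <- read_annotations(f, dialect = "tsv", excluded_evidence = "IEA")
    parts <- strsplit(rows, "\t")
    kept <- unique(t(sapply(parts, function(p) c(p[1], p[2],
                                                 if (length(p) > 2) p[3] else ""))))
    kept <- kept[kept[, 3] != "IEA", , drop = FALSE]
    expect_equal(nrow(ann), nrow(kept))
  })
})

test_that("missing entity or class errors with the line number", {
  f <- tempfile()
  writeLines(c("P1\tGO:1", "\tGO:2"), f)
  expect_error(read_annotations(f, dialect = "tsv"), "line 2")
})

test_that("entity identifiers must not collide with the CURIE space", {
  f <- tempfile()
  writeLines(c("X:9\tGO:1"), f)
  expect_error(read_annotations(f, dialect = "tsv"), "ENT")
  writeLines(c("ENT:9\tGO:1"), f)
  expect_equal(read_annotations(f, dialect = "tsv")$entity, "ENT:9")
})

test_that("logical corpus serializes axioms and annotations as sentences", {
  o <- ontology_set(list(axiom("SubClassOf", "GO:0019556",
                               ce_some("has_participant", "CHEBI:16397"))))
  ann <- data.frame(entity = "P1", class = "GO:0019556",
                    evidence = NA_character_)
  cp <- build_logical_corpus(o, ann)
  expect_length(cp, 2L)
  expect_equal(cp[[1]], c("GO:0019556", "SubClassOf", "has_participant",
                          "some", "CHEBI:16397"))
  expect_equal(cp[[2]], c("P1", "hasAssociation", "GO:0019556"))
})

test_that("single annotation with empty ontology gives one 3-token sentence", {
  cp <- build_logical_corpus(ontology_set(),
                             data.frame(entity = "P1", class = "GO:1",
                                        evidence = NA_character_))
  expect_length(cp, 1L)
  expect_length(cp[[1]], 3L)
})

test_that("sentence count is |axioms| + |annotation pairs| and is stable", {
  withr::with_seed(5, {
    for (i in 1:5) {
      descs <- random_ontology_descs(10, sample(5:25, 1))
      o <- ontology_set(lapply(descs, desc_to_axiom))
      n_ann <- sample(3:12, 1)
      ann <- unique(data.frame(entity = sprintf("P%d", sample(6, n_ann, TRUE)),
                               class = sprintf("T:%d", sample(10, n_ann, TRUE)),
                               evidence = NA_character_))
      cp <- build_logical_corpus(o, ann)
      expect_length(cp, n_axioms(o) + nrow(ann))
      expect_identical(cp, build_logical_corpus(o, ann))  # bit-identical
    }
  })
})

test_that("metadata corpus tokenizes the class-name example", {
  md <- data.frame(subject = "GO:0019556", property = "label",
                   text = "Histidine catabolic process to glutamate and formamide")
  o <- ontology_set(metadata = md)
  cp <- build_metadata_corpus(o)
  expect_length(cp, 1L)
  expect_equal(cp[[1]], c("GO:0019556", "label", "histidine", "catabolic",
                          "process", "to", "glutamate", "and", "formamide"))
})

test_that("empty property selection yields an empty corpus", {
  md <- data.frame(subject = "A:1", property = "label", text = "alpha")
  expect_length(build_metadata_corpus(ontology_set(metadata = md),
                                      properties = character()), 0L)
})

test_that("metadata tokens match an independent character-walk tokenizer", {
  texts <- c("Histidine catabolic process (GO:0019556).",
             '15-HETE; "(5Z,8Z)-acid" [formula C20H32O3]',
             "a,b;c{d}(e) CHEBI:16397 end.")
  md <- data.frame(subject = sprintf("A:%d", seq_along(texts)),
                   property = "definition", text = texts)
  cp <- build_metadata_corpus(ontology_set(metadata = md),
                              properties = "definition")
  got <- sort(unlist(lapply(cp, function(s) s[-(1:2)])))
  want <- sort(unlist(lapply(texts, oracle_tokenize)))
  expect_equal(got, want)
})

test_that("corpus text round-trips through write/read", {
  cp <- corpus(list(c("A:1", "SubClassOf", "A:2"), c("P1", "x", "GO:1")))
  f <- tempfile()
  write_corpus(cp, f)
  expect_identical(unclass(read_corpus(f)), unclass(cp))
})

test_that("background text becomes tokenized sentences", {
  f <- tempfile()
  writeLines(c("Histidine catabolism yields formamide.", ""), f)
  bg <- read_background_text(f)
  expect_length(bg, 1L)
  expect_equal(bg[[1]], c("histidine", "catabolism", "yields", "formamide"))
  joint <- corpus_append(bg, corpus(list(c("a", "b"))))
  expect_length(joint, 2L)
})
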