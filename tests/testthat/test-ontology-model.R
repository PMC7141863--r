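# Parsing, canonicalization, writing, namespace restriction and
# merge/substitution of ontology axiom sets.

write_tmp <- function(lines, ext = ".axioms") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("axiom-lines parsing handles the cross-ontology existential motif", {
  o <- parse_ontology(write_tmp(
    "GO:0019556 SubClassOf has_participant some CHEBI:16397"),
    format = "axiom-lines")
  expect_equal(n_axioms(o), 1L)
  ax <- o$axioms
  expect_equal(ax$kind, "SubClassOf")
  expect_equal(ax$subject, "GO:0019556")
  expect_equal(ax$object[[1]]$type, "some")
  expect_equal(ax$object[[1]]$rel, "has_participant")
  expect_equal(ax$object[[1]]$filler$id, "CHEBI:16397")
  expect_equal(ax$origin, "asserted")
  expect_setequal(o$prefixes, c("GO", "CHEBI"))
})

test_that("empty input yields an empty ontology set", {
  o <- parse_ontology(write_tmp(character(0)), format = "axiom-lines")
  expect_equal(n_axioms(o), 0L)
  expect_equal(nrow(o$metadata), 0L)
})

test_that("parse order does not affect the resulting set", {
  lines <- c("A:1 SubClassOf A:2",
             "B:1 EquivalentTo ( A:2 and r some A:1 )",
             "A:2 DisjointWith B:2")
  o1 <- parse_ontology(write_tmp(lines), format = "axiom-lines", source = "x")
  o2 <- parse_ontology(write_tmp(rev(lines)), format = "axiom-lines",
                       source = "x")
  expect_identical(o1$axioms$obj, o2$axioms$obj)
  expect_identical(o1$axioms$subject, o2$axioms$subject)
})

test_that("conjunctions are canonicalized and duplicates removed", {
  o <- parse_ontology(write_tmp(c(
    "B:1 EquivalentTo A:2 and A:1",
    "B:1 EquivalentTo A:1 and A:2",
    "B:1 EquivalentTo ( A:1 and A:2 )")), format = "axiom-lines")
  expect_equal(n_axioms(o), 1L)
  expect_equal(o$axioms$obj, "A:1 and A:2")
})

test_that("some binds tighter than and; parentheses override", {
  o <- parse_ontology(write_tmp(c(
    "X:1 SubClassOf r some A:1 and A:2",
    "X:2 SubClassOf r some ( A:1 and A:2 )")), format = "axiom-lines")
  ob1 <- o$axioms$object[[match("X:1", o$axioms$subject)]]
  ob2 <- o$axioms$object[[match("X:2", o$axioms$subject)]]
  expect_equal(ob1$type, "and")
  expect_equal(ob2$type, "some")
  expect_equal(ob2$filler$type, "and")
})

test_that("malformed axiom lines report their line number", {
  expect_error(parse_ontology(write_tmp(c("A:1 SubClassOf A:2",
                                          "A:3 BogusKind A:4")),
                              format = "axiom-lines"), "line 2")
  expect_error(parse_ontology(write_tmp("A:1 SubClassOf ( A:2"),
                              format = "axiom-lines"), "line 1")
  expect_error(parse_ontology(write_tmp("A:1 DisjointWith r some A:2"),
                              format = "axiom-lines"), "line 1")
})

test_that("OBO term stanzas map to axioms and metadata", {
  f <- write_tmp(c("format-version: 1.4", "",
                   "[Term]", "id: A:1", "name: alpha", "is_a: A:2",
                   'synonym: "first letter" EXACT []',
                   'def: "the first term" []',
                   "relationship: part_of A:3",
                   "disjoint_from: A:4", "",
                   "[Term]", "id: A:5",
                   "intersection_of: A:2",
                   "intersection_of: part_of A:3"), ext = ".obo")
  o <- parse_ontology(f, format = "obo")
  expect_equal(n_axioms(o), 4L)
  keys <- paste(o$axioms$subject, o$axioms$kind, o$axioms$obj)
  expect_setequal(keys, c("A:1 SubClassOf A:2",
                          "A:1 SubClassOf part_of some A:3",
                          "A:1 DisjointWith A:4",
                          "A:5 EquivalentTo A:2 and part_of some A:3"))
  expect_setequal(o$metadata$property, c("label", "synonym", "definition"))
  expect_true("first letter" %in% o$metadata$text)
})

test_that("OBO round trip reproduces the identical set", {
  md <- data.frame(subject = c("A:1", "A:1", "A:5"),
                   property = c("label", "synonym", "definition"),
                   text = c("alpha", "first letter", "a defined term"))
  o <- ontology_set(list(
    axiom("SubClassOf", "A:1", "A:2"),
    axiom("SubClassOf", "A:1", ce_some("part_of", "A:3")),
    axiom("DisjointWith", "A:1", "A:4"),
    axiom("EquivalentTo", "A:5",
          ce_and(list(ce_class("A:2"), ce_some("part_of", "A:3"))))),
    metadata = md)
  f <- tempfile(fileext = ".obo")
  write_ontology(o, f, format = "obo")
  o2 <- parse_ontology(f, format = "obo")
  expect_identical(o$axioms$obj, o2$axioms$obj)
  expect_identical(o$axioms$subject, o2$axioms$subject)
  expect_identical(o$metadata, o2$metadata)
  # fixpoint: writing the re-parsed set changes nothing
  f2 <- tempfile(fileext = ".obo")
  write_ontology(o2, f2, format = "obo")
  expect_identical(readLines(f), readLines(f2))
})

test_that("axiom-lines round trip is a fixpoint", {
  lines <- c("A:1 SubClassOf A:2",
             "B:1 EquivalentTo A:2 and r some ( A:1 and A:3 )",
             "A:2 DisjointWith B:2")
  o <- parse_ontology(write_tmp(lines), format = "axiom-lines")
  f <- tempfile()
  write_ontology(o, f, format = "axiom-lines")
  o2 <- parse_ontology(f, format = "axiom-lines")
  expect_identical(o$axioms$obj, o2$axioms$obj)
})

test_that("namespace restriction keeps base-internal plus one external link", {
  o <- parse_ontology(write_tmp(c(
    "GO:1 SubClassOf GO:2",
    "GO:1 SubClassOf has_participant some CHEBI:16397",
    "GO:2 SubClassOf part_of some PATO:1")), format = "axiom-lines")
  r <- restrict_to_namespace_links(o, "CHEBI", "GO")
  expect_equal(n_axioms(r), 2L)
  expect_false(any(grepl("PATO", r$axioms$obj)))
  # idempotent and a subset of the input
  r2 <- restrict_to_namespace_links(r, "CHEBI", "GO")
  expect_identical(r$axioms$obj, r2$axioms$obj)
  expect_true(all(r$axioms$obj %in% o$axioms$obj))
})

test_that("absent external prefix leaves base-internal axioms only", {
  o <- parse_ontology(write_tmp(c("GO:1 SubClassOf GO:2",
                                  "GO:2 SubClassOf part_of some PATO:1")),
                      format = "axiom-lines")
  r <- restrict_to_namespace_links(o, "NOSUCH", "GO")
  expect_equal(n_axioms(r), 1L)
  expect_equal(r$axioms$obj, "GO:2")
})

test_that("namespace restriction equals brute-force prefix scan on random axioms", {
  withr::with_seed(42, {
    prefixes <- c("GO", "CHEBI", "PATO")
    lines <- replicate(50, {
      cl <- function() sprintf("%s:%d", sample(prefixes, 1), sample(9, 1))
      if (runif(1) < 0.5) paste(cl(), "SubClassOf", cl())
      else paste(cl(), "SubClassOf rel some", cl())
    })
    o <- parse_ontology(write_tmp(lines), format = "axiom-lines")
    r <- restrict_to_namespace_links(o, "CHEBI", "GO")
    canon <- paste(o$axioms$subject, o$axioms$kind, o$axioms$obj)
    keep <- brute_restrict_keep(canon, "GO", "CHEBI")
    expect_setequal(paste(r$axioms$subject, r$axioms$kind, r$axioms$obj),
                    canon[keep])
  })
})

test_that("merge with self or empty set is identity; union deduplicates", {
  o <- tiny_ontology()
  expect_equal(n_axioms(merge_or_substitute(o, o)), n_axioms(o))
  expect_equal(n_axioms(merge_or_substitute(o, ontology_set())), n_axioms(o))
  # commutative
  o2 <- ontology_set(list(axiom("SubClassOf", "X:1", "X:2")))
  m1 <- merge_or_substitute(o, o2)
  m2 <- merge_or_substitute(o2, o)
  expect_identical(m1$axioms$obj, m2$axioms$obj)
})

test_that("substitution removes prefix-internal axioms and keeps cross links", {
  host <- parse_ontology(write_tmp(c(
    "GO:1 SubClassOf GO:2", "GO:2 SubClassOf GO:3", "GO:3 SubClassOf GO:4",
    "HP:1 SubClassOf part_of some GO:1",
    "HP:2 SubClassOf GO:2")), format = "axiom-lines")
  incoming <- parse_ontology(write_tmp(c(
    "GO:1 SubClassOf GO:9",
    "GO:9 SubClassOf has_part some CHEBI:1")), format = "axiom-lines")
  m <- merge_or_substitute(host, incoming, replace_prefix = "GO")
  keys <- paste(m$axioms$subject, m$axioms$kind, m$axioms$obj)
  expect_setequal(keys, c("HP:1 SubClassOf part_of some GO:1",
                          "HP:2 SubClassOf GO:2",
                          "GO:1 SubClassOf GO:9",
                          "GO:9 SubClassOf has_part some CHEBI:1"))
})

test_that("unsupported OBO constructs are skipped with a warning and reported", {
  f <- write_tmp(c("[Term]", "id: A:1", "union_of: A:2", "is_a: A:3"),
                 ext = ".obo")
  expect_warning(o <- parse_ontology(f, format = "obo"), "unsupported")
  expect_equal(n_axioms(o), 1L)
  expect_length(parse_report(o)$skipped, 1L)
})
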