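# Synthetic-study generator: determinism, positive-rate arithmetic,
# module scattering, label planting.

test_that("generation is deterministic and positives are fixed data", {
  cfg <- synth_config(n_entities = 60, n_primary_classes = 60,
                      n_modules = 4, module_size = 3, seed = 5)
  s1 <- generate_study(cfg, tempfile())
  s2 <- generate_study(cfg, tempfile())
  for (f in c("primary", "external", "bridge", "annotations", "positives")) {
    expect_identical(readLines(s1$paths[[f]]), readLines(s2$paths[[f]]))
  }
})

test_that("positive count matches the closed-form expectation", {
  for (seed in 1:5) {
    cfg <- synth_config(seed = seed)
    st <- generate_study(cfg, tempfile())
    tr <- st$truth
    L <- tr$n_pairs_linked
    T_ <- tr$n_pairs_total
    mu <- cfg$pi1 * L + cfg$pi0 * (T_ - L)
    sigma <- sqrt(cfg$pi1 * (1 - cfg$pi1) * L +
                  cfg$pi0 * (1 - cfg$pi0) * (T_ - L))
    expect_lt(abs(tr$n_positive - mu), 3 * sigma)
  }
})

test_that("a null study carries no linkage signal", {
  for (seed in 1:5) {
    cfg <- synth_config(seed = seed, pi1 = 0.03, pi0 = 0.03)
    st <- generate_study(cfg, tempfile())
    tr <- st$truth
    tab <- matrix(c(tr$n_positive_linked,
                    tr$n_pairs_linked - tr$n_positive_linked,
                    tr$n_positive_unlinked,
                    (tr$n_pairs_total - tr$n_pairs_linked) -
                      tr$n_positive_unlinked), 2)
    expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.01)
  }
})

test_that("same-module leaves are farther apart than sibling leaves", {
  cfg <- synth_config(seed = 3)
  st <- generate_study(cfg, tempfile())
  o <- parse_ontology(st$paths$primary, format = "obo")
  sub <- o$axioms[o$axioms$kind == "SubClassOf", ]
  named <- vapply(sub$object, function(e) e$type == "class", logical(1))
  parent <- setNames(vapply(sub$object[named], `[[`, character(1), "id"),
                     sub$subject[named])
  depth_chain <- function(x) {
    chain <- x
    while (!is.na(parent[x])) { x <- parent[[x]]; chain <- c(chain, x) }
    chain
  }
  tree_dist <- function(a, b) {
    ca <- depth_chain(a); cb <- depth_chain(b)
    anc <- intersect(ca, cb)[1]
    (match(anc, ca) - 1) + (match(anc, cb) - 1)
  }
  module_of <- unlist(st$truth$module_of)
  mod_pairs <- do.call(rbind, lapply(split(names(module_of), module_of),
                                     function(m) t(combn(m, 2))))
  d_mod <- mean(apply(mod_pairs, 1, function(p) tree_dist(p[1], p[2])))
  # random sibling leaves: distance exactly 2
  sibs <- split(names(parent), parent)
  sibs <- sibs[vapply(sibs, length, integer(1)) >= 2]
  expect_gt(d_mod, 2)
})

test_that("bridge axioms connect module leaves to the module target", {
  cfg <- synth_config(seed = 9, link_probability = 1)
  st <- generate_study(cfg, tempfile())
  br <- parse_ontology(st$paths$bridge, format = "axiom-lines")
  expect_equal(n_axioms(br), cfg$n_modules * cfg$module_size)
  module_of <- unlist(st$truth$module_of)
  targets <- unlist(st$truth$module_targets)
  for (i in seq_len(nrow(br$axioms))) {
    leaf <- br$axioms$subject[[i]]
    expect_equal(br$axioms$object[[i]]$filler$id,
                 unname(targets[module_of[[leaf]]]))
  }
})

test_that("marker words label at least 80 percent of module members", {
  cfg <- synth_config(seed = 2, metadata_signal = "labels-share-module-words")
  st <- generate_study(cfg, tempfile())
  o <- parse_ontology(st$paths$primary, format = "obo")
  labels <- o$metadata[o$metadata$property == "label", ]
  module_of <- unlist(st$truth$module_of)
  hit <- vapply(names(module_of), function(cl) {
    grepl(sprintf("mkw%02d", module_of[[cl]]),
          labels$text[labels$subject == cl])
  }, logical(1))
  expect_gte(mean(hit), 0.8)
})

test_that("null labels carry no module-predictive word", {
  cfg <- synth_config(seed = 2, metadata_signal = "none")
  st <- generate_study(cfg, tempfile())
  o <- parse_ontology(st$paths$primary, format = "obo")
  labels <- o$metadata[o$metadata$property == "label", ]
  expect_false(any(grepl("mkw", labels$text)))
  # mutual information between each word and module membership is tiny
  module_of <- unlist(st$truth$module_of)
  members <- labels[labels$subject %in% names(module_of), ]
  words <- strsplit(members$text, " ")
  mods <- module_of[members$subject]
  voc <- unique(unlist(words))
  mi <- vapply(voc, function(w) {
    has <- vapply(words, function(x) w %in% x, logical(1))
    if (sum(has) < 2) return(0)
    tab <- table(has, mods)
    suppressWarnings(unname(chisq.test(tab)$statistic)) / (2 * length(has))
  }, numeric(1))
  expect_lt(max(mi), 0.5)
})

test_that("labels round-trip verbatim through the OBO writer", {
  cfg <- synth_config(seed = 4, metadata_signal = "labels-share-module-words")
  st <- generate_study(cfg, tempfile())
  o <- parse_ontology(st$paths$primary, format = "obo")
  f <- tempfile(fileext = ".obo")
  write_ontology(o, f, format = "obo")
  o2 <- parse_ontology(f, format = "obo")
  expect_identical(o$metadata, o2$metadata)
})

test_that("replanting metadata flips the signal without touching axioms", {
  cfg_on <- synth_config(seed = 6, metadata_signal = "labels-share-module-words")
  st <- generate_study(cfg_on, tempfile())
  ax_before <- parse_ontology(st$paths$primary, format = "obo")$axioms$obj
  plant_metadata(synth_config(seed = 6, metadata_signal = "none"), st)
  o2 <- parse_ontology(st$paths$primary, format = "obo")
  expect_identical(o2$axioms$obj, ax_before)
  expect_false(any(grepl("mkw", o2$metadata$text)))
})

test_that("infeasible sizes error", {
  expect_error(generate_study(synth_config(n_primary_classes = 12,
                                           n_modules = 8, module_size = 6,
                                           seed = 1), tempfile()),
               "infeasible")
})
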