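# Independent oracles: these re-derive expected results by brute force,
# without going through the package's own implementation paths.

# --- structural axiom descriptions (test-side, not package objects) ----
# ocls(id), osome(rel, filler), oand(args): plain nested lists.

ocls <- function(id) list(type = "class", id = id)
osome <- function(rel, filler) list(type = "some", rel = rel, filler = filler)
oand <- function(args) list(type = "and", args = args)

# serializer mirroring the canonical axiom-string contract
oracle_ser <- function(e) {
  if (e$type == "class") return(e$id)
  if (e$type == "some") {
    f <- oracle_ser(e$filler)
    if (e$filler$type == "and") f <- paste0("( ", f, " )")
    return(paste(e$rel, "some", f))
  }
  paste(sort(vapply(e$args, oracle_ser, character(1))), collapse = " and ")
}

oracle_key <- function(a) paste(a$subject, a$kind, oracle_ser(a$object))

# structural description -> package Axiom
desc_to_axiom <- function(a) {
  to_ce <- function(e) {
    switch(e$type,
      class = ce_class(e$id),
      some = ce_some(e$rel, to_ce(e$filler)),
      and = ce_and(lapply(e$args, to_ce)))
  }
  axiom(a$kind, a$subject, to_ce(a$object))
}

# --- naive rule-application-to-fixpoint saturation oracle --------------
oracle_saturate <- function(descs) {
  env <- new.env(parent = emptyenv())
  add <- function(a) {
    k <- oracle_key(a)
    if (is.null(env[[k]])) { env[[k]] <- a; TRUE } else FALSE
  }
  for (a in descs) add(a)
  repeat {
    changed <- FALSE
    items <- as.list(env)
    subs <- Filter(function(a) {
      a$kind == "SubClassOf" && a$object$type == "class"
    }, items)
    for (a in items) {
      if (a$kind == "EquivalentTo") {
        conj <- if (a$object$type == "and") a$object$args else list(a$object)
        for (cc in conj) {
          changed <- add(list(kind = "SubClassOf", subject = a$subject,
                              object = cc)) || changed
        }
        if (a$object$type == "class") {
          changed <- add(list(kind = "SubClassOf", subject = a$object$id,
                              object = ocls(a$subject))) || changed
        }
      } else if (a$kind == "SubClassOf") {
        if (a$object$type == "class") {
          for (b in subs) {
            if (b$subject == a$object$id) {
              changed <- add(list(kind = "SubClassOf", subject = a$subject,
                                  object = b$object)) || changed
            }
          }
        } else if (a$object$type == "some" &&
                   a$object$filler$type == "class") {
          for (b in subs) {
            if (b$subject == a$object$filler$id) {
              changed <- add(list(kind = "SubClassOf", subject = a$subject,
                                  object = osome(a$object$rel, b$object))) ||
                changed
            }
          }
        }
      }
    }
    if (!changed) break
  }
  sort(ls(env))
}

# random ontology as structural descriptions
random_ontology_descs <- function(n_classes, n_axioms) {
  cls <- sprintf("T:%d", seq_len(n_classes))
  rels <- c("r1", "r2", "part_of")
  rnd_expr <- function(allow_and = TRUE) {
    u <- runif(1)
    if (u < 0.55 || !allow_and) {
      ocls(sample(cls, 1))
    } else if (u < 0.85) {
      osome(sample(rels, 1), ocls(sample(cls, 1)))
    } else {
      k <- sample(2:3, 1)
      oand(lapply(seq_len(k), function(i) {
        if (runif(1) < 0.6) ocls(sample(cls, 1))
        else osome(sample(rels, 1), ocls(sample(cls, 1)))
      }))
    }
  }
  lapply(seq_len(n_axioms), function(i) {
    kind <- sample(c("SubClassOf", "SubClassOf", "SubClassOf",
                     "EquivalentTo", "DisjointWith"), 1)
    obj <- if (kind == "DisjointWith") ocls(sample(cls, 1)) else rnd_expr()
    list(kind = kind, subject = sample(cls, 1), object = obj)
  })
}

# --- AUC by brute-force double loop ------------------------------------
brute_auc <- function(s, y) {
  ps <- s[y == 1]
  ns <- s[y == 0]
  tot <- 0
  for (p in ps) tot <- tot + sum(p > ns) + 0.5 * sum(p == ns)
  tot / (length(ps) * length(ns))
}

# --- namespace-restriction by raw token scan ---------------------------
# (for fixtures whose relations are bare identifiers, every CURIE token
# on an axiom line is a class mention)
brute_restrict_keep <- function(axiom_lines, base, external) {
  vapply(axiom_lines, function(line) {
    toks <- strsplit(line, "[[:space:]]+")[[1]]
    curies <- toks[grepl("^[A-Za-z][A-Za-z0-9_]*:[A-Za-z0-9_]+$", toks)]
    prefixes <- unique(sub(":.*", "", curies))
    all(prefixes %in% c(base, external))
  }, logical(1), USE.NAMES = FALSE)
}

# --- independent text tokenizer (character walk) -----------------------
oracle_tokenize <- function(text) {
  text <- tolower(text)
  seps <- c(" ", "\t", ".", ",", ";", "(", ")", "[", "]", "{", "}", '"')
  out <- character(0)
  cur <- ""
  for (ch in strsplit(text, "")[[1]]) {
    if (ch %in% seps) {
      if (nzchar(cur)) out <- c(out, cur)
      cur <- ""
    } else cur <- paste0(cur, ch)
  }
  if (nzchar(cur)) out <- c(out, cur)
  out
}
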