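# Shared fixtures and independent oracles used across the suite.

# Random single-module ontology: a DAG of named concepts (edges only from
# higher to lower index, so acyclic by construction), a few properties,
# random existential assertions, and defined concepts restricted over random
# (property, filler) pairs. Defined concepts are never parents, so inferred
# membership can be compared to the oracle as a plain edge set.
random_ontology <- function(n_concepts, n_props = 3L, n_defined = 5L,
                            edge_prob = 2 / n_concepts, assert_rate = 0.3) {
  cs <- sprintf("c%03d", seq_len(n_concepts))
  ps <- sprintf("p%d", seq_len(n_props))
  ds <- sprintf("D%d", seq_len(n_defined))
  parents <- list()
  for (i in seq_len(n_concepts)[-1]) {
    up <- which(stats::runif(i - 1L) < edge_prob)
    for (u in up) parents[[length(parents) + 1L]] <-
      data.frame(child = cs[i], parent = cs[u], provenance = "asserted",
                 stringsAsFactors = FALSE)
  }
  n_assert <- stats::rpois(1, assert_rate * n_concepts)
  assertions <- if (n_assert > 0) data.frame(
    iri = sample(cs, n_assert, replace = TRUE),
    property = sample(ps, n_assert, replace = TRUE),
    filler = sample(cs, n_assert, replace = TRUE),
    stringsAsFactors = FALSE) else NULL
  defined <- data.frame(iri = ds, module = "rand",
                        property = sample(ps, n_defined, replace = TRUE),
                        filler = sample(cs, n_defined, replace = TRUE),
                        stringsAsFactors = FALSE)
  mod <- onto_module(
    "rand",
    concepts = data.frame(iri = cs, module = "rand", stringsAsFactors = FALSE),
    properties = data.frame(iri = ps, module = "rand", stringsAsFactors = FALSE),
    defined = defined,
    parents = if (length(parents)) do.call(rbind, parents) else
      data.frame(child = character(), parent = character(), provenance = character(),
                 stringsAsFactors = FALSE),
    assertions = if (!is.null(assertions)) unique(assertions) else
      data.frame(iri = character(), property = character(), filler = character(),
                 stringsAsFactors = FALSE)
  )
  consolidate(list(mod))
}

# fixpoint oracle: reflexive ancestor sets by repeated edge relaxation
oracle_ancestors <- function(ont) {
  nodes <- c(ont$concepts$iri, ont$defined$iri)
  anc <- stats::setNames(as.list(nodes), nodes)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(ont$parents))) {
      ch <- ont$parents$child[k]
      new <- union(anc[[ch]], anc[[ont$parents$parent[k]]])
      if (length(new) > length(anc[[ch]])) { anc[[ch]] <- new; changed <- TRUE }
    }
    if (!changed) break
  }
  anc
}

# brute-force membership oracle: tests every (concept, defined concept) pair
# by the definition, with assertions inherited from asserted ancestors and
# F' <= F decided through the ancestor sets (F' below F iff F in anc(F')).
oracle_infer <- function(ont) {
  anc <- oracle_ancestors(ont)
  out <- list()
  for (j in seq_len(nrow(ont$defined))) {
    D <- ont$defined$iri[j]; P <- ont$defined$property[j]; FL <- ont$defined$filler[j]
    for (C in ont$concepts$iri) {
      inh <- ont$assertions[ont$assertions$iri %in% anc[[C]], , drop = FALSE]
      if (!nrow(inh)) next
      ok <- inh$property == P &
        vapply(inh$filler, function(f) FL %in% anc[[f]], TRUE)
      if (any(ok)) out[[length(out) + 1L]] <- data.frame(child = C, parent = D,
                                                         stringsAsFactors = FALSE)
    }
  }
  edges <- do.call(rbind, c(out, list(data.frame(child = character(), parent = character(),
                                                 stringsAsFactors = FALSE))))
  edges[order(edges$child, edges$parent), , drop = FALSE]
}

# fixpoint oracle for reflexive-transitive descendants over all edges
oracle_descendants <- function(ont, iri) {
  edges <- rbind(ont$parents[c("child", "parent")], ont$inferred[c("child", "parent")])
  out <- iri
  repeat {
    more <- edges$child[edges$parent %in% out]
    new <- union(out, more)
    if (length(new) == length(out)) break
    out <- new
  }
  sort(out)
}

edge_key <- function(df) sort(paste(df$child, df$parent))

# write text with an explicit UTF-8 connection (fixtures with accents)
write_utf8 <- function(lines, path) {
  con <- file(path, "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  path
}

fixture_dir <- function() system.file("extdata", "ontology", package = "ontopath")

load_fixture_modules <- function() {
  lapply(list.files(fixture_dir(), pattern = "[.]onto$", full.names = TRUE), load_module)
}
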