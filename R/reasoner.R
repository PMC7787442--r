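# Inference over fully defined concepts.
#
# A fully defined concept D is equivalent to an existential restriction
# some(P, F). A named concept C classifies under D when C carries an
# assertion (P, F') -- either directly or inherited from an asserted
# ancestor -- with F' in the reflexive descending closure of F over the
# asserted subclass hierarchy. This is the EL fragment the ontology uses;
# no subproperty reasoning, no conjunctions.

# reflexive ancestors of every node under the asserted edge set, as a list
asserted_ancestors <- function(ont) {
  up <- split(ont$parents$parent, factor(ont$parents$child,
                                         levels = unique(ont$parents$child)))
  memo <- new.env(parent = emptyenv())
  anc <- function(iri) {
    if (!is.null(memo[[iri]])) return(memo[[iri]])
    memo[[iri]] <- iri            # cycle guard; hierarchy is validated acyclic
    ps <- up[[iri]]
    out <- iri
    for (p in ps) out <- union(out, anc(p))
    memo[[iri]] <- out
    out
  }
  nodes <- c(ont$concepts$iri, ont$defined$iri)
  setNames(lapply(nodes, anc), nodes)
}

# reflexive descendants under asserted edges (children map inverted)
asserted_descendants_map <- function(ont) {
  down <- split(ont$parents$child, factor(ont$parents$parent,
                                          levels = unique(ont$parents$parent)))
  memo <- new.env(parent = emptyenv())
  desc <- function(iri) {
    if (!is.null(memo[[iri]])) return(memo[[iri]])
    memo[[iri]] <- iri
    ch <- down[[iri]]
    out <- iri
    for (k in ch) out <- union(out, desc(k))
    memo[[iri]] <- out
    out
  }
  function(iri) desc(iri)
}

#' Infer memberships under the fully defined concepts
#'
#' For every fully defined concept `D ≡ ∃P.F`, adds an inferred subclass edge
#' `C ⊑ D` for each named concept `C` whose (direct or inherited) assertions
#' contain `(P, F')` with `F'` at or below `F` in the asserted hierarchy.
#' Assertions are inherited down the asserted subclass hierarchy, and filler
#' matching respects the filler's subclass closure, matching standard
#' description-logic semantics. The operation is idempotent, and never makes
#' a defined concept a child of another defined concept unless asserted.
#'
#' @param ontology a consolidated `ontology`.
#' @return The ontology with its `inferred` edge set filled (provenance
#'   `"defined-concept-inference"`) and attribute `reasoned = TRUE`.
#' @export
infer_defined_members <- function(ontology) {
  stopifnot(inherits(ontology, "ontology"))
  bad_p <- setdiff(ontology$defined$property, ontology$properties$iri)
  bad_f <- setdiff(ontology$defined$filler, c(ontology$concepts$iri, ontology$defined$iri))
  if (length(bad_p) || length(bad_f))
    stop("defined-concept restriction references unknown iri(s): ",
         paste(c(bad_p, bad_f), collapse = ", "), call. = FALSE)

  edges <- onto_empty_parents()
  if (nrow(ontology$defined) && nrow(ontology$assertions)) {
    anc <- asserted_ancestors(ontology)
    desc <- asserted_descendants_map(ontology)
    asr <- ontology$assertions
    # inherited assertion table: concept C owns every assertion of its ancestors
    own <- split(seq_len(nrow(asr)), asr$iri)
    chunks <- vector("list", nrow(ontology$defined))
    for (j in seq_len(nrow(ontology$defined))) {
      D <- ontology$defined$iri[j]
      P <- ontology$defined$property[j]
      fillers <- desc(ontology$defined$filler[j])
      members <- character()
      for (C in ontology$concepts$iri) {
        rows <- unlist(own[intersect(anc[[C]], names(own))], use.names = FALSE)
        if (!length(rows)) next
        hit <- asr$property[rows] == P & asr$filler[rows] %in% fillers
        if (any(hit)) members <- c(members, C)
      }
      if (length(members))
        chunks[[j]] <- data.frame(child = members, parent = D,
                                  provenance = "defined-concept-inference",
                                  stringsAsFactors = FALSE)
    }
    edges <- do.call(rbind, c(chunks[!vapply(chunks, is.null, TRUE)],
                              list(onto_empty_parents())))
  }
  # drop any inferred edge that duplicates an asserted edge
  if (nrow(edges)) {
    key_a <- paste(ontology$parents$child, ontology$parents$parent, sep = "\r")
    edges <- edges[!(paste(edges$child, edges$parent, sep = "\r") %in% key_a), , drop = FALSE]
  }
  ontology$inferred <- order_df(unique(edges), c("child", "parent"))
  attr(ontology, "reasoned") <- TRUE
  ontology
}

#' Reflexive-transitive descendants of a concept
#'
#' Closure under the union of asserted and inferred subclass edges, used by
#' the aggregator to collect every concept that counts toward a fully
#' defined concept.
#'
#' @param ontology a consolidated (usually reasoned) `ontology`.
#' @param iri a concept IRI present in the ontology.
#' @return character vector of IRIs, including `iri` itself.
#' @export
descendants <- function(ontology, iri) {
  stopifnot(inherits(ontology, "ontology"))
  known <- c(ontology$concepts$iri, ontology$defined$iri)
  if (!iri %in% known) stop("unknown iri: ", iri, call. = FALSE)
  edges <- rbind(ontology$parents, ontology$inferred)
  down <- split(edges$child, factor(edges$parent, levels = unique(edges$parent)))
  out <- character(); frontier <- iri
  seen <- new.env(parent = emptyenv())
  while (length(frontier)) {
    nxt <- character()
    for (n in frontier) {
      if (!is.null(seen[[n]])) next
      seen[[n]] <- TRUE
      out <- c(out, n)
      nxt <- c(nxt, down[[n]])
    }
    frontier <- unique(nxt)
  }
  sort(out)
}

#' Export a reasoned ontology
#'
#' Writes the consolidated ontology with its inferred edges flagged by
#' provenance, in either the plaintext dialect or RDF/XML. Reloading the
#' exported file reproduces the inferred edge set without re-running
#' inference.
#'
#' @param ontology a reasoned `ontology` (see [infer_defined_members()]).
#' @param path output file path.
#' @param format `"plaintext"` or `"rdfxml"`.
#' @return `path`, invisibly.
#' @export
export_reasoned <- function(ontology, path, format = c("plaintext", "rdfxml")) {
  format <- match.arg(format)
  stopifnot(inherits(ontology, "ontology"))
  if (!isTRUE(attr(ontology, "reasoned")))
    stop("run infer_defined_members() before exporting a reasoned ontology", call. = FALSE)
  if (format == "plaintext") write_ontology(ontology, path) else write_ontology_rdfxml(ontology, path)
  invisible(path)
}

#' Load a reasoned ontology from a single exported file
#'
#' Convenience inverse of [export_reasoned()]: loads one consolidated file as
#' a single-module set and consolidates it, preserving inferred edges.
#'
#' @param path file written by [export_reasoned()].
#' @param format `"plaintext"` or `"rdfxml"`.
#' @return An `ontology`.
#' @export
load_reasoned <- function(path, format = c("plaintext", "rdfxml")) {
  format <- match.arg(format)
  mod <- load_module(path, format = format)
  ont <- consolidate(list(mod))
  if (nrow(ont$inferred)) ont$inferred$provenance <- "defined-concept-inference"
  ont
}
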