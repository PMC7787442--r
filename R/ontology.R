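#' @keywords internal
"_PACKAGE"

# ---- internal frame constructors -------------------------------------------

onto_empty_concepts  <- function() data.frame(iri = character(), module = character(), stringsAsFactors = FALSE)
onto_empty_properties<- function() data.frame(iri = character(), module = character(), stringsAsFactors = FALSE)
onto_empty_defined   <- function() data.frame(iri = character(), module = character(),
                                              property = character(), filler = character(),
                                              stringsAsFactors = FALSE)
onto_empty_labels    <- function() data.frame(iri = character(), kind = character(),
                                              lang = character(), text = character(),
                                              stringsAsFactors = FALSE)
onto_empty_parents   <- function() data.frame(child = character(), parent = character(),
                                              provenance = character(), stringsAsFactors = FALSE)
onto_empty_assertions<- function() data.frame(iri = character(), property = character(),
                                              filler = character(), stringsAsFactors = FALSE)

#' Create an ontology module
#'
#' A module is the unit of authorship of the modular ontology: a named set of
#' concepts, object properties and fully defined concepts, together with its
#' labels, asserted subclass links and existential property assertions.
#' Modules import one another; a consolidation module imports everything and
#' declares no concepts of its own.
#'
#' @param name module name (e.g. `"core"`, `"medical"`).
#' @param imports character vector of module names this module imports.
#' @param concepts,properties,defined,labels,parents,assertions data frames in
#'   the internal layout; usually filled by [load_module()] rather than by hand.
#' @return An object of class `onto_module`.
#' @seealso [load_module()], [consolidate()]
#' @export
onto_module <- function(name, imports = character(),
                        concepts = onto_empty_concepts(),
                        properties = onto_empty_properties(),
                        defined = onto_empty_defined(),
                        labels = onto_empty_labels(),
                        parents = onto_empty_parents(),
                        assertions = onto_empty_assertions()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  mod <- structure(list(name = name, imports = imports,
                        concepts = concepts, properties = properties,
                        defined = defined, labels = labels,
                        parents = parents, assertions = assertions),
                   class = "onto_module")
  validate_module(mod)
}

validate_module <- function(mod) {
  all_iris <- c(mod$concepts$iri, mod$defined$iri, mod$properties$iri)
  if (anyDuplicated(all_iris)) {
    dup <- unique(all_iris[duplicated(all_iris)])
    stop("duplicate iri within module '", mod$name, "': ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(all_iris))) stop("empty iri in module '", mod$name, "'", call. = FALSE)
  # a defined concept carries exactly its restriction, never ordinary assertions
  bad <- intersect(mod$defined$iri, mod$assertions$iri)
  if (length(bad)) {
    stop("defined concept(s) with ordinary assertions in module '", mod$name, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(mod$defined$iri)) {
    dup <- unique(mod$defined$iri[duplicated(mod$defined$iri)])
    stop("multiple restrictions for defined concept(s) in module '", mod$name, "': ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  # alt labels must not duplicate the pref label of the same language
  lab <- mod$labels
  if (nrow(lab)) {
    pref <- lab[lab$kind == "pref", , drop = FALSE]
    alt  <- lab[lab$kind == "alt",  , drop = FALSE]
    key_p <- paste(pref$iri, pref$lang, pref$text, sep = "\r")
    key_a <- paste(alt$iri,  alt$lang,  alt$text,  sep = "\r")
    clash <- key_a %in% key_p
    if (any(clash)) {
      warning("dropping alt label(s) identical to the pref label in module '",
              mod$name, "': ", paste(unique(alt$text[clash]), collapse = ", "),
              call. = FALSE)
      keep <- !(lab$kind == "alt" & key_of_label(lab) %in% key_p)
      mod$labels <- lab[keep, , drop = FALSE]
    }
    # exact duplicate label rows collapse to one
    mod$labels <- unique(mod$labels)
    rownames(mod$labels) <- NULL
  }
  mod
}

key_of_label <- function(lab) paste(lab$iri, lab$lang, lab$text, sep = "\r")

ref_df <- function(ref, role) data.frame(ref = ref, role = rep(role, length(ref)),
                                         stringsAsFactors = FALSE)

# iris declared locally in a module (concepts, defined, properties)
module_local_iris <- function(mod) c(mod$concepts$iri, mod$defined$iri, mod$properties$iri)

#' References a module makes that it does not itself declare
#'
#' Parent, property and filler references pointing outside the module are
#' legal: they stay pending until [consolidate()] merges all modules and
#' checks that each one resolves.
#'
#' @param mod an `onto_module`.
#' @return data frame with columns `ref` and `role`.
#' @export
pending_refs <- function(mod) {
  local <- module_local_iris(mod)
  refs <- rbind(
    ref_df(mod$parents$parent, "parent"),
    ref_df(mod$assertions$property, "property"),
    ref_df(mod$assertions$filler, "filler"),
    ref_df(mod$defined$property, "property"),
    ref_df(mod$defined$filler, "filler")
  )
  refs <- refs[!(refs$ref %in% local), , drop = FALSE]
  refs <- unique(refs)
  rownames(refs) <- NULL
  refs
}

#' @export
print.onto_module <- function(x, ...) {
  cat("<ontology module '", x$name, "'>\n", sep = "")
  cat("  concepts: ", nrow(x$concepts),
      "  defined: ", nrow(x$defined),
      "  properties: ", nrow(x$properties),
      "  labels: ", nrow(x$labels), "\n", sep = "")
  if (length(x$imports)) cat("  imports: ", paste(x$imports, collapse = ", "), "\n", sep = "")
  pend <- pending_refs(x)
  if (nrow(pend)) cat("  pending references: ", nrow(pend), "\n", sep = "")
  invisible(x)
}

# ---- plaintext dialect ------------------------------------------------------

#' Load an ontology module from a file
#'
#' Two on-disk formats are supported. `"plaintext"` is this package's
#' line-oriented, tab-separated interchange dialect (hand-writable and
#' diffable; see Details). `"rdfxml"` reads the OWL subset used by the
#' published ontology artifact: named classes, `rdfs:subClassOf` to named
#' classes or to `owl:Restriction`/`owl:someValuesFrom`, `owl:equivalentClass`
#' to a restriction (the fully defined concepts), object properties and
#' `skos:prefLabel`/`skos:altLabel` with `rdfs:label` fallback.
#'
#' @details
#' The plaintext dialect is UTF-8, one record per line, fields separated by
#' tabs, `#` starts a comment line:
#' \preformatted{
#' MODULE   <name>
#' IMPORT   <module name>            # repeatable
#' PROPERTY <iri>
#' CONCEPT  <iri>
#' DEFINED  <iri>
#' LABEL    <pref|alt> [lang] <text> # attaches to the last PROPERTY/CONCEPT/DEFINED
#' PARENT   <parent iri> [asserted|inferred]   # attaches likewise
#' ASSERT   <property iri> <filler iri>        # on a DEFINED line: its restriction
#' }
#' Labels without a language tag default to `"fr"`, the corpus language.
#' A `DEFINED` record takes exactly one `ASSERT` (its necessary-and-sufficient
#' restriction); more than one is a validation error. Module membership is
#' declared by the file, never inferred from IRI namespaces.
#'
#' @param path file path.
#' @param format `"plaintext"` or `"rdfxml"`.
#' @param name module name override (defaults to the `MODULE` record or, for
#'   RDF/XML, the file base name).
#' @return An `onto_module`.
#' @export
load_module <- function(path, format = c("plaintext", "rdfxml"), name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  switch(format,
         plaintext = read_module_dialect(path, name = name),
         rdfxml = read_module_rdfxml(path, name = name))
}

read_module_dialect <- function(path, name = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  mod_name <- name
  imports <- character()
  concepts <- list(); defined <- list(); properties <- list()
  labels <- list(); parents <- list(); assertions <- list()
  cur <- NULL; cur_type <- NULL
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line)) || startsWith(trimws(line), "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    rec <- f[[1]]
    bad <- function(msg) stop(sprintf("%s:%d: %s", path, i, msg), call. = FALSE)
    switch(rec,
      MODULE = { if (length(f) < 2L) bad("MODULE needs a name"); if (is.null(mod_name)) mod_name <- f[[2]] },
      IMPORT = { if (length(f) < 2L) bad("IMPORT needs a module name"); imports <- c(imports, f[[2]]) },
      PROPERTY = { if (length(f) < 2L) bad("PROPERTY needs an iri")
                   properties[[length(properties) + 1L]] <- f[[2]]
                   cur <- f[[2]]; cur_type <- "property" },
      CONCEPT = { if (length(f) < 2L) bad("CONCEPT needs an iri")
                  concepts[[length(concepts) + 1L]] <- f[[2]]
                  cur <- f[[2]]; cur_type <- "concept" },
      DEFINED = { if (length(f) < 2L) bad("DEFINED needs an iri")
                  defined[[length(defined) + 1L]] <- list(iri = f[[2]], property = NA_character_, filler = NA_character_)
                  cur <- f[[2]]; cur_type <- "defined" },
      LABEL = { if (is.null(cur)) bad("LABEL before any subject")
                if (length(f) == 3L) { kind <- f[[2]]; lang <- "fr"; text <- f[[3]] }
                else if (length(f) >= 4L) { kind <- f[[2]]; lang <- f[[3]]; text <- f[[4]] }
                else bad("LABEL needs kind and text")
                if (!kind %in% c("pref", "alt")) bad("label kind must be pref or alt")
                if (!nzchar(lang)) lang <- "fr"
                labels[[length(labels) + 1L]] <- list(iri = cur, kind = kind, lang = lang, text = text) },
      PARENT = { if (is.null(cur) || cur_type == "property") bad("PARENT needs a concept subject")
                 if (length(f) < 2L) bad("PARENT needs an iri")
                 prov <- if (length(f) >= 3L) f[[3]] else "asserted"
                 if (!prov %in% c("asserted", "inferred")) bad("PARENT provenance must be asserted or inferred")
                 parents[[length(parents) + 1L]] <- list(child = cur, parent = f[[2]], provenance = prov) },
      ASSERT = { if (is.null(cur) || cur_type == "property") bad("ASSERT needs a concept subject")
                 if (length(f) < 3L) bad("ASSERT needs property and filler iris")
                 if (cur_type == "defined") {
                   k <- length(defined)
                   if (!is.na(defined[[k]]$property))
                     bad(paste0("multiple restrictions on defined concept ", cur))
                   defined[[k]]$property <- f[[2]]; defined[[k]]$filler <- f[[3]]
                 } else {
                   assertions[[length(assertions) + 1L]] <- list(iri = cur, property = f[[2]], filler = f[[3]])
                 } },
      bad(paste0("unknown record type '", rec, "'"))
    )
  }
  if (is.null(mod_name)) mod_name <- tools::file_path_sans_ext(basename(path))
  def_df <- if (length(defined)) {
    d <- do.call(rbind, lapply(defined, function(x) data.frame(iri = x$iri, property = x$property,
                                                               filler = x$filler, stringsAsFactors = FALSE)))
    if (anyNA(d$property)) stop(path, ": defined concept(s) without a restriction: ",
                                paste(d$iri[is.na(d$property)], collapse = ", "), call. = FALSE)
    data.frame(iri = d$iri, module = mod_name, property = d$property, filler = d$filler,
               stringsAsFactors = FALSE)
  } else onto_empty_defined()
  list_to_df <- function(lst, empty) {
    if (!length(lst)) return(empty)
    out <- do.call(rbind, lapply(lst, function(x) as.data.frame(x, stringsAsFactors = FALSE)))
    rownames(out) <- NULL
    out
  }
  onto_module(
    name = mod_name, imports = unique(imports),
    concepts = if (length(concepts)) data.frame(iri = unlist(concepts), module = mod_name,
                                                stringsAsFactors = FALSE) else onto_empty_concepts(),
    properties = if (length(properties)) data.frame(iri = unlist(properties), module = mod_name,
                                                    stringsAsFactors = FALSE) else onto_empty_properties(),
    defined = def_df,
    labels = list_to_df(labels, onto_empty_labels()),
    parents = list_to_df(parents, onto_empty_parents()),
    assertions = list_to_df(assertions, onto_empty_assertions())
  )
}

#' Write a module or consolidated ontology in the plaintext dialect
#'
#' Records are emitted in a canonical order (properties, concepts, defined
#' concepts, each sorted by IRI) so that output is deterministic and
#' re-loading reproduces an isomorphic graph. Inferred subclass edges, if
#' present, are written with the `inferred` provenance flag and survive a
#' round trip without re-running inference.
#'
#' @param x an `onto_module` or `ontology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(x, path) {
  stopifnot(inherits(x, c("onto_module", "ontology")))
  name <- if (inherits(x, "onto_module")) x$name else "consolidated"
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(paste(..., sep = "\t"), con, useBytes = FALSE)
  w("MODULE", name)
  if (inherits(x, "onto_module")) for (im in x$imports) w("IMPORT", im)
  lab <- x$labels
  emit_labels <- function(iri) {
    li <- lab[lab$iri == iri, , drop = FALSE]
    li <- li[order(li$kind, li$lang, li$text), , drop = FALSE]
    for (j in seq_len(nrow(li))) w("LABEL", li$kind[j], li$lang[j], li$text[j])
  }
  for (p in sort(x$properties$iri)) { w("PROPERTY", p); emit_labels(p) }
  par <- x$parents
  inf <- if (!is.null(x$inferred)) x$inferred else onto_empty_parents()
  asr <- x$assertions
  for (ci in sort(x$concepts$iri)) {
    w("CONCEPT", ci); emit_labels(ci)
    pi <- par[par$child == ci, , drop = FALSE]
    for (j in order(pi$parent)) w("PARENT", pi$parent[j], "asserted")
    fi <- inf[inf$child == ci, , drop = FALSE]
    for (j in order(fi$parent)) w("PARENT", fi$parent[j], "inferred")
    ai <- asr[asr$iri == ci, , drop = FALSE]
    for (j in order(ai$property, ai$filler)) w("ASSERT", ai$property[j], ai$filler[j])
  }
  dd <- x$defined
  for (j in order(dd$iri)) {
    w("DEFINED", dd$iri[j]); emit_labels(dd$iri[j])
    pi <- par[par$child == dd$iri[j], , drop = FALSE]
    for (k in order(pi$parent)) w("PARENT", pi$parent[k], "asserted")
    w("ASSERT", dd$property[j], dd$filler[j])
  }
  invisible(path)
}

# ---- RDF/XML (OWL subset) ---------------------------------------------------

owl_ns <- c(
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl  = "http://www.w3.org/2002/07/owl#",
  skos = "http://www.w3.org/2004/02/skos/core#"
)

read_module_rdfxml <- function(path, name = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("RDF/XML parse failure in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  ns <- owl_ns
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  classes <- xml2::xml_find_all(doc, "//owl:Class[@rdf:about]", ns)
  props   <- xml2::xml_find_all(doc, "//owl:ObjectProperty[@rdf:about]", ns)
  about <- function(nodes) xml2::xml_attr(nodes, "rdf:about", ns)

  concepts <- list(); defined <- list(); labels <- list()
  parents <- list(); assertions <- list()

  grab_labels <- function(node, iri) {
    for (spec in list(c("skos:prefLabel", "pref"), c("skos:altLabel", "alt"))) {
      for (ln in xml2::xml_find_all(node, spec[1], ns)) {
        lang <- xml2::xml_attr(ln, "lang")
        if (is.na(lang) || !nzchar(lang)) lang <- "fr"
        labels[[length(labels) + 1L]] <<- list(iri = iri, kind = spec[2], lang = lang,
                                               text = xml2::xml_text(ln))
      }
    }
    # rdfs:label fallback only when no skos pref label present
    if (!length(xml2::xml_find_all(node, "skos:prefLabel", ns))) {
      for (ln in xml2::xml_find_all(node, "rdfs:label", ns)) {
        lang <- xml2::xml_attr(ln, "lang")
        if (is.na(lang) || !nzchar(lang)) lang <- "fr"
        labels[[length(labels) + 1L]] <<- list(iri = iri, kind = "pref", lang = lang,
                                               text = xml2::xml_text(ln))
      }
    }
  }

  parse_restriction <- function(rnode, where) {
    prop <- xml2::xml_attr(xml2::xml_find_first(rnode, "owl:onProperty", ns), "rdf:resource", ns)
    fill <- xml2::xml_attr(xml2::xml_find_first(rnode, "owl:someValuesFrom", ns), "rdf:resource", ns)
    if (is.na(prop) || is.na(fill))
      stop("unsupported restriction (need onProperty + someValuesFrom resources) at ", where,
           call. = FALSE)
    c(prop, fill)
  }

  for (cl in classes) {
    iri <- xml2::xml_attr(cl, "rdf:about", ns)
    eq <- xml2::xml_find_first(cl, "owl:equivalentClass/owl:Restriction", ns)
    if (!inherits(eq, "xml_missing")) {
      pf <- parse_restriction(eq, iri)
      defined[[length(defined) + 1L]] <- list(iri = iri, property = pf[1], filler = pf[2])
    } else {
      concepts[[length(concepts) + 1L]] <- iri
    }
    for (sc in xml2::xml_find_all(cl, "rdfs:subClassOf", ns)) {
      res <- xml2::xml_attr(sc, "rdf:resource", ns)
      if (!is.na(res)) {
        prov <- xml2::xml_attr(sc, "provenance")
        parents[[length(parents) + 1L]] <- list(child = iri, parent = res,
                                                provenance = if (!is.na(prov) && prov == "inferred") "inferred" else "asserted")
      } else {
        rn <- xml2::xml_find_first(sc, "owl:Restriction", ns)
        if (!inherits(rn, "xml_missing")) {
          pf <- parse_restriction(rn, iri)
          assertions[[length(assertions) + 1L]] <- list(iri = iri, property = pf[1], filler = pf[2])
        }
      }
    }
    grab_labels(cl, iri)
  }
  for (pr in props) grab_labels(pr, xml2::xml_attr(pr, "rdf:about", ns))

  to_df <- function(lst, empty) {
    if (!length(lst)) return(empty)
    out <- do.call(rbind, lapply(lst, function(x) as.data.frame(x, stringsAsFactors = FALSE)))
    rownames(out) <- NULL
    out
  }
  def <- to_df(defined, data.frame(iri = character(), property = character(),
                                   filler = character(), stringsAsFactors = FALSE))
  def <- if (nrow(def)) data.frame(iri = def$iri, module = name, property = def$property,
                                   filler = def$filler, stringsAsFactors = FALSE) else onto_empty_defined()
  onto_module(
    name = name, imports = character(),
    concepts = if (length(concepts)) data.frame(iri = unlist(concepts), module = name,
                                                stringsAsFactors = FALSE) else onto_empty_concepts(),
    properties = if (length(props)) data.frame(iri = about(props), module = name,
                                               stringsAsFactors = FALSE) else onto_empty_properties(),
    defined = def,
    labels = to_df(labels, onto_empty_labels()),
    parents = to_df(parents, onto_empty_parents()),
    assertions = to_df(assertions, onto_empty_assertions())
  )
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Write an ontology as RDF/XML
#'
#' Emits the same OWL subset [load_module()] reads. Inferred subclass edges,
#' if present, carry a `provenance="inferred"` attribute on the
#' `rdfs:subClassOf` element so a reload reproduces them without re-running
#' inference.
#'
#' @param x an `onto_module` or `ontology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ontology_rdfxml <- function(x, path) {
  stopifnot(inherits(x, c("onto_module", "ontology")))
  lab <- x$labels
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<rdf:RDF xmlns:rdf="', owl_ns[["rdf"]], '" xmlns:rdfs="', owl_ns[["rdfs"]],
    '" xmlns:owl="', owl_ns[["owl"]], '" xmlns:skos="', owl_ns[["skos"]], '">')
  emit_labels <- function(iri) {
    li <- lab[lab$iri == iri, , drop = FALSE]
    li <- li[order(li$kind, li$lang, li$text), , drop = FALSE]
    for (j in seq_len(nrow(li))) {
      tag <- if (li$kind[j] == "pref") "skos:prefLabel" else "skos:altLabel"
      w('    <', tag, ' xml:lang="', li$lang[j], '">', xml_escape(li$text[j]), '</', tag, '>')
    }
  }
  for (p in sort(x$properties$iri)) {
    w('  <owl:ObjectProperty rdf:about="', xml_escape(p), '">')
    emit_labels(p)
    w('  </owl:ObjectProperty>')
  }
  par <- x$parents
  inf <- if (!is.null(x$inferred)) x$inferred else onto_empty_parents()
  asr <- x$assertions
  for (ci in sort(x$concepts$iri)) {
    w('  <owl:Class rdf:about="', xml_escape(ci), '">')
    emit_labels(ci)
    pi <- par[par$child == ci, , drop = FALSE]
    for (j in order(pi$parent)) w('    <rdfs:subClassOf rdf:resource="', xml_escape(pi$parent[j]), '"/>')
    fi <- inf[inf$child == ci, , drop = FALSE]
    for (j in order(fi$parent))
      w('    <rdfs:subClassOf rdf:resource="', xml_escape(fi$parent[j]), '" provenance="inferred"/>')
    ai <- asr[asr$iri == ci, , drop = FALSE]
    for (j in order(ai$property, ai$filler)) {
      w('    <rdfs:subClassOf><owl:Restriction>')
      w('      <owl:onProperty rdf:resource="', xml_escape(ai$property[j]), '"/>')
      w('      <owl:someValuesFrom rdf:resource="', xml_escape(ai$filler[j]), '"/>')
      w('    </owl:Restriction></rdfs:subClassOf>')
    }
    w('  </owl:Class>')
  }
  dd <- x$defined
  for (j in order(dd$iri)) {
    w('  <owl:Class rdf:about="', xml_escape(dd$iri[j]), '">')
    emit_labels(dd$iri[j])
    pi <- par[par$child == dd$iri[j], , drop = FALSE]
    for (k in order(pi$parent)) w('    <rdfs:subClassOf rdf:resource="', xml_escape(pi$parent[k]), '"/>')
    w('    <owl:equivalentClass><owl:Restriction>')
    w('      <owl:onProperty rdf:resource="', xml_escape(dd$property[j]), '"/>')
    w('      <owl:someValuesFrom rdf:resource="', xml_escape(dd$filler[j]), '"/>')
    w('    </owl:Restriction></owl:equivalentClass>')
    w('  </owl:Class>')
  }
  w('</rdf:RDF>')
  invisible(path)
}

# ---- consolidation ----------------------------------------------------------

#' Consolidate ontology modules
#'
#' Merges a set of modules into one ontology, mirroring the role of the
#' consolidation module: it contributes no concepts of its own, it only
#' aggregates. Checks that the import graph is acyclic, that IRIs do not
#' collide across modules, and that every parent/property/filler reference
#' left pending by the individual modules resolves in the merged set.
#' The result is canonically ordered, so consolidation is invariant under
#' permutation of the module list.
#'
#' @param modules list of `onto_module` objects.
#' @return An object of class `ontology` with merged `concepts`, `properties`,
#'   `defined`, `labels`, `parents` (asserted subclass edges), `assertions`
#'   and an initially empty `inferred` edge set.
#' @export
consolidate <- function(modules) {
  stopifnot(is.list(modules), all(vapply(modules, inherits, TRUE, "onto_module")))
  names <- vapply(modules, `[[`, "", "name")
  if (anyDuplicated(names)) stop("duplicate module names: ",
                                 paste(unique(names[duplicated(names)]), collapse = ", "),
                                 call. = FALSE)
  # import graph must be acyclic (imports outside the set are ignored)
  imports <- lapply(modules, function(m) intersect(m$imports, names))
  names(imports) <- names
  check_import_dag(imports)

  cat_df <- function(field, empty) {
    parts <- lapply(modules, `[[`, field)
    out <- do.call(rbind, c(parts, list(empty)))
    rownames(out) <- NULL
    out
  }
  concepts <- cat_df("concepts", onto_empty_concepts())
  defined  <- cat_df("defined", onto_empty_defined())
  properties <- cat_df("properties", onto_empty_properties())
  all_iris <- c(concepts$iri, defined$iri, properties$iri)
  if (anyDuplicated(all_iris)) {
    dup <- unique(all_iris[duplicated(all_iris)])
    stop("iri collision across modules: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  ont <- structure(list(
    modules = sort(names),
    module_imports = imports[sort(names)],
    concepts = order_df(concepts, "iri"),
    properties = order_df(properties, "iri"),
    defined = order_df(defined, "iri"),
    labels = order_df(unique(cat_df("labels", onto_empty_labels())), c("iri", "kind", "lang", "text")),
    parents = order_df(unique(cat_df("parents", onto_empty_parents())), c("child", "parent")),
    assertions = order_df(unique(cat_df("assertions", onto_empty_assertions())), c("iri", "property", "filler")),
    inferred = onto_empty_parents()
  ), class = "ontology")
  # separate pre-loaded inferred edges (round-tripped reasoned files)
  inf <- ont$parents[ont$parents$provenance == "inferred", , drop = FALSE]
  ont$parents <- ont$parents[ont$parents$provenance == "asserted", , drop = FALSE]
  rownames(ont$parents) <- NULL
  if (nrow(inf)) { rownames(inf) <- NULL; ont$inferred <- inf; attr(ont, "reasoned") <- TRUE }

  unresolved <- check_resolution(ont)
  if (nrow(unresolved))
    stop("unresolved iri(s) after consolidation: ",
         paste(unique(unresolved$ref), collapse = ", "), call. = FALSE)
  check_subclass_acyclic(ont)
  ont
}

order_df <- function(df, cols) {
  if (!nrow(df)) return(df)
  out <- df[do.call(order, df[cols]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

check_import_dag <- function(imports) {
  state <- setNames(rep(0L, length(imports)), names(imports))
  visit <- function(n) {
    if (state[[n]] == 1L) stop("import cycle involving module '", n, "'", call. = FALSE)
    if (state[[n]] == 2L) return(invisible())
    state[[n]] <<- 1L
    for (m in imports[[n]]) visit(m)
    state[[n]] <<- 2L
  }
  for (n in names(imports)) visit(n)
  invisible(TRUE)
}

check_resolution <- function(ont) {
  known_cls <- c(ont$concepts$iri, ont$defined$iri)
  known_prp <- ont$properties$iri
  refs <- rbind(
    ref_df(ont$parents$parent, "parent"),
    ref_df(ont$inferred$parent, "parent"),
    ref_df(ont$assertions$property, "property"),
    ref_df(ont$assertions$filler, "filler"),
    ref_df(ont$defined$property, "property"),
    ref_df(ont$defined$filler, "filler")
  )
  ok <- ifelse(refs$role == "property", refs$ref %in% known_prp, refs$ref %in% known_cls)
  unique(refs[!ok, , drop = FALSE])
}

check_subclass_acyclic <- function(ont) {
  # asserted subclass relation must be acyclic over named (non-defined) concepts
  edges <- ont$parents[!(ont$parents$child %in% ont$defined$iri) &
                       !(ont$parents$parent %in% ont$defined$iri), , drop = FALSE]
  nodes <- unique(c(edges$child, edges$parent))
  if (!length(nodes)) return(invisible(TRUE))
  adj <- split(edges$parent, factor(edges$child, levels = nodes))
  state <- setNames(rep(0L, length(nodes)), nodes)
  for (start in nodes) {
    if (state[[start]] != 0L) next
    stack <- list(list(node = start, i = 0L))
    state[[start]] <- 1L
    while (length(stack)) {
      top <- stack[[length(stack)]]
      nb <- adj[[top$node]]
      if (is.null(nb)) nb <- character()
      if (top$i < length(nb)) {
        stack[[length(stack)]]$i <- top$i + 1L
        nxt <- nb[[top$i + 1L]]
        if (state[[nxt]] == 1L)
          stop("subclass cycle involving '", nxt, "'", call. = FALSE)
        if (state[[nxt]] == 0L) {
          state[[nxt]] <- 1L
          stack[[length(stack) + 1L]] <- list(node = nxt, i = 0L)
        }
      } else {
        state[[top$node]] <- 2L
        stack[[length(stack)]] <- NULL
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.ontology <- function(x, ...) {
  cat("<consolidated ontology>\n")
  cat("  modules: ", paste(x$modules, collapse = ", "), "\n", sep = "")
  cat("  classes: ", nrow(x$concepts) + nrow(x$defined),
      " (", nrow(x$defined), " fully defined)",
      "  properties: ", nrow(x$properties), "\n", sep = "")
  cat("  subclass edges: ", nrow(x$parents), " asserted",
      if (nrow(x$inferred)) paste0(", ", nrow(x$inferred), " inferred"), "\n", sep = "")
  invisible(x)
}

#' Structural metrics of a consolidated ontology
#'
#' Per-module and total counts of classes (named concepts plus fully defined
#' concepts), declared object properties and fully defined concepts. Totals
#' are exact sums over modules.
#'
#' @param ontology a consolidated `ontology`.
#' @return data frame with one row per module plus a `total` row and columns
#'   `module`, `n_classes`, `n_properties`, `n_defined`.
#' @export
ontology_metrics <- function(ontology) {
  stopifnot(inherits(ontology, "ontology"))
  mods <- ontology$modules
  count_by <- function(df) {
    tab <- table(factor(df$module, levels = mods))
    as.integer(tab)
  }
  n_named <- count_by(ontology$concepts)
  n_def <- count_by(ontology$defined)
  out <- data.frame(
    module = mods,
    n_classes = n_named + n_def,
    n_properties = count_by(ontology$properties),
    n_defined = n_def,
    stringsAsFactors = FALSE
  )
  rbind(out, data.frame(module = "total",
                        n_classes = sum(out$n_classes),
                        n_properties = sum(out$n_properties),
                        n_defined = sum(out$n_defined),
                        stringsAsFactors = FALSE))
}

#' Look up the preferred label of a concept
#'
#' @param ontology a consolidated `ontology`.
#' @param iri concept IRI (vectorised).
#' @param lang language tag, default `"fr"`.
#' @return character vector; the IRI itself where no label exists.
#' @export
pref_label <- function(ontology, iri, lang = "fr") {
  lab <- ontology$labels
  lab <- lab[lab$kind == "pref" & lab$lang == lang, , drop = FALSE]
  out <- lab$text[match(iri, lab$iri)]
  ifelse(is.na(out), iri, out)
}
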