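table1_text <- paste0(
  "Information du ssiad de VILLE, PROFESSIONEL: a débuté la PEC ce jour mais ",
  "le logement n’est pas du tout adapté. Nous ne pourrons pas lui faire la ",
  "douche car la SDB n’est pas du tout adaptée.")

test_that("preprocessing splits sentences and keeps offsets faithful", {
  doc <- onto_document("e1", table1_text)
  sents <- preprocess(doc)
  expect_gte(length(sents), 2L)
  expect_true("SDB" %in% unlist(lapply(sents, `[[`, "surface")))
  for (s in sents) {
    expect_identical(substring(doc$text, s$start + 1, s$end), s$surface)
  }
  expect_equal(preprocess(onto_document("e0", "")), list())
})

test_that("token spans slice back to surfaces on fuzzed documents", {
  set.seed(21)
  pool <- c(letters, "é", "è", "ç", " ", ".", "!", "'", "\n", ",", ":", "3")
  for (k in 1:40) {
    txt <- paste(sample(pool, 80, replace = TRUE), collapse = "")
    sents <- preprocess(onto_document("f", txt))
    for (s in sents) expect_identical(substring(txt, s$start + 1, s$end), s$surface)
  }
})

test_that("a custom lemmatizer is accepted through the contract", {
  upper <- function(tokens) toupper(tokens)
  sents <- preprocess(onto_document("d", "la SDB est adaptée"), lemmatizer = upper)
  expect_equal(sents[[1]]$lemma, toupper(sents[[1]]$norm))
})

test_that("abbreviated mentions map to their concepts", {
  idx <- build_term_index(fixture_ontology())
  doc <- onto_document("e2", "Demande si COORDINATEUR SLA peut le rappeler pour son pb de FRE.")
  ann <- annotate_document(doc, idx)
  expect_true("soc:FauteuilRoulantElectrique" %in% ann$iri)       # FRE
  fre <- ann[ann$iri == "soc:FauteuilRoulantElectrique", ]
  expect_equal(fre$surface, "FRE")
  expect_equal(substring(doc$text, fre$start + 1, fre$end), "FRE")
  expect_true("coord:Coordinateur" %in% ann$iri)                  # two-token alt label
  # no lexicon term present -> empty
  expect_equal(nrow(annotate_document(onto_document("e3", "rien à signaler aujourd'hui"), idx)), 0L)
})

test_that("longest match dominates a strict token-prefix term", {
  mod <- onto_module("m",
    concepts = data.frame(iri = c("short", "long"), module = "m", stringsAsFactors = FALSE),
    labels = data.frame(iri = c("short", "long"), kind = "pref", lang = "fr",
                        text = c("fauteuil", "fauteuil roulant"), stringsAsFactors = FALSE))
  idx <- build_term_index(consolidate(list(mod)))
  ann <- annotate_document(onto_document("d", "un fauteuil roulant neuf"), idx)
  expect_equal(ann$iri, "long")                       # only the longer term fires
  ann2 <- annotate_document(onto_document("d", "un fauteuil neuf"), idx)
  expect_equal(ann2$iri, "short")
})

test_that("concepts sharing a surface each get an annotation at the same span", {
  mod <- onto_module("m",
    concepts = data.frame(iri = c("c1", "c2"), module = "m", stringsAsFactors = FALSE),
    labels = data.frame(iri = c("c1", "c2"), kind = "pref", lang = "fr",
                        text = "ambigu", stringsAsFactors = FALSE))
  idx <- build_term_index(consolidate(list(mod)))
  ann <- annotate_document(onto_document("d", "cas ambigu ici"), idx)
  expect_setequal(ann$iri, c("c1", "c2"))
  expect_equal(unique(ann$start), ann$start[1])
})

test_that("lemma-level fallback matches inflected mentions", {
  idx <- build_term_index(fixture_ontology())
  ann <- annotate_document(onto_document("d", "deux chutes cette semaine"), idx)
  expect_true("med:Chute" %in% ann$iri)
  expect_equal(ann$source[ann$iri == "med:Chute"], "lemma")
  ann2 <- annotate_document(onto_document("d", "deux chutes cette semaine"), idx,
                            lemma_matching = FALSE)
  expect_false("med:Chute" %in% ann2$iri)
})

test_that("negation is detected from Table-1-style sentences", {
  idx <- build_term_index(fixture_ontology())
  ann <- annotate_document(onto_document("e1", table1_text), idx)
  sdb <- ann[ann$iri == "soc:SalleDeBain", ]
  expect_equal(nrow(sdb), 1L)
  expect_true(sdb$negated)          # "ne pourrons pas ... la SDB n'est pas"
  # trigger-free sentence: all flags false
  ann2 <- annotate_document(onto_document("d", "la SDB est adaptée"), idx)
  expect_false(any(ann2$negated))
})

test_that("negation flags equal a brute-force application of the window rule", {
  set.seed(31)
  filler <- c("le", "patient", "demande", "une", "aide", "pour", "son", "retour")
  trig <- c("ne", "pas", "sans", "aucun", "jamais", "non", "plus")
  oracle_negated <- function(norm, pos, W = 5L) {
    is_ne <- norm == "ne"
    before <- seq_len(pos - 1L)
    window <- before[before >= pos - W]
    plain <- c("ne", "pas", "aucun", "aucune", "sans", "jamais", "non")
    if (any(norm[window] %in% plain)) return(TRUE)
    ne_at <- before[is_ne[before]]
    comp <- before[norm[before] %in% c("pas", "plus")]
    length(ne_at) > 0 && any(comp > min(ne_at))
  }
  for (k in 1:60) {
    n <- sample(6:14, 1)
    words <- sample(c(filler, trig), n, replace = TRUE, prob = c(rep(3, 8), rep(1, 7)))
    starts <- cumsum(c(0L, nchar(words[-n]) + 1L))
    sent <- data.frame(surface = words, start = starts, end = starts + nchar(words),
                       norm = words, lemma = words, stringsAsFactors = FALSE)
    ann_at <- sample(n, min(3, n))
    got <- detect_negation(sent, sent$start[ann_at])
    want <- vapply(ann_at, function(i) oracle_negated(words, i), TRUE)
    expect_identical(got, want)
  }
})

test_that("inline XML strips back to the original text byte for byte", {
  idx <- build_term_index(fixture_ontology())
  doc <- onto_document("x1", table1_text)
  ann <- annotate_document(doc, idx)
  f <- tempfile(fileext = ".xml")
  export_inline_xml(doc, ann, f)
  expect_identical(strip_inline_xml(f), doc$text)
  xml2::read_xml(f)   # well-formed
  # escaping: specials in text survive the round trip
  doc2 <- onto_document("x2", "a < b & \"c\" > d; la SDB est là")
  f2 <- tempfile(fileext = ".xml")
  export_inline_xml(doc2, annotate_document(doc2, idx), f2)
  expect_identical(strip_inline_xml(f2), doc2$text)
  xml2::read_xml(f2)
})

test_that("non-nestable overlaps are dropped with a warning on export", {
  doc <- onto_document("d", "abcdefghij")
  ann <- data.frame(doc_id = "d", start = c(0L, 3L), end = c(5L, 8L),
                    surface = c("abcde", "defgh"), iri = c("a", "b"),
                    kind = "pref", source = "surface", negated = FALSE,
                    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".xml")
  expect_warning(export_inline_xml(doc, ann, f), "overlap")
  expect_identical(strip_inline_xml(f), doc$text)
})

test_that("annotation is deterministic and standoff files round trip", {
  idx <- build_term_index(fixture_ontology())
  doc <- onto_document("d1", table1_text)
  a1 <- annotate_document(doc, idx)
  a2 <- annotate_document(doc, idx)
  expect_identical(a1, a2)
  f <- tempfile(fileext = ".tsv")
  write_standoff(a1, f)
  back <- read_standoff(f)
  expect_identical(back, a1[c("doc_id", "start", "end", "surface", "iri", "negated")])
})

test_that("corpus directories round trip through the sidecar CSV", {
  docs <- data.frame(doc_id = c("P1_E001", "P1_E002"), patient_id = "P1",
                     date = c("2024-01-05", "2024-02-01"),
                     text = c("ligne un\nligne deux", "pb de FRE"),
                     stringsAsFactors = FALSE)
  d <- file.path(tempfile(), "corpus")
  write_corpus(docs, d)
  back <- read_corpus(d)
  expect_identical(back[order(back$doc_id), ]$text, docs$text)
  expect_identical(back$patient_id, docs$patient_id)
})
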