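make_ann <- function(doc_id, iri, negated = FALSE) {
  n <- max(length(doc_id), length(iri))
  data.frame(doc_id = rep_len(doc_id, n), start = rep_len(0L, n),
             end = rep_len(1L, n), surface = rep_len("x", n),
             iri = rep_len(iri, n), kind = rep_len("pref", n),
             source = rep_len("surface", n),
             negated = rep_len(negated, n), stringsAsFactors = FALSE)
}

test_that("a hand-built exhaustion scenario sums to 3 under the exhaustion domain", {
  ont <- fixture_ontology()
  docs <- data.frame(doc_id = c("d1", "d2"), patient_id = "P1", stringsAsFactors = FALSE)
  ann <- make_ann(c("d1", "d1", "d2"),
                  c("soc:EpuisementAidant", "soc:EpuisementAidant", "coord:DemandeSejourRepit"))
  m <- aggregate_counts(ann, docs, ont, mode = "defined_only")
  expect_equal(m["P1", "core:DomaineEpuisement"], 3L)
  expect_equal(sum(m["P1", colnames(m) != "core:DomaineEpuisement"]), 0L)
  # presence after dichotomization
  expect_equal(dichotomize(m)["P1", "core:DomaineEpuisement"], 1L)
})

test_that("no annotations give an all-zero matrix with the full column set", {
  ont <- fixture_ontology()
  docs <- data.frame(doc_id = "d1", patient_id = "P1", stringsAsFactors = FALSE)
  m <- aggregate_counts(make_ann(character(), character()), docs, ont,
                        mode = "defined_only", patient_ids = c("P1", "P2"))
  expect_equal(dim(m), c(2L, nrow(ont$defined)))
  expect_true(all(m == 0L))
  expect_equal(colnames(m), ont$defined$iri)
  expect_equal(rownames(m), c("P1", "P2"))   # cohort frame from the patient table
})

test_that("all-concepts totals conserve the number of non-filtered annotations", {
  ont <- fixture_ontology()
  set.seed(41)
  docs <- data.frame(doc_id = sprintf("d%d", 1:20),
                     patient_id = sample(c("P1", "P2", "P3"), 20, replace = TRUE),
                     stringsAsFactors = FALSE)
  ann <- make_ann(sample(docs$doc_id, 60, replace = TRUE),
                  sample(ont$concepts$iri, 60, replace = TRUE),
                  negated = stats::runif(60) < 0.3)
  m_ex <- aggregate_counts(ann, docs, ont, mode = "all_concepts")
  expect_equal(sum(m_ex), sum(!ann$negated))
  m_all <- aggregate_counts(ann, docs, ont, mode = "all_concepts",
                            negation_policy = "include_all")
  expect_equal(sum(m_all), nrow(ann))
  # monotone in the negation policy
  expect_true(all(m_all >= m_ex))
})

test_that("defined-only cells equal the brute-force descendant-set sum", {
  ont <- fixture_ontology()
  set.seed(42)
  docs <- data.frame(doc_id = sprintf("d%d", 1:30),
                     patient_id = sample(sprintf("P%d", 1:5), 30, replace = TRUE),
                     stringsAsFactors = FALSE)
  ann <- make_ann(sample(docs$doc_id, 200, replace = TRUE),
                  sample(c(ont$concepts$iri, ont$defined$iri), 200, replace = TRUE))
  m <- aggregate_counts(ann, docs, ont, mode = "defined_only")
  pid <- docs$patient_id[match(ann$doc_id, docs$doc_id)]
  for (D in ont$defined$iri) {
    members <- oracle_descendants(ont, D)
    for (p in rownames(m)) {
      expect_equal(m[p, D], sum(pid == p & ann$iri %in% members))
    }
  }
  # defined-only totals dominate direct counts of the defined concept alone
  direct <- table(factor(pid, rownames(m)), factor(ann$iri, ont$defined$iri))
  expect_true(all(m >= as.matrix(direct)[rownames(m), colnames(m)]))
})

test_that("annotations outside the ontology or corpus are hard errors", {
  ont <- fixture_ontology()
  docs <- data.frame(doc_id = "d1", patient_id = "P1", stringsAsFactors = FALSE)
  expect_error(aggregate_counts(make_ann("d1", "zz:Nope"), docs, ont), "mismatch")
  expect_error(aggregate_counts(make_ann("d9", "med:Chute"), docs, ont), "doc_id")
  expect_error(aggregate_counts(make_ann("d1", "med:Chute"), docs,
                                fixture_ontology(reasoned = FALSE)), "reasoned")
})

test_that("dichotomization thresholds counts as presence", {
  m <- matrix(c(0L, 1L, 5L), nrow = 3, dimnames = list(c("a", "b", "c"), "X"))
  expect_equal(as.vector(dichotomize(m, 1L)), c(0L, 1L, 1L))
  expect_equal(as.vector(dichotomize(m, 2L)), c(0L, 0L, 1L))
  # presence percentage equals a direct recount
  set.seed(43)
  counts <- matrix(rpois(60, 0.8), nrow = 20,
                   dimnames = list(sprintf("P%d", 1:20), c("A", "B", "C")))
  bin <- dichotomize(counts)
  expect_equal(colSums(bin), colSums(counts >= 1))
})

test_that("CSV export carries labels and parses back to the same counts", {
  ont <- fixture_ontology()
  docs <- data.frame(doc_id = "d1", patient_id = "P1", stringsAsFactors = FALSE)
  ann <- make_ann(c("d1", "d1"), c("soc:EpuisementAidant", "med:Chute"))
  m <- aggregate_counts(ann, docs, ont, mode = "defined_only")
  f <- tempfile(fileext = ".csv")
  export_matrix_csv(m, f, ontology = ont)
  back <- utils::read.csv(f, check.names = FALSE)
  expect_equal(names(back)[-1], pref_label(ont, colnames(m)))
  expect_equal(unname(unlist(back[1, -1])), unname(m["P1", ]))
  f2 <- tempfile(fileext = ".tsv")
  export_matrix_long(m, f2)
  long <- utils::read.table(f2, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(sum(long$count), sum(m))
})
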