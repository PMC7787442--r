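std <- function(doc, start, end, iri, negated = FALSE) {
  data.frame(doc_id = doc, start = start, end = end,
             surface = substring(paste(rep("x", 99), collapse = ""), start + 1, end),
             iri = iri, negated = negated, stringsAsFactors = FALSE)
}

test_that("identical gold and system score 1.0 under any policy", {
  g <- std("d1", c(0L, 10L, 20L), c(5L, 14L, 26L), c("a", "b", "a"))
  for (sm in c("exact", "overlap")) for (nm in c(TRUE, FALSE)) {
    ev <- evaluate_annotations(g, g, match_policy(span_mode = sm,
                                                  negation_must_match = nm))
    expect_equal(ev$precision, 1)
    expect_equal(ev$recall, 1)
    expect_equal(ev$f_measure, 1)
  }
})

test_that("the standard formulas apply to raw counts", {
  ev <- rep_from_counts(9, 1, 1)
  expect_equal(ev$precision, 0.9)
  expect_equal(ev$recall, 0.9)
  expect_equal(ev$f_measure, 0.9)
})

test_that("counting identities and symmetry hold on random annotation sets", {
  set.seed(51)
  for (k in 1:10) {
    g <- std("d1", seq(0, 90, 10), seq(4, 94, 10),
             sample(c("a", "b", "c"), 10, replace = TRUE))
    s <- g[sample(10, 7), ]
    s$iri[1] <- "zz"                        # concept error
    s <- rbind(s, std("d1", 95L, 99L, "a")) # spurious
    ev <- evaluate_annotations(g, s)
    expect_equal(ev$tp + ev$fn, nrow(g))
    expect_equal(ev$tp + ev$fp, nrow(s))
    swapped <- evaluate_annotations(s, g)
    expect_equal(swapped$precision, ev$recall)
    expect_equal(swapped$recall, ev$precision)
    # F between min and max of P and R
    if (ev$precision + ev$recall > 0) {
      expect_gte(ev$f_measure, min(ev$precision, ev$recall) - 1e-12)
      expect_lte(ev$f_measure, max(ev$precision, ev$recall) + 1e-12)
    }
  }
})

test_that("zero-denominator conventions are fixed", {
  g <- std("d1", 0L, 4L, "a")
  none <- g[0, ]
  ev <- evaluate_annotations(g, none)
  expect_equal(ev$precision, 0)
  expect_equal(ev$recall, 0)
  expect_equal(ev$f_measure, 0)
  both <- evaluate_annotations(none, none)
  expect_equal(both$precision, 1)
  expect_equal(both$recall, 1)
})

test_that("matches under the strict policy survive laxer policies", {
  ont <- fixture_ontology()
  g <- std("d1", c(0L, 10L), c(5L, 18L), c("med:Chute", "soc:BesoinRepit"))
  s <- std("d1", c(0L, 11L), c(5L, 18L), c("med:ChuteRepetee", "soc:BesoinRepit"))
  strict <- evaluate_annotations(g, s)
  lax <- evaluate_annotations(g, s, match_policy(span_mode = "overlap",
                                                 concept_mode = "ancestor_ok"),
                              ontology = ont)
  expect_gte(lax$tp, strict$tp)
  expect_equal(lax$tp, 2L)   # subclass concept + overlapping span both accepted
  expect_equal(strict$tp, 0L)
  expect_error(evaluate_annotations(g, s, match_policy(concept_mode = "ancestor_ok")),
               "ontology")
})

test_that("per-concept breakdown partitions the corpus-level counts", {
  g <- std("d1", c(0L, 10L, 20L), c(5L, 15L, 25L), c("a", "a", "b"))
  s <- std("d1", c(0L, 10L, 40L), c(5L, 15L, 45L), c("a", "b", "b"))
  ev <- evaluate_annotations(g, s)
  pc <- ev$per_concept
  expect_equal(sum(pc$tp), ev$tp)
  expect_equal(sum(pc$fp), ev$fp)
  expect_equal(sum(pc$fn), ev$fn)
})

test_that("misses on a noisy bundle are exactly the corrupted mentions", {
  ont <- fixture_ontology()
  idx <- build_term_index(ont)
  b <- generate_cohort(sim_config(seed = 19, n_patients = 6, misspell_rate = 0.12,
                                  negation_rate = 0.1), ont)
  ann <- annotate_corpus(b$docs, idx)
  ev <- evaluate_annotations(b$gold, ann)
  expect_lt(ev$recall, 1)
  expect_equal(ev$fn, sum(b$gold$corrupted))
  # every miss is a corrupted planted surface
  key <- function(d) paste(d$doc_id, d$start, d$end, d$iri)
  missed <- setdiff(key(b$gold), key(ann))
  expect_true(all(missed %in% key(b$gold[b$gold$corrupted, ])))
  # report files are written
  f <- tempfile(fileext = ".json")
  write_eval_report(ev, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$tp, ev$tp)
})
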