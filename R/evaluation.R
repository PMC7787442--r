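# Annotation-quality evaluation: precision, recall and F-measure of a system
# annotation set against an expert gold standard, under a configurable
# matching policy.

#' Matching policy for annotation evaluation
#'
#' @param span_mode `"exact"` (spans must be identical) or `"overlap"`
#'   (any character overlap).
#' @param concept_mode `"exact_iri"` or `"ancestor_ok"` (a system concept
#'   matches a gold concept that is one of its ancestors or descendants in
#'   the reasoned hierarchy; needs `ontology` at evaluation time).
#' @param negation_must_match require equal negation flags (default FALSE).
#' @return list of class `match_policy`.
#' @export
match_policy <- function(span_mode = c("exact", "overlap"),
                         concept_mode = c("exact_iri", "ancestor_ok"),
                         negation_must_match = FALSE) {
  structure(list(span_mode = match.arg(span_mode),
                 concept_mode = match.arg(concept_mode),
                 negation_must_match = isTRUE(negation_must_match)),
            class = "match_policy")
}

#' Evaluate system annotations against a gold standard
#'
#' Pairs gold and system annotations one-to-one, greedily in (doc, span)
#' order: each system annotation is matched to the first unmatched gold
#' annotation compatible under the policy. Under the default strict policy
#' (exact span, exact IRI, negation ignored) the pairing is unambiguous.
#' Always `TP + FN = |gold|` and `TP + FP = |system|`.
#'
#' Zero-denominator conventions: with an empty system and non-empty gold,
#' precision is defined as 0 (and recall and F are 0); with both sets empty
#' all three measures are defined as 1.
#'
#' @param gold,system annotation data frames (standoff layout: `doc_id`,
#'   `start`, `end`, `iri`, `negated`).
#' @param policy a [match_policy()].
#' @param ontology reasoned `ontology`, required for
#'   `concept_mode = "ancestor_ok"`.
#' @return list of class `eval_report`: `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f_measure`, and `per_concept` (same counts by gold IRI).
#' @export
evaluate_annotations <- function(gold, system, policy = match_policy(),
                                 ontology = NULL) {
  stopifnot(inherits(policy, "match_policy"))
  if (policy$concept_mode == "ancestor_ok" && is.null(ontology))
    stop("concept_mode 'ancestor_ok' needs the ontology", call. = FALSE)
  g <- gold[order(gold$doc_id, gold$start, gold$end, gold$iri), , drop = FALSE]
  s <- system[order(system$doc_id, system$start, system$end, system$iri), , drop = FALSE]
  ng <- nrow(g); ns <- nrow(s)

  concept_ok <- if (policy$concept_mode == "exact_iri") {
    function(gi, si) gi == si
  } else {
    desc_memo <- new.env(parent = emptyenv())
    desc_of <- function(iri) {
      if (is.null(desc_memo[[iri]])) desc_memo[[iri]] <- descendants(ontology, iri)
      desc_memo[[iri]]
    }
    function(gi, si) gi == si || si %in% desc_of(gi) || gi %in% desc_of(si)
  }
  span_ok <- if (policy$span_mode == "exact") {
    function(i, j) g$start[i] == s$start[j] && g$end[i] == s$end[j]
  } else {
    function(i, j) g$start[i] < s$end[j] && s$start[j] < g$end[i]
  }

  matched_g <- rep(FALSE, ng)
  matched_s <- rep(FALSE, ns)
  gi_by_doc <- split(seq_len(ng), if (ng) g$doc_id else character())
  for (j in seq_len(ns)) {
    cand <- gi_by_doc[[s$doc_id[j]]]
    if (is.null(cand)) next
    for (i in cand) {
      if (matched_g[i]) next
      if (!span_ok(i, j)) next
      if (!concept_ok(g$iri[i], s$iri[j])) next
      if (policy$negation_must_match && !identical(g$negated[i], s$negated[j])) next
      matched_g[i] <- TRUE; matched_s[j] <- TRUE
      break
    }
  }
  tp <- sum(matched_s); fp <- ns - tp; fn <- ng - tp
  rep_from_counts(tp, fp, fn,
                  per_concept = per_concept_breakdown(g, s, matched_g, matched_s))
}

per_concept_breakdown <- function(g, s, matched_g, matched_s) {
  iris <- sort(unique(c(g$iri, s$iri)))
  do.call(rbind, lapply(iris, function(ci) {
    tp <- sum(matched_g[g$iri == ci])
    fn <- sum(!matched_g[g$iri == ci])
    fp <- sum(!matched_s[s$iri == ci])
    data.frame(iri = ci, tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Evaluation report from raw counts
#'
#' Direct application of the standard formulas: P = TP/(TP+FP),
#' R = TP/(TP+FN), F = 2PR/(P+R), with the zero-denominator conventions of
#' [evaluate_annotations()].
#'
#' @param tp,fp,fn non-negative integer counts.
#' @param per_concept optional per-concept breakdown data frame.
#' @return list of class `eval_report`.
#' @export
rep_from_counts <- function(tp, fp, fn, per_concept = NULL) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp + fn == 0) {
    p <- r <- f <- 1
  } else {
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
                 precision = p, recall = r, f_measure = f,
                 per_concept = per_concept),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat("<annotation evaluation>\n")
  cat(sprintf("  TP %d  FP %d  FN %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  precision %.*f  recall %.*f  F-measure %.*f\n",
              digits, x$precision, digits, x$recall, digits, x$f_measure))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report an `eval_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  out <- report[c("tp", "fp", "fn", "precision", "recall", "f_measure")]
  if (!is.null(report$per_concept)) out$per_concept <- report$per_concept
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
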