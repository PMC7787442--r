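---
title: "From coordination notes to count matrices: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From coordination notes to count matrices: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontopath)
```

`ontopath` converts a corpus of short, pseudo-anonymized French
care-coordination notes into patient × concept count matrices and runs the
association analyses those matrices support. This vignette is the package's
account of how each stage works, which knobs matter, and where the design
was genuinely open.

## The ontology model and what "fully defined" means

An ontology here is a set of modules, each declaring named concepts with
multilingual preferred/alternative labels, asserted subclass links,
existential property assertions `(P, F)` on classes, and *fully defined
concepts*: classes equivalent to a single existential restriction,
`D ≡ ∃P.F`, i.e. necessary **and** sufficient conditions. A consolidation
step merges the modules after checking three things: the import graph is
acyclic, IRIs never collide across modules, and every reference left
pending by an individual module (a parent, property or filler declared
elsewhere) resolves in the merged set. IRIs are opaque strings and module
membership is declared per concept, never parsed out of a namespace. The
merged frames are canonically sorted, which is what makes consolidation
provably order-independent (a tested invariant).

Only one restriction per defined concept is supported; a second `ASSERT`
on a `DEFINED` record is a validation error rather than a silent
conjunction, because silent conjunction would change aggregation semantics
without any visible signal in the data files.

### Inference

The reasoner implements exactly the fragment the model uses (a small EL
subset): for each `D ≡ ∃P.F`, a named concept `C` is inferred below `D`
iff some assertion `(P, F′)` with `F′ ⊑ F` is found on `C` **or on one of
its asserted ancestors**. Both choices — assertion inheritance and filler
subclass closure — are standard description-logic semantics: a subclass of
"patient carer exhaustion" must classify under the exhaustion theme even
though it carries no assertion of its own. Two deliberate restrictions:
no subproperty reasoning (the model declares none), and inference never
places one defined concept below another unless that link is asserted.
Correctness is established in the test suite against a brute-force oracle
that evaluates every (concept, defined concept) pair from the definition,
over seeded random ontologies of up to 500 concepts; idempotence and
monotonicity under added assertions are tested as properties.

## Normalization, matching and negation

Labels and documents pass through the *same* tokenizer and normalizer —
the only consistency dictionary matching actually requires. Tokens are
maximal letter/digit runs; every other non-space character is its own
token, so apostrophes and hyphens split (`aujourd'hui` →
`aujourd / ' / hui`). Normalization lowercases and folds French diacritics
and ligatures to ASCII. Raw label surfaces are preserved in the index, so
label-count metrics are computed on raw strings even when folding makes
two variants (e.g. `med tt` / `méd tt`) collide on one key; such keys
simply hold several entries.

The annotator scans each sentence left to right and takes the **longest**
matching term at each position, resuming after it; the matching policy is
the standard gazetteer behaviour and is required so that
`fauteuil roulant électrique` beats any embedded shorter term. Surface
tokens are tried first, then lemmas from a pluggable lemmatizer (the
default is a small exception table plus conservative French suffix rules;
any `function(tokens) -> lemmas` can be substituted). When several
concepts share the winning term, each gets an annotation — no word-sense
disambiguation is attempted, and aggregation tolerates the multiplicity.
Spelling correction is a configurable substitution table applied to
normalized tokens, not an automatic corrector: a table is auditable and
its effect attributable.

Negation: an annotation is negated iff a trigger from the French lexicon
(`ne`, `n'`, `pas`, `aucun`, `aucune`, `sans`, `jamais`, `non`) occurs in
the same sentence within **W = 5** tokens before the annotation, or
`pas`/`plus` completes a preceding `ne` anywhere between that `ne` and the
annotation (`plus` only ever counts in the `ne … plus` pattern). The
elided `n'` is recognised as token `n` followed by an apostrophe, because
that is what the tokenizer produces. W = 5 is the default window; both the
window and the trigger list are arguments. Sentence boundaries fall after
`. ! ? ; …` and at line breaks — sentence splitting rules are this
package's own, stated here because upstream annotation frameworks leave
them implicit.

Offsets are 0-based half-open on the original, pre-normalization text.
That makes the inline-XML export lossless: stripping the tags reproduces
the input byte for byte (a fuzz-tested invariant). Annotations emitted by
the annotator are disjoint or span-identical; if hand-made standoff input
contains a partial overlap that cannot nest, the later-starting annotation
is dropped with a warning.

## Aggregation

`all_concepts` mode counts direct matches per concept — no ancestor
propagation, because the export is of occurrences *identified*.
`defined_only` mode sums, for each fully defined concept, over its
reflexive inferred descendant closure, counting each annotation once per
defined concept even when the closure reaches it through several paths
(set semantics; avoids double counting in a DAG). Negated mentions are
**excluded by default** and kept under `negation_policy = "include_all"`:
whether negated mentions should count downstream is genuinely open — the
upstream material handles negation but never states the counting policy —
so both behaviours exist and the default is the conservative one.
Where one span carries several concepts, each counts once; this
once-per-concept policy is likewise documented rather than assumed.
The cohort frame comes from the patient table, not the corpus: patients
with zero documents appear as all-zero rows, which matters because real
cohorts contain patients with a single recorded event.

## Evaluation

Precision = TP/(TP+FP), recall = TP/(TP+FN), F = 2PR/(P+R), with a
one-to-one greedy pairing in (document, span) order. The default policy is
the strictest reproducible one — exact span, exact concept IRI, negation
ignored — with laxer options (character overlap, ancestor-compatible
concepts) because human evaluation of annotations is typically per event,
not per character. Zero-denominator conventions are fixed: empty system
against non-empty gold gives P = R = F = 0; two empty sets give 1.

## The synthetic cohort generator

The generator exists so that every stage is testable with *no* access to
the private clinical database. It emulates precisely the features the
pipeline is sensitive to, and nothing else:

* telegraphic template sentences with role placeholders (PROFESSIONNEL,
  NEUROLOGUE, COORDINATEUR SLA) — not natural language, since matching is
  lexical and realism beyond lexicon usage adds nothing testable;
* events per patient lognormal matched to mean 33.6 / SD 32.13 (floored at
  one event), the observed heterogeneity of coordination recording;
* cohort margins fixed once at realistic values: 52% men; spinal onset
  71% in men / 60% in women; ages ~N(63.4, 11.9) for men, N(67.15, 11.8)
  for women, truncated to 20–90; follow-up lognormal with mean 550 days;
  marital-status and lifestyle margins of a typical ALS network cohort;
* per-event theme mention rates (defaults: technical aids 0.86,
  coordination actions 2.2, exhaustion / human help / social help ≈ 0.11,
  motor signs 0.13, cognitive signs 0.015) chosen once so that per-patient
  totals have the magnitude seen in such cohorts — frequent technical-aid
  and coordination mentions, rare cognitive mentions;
* a latent standard-normal motor severity per patient that multiplies the
  motor-theme rate by `exp(0.8 z)` and — the planted effect — the
  exhaustion-theme rate by `exp(β z)` with β = 0.5 by default;
* abbreviation variants with probability 0.5, misspellings as recorded
  single-character edits applied **only to planted mentions** (so recall
  loss is attributable mention by mention), and negation wrappers drawn
  from trigger-bearing templates.

Template vocabulary deliberately avoids every lexicon surface except the
planted ones, so on a clean bundle (no misspelling) system annotations
equal gold exactly and precision = recall = 1 by construction — that
end-to-end identity is itself a test. What the generator does **not**
emulate: out-of-lexicon paraphrase, word-sense ambiguity, real misspelling
distributions, discourse structure, temporal dynamics. Passing tests on
synthetic data therefore demonstrate the mechanics of the pipeline, not
annotation quality on real clinical text — that still requires expert
evaluation, which is what the evaluation module scores.

Determinism: the same seed, config and ontology give byte-identical
corpora and gold files (tested via checksums).

## Statistics

`describe_population()` reports mean/SD/min–max per sex and overall for
numeric fields and n(%) for categorical ones; the SD of a single
observation is reported as 0 by convention (the sample SD is undefined at
n = 1). `association_scan()` fits one OLS model per outcome with the full
predictor set by default (`joint = FALSE` gives single-predictor models;
which of the two a published per-outcome table used is typically
unstated, so both exist). Per-predictor p-values come from `drop1` F
tests, which treat numeric covariates and multi-level factors uniformly.
The Benjamini–Hochberg family is the set of predictors within one
outcome's scan — matching the per-outcome block structure of the tables
such scans feed — and LogWorth = −log₁₀(adjusted p) is the ranking
statistic. Clinical-state predictors ("motor state", "cognitive state")
are operationalized as the patient's own defined-concept counts joined
onto the patient table, the natural coding when those states are
themselves annotation-derived. Missing covariates are dropped per scan
(complete cases); constant outcomes are flagged and get no p-values.

## Problem sizes and numerical conventions

The test suite and the acceptance script use: 100 seeded random
ontologies of 20–500 concepts for the reasoner/oracle comparison; a
50-patient clean bundle (~1,700 documents) for the end-to-end identity;
20 replicates of a 500-patient cohort for rank recovery of the planted
motor→exhaustion effect; 1,000 fuzzed documents for the XML round trip.
These sizes make the full suite run in a few minutes while leaving the
statistical checks well-powered. Other conventions: BH-adjusted p-values
are compared at numeric tolerance (floating point), dichotomization uses
threshold ≥ 1, and exported CSV/TSV files are UTF-8 with deterministic
column order (ontology declaration order).

## Known limitations

* The RDF/XML reader covers the OWL subset the model needs (named
  classes, subclass links, someValuesFrom restrictions, equivalentClass
  restrictions, SKOS/RDFS labels) — not unions, cardinalities or property
  chains; files using those constructs fail loudly.
* The default lemmatizer is intentionally shallow; plug in a full French
  lemmatizer through the contract where lemma-level recall matters.
* Negation is trigger-and-window based; it does not model scope-ending
  cues or double negation.
* No temporal binning: counts collapse a patient's whole history, so
  chronology-dependent questions are out of reach of the matrices this
  package produces.
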