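# ontopath

Turning unstructured French care-coordination notes into structured,
analysable quantitative data.

Regional coordination networks for neurodegenerative diseases (the motivating
case is amyotrophic lateral sclerosis) record most of what happens to a
patient as short free-text "events": call transcriptions, transmissions,
reports. These notes are telegraphic, heavy with ad-hoc abbreviations
("PEC" for *prise en charge*, "SDB" for *salle de bain*, "FRE" for *fauteuil
roulant électrique*), and pseudo-anonymized with role tokens (PROFESSIONNEL,
NEUROLOGUE). `ontopath` implements the full pipeline that makes such a corpus
quantitatively usable, for clinical-informatics researchers studying care
pathways:

1. **Modular ontology model** — load, validate and consolidate ontology
   modules (core, medical, socio-environmental, coordination, plus a
   consolidation module that declares no concepts of its own), from RDF/XML
   (OWL subset) or a hand-writable plaintext dialect. Concepts carry
   multilingual preferred and alternative labels (synonyms, acronyms,
   spelling variants).
2. **Reasoner** — *fully defined concepts* are classes equivalent to an
   existential restriction, D ≡ ∃P.F. The reasoner infers C ⊑ D for every
   named concept C carrying an assertion (P, F′) with F′ ⊑ F, where
   assertions are inherited down the asserted hierarchy. This groups every
   concept touching one theme (e.g. a "field of exhaustion" spanning carer
   exhaustion, respite-care needs, requests and proposals) under a single
   analytic variable, across modules.
3. **Lexicon + annotator** — ontology labels are compiled into an exact
   multi-word term index (lower-casing, French accent folding, punctuation
   splitting); documents are annotated by a left-to-right longest-match scan,
   surface first, lemmas as fallback, with French negation detection
   ("ne … pas", "sans", "aucun", …) and lossless inline-XML plus standoff
   TSV export.
4. **Aggregator** — patient × concept count matrices, either over all
   concepts (direct matches) or restricted to the fully defined concepts
   (counts summed over the inferred descendant closure), with presence/absence
   dichotomization and CSV export.
5. **Evaluation** — precision, recall and F-measure (F = 2PR/(P+R)) of system
   annotations against an expert gold standard under configurable matching
   policies.
6. **Statistics** — cohort descriptions, per-concept presence tables, OLS
   association scans of concept counts on patient covariates with
   Benjamini–Hochberg FDR adjustment and LogWorth (−log₁₀ adjusted p)
   ranking, two-group contrasts, Pearson correlations.
7. **Synthetic cohort generator** — a seeded generator of patient tables,
   French-like event documents and gold annotations with known planted
   structure (abbreviation use, misspellings, negations, covariate effects),
   so the whole pipeline is testable without any private clinical data.

## Worked example

```r
library(ontopath)

ont <- fixture_ontology()          # bundled five-module ontology, reasoned
idx <- build_term_index(ont)       # French term index from pref/alt labels

doc <- onto_document("evt1",
  "Appel de PROFESSIONNEL : nous ne pourrons pas utiliser la SDB. Demande pour son pb de FRE.",
  patient_id = "P0001")
ann <- annotate_document(doc, idx)
ann[, c("start", "end", "surface", "iri", "negated")]
#>   start end       surface                           iri negated
#> 1     9  22 PROFESSIONNEL        med:ProfessionnelSante   FALSE
#> 2    58  61           SDB               soc:SalleDeBain    TRUE
#> 3    86  89           FRE soc:FauteuilRoulantElectrique   FALSE
```

The abbreviation "FRE" resolves to the electric-wheelchair concept, and the
bathroom mention is flagged negated because it sits in the scope of
"ne pourrons pas". Aggregating to the fully defined concepts (negated
mentions excluded by default):

```r
docs <- data.frame(doc_id = "evt1", patient_id = "P0001")
m <- aggregate_counts(ann, docs, ont, mode = "defined_only")
m[, colSums(m) > 0, drop = FALSE]
#>       core:DomaineAideTechnique
#> P0001                         1
```

The wheelchair mention counts once under the technical-aids domain; the
negated bathroom mention counts nowhere. On a synthetic cohort the round
trip is exact by construction:

```r
b <- generate_cohort(sim_config(seed = 42, n_patients = 20), ont)
evaluate_annotations(b$gold, annotate_corpus(b$docs, idx))
#> <annotation evaluation>
#>   TP 2653  FP 0  FN 0
#>   precision 1.000  recall 1.000  F-measure 1.000
```

From there, `dichotomize()`, `presence_table()`, `association_scan()`,
`group_contrast()` and `correlate()` reproduce the downstream analyses on
(patient table × count matrix). See the methods vignette
(`vignettes/ontopath-methods.Rmd`) for the model, the matching and negation
rules, the generator's design and its limitations.

A thin command-line front end covering the whole pipeline
(consolidate / reason / lexicon / annotate / aggregate / evaluate / simulate)
is installed at `system.file("cli", "ontopath.R", package = "ontopath")`.

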