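# Patient x concept count matrices from annotation streams.

#' Aggregate annotations into a patient-by-concept count matrix
#'
#' In `all_concepts` mode, cell (p, c) is the number of annotations of
#' exactly concept c across patient p's documents (no ancestor propagation:
#' the export is of occurrences identified, i.e. direct matches). In
#' `defined_only` mode the columns are the ontology's fully defined concepts
#' and cell (p, D) sums the counts over the reflexive inferred descendant
#' closure of D, counting each annotation once per defined concept even when
#' it reaches D through several paths. Negated mentions are excluded by
#' default; `include_all` keeps them.
#'
#' Patients with zero documents still appear as all-zero rows when
#' `patient_ids` supplies the cohort frame (the cohort comes from the
#' patient table, not the corpus).
#'
#' @param annotations annotation data frame (`doc_id`, `iri`, `negated`, ...).
#' @param docs corpus data frame mapping `doc_id` to `patient_id`.
#' @param ontology a consolidated `ontology`; must be reasoned
#'   (see [infer_defined_members()]) when `mode = "defined_only"`.
#' @param mode `"defined_only"` (default) or `"all_concepts"`.
#' @param negation_policy `"exclude_negated"` (default) or `"include_all"`.
#' @param patient_ids optional character vector fixing the row frame.
#' @return integer matrix with patient ids as rows and concept IRIs as
#'   columns (ontology declaration order), with attributes `mode` and
#'   `negation_policy`.
#' @export
aggregate_counts <- function(annotations, docs, ontology,
                             mode = c("defined_only", "all_concepts"),
                             negation_policy = c("exclude_negated", "include_all"),
                             patient_ids = NULL) {
  mode <- match.arg(mode)
  negation_policy <- match.arg(negation_policy)
  stopifnot(inherits(ontology, "ontology"))
  known <- c(ontology$concepts$iri, ontology$defined$iri)
  stray <- setdiff(unique(annotations$iri), known)
  if (length(stray))
    stop("annotation(s) reference iri(s) absent from the ontology ",
         "(lexicon/ontology mismatch): ", paste(utils::head(stray, 5L), collapse = ", "),
         call. = FALSE)
  if (mode == "defined_only" && !isTRUE(attr(ontology, "reasoned")))
    stop("defined_only aggregation needs a reasoned ontology; run infer_defined_members()",
         call. = FALSE)

  ann <- annotations
  if (negation_policy == "exclude_negated") ann <- ann[!ann$negated, , drop = FALSE]
  pid <- docs$patient_id[match(ann$doc_id, docs$doc_id)]
  if (anyNA(pid) && nrow(ann))
    stop("annotation(s) reference doc_id(s) missing from the corpus table", call. = FALSE)
  rows <- if (!is.null(patient_ids)) as.character(patient_ids) else sort(unique(docs$patient_id))
  if (anyDuplicated(rows)) stop("duplicate patient ids", call. = FALSE)

  if (mode == "all_concepts") {
    cols <- known   # declaration order: named concepts then defined concepts
    tab <- table(factor(pid, levels = rows), factor(ann$iri, levels = cols))
    m <- matrix(as.integer(tab), nrow = length(rows), ncol = length(cols),
                dimnames = list(rows, cols))
  } else {
    cols <- ontology$defined$iri
    m <- matrix(0L, nrow = length(rows), ncol = length(cols),
                dimnames = list(rows, cols))
    for (j in seq_along(cols)) {
      members <- descendants(ontology, cols[j])
      hit <- ann$iri %in% members
      if (any(hit)) {
        cnt <- table(factor(pid[hit], levels = rows))
        m[, j] <- as.integer(cnt)
      }
    }
  }
  attr(m, "mode") <- mode
  attr(m, "negation_policy") <- negation_policy
  m
}

#' Dichotomize a count matrix
#'
#' Presence/absence transform: a cell becomes 1 when its count reaches the
#' threshold (default 1), else 0.
#'
#' @param matrix a count matrix from [aggregate_counts()].
#' @param threshold integer >= 1.
#' @return integer 0/1 matrix with the same dimnames.
#' @export
dichotomize <- function(matrix, threshold = 1L) {
  stopifnot(threshold >= 1L)
  out <- (matrix >= threshold) + 0L
  attr(out, "mode") <- attr(matrix, "mode")
  attr(out, "threshold") <- as.integer(threshold)
  out
}

#' Export a count matrix as CSV
#'
#' RFC-4180 CSV, UTF-8, one row per patient. The header row carries the
#' concepts' preferred labels in the requested language; with
#' `iri_header = TRUE` a second header line carries the IRIs. Column order
#' is the matrix (= ontology declaration) order.
#'
#' @param matrix count matrix.
#' @param path output path.
#' @param ontology optional `ontology` supplying preferred labels; without
#'   it the IRIs are used as headers.
#' @param lang label language, default `"fr"`.
#' @param iri_header also write an IRI header line (default FALSE).
#' @return `path`, invisibly.
#' @export
export_matrix_csv <- function(matrix, path, ontology = NULL, lang = "fr",
                              iri_header = FALSE) {
  labels <- if (!is.null(ontology)) pref_label(ontology, colnames(matrix), lang) else colnames(matrix)
  con <- file(path, "wt", encoding = "UTF-8")
  on.exit(close(con))
  csv_quote <- function(x) {
    needs <- grepl('[",\n]', x)
    x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
    x
  }
  writeLines(paste(c("patient_id", csv_quote(labels)), collapse = ","), con)
  if (iri_header) writeLines(paste(c("#iri", csv_quote(colnames(matrix))), collapse = ","), con)
  body <- apply(matrix, 1, function(r) paste(r, collapse = ","))
  writeLines(paste(csv_quote(rownames(matrix)), body, sep = ","), con)
  invisible(path)
}

#' Export a count matrix in long format
#'
#' @param matrix count matrix.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_matrix_long <- function(matrix, path) {
  long <- data.frame(patient_id = rep(rownames(matrix), times = ncol(matrix)),
                     iri = rep(colnames(matrix), each = nrow(matrix)),
                     count = as.vector(matrix), stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
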