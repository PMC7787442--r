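# Dictionary-based semantic annotator for French coordination notes:
# preprocessing (tokens with offsets, sentences, lemmas), longest-match
# concept recognition against the term index, negation flagging, and
# inline-XML / standoff export.

#' Build a document
#'
#' @param doc_id unique document identifier.
#' @param text document text (UTF-8).
#' @param patient_id patient the event belongs to.
#' @param date optional ISO-8601 date string.
#' @param language language tag, default `"fr"`.
#' @return list of class `onto_document`.
#' @export
onto_document <- function(doc_id, text, patient_id = NA_character_,
                          date = NA_character_, language = "fr") {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id),
            is.character(text), length(text) == 1L)
  structure(list(doc_id = doc_id, patient_id = patient_id, date = date,
                 language = language, text = text),
            class = "onto_document")
}

# ---- lemmatization ----------------------------------------------------------

# Default French lemmatizer: small exception table plus suffix heuristics.
# Any function(character tokens) -> character lemmas satisfies the contract
# and can be plugged into preprocess()/annotate_document().
french_lemma_exceptions <- c(
  "suis" = "etre", "es" = "etre", "est" = "etre", "sommes" = "etre",
  "etes" = "etre", "sont" = "etre", "etait" = "etre", "etaient" = "etre",
  "a" = "avoir", "ont" = "avoir", "avait" = "avoir", "avaient" = "avoir",
  "va" = "aller", "vont" = "aller",
  "yeux" = "oeil", "aux" = "aux"
)

#' Default French lemmatizer
#'
#' Works on normalized (lowercased, accent-folded) tokens: an exception table
#' for frequent irregular verbs, then suffix rules (`-eaux`/`-aux` plurals,
#' plural `-s`/`-x`, feminine `-ee`). Intentionally conservative - dictionary
#' matching only needs lemma agreement between labels and text, both of which
#' pass through the same function. Replaceable by any `function(tokens)`
#' returning one lemma per token.
#'
#' @param tokens character vector of normalized tokens.
#' @return character vector of lemmas, same length.
#' @export
french_lemmatizer <- function(tokens) {
  if (!length(tokens)) return(character())
  out <- tokens
  hit <- tokens %in% names(french_lemma_exceptions)
  out[hit] <- french_lemma_exceptions[tokens[hit]]
  rest <- !hit
  out[rest] <- sub("eaux$", "eau", out[rest])
  out[rest] <- sub("(...)aux$", "\\1al", out[rest])
  long <- rest & nchar(out) > 3L
  out[long] <- sub("(..)ees$", "\\1e", out[long])
  out[long] <- sub("(..)es$", "\\1e", out[long])
  long <- rest & nchar(out) > 3L
  out[long] <- sub("([^s])s$", "\\1", out[long])
  out[long] <- sub("(...)x$", "\\1", out[long])
  out
}

sentence_final <- c(".", "!", "?", "…", ";")

#' Preprocess a document into sentences of tokens
#'
#' Tokenizes with character offsets, normalizes each token (lowercase, accent
#' folding), attaches lemmas from the pluggable lemmatizer, and splits into
#' sentences. Sentence boundaries fall after sentence-final punctuation
#' (`. ! ? ; …`) and at line breaks in the original text.
#'
#' @param doc an `onto_document` (or a single string).
#' @param lemmatizer `function(tokens) -> lemmas`; default [french_lemmatizer()].
#' @param spelling optional named character vector applied to normalized
#'   tokens before matching (configurable substitution table standing in for
#'   spelling correction; auditable, never automatic).
#' @return list of data frames, one per sentence, with columns `surface`,
#'   `start`, `end`, `norm`, `lemma`.
#' @export
preprocess <- function(doc, lemmatizer = french_lemmatizer, spelling = NULL) {
  text <- if (inherits(doc, "onto_document")) doc$text else doc
  toks <- tokenize(text)
  if (!nrow(toks)) return(list())
  toks$norm <- tolower(fold_diacritics(toks$surface))
  if (!is.null(spelling) && length(spelling)) {
    hit <- toks$norm %in% names(spelling)
    toks$norm[hit] <- unname(spelling[toks$norm[hit]])
  }
  toks$lemma <- lemmatizer(toks$norm)
  stopifnot(length(toks$lemma) == nrow(toks))
  # boundary after sentence-final punctuation or when a newline separates tokens
  n <- nrow(toks)
  brk <- logical(n)
  if (n > 1L) {
    gap_text <- substring(text, toks$end[-n] + 1L, toks$start[-1])
    brk[-n] <- toks$surface[-n] %in% sentence_final | grepl("\n", gap_text, fixed = TRUE)
  }
  sent_id <- cumsum(c(1L, brk[-n]))
  out <- split(toks, sent_id)
  names(out) <- NULL
  lapply(out, function(d) { rownames(d) <- NULL; d })
}

# ---- negation ---------------------------------------------------------------

#' Default French negation trigger lexicon
#'
#' The triggers recognised by [detect_negation()]; `"plus"` is handled
#' separately, only as the completion of a preceding `ne`.
#' @export
default_negation_triggers <- c("ne", "n'", "pas", "aucun", "aucune", "sans",
                               "jamais", "non")

#' Flag negated annotations within one sentence
#'
#' An annotation is negated when a French negation trigger occurs in the same
#' sentence within `window` tokens before the annotation start, or when
#' `pas`/`plus` completes a preceding `ne`/`n'` anywhere between that `ne`
#' and the annotation (`plus` only ever counts in the "ne ... plus" pattern).
#' The elided `n'` is recognised as the token `n` immediately followed by an
#' apostrophe, matching the tokenizer's splitting of `n'est`.
#'
#' @param sentence one sentence data frame from [preprocess()].
#' @param ann_starts integer vector of annotation start offsets (0-based,
#'   character offsets into the document).
#' @param window token window before the annotation, default 5.
#' @param triggers trigger lexicon, default [default_negation_triggers].
#' @return logical vector parallel to `ann_starts`.
#' @export
detect_negation <- function(sentence, ann_starts, window = 5L,
                            triggers = default_negation_triggers) {
  if (!length(ann_starts)) return(logical())
  n <- nrow(sentence)
  norm <- sentence$norm
  is_ne <- norm == "ne" | (norm == "n" & c(norm[-1] == "'", FALSE))
  plain <- setdiff(triggers, c("n'", "plus"))
  is_trig <- norm %in% plain | (("n'" %in% triggers) & is_ne & norm == "n") |
             (("ne" %in% triggers) & is_ne)
  vapply(ann_starts, function(st) {
    # first token index at or after the annotation start
    pos <- match(TRUE, sentence$start >= st)
    if (is.na(pos)) pos <- n + 1L
    before <- seq_len(pos - 1L)
    lo <- max(1L, pos - window)
    in_window <- before[before >= lo]
    if (any(is_trig[in_window])) return(TRUE)
    # "ne ... pas/plus" completion between the ne and the annotation
    ne_pos <- before[is_ne[before]]
    if (length(ne_pos)) {
      comp <- before[norm[before] %in% c("pas", "plus")]
      if (any(comp > min(ne_pos))) return(TRUE)
    }
    FALSE
  }, logical(1))
}

# ---- annotation -------------------------------------------------------------

empty_annotations <- function() {
  data.frame(doc_id = character(), start = integer(), end = integer(),
             surface = character(), iri = character(), kind = character(),
             source = character(), negated = logical(), stringsAsFactors = FALSE)
}

#' Annotate a document against a term index
#'
#' Left-to-right longest-match scan over the normalized token sequence of
#' each sentence: at each position the longest term in the index that
#' matches wins, one annotation is emitted per concept sharing that term
#' (no disambiguation), and the scan resumes after the matched tokens.
#' Matching is attempted on normalized surface tokens first, then on lemmas.
#' Spans are 0-based half-open character offsets into the original text, so
#' `matched_surface` is exactly the text slice. Negation flags come from
#' [detect_negation()] applied per sentence.
#'
#' @param doc an `onto_document`.
#' @param index a `term_index` built with the same normalization rules.
#' @param lemmatizer,spelling passed to [preprocess()].
#' @param negation_window,negation_triggers passed to [detect_negation()].
#' @param lemma_matching set `FALSE` to disable the lemma-level fallback.
#' @return data frame of annotations: `doc_id`, `start`, `end`, `surface`,
#'   `iri`, `kind` (label kind matched), `source` (`surface` or `lemma`),
#'   `negated`.
#' @export
annotate_document <- function(doc, index, lemmatizer = french_lemmatizer,
                              spelling = NULL, negation_window = 5L,
                              negation_triggers = default_negation_triggers,
                              lemma_matching = TRUE) {
  stopifnot(inherits(doc, "onto_document"), inherits(index, "term_index"))
  sents <- preprocess(doc, lemmatizer = lemmatizer, spelling = spelling)
  if (!length(sents) || index$max_len == 0L) return(empty_annotations())
  keys <- index$keys; entries <- index$entries
  out <- vector("list", length(sents))
  for (s in seq_along(sents)) {
    sent <- sents[[s]]
    n <- nrow(sent)
    a_start <- integer(); a_end <- integer(); a_rows <- integer()
    a_src <- character(); a_n <- integer()
    i <- 1L
    while (i <= n) {
      rows <- NULL; matched_len <- 0L; matched_source <- NA_character_
      for (len in seq(min(index$max_len, n - i + 1L), 1L)) {
        j <- i + len - 1L
        rows <- keys[[paste(sent$norm[i:j], collapse = " ")]]
        matched_source <- "surface"
        if (is.null(rows) && lemma_matching) {
          rows <- keys[[paste(sent$lemma[i:j], collapse = " ")]]
          matched_source <- "lemma"
        }
        if (!is.null(rows)) { matched_len <- len; break }
      }
      if (is.null(rows)) { i <- i + 1L; next }
      # one annotation per concept sharing the winning term
      rows <- rows[!duplicated(entries$iri[rows])]
      a_start <- c(a_start, sent$start[i])
      a_end <- c(a_end, sent$end[i + matched_len - 1L])
      a_rows <- c(a_rows, rows)
      a_src <- c(a_src, matched_source)
      a_n <- c(a_n, length(rows))
      i <- i + matched_len
    }
    if (length(a_start)) {
      neg <- detect_negation(sent, a_start, window = negation_window,
                             triggers = negation_triggers)
      out[[s]] <- data.frame(
        doc_id = doc$doc_id,
        start = rep(a_start, a_n), end = rep(a_end, a_n),
        surface = substring(doc$text, rep(a_start, a_n) + 1L, rep(a_end, a_n)),
        iri = entries$iri[a_rows], kind = entries$kind[a_rows],
        source = rep(a_src, a_n), negated = rep(neg, a_n),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(out[!vapply(out, is.null, TRUE)], list(empty_annotations())))
  rownames(res) <- NULL
  res
}

#' Annotate a whole corpus
#'
#' @param docs data frame with columns `doc_id`, `patient_id`, `text` (and
#'   optionally `date`), or a list of `onto_document`s.
#' @param index a `term_index`.
#' @param ... passed to [annotate_document()].
#' @return one annotation data frame for the corpus.
#' @export
annotate_corpus <- function(docs, index, ...) {
  dl <- as_document_list(docs)
  res <- lapply(dl, annotate_document, index = index, ...)
  out <- do.call(rbind, c(res, list(empty_annotations())))
  rownames(out) <- NULL
  out
}

as_document_list <- function(docs) {
  if (is.data.frame(docs)) {
    stopifnot(all(c("doc_id", "text") %in% names(docs)))
    if (anyDuplicated(docs$doc_id)) stop("duplicate doc_id in corpus", call. = FALSE)
    lapply(seq_len(nrow(docs)), function(i)
      onto_document(docs$doc_id[i], docs$text[i],
                    patient_id = if ("patient_id" %in% names(docs)) docs$patient_id[i] else NA_character_,
                    date = if ("date" %in% names(docs)) docs$date[i] else NA_character_))
  } else {
    stopifnot(all(vapply(docs, inherits, TRUE, "onto_document")))
    docs
  }
}

# ---- export -----------------------------------------------------------------

#' Export annotations as inline XML
#'
#' Wraps each annotated span in a `<mention>` element carrying the concept
#' IRI, the label kind and the negation flag, inside a `<doc>` root. The
#' original text is escaped but otherwise untouched: stripping the tags with
#' [strip_inline_xml()] reproduces it byte for byte. Annotations sharing one
#' span nest naturally; a partial overlap (impossible for output of
#' [annotate_document()], whose matches are disjoint or span-identical) is
#' resolved by dropping the later-starting annotation with a warning.
#'
#' @param doc an `onto_document`.
#' @param annotations annotation data frame for this document.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_inline_xml <- function(doc, annotations, path) {
  stopifnot(inherits(doc, "onto_document"))
  ann <- annotations[annotations$doc_id == doc$doc_id, , drop = FALSE]
  ann <- ann[order(ann$start, -ann$end), , drop = FALSE]
  if (nrow(ann) > 1L) {
    # keep only nestable spans: walk in (start, -end) order with a stack of
    # open spans; a span crossing the innermost open one cannot nest -> drop
    keep <- rep(TRUE, nrow(ann))
    open_ends <- integer()
    for (i in seq_len(nrow(ann))) {
      open_ends <- open_ends[open_ends > ann$start[i]]
      if (length(open_ends) && ann$end[i] > open_ends[length(open_ends)]) {
        keep[i] <- FALSE
        next
      }
      open_ends <- c(open_ends, ann$end[i])
    }
    if (!all(keep)) warning("dropping ", sum(!keep), " non-nestable overlapping annotation(s)",
                            call. = FALSE)
    ann <- ann[keep, , drop = FALSE]
  }
  text <- doc$text
  # build as segments: emit opening/closing tags at boundaries, escaping text
  events <- rbind(
    data.frame(pos = ann$start, open = rep(TRUE, nrow(ann)), idx = seq_len(nrow(ann))),
    data.frame(pos = ann$end, open = rep(FALSE, nrow(ann)), idx = seq_len(nrow(ann)))
  )
  # at equal position: close tags before open tags; wider spans open first /
  # close last so identical spans nest
  events <- events[order(events$pos, events$open,
                         ifelse(events$open, -(ann$end[events$idx]), -(ann$start[events$idx])),
                         ifelse(events$open, events$idx, -events$idx)), , drop = FALSE]
  pieces <- character(); cursor <- 0L
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    if (e$pos > cursor) pieces <- c(pieces, xml_escape(substring(text, cursor + 1L, e$pos)))
    cursor <- e$pos
    a <- ann[e$idx, ]
    pieces <- c(pieces,
                if (e$open) sprintf('<mention iri="%s" kind="%s" negated="%s">',
                                    xml_escape(a$iri), xml_escape(a$kind),
                                    tolower(as.character(a$negated)))
                else "</mention>")
  }
  if (cursor < nchar(text)) pieces <- c(pieces, xml_escape(substring(text, cursor + 1L, nchar(text))))
  xml <- paste0('<doc id="', xml_escape(doc$doc_id), '">',
                paste(pieces, collapse = ""), "</doc>")
  writeLines(xml, path, useBytes = FALSE, sep = "")
  invisible(path)
}

#' Strip inline XML back to the original text
#'
#' Inverse of [export_inline_xml()]: removes the `<doc>` wrapper and all
#' `<mention>` tags and unescapes entities, reproducing the original
#' document text byte for byte.
#'
#' @param path file written by [export_inline_xml()], or its contents.
#' @return the reconstructed document text.
#' @export
strip_inline_xml <- function(path) {
  x <- if (file.exists(path)) readChar(path, file.info(path)$size, useBytes = FALSE) else path
  Encoding(x) <- "UTF-8"
  x <- sub("^<doc id=\"(?:[^\"]*)\">", "", x, perl = TRUE)
  x <- sub("</doc>$", "", x)
  x <- gsub("<mention [^>]*>|</mention>", "", x, perl = TRUE)
  x <- gsub("&lt;", "<", x, fixed = TRUE)
  x <- gsub("&gt;", ">", x, fixed = TRUE)
  x <- gsub("&quot;", "\"", x, fixed = TRUE)
  gsub("&amp;", "&", x, fixed = TRUE)
}

#' Write annotations as a standoff TSV
#'
#' One row per annotation: `doc_id`, `start`, `end`, `surface`, `iri`,
#' `negated`. Tabs or newlines inside a surface are replaced by spaces so
#' the file stays line-oriented.
#'
#' @param annotations annotation data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_standoff <- function(annotations, path) {
  out <- annotations[, c("doc_id", "start", "end", "surface", "iri", "negated")]
  out$surface <- gsub("[\t\n\r]", " ", out$surface)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a standoff TSV
#'
#' @param path file written by [write_standoff()].
#' @return annotation data frame.
#' @export
read_standoff <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          colClasses = c(doc_id = "character", start = "integer",
                                         end = "integer", surface = "character",
                                         iri = "character", negated = "logical"),
                          fileEncoding = "UTF-8")
  df
}

#' Read a corpus directory
#'
#' A corpus is a directory of UTF-8 `.txt` files (one per event document)
#' plus a sidecar CSV with columns `doc_id`, `patient_id` and optionally
#' `date`; `doc_id` matches the file base name.
#'
#' @param dir corpus directory.
#' @param sidecar path to the sidecar CSV, default `file.path(dir, "corpus.csv")`.
#' @return data frame with `doc_id`, `patient_id`, `date`, `text`.
#' @export
read_corpus <- function(dir, sidecar = file.path(dir, "corpus.csv")) {
  meta <- utils::read.csv(sidecar, stringsAsFactors = FALSE, colClasses = "character")
  stopifnot(all(c("doc_id", "patient_id") %in% names(meta)))
  if (!"date" %in% names(meta)) meta$date <- NA_character_
  meta$text <- vapply(meta$doc_id, function(id) {
    f <- file.path(dir, paste0(id, ".txt"))
    if (!file.exists(f)) stop("missing corpus file: ", f, call. = FALSE)
    paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  }, "")
  meta
}

#' Write a corpus directory
#'
#' @param docs data frame with `doc_id`, `patient_id`, `text` (optionally `date`).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(docs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(docs))) {
    con <- file(file.path(dir, paste0(docs$doc_id[i], ".txt")), "wt", encoding = "UTF-8")
    writeLines(docs$text[i], con, sep = "")
    close(con)
  }
  meta <- docs[, intersect(c("doc_id", "patient_id", "date"), names(docs)), drop = FALSE]
  utils::write.csv(meta, file.path(dir, "corpus.csv"), row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(dir)
}
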