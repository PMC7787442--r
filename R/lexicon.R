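# Text normalization and the multi-word term index compiled from ontology
# labels. The one consistency that matters for dictionary matching is that
# labels and document text go through the identical tokenizer and
# normalization, so both live here.

# French diacritics folding; multi-char ligatures first, then 1:1 chartr.
fold_diacritics <- function(x) {
  x <- gsub("œ", "oe", x, fixed = TRUE)   # œ
  x <- gsub("Œ", "OE", x, fixed = TRUE)
  x <- gsub("æ", "ae", x, fixed = TRUE)   # æ
  x <- gsub("Æ", "AE", x, fixed = TRUE)
  from <- "àâäáãéèêëîïíôöóõùûüúçñÿÀÂÄÉÈÊËÎÏÔÖÙÛÜÇ"
  to   <- "aaaaaeeeeiiioooouuuucnyAAAEEEEIIOOUUUC"
  chartr(from, to, x)
}

# word characters (letters/digits) run together; any other non-space char is
# its own token. Apostrophes and hyphens therefore split: "aujourd'hui" ->
# aujourd / ' / hui, identically for labels and documents.
token_pattern <- "[\\p{L}\\p{N}]+|[^\\p{L}\\p{N}\\s]"

#' Tokenize text, keeping character offsets
#'
#' Splits text into maximal letter/digit runs and single punctuation marks.
#' Spans are 0-based half-open offsets into the original text, so
#' `substring(text, start + 1, end)` reproduces each surface exactly and
#' concatenated surfaces cover all non-whitespace characters.
#'
#' @param text a single string.
#' @return data frame with columns `surface`, `start`, `end`.
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text))
    return(data.frame(surface = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  m <- gregexpr(token_pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(surface = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(surface = substring(text, start + 1L, start + len),
             start = start, end = start + len, stringsAsFactors = FALSE)
}

#' Normalize text to a token sequence
#'
#' Lowercases, folds French diacritics and ligatures to ASCII, splits
#' punctuation into separate tokens and collapses whitespace. Deterministic
#' and idempotent; the same function is applied to ontology labels and to
#' documents so that matching is exact.
#'
#' @param text a single string (empty input gives an empty sequence).
#' @return character vector of normalized tokens.
#' @examples
#' normalize_text("méd tt")   # "med" "tt"
#' @export
normalize_text <- function(text) {
  toks <- tokenize(text)$surface
  if (!length(toks)) return(character())
  tolower(fold_diacritics(toks))
}

#' Build the term index from ontology labels
#'
#' Collects every preferred and alternative label of the consolidated
#' ontology in the requested languages, normalizes each one with
#' [normalize_text()], and stores it in an exact-lookup index keyed by the
#' normalized token sequence. Raw surfaces are preserved, so label counts
#' (e.g. the number of alternative spellings registered for a concept) are
#' computed on raw strings even when accent folding makes two of them
#' collide on one key; a colliding key simply maps to several entries.
#'
#' @param ontology a consolidated `ontology`.
#' @param languages language tags to include (default `"fr"`).
#' @param include_defined also index labels of fully defined concepts
#'   (default TRUE; they are ordinary ontology classes for matching).
#' @return An object of class `term_index`: list with `entries` (data frame
#'   `surface`, `normalized`, `iri`, `kind`, `lang`), `keys` (environment
#'   mapping normalized key to entry row indices) and `max_len` (longest
#'   stored sequence, in tokens).
#' @export
build_term_index <- function(ontology, languages = "fr", include_defined = TRUE) {
  stopifnot(inherits(ontology, "ontology"))
  lab <- ontology$labels
  class_iris <- c(ontology$concepts$iri, if (include_defined) ontology$defined$iri)
  lab <- lab[lab$iri %in% class_iris & lab$lang %in% languages, , drop = FALSE]

  unlabeled <- setdiff(class_iris, lab$iri)
  if (length(unlabeled))
    warning(length(unlabeled), " concept(s) have no label in language(s) ",
            paste(languages, collapse = ","),
            " and can never be matched: ",
            paste(utils::head(unlabeled, 5L), collapse = ", "),
            if (length(unlabeled) > 5L) ", ...", call. = FALSE)

  norm <- lapply(lab$text, normalize_text)
  keep <- lengths(norm) > 0L
  if (any(!keep))
    warning("dropping ", sum(!keep), " label(s) that normalize to nothing", call. = FALSE)
  lab <- lab[keep, , drop = FALSE]
  norm <- norm[keep]
  entries <- data.frame(
    surface = lab$text,
    normalized = vapply(norm, paste, "", collapse = " "),
    iri = lab$iri, kind = lab$kind, lang = lab$lang,
    stringsAsFactors = FALSE
  )
  entries <- order_df(entries, c("normalized", "iri", "kind", "lang", "surface"))
  # one entry per (normalized, iri, kind, lang, surface); raw duplicates across
  # kinds/langs stay distinct rows
  entries <- unique(entries)
  rownames(entries) <- NULL
  keys <- new.env(parent = emptyenv(), size = max(16L, nrow(entries)))
  for (i in seq_len(nrow(entries))) {
    k <- entries$normalized[i]
    keys[[k]] <- c(keys[[k]], i)
  }
  structure(list(entries = entries, keys = keys,
                 max_len = if (nrow(entries)) max(lengths(norm)) else 0L,
                 languages = languages),
            class = "term_index")
}

#' @export
print.term_index <- function(x, ...) {
  cat("<term index>\n  entries: ", nrow(x$entries),
      "  keys: ", length(ls(x$keys)),
      "  max term length: ", x$max_len, " token(s)\n", sep = "")
  invisible(x)
}

#' Look up a normalized token sequence in the index
#'
#' @param index a `term_index`.
#' @param tokens character vector of normalized tokens.
#' @return data frame of matching entries (zero rows when absent).
#' @export
index_lookup <- function(index, tokens) {
  k <- paste(tokens, collapse = " ")
  idx <- index$keys[[k]]
  if (is.null(idx)) index$entries[0, , drop = FALSE]
  else index$entries[idx, , drop = FALSE]
}

#' Write a term index to TSV for inspection
#'
#' @param index a `term_index`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_term_index <- function(index, path) {
  utils::write.table(index$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
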