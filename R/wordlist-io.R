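.default_column_maps <- list(
  cldf = c(id = "ID", language = "Language_ID", family = "Family",
           concept = "Parameter_ID", form = "Form", segments = "Segments"),
  tsv = c(id = "ID", language = "DOCULECT", family = "FAMILY",
          concept = "CONCEPT", form = "FORM", segments = "TOKENS")
)

.norm <- function(x) stringi::stri_trans_nfc(x)

# Clean one space-split token vector: resolve source/target slash notation
# (keep the part after the last "/"), optionally drop morpheme-boundary ("+")
# and juncture ("_") markers, which are annotations rather than sounds.
.clean_tokens <- function(tokens, keep_boundaries = FALSE) {
  tokens <- tokens[nzchar(tokens)]
  slash <- grepl("/", tokens, fixed = TRUE)
  if (any(slash)) tokens[slash] <- sub("^.*/", "", tokens[slash])
  if (!keep_boundaries) tokens <- tokens[!tokens %in% c("+", "_")]
  tokens[nzchar(tokens)]
}

.tokenize <- function(form, segments, tokenizer, keep_boundaries = FALSE) {
  raw <- switch(tokenizer,
    segments = strsplit(segments, "[[:space:]]+"),
    whitespace = strsplit(form, "[[:space:]]+"),
    character = strsplit(form, "", fixed = TRUE),
    stop("unknown tokenizer: ", tokenizer)
  )
  lapply(raw, .clean_tokens, keep_boundaries = keep_boundaries)
}

#' Build a Wordlist from an in-memory table
#'
#' Normalizes a data frame of word forms into a [Wordlist-class]: resolves the
#' column mapping, NFC-normalizes all strings, tokenizes forms, drops rows
#' without an admissible form, optionally deduplicates repeated
#' (language, concept, form) rows, and sorts entries deterministically.
#'
#' @param x data.frame with one row per word form.
#' @param columnMap named character vector mapping the roles `id`, `language`,
#'   `family`, `concept`, `form`, `segments` to column names of `x`. Roles
#'   `language`, `concept`, `form` are required; the others are optional.
#' @param tokenizer how to obtain sound tokens: `"segments"` splits the
#'   mapped segments column on whitespace (the normal case for phonetically
#'   segmented data), `"whitespace"` splits the form itself, `"character"`
#'   splits the form into single characters (for orthographic toy data).
#' @param dedup drop repeated (language, concept, form) rows? Default `TRUE`:
#'   duplicates would inflate edge weights without adding evidence.
#' @param lowercase lowercase forms before tokenizing? Intended for
#'   orthographic data where e.g. "Hand" should match inside "Handschuh".
#' @param keepBoundaries keep `+`/`_` boundary markers as tokens? Default
#'   `FALSE` (they are not sounds and would corrupt affix lengths).
#' @param source character label recorded in the metadata.
#' @return A [Wordlist-class] object.
#' @export
wordlistFromTable <- function(x, columnMap = .default_column_maps$tsv,
                              tokenizer = c("segments", "whitespace", "character"),
                              dedup = TRUE, lowercase = FALSE,
                              keepBoundaries = FALSE, source = "memory") {
  tokenizer <- match.arg(tokenizer)
  stopifnot(is.data.frame(x))
  cm_get <- function(role) {
    v <- unname(columnMap[role])
    if (!length(v)) NA_character_ else v
  }
  for (role in c("language", "concept", "form")) {
    col <- cm_get(role)
    if (is.na(col) || !col %in% names(x))
      stop("required column for role '", role, "' not found: ",
           if (is.na(col)) "<unmapped>" else col)
  }
  if (tokenizer == "segments") {
    col <- cm_get("segments")
    if (is.na(col) || !col %in% names(x))
      stop("tokenizer 'segments' needs a segments column; not found: ",
           if (is.na(col)) "<unmapped>" else col)
  }
  get_col <- function(role, default = NULL) {
    col <- cm_get(role)
    if (!is.na(col) && col %in% names(x)) as.character(x[[col]]) else default
  }
  n <- nrow(x)
  form <- .norm(get_col("form", character(n)))
  form[is.na(form)] <- ""
  if (lowercase) form <- tolower(form)
  keep <- nzchar(trimws(form))
  dropped <- sum(!keep)

  ids <- get_col("id", as.character(seq_len(n)))
  ids[is.na(ids) | !nzchar(ids)] <- as.character(which(is.na(ids) | !nzchar(ids)))
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "-")
  language <- .norm(get_col("language", character(n)))
  concept <- .norm(get_col("concept", character(n)))
  family <- get_col("family", NULL)
  # family-less data: each language counts as its own family, so that
  # weight_families stays well-defined
  if (is.null(family)) family <- language else {
    family <- .norm(family)
    miss <- is.na(family) | !nzchar(family)
    family[miss] <- language[miss]
  }
  segments_raw <- get_col("segments", character(n))
  segments_raw[is.na(segments_raw)] <- ""
  segments_raw <- .norm(segments_raw)
  if (lowercase) segments_raw <- tolower(segments_raw)

  e <- data.frame(entry_id = ids, language_id = language, family = family,
                  concept_id = concept, form = form,
                  stringsAsFactors = FALSE)[keep, , drop = FALSE]
  e$segments <- .tokenize(e$form, segments_raw[keep], tokenizer, keepBoundaries)

  # rows whose tokenization is empty are inadmissible too
  ok <- lengths(e$segments) >= 1L
  dropped <- dropped + sum(!ok)
  e <- e[ok, , drop = FALSE]
  if (!nrow(e)) stop("no admissible rows: every row lacks a non-empty form/segmentation")

  if (dedup) {
    key <- paste(e$language_id, e$concept_id,
                 vapply(e$segments, paste, "", collapse = " "), sep = "\r")
    e <- e[!duplicated(key), , drop = FALSE]
  }
  e <- e[order(e$language_id, e$entry_id, method = "radix"), , drop = FALSE]
  rownames(e) <- NULL
  new("Wordlist", entries = e,
      metadata = list(source = source, column_map = columnMap,
                      tokenizer = tokenizer, dropped = dropped,
                      dedup = dedup, lowercase = lowercase,
                      keep_boundaries = keepBoundaries))
}

#' Read a multilingual wordlist from disk
#'
#' Reads a CLDF-style forms table (comma-separated, columns `ID`,
#' `Language_ID`, `Parameter_ID`, `Form`, `Segments`) or a plain
#' tab-separated wordlist (columns `DOCULECT`, `CONCEPT`, `FORM`, `TOKENS`),
#' then normalizes it via [wordlistFromTable()]. Rows with empty forms are
#' dropped and counted in `metadata(wl)$dropped`.
#'
#' @param path path to the file.
#' @param dialect `"cldf"` (CSV) or `"tsv"`; decides the separator and the
#'   default column map.
#' @param columnMap overrides for the dialect's default column mapping.
#' @param verbose print per-language entry counts and the dropped-row count?
#' @inheritParams wordlistFromTable
#' @return A [Wordlist-class] object.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("DOCULECT\tCONCEPT\tFORM", "German\tEARTH\tErde",
#'              "German\tWORLD\tErde", "German\tWORLD\tWelt"), tf)
#' wl <- readWordlist(tf, dialect = "tsv", tokenizer = "character")
#' nForms(wl)
#' @export
readWordlist <- function(path, dialect = c("cldf", "tsv"), columnMap = NULL,
                         tokenizer = c("segments", "whitespace", "character"),
                         dedup = TRUE, lowercase = FALSE, keepBoundaries = FALSE,
                         verbose = FALSE) {
  dialect <- match.arg(dialect)
  tokenizer <- match.arg(tokenizer)
  if (!file.exists(path)) stop("cannot read wordlist: no such file: ", path)
  cm <- .default_column_maps[[dialect]]
  if (!is.null(columnMap)) cm[names(columnMap)] <- columnMap
  x <- utils::read.delim(path, sep = if (dialect == "cldf") "," else "\t",
                         header = TRUE, quote = "\"", stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character",
                         encoding = "UTF-8", na.strings = NULL)
  wl <- wordlistFromTable(x, columnMap = cm, tokenizer = tokenizer,
                          dedup = dedup, lowercase = lowercase,
                          keepBoundaries = keepBoundaries, source = path)
  if (verbose) {
    message("read ", nForms(wl), " entries from ", length(languageIds(wl)),
            " languages (dropped ", wl@metadata$dropped, " rows)")
    print(table(entries(wl)$language_id))
  }
  wl
}

#' Write a Wordlist to a tab-separated file
#'
#' Writes the entries as TSV with columns `ID`, `DOCULECT`, `FAMILY`,
#' `CONCEPT`, `FORM`, `TOKENS` (space-joined sound tokens). Re-reading the
#' file with `readWordlist(path, "tsv", tokenizer = "segments", dedup = FALSE)`
#' reproduces the same entries.
#'
#' @param x a [Wordlist-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeWordlist <- function(x, path) {
  stopifnot(is(x, "Wordlist"))
  e <- x@entries
  out <- data.frame(ID = e$entry_id, DOCULECT = e$language_id,
                    FAMILY = e$family, CONCEPT = e$concept_id, FORM = e$form,
                    TOKENS = vapply(e$segments, paste, "", collapse = " "),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Accessors for Wordlist objects
#'
#' `entries()` returns the entry table (one row per admitted form),
#' `languageIds()` the sorted language identifiers, `concepts()` the sorted
#' concept identifiers, `nForms()` the number of entries, and `metadata()`
#' the reader provenance list.
#'
#' @param x a [Wordlist-class].
#' @param ... ignored.
#' @return See each function's description.
#' @name Wordlist-accessors
#' @aliases entries languageIds concepts nForms
NULL

#' @rdname Wordlist-accessors
#' @export
setMethod("entries", "Wordlist", function(x, ...) x@entries)

#' @rdname Wordlist-accessors
#' @export
setMethod("languageIds", "Wordlist", function(x, ...)
  sort(unique(x@entries$language_id), method = "radix"))

#' @rdname Wordlist-accessors
#' @export
setMethod("concepts", "Wordlist", function(x, ...)
  sort(unique(x@entries$concept_id), method = "radix"))

#' @rdname Wordlist-accessors
#' @export
setMethod("nForms", "Wordlist", function(x, ...) nrow(x@entries))

#' @rdname Wordlist-accessors
#' @export
metadata <- function(x) x@metadata

#' Forms of one language
#'
#' Returns the entries of a single language, sorted by entry identifier, as a
#' data frame with the same columns as [entries()].
#'
#' @param x a [Wordlist-class].
#' @param language a language identifier present in `x`.
#' @param ... ignored.
#' @return data.frame of that language's entries.
#' @export
setMethod("languageForms", "Wordlist", function(x, language, ...) {
  e <- x@entries
  if (!language %in% e$language_id)
    stop("unknown language: ", language)
  out <- e[e$language_id == language, , drop = FALSE]
  out <- out[order(out$entry_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
})

setMethod("show", "Wordlist", function(object) {
  e <- object@entries
  cat("Wordlist with", nrow(e), "forms,",
      length(unique(e$language_id)), "languages,",
      length(unique(e$concept_id)), "concepts\n")
  cat("  source:", object@metadata$source %||% "?",
      "| tokenizer:", object@metadata$tokenizer %||% "?",
      "| dropped rows:", object@metadata$dropped %||% 0, "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
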