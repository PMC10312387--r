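#' @import methods
NULL

#' Multilingual wordlist
#'
#' An S4 container for a multilingual wordlist: one row per word form, each
#' annotated with a language, an optional language family, a concept, the raw
#' form string, and its segmentation into sound tokens. Rows are held in a
#' data frame with a list-column of token vectors; entries are kept sorted by
#' language and entry identifier so that iteration is deterministic.
#'
#' @slot entries data.frame with columns `entry_id`, `language_id`, `family`,
#'   `concept_id`, `form` (character) and `segments` (list of character
#'   vectors, one sound token per element).
#' @slot metadata list with provenance: `source`, `column_map`, `tokenizer`,
#'   `dropped` (count of rows discarded on read), and any reader options.
#'
#' @seealso [readWordlist()], [languageForms()], [buildNetwork()]
#' @export
setClass("Wordlist",
  representation(entries = "data.frame", metadata = "list"),
  prototype(entries = data.frame(), metadata = list())
)

setValidity("Wordlist", function(object) {
  e <- object@entries
  msgs <- character()
  need <- c("entry_id", "language_id", "family", "concept_id", "form", "segments")
  if (!all(need %in% names(e))) {
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(e)) {
    if (!is.list(e$segments)) msgs <- c(msgs, "segments must be a list-column")
    if (any(!nzchar(e$concept_id))) msgs <- c(msgs, "empty concept_id")
    if (any(!nzchar(e$language_id))) msgs <- c(msgs, "empty language_id")
    nt <- lengths(e$segments)
    if (any(nt < 1L)) msgs <- c(msgs, "every entry needs at least one sound token")
    bad <- vapply(e$segments, function(s) any(!nzchar(s) | grepl(" ", s, fixed = TRUE)),
                  logical(1))
    if (any(bad)) msgs <- c(msgs, "tokens must be non-empty and free of spaces")
    if (anyDuplicated(e$entry_id)) msgs <- c(msgs, "entry_id must be unique")
    o <- order(e$language_id, e$entry_id, method = "radix")
    if (!identical(o, seq_len(nrow(e)))) {
      msgs <- c(msgs, "entries must be sorted by (language_id, entry_id)")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Thresholds and options for partial-colexification inference
#'
#' Holds the two length thresholds that gate affix candidates, the sides to
#' index, and the side-mixing policy for overlap detection. Both thresholds
#' are strict: an admitted affix has more than `affixMin` tokens and leaves a
#' remainder of more than `residueMin` tokens, so the defaults (2, 2) for
#' affix inference admit affixes of 3+ sounds on hosts whose unshared part has
#' 3+ sounds, and the overlap defaults (4, 3) admit shared substrings of 5+
#' sounds with 4+ sound remainders on both forms.
#'
#' @slot affixMin integer, strict lower bound on affix length in tokens.
#' @slot residueMin integer, strict lower bound on the unshared remainder.
#' @slot sides character, which word peripheries to index: "prefix", "suffix"
#'   or "both".
#' @slot sameSideOnly logical; if `TRUE`, an overlap is only admitted when the
#'   shared substring sits on the same side (prefix/prefix or suffix/suffix)
#'   of both forms.
#'
#' @seealso [colexParams()]
#' @export
setClass("ColexParams",
  representation(affixMin = "integer", residueMin = "integer",
                 sides = "character", sameSideOnly = "logical"),
  prototype(affixMin = 2L, residueMin = 2L, sides = "both", sameSideOnly = FALSE)
)

setValidity("ColexParams", function(object) {
  msgs <- character()
  if (length(object@affixMin) != 1L || is.na(object@affixMin) || object@affixMin < 1L)
    msgs <- c(msgs, "affixMin must be a single integer >= 1")
  if (length(object@residueMin) != 1L || is.na(object@residueMin) || object@residueMin < 0L)
    msgs <- c(msgs, "residueMin must be a single integer >= 0")
  if (!object@sides %in% c("prefix", "suffix", "both"))
    msgs <- c(msgs, "sides must be one of 'prefix', 'suffix', 'both'")
  if (length(msgs)) msgs else TRUE
})

#' Annotated colexification network
#'
#' A weighted concept graph aggregated across the languages of a wordlist.
#' Full and overlap networks are undirected; affix networks are directed,
#' with edges pointing from the concept whose word recurs as an affix to the
#' concept of the word containing it. Every edge carries three weights —
#' `weight_forms` (number of witnessing form pairs), `weight_languages`, and
#' `weight_families` — plus a collapsed witness annotation; the full witness
#' table (one row per colexification instance, including the shared token
#' sequence and its side in each form) is kept in the `instances` slot.
#'
#' @slot kind "full", "affix" or "overlap".
#' @slot graph igraph object; directed iff `kind == "affix"`. Vertices carry
#'   `n_forms`, `n_languages`, `n_families` and a `forms` annotation.
#' @slot instances data.frame of witness instances backing the edges.
#' @slot params the [ColexParams-class] used for inference (ignored for
#'   `kind == "full"`).
#'
#' @seealso [buildNetwork()], [degreeVector()], [exportNetwork()]
#' @export
setClass("ColexNetwork",
  representation(kind = "character", graph = "ANY",
                 instances = "data.frame", params = "ANY")
)

setValidity("ColexNetwork", function(object) {
  msgs <- character()
  if (!object@kind %in% c("full", "affix", "overlap"))
    msgs <- c(msgs, "kind must be 'full', 'affix' or 'overlap'")
  g <- object@graph
  if (!igraph::is_igraph(g)) return(c(msgs, "graph must be an igraph object"))
  if (igraph::is_directed(g) != (object@kind == "affix"))
    msgs <- c(msgs, "affix networks must be directed; full/overlap undirected")
  if (igraph::ecount(g)) {
    if (any(igraph::which_loop(g))) msgs <- c(msgs, "self-loop edges are not allowed")
    wf <- igraph::E(g)$weight_forms
    wl <- igraph::E(g)$weight_languages
    wff <- igraph::E(g)$weight_families
    if (is.null(wf) || is.null(wl) || is.null(wff)) {
      msgs <- c(msgs, "edges must carry weight_forms, weight_languages, weight_families")
    } else if (any(wff > wl) || any(wl > wf)) {
      msgs <- c(msgs, "edge weights must satisfy families <= languages <= forms")
    }
  }
  if (length(msgs)) msgs else TRUE
})
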