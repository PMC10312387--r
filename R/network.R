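#' Build a colexification network from a wordlist
#'
#' Runs the per-language inference for the requested kind over every language
#' of the wordlist (in deterministic order) and merges the resulting witness
#' instances into a weighted concept graph. Edges are keyed by the concept
#' pair (ordered pair for the directed affix kind) and annotated with
#' `weight_forms` (number of witnessing form pairs), `weight_languages` and
#' `weight_families` (distinct languages/families attesting the pair), and a
#' collapsed `witnesses` string. Nodes cover every concept attested in the
#' wordlist — including concepts without any colexification — and carry
#' `n_forms`, `n_languages`, `n_families` and a `forms` annotation listing
#' the attested forms per language.
#'
#' @param x a [Wordlist-class].
#' @param kind `"full"`, `"affix"` or `"overlap"`.
#' @param params a [ColexParams-class]; defaults to `colexParams(kind)` for
#'   the partial kinds, ignored for `"full"`.
#' @param ... ignored.
#' @return A [ColexNetwork-class].
#' @examples
#' df <- data.frame(DOCULECT = "German",
#'                  CONCEPT = c("HAND", "SHOE", "GLOVE"),
#'                  FORM = c("hand", "schuh", "handschuh"))
#' wl <- wordlistFromTable(df, tokenizer = "character")
#' net <- buildNetwork(wl, "affix")
#' edgeTable(net)
#' @export
setMethod("buildNetwork", "Wordlist", function(x, kind = c("full", "affix", "overlap"),
                                               params = NULL, ...) {
  kind <- match.arg(kind)
  if (is.null(params) && kind != "full") params <- colexParams(kind)
  if (!is.null(params)) stopifnot(is(params, "ColexParams"))
  infer <- switch(kind,
    full = function(f) fullColexifications(f),
    affix = function(f) affixColexifications(f, params),
    overlap = function(f) overlapColexifications(f, params))
  inst <- lapply(languageIds(x), function(lg) infer(languageForms(x, lg)))
  inst <- do.call(rbind, c(inst, list(.empty_instances())))
  .network_from_instances(x, inst, kind, params)
})

# aggregate a witness-instance table into an annotated igraph
.network_from_instances <- function(wl, inst, kind, params) {
  directed <- kind == "affix"
  e <- entries(wl)
  agg2 <- function(v, by) vapply(split(v, by), function(z) length(unique(z)), 0L)
  nodes <- data.frame(name = concepts(wl), stringsAsFactors = FALSE)
  nf <- table(e$concept_id)
  nodes$n_forms <- as.integer(nf[nodes$name])
  nodes$n_languages <- as.integer(agg2(e$language_id, e$concept_id)[nodes$name])
  nodes$n_families <- as.integer(agg2(e$family, e$concept_id)[nodes$name])
  fb <- vapply(split(paste0(e$language_id, ":", e$form), e$concept_id),
               paste, "", collapse = ";")
  nodes$forms <- unname(fb[nodes$name])

  if (nrow(inst)) {
    ekey <- paste(inst$concept_a, inst$concept_b, sep = "\r")
    uk <- unique(ekey)
    edges <- data.frame(
      concept_a = inst$concept_a[match(uk, ekey)],
      concept_b = inst$concept_b[match(uk, ekey)],
      weight_forms = as.integer(table(ekey)[uk]),
      weight_languages = unname(agg2(inst$language_id, ekey)[uk]),
      weight_families = unname(agg2(inst$family, ekey)[uk]),
      stringsAsFactors = FALSE)
    wit <- vapply(split(paste0(inst$language_id, ":", inst$form_a, "~",
                               inst$form_b, "~", inst$shared), ekey),
                  paste, "", collapse = ";")
    edges$witnesses <- unname(wit[uk])
    edges <- edges[order(edges$concept_a, edges$concept_b, method = "radix"), ,
                   drop = FALSE]
  } else {
    edges <- data.frame(concept_a = character(), concept_b = character(),
                        weight_forms = integer(), weight_languages = integer(),
                        weight_families = integer(), witnesses = character(),
                        stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = directed, vertices = nodes)
  new("ColexNetwork", kind = kind, graph = g, instances = inst,
      params = params)
}

#' Accessors for ColexNetwork objects
#'
#' `networkKind()` returns "full"/"affix"/"overlap"; `networkGraph()` the
#' underlying igraph object; `witnesses()` the full instance table backing
#' the edges; `edgeTable()` a flat edge data frame with the three weights.
#'
#' @param x a [ColexNetwork-class].
#' @param ... ignored.
#' @name ColexNetwork-accessors
NULL

#' @rdname ColexNetwork-accessors
#' @export
setMethod("networkKind", "ColexNetwork", function(x) x@kind)

#' @rdname ColexNetwork-accessors
#' @export
setMethod("networkGraph", "ColexNetwork", function(x) x@graph)

#' @rdname ColexNetwork-accessors
#' @export
setMethod("witnesses", "ColexNetwork", function(x, ...) x@instances)

#' @rdname ColexNetwork-accessors
#' @export
setMethod("edgeTable", "ColexNetwork", function(x, ...) {
  g <- x@graph
  if (!igraph::ecount(g)) {
    return(data.frame(concept_a = character(), concept_b = character(),
                      direction = character(), weight_forms = integer(),
                      weight_languages = integer(), weight_families = integer(),
                      stringsAsFactors = FALSE))
  }
  ends <- igraph::as_edgelist(g)
  data.frame(concept_a = ends[, 1], concept_b = ends[, 2],
             direction = if (x@kind == "affix") "directed" else "undirected",
             weight_forms = igraph::E(g)$weight_forms,
             weight_languages = igraph::E(g)$weight_languages,
             weight_families = igraph::E(g)$weight_families,
             stringsAsFactors = FALSE)
})

setMethod("show", "ColexNetwork", function(object) {
  g <- object@graph
  cat("ColexNetwork (", object@kind, ", ",
      if (igraph::is_directed(g)) "directed" else "undirected", ")\n", sep = "")
  cat("  ", igraph::vcount(g), " concepts, ", igraph::ecount(g), " edges, ",
      nrow(object@instances), " witness instances\n", sep = "")
  if (!is.null(object@params)) show(object@params)
})
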