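.weight_vec <- function(g, weight) {
  if (weight == "unweighted") return(NULL)
  w <- switch(weight, forms = igraph::E(g)$weight_forms,
              languages = igraph::E(g)$weight_languages,
              families = igraph::E(g)$weight_families)
  if (is.null(w) && igraph::ecount(g) > 0)
    stop("network edges carry no '", weight, "' weight")
  w
}

#' Weighted degree vector of a colexification network
#'
#' Returns, for every concept of the network (including isolated ones, which
#' get 0), the sum of the weights of its incident edges; for directed affix
#' networks the incoming and outgoing edges give separate in- and out-degree
#' vectors. The default weight is `weight_families`, the most conservative of
#' the three edge weights (a colexification recurring across families is less
#' likely to be family-internal homophony).
#'
#' @param x a [ColexNetwork-class].
#' @param mode `"undirected"` (only for undirected networks) or `"in"`/
#'   `"out"` (only for directed affix networks).
#' @param weight which edge weight to sum: `"families"`, `"languages"`,
#'   `"forms"`, or `"unweighted"` (count edges).
#' @param ... ignored.
#' @return named numeric vector, one element per concept, with attributes
#'   `mode` and `weight`.
#' @export
setMethod("degreeVector", "ColexNetwork",
          function(x, mode = c("undirected", "in", "out"),
                   weight = c("families", "languages", "forms", "unweighted"), ...) {
  mode <- match.arg(mode)
  weight <- match.arg(weight)
  g <- x@graph
  if (igraph::is_directed(g) && mode == "undirected")
    stop("directed (affix) network: request mode 'in' or 'out'")
  if (!igraph::is_directed(g) && mode != "undirected")
    stop("mode '", mode, "' is only defined for directed (affix) networks")
  w <- .weight_vec(g, weight)
  imode <- if (mode == "undirected") "all" else mode
  d <- if (is.null(w)) igraph::degree(g, mode = imode)
       else igraph::strength(g, mode = imode, weights = w)
  d <- d[sort(names(d), method = "radix")]
  attr(d, "mode") <- mode
  attr(d, "weight") <- weight
  d
})

#' Compare two degree vectors by Spearman rank correlation
#'
#' Restricts both vectors to their shared concepts and computes the Spearman
#' rank correlation with average ranks for ties. The p-value is two-sided;
#' for n <= 10 without ties the exact null distribution is used, otherwise
#' the large-sample approximation.
#'
#' @param va,vb named numeric degree vectors (see [degreeVector()]).
#' @return list with elements `rho`, `p_value`, and `n` (number of shared
#'   concepts compared).
#' @export
compareDegrees <- function(va, vb) {
  stopifnot(!is.null(names(va)), !is.null(names(vb)))
  shared <- intersect(names(va), names(vb))
  n <- length(shared)
  if (n < 3L) stop("need at least 3 shared concepts for a defined correlation")
  a <- as.numeric(va[shared]); b <- as.numeric(vb[shared])
  exact <- n <= 10L && !anyDuplicated(a) && !anyDuplicated(b)
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                         exact = exact, alternative = "two.sided"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Induced subgraph on a set of concepts
#'
#' Returns the induced subgraph of the network on the requested concepts,
#' preserving all node and edge annotations, the kind, and the directedness.
#' Requested concepts absent from the network are added as isolated nodes
#' with a warning.
#'
#' @param x a [ColexNetwork-class].
#' @param concepts character vector of concept identifiers.
#' @param ... ignored.
#' @return A [ColexNetwork-class].
#' @export
setMethod("extractSubgraph", "ColexNetwork", function(x, concepts, ...) {
  stopifnot(length(concepts) >= 1L)
  concepts <- unique(as.character(concepts))
  g <- x@graph
  known <- intersect(concepts, igraph::V(g)$name)
  missing <- setdiff(concepts, known)
  sg <- igraph::induced_subgraph(g, known)
  if (length(missing)) {
    warning("concepts not in network, added as isolated nodes: ",
            paste(missing, collapse = ", "))
    sg <- igraph::add_vertices(sg, length(missing), name = missing)
  }
  inst <- x@instances
  inst <- inst[inst$concept_a %in% concepts & inst$concept_b %in% concepts, ,
               drop = FALSE]
  rownames(inst) <- NULL
  new("ColexNetwork", kind = x@kind, graph = sg, instances = inst,
      params = x@params)
})

#' Community detection on an undirected colexification network
#'
#' Partitions the concepts of an undirected (full or overlap) network into
#' communities using an established graph-library backend: the Infomap
#' random-walk algorithm or label propagation. Edge weights (default
#' `weight_families`) inform both algorithms; the result is deterministic
#' for a fixed seed.
#'
#' @param x an undirected [ColexNetwork-class].
#' @param algorithm `"infomap"` or `"label-propagation"`.
#' @param seed integer seed for the stochastic backends.
#' @param weight which edge weight to use (as in [degreeVector()]).
#' @param ... ignored.
#' @return named integer vector mapping every concept to a community id.
#' @export
setMethod("detectCommunities", "ColexNetwork",
          function(x, algorithm = c("infomap", "label-propagation"),
                   seed = NULL,
                   weight = c("families", "languages", "forms", "unweighted"), ...) {
  algorithm <- match.arg(algorithm)
  weight <- match.arg(weight)
  g <- x@graph
  if (igraph::is_directed(g))
    stop("communities are computed on undirected (full/overlap) networks")
  w <- .weight_vec(g, weight)
  if (!is.null(seed)) set.seed(seed)
  comm <- switch(algorithm,
    infomap = igraph::cluster_infomap(g, e.weights = w),
    `label-propagation` = igraph::cluster_label_prop(g, weights = w))
  m <- igraph::membership(comm)
  out <- as.integer(m)
  names(out) <- names(m)
  out[sort(names(out), method = "radix")]
})
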