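#' @rdname Wordlist-accessors
#' @export
setGeneric("entries", function(x, ...) standardGeneric("entries"))

#' @rdname Wordlist-accessors
#' @export
setGeneric("languageIds", function(x, ...) standardGeneric("languageIds"))

#' @rdname Wordlist-accessors
#' @export
setGeneric("concepts", function(x, ...) standardGeneric("concepts"))

#' @rdname Wordlist-accessors
#' @export
setGeneric("nForms", function(x, ...) standardGeneric("nForms"))

#' @rdname languageForms
#' @export
setGeneric("languageForms", function(x, language, ...) standardGeneric("languageForms"))

#' @rdname buildNetwork
#' @export
setGeneric("buildNetwork", function(x, kind = c("full", "affix", "overlap"),
                                    params = NULL, ...) standardGeneric("buildNetwork"))

#' @rdname ColexNetwork-accessors
#' @export
setGeneric("networkKind", function(x) standardGeneric("networkKind"))

#' @rdname ColexNetwork-accessors
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname ColexNetwork-accessors
#' @export
setGeneric("witnesses", function(x, ...) standardGeneric("witnesses"))

#' @rdname ColexNetwork-accessors
#' @export
setGeneric("edgeTable", function(x, ...) standardGeneric("edgeTable"))

#' @rdname degreeVector
#' @export
setGeneric("degreeVector", function(x, mode = c("undirected", "in", "out"),
                                    weight = c("families", "languages", "forms",
                                               "unweighted"), ...)
  standardGeneric("degreeVector"))

#' @rdname extractSubgraph
#' @export
setGeneric("extractSubgraph", function(x, concepts, ...) standardGeneric("extractSubgraph"))

#' @rdname detectCommunities
#' @export
setGeneric("detectCommunities", function(x, algorithm = c("infomap", "label-propagation"),
                                         seed = NULL, ...)
  standardGeneric("detectCommunities"))

#' @rdname exportNetwork
#' @export
setGeneric("exportNetwork", function(x, path, format = c("gml", "graphml", "json", "tsv"),
                                     ...) standardGeneric("exportNetwork"))
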