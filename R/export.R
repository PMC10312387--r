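#' Export a colexification network to disk
#'
#' Writes the network in a plain-text graph format suitable for downstream
#' tools: `"gml"` and `"graphml"` (readable by Cytoscape and Gephi) carry all
#' node and edge annotations, `"json"` is an edge list embedding the full
#' witness instances, `"tsv"` is a flat edge table (`concept_a`, `concept_b`,
#' `direction`, and the three weights). Output is byte-deterministic for a
#' given network.
#'
#' @param x a [ColexNetwork-class].
#' @param path output file path.
#' @param format one of `"gml"`, `"graphml"`, `"json"`, `"tsv"`.
#' @param ... ignored.
#' @return `path`, invisibly.
#' @export
setMethod("exportNetwork", "ColexNetwork",
          function(x, path, format = c("gml", "graphml", "json", "tsv"), ...) {
  format <- match.arg(format)
  g <- x@graph
  if (format %in% c("gml", "graphml")) {
    igraph::write_graph(g, path, format = format)
    if (format == "gml") {
      # igraph stamps the Creator line with a timestamp; fix it so that
      # identical networks export byte-identically
      lines <- readLines(path, warn = FALSE)
      if (length(lines) && startsWith(lines[1], "Creator"))
        lines[1] <- "Creator \"colexnet\""
      writeLines(lines, path)
    }
  } else if (format == "tsv") {
    utils::write.table(edgeTable(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    nodes <- data.frame(concept = igraph::V(g)$name,
                        n_forms = igraph::V(g)$n_forms,
                        n_languages = igraph::V(g)$n_languages,
                        n_families = igraph::V(g)$n_families,
                        stringsAsFactors = FALSE)
    et <- edgeTable(x)
    inst <- x@instances
    edge_list <- lapply(seq_len(nrow(et)), function(i) {
      sel <- inst$concept_a == et$concept_a[i] & inst$concept_b == et$concept_b[i]
      c(as.list(et[i, ]), list(witnesses = inst[sel, , drop = FALSE]))
    })
    jsonlite::write_json(list(kind = x@kind,
                              directed = igraph::is_directed(g),
                              nodes = nodes, edges = edge_list),
                         path, auto_unbox = TRUE, dataframe = "rows",
                         pretty = TRUE, digits = NA)
  }
  invisible(path)
})
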