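.default_run_config <- function() {
  list(input = NULL, dialect = "tsv", column_map = NULL,
       tokenizer = "segments", dedup = TRUE, lowercase = FALSE,
       keep_boundaries = FALSE,
       kind = "full", affix_min = NULL, residue_min = NULL,
       sides = "both", same_side_only = FALSE,
       output = NULL, format = "gml",
       degrees = NULL,   # optional: list(mode, weight, output)
       manifest = NULL,  # optional path for a reproducibility manifest
       seed = 1L)
}

#' Read / write a pipeline run configuration
#'
#' A run configuration is a plain list (JSON on disk) bundling every option
#' of the read–infer–export pipeline: input path and dialect, tokenizer
#' options, inference kind and thresholds, output path and format, optional
#' degree output and manifest path. Unknown fields are rejected; omitted
#' fields take their defaults.
#'
#' @param path JSON file path.
#' @return `readRunConfig()`: the completed configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- .default_run_config()
  bad <- setdiff(names(cfg), names(base))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  base[names(cfg)] <- cfg
  base
}

#' @rdname readRunConfig
#' @param cfg configuration list.
#' @export
writeRunConfig <- function(cfg, path) {
  base <- .default_run_config()
  bad <- setdiff(names(cfg), names(base))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  jsonlite::write_json(cfg[!vapply(cfg, is.null, TRUE)], path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Run the read–infer–export pipeline
#'
#' Reads a wordlist, builds the requested colexification network, writes it
#' in the requested format, optionally writes a concept/degree table, and
#' optionally records a manifest (config echo, input checksum) for
#' reproducibility. Identical configuration and input produce byte-identical
#' outputs.
#'
#' @param cfg configuration list (see [readRunConfig()]) or path to a JSON
#'   configuration file.
#' @param verbose print a run summary?
#' @return invisibly, a list with the `wordlist`, the `network`, and the
#'   paths written.
#' @export
runPipeline <- function(cfg, verbose = TRUE) {
  if (is.character(cfg) && length(cfg) == 1L) cfg <- readRunConfig(cfg)
  base <- .default_run_config()
  bad <- setdiff(names(cfg), names(base))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  base[names(cfg)] <- cfg
  cfg <- base
  if (is.null(cfg$input)) stop("config needs an 'input' wordlist path")
  if (!cfg$kind %in% c("full", "affix", "overlap"))
    stop("unknown inference kind: ", cfg$kind)

  cm <- cfg$column_map
  if (!is.null(cm)) cm <- unlist(cm)
  wl <- readWordlist(cfg$input, dialect = cfg$dialect, columnMap = cm,
                     tokenizer = cfg$tokenizer, dedup = isTRUE(cfg$dedup),
                     lowercase = isTRUE(cfg$lowercase),
                     keepBoundaries = isTRUE(cfg$keep_boundaries))
  params <- if (cfg$kind == "full") NULL else
    colexParams(cfg$kind, affixMin = cfg$affix_min, residueMin = cfg$residue_min,
                sides = cfg$sides, sameSideOnly = isTRUE(cfg$same_side_only))
  net <- buildNetwork(wl, cfg$kind, params)

  written <- character()
  if (!is.null(cfg$output)) {
    exportNetwork(net, cfg$output, format = cfg$format)
    written <- c(written, cfg$output)
  }
  if (!is.null(cfg$degrees)) {
    dg <- cfg$degrees
    mode <- dg$mode %||% if (cfg$kind == "affix") "out" else "undirected"
    wt <- dg$weight %||% "families"
    d <- degreeVector(net, mode = mode, weight = wt)
    utils::write.table(data.frame(concept = names(d), degree = as.numeric(d)),
                       dg$output, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    written <- c(written, dg$output)
  }
  if (!is.null(cfg$manifest)) {
    cfg_txt <- jsonlite::toJSON(cfg[!vapply(cfg, is.null, TRUE)],
                                auto_unbox = TRUE, digits = NA)
    tf <- tempfile(); writeLines(cfg_txt, tf)
    manifest <- list(config = cfg[!vapply(cfg, is.null, TRUE)],
                     config_md5 = unname(tools::md5sum(tf)),
                     input_md5 = unname(tools::md5sum(cfg$input)),
                     n_forms = nForms(wl),
                     n_languages = length(languageIds(wl)),
                     n_nodes = igraph::vcount(networkGraph(net)),
                     n_edges = igraph::ecount(networkGraph(net)))
    unlink(tf)
    jsonlite::write_json(manifest, cfg$manifest, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    written <- c(written, cfg$manifest)
  }
  if (verbose) {
    cat("languages:", length(languageIds(wl)),
        "| forms:", nForms(wl),
        "| kind:", cfg$kind,
        "| nodes:", igraph::vcount(networkGraph(net)),
        "| edges:", igraph::ecount(networkGraph(net)), "\n")
  }
  invisible(list(wordlist = wl, network = net, files = written))
}
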