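#' Write a model to the self-describing JSON graph document
#'
#' The JSON document (`species`, `nodes[]`, `edges[]` with inline evidence,
#' `signatures[]`) round-trips losslessly through [read_model_json()] and is
#' also the import format for externally obtained models (e.g. a conversion
#' of a hosted causal network download).
#'
#' @param model a `layered_model` or `causal_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  if (inherits(model, "causal_network")) model <- split_layers(model)
  stopifnot(inherits(model, "layered_model"))
  nodes <- model$network$nodes
  doc <- list(
    format = "cbnet-model",
    version = 1L,
    species = model$species,
    nodes = purrr::pmap(
      list(nodes$id, nodes$fn, nodes$ns, nodes$value, nodes$layer),
      function(id, fn, ns, value, layer) {
        list(id = id, fn = fn, ns = ns, value = value, layer = layer)
      }),
    edges = purrr::pmap(
      list(model$network$edges$source, model$network$edges$target,
           model$network$edges$sign, model$network$edges$evidence),
      function(source, target, sign, evidence) {
        list(source = source, target = target, sign = sign,
             evidence = evidence)
      }),
    signatures = model$signatures
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a model from the JSON graph document
#'
#' @param path path to a JSON file written by [write_model_json()] (or an
#'   external model converted to that format).
#' @return a `layered_model`.
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("model file not found: %s", path),
                 class = c("cbn_io_error", "cbn_error"))
  }
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "cbnet-model")) {
    rlang::abort(sprintf("%s is not a cbnet model document", path),
                 class = c("cbn_io_error", "cbn_error"))
  }
  nodes <- if (length(doc$nodes)) {
    ids <- purrr::map_chr(doc$nodes, "id")
    tibble::tibble(
      id = ids,
      fn = purrr::map_chr(doc$nodes, "fn"),
      ns = purrr::map_chr(doc$nodes, "ns"),
      value = purrr::map_chr(doc$nodes, "value"),
      term = purrr::map(ids, parse_term),
      layer = purrr::map_chr(doc$nodes, "layer")
    )
  } else {
    dplyr::mutate(empty_nodes(), layer = character())
  }
  edges <- if (length(doc$edges)) {
    tibble::tibble(
      source = purrr::map_chr(doc$edges, "source"),
      target = purrr::map_chr(doc$edges, "target"),
      sign = purrr::map_int(doc$edges, \(e) as.integer(e$sign)),
      evidence = purrr::map(doc$edges, \(e) evidence_from_json(e$evidence))
    )
  } else {
    empty_edges()
  }
  signatures <- if (length(doc$signatures)) {
    tibble::tibble(
      node = purrr::map_chr(doc$signatures, "node"),
      gene = purrr::map_chr(doc$signatures, "gene"),
      sign = purrr::map_int(doc$signatures, \(s) as.integer(s$sign))
    )
  } else {
    empty_signatures()
  }
  network <- new_causal_network(nodes, edges, doc$species %||% "mixed")
  structure(
    list(network = network, signatures = signatures,
         dropped = empty_signatures(), species = network$species),
    class = "layered_model"
  )
}

evidence_from_json <- function(evidence) {
  purrr::map_dfr(evidence, function(row) {
    tibble::tibble(
      citation = row$citation %||% NA_character_,
      species = row$species %||% NA_character_,
      tissue = row$tissue %||% NA_character_,
      evidence = row$evidence %||% NA_character_,
      statement = row$statement %||% NA_character_
    )
  })
}

sign_relation <- c(`-1` = "decreases", `0` = "association", `1` = "increases")

#' Export a model as SIF (simple interaction format)
#'
#' One line per edge: `source<TAB>relation<TAB>target` with relation in
#' `{increases, decreases, association}` — the minimal format Cytoscape-type
#' viewers ingest.
#'
#' @param model a `layered_model` or `causal_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(model, path) {
  network <- if (inherits(model, "layered_model")) model$network else model
  stopifnot(inherits(network, "causal_network"))
  lines <- sprintf("%s\t%s\t%s", network$edges$source,
                   sign_relation[as.character(network$edges$sign)],
                   network$edges$target)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Export a model as GraphML with node and edge attributes
#'
#' Nodes carry `layer`, `function` and `namespace` attributes; edges carry
#' `sign` and `n_evidence`, for downstream styling in Cytoscape-type
#' viewers.
#'
#' @param model a `layered_model` or `causal_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(model, path) {
  if (inherits(model, "causal_network")) model <- split_layers(model)
  stopifnot(inherits(model, "layered_model"))
  nodes <- model$network$nodes
  edges <- model$network$edges
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns"
  )
  keydefs <- list(
    c("d_layer", "node", "layer", "string"),
    c("d_function", "node", "function", "string"),
    c("d_namespace", "node", "namespace", "string"),
    c("d_sign", "edge", "sign", "int"),
    c("d_nev", "edge", "n_evidence", "int")
  )
  for (k in keydefs) {
    xml2::xml_add_child(doc, "key", id = k[1], `for` = k[2],
                        attr.name = k[3], attr.type = k[4])
  }
  graph <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "directed")
  for (i in seq_len(nrow(nodes))) {
    node <- xml2::xml_add_child(graph, "node", id = nodes$id[i])
    xml2::xml_add_child(node, "data", nodes$layer[i], key = "d_layer")
    xml2::xml_add_child(node, "data", nodes$fn[i], key = "d_function")
    xml2::xml_add_child(node, "data", nodes$ns[i], key = "d_namespace")
  }
  for (i in seq_len(nrow(edges))) {
    edge <- xml2::xml_add_child(graph, "edge",
                                source = edges$source[i],
                                target = edges$target[i])
    xml2::xml_add_child(edge, "data", as.character(edges$sign[i]),
                        key = "d_sign")
    xml2::xml_add_child(edge, "data",
                        as.character(nrow(edges$evidence[[i]])),
                        key = "d_nev")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Export a model in a chosen graph format
#'
#' @param model a `layered_model` or `causal_network`.
#' @param path output path.
#' @param format one of `"sif"`, `"graphml"`, `"json"`.
#' @return `path`, invisibly.
#' @export
export_model <- function(model, path, format = c("sif", "graphml", "json")) {
  if (is.character(format) && length(format) == 1 &&
      !format %in% c("sif", "graphml", "json")) {
    rlang::abort(sprintf("unknown export format '%s' (use sif, graphml or json)",
                         format),
                 class = c("cbn_unknown_format", "cbn_error"))
  }
  format <- match.arg(format)
  switch(format,
         sif = write_sif(model, path),
         graphml = write_graphml(model, path),
         json = write_model_json(model, path))
}
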