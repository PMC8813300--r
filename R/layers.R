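#' Split a causal network into backbone and downstream mRNA layers
#'
#' A node belongs to the downstream layer iff its function is `r`
#' (transcript abundance) and it has no outgoing causal edges — i.e. it is a
#' leaf transcript regulated by the backbone. Everything else is backbone.
#' Each backbone node's signature is the set of `(gene symbol, sign)` pairs
#' over its signed (non-association) edges into downstream nodes; a gene a
#' node both up- and down-regulates carries no usable direction and is
#' dropped from that node's signature (reported in `dropped`). Backbone
#' nodes with a non-empty signature are the inferable nodes ("iNodes") —
#' the only nodes whose activity can be scored from expression data.
#'
#' @param network a `causal_network`.
#' @return a `layered_model`: list with `network` (nodes gain a `layer`
#'   column), `signatures` (tibble `node`, `gene`, `sign`), `dropped`
#'   (tibble of ambiguous dual-sign entries) and `species`.
#' @export
split_layers <- function(network) {
  stopifnot(inherits(network, "causal_network"))
  nodes <- network$nodes
  has_out <- nodes$id %in% network$edges$source
  layer <- ifelse(nodes$fn == "r" & !has_out, "downstream", "backbone")
  nodes$layer <- layer
  downstream_ids <- nodes$id[layer == "downstream"]
  gene_of <- stats::setNames(nodes$value, nodes$id)
  sig <- network$edges |>
    dplyr::filter(.data$target %in% downstream_ids, .data$sign != 0L) |>
    dplyr::transmute(node = .data$source,
                     gene = unname(gene_of[.data$target]),
                     sign = .data$sign) |>
    dplyr::distinct()
  pruned <- prune_dual_signs(sig)
  network$nodes <- nodes
  structure(
    list(network = network, signatures = pruned$signatures,
         dropped = pruned$dropped, species = network$species),
    class = "layered_model"
  )
}

prune_dual_signs <- function(sig) {
  if (nrow(sig) == 0) {
    return(list(signatures = empty_signatures(), dropped = empty_signatures()))
  }
  ambiguous <- sig |>
    dplyr::distinct(.data$node, .data$gene, .data$sign) |>
    dplyr::count(.data$node, .data$gene) |>
    dplyr::filter(.data$n > 1) |>
    dplyr::select(-"n")
  dropped <- dplyr::semi_join(sig, ambiguous, by = c("node", "gene"))
  if (nrow(dropped)) {
    rlang::inform(sprintf(
      "dropped %d dual-sign signature gene(s): %s",
      nrow(ambiguous),
      paste(paste0(ambiguous$node, "/", ambiguous$gene), collapse = ", ")))
  }
  keep <- dplyr::anti_join(sig, ambiguous, by = c("node", "gene")) |>
    dplyr::arrange(.data$node, .data$gene)
  list(signatures = keep, dropped = dropped)
}

empty_signatures <- function() {
  tibble::tibble(node = character(), gene = character(), sign = integer())
}

#' @export
print.layered_model <- function(x, ...) {
  s <- network_stats(x)
  cat(sprintf("<layered_model> %d backbone + %d downstream nodes, %d edges, %d iNodes (species: %s)\n",
              s$n_backbone, s$n_downstream, s$n_edges, s$n_inferable, x$species))
  invisible(x)
}

#' Inferable backbone nodes of a layered model
#'
#' @param model a `layered_model`.
#' @return character vector of backbone node ids with non-empty signatures.
#' @export
inferable_nodes <- function(model) {
  stopifnot(inherits(model, "layered_model"))
  sort(unique(model$signatures$node))
}

#' Backbone-only view of a layered model
#'
#' @param model a `layered_model`.
#' @return a `causal_network` restricted to backbone nodes and the edges
#'   among them.
#' @export
backbone_network <- function(model) {
  stopifnot(inherits(model, "layered_model"))
  nodes <- dplyr::filter(model$network$nodes, .data$layer == "backbone")
  edges <- dplyr::filter(model$network$edges,
                         .data$source %in% nodes$id, .data$target %in% nodes$id)
  new_causal_network(nodes, edges, model$species)
}

#' Read an external signature table
#'
#' Tab-separated text with header columns `node_id`, `gene_symbol`, `sign`
#' (`sign` in `{+1, -1}`) — the format in which dataset-derived downstream
#' signatures (regulons) are supplied for models whose mRNA layer was built
#' from public transcriptomic data rather than curated statements.
#'
#' @param path path to the TSV file.
#' @return a tibble `node`, `gene`, `sign`.
#' @export
read_signature_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    node_id = "c", gene_symbol = "c", sign = "i"), progress = FALSE)
  if (!all(c("node_id", "gene_symbol", "sign") %in% names(tbl))) {
    rlang::abort("signature table must have columns node_id, gene_symbol, sign",
                 class = c("cbn_invalid_signature_table", "cbn_error"))
  }
  if (nrow(tbl) && !all(tbl$sign %in% c(-1L, 1L))) {
    rlang::abort("signature table sign must be +1 or -1",
                 class = c("cbn_invalid_signature_table", "cbn_error"))
  }
  tibble::tibble(node = tbl$node_id, gene = tbl$gene_symbol, sign = tbl$sign)
}

#' Attach an external signature table to a layered model
#'
#' @param model a `layered_model`.
#' @param table a signature tibble (`node`, `gene`, `sign`), e.g. from
#'   [read_signature_table()].
#' @param mode `"merge"` (default) unions the table with the
#'   statement-derived signatures (dual-sign genes re-pruned); `"replace"`
#'   discards the statement-derived signatures in favour of the table.
#' @return the updated `layered_model` with the inferable set recomputed.
#' @export
attach_signatures <- function(model, table, mode = c("merge", "replace")) {
  stopifnot(inherits(model, "layered_model"))
  mode <- match.arg(mode)
  table <- tibble::as_tibble(table)
  backbone_ids <- model$network$nodes$id[model$network$nodes$layer == "backbone"]
  unknown <- setdiff(unique(table$node), backbone_ids)
  if (length(unknown)) {
    rlang::abort(sprintf("signature table references unknown backbone node(s): %s",
                         paste(unknown, collapse = ", ")),
                 class = c("cbn_unknown_node", "cbn_error"), nodes = unknown)
  }
  sig <- if (mode == "merge") {
    dplyr::distinct(dplyr::bind_rows(model$signatures, table))
  } else {
    dplyr::distinct(table)
  }
  pruned <- prune_dual_signs(sig)
  model$signatures <- pruned$signatures
  model$dropped <- dplyr::bind_rows(model$dropped, pruned$dropped)
  model
}

#' Summary statistics of a network or layered model
#'
#' Reports node/edge counts, the backbone/downstream partition, the
#' inferable-node count, the edge sign distribution, and the number of
#' contradictions (node pairs connected by both a +1 and a -1 edge). A bare
#' `causal_network` is layered on the fly, so both the backbone-only and
#' whole-model readings of a published node/edge count can be checked.
#'
#' @param x a `causal_network` or `layered_model`.
#' @return a one-row tibble.
#' @export
network_stats <- function(x) {
  if (inherits(x, "causal_network")) x <- split_layers(x)
  stopifnot(inherits(x, "layered_model"))
  nodes <- x$network$nodes
  edges <- x$network$edges
  contradictions <- if (nrow(edges)) {
    edges |>
      dplyr::distinct(.data$source, .data$target, .data$sign) |>
      dplyr::filter(.data$sign != 0L) |>
      dplyr::count(.data$source, .data$target) |>
      dplyr::filter(.data$n > 1) |>
      nrow()
  } else 0L
  tibble::tibble(
    n_nodes = nrow(nodes),
    n_edges = nrow(edges),
    n_backbone = sum(nodes$layer == "backbone"),
    n_downstream = sum(nodes$layer == "downstream"),
    n_inferable = length(inferable_nodes(x)),
    n_edges_positive = sum(edges$sign == 1L),
    n_edges_negative = sum(edges$sign == -1L),
    n_edges_association = sum(edges$sign == 0L),
    n_contradictions = contradictions
  )
}
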