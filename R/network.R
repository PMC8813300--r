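#' Assemble parsed statements into a signed causal network
#'
#' Compiles a statement table into a network with one node per distinct
#' canonical term and one edge per `(source, target, sign)` triple. All
#' statements supporting an edge are attached as evidence, so contradictory
#' curation (`A increases B` alongside `A decreases B`) yields two parallel
#' edges with opposite signs, and `association` statements yield sign-0
#' edges.
#'
#' @param statements a statement tibble from [read_bel()] /
#'   [parse_bel_lines()], or a list of `bel_statement` objects.
#' @param species species/nomenclature tag for the assembly (default
#'   `"mixed"` until orthologized).
#' @return a `causal_network`: list with `nodes` (tibble: `id`, `fn`, `ns`,
#'   `value`, list-column `term`), `edges` (tibble: `source`, `target`,
#'   `sign`, list-column `evidence` of per-statement provenance tibbles) and
#'   `species`.
#' @export
assemble <- function(statements, species = "mixed") {
  statements <- as_statement_table(statements)
  if (nrow(statements) == 0) {
    return(new_causal_network(empty_nodes(), empty_edges(), species))
  }
  terms <- c(statements$subject_term, statements$object_term)
  ids <- purrr::map_chr(terms, serialize_term)
  keep <- !duplicated(ids)
  nodes <- node_table(terms[keep])
  edges <- statements |>
    dplyr::mutate(evidence_row = purrr::pmap(
      list(.data$citation, .data$species, .data$tissue, .data$evidence,
           .data$subject, .data$relationship, .data$object),
      function(citation, species, tissue, evidence, subject, relationship, object) {
        tibble::tibble(citation = citation, species = species, tissue = tissue,
                       evidence = evidence,
                       statement = paste(subject, relationship, object))
      }
    )) |>
    dplyr::group_by(source = .data$subject, target = .data$object, sign = .data$sign) |>
    dplyr::summarise(evidence = list(dplyr::bind_rows(.data$evidence_row)),
                     .groups = "drop") |>
    dplyr::arrange(.data$source, .data$target, .data$sign)
  new_causal_network(nodes, edges, species)
}

as_statement_table <- function(statements) {
  if (is.data.frame(statements)) return(statements)
  if (is.list(statements) &&
      all(purrr::map_lgl(statements, inherits, "bel_statement"))) {
    rows <- purrr::imap(statements, function(s, i) {
      tibble::tibble(
        line = i, subject = serialize_term(s$subject),
        relationship = s$relationship, object = serialize_term(s$object),
        sign = s$sign, citation = s$annotations$citation,
        species = s$annotations$species,
        tissue = s$annotations$tissue %||% NA_character_,
        evidence = s$annotations$evidence %||% NA_character_,
        subject_term = list(s$subject), object_term = list(s$object)
      )
    })
    return(if (length(rows)) dplyr::bind_rows(rows) else empty_statements())
  }
  rlang::abort("`statements` must be a statement tibble or a list of bel_statement objects",
               class = "cbn_error")
}

node_table <- function(terms) {
  if (!length(terms)) return(empty_nodes())
  tibble::tibble(
    id = purrr::map_chr(terms, serialize_term),
    fn = purrr::map_chr(terms, term_fn),
    ns = purrr::map_chr(terms, \(t) term_leaf(t)$ns),
    value = purrr::map_chr(terms, \(t) term_leaf(t)$value),
    term = terms
  ) |> dplyr::arrange(.data$id)
}

empty_nodes <- function() {
  tibble::tibble(id = character(), fn = character(), ns = character(),
                 value = character(), term = list())
}

empty_edges <- function() {
  tibble::tibble(source = character(), target = character(), sign = integer(),
                 evidence = list())
}

new_causal_network <- function(nodes, edges, species) {
  structure(list(nodes = nodes, edges = edges, species = species),
            class = "causal_network")
}

#' @export
print.causal_network <- function(x, ...) {
  cat(sprintf("<causal_network> %d nodes, %d edges (species: %s)\n",
              nrow(x$nodes), nrow(x$edges), x$species))
  invisible(x)
}

#' Read an ortholog mapping table
#'
#' Expects tab-separated text with header columns `source_namespace`,
#' `source_symbol`, `target_symbol`. Each `(source_namespace,
#' source_symbol)` key must map to exactly one target symbol; duplicated
#' keys are a validation error (two source symbols mapping onto one target
#' symbol are fine and produce a node merge).
#'
#' @param path path to the TSV file.
#' @param target_namespace namespace the targets live in (default `"HGNC"`).
#' @return a tibble of class `ortholog_map` with attribute
#'   `target_namespace`.
#' @export
read_ortholog_map <- function(path, target_namespace = "HGNC") {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  as_ortholog_map(tbl, target_namespace)
}

#' @rdname read_ortholog_map
#' @param tbl a data frame with the three required columns.
#' @export
as_ortholog_map <- function(tbl, target_namespace = "HGNC") {
  required <- c("source_namespace", "source_symbol", "target_symbol")
  if (!all(required %in% names(tbl))) {
    rlang::abort(sprintf("ortholog map must have columns: %s",
                         paste(required, collapse = ", ")),
                 class = c("cbn_invalid_map", "cbn_error"))
  }
  tbl <- tibble::as_tibble(tbl[required])
  dup <- tbl |>
    dplyr::count(.data$source_namespace, .data$source_symbol) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    rlang::abort(sprintf("ortholog map keys mapped more than once: %s",
                         paste(paste0(dup$source_namespace, ":", dup$source_symbol),
                               collapse = ", ")),
                 class = c("cbn_invalid_map", "cbn_error"))
  }
  structure(tbl, class = c("ortholog_map", class(tbl)),
            target_namespace = target_namespace)
}

#' Orthologize a network to a single gene nomenclature
#'
#' Rewrites every mouse (MGI) and rat (RGD) gene symbol — at any wrapper
#' nesting level — to its ortholog in the target namespace, then merges
#' nodes that become identical, unioning their edges and evidence. Non-gene
#' namespaces are untouched. Running the operation twice is a no-op: after
#' one strict pass no MGI/RGD node remains.
#'
#' @param network a `causal_network`.
#' @param map an `ortholog_map` from [read_ortholog_map()].
#' @param strict if `TRUE` (default) an MGI/RGD symbol missing from the map
#'   aborts; if `FALSE` unmapped nodes keep their original namespace, a
#'   warning lists them, and the result keeps species tag `"mixed"`.
#' @return the orthologized `causal_network`, tagged with the target
#'   species nomenclature.
#' @export
orthologize <- function(network, map, strict = TRUE) {
  stopifnot(inherits(network, "causal_network"))
  map <- if (inherits(map, "ortholog_map")) map else as_ortholog_map(map)
  target_ns <- attr(map, "target_namespace")
  lookup <- stats::setNames(map$target_symbol,
                            paste(map$source_namespace, map$source_symbol, sep = ":"))
  unmapped <- character()
  rewrite <- function(term) {
    if (!is.null(term$inner)) {
      term$inner <- rewrite(term$inner)
      return(term)
    }
    if (term$ns %in% setdiff(names(gene_namespaces), target_ns)) {
      key <- paste(term$ns, term$value, sep = ":")
      hit <- lookup[key]
      if (is.na(hit)) {
        unmapped <<- c(unmapped, key)
      } else {
        term$ns <- target_ns
        term$value <- unname(hit)
      }
    }
    term
  }
  new_terms <- purrr::map(network$nodes$term, rewrite)
  unmapped <- unique(unmapped)
  if (length(unmapped)) {
    msg <- sprintf("unmapped gene symbols: %s", paste(unmapped, collapse = ", "))
    if (strict) {
      rlang::abort(msg, class = c("cbn_unmapped_symbol", "cbn_error"),
                   symbols = unmapped)
    }
    rlang::warn(msg)
  }
  id_map <- stats::setNames(purrr::map_chr(new_terms, serialize_term),
                            network$nodes$id)
  keep <- !duplicated(unname(id_map))
  nodes <- node_table(new_terms[keep])
  edges <- network$edges |>
    dplyr::mutate(source = unname(id_map[.data$source]),
                  target = unname(id_map[.data$target]))
  loops <- edges$source == edges$target
  if (any(loops)) {
    rlang::warn(sprintf("dropping %d self-loop edge(s) created by ortholog merging",
                        sum(loops)))
    edges <- edges[!loops, ]
  }
  edges <- edges |>
    dplyr::group_by(.data$source, .data$target, .data$sign) |>
    dplyr::summarise(evidence = list(dplyr::bind_rows(.data$evidence)),
                     .groups = "drop") |>
    dplyr::arrange(.data$source, .data$target, .data$sign)
  sp <- gene_namespaces[target_ns]
  species <- if (length(unmapped)) "mixed" else
    if (is.na(sp)) target_ns else unname(sp)
  new_causal_network(nodes, edges, species)
}
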