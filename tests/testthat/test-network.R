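test_that("assemble deduplicates triples and keeps all evidence", {
  lines <- c(
    'SET Citation = "PMID:1"',
    "p(HGNC:A) increases p(HGNC:B)",
    'SET Citation = "PMID:2"',
    "p(HGNC:A) increases p(HGNC:B)",
    "p(HGNC:B) decreases p(HGNC:C)"
  )
  path <- withr::local_tempfile(fileext = ".bel")
  writeLines(lines, path)
  net <- assemble(read_bel(path))
  expect_identical(nrow(net$nodes), 3L)
  expect_identical(nrow(net$edges), 2L)
  ab <- dplyr::filter(tidy(net), source == "p(HGNC:A)")
  expect_identical(ab$n_evidence, 2L)
  expect_identical(ab$relation, "increases")
  # evidence records both citations
  ev <- net$edges$evidence[[which(net$edges$source == "p(HGNC:A)")]]
  expect_setequal(ev$citation, c("PMID:1", "PMID:2"))
})

test_that("contradictory statements yield parallel edges with opposite signs", {
  lines <- c('SET Citation = "PMID:1"',
             "p(HGNC:A) increases p(HGNC:B)",
             "p(HGNC:A) decreases p(HGNC:B)")
  path <- withr::local_tempfile(fileext = ".bel")
  writeLines(lines, path)
  net <- assemble(read_bel(path))
  expect_identical(nrow(net$edges), 2L)
  expect_setequal(net$edges$sign, c(1L, -1L))
  expect_identical(network_stats(net)$n_contradictions, 1L)
})

test_that("assembly conserves evidence: statement count equals total evidence", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      p <- sim_params(n_backbone = sample(2:6, 1), n_genes_per_node = sample(2:5, 1),
                      edge_density = 0.4, seed = sample.int(1000, 1))
      sim <- simulate_model(p)
      net <- sim$model$network
      total_evidence <- sum(purrr::map_int(net$edges$evidence, nrow))
      # the generator emits one statement per (source, target, sign) triple
      expect_identical(total_evidence, nrow(net$edges))
    }
  })
})

test_that("empty statement list gives an empty network with zeroed stats", {
  net <- assemble(list())
  expect_identical(nrow(net$nodes), 0L)
  expect_identical(nrow(net$edges), 0L)
  stats <- network_stats(net)
  expect_true(all(unlist(stats) == 0))
})

test_that("orthologize rewrites MGI/RGD symbols and merges duplicate nodes", {
  lines <- c(
    'SET Citation = "PMID:1"',
    "p(HGNC:TLR4) increases r(HGNC:IL1B)",
    'SET Citation = "PMID:2"',
    "p(MGI:Tlr4) increases r(HGNC:IL1B)",
    "act(p(RGD:Tlr4)) decreases r(HGNC:IL18)"
  )
  path <- withr::local_tempfile(fileext = ".bel")
  writeLines(lines, path)
  map <- as_ortholog_map(tibble::tibble(
    source_namespace = c("MGI", "RGD"),
    source_symbol = c("Tlr4", "Tlr4"),
    target_symbol = c("TLR4", "TLR4")
  ))
  net <- orthologize(assemble(read_bel(path)), map)
  expect_identical(net$species, "human")
  # p(MGI:Tlr4) merged into p(HGNC:TLR4); wrapped RGD term rewritten too
  expect_true("p(HGNC:TLR4)" %in% net$nodes$id)
  expect_true("act(p(HGNC:TLR4))" %in% net$nodes$id)
  expect_false(any(grepl("MGI|RGD", net$nodes$id)))
  # merged edge unions evidence from both species' statements
  ev <- net$edges$evidence[[which(net$edges$source == "p(HGNC:TLR4)")]]
  expect_setequal(ev$citation, c("PMID:1", "PMID:2"))
  # idempotent: a second pass changes nothing
  again <- orthologize(net, map)
  expect_identical(again$nodes$id, net$nodes$id)
  expect_identical(tidy(again), tidy(net))
})

test_that("orthologize merging never loses evidence", {
  lines <- c(
    'SET Citation = "PMID:1"',
    "p(HGNC:TLR4) increases r(HGNC:G1)",
    "p(MGI:Tlr4) increases r(HGNC:G1)",
    "p(MGI:Tlr4) increases r(MGI:G2m)",
    "p(HGNC:OTHER) decreases r(HGNC:G2)"
  )
  path <- withr::local_tempfile(fileext = ".bel")
  writeLines(lines, path)
  net <- assemble(read_bel(path))
  before <- sum(purrr::map_int(net$edges$evidence, nrow))
  map <- as_ortholog_map(tibble::tibble(
    source_namespace = c("MGI", "MGI"), source_symbol = c("Tlr4", "G2m"),
    target_symbol = c("TLR4", "G2")))
  after_net <- orthologize(net, map)
  after <- sum(purrr::map_int(after_net$edges$evidence, nrow))
  expect_identical(after, before)
  expect_lte(nrow(after_net$edges), nrow(net$edges))
})

test_that("unmapped symbols abort in strict mode, are kept in lenient mode", {
  lines <- c('SET Citation = "PMID:1"', "p(MGI:Unknown9) increases p(HGNC:B)")
  path <- withr::local_tempfile(fileext = ".bel")
  writeLines(lines, path)
  net <- assemble(read_bel(path))
  map <- as_ortholog_map(tibble::tibble(
    source_namespace = "MGI", source_symbol = "Tlr4", target_symbol = "TLR4"))
  err <- expect_error(orthologize(net, map), class = "cbn_unmapped_symbol")
  expect_identical(err$symbols, "MGI:Unknown9")
  expect_warning(lenient <- orthologize(net, map, strict = FALSE), "unmapped")
  expect_true("p(MGI:Unknown9)" %in% lenient$nodes$id)
  expect_identical(lenient$species, "mixed")
})

test_that("a many-to-many ortholog source key is a map validation error", {
  expect_error(
    as_ortholog_map(tibble::tibble(
      source_namespace = c("MGI", "MGI"), source_symbol = c("Tlr4", "Tlr4"),
      target_symbol = c("TLR4", "TLR2"))),
    class = "cbn_invalid_map"
  )
})

test_that("split_layers partitions nodes and derives signed signatures", {
  model <- tiny_model()
  nodes <- model$network$nodes
  expect_setequal(nodes$layer, c("backbone", "downstream"))
  expect_identical(sum(nodes$layer == "backbone"), 2L) # X and Y
  expect_identical(sum(nodes$layer == "downstream"), 3L)
  sig <- model$signatures
  expect_identical(sig$node, rep("p(HGNC:X)", 3))
  expect_identical(sig$sign[sig$gene == "G3"], -1L)
  expect_identical(inferable_nodes(model), "p(HGNC:X)")
  # backbone-only view drops the transcript layer
  bb <- backbone_network(model)
  expect_identical(sort(bb$nodes$id), c("p(HGNC:X)", "p(HGNC:Y)"))
})

test_that("an r() node with outgoing edges stays in the backbone", {
  lines <- c('SET Citation = "PMID:1"',
             "p(HGNC:X) increases r(HGNC:G1)",
             "r(HGNC:G1) increases p(HGNC:Z)")
  path <- withr::local_tempfile(fileext = ".bel")
  writeLines(lines, path)
  model <- split_layers(assemble(read_bel(path)))
  g1 <- dplyr::filter(model$network$nodes, id == "r(HGNC:G1)")
  expect_identical(g1$layer, "backbone")
  expect_identical(nrow(model$signatures), 0L)
})

test_that("association edges never enter signatures", {
  lines <- c('SET Citation = "PMID:1"',
             "p(HGNC:X) increases r(HGNC:G1)",
             "p(HGNC:X) association r(HGNC:G2)")
  path <- withr::local_tempfile(fileext = ".bel")
  writeLines(lines, path)
  model <- split_layers(assemble(read_bel(path)))
  expect_identical(model$signatures$gene, "G1")
})

test_that("dual-sign signature genes are dropped and reported", {
  lines <- c('SET Citation = "PMID:1"',
             "p(HGNC:X) increases r(HGNC:G1)",
             "p(HGNC:X) decreases r(HGNC:G1)",
             "p(HGNC:X) increases r(HGNC:G2)")
  path <- withr::local_tempfile(fileext = ".bel")
  writeLines(lines, path)
  expect_message(model <- split_layers(assemble(read_bel(path))), "dual-sign")
  expect_identical(model$signatures$gene, "G2")
  expect_setequal(model$dropped$gene, "G1")
})

test_that("layer partition and signature-edge correspondence hold on random models", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      sim <- simulate_model(sim_params(n_backbone = sample(3:8, 1),
                                       n_genes_per_node = sample(3:10, 1),
                                       seed = sample.int(1000, 1)))
      nodes <- sim$model$network$nodes
      expect_identical(sum(nodes$layer %in% c("backbone", "downstream")),
                       nrow(nodes))
      edges <- tidy(backbone_network(sim$model))
      # every signature entry corresponds to a network edge of matching sign
      sig <- sim$model$signatures
      gene_id <- sprintf("r(HGNC:%s)", sig$gene)
      full_edges <- sim$model$network$edges
      for (i in seq_len(nrow(sig))) {
        hit <- dplyr::filter(full_edges, source == sig$node[i],
                             target == gene_id[i], sign == sig$sign[i])
        expect_identical(nrow(hit), 1L)
      }
    }
  })
})

test_that("attach_signatures merges or replaces and recomputes inferability", {
  model <- tiny_model()
  extra <- tibble::tibble(node = "p(HGNC:Y)", gene = c("H1", "H2", "H3"),
                          sign = c(1L, 1L, -1L))
  merged <- attach_signatures(model, extra)
  expect_setequal(inferable_nodes(merged), c("p(HGNC:X)", "p(HGNC:Y)"))
  expect_identical(nrow(merged$signatures), 6L)

  replaced <- attach_signatures(model, extra, mode = "replace")
  expect_identical(inferable_nodes(replaced), "p(HGNC:Y)")

  none <- attach_signatures(model, model$signatures[0, ], mode = "replace")
  expect_identical(length(inferable_nodes(none)), 0L)

  expect_error(
    attach_signatures(model, tibble::tibble(node = "p(HGNC:NOPE)",
                                            gene = "G", sign = 1L)),
    class = "cbn_unknown_node"
  )
})

test_that("network_stats reports simulator bookkeeping", {
  sim <- simulate_model(sim_params(n_backbone = 10, n_genes_per_node = 5, seed = 2))
  s <- network_stats(sim$model)
  expect_identical(s$n_backbone, 10L)
  expect_lte(s$n_downstream, 50L)
  expect_identical(s$n_inferable, 10L)
  expect_identical(nrow(sim$model$signatures), 50L)
})
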