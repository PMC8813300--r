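#' Simulation parameters
#'
#' Defaults describe a small but realistic curated-network world: 10
#' backbone entities, 20 downstream transcripts per node, activation-
#' dominated curation (30% negative signs), a sparse backbone
#' (`edge_density` 0.15), true activities of 2 log2 units on half the
#' nodes, per-gene noise of 0.5 log2 units, and 500 background genes that
#' belong to no node — emulating the bulk of an expression array that a
#' focused pathway model does not explain.
#'
#' @param n_backbone number of backbone nodes.
#' @param n_genes_per_node downstream transcripts per backbone node (single
#'   value or length-2 range sampled uniformly per node).
#' @param edge_density probability of a causal edge between an ordered pair
#'   of backbone nodes.
#' @param frac_negative fraction of -1 signs among backbone edges and
#'   signature entries.
#' @param active_nodes optional named numeric vector of true amplitudes
#'   (log2 units) keyed by node id; by default every other backbone node is
#'   active with amplitude `effect`, alternating sign.
#' @param effect default absolute true amplitude used when `active_nodes`
#'   is not given.
#' @param noise_sd standard deviation of additive Gaussian noise on gene
#'   log2 fold changes.
#' @param noise_df degrees of freedom for optional Student-t noise
#'   (`Inf`, the default, means Gaussian) — for stress-testing calibration
#'   under heavy tails.
#' @param n_background_genes genes unattached to any node.
#' @param overlap_frac fraction of each node's signature genes drawn from
#'   genes already assigned to earlier nodes (default 0: non-overlapping
#'   signatures).
#' @param seed integer seed; everything the generator emits is a pure
#'   function of the parameters.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(n_backbone = 10L, n_genes_per_node = 20L,
                       edge_density = 0.15, frac_negative = 0.3,
                       active_nodes = NULL, effect = 2,
                       noise_sd = 0.5, noise_df = Inf,
                       n_background_genes = 500L, overlap_frac = 0,
                       seed = 1L) {
  stopifnot(n_backbone >= 0, all(n_genes_per_node >= 1),
            edge_density >= 0, edge_density <= 1,
            frac_negative >= 0, frac_negative <= 1,
            noise_sd >= 0, n_background_genes >= 0,
            overlap_frac >= 0, overlap_frac < 1)
  structure(
    list(n_backbone = as.integer(n_backbone),
         n_genes_per_node = as.integer(n_genes_per_node),
         edge_density = edge_density, frac_negative = frac_negative,
         active_nodes = active_nodes, effect = effect,
         noise_sd = noise_sd, noise_df = noise_df,
         n_background_genes = as.integer(n_background_genes),
         overlap_frac = overlap_frac, seed = as.integer(seed)),
    class = "sim_params"
  )
}

# backbone term templates: the eight non-transcript vocabulary functions,
# cycled so fixtures exercise the whole grammar (r() appears on every
# downstream node)
backbone_term_text <- function(i) {
  label <- sprintf("NB%02d", i)
  templates <- c(
    sprintf("p(HGNC:%s)", label),
    sprintf("act(p(HGNC:%s))", label),
    sprintf('complex(SCOMP:"%s Complex")', label),
    sprintf('bp(GOBP:"%s process")', label),
    sprintf('a(CHEBI:"%s compound")', label),
    sprintf("path(MESHD:%s)", label),
    sprintf("m(HGNC:MIR%s)", label),
    sprintf("sec(p(HGNC:%s))", label)
  )
  templates[((i - 1) %% length(templates)) + 1]
}

#' Simulate a two-layer causal network with known ground truth
#'
#' Generates `n_backbone` backbone nodes (terms cycle through the
#' non-transcript vocabulary functions), random signed backbone edges at
#' `edge_density`, and a downstream `r()` transcript layer with signs
#' negative at rate `frac_negative`. The companion ground-truth record
#' holds each node's true amplitude and every gene's `(node, sign)`
#' assignment.
#'
#' @param params a [sim_params()] list.
#' @return a list with elements `model` (a `layered_model`) and `truth`
#'   (list: `true_amplitudes` named numeric, `gene_assignments` tibble
#'   `gene`, `node`, `sign`).
#' @export
simulate_model <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(params$seed, simulate_model_impl(params))
}

simulate_model_impl <- function(params) {
  nb <- params$n_backbone
  backbone_ids <- vapply(seq_len(nb), backbone_term_text, character(1))
  statements <- list()
  add <- function(subject, rel, object, species = "human", citation = "SYN") {
    statements[[length(statements) + 1L]] <<- tibble::tibble(
      line = length(statements) + 1L, subject = subject, relationship = rel,
      object = object, sign = unname(bel_relationships[rel]),
      citation = citation, species = species,
      tissue = NA_character_, evidence = NA_character_,
      subject_term = list(parse_term(subject)),
      object_term = list(parse_term(object))
    )
  }
  # backbone edges
  for (i in seq_len(nb)) {
    for (j in seq_len(nb)) {
      if (i == j) next
      if (stats::runif(1) < params$edge_density) {
        rel <- if (stats::runif(1) < params$frac_negative) "decreases" else "increases"
        add(backbone_ids[i], rel, backbone_ids[j])
      }
    }
  }
  # downstream transcript layer
  gene_counter <- 0L
  assignments <- list()
  for (i in seq_len(nb)) {
    k <- if (length(params$n_genes_per_node) == 2) {
      sample(seq(params$n_genes_per_node[1], params$n_genes_per_node[2]), 1)
    } else {
      params$n_genes_per_node
    }
    n_shared <- if (params$overlap_frac > 0 && length(assignments)) {
      min(floor(k * params$overlap_frac),
          length(unique(dplyr::bind_rows(assignments)$gene)))
    } else 0L
    pool <- if (n_shared > 0) {
      sample(unique(dplyr::bind_rows(assignments)$gene), n_shared)
    } else character()
    fresh <- sprintf("G%04d", gene_counter + seq_len(k - n_shared))
    gene_counter <- gene_counter + k - n_shared
    genes <- c(fresh, pool)
    signs <- ifelse(stats::runif(k) < params$frac_negative, -1L, 1L)
    for (g in seq_along(genes)) {
      rel <- if (signs[g] == -1L) "decreases" else "increases"
      add(backbone_ids[i], rel, sprintf("r(HGNC:%s)", genes[g]))
      assignments[[length(assignments) + 1L]] <- tibble::tibble(
        gene = genes[g], node = backbone_ids[i], sign = signs[g])
    }
  }
  stmts <- if (length(statements)) dplyr::bind_rows(statements) else empty_statements()
  model <- split_layers(assemble(stmts, species = "human"))
  true_amps <- if (!is.null(params$active_nodes)) {
    amps <- stats::setNames(rep(0, nb), backbone_ids)
    amps[names(params$active_nodes)] <- params$active_nodes
    amps
  } else {
    amps <- rep(0, nb)
    active <- if (nb > 0) seq(1, nb, by = 2) else integer()
    amps[active] <- params$effect * rep_len(c(1, -1), length(active))
    stats::setNames(amps, backbone_ids)
  }
  truth <- list(
    true_amplitudes = true_amps,
    gene_assignments = if (length(assignments)) dplyr::bind_rows(assignments)
      else tibble::tibble(gene = character(), node = character(), sign = integer())
  )
  list(model = model, truth = truth)
}

#' Simulate an expression contrast from true node activities
#'
#' Each gene assigned to node `j` with sign `s` gets
#' `log2fc = s * amplitude_j + noise`; background genes are pure noise.
#' Noise is Gaussian with sd `noise_sd` (Student-t scaled to that sd when
#' `noise_df` is finite). Genes shared by several nodes (overlapping
#' signatures) sum their contributions.
#'
#' @param model a `layered_model` from [simulate_model()].
#' @param truth the matching ground-truth record.
#' @param params the [sim_params()] used for the model.
#' @param seed optional seed for this contrast; defaults to a fixed offset
#'   of `params$seed` so that model and contrast draws do not alias. Vary
#'   it to draw replicate contrasts from the same model.
#' @param label contrast label.
#' @return an `expression_contrast` tibble.
#' @export
simulate_contrast <- function(model, truth, params = sim_params(),
                              seed = NULL, label = "simulated") {
  stopifnot(inherits(model, "layered_model"))
  if (is.null(seed)) seed <- (params$seed + 77003L) %% 2147483647L
  withr::with_seed(seed, {
    assigned <- truth$gene_assignments |>
      dplyr::mutate(amplitude = unname(truth$true_amplitudes[.data$node])) |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(mu = sum(.data$sign * .data$amplitude), .groups = "drop")
    background <- if (params$n_background_genes > 0) {
      tibble::tibble(gene = sprintf("BG%04d", seq_len(params$n_background_genes)),
                     mu = 0)
    } else {
      tibble::tibble(gene = character(), mu = double())
    }
    all_genes <- dplyr::bind_rows(assigned, background)
    noise <- if (is.finite(params$noise_df)) {
      scale <- params$noise_sd / sqrt(params$noise_df / (params$noise_df - 2))
      stats::rt(nrow(all_genes), df = params$noise_df) * scale
    } else {
      stats::rnorm(nrow(all_genes), sd = params$noise_sd)
    }
    as_contrast(
      tibble::tibble(gene = all_genes$gene, log2fc = all_genes$mu + noise),
      label = label
    )
  })
}

#' Write a self-contained fixture suite
#'
#' Emits, under `dir`: `network.bel` (the simulated model as BEL
#' statements, including MGI-namespaced duplicate transcripts and one
#' contradictory statement pair to exercise orthologization and
#' contradiction handling), `orthologs.tsv`, `signatures.tsv` (the model's
#' derived signatures in external-table form), `contrast.tsv` (a simulated
#' contrast) and `truth.json` (ground truth plus the generating
#' parameters). All files are plain text and byte-identical across runs
#' with equal parameters.
#'
#' @param dir output directory (created if missing).
#' @param params a [sim_params()] list.
#' @return invisibly, a list with `files` (named paths), `model`, `truth`
#'   and `contrast`.
#' @export
write_fixture_suite <- function(dir, params = sim_params()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_model(params)
  contrast <- simulate_contrast(sim$model, sim$truth, params)

  nodes <- sim$model$network$nodes
  edges <- sim$model$network$edges
  lines <- c("# synthetic two-layer causal network fixture",
             'SET Citation = "SYN"', 'SET Species = "human"')
  rel_of <- function(sign) unname(sign_relation[as.character(sign)])
  for (i in seq_len(nrow(edges))) {
    lines <- c(lines, sprintf("%s %s %s", edges$source[i],
                              rel_of(edges$sign[i]), edges$target[i]))
  }
  # mouse-namespaced duplicates of up to three downstream transcripts: after
  # orthologization these merge back onto their HGNC twins
  sig <- sim$model$signatures
  ortho_rows <- character()
  if (nrow(sig) >= 1) {
    dup <- utils::head(sig, 3)
    lines <- c(lines, 'SET Species = "mouse"')
    for (i in seq_len(nrow(dup))) {
      mouse_sym <- paste0("m", dup$gene[i])
      lines <- c(lines, sprintf("%s %s r(MGI:%s)", dup$node[i],
                                rel_of(dup$sign[i]), mouse_sym))
      ortho_rows <- c(ortho_rows, sprintf("MGI\t%s\t%s", mouse_sym, dup$gene[i]))
    }
  }
  # one contradictory pair between the first two backbone nodes
  backbone <- nodes$id[nodes$layer == "backbone"]
  if (length(backbone) >= 2) {
    lines <- c(lines, 'SET Species = "human"',
               sprintf("%s increases %s", backbone[1], backbone[2]),
               sprintf("%s decreases %s", backbone[1], backbone[2]))
  }
  files <- c(
    bel = file.path(dir, "network.bel"),
    orthologs = file.path(dir, "orthologs.tsv"),
    signatures = file.path(dir, "signatures.tsv"),
    contrast = file.path(dir, "contrast.tsv"),
    truth = file.path(dir, "truth.json")
  )
  writeLines(lines, files[["bel"]], useBytes = TRUE)
  writeLines(c("source_namespace\tsource_symbol\ttarget_symbol", ortho_rows),
             files[["orthologs"]], useBytes = TRUE)
  writeLines(
    c("node_id\tgene_symbol\tsign",
      sprintf("%s\t%s\t%d", sig$node, sig$gene, sig$sign)),
    files[["signatures"]], useBytes = TRUE)
  writeLines(
    c("gene\tlog2fc", sprintf("%s\t%.6f", contrast$gene, contrast$log2fc)),
    files[["contrast"]], useBytes = TRUE)
  jsonlite::write_json(
    list(true_amplitudes = as.list(sim$truth$true_amplitudes),
         gene_assignments = sim$truth$gene_assignments,
         params = unclass(params)[setdiff(names(params), "active_nodes")]),
    files[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(files = files, model = sim$model, truth = sim$truth,
                 contrast = contrast))
}
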