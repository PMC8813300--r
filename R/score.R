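#' Scoring configuration
#'
#' Controls node-activity inference. `min_downstream` guards against
#' noise-dominated amplitudes over 1-2 genes (set to 1 to score every
#' inferable node); the permutation count trades p-value resolution for run
#' time; `exhaustive = TRUE` replaces Monte-Carlo sampling by complete
#' enumeration of ordered gene draws (only sensible for small universes).
#'
#' @param min_downstream minimum number of signature genes measured in the
#'   contrast for a node to be scored (default 3).
#' @param n_permutations number of Monte-Carlo permutations (>= 100,
#'   default 2000).
#' @param alpha significance level in (0, 1), default 0.05.
#' @param seed integer seed driving all permutation draws. Each node's
#'   generator is derived from `seed` plus a hash of the node id, so no
#'   node's p-value depends on the order in which nodes are scored.
#' @param adjust multiple-testing adjustment across scored nodes: `"BH"`
#'   (Benjamini-Hochberg, default) or `"none"`.
#' @param exhaustive enumerate all ordered draws instead of sampling.
#' @return a list of class `scoring_config`.
#' @export
scoring_config <- function(min_downstream = 3L, n_permutations = 2000L,
                           alpha = 0.05, seed = 1L,
                           adjust = c("BH", "none"), exhaustive = FALSE) {
  adjust <- match.arg(adjust)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    rlang::abort("`alpha` must be in (0, 1)", class = "cbn_error")
  }
  if (!is.numeric(n_permutations) || n_permutations < 100) {
    rlang::abort("`n_permutations` must be >= 100", class = "cbn_error")
  }
  if (!is.numeric(min_downstream) || min_downstream < 1) {
    rlang::abort("`min_downstream` must be a positive integer", class = "cbn_error")
  }
  structure(
    list(min_downstream = as.integer(min_downstream),
         n_permutations = as.integer(n_permutations),
         alpha = alpha, seed = as.integer(seed), adjust = adjust,
         exhaustive = isTRUE(exhaustive)),
    class = "scoring_config"
  )
}

# deterministic 31-bit hash of a node id, mixed with the run seed so that
# per-node RNG streams are independent of scoring order
node_seed <- function(seed, node) {
  codes <- utf8ToInt(node)
  h <- 0
  m <- 2147483647 # 2^31 - 1
  for (code in codes) h <- (h * 31 + code) %% m
  as.integer((h + as.numeric(seed)) %% m)
}

# measured signature of one node: its signature genes joined to the contrast
measured_signature <- function(node, model, contrast) {
  sig <- dplyr::filter(model$signatures, .data$node == !!node)
  if (nrow(sig) == 0) {
    rlang::abort(sprintf("node %s has no downstream signature (not inferable)", node),
                 class = c("cbn_not_inferable", "cbn_error"))
  }
  dplyr::inner_join(sig, contrast, by = "gene")
}

amplitude_stat <- function(signs, log2fc) mean(signs * log2fc)

#' Score one backbone node against a contrast
#'
#' The node's inferred amplitude is the mean of signed log2 fold changes
#' over its measured signature: with signature pairs (g, s_g) and contrast
#' values beta_g, `amplitude = mean(s_g * beta_g)`. No fold-change or
#' p-value threshold is applied to the contrast (the inference is
#' threshold-free); signature genes absent from the contrast are dropped,
#' not imputed as zero. Significance comes from a gene-sampling permutation
#' null (see [permutation_p()]).
#'
#' @param node a backbone node id.
#' @param model a `layered_model`.
#' @param contrast an `expression_contrast`.
#' @param config a [scoring_config()].
#' @param p_value compute the permutation p-value (default `TRUE`); when
#'   `FALSE` only the amplitude is returned, which is much faster for
#'   simulation studies of the estimator itself.
#' @return a one-row tibble: `node`, `n_genes`, `amplitude`, `p_value`,
#'   `direction`, `significant` (direction/significance use the unadjusted
#'   p at `config$alpha`; [score_all()] applies the configured adjustment).
#' @export
score_node <- function(node, model, contrast, config = scoring_config(),
                       p_value = TRUE) {
  d <- measured_signature(node, model, contrast)
  if (nrow(d) < config$min_downstream) {
    rlang::abort(
      sprintf("node %s: %d signature gene(s) measured, need >= %d",
              node, nrow(d), config$min_downstream),
      class = c("cbn_insufficient_coverage", "cbn_error"),
      n_genes = nrow(d))
  }
  amplitude <- amplitude_stat(d$sign, d$log2fc)
  p <- if (p_value) permutation_p(node, model, contrast, config) else NA_real_
  significant <- !is.na(p) && p <= config$alpha
  tibble::tibble(
    node = node, n_genes = nrow(d), amplitude = amplitude, p_value = p,
    direction = score_direction(amplitude, significant),
    significant = significant
  )
}

score_direction <- function(amplitude, significant) {
  dplyr::case_when(
    significant & amplitude > 0 ~ "up",
    significant & amplitude < 0 ~ "down",
    .default = "none"
  )
}

#' Permutation p-value for a node score
#'
#' The null distribution is built by repeatedly drawing `|D|` genes
#' uniformly without replacement from the full contrast universe, assigning
#' them the node's signature signs in draw order, and recomputing the
#' amplitude. The p-value is the two-sided tail `P(|null| >= |observed|)`
#' with add-one correction `(1 + k) / (1 + n_permutations)`; ties count
#' toward the tail. In exhaustive mode all ordered draws are enumerated and
#' the exact tail fraction is returned (no add-one correction needed — the
#' observed assignment is itself one of the draws).
#'
#' @inheritParams score_node
#' @return a p-value in (0, 1].
#' @export
permutation_p <- function(node, model, contrast, config = scoring_config()) {
  d <- measured_signature(node, model, contrast)
  beta <- contrast$log2fc
  n <- length(beta)
  k <- nrow(d)
  if (n <= k) {
    rlang::abort(sprintf(
      "node %s: contrast universe (%d genes) must exceed signature size (%d)",
      node, n, k),
      class = c("cbn_universe_too_small", "cbn_error"))
  }
  observed <- amplitude_stat(d$sign, d$log2fc)
  if (config$exhaustive) {
    null <- exhaustive_null(d$sign, beta)
    return(mean(tail_hits(null, observed)))
  }
  null <- mc_null(d$sign, beta, config$n_permutations,
                  node_seed(config$seed, node))
  (1 + sum(tail_hits(null, observed))) / (1 + config$n_permutations)
}

# tie-robust two-sided tail comparison
tail_hits <- function(null, observed) {
  signif(abs(null), 12) >= signif(abs(observed), 12)
}

mc_null <- function(signs, beta, n_draws, seed) {
  k <- length(signs)
  n <- length(beta)
  idx <- withr::with_seed(
    seed,
    vapply(seq_len(n_draws), function(i) sample.int(n, k), integer(k))
  )
  drawn <- matrix(beta[idx], nrow = k)
  as.vector(crossprod(signs, drawn)) / k
}

# all ordered draws of length(signs) indices from the universe
exhaustive_null <- function(signs, beta) {
  n <- length(beta)
  k <- length(signs)
  idx <- ordered_draws(n, k)
  drawn <- matrix(beta[t(idx)], nrow = k)
  as.vector(crossprod(signs, drawn)) / k
}

ordered_draws <- function(n, k) {
  if (k == 1) return(matrix(seq_len(n), ncol = 1))
  sub <- ordered_draws(n, k - 1)
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    keep <- rowSums(sub == i) == 0
    cbind(i, sub[keep, , drop = FALSE])
  }))
  unname(out)
}

#' Score every inferable node of a model against a contrast
#'
#' Applies [score_node()] to each inferable node with sufficient signature
#' coverage, adjusts p-values across the scored nodes per
#' `config$adjust`, and flags significance at `config$alpha` on the
#' adjusted scale. Nodes that cannot be scored are reported in the
#' `unscored` attribute with a reason, mirroring backbone nodes left out of
#' model scoring because their downstream layer is unpopulated.
#'
#' @inheritParams score_node
#' @param model a `layered_model`.
#' @return a tibble of class `cbn_scores` with columns `node`, `n_genes`,
#'   `amplitude`, `p_value`, `p_adjusted`, `direction`, `significant`;
#'   attributes `config`, `contrast` (label) and `unscored` (tibble
#'   `node`, `reason`).
#' @export
score_all <- function(model, contrast, config = scoring_config()) {
  stopifnot(inherits(model, "layered_model"))
  if (!inherits(contrast, "expression_contrast")) contrast <- as_contrast(contrast)
  if (nrow(contrast) == 0) {
    rlang::abort("contrast is empty", class = c("cbn_empty_contrast", "cbn_error"))
  }
  nodes <- inferable_nodes(model)
  scored <- list()
  unscored <- list()
  for (nd in nodes) {
    res <- tryCatch(
      score_node(nd, model, contrast, config),
      cbn_insufficient_coverage = function(cnd) cnd,
      cbn_universe_too_small = function(cnd) cnd
    )
    if (rlang::is_condition(res)) {
      reason <- if (inherits(res, "cbn_insufficient_coverage"))
        "insufficient_coverage" else "universe_too_small"
      unscored[[length(unscored) + 1L]] <-
        tibble::tibble(node = nd, reason = reason,
                       n_genes = res$n_genes %||% NA_integer_)
    } else {
      scored[[length(scored) + 1L]] <- res
    }
  }
  out <- if (length(scored)) dplyr::bind_rows(scored) else tibble::tibble(
    node = character(), n_genes = integer(), amplitude = double(),
    p_value = double(), direction = character(), significant = logical()
  )
  out$p_adjusted <- if (config$adjust == "BH") {
    stats::p.adjust(out$p_value, method = "BH")
  } else {
    out$p_value
  }
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted <= config$alpha
  out$direction <- score_direction(out$amplitude, out$significant)
  out <- out[, c("node", "n_genes", "amplitude", "p_value", "p_adjusted",
                 "direction", "significant")]
  structure(
    out,
    class = c("cbn_scores", class(tibble::tibble())),
    config = config,
    contrast = contrast_label(contrast),
    unscored = if (length(unscored)) dplyr::bind_rows(unscored) else
      tibble::tibble(node = character(), reason = character(),
                     n_genes = integer())
  )
}

#' @export
print.cbn_scores <- function(x, ...) {
  cat(sprintf("# iNode scores for contrast '%s': %d scored, %d significant, %d unscored\n",
              attr(x, "contrast"), nrow(x), sum(x$significant),
              nrow(attr(x, "unscored"))))
  NextMethod()
}

#' Compare two score sets node by node
#'
#' Joins two scorings (e.g. two diseases scored on the same model) on node
#' id and classifies each node's agreement — the workflow behind
#' disease-contrast comparisons in which a handful of upstream regulators
#' carry opposite inferred scores.
#'
#' @param results_a,results_b `cbn_scores` tibbles from [score_all()].
#' @param labels length-2 character, names for the two result sets.
#' @return a tibble with both scorings' amplitude/direction/significance
#'   columns (suffixed by label) and an `agreement` column in
#'   `{"same-direction", "opposite-direction", "discordant-significance",
#'   "neither-significant", "not-comparable"}`.
#' @export
compare_scores <- function(results_a, results_b, labels = c("a", "b")) {
  stopifnot(length(labels) == 2)
  cols <- c("node", "amplitude", "p_adjusted", "direction", "significant")
  a <- tibble::as_tibble(results_a)[cols]
  b <- tibble::as_tibble(results_b)[cols]
  joined <- dplyr::full_join(a, b, by = "node",
                             suffix = paste0("_", labels))
  sig_a <- joined[[paste0("significant_", labels[1])]]
  sig_b <- joined[[paste0("significant_", labels[2])]]
  amp_a <- joined[[paste0("amplitude_", labels[1])]]
  amp_b <- joined[[paste0("amplitude_", labels[2])]]
  joined$agreement <- dplyr::case_when(
    is.na(sig_a) | is.na(sig_b) ~ "not-comparable",
    sig_a & sig_b & sign(amp_a) == sign(amp_b) ~ "same-direction",
    sig_a & sig_b ~ "opposite-direction",
    xor(sig_a, sig_b) ~ "discordant-significance",
    .default = "neither-significant"
  )
  dplyr::arrange(joined, .data$node)
}
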