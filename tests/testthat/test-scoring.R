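test_that("amplitude is the mean of signed log2 fold changes", {
  model <- tiny_model() # X regulates G1 (+), G2 (+), G3 (-)
  contrast <- tiny_contrast(c(G1 = 2.0, G2 = 1.0, G3 = -1.0, B1 = 0, B2 = 0))
  res <- score_node("p(HGNC:X)", model, contrast,
                    scoring_config(n_permutations = 100, seed = 1),
                    p_value = FALSE)
  expect_equal(res$amplitude, (2.0 + 1.0 + 1.0) / 3)
  expect_identical(res$n_genes, 3L)

  # all-zero contrast values give amplitude 0 and direction none
  zero <- tiny_contrast(c(G1 = 0, G2 = 0, G3 = 0, B1 = 0, B2 = 0))
  res0 <- score_node("p(HGNC:X)", model, zero,
                     scoring_config(n_permutations = 100, seed = 1))
  expect_identical(res0$amplitude, 0)
  expect_identical(res0$direction, "none")
  expect_equal(res0$p_value, 1, tolerance = 0.05)
})

test_that("coverage and inferability guards fire", {
  model <- tiny_model()
  expect_error(score_node("p(HGNC:Y)", model, tiny_contrast()),
               class = "cbn_not_inferable")
  # only 2 of 3 signature genes measured, min_downstream 3
  partial <- as_contrast(tibble::tibble(gene = c("G1", "G2", "B1", "B2"),
                                        log2fc = c(1, 1, 0, 0)))
  expect_error(score_node("p(HGNC:X)", model, partial),
               class = "cbn_insufficient_coverage")
  # scoreable at min_downstream 1 (missing genes dropped, not imputed)
  res <- score_node("p(HGNC:X)", model, partial,
                    scoring_config(min_downstream = 1, n_permutations = 100),
                    p_value = FALSE)
  expect_identical(res$n_genes, 2L)
  expect_equal(res$amplitude, 1)
  # universe must exceed signature size
  tiny_universe <- as_contrast(tibble::tibble(gene = c("G1", "G2", "G3"),
                                              log2fc = c(1, 1, 1)))
  expect_error(permutation_p("p(HGNC:X)", model, tiny_universe),
               class = "cbn_universe_too_small")
})

test_that("config validation rejects bad parameters", {
  expect_error(scoring_config(alpha = 0), "alpha")
  expect_error(scoring_config(alpha = 1.2), "alpha")
  expect_error(scoring_config(n_permutations = 50), "n_permutations")
  expect_error(scoring_config(min_downstream = 0), "min_downstream")
})

test_that("exhaustive permutation p matches an independent brute-force oracle", {
  # universe of 5 genes, signature of 2: all 20 ordered draws
  beta <- c(G1 = 2.0, G2 = 1.0, G3 = -1.0, G4 = 0.5, G5 = 0.0)
  contrast <- as_contrast(tibble::tibble(gene = names(beta), log2fc = unname(beta)))
  cases <- list(c(1L, 1L), c(1L, -1L), c(-1L, -1L))
  for (signs in cases) {
    model <- signature_model(c("G1", "G2"), signs)
    p_exh <- permutation_p("p(HGNC:X)", model, contrast,
                           scoring_config(exhaustive = TRUE))
    # independent oracle: explicit double loop over ordered index pairs
    b <- contrast$log2fc
    obs <- mean(signs * b[match(c("G1", "G2"), contrast$gene)])
    null <- c()
    for (i in seq_along(b)) for (j in seq_along(b)) {
      if (i != j) null <- c(null, (signs[1] * b[i] + signs[2] * b[j]) / 2)
    }
    expect_identical(length(null), 20L)
    expect_equal(p_exh, mean(abs(null) >= abs(obs) - 1e-12))
  }
  # frozen value for the ++ signature: only the draws {G1,G2} reach |1.5|
  model <- signature_model(c("G1", "G2"), c(1L, 1L))
  expect_equal(
    permutation_p("p(HGNC:X)", model, contrast, scoring_config(exhaustive = TRUE)),
    2 / 20
  )
})

test_that("Monte-Carlo p is deterministic given seed and order-independent", {
  model <- tiny_model()
  contrast <- tiny_contrast()
  cfg <- scoring_config(n_permutations = 300, seed = 42)
  p1 <- permutation_p("p(HGNC:X)", model, contrast, cfg)
  p2 <- permutation_p("p(HGNC:X)", model, contrast, cfg)
  expect_identical(p1, p2)
  # the same node scored inside score_all gets the same p
  all_scores <- score_all(model, contrast, cfg)
  expect_identical(all_scores$p_value[all_scores$node == "p(HGNC:X)"], p1)
})

test_that("sign-flip and positive-scaling equivariance hold", {
  withr::with_seed(8, {
    for (rep in 1:3) {
      p <- sim_params(n_backbone = 5, n_genes_per_node = 6,
                      n_background_genes = 40, seed = sample.int(1000, 1))
      sim <- simulate_model(p)
      contrast <- simulate_contrast(sim$model, sim$truth, p)
      cfg <- scoring_config(n_permutations = 200, seed = 7, min_downstream = 1)
      base <- score_all(sim$model, contrast, cfg)

      flipped <- as_contrast(tibble::tibble(gene = contrast$gene,
                                            log2fc = -contrast$log2fc))
      neg <- score_all(sim$model, flipped, cfg)
      expect_equal(neg$amplitude, -base$amplitude)
      expect_equal(neg$p_value, base$p_value)

      scaled <- as_contrast(tibble::tibble(gene = contrast$gene,
                                           log2fc = 2.5 * contrast$log2fc))
      sc <- score_all(sim$model, scaled, cfg)
      expect_equal(sc$amplitude, 2.5 * base$amplitude)
      expect_equal(sc$p_value, base$p_value)
    }
  })
})

test_that("score_all separates scored and unscored nodes and adjusts p-values", {
  model <- tiny_model()
  model <- attach_signatures(
    model, tibble::tibble(node = "p(HGNC:Y)", gene = c("H1", "H2"), sign = 1L))
  # H1/H2 unmeasured: Y lacks coverage, X scored
  contrast <- tiny_contrast()
  res <- score_all(model, contrast, scoring_config(n_permutations = 100, seed = 1))
  expect_identical(nrow(res), 1L)
  un <- attr(res, "unscored")
  expect_identical(un$node, "p(HGNC:Y)")
  expect_identical(un$reason, "insufficient_coverage")
  # BH adjustment across scored nodes
  expect_true(all(res$p_adjusted >= res$p_value))
  # direction is up iff amplitude > 0 and significant
  expect_identical(res$direction,
                   ifelse(res$significant & res$amplitude > 0, "up",
                          ifelse(res$significant & res$amplitude < 0, "down", "none")))
  # no signature overlap at all -> everything unscored
  foreign <- as_contrast(tibble::tibble(gene = c("Z1", "Z2", "Z3", "Z4"),
                                        log2fc = c(1, 2, 3, 4)))
  res2 <- score_all(model, foreign, scoring_config(n_permutations = 100))
  expect_identical(nrow(res2), 0L)
  expect_identical(nrow(attr(res2, "unscored")), 2L)
  # empty contrast errors
  expect_error(score_all(model, tiny_contrast()[0, ]),
               class = "cbn_empty_contrast")
})

test_that("duplicate gene measurements collapse deterministically", {
  dup <- tibble::tibble(gene = c("G1", "G1", "G2"), log2fc = c(1, -3, 2))
  expect_identical(as_contrast(dup)$log2fc[1], -3) # max-abs keeps -3
  expect_identical(as_contrast(dup, collapse = "mean")$log2fc[1], -1)
  expect_warning(as_contrast(tibble::tibble(gene = "G1", log2fc = NA_real_)),
                 "non-finite")
})

test_that("compare_scores classifies node agreement", {
  mk <- function(nodes, amp, sig) {
    tibble::tibble(node = nodes, n_genes = 5L, amplitude = amp,
                   p_value = ifelse(sig, 0.001, 0.5),
                   p_adjusted = ifelse(sig, 0.002, 0.6),
                   direction = ifelse(!sig, "none", ifelse(amp > 0, "up", "down")),
                   significant = sig)
  }
  a <- mk(c("N1", "N2", "N3", "N4"), c(1, 2, -1, 0.5), c(TRUE, TRUE, TRUE, FALSE))
  b <- mk(c("N1", "N2", "N3", "N5"), c(-1, 2.5, -2, 1), c(TRUE, TRUE, FALSE, TRUE))
  cmp <- compare_scores(a, b)
  got <- setNames(cmp$agreement, cmp$node)
  expect_identical(got[["N1"]], "opposite-direction")
  expect_identical(got[["N2"]], "same-direction")
  expect_identical(got[["N3"]], "discordant-significance")
  expect_identical(got[["N4"]], "not-comparable")
  expect_identical(got[["N5"]], "not-comparable")
  # identical inputs: nothing opposite
  self <- compare_scores(a, a)
  expect_false(any(self$agreement == "opposite-direction"))
})
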