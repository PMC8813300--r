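#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a causal network into an edge table
#'
#' @param x a `causal_network`.
#' @param ... unused.
#' @return a tibble with one row per edge: `source`, `target`, `sign`,
#'   `relation`, `n_evidence`.
#' @method tidy causal_network
#' @export
tidy.causal_network <- function(x, ...) {
  tibble::tibble(
    source = x$edges$source,
    target = x$edges$target,
    sign = x$edges$sign,
    relation = unname(sign_relation[as.character(x$edges$sign)]),
    n_evidence = purrr::map_int(x$edges$evidence, nrow)
  )
}

#' @rdname tidy.causal_network
#' @method glance causal_network
#' @export
glance.causal_network <- function(x, ...) network_stats(x)

#' Tidy a layered model into its signature table
#'
#' @param x a `layered_model`.
#' @param ... unused.
#' @return the signature tibble (`node`, `gene`, `sign`).
#' @method tidy layered_model
#' @export
tidy.layered_model <- function(x, ...) x$signatures

#' @rdname tidy.layered_model
#' @method glance layered_model
#' @export
glance.layered_model <- function(x, ...) network_stats(x)

#' Tidy node scores
#'
#' @param x a `cbn_scores` object from [score_all()].
#' @param ... unused.
#' @return the score tibble stripped of its class and attributes.
#' @method tidy cbn_scores
#' @export
tidy.cbn_scores <- function(x, ...) {
  out <- x
  attr(out, "config") <- NULL
  attr(out, "contrast") <- NULL
  attr(out, "unscored") <- NULL
  class(out) <- setdiff(class(out), "cbn_scores")
  tibble::as_tibble(out)
}

#' @rdname tidy.cbn_scores
#' @method glance cbn_scores
#' @export
glance.cbn_scores <- function(x, ...) {
  config <- attr(x, "config")
  tibble::tibble(
    contrast = attr(x, "contrast"),
    n_scored = nrow(x),
    n_significant = sum(x$significant),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down"),
    n_unscored = nrow(attr(x, "unscored")),
    alpha = config$alpha,
    n_permutations = config$n_permutations,
    adjust = config$adjust,
    seed = config$seed
  )
}
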