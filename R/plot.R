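#' Bar chart of inferred node activities
#'
#' Renders one bar per scored node: yellow bars for inferred upregulation,
#' blue for inferred downregulation, grey for nodes whose score did not
#' reach significance; significant nodes get a black outline. With several
#' contrasts (see [plot_node_scores()]) bars are dodged per contrast so
#' time courses and disease comparisons read side by side.
#'
#' @param object a `cbn_scores` tibble from [score_all()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cbn_scores
#' @export
autoplot.cbn_scores <- function(object, ...) {
  plot_node_scores(stats::setNames(list(object), attr(object, "contrast")))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname autoplot.cbn_scores
#' @param results a named list of `cbn_scores` (one element per contrast).
#' @export
plot_node_scores <- function(results) {
  stopifnot(is.list(results), length(results) >= 1)
  if (is.null(names(results))) {
    names(results) <- purrr::map_chr(results, \(r) attr(r, "contrast") %||% "contrast")
  }
  data <- purrr::imap_dfr(results, \(r, nm) dplyr::mutate(tidy(r), contrast = nm))
  ggplot2::ggplot(
    data,
    ggplot2::aes(x = .data$node, y = .data$amplitude,
                 fill = .data$direction, group = .data$contrast)
  ) +
    ggplot2::geom_col(
      position = ggplot2::position_dodge(width = 0.8), width = 0.7,
      ggplot2::aes(colour = .data$significant), linewidth = 0.6
    ) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(
      values = c(up = "#E6C229", down = "#2166AC", none = "grey80"),
      name = "inferred direction"
    ) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "black", `FALSE` = NA),
      name = "significant", na.value = NA
    ) +
    ggplot2::labs(x = NULL, y = "inferred fold change (log2)") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal() +
    ggplot2::facet_wrap(~contrast)
}
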