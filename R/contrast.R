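#' Build an expression contrast from a data frame
#'
#' A contrast is a per-gene table of log2 fold changes for a treatment (or
#' disease) condition versus its control — the scoring input. Gene symbols
#' must be unique after probe-to-gene collapsing; values must be finite.
#'
#' @param x a data frame with columns `gene`, `log2fc` and optionally
#'   `pvalue`.
#' @param label contrast label carried through to results.
#' @param collapse how duplicate gene measurements (multiple probes) are
#'   collapsed: `"max-abs"` (default) keeps the value of largest absolute
#'   magnitude, `"mean"` averages them.
#' @param uppercase if `TRUE`, gene symbols are uppercased before matching
#'   (useful when pairing mouse-symbol arrays with an HGNC model without an
#'   explicit ortholog map). Default `FALSE`: matching is case-sensitive.
#' @return a tibble of class `expression_contrast` with attribute `label`.
#' @export
as_contrast <- function(x, label = "contrast",
                        collapse = c("max-abs", "mean"), uppercase = FALSE) {
  collapse <- match.arg(collapse)
  if (!all(c("gene", "log2fc") %in% names(x))) {
    rlang::abort("a contrast needs columns `gene` and `log2fc`",
                 class = c("cbn_invalid_contrast", "cbn_error"))
  }
  x <- tibble::as_tibble(x)
  x$gene <- as.character(x$gene)
  if (uppercase) x$gene <- toupper(x$gene)
  if (!all(is.finite(x$log2fc))) {
    n_bad <- sum(!is.finite(x$log2fc))
    rlang::warn(sprintf("dropping %d non-finite log2fc value(s)", n_bad))
    x <- x[is.finite(x$log2fc), ]
  }
  if (anyDuplicated(x$gene)) {
    x <- if (collapse == "mean") {
      x |>
        dplyr::group_by(.data$gene) |>
        dplyr::summarise(log2fc = mean(.data$log2fc),
                         dplyr::across(dplyr::any_of("pvalue"), mean),
                         .groups = "drop")
    } else {
      x |>
        dplyr::group_by(.data$gene) |>
        dplyr::arrange(dplyr::desc(abs(.data$log2fc)), .by_group = TRUE) |>
        dplyr::slice(1) |>
        dplyr::ungroup()
    }
  }
  x <- dplyr::arrange(x, .data$gene)
  structure(x, class = c("expression_contrast", class(x)), label = label)
}

#' Read a contrast table from delimited text
#'
#' Tab- or comma-separated with a header; columns `gene`, `log2fc` and
#' optionally `pvalue`.
#'
#' @param path path to the file.
#' @param label contrast label; defaults to the file name without extension.
#' @inheritParams as_contrast
#' @return an `expression_contrast` tibble.
#' @export
read_contrast <- function(path, label = NULL,
                          collapse = c("max-abs", "mean"), uppercase = FALSE) {
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tbl <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE)
  as_contrast(tbl, label = label, collapse = collapse, uppercase = uppercase)
}

contrast_label <- function(contrast) attr(contrast, "label") %||% "contrast"
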