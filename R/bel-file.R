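#' Read a BEL statement file
#'
#' The file dialect is line-oriented UTF-8: `#` starts a comment line,
#' `SET Key = "value"` lines set an annotation (`Citation`, `Species`,
#' `Tissue`, `Evidence`) that applies to all subsequent statements until
#' changed or `UNSET Key`; every other non-blank line is one BEL statement.
#'
#' @param path path to a `.bel` file.
#' @param strict if `TRUE` (default) the first malformed line aborts with
#'   its line number; if `FALSE` malformed lines are skipped, a warning is
#'   emitted per line, and the failures are returned in the `errors`
#'   attribute of the result.
#' @return a tibble with one row per statement: columns `line`, `subject`,
#'   `relationship`, `object`, `sign`, `citation`, `species`, `tissue`,
#'   `evidence`, and list-columns `subject_term`, `object_term` holding the
#'   parsed [bel_term][parse_term()] objects. Attribute `errors` is a tibble
#'   `(line, message)` of skipped lines (empty when strict).
#' @export
read_bel <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("BEL file not found: %s", path),
                 class = c("cbn_io_error", "cbn_error"))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  parse_bel_lines(lines, strict = strict, source = path)
}

parse_bel_lines <- function(lines, strict = TRUE, source = "<text>") {
  ann <- list(Citation = NA_character_, Species = NA_character_,
              Tissue = NA_character_, Evidence = NA_character_)
  rows <- list()
  errors <- list()
  fail <- function(lineno, message) {
    if (strict) {
      rlang::abort(sprintf("%s:%d: %s", source, lineno, message),
                   class = c("cbn_bel_file_error", "cbn_error"), line = lineno)
    }
    rlang::warn(sprintf("%s:%d: skipped: %s", source, lineno, message))
    errors[[length(errors) + 1L]] <<- tibble::tibble(line = lineno, message = message)
  }
  set_rx <- "^SET\\s+([A-Za-z]+)\\s*=\\s*(.*)$"
  unset_rx <- "^UNSET\\s+([A-Za-z]+)\\s*$"
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (grepl(set_rx, line)) {
      key <- sub(set_rx, "\\1", line)
      value <- trimws(sub(set_rx, "\\2", line))
      value <- sub('^"(.*)"$', "\\1", value)
      if (!key %in% names(ann)) {
        fail(i, sprintf("unknown annotation key '%s'", key))
        next
      }
      ann[[key]] <- value
      next
    }
    if (grepl(unset_rx, line)) {
      key <- sub(unset_rx, "\\1", line)
      if (!key %in% names(ann)) {
        fail(i, sprintf("unknown annotation key '%s'", key))
        next
      }
      ann[[key]] <- NA_character_
      next
    }
    if (is.na(ann$Citation)) {
      fail(i, "statement before any SET Citation line (citation is mandatory)")
      next
    }
    stmt <- tryCatch(
      parse_statement(line, statement_annotations(
        ann$Citation, species = ann$Species %||% "other",
        tissue = ann$Tissue, evidence = ann$Evidence
      )),
      cbn_error = function(cnd) cnd
    )
    if (rlang::is_condition(stmt)) {
      fail(i, rlang::cnd_message(stmt))
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      line = i,
      subject = serialize_term(stmt$subject),
      relationship = stmt$relationship,
      object = serialize_term(stmt$object),
      sign = stmt$sign,
      citation = stmt$annotations$citation,
      species = stmt$annotations$species,
      tissue = stmt$annotations$tissue %||% NA_character_,
      evidence = stmt$annotations$evidence %||% NA_character_,
      subject_term = list(stmt$subject),
      object_term = list(stmt$object)
    )
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else empty_statements()
  attr(out, "errors") <- if (length(errors)) dplyr::bind_rows(errors) else
    tibble::tibble(line = integer(), message = character())
  out
}

empty_statements <- function() {
  tibble::tibble(
    line = integer(), subject = character(), relationship = character(),
    object = character(), sign = integer(), citation = character(),
    species = character(), tissue = character(), evidence = character(),
    subject_term = list(), object_term = list()
  )
}

#' Write statements back to the BEL file dialect
#'
#' Emits `SET` lines whenever an annotation changes between consecutive
#' statements, so `read_bel(write_bel(x))` round-trips the statement table.
#'
#' @param statements a statement tibble as returned by [read_bel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bel <- function(statements, path) {
  out <- character()
  prev <- list(Citation = NA_character_, Species = NA_character_,
               Tissue = NA_character_, Evidence = NA_character_)
  keys <- c(Citation = "citation", Species = "species",
            Tissue = "tissue", Evidence = "evidence")
  for (i in seq_len(nrow(statements))) {
    row <- statements[i, ]
    for (key in names(keys)) {
      value <- row[[keys[[key]]]]
      if (!identical(value, prev[[key]])) {
        if (is.na(value)) {
          out <- c(out, sprintf("UNSET %s", key))
        } else {
          out <- c(out, sprintf('SET %s = "%s"', key, value))
        }
        prev[[key]] <- value
      }
    }
    out <- c(out, sprintf("%s %s %s", row$subject, row$relationship, row$object))
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
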