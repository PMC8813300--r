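#' Build a statement annotation record
#'
#' Every curated statement carries its literature provenance: a citation
#' (mandatory — all statements are literature-derived), the species of the
#' experimental model, and free-text tissue and evidence fields.
#'
#' @param citation non-empty reference identifier (e.g. a PMID).
#' @param species one of `"human"`, `"mouse"`, `"rat"`, `"other"`.
#' @param tissue,evidence optional free text.
#' @return a named list of class `bel_annotations`.
#' @export
statement_annotations <- function(citation, species = "other",
                                  tissue = NA_character_,
                                  evidence = NA_character_) {
  if (!is.character(citation) || length(citation) != 1 || is.na(citation) ||
      !nzchar(trimws(citation))) {
    rlang::abort("`citation` must be a non-empty string",
                 class = c("cbn_invalid_annotation", "cbn_error"))
  }
  species <- normalize_species(species)
  structure(
    list(citation = citation, species = species,
         tissue = as.character(tissue), evidence = as.character(evidence)),
    class = "bel_annotations"
  )
}

normalize_species <- function(species) {
  s <- tolower(trimws(as.character(species)))
  if (!length(s) || is.na(s) || !nzchar(s)) return("other")
  if (s %in% c("human", "mouse", "rat")) s else "other"
}

#' Map a relationship keyword to its causal sign
#'
#' `increases`/`directlyIncreases` carry sign +1, `decreases`/
#' `directlyDecreases` sign -1, and `association` sign 0. The mapping is
#' total on the supported vocabulary and errors on anything else.
#'
#' @param kind a relationship keyword.
#' @return an integer in `{-1, 0, 1}`.
#' @export
relationship_sign <- function(kind) {
  if (!all(kind %in% names(bel_relationships))) {
    bad <- setdiff(unique(kind), names(bel_relationships))
    rlang::abort(sprintf("unknown relationship keyword: %s",
                         paste(bad, collapse = ", ")),
                 class = c("cbn_unknown_relationship", "cbn_error"))
  }
  unname(bel_relationships[kind])
}

#' Parse a BEL statement line
#'
#' A statement is `subject RELATIONSHIP object` with exactly one relationship
#' keyword at top level (outside parentheses and quotes). Subject and object
#' are parsed with [parse_term()]; a statement whose subject and object have
#' identical canonical serializations is rejected as a self-loop.
#'
#' @param text one statement line.
#' @param annotations a `bel_annotations` record, see
#'   [statement_annotations()].
#' @return a `bel_statement` with fields `subject`, `relationship`, `sign`,
#'   `object`, `annotations`.
#' @examples
#' parse_statement(
#'   'p(HGNC:TLR4) increases complex(GOCC:"NF-kappaB complex")',
#'   statement_annotations("PMID:1", species = "human")
#' )
#' @export
parse_statement <- function(text, annotations) {
  stopifnot(is.character(text), length(text) == 1)
  if (!inherits(annotations, "bel_annotations")) {
    annotations <- do.call(statement_annotations, as.list(annotations))
  }
  text <- trimws(text)
  hits <- find_top_level_relationships(text)
  if (nrow(hits) == 0) {
    rlang::abort(sprintf("no relationship keyword found in: %s", text),
                 class = c("cbn_no_relationship", "cbn_parse_error", "cbn_error"))
  }
  if (nrow(hits) > 1) {
    rlang::abort(sprintf("multiple relationship keywords (%s) in: %s",
                         paste(hits$keyword, collapse = ", "), text),
                 class = c("cbn_multiple_relationships", "cbn_parse_error", "cbn_error"))
  }
  subject_text <- substr(text, 1L, hits$start - 1L)
  object_text <- substr(text, hits$end + 1L, nchar(text))
  subject <- with_side(parse_term(subject_text), "subject")
  object <- with_side(parse_term(object_text), "object")
  if (serialize_term(subject) == serialize_term(object)) {
    rlang::abort(sprintf("self-loop statement: subject and object are both %s",
                         serialize_term(subject)),
                 class = c("cbn_self_loop", "cbn_parse_error", "cbn_error"))
  }
  structure(
    list(subject = subject, relationship = hits$keyword,
         sign = relationship_sign(hits$keyword), object = object,
         annotations = annotations),
    class = "bel_statement"
  )
}

# re-throw term errors with the statement side identified
with_side <- function(expr, side) {
  withCallingHandlers(
    expr,
    cbn_parse_error = function(cnd) {
      rlang::abort(sprintf("in %s term: %s", side, rlang::cnd_message(cnd)),
                   class = class(cnd), side = side,
                   token = cnd$token, offset = cnd$offset)
    }
  )
}

# locate relationship keywords sitting at parenthesis depth 0 outside quotes
find_top_level_relationships <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  depth <- 0L
  in_quote <- FALSE
  tokens <- list()
  tok_start <- NA_integer_
  i <- 1L
  while (i <= n + 1L) {
    ch <- if (i <= n) chars[i] else " "
    if (in_quote) {
      if (ch == "\\") i <- i + 1L else if (ch == '"') in_quote <- FALSE
    } else if (ch == '"') {
      in_quote <- TRUE
    } else if (ch == "(") {
      depth <- depth + 1L
    } else if (ch == ")") {
      depth <- max(depth - 1L, 0L)
    } else if (depth == 0L) {
      if (grepl("\\s", ch)) {
        if (!is.na(tok_start)) {
          tokens[[length(tokens) + 1L]] <- c(tok_start, i - 1L)
          tok_start <- NA_integer_
        }
      } else if (is.na(tok_start)) {
        tok_start <- i
      }
    }
    i <- i + 1L
  }
  out <- purrr::map_dfr(tokens, function(tk) {
    kw <- substr(text, tk[1], tk[2])
    if (kw %in% names(bel_relationships)) {
      tibble::tibble(keyword = kw, start = tk[1], end = tk[2])
    } else {
      tibble::tibble()
    }
  })
  out
}

#' Serialize a BEL statement to its canonical single-line form
#'
#' The canonical form is `subject relationship object` with canonical term
#' serialization on both sides; `parse_statement()` of the result (with the
#' same annotations) reproduces the statement.
#'
#' @param stmt a `bel_statement`.
#' @return a single line of text.
#' @export
serialize_statement <- function(stmt) {
  stopifnot(inherits(stmt, "bel_statement"))
  sprintf("%s %s %s", serialize_term(stmt$subject), stmt$relationship,
          serialize_term(stmt$object))
}

#' @export
format.bel_statement <- function(x, ...) serialize_statement(x)

#' @export
print.bel_statement <- function(x, ...) {
  cat("<bel_statement> ", serialize_statement(x), "\n", sep = "")
  cat("  citation: ", x$annotations$citation,
      "  species: ", x$annotations$species, "\n", sep = "")
  invisible(x)
}
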