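#' BEL vocabulary used by inflammation-type causal network models
#'
#' The parser supports a nine-function subset of BEL 1.0: seven leaf
#' functions that take a `NAMESPACE:value` argument and two wrapper
#' functions (`act`, `sec`) that take exactly one inner term.
#'
#' @format `bel_functions` is a character vector of the nine function codes;
#'   `bel_namespaces` a character vector of the fifteen namespace
#'   identifiers; `bel_relationships` a named integer vector mapping each
#'   relationship keyword to its causal sign (+1, -1, or 0 for association).
#' @name bel-vocabulary
NULL

#' @rdname bel-vocabulary
#' @export
bel_functions <- c("a", "act", "bp", "complex", "m", "p", "path", "r", "sec")

#' @rdname bel-vocabulary
#' @export
bel_wrapper_functions <- c("act", "sec")

#' @rdname bel-vocabulary
#' @export
bel_namespaces <- c(
  "HGNC", "MGI", "RGD", "SARSCOV2", "CHEBI", "SCHEM", "GOBP", "GOCC",
  "SCOMP", "SFAM", "MESHD", "PMIBP", "PMICOMP", "PMIDIS", "PMIPFAM"
)

#' @rdname bel-vocabulary
#' @export
bel_relationships <- c(
  increases = 1L, directlyIncreases = 1L,
  decreases = -1L, directlyDecreases = -1L,
  association = 0L
)

# namespaces whose values are species-scoped gene symbols, eligible for
# orthologization (human / mouse / rat)
gene_namespaces <- c(HGNC = "human", MGI = "mouse", RGD = "rat")

bare_value_rx <- "^[A-Za-z0-9_-]+$"

parse_abort <- function(class, message, token = NULL, offset = NULL) {
  rlang::abort(
    message,
    class = c(class, "cbn_parse_error", "cbn_error"),
    token = token, offset = offset
  )
}

new_bel_term <- function(fn, ns = NULL, value = NULL, inner = NULL) {
  structure(
    list(fn = fn, ns = ns, value = value, inner = inner),
    class = "bel_term"
  )
}

#' Parse a BEL term
#'
#' Parses the canonical text form `fn(NS:value)`, `fn(NS:"value")` or, for
#' the wrapper functions `act()`/`sec()`, `fn(innerterm)`. Values containing
#' any character outside `[A-Za-z0-9_-]` must be double-quoted; quotes may be
#' escaped with a backslash. Wrapper nesting is limited to one level (a
#' wrapper may not wrap another wrapper).
#'
#' @param text a single BEL term string, e.g. `'p(HGNC:NLRP3)'` or
#'   `'a(CHEBI:"calcium(2+)")'`.
#' @return a `bel_term` object with fields `fn`, and either `ns` + `value`
#'   (leaf term) or `inner` (wrapper term).
#' @examples
#' parse_term("act(p(HGNC:NLRP3))")
#' parse_term('complex(GOCC:"NF-kappaB complex")')
#' @export
parse_term <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- trimws(text)
  if (!nzchar(text)) {
    parse_abort("cbn_malformed_syntax", "empty term", offset = 1L)
  }
  st <- term_scanner(text)
  term <- scan_term(st, depth = 1L)
  if (st$pos <= st$n) {
    parse_abort(
      "cbn_malformed_syntax",
      sprintf("unexpected trailing text '%s' at offset %d",
              substr(text, st$pos, st$n), st$pos),
      token = substr(text, st$pos, st$n), offset = st$pos
    )
  }
  term
}

term_scanner <- function(text) {
  env <- new.env(parent = emptyenv())
  env$text <- text
  env$chars <- strsplit(text, "", fixed = TRUE)[[1]]
  env$n <- nchar(text)
  env$pos <- 1L
  env
}

scan_while <- function(st, rx) {
  start <- st$pos
  while (st$pos <= st$n && grepl(rx, st$chars[st$pos])) st$pos <- st$pos + 1L
  if (st$pos > start) substr(st$text, start, st$pos - 1L) else ""
}

expect_char <- function(st, ch, context) {
  if (st$pos > st$n || st$chars[st$pos] != ch) {
    found <- if (st$pos > st$n) "end of input" else sprintf("'%s'", st$chars[st$pos])
    parse_abort(
      "cbn_malformed_syntax",
      sprintf("expected '%s' %s at offset %d, found %s", ch, context, st$pos, found),
      token = if (st$pos <= st$n) st$chars[st$pos] else "", offset = st$pos
    )
  }
  st$pos <- st$pos + 1L
}

scan_term <- function(st, depth) {
  fn_start <- st$pos
  fn <- scan_while(st, "[A-Za-z]")
  if (!nzchar(fn)) {
    parse_abort("cbn_malformed_syntax",
                sprintf("expected a BEL function at offset %d", st$pos),
                offset = st$pos)
  }
  if (!fn %in% bel_functions) {
    parse_abort("cbn_unknown_function",
                sprintf("unknown BEL function '%s' at offset %d", fn, fn_start),
                token = fn, offset = fn_start)
  }
  expect_char(st, "(", sprintf("after function '%s'", fn))
  if (fn %in% bel_wrapper_functions) {
    if (depth >= 2L) {
      parse_abort("cbn_arity_violation",
                  sprintf("wrapper '%s' at offset %d: wrappers may not be nested inside wrappers",
                          fn, fn_start),
                  token = fn, offset = fn_start)
    }
    # wrapper content must itself look like a term; a NAMESPACE:value here is
    # an arity violation, not an unknown function
    probe <- st$pos
    ident <- scan_while(st, "[A-Za-z0-9]")
    nxt <- if (st$pos <= st$n) st$chars[st$pos] else ""
    if (!nzchar(ident) || nxt != "(") {
      if (nxt == ":") {
        parse_abort("cbn_arity_violation",
                    sprintf("wrapper '%s' requires an inner term, found namespace value '%s' at offset %d",
                            fn, ident, probe),
                    token = ident, offset = probe)
      }
      parse_abort("cbn_malformed_syntax",
                  sprintf("expected an inner term inside '%s' at offset %d", fn, probe),
                  token = ident, offset = probe)
    }
    st$pos <- probe
    inner <- scan_term(st, depth + 1L)
    expect_char(st, ")", sprintf("closing wrapper '%s'", fn))
    return(new_bel_term(fn, inner = inner))
  }
  ns_start <- st$pos
  ns <- scan_while(st, "[A-Za-z0-9]")
  nxt <- if (st$pos <= st$n) st$chars[st$pos] else ""
  if (nxt == "(") {
    parse_abort("cbn_arity_violation",
                sprintf("function '%s' takes a namespace value, found an inner term at offset %d",
                        fn, ns_start),
                token = ns, offset = ns_start)
  }
  if (!nzchar(ns) || nxt != ":") {
    parse_abort("cbn_malformed_syntax",
                sprintf("expected NAMESPACE:value inside '%s' at offset %d", fn, ns_start),
                token = ns, offset = ns_start)
  }
  if (!ns %in% bel_namespaces) {
    parse_abort("cbn_unknown_namespace",
                sprintf("unknown namespace '%s' at offset %d", ns, ns_start),
                token = ns, offset = ns_start)
  }
  st$pos <- st$pos + 1L # consume ':'
  value <- scan_value(st)
  expect_char(st, ")", sprintf("closing '%s'", fn))
  new_bel_term(fn, ns = ns, value = value)
}

scan_value <- function(st) {
  if (st$pos > st$n) {
    parse_abort("cbn_malformed_syntax",
                sprintf("expected an entity value at offset %d", st$pos),
                offset = st$pos)
  }
  if (st$chars[st$pos] == '"') {
    start <- st$pos
    st$pos <- st$pos + 1L
    out <- character()
    while (st$pos <= st$n) {
      ch <- st$chars[st$pos]
      if (ch == "\\" && st$pos < st$n && st$chars[st$pos + 1L] %in% c('"', "\\")) {
        out <- c(out, st$chars[st$pos + 1L])
        st$pos <- st$pos + 2L
      } else if (ch == '"') {
        st$pos <- st$pos + 1L
        value <- paste(out, collapse = "")
        if (!nzchar(value)) {
          parse_abort("cbn_malformed_syntax",
                      sprintf("empty quoted value at offset %d", start),
                      offset = start)
        }
        return(value)
      } else {
        out <- c(out, ch)
        st$pos <- st$pos + 1L
      }
    }
    parse_abort("cbn_malformed_syntax",
                sprintf("unterminated quoted value starting at offset %d", start),
                token = '"', offset = start)
  }
  start <- st$pos
  value <- scan_while(st, "[A-Za-z0-9_-]")
  if (!nzchar(value)) {
    parse_abort("cbn_malformed_syntax",
                sprintf("expected an entity value at offset %d (bare values use [A-Za-z0-9_-]; quote anything else)",
                        start),
                token = if (st$pos <= st$n) st$chars[st$pos] else "", offset = start)
  }
  value
}

#' Serialize a BEL term to its canonical text form
#'
#' The canonical form quotes a value if and only if it contains a character
#' outside `[A-Za-z0-9_-]`; `parse_term()` of the result returns an equal
#' term.
#'
#' @param term a `bel_term`.
#' @return a single string.
#' @export
serialize_term <- function(term) {
  stopifnot(inherits(term, "bel_term"))
  if (!is.null(term$inner)) {
    return(sprintf("%s(%s)", term$fn, serialize_term(term$inner)))
  }
  value <- term$value
  if (!grepl(bare_value_rx, value)) {
    value <- sprintf('"%s"', gsub('(["\\\\])', "\\\\\\1", value))
  }
  sprintf("%s(%s:%s)", term$fn, term$ns, value)
}

#' @export
format.bel_term <- function(x, ...) serialize_term(x)

#' @export
print.bel_term <- function(x, ...) {
  cat("<bel_term> ", serialize_term(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.bel_term` <- function(e1, e2) serialize_term(e1) == serialize_term(e2)

# innermost leaf of a (possibly wrapped) term
term_leaf <- function(term) {
  while (!is.null(term$inner)) term <- term$inner
  term
}

# outermost function code
term_fn <- function(term) term$fn
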