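# shared fixtures built in code

# tiny hand-written model: two backbone nodes, X with a 3-gene signature,
# Y with none (not inferable)
tiny_statements <- function() {
  lines <- c(
    'SET Citation = "PMID:1"',
    'SET Species = "human"',
    "p(HGNC:X) increases p(HGNC:Y)",
    "p(HGNC:X) increases r(HGNC:G1)",
    "p(HGNC:X) increases r(HGNC:G2)",
    "p(HGNC:X) decreases r(HGNC:G3)"
  )
  path <- withr::local_tempfile(fileext = ".bel", .local_envir = parent.frame())
  writeLines(lines, path)
  read_bel(path)
}

tiny_model <- function() split_layers(assemble(tiny_statements()))

tiny_contrast <- function(values = c(G1 = 2, G2 = 1, G3 = -1, B1 = 0.1, B2 = -0.2,
                                     B3 = 0.05, B4 = 0.3)) {
  as_contrast(tibble::tibble(gene = names(values), log2fc = unname(values)))
}

# minimal layered model holding only backbone nodes + a signature table,
# for permutation and calibration tests
signature_table_model <- function(sig) {
  ids <- unique(sig$node)
  structure(
    list(
      network = structure(
        list(nodes = tibble::tibble(
               id = ids,
               fn = "p", ns = "HGNC",
               value = sub("^p\\(HGNC:(.*)\\)$", "\\1", ids),
               term = lapply(ids, parse_term), layer = "backbone"),
             edges = tibble::tibble(source = character(), target = character(),
                                    sign = integer(), evidence = list()),
             species = "human"),
        class = "causal_network"),
      signatures = sig,
      dropped = sig[0, ],
      species = "human"
    ),
    class = "layered_model"
  )
}

signature_model <- function(genes, signs, node = "p(HGNC:X)") {
  signature_table_model(
    tibble::tibble(node = node, gene = genes, sign = as.integer(signs))
  )
}

vocab_function_examples <- c(
  'a(CHEBI:"calcium(2+)")',
  "act(p(HGNC:NLRP3))",
  "bp(GOBP:autophagy)",
  'complex(GOCC:"NLRP3 inflammasome complex")',
  "m(HGNC:MIR146A)",
  "p(HGNC:NLRP3)",
  "path(MESHD:Sepsis)",
  "r(HGNC:IL1B)",
  "sec(p(HGNC:IL18))"
)

vocab_namespace_examples <- c(
  "p(HGNC:TLR4)",
  "p(MGI:Tlr4)",
  "p(RGD:Tlr4)",
  "p(SARSCOV2:E)",
  'a(CHEBI:"nitric oxide")',
  'a(SCHEM:"Toxin B, Clostridium difficile")',
  'bp(GOBP:"mitochondrial depolarization")',
  'complex(GOCC:"NF-kappaB complex")',
  'complex(SCOMP:"CHRN Complex")',
  'act(p(SFAM:"TNFRSF Family"))',
  "path(MESHD:Inflammation)",
  "bp(PMIBP:Inflammaging)",
  'complex(PMICOMP:"pyrin inflammasome complex")',
  'path(PMIDIS:"influenza A virus infection")',
  'p(PMIPFAM:"TLR Family")'
)

# random canonical term generator for round-trip property tests
random_term <- function() {
  fn <- sample(setdiff(bel_functions, bel_wrapper_functions), 1)
  ns <- sample(bel_namespaces, 1)
  value <- if (stats::runif(1) < 0.5) {
    paste(sample(c(LETTERS, 0:9, "_", "-"), sample(1:8, 1), replace = TRUE),
          collapse = "")
  } else {
    # quoted value with awkward characters
    paste(sample(c(LETTERS, letters, " ", "(", ")", "+", ",", ":", '"', "\\"),
                 sample(2:10, 1), replace = TRUE), collapse = "")
  }
  leaf <- sprintf("%s(%s:%s)", fn, ns,
                  if (grepl("^[A-Za-z0-9_-]+$", value)) value else
                    sprintf('"%s"', gsub('(["\\\\])', "\\\\\\1", value)))
  if (stats::runif(1) < 0.3) {
    sprintf("%s(%s)", sample(bel_wrapper_functions, 1), leaf)
  } else {
    leaf
  }
}
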