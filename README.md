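# cbnet

Causal biological network (CBN) models compiled from literature-curated
causal statements, scored with transcriptomic data.

Pathway biologists curate mechanistic findings — "NF-κB drives NLRP3
transcription", "SIRT1 blocks NF-κB" — as subject–relationship–object
triples in a controlled vocabulary (a subset of the Biological Expression
Language, BEL). `cbnet` turns such statement collections into a **two-layer
signed network**: a *backbone* of biological entities (protein activities,
complexes, chemicals, processes) connected by causal edges, plus a
*downstream layer* of leaf mRNA nodes regulated by some backbone entities.
A backbone node with a populated mRNA layer is an **inferable node
(iNode)**: its activity can be deduced from a differential-expression
contrast by *back-reasoning* over its transcripts, rather than from its own
mRNA abundance.

For an iNode with downstream signature D = {(g, s_g)} (gene g regulated with
sign s_g ∈ {+1, −1}) and a contrast with log2 fold changes β_g, the inferred
amplitude is the signed concordance statistic

    amplitude = (1 / |D|) · Σ_{g ∈ D} s_g · β_g

— a threshold-free "inferred fold change" in log2 units: positive when the
transcripts move concordantly with activation, negative with inhibition.
Significance comes from a gene-sampling permutation null: |D| genes are
repeatedly drawn from the whole contrast, assigned the signature signs, and
the amplitude recomputed; the two-sided, add-one-corrected tail probability
is the p-value, adjusted across iNodes (Benjamini–Hochberg by default).

The package also ships a synthetic-data generator with known ground-truth
node activities, ortholog harmonization (mouse MGI / rat RGD → human HGNC),
Cytoscape-oriented SIF/GraphML export, a lossless JSON model format, and a
command-line interface.

## Worked example

Six curated statements around NLRP3 inflammasome activation, one of them
from a mouse study:

```r
library(cbnet)

writeLines(c(
  'SET Citation = "PMID:30487600"',
  'SET Species = "human"',
  'complex(GOCC:"NF-kappaB complex") increases r(HGNC:NLRP3)',
  'act(p(HGNC:NLRP3)) increases act(p(HGNC:CASP1))',
  'act(p(HGNC:NLRP3)) increases r(HGNC:IL1B)',
  'act(p(HGNC:NLRP3)) increases r(HGNC:CASP1)',
  'act(p(HGNC:NLRP3)) increases r(HGNC:PYCARD)',
  'SET Citation = "PMID:21124315"',
  'SET Species = "mouse"',
  'act(p(MGI:Nlrp3)) increases r(MGI:Il18)'
), "inflammasome_mini.bel")
writeLines(c("source_namespace\tsource_symbol\ttarget_symbol",
             "MGI\tNlrp3\tNLRP3", "MGI\tIl18\tIL18"), "orthologs.tsv")

model <- read_bel("inflammasome_mini.bel") |>
  assemble() |>
  orthologize(read_ortholog_map("orthologs.tsv")) |>
  split_layers()
model
#> <layered_model> 3 backbone + 5 downstream nodes, 6 edges, 2 iNodes (species: human)

tidy(model)   # downstream signatures; the mouse Il18 edge merged into HGNC
#> # A tibble: 5 × 3
#>   node                                  gene    sign
#>   <chr>                                 <chr>  <int>
#> 1 "act(p(HGNC:NLRP3))"                  CASP1      1
#> 2 "act(p(HGNC:NLRP3))"                  IL18       1
#> 3 "act(p(HGNC:NLRP3))"                  IL1B       1
#> 4 "act(p(HGNC:NLRP3))"                  PYCARD     1
#> 5 "complex(GOCC:\"NF-kappaB complex\")" NLRP3      1

set.seed(99)
contrast <- as_contrast(tibble::tibble(
  gene = c("NLRP3", "IL1B", "CASP1", "PYCARD", "IL18", sprintf("BG%02d", 1:40)),
  log2fc = c(1.8, 2.2, 1.1, 0.9, 1.4, rnorm(40, sd = 0.4))
), label = "infected_vs_mock")

scores <- score_all(model, contrast, scoring_config(seed = 1))
scores
#> # iNode scores for contrast 'infected_vs_mock': 1 scored, 1 significant, 1 unscored
#> # A tibble: 1 × 7
#>   node               n_genes amplitude  p_value p_adjusted direction significant
#> * <chr>                <int>     <dbl>    <dbl>      <dbl> <chr>     <lgl>
#> 1 act(p(HGNC:NLRP3))       4       1.4 0.000500 0.000500   up        TRUE
```

NLRP3 activity is inferred **up** with amplitude 1.4 — the mean signed log2
fold change of its four measured signature transcripts — and none of 2000
permuted gene draws matched it, so p = (1+0)/(1+2000) ≈ 5·10⁻⁴. The NF-κB
node has only one signature gene, below the default `min_downstream = 3`,
and is reported as unscored rather than given a noise-dominated score.
`autoplot(scores)` renders the conventional report: yellow bars for inferred
upregulation, blue for downregulation, black outlines marking significance.

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/cbnet.R", package="cbnet"))') \
    simulate --out fixtures --seed 1
# ... assemble --bel fixtures/network.bel --orthologs fixtures/orthologs.tsv --out model.json
# ... score --model model.json --contrast fixtures/contrast.tsv --seed 1 --out results
# ... export --model model.json --format graphml --out model.graphml
```

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch against the
installed package — simulate a ground-truth network, write the fixture
suite to disk, parse it back, assemble, orthologize, split layers, score —
and writes a JSON result document:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
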