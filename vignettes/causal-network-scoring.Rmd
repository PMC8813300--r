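---
title: "Inferring backbone-node activity in causal biological network models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring backbone-node activity in causal biological network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbnet)
```

## The model

A causal biological network (CBN) model is a literature-curated, signed,
directed graph. Curators read mechanistic studies and record each finding as
a triple — subject, relationship, object — in a controlled vocabulary, plus
annotations for the citation and the experimental system (species, tissue).
`cbnet` supports a nine-function, fifteen-namespace subset of BEL 1.0
sufficient for inflammation-type pathway models: leaf terms
`fn(NAMESPACE:value)` for proteins (`p`), transcripts (`r`), microRNAs
(`m`), chemicals (`a`), complexes (`complex`), biological processes (`bp`)
and pathologies (`path`), and the wrappers `act()` (activity of) and
`sec()` (secretion of) around a single inner term. Relationships are
`increases`/`directlyIncreases` (+1), `decreases`/`directlyDecreases` (−1),
and `association` (0). Direct and indirect causation carry the same sign
because scoring only consumes direction; the distinction is preserved in
the statement table for provenance.

Compilation (`assemble()`) creates one node per distinct canonical term and
one edge per `(source, target, sign)`, attaching every supporting statement
as evidence. Contradicting findings are deliberately kept as parallel +1/−1
edges — curation records the literature as it is, and resolution belongs to
analysis, not parsing. Because models mix human, mouse and rat studies,
`orthologize()` rewrites MGI/RGD gene symbols to HGNC (at any wrapper
depth) and merges nodes that become identical, unioning evidence, so one
gene is one node regardless of the species it was studied in.

`split_layers()` then partitions nodes: a node is **downstream** iff it is a
transcript (`r`) with no outgoing causal edges — a leaf mRNA readout; all
other nodes, including transcripts that themselves regulate something, form
the **backbone**. Each backbone node's *signature* is the signed set of
downstream genes it regulates. This leaf-transcript rule is the minimal
operational reading of a "downstream mRNA layer"; it is a design choice,
made because it is decidable from topology alone and errs toward keeping
ambiguous nodes in the backbone. Two further rules are deliberate:
association (sign-0) edges never enter signatures (no direction, no
concordance), and a gene that one node both up- and down-regulates is
dropped from that node's signature — it carries no usable direction, and
exclusion is conservative and reported.

## The inference

A backbone node with a non-empty signature is an inferable node (iNode).
Given a contrast of per-gene log2 fold changes $\beta_g$, the node's
inferred amplitude is

$$\hat a = \frac{1}{|D|} \sum_{(g, s_g) \in D} s_g\,\beta_g,$$

the mean of signed fold changes over the *measured* signature $D$
(signature genes absent from the platform are dropped, not imputed as zero:
absence from an array is not evidence of no change). The statistic is
threshold-free — no fold-change or p-value cutoff is applied to the
contrast — and reads directly as an inferred log2 fold change: the common
shift of the node's transcripts after orienting each by its curated sign.
It is linear, so it is exactly sign- and scale-equivariant, two properties
the test suite checks as invariants.

Published scoring pipelines for such models use a family of network
perturbation amplitude statistics whose exact form lives outside this
package's sources; `cbnet` deliberately specifies its own minimal
concordance statistic instead, and numerical agreement with other
implementations is therefore *not* claimed — direction and significance
calls are the comparable outputs.

### Significance

No significance procedure is inherited either, so the package states one:
a gene-sampling permutation null. For each node, `n_permutations` times,
$|D|$ genes are drawn uniformly without replacement from the whole contrast
universe, the node's signature signs are assigned in draw order, and the
amplitude recomputed. The p-value is the two-sided tail

$$p = \frac{1 + \#\{|\hat a^{null}| \ge |\hat a|\}}{1 + n_{perm}},$$

with ties counted toward the tail (conservative) and the add-one correction
preventing $p = 0$. Comparisons are made after rounding to 12 significant
digits so floating-point noise cannot break a genuine tie. For tiny
universes an exhaustive mode enumerates every ordered draw and returns the
exact tail fraction (the observed assignment is itself one of the draws, so
no correction is needed); the test suite uses it as the oracle the
Monte-Carlo sampler must reproduce.

Each node's generator is seeded by `seed` plus a deterministic hash of the
node id: results are reproducible and no node's p-value depends on the
order in which nodes are scored. Across nodes, p-values are adjusted by
Benjamini–Hochberg by default (`adjust = "none"` disables this), and
`direction` is `up`/`down` only for significant nodes — mirroring the
reporting convention of activated / inhibited / not impacted.

### Tunable parameters

* `min_downstream` (default 3): amplitudes over one or two genes are
  noise-dominated; nodes below the floor are reported as *unscored* rather
  than scored badly. Set to 1 to score every iNode.
* `n_permutations` (default 2000): p-value resolution is $1/(n+1)$; 2000
  resolves well past a BH-adjusted 0.05 for models with tens of iNodes.
* `alpha` (default 0.05) on the adjusted scale.
* Probe collapsing (`collapse`): duplicate measurements of a gene are
  collapsed by maximum absolute value by default (keeps the responsive
  probe), or by mean; the choice is explicit because it must be
  deterministic and stated.

## The synthetic world

Because real curated models and their scoring datasets cannot be bundled,
`simulate_model()` generates the whole object with known truth: backbone
terms cycling through the non-transcript vocabulary functions (so fixture
files exercise the entire grammar), random signed backbone edges, and a
downstream `r()` layer. `simulate_contrast()` emits
$\beta_g = s_g \cdot a_{node(g)} + \varepsilon$ with Gaussian noise, plus
pure-noise background genes. The defaults are a single stated world: 10
backbone nodes, 20 genes per node, true amplitudes of ±2 log2 units on
every other node, noise sd 0.5, 500 background genes, 30% negative signs,
edge density 0.15. The effect/noise/coverage values are the regime the
package's recovery guarantees are stated for; the sign split and density
were chosen once as typical of activation-dominated curated inflammation
networks and are not revisited per test. Options exist for Student-t noise
(heavy-tail stress tests) and overlapping signatures (real regulators share
transcripts), both off by default.

What a green simulation test establishes: parsing, assembly,
orthologization, layer splitting and scoring compose correctly, the
estimator is unbiased under additive noise, and the permutation null is
calibrated under symmetric noise. What it does not establish: performance
under correlated genes (array co-expression violates the independent-draw
null and can make it anti-conservative), platform effects, or the biology
of any specific pathway.

## Numerical and degenerate-input choices

* Self-loop statements are rejected at parse time; self-loops arising from
  ortholog merges are dropped with a warning (distinct biology collapsing
  onto one symbol is a curation problem the software cannot resolve).
* A many-to-many ortholog key is a map validation error; many-to-one is a
  legitimate merge.
* Empty models, empty signatures, empty contrasts and zero-node simulations
  all produce well-formed empty results or typed errors, never crashes.
* Strict mode (default) aborts on the first malformed BEL line with its
  line number; lenient mode skips, warns and returns the failures.

## Limitations

* The statistic weighs every signature gene equally; no variance weighting
  or leading-gene decomposition is attempted.
* The permutation null treats genes as exchangeable; correlated transcripts
  under-disperse it. With typical signature sizes the BH adjustment absorbs
  some of this, but calibration claims are for independent noise only.
* The backbone topology is carried and exported but not itself scored; no
  network-level aggregate perturbation score is computed.
* BEL coverage is the nine-function subset: translocations, reactions,
  protein modifications and variants are out of scope, as is namespace
  resolution against terminology servers.
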