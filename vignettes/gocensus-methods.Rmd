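---
title: "A genomic census of terminal molecular functions as phylogenetic characters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A genomic census of terminal molecular functions as phylogenetic characters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The method

gocensus treats the functional repertoire of a genome — the multiset of
terminal Gene Ontology molecular-function (GO-TMF) terms its proteins are
annotated with — as a set of phylogenetic characters.  Terminal terms are
the leaves of the molecular_function `is_a` hierarchy: the most specialised
annotations, specific enough to vary informatively across taxa.  Counting
how many annotation records in genome $a$ point at term $b$ gives a raw
abundance $g_{ab}$; a genomes-by-terms matrix of these counts is the
*census of molecular functions*.  From one encoded matrix the package
builds two rooted phylogenies:

* a **tree of life (ToL)** — taxa are genomes, characters are terms — that
  groups organisms by their functional repertoires, and
* a **tree of functions (ToF)** — taxa are terms, characters are genomes —
  that orders molecular functions by their pattern of presence and
  abundance across life.

Everything downstream (relative ages, distribution indices, Venn taxonomic
groups, persistence metrics) reads off these trees and the census.

## Dataset assembly

`parse_obo()` loads an OBO 1.2 ontology keeping only `is_a` edges: the
backbone relationship is what defines terminality, and mixing in `part_of`
or regulatory edges would make "leaf" ambiguous.  Obsolete terms are kept
but flagged, and annotations pointing at them are dropped with a warning.
Annotations to non-terminal terms are dropped, never propagated up or down
the graph — the unit of analysis is the terminal term itself.

`filter_organisms()` applies three exclusion rules, each logged with the
first rule that fired:

1. **strain** — only type strains are kept, using the metadata flag
   (name-parsing heuristics are deliberately out of scope);
2. **lifestyle** — parasites and facultative parasites are removed, since
   host co-evolution distorts genome content;
3. **coverage** — genomes where fewer than 50% of proteins carry a
   terminal molecular-function annotation are removed as under-annotated.

Coverage counts proteins annotated *to terminal MF terms* (not to any GO
term) divided by proteome size, and the threshold is inclusive: exactly
50% is retained.  Both choices are configurable; the coverage definition
is the one matching the filter's stated purpose, but a user can probe
sensitivity by changing the terminal set passed in.

## The horizontal-transfer screen

Lateral acquisition makes a term's distribution reticulate rather than
tree-like, so terms enriched among horizontally transferred proteins
(HTPs) are removed before tree building.  `flag_hgt_terms()` cross-lists
per-genome HTP protein lists with the annotation records behind the
census and tests each term with an upper-tail hypergeometric test.  The
sampling frame is annotation records: $N$ records in the census, $K$ of
the focal term, $n$ on HTP proteins, $k$ of the focal term on HTP
proteins, and

$$p = P(X \ge k), \qquad X \sim \mathrm{Hypergeometric}(N, K, n).$$

Only the upper tail is tested (enrichment, not depletion), Benjamini–
Hochberg correction is applied across terms, and terms with adjusted
$p < 0.05$ are excluded from the whole dataset, all genomes at once.  The
correction method and $\alpha$ are exposed as arguments.  On synthetic
corpora with planted transfers at high copy number the screen recovers
essentially all planted terms while flagging none under a null HTP list
(both behaviours are asserted in the test suite).

## Character encoding

Raw abundances are right-skewed and scale with genome size, so they are
log-damped and rescaled into 32 ordered states:

$$g_{ab}^{\mathrm{norm}} = \mathrm{round}\!\left(\frac{\ln(g_{ab}+1)}{\ln(g_{\max}+1)} \times 31\right),$$

with $g_{\max}$ the single matrix-wide maximum (taken after HGT-term
exclusion, since encoding follows exclusion in the pipeline order).
Absence maps to state 0, the heaviest cell to state 31, and states print
as the alphanumeric symbols 0–9, A–V for NEXUS interchange.  Two
numerical choices are fixed and documented rather than left to platform
behaviour: rounding is half-up (0.5 moves to the next state; base R's
banker's rounding would silently shift state boundaries), and the
multiplication by 31 happens before rounding (rounding the bare ratio
first would collapse the alphabet to \{0, 31\}, contradicting the
32-state design).  Note that states adjacent to $g_{\max}$ can also round
to 31: "only the maximum reaches 31" holds only when the next-largest
abundance keeps a relative gap.

`write_nexus()` emits the DATA block with `SYMBOLS="0~9A~V"`, an
ASSUMPTIONS block declaring characters ordered, the ancestral state (V
for ToF polarity, 0 for ToL polarity) and a comment carrying the Lundberg
rooting directive, for interoperability with external parsimony software.
Inference itself is done in-package.

## Maximum-parsimony engine

Characters are **ordered** (Wagner): moving between states $i$ and $j$
costs $|i-j|$, so large abundance jumps count more than small ones, which
is what the dual min/max rooting polarity presupposes.  An unordered
(Fitch) mode is available for sensitivity checks.  Scoring uses three
mutually checking implementations in C++: a Sankoff dynamic program under
an arbitrary cost matrix (the reference; handles multifurcations), a
Farris interval pass for ordered states, and a bitmask Fitch pass for
unordered states.  All costs are integers, so scores are exact.

The search (`mp_search()`) is classical: random-addition starting trees,
first-improvement NNI to a local optimum, then SPR sweeps returning to
NNI after every accepted move.  Defaults (10 starts; bootstrap replicates
use 2 starts, NNI only) were chosen for desk-scale matrices of tens to a
few hundred taxa.  All distinct best topologies found are returned in
canonical order (lexicographic canonical Newick), and ties are flagged
rather than silently broken; every seed-bearing function restores the
caller's RNG state.  On matrices of up to 7 taxa the heuristic provably
attains the exhaustive-enumeration minimum in the test suite.

**Lundberg rooting** places the root without an outgroup: a hypothetical
ancestor with every character at the ancestral state (31 = "V" for ToFs
— the most abundant function is oldest; 0 for ToLs — the ancestral
genome is minimal) is attached to each branch in turn, and the root goes
where total length is minimised.  Branch enumeration order is canonical
(by the sorted tip set under each branch), ties pick the first branch and
set a `root_tie` attribute.

**Bootstrap support** resamples characters with replacement and reports,
for every clade of the full-data rooted tree, the percentage of
replicates whose best tree contains the corresponding bipartition
(counted with ape's `prop.clades`).  Each replicate's search seed is
derived from the resampled column multiset plus the master seed, so
identical replicate datasets always yield identical trees — this keeps
the degenerate one-character case exactly at \{0, 100\} while remaining
fully deterministic under one seed.

`fit_indices()` reports ensemble CI, RI and RC.  Per character the
minimum conceivable steps are the tip-state range (ordered) or the state
count minus one (unordered); the maximum steps are those on a completely
unresolved tree; invariant characters are excluded with a message.

## Evolutionary statistics

**Node distance (nd)** proxies relative age on the ToF: for each tip,
count the internal nodes strictly between it and the root, then rescale
to $[0,1]$.  The default anchors the basal-most tip at 0 and the deepest
at 1, i.e. $(r - r_{\min})/(r_{\max} - r_{\min})$; when a tip hangs
directly off the root (the typical Lundberg outcome with a basal taxon)
this coincides with plain division by the maximum count.  The literal
variant that divides by the number of taxa is available as
`normalize = "n_taxa"`, but it can never reach nd = 1 and is kept only
for comparison.  When several equally parsimonious trees exist, nd is
computed on the canonical best tree.

**Distribution index (f)** is the fraction of genomes encoding a term,
globally or within a superkingdom; $f = 1$ is ubiquity.  The global f is
exactly the genome-count-weighted mean of the three kingdom values (an
asserted invariant — note that per-kingdom f can sit on either side of
the global value).

**Venn taxonomic groups** classify each term by the set of superkingdoms
containing it (A, B, E, AB, AE, BE, ABE); the seven groups partition the
term set.  **Group appearance** summarises nd per group with type-7
quartiles and Tukey 1.5×IQR outliers, and reports the appearance order
both from raw minima and after removing low outliers — an early lateral
transfer can make a group look older than it is, and the outlier-excluded
order is the robust one.

**Persistence metrics** per genome: economy (distinct terms), flexibility
(total redundant annotations) and robustness (their ratio; undefined and
flagged for empty genomes).

## The synthetic generator

No public archive preserves the 2009-era proteome annotation files the
method was developed on, so the package ships a generator
(`generate_ontology()`, `simulate_genomes()`) whose outputs stand in for
them with known ground truth.  It emulates the features the pipeline is
sensitive to:

* a rooted molecular_function DAG with multi-parent terms, plus
  biological_process and obsolete decoys for the filters;
* a fixed pectinate species tree whose Archaea-like clade branches first,
  so rooting tests have an unambiguous expectation;
* a rich ancestral repertoire shared by all genomes; clade-wide loss of
  each ancestral term on the A stem with probability
  `loss_rate_per_clade` (genome reduction, creating BE terms);
* lineage-specific eukaryal novelties assigned round-robin to E tips
  (late functional diversification, creating E terms);
* abundance $1 + \mathrm{Poisson}(\lambda)$ per present term — the
  simplest right-skewed count model consistent with duplication-driven
  heterogeneity; real abundance distributions are heavier-tailed, which
  the log encoding absorbs by design;
* planted lateral transfers: terms lost from Archaea copied from a
  free-living B donor into a free-living A recipient, with the
  recipient's carrier proteins written to its HTP list;
* parasite and low-coverage labels assigned by deterministic per-clade
  quota (`floor(fraction × n + 0.5)` tips from the end of each clade), so
  filter tests are exact rather than stochastic.

Defaults are a desk-scale corpus: 6+6+6 genomes, 60-term ontology, 30
ancestral terms, 25% stem loss, duplication mean 0.8, 2 planted
transfers, 10% parasites and 10% low-coverage genomes.
`simulate_reference_corpus()` scales the same design to the original
study's bookkeeping: 49+199+23 genomes with 4% quotas leave 45+183+21 =
249 after filtering; 989 ancestral plus 1,150 eukaryal novel terms leave
2,039 detected in the retained census; excluding the 115 planted
HGT-acquired terms leaves 1,924.

What the generator does **not** emulate: sequence evolution, gradual
per-tip loss within clades, endosymbiosis, annotation-error noise, or the
taxonomic idiosyncrasies of the real corpus.  Passing recovery tests
therefore show that the pipeline recovers the signal it is designed for
when that signal is present — not that real annotation data contain the
signal.

## Problem sizes and determinism

The shipped tests run the full pipeline on 12–18 genome corpora with
40–60 terms, tree searches on up to ~60 taxa, 100-replicate bootstraps on
15 taxa, and exhaustive search oracles on up to 7 taxa (945 topologies);
the whole suite completes in about a minute.  One seed drives ontology
generation, genome simulation, search starts and bootstrap resampling;
identical configurations give byte-identical artifacts, and the pipeline
manifest records an md5 over the configuration, stage counts and output
files so reruns can be compared at a glance.

## Known limitations

* Wagner/Fitch scoring assumes binary trees inside the search; arbitrary
  multifurcating input trees are scored via the Sankoff reference (and
  binarised with zero-length splits for rooting).
* The search is a hill-climber: beyond the exhaustively verified sizes,
  "best length" means best found under the schedule, as with any
  heuristic parsimony software.
* nd is a node-counting clock: it assumes cladogenesis density proxies
  time, and is only as good as the ToF topology and rooting.
* The hypergeometric screen inherits the record-level independence
  assumption of annotation draws; strongly duplicated non-transferred
  families can dilute its power.
* Newick export sanitises GO accessions (`GO:123` becomes `GO_123`)
  because unquoted Newick reserves the colon.
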