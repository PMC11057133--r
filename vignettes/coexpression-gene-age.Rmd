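---
title: "Methods: co-expression modules, gene age, and tumor-specific rewiring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression modules, gene age, and tumor-specific rewiring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexage)
```

# The model

`coexage` studies the co-expression of genes of unicellular (UC) and
multicellular (MC) evolutionary origin in paired tumor/normal expression
cohorts. Its working model is that healthy tissues maintain stable
co-expression programs — detectable as modules of a weighted correlation
network — and that tumors rewire these programs, most strongly at the
interface between UC and MC genes. The package quantifies that rewiring
three ways: by the age composition of modules, by a tumor-specificity
("novelty") score relative to the matched normal modules, and by per-sample
module activity.

## Gene age

Genes are dated on a 16-level phylostratum scale; strata 1–3 (orthologs in
bacteria or unicellular eukaryotes) are UC, strata 4–16 MC. The package
consumes a precomputed two-column table; it never infers strata from
sequence data, and gene identifiers are treated as opaque strings. Genes in
an expression matrix but missing from the age table are labeled `unknown`
and excluded from both module and background counts of the age-enrichment
tests, since those tests are defined over classified genes only.

## Networks and modules

Counts are filtered to genes with CPM > 1 in *all* tumor or *all* normal
samples (strict inequality; the all-samples rule makes the filter robust to
a single highly expressed outlier sample), then log2-CPM transformed.
Samples are screened by average-linkage clustering on Euclidean distance;
the tree is cut at `mean + k·sd` of the merge heights (`k = 2.5` by
default) and only the largest cluster is kept, with a dropped sample taking
its pair partner with it. In the cohort pipeline this screen runs within
each condition separately: tumors and normals (and tumor grades) differ
biologically, and a joint screen would read that separation as
outlierness and discard legitimate subgroups. The `k` threshold is a convention — the screening
procedure in the literature names no cutoff — and both it and the decision
to anchor on merge heights are exposed as arguments.

The network is unsigned: `a_ij = |cor|^β` with β = 6, the conventional
default for unsigned networks. No scale-free-fit selection is implemented;
β is an explicit argument everywhere. The topological overlap
transformation rewards shared neighborhoods and suppresses spurious
pairwise correlation; it is computed by matrix multiplication and verified
in the tests against a literal triple-loop evaluation of its formula to
1e-10.

Module detection is deliberately simple and deterministic: average-linkage
clustering of `1 − TOM`, a fixed-height cut at 0.99 (the common default for
tree-based dynamic cutting on this dissimilarity scale), and pooling of
branches below `min_size = 30` into the grey set. We chose this over the
hybrid PAM-like dynamic cut because the package's accuracy contract is
planted-module recovery — measured by adjusted Rand index on synthetic
cohorts — rather than bit-equivalence with any particular reference
implementation, and a fixed-height cut makes results reproducible to the
byte across platforms. No eigengene-based module merging is performed.
Labels are `M1, M2, …` by decreasing size, ties broken by the
alphabetically first member gene; `grey` is reserved.

## Module age classification

Each module is tested for UC over-representation and, separately, MC
over-representation with one-sided Fisher tests against the cohort
background (all genes surviving the expression filter). BH adjustment is
applied per direction across the modules of one cohort; pooling both
directions into one family is available as an option since the reporting
convention does not pin this down. A module is UC-enriched or MC-enriched
at adjusted p < 0.05, otherwise mixed UC-MC. With a two-class labeling the
two one-sided tests can never both be significant, which the test suite
asserts on randomized inputs.

Reported odds ratios are unconditional cross-product estimates `ad/bc` —
the quantity obtained by direct arithmetic on module count tables — rather
than the conditional MLE that `fisher.test()` prints; the conditional
estimate is available behind a flag. A Haldane–Anscombe 0.5 correction is
applied to the odds ratio only when a cell is zero, and flagged.

## Novelty

The raw novelty `N` of a tumor module is the minimum number of reference
(normal) modules needed to cover at least 50% of its genes. References are
sorted by decreasing overlap (ties: larger module first, then label — fully
deterministic) and accumulated; coverage counts distinct genes, which for
disjoint reference modules coincides with summed overlaps and makes the
greedy rule exactly optimal (certified in the tests by exhaustive subset
enumeration). Grey pools are excluded from the reference. When the
threshold is unreachable — the target's genes are absent from every
reference module — we set `N = (number of overlapping modules) + 1` and
flag the result, preserving the "more modules needed ⇒ more novel"
ordering without sentinel infinities. The coverage threshold (0.5,
non-strict) is configurable.

The score `N/S` is classified into tertiles at the 1/3 and 2/3 quantiles,
computed with the linear-interpolation quantile (R type 7), within one
tumor-versus-reference comparison; cutoffs are non-strict so an all-equal
score set is uniformly "low". Tertiles are per comparison because cohorts
differ in module size distributions; a pooled mode would be a one-line
change for callers who need it.

## Module activity

Per-sample activity is a single-sample GSEA: genes ranked by decreasing
expression (ties broken by gene id for determinism), weights `rank^0.25`
taken from the ascending ranks so the most expressed genes weigh most, and
the score is the accumulated difference between the weighted in-set and
uniform out-of-set running fractions. α = 0.25 and the global min–max
matrix normalization mirror the defaults of the package that popularized
the method; both are arguments, and whether to normalize at all is exposed
because reporting conventions vary. The score is a rank statistic —
invariant under any strictly increasing per-sample transform — which the
tests assert property-style.

## Somatic mutations, CNAs, and centrality

A gene is recurrently point mutated with missense/LoF mutations in ≥ 3
patients *and* a non-synonymous/synonymous ratio below 1; a zero synonymous
count yields ratio +∞ and fails the filter (the literal reading of the
rule; the direction is configurable because it runs against positive
selection intuition). Copy-number calls are per-gene per-patient: the
segment overlapping the gene's midpoint, focal when the segment spans at
most 25% of its chromosome. The published focality description (an upper
quantile of mean aberrant-chromosome fractions) does not determine an
algorithm, so the bounded-span rule is our operational definition, with the
fraction configurable. Coordinates are 0-based half-open and `chr` prefixes
are normalized away. Recurrence is ≥ 10% of patients, module flags at
≥ 10% recurrent genes, both non-strict.

Centrality within a module is the summed edge weight (degree), normalized
by the module median degree, ranked ascending with averaged ties, divided
by module size, minus 1 — so hubs sit at 0 and the periphery approaches −1,
and values are comparable across modules of different size and strength.

The strong-edge robustness filter removes edges strictly below the module's
median off-diagonal weight (ties at the median survive) and then keeps
genes connected to at least `⌈S/2⌉` retained edges, with `S` the original
module size — "half of the genes in the module" is read against the
pre-filter module. Filtered module sets feed the unchanged age and novelty
code paths.

## Progression and classification

Stage chains build modules per stage independently and score each stage's
modules against the previous stage's, so rewiring accumulating along
progression appears as rising novelty per link. The grade classifier is a
random forest (500 trees, default `√p` feature subsampling, no class
weights) on module activity scores over 100 stratified 70/30 splits;
stratification is our choice — plain random splits can produce single-class
test sets at small n — and the forest size is the package default since
none is prescribed. AUCs and mean decreases in Gini impurity are recorded
per iteration; a module is "important" above a mean decrease of 5. All
randomness flows from a single master seed through per-iteration seeds, so
reports are byte-identical for identical inputs.

# The synthetic cohort generator

The generator is a first-class module, not a fixture: it emulates exactly
the statistical structure the pipeline assumes. Defaults: 600 genes, 60
tumor/normal pairs, six planted gene blocks of 40–60 genes. Two blocks are
preserved modules (active in both conditions; one 80% UC, one 20% UC);
three are mixed-age donor modules active only in normal tissue; one is a
mixed-age block active only in high-grade tumors. Two tumor-only modules of
50 and 45 genes are *recombinations* of donor genes — in normal samples
those genes follow their donor factors, in tumors they are driven jointly
by a new factor. This is the key design choice: it reproduces the
rewiring phenomenon (tumor modules stitched from several normal modules)
so that novelty `N ≥ 2` arises through the real detection path, rather than
through genes that are simply silent in normals.

Expression is negative-binomial (dispersion φ = 0.2) around log-normal
means: baseline log2 means U(3, 9), factor loadings λ = 1.2 on N(0, 1)
per-module per-sample factors, extra log2 noise sd 0.3, library factors
U(0.7, 1.3), plus 20 near-silent background genes (baseline log2 mean
U(−5, −3)) so the CPM filter has real work to do. Tumor-only and
high-grade-only modules carry a +1 log2 mean shift when active, reflecting
that tumor-specific programs are actively expressed. Amplification drivers
(3 genes) are hubs of the first tumor-only module (loading 1.8 in tumors,
0.5 in their normal donor module), shifted +1.5 log2 in the 30% of tumor
patients carrying a focal amplification; deletion drivers mirror this at
lower frequency. Point mutations include genes engineered to pass and to
fail each recurrence rule. These values were chosen once as a realistic
desk-scale cohort and are all configurable; the sizes keep the full test
suite in the minutes range on a single CPU.

What the generator does **not** emulate: batch effects, tumor purity
mixtures, correlated library composition, overlapping or hierarchical
modules, isoform structure, and single-cell data. Passing tests therefore
demonstrate correctness of the algorithms under the stated generative
model, not performance on real cohorts, where noise is heavier-tailed and
module boundaries are fuzzier.

# Numerical and degenerate-input choices

* Adjacency and TOM are symmetrized after computation to absorb
  floating-point asymmetry; both are validated against brute-force oracles
  to 1e-10.
* Zero-variance genes are an error at `adjacency()` (they have no defined
  correlation) and are silently removed by the upstream quality filter, so
  pipelines never hit the error path.
* A module set with no module of `min_size` is a valid all-grey result, not
  an error; downstream steps degrade cleanly (empty tables, no scores).
* `fisher_2x2` flags tables with a zero row/column total and returns `NA`
  for the odds ratio rather than a corrected pseudo-value.
* Ties: expression ties in ssGSEA break by gene id; centrality ranks
  average ties; reference-module sorting in novelty breaks ties by size
  then label; tertile and quartile cutoffs are non-strict.

# Problem sizes used by the test suite

Oracle comparisons run on 200 random networks up to 50 genes, 1000 random
novelty instances with up to 6 reference modules and 12-gene targets
(exhaustively enumerable), and 500 random ssGSEA draws. End-to-end checks
use the default 600-gene/60-pair cohort: one fixed-seed cohort for
planted-module recovery and 20 replicates for the novelty separation of
rewired versus preserved modules. The classifier checks use 100 forests on
15 modules × 100 samples. These sizes were chosen so the whole suite runs
in a few minutes on one CPU while every statistic is still well inside its
asymptotic regime.

# Known limitations

* The fixed-height tree cut will not resolve nested module structure that
  the hybrid dynamic cut can; for data with strong sub-module hierarchy,
  lower `cut_height` or smaller `min_size` are the available levers.
* Novelty with a *non-disjoint* reference (not produced by this package,
  but accepted by the API) makes the greedy rule a heuristic; coverage is
  counted over distinct genes, which is the sensible generalization, but
  optimality is only guaranteed for disjoint references.
* The ssGSEA implementation is the rank-weight running-sum variant only;
  the kernel-density variant of the popularizing package is out of scope.
* Signed networks, alternative correlation estimators (bicor, Spearman),
  and out-of-core blockwise detection are not implemented.
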