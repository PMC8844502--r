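---
title: "Models and methods behind sbftools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sbftools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbftools)
```

sbftools analyzes the evolution of gene expression across species measured
in homologous tissues (in the motivating colonial-animal setting, zooids).
This vignette documents the models, the parameters that matter, the
numerical conventions, and the choices made where the design was genuinely
open. It states no empirical result beyond what the package's tests and
acceptance script themselves compute.

## Normalization: TPM10K

TPM makes libraries comparable within a species, but its scale depends on
the reference gene count `n`: the library mean is `1e6 / n`, so a species
with a more complete reference appears to express every gene less. TPM10K
multiplies TPM by `n / 1e4`, giving every library mean 100 regardless of
`n`. The divisor 1e4 only keeps magnitudes convenient.

Two conventions matter:

* **`n` is the size of the full reference**, supplied per species, not the
  number of genes surviving the expression filters. Normalization is
  conceptually upstream of filtering; inferring `n` from a filtered matrix
  would re-introduce the reference-completeness artifact TPM10K removes.
* Gene filtering (drop rRNA, keep protein-coding, require a positive count
  in at least two libraries) runs on the count table before TPM so that
  excluded genes never enter downstream summaries, but the TPM denominator
  of a library is always the sum over the genes present in that table.

## Replicate summary, log transform, ratios

Replicates of a (species, tissue) are averaged on the TPM10K scale and then
log-transformed. The transformation base was an open choice; the default is
the natural log (`log_base` configurable), which makes ratio traits plain
log-fold-changes and leaves the downstream Brownian model invariant up to a
global scale. Zeros under the log are handled by a pseudocount (default 1,
configurable); with `pseudocount = 0` non-finite values are dropped with a
warning rather than propagating `-Inf`.

Tissue ratios are computed as differences of log values against a
denominator tissue (the most commonly sampled one; the package default
is `"gastrozooid_mature"`). Since reconstruction under Brownian motion is a
linear operation on tip values, subtraction commutes with it: when both
tissues are observed on the same tips, the ratio of reconstructions equals
the reconstruction of ratios. A gene-by-species counting-efficiency factor
multiplies both numerator and denominator of a ratio and cancels exactly
at the expression level; the per-library TPM normalizer leaves a
gene-independent offset per (species, tissue) of order `1 / sqrt(n)` for a
reference of `n` genes, which is why ratio-based analyses assume reasonably
large references. Exactness of the cancellation requires `pseudocount = 0`;
with a pseudocount the cancellation is approximate, best for well-expressed
genes.

## Event annotation and null nodes

Gene-tree internal nodes are labeled by the species-overlap rule: a node is
a duplication iff its child subtrees share at least one species, otherwise
a speciation. Precomputed events carried in NHX tags (`Ev=S|D`) take
precedence, so reconciliations from upstream tools can be consumed
unchanged; `overwrite = TRUE` forces relabeling. Non-binary nodes are
treated as a single event over all children, with a warning — tolerance
only, since the intended inputs are binary.

Speciation nodes are mapped to the species tree by the MRCA of their
descendant species. Because species-overlap can call nested nodes
speciations even when the topology conflicts with the species tree, nested
speciation nodes mapping to an already-claimed species node are demoted to
*null*: they carry no calibration constraint and do not delimit
species-equivalent branches. The scan runs root-to-tips and considers **any**
non-null speciation ancestor on the path, not only the nearest one, and
intervening duplication nodes do not reset it; both choices follow from the
purpose of the rule (avoiding equal-age constraints on nested nodes —
resetting at duplications would reintroduce exactly those).

## Gene-tree filters

A tree is discarded when any rule fires (thresholds all configurable):
maximum branch length > 2 substitutions/site; more than 0.25 of branches at
the default length 1e-6 (the value upstream tree inference assigns to
zero-length branches; equality is tested exactly); more than 0.3 null nodes
per internal node; fewer than 1 speciation node; calibrated root age > 5
(species-tree root = 1); fewer than 3 expression-bearing tips. The
long-branch and default-fraction rules are combined with OR by default:
the stated goal of the filter is to exclude trees with *either* pathology,
and an AND combination (also available via `combine_length_rules`) would
keep a tree whose branch lengths are doubly degenerate. Branch statistics
are always computed on the substitution lengths, also after calibration.

## Time calibration

Calibration pins every tip at age 0 and every non-null speciation node at
the age of its species-tree node, exactly. The reference method for this
step is penalized-likelihood dating; its smoothing model and penalty are
free parameters that trade reproducibility for model realism, so the
package default is a deterministic, dependency-free rule that satisfies the
contract any such method must: constrained ages exact, parent strictly
older than child. Unconstrained nodes (duplications, nulls) are placed by
interpolating along the path from the nearest constrained ancestor to the
oldest constrained descendant, proportionally to the original substitution
lengths; when every length on the path is at the 1e-6 default, ages are
spread evenly by hop count instead (proportional interpolation would
degenerate to zero-length calibrated branches). An unconstrained root is
extrapolated above its oldest constrained descendant `d` at the implied
rate `age(d) / depth(d)` of that subtree, falling back to even hop spacing
when `d`'s subtree has no substitution depth. Infeasible inputs — a
constrained node at least as old as a constrained ancestor, which can only
arise from externally supplied annotations since MRCA mapping is monotone —
are rejected with the violating node pair. Calibration is idempotent:
recalibrating a calibrated tree reproduces its ages.

## Ancestral reconstruction

Per tissue, trees are pruned to tips with observed values (degree-2 nodes
suppressed, their incident times summed, so tip-to-tip path lengths are
conserved), and ancestral values are the joint maximum-likelihood states
under Brownian motion — equivalently the minimizers of the weighted least
squares `sum((child - parent)^2 / t)` — computed by a two-pass linear-time
message-passing scheme and checked in the tests against a generic
least-squares solve, a numerical optimizer, and an independent R
implementation. Values are mapped back onto the unpruned tree; suppressed
nodes get no value (provenance `"absent"`) rather than an invented
interpolation, and branch changes are only computed where both endpoints
carry values. Each tissue is reconstructed independently; ratio traits are
formed node-wise from two tissues' maps at co-valued nodes only.
Calibrated branch times below 1e-9 are floored (with a warning or a record
flag) so scaled changes stay finite.

## Scaled changes and species-equivalent branches

The change across a branch is `(child - parent) / time`. Classification
uses a neutral band `[-2, 2]` with the boundaries neutral — the package
follows the convention stated for the classification figure of the
original analyses over a conflicting inline phrasing — and `|change| > 5`
flags very large changes. A branch is species-equivalent when its parent
is a non-null speciation node and its child is either a non-null
speciation node mapping to a child of the parent's species node, or a tip
whose species hangs off the parent's species node; tip branches are
therefore eligible (the terminal species-tree branches receive them).
Tallies count records per (species branch, tissue, class); branch/tissue
combinations without records (e.g. ratios in species lacking the
denominator tissue) are simply absent.

## STF: variance partition

Strict orthologs are gene trees contributing exactly one gene for every
listed species with a duplication- and null-free connecting subtree;
external single-copy tables are validated and passed through. Per ortholog
the additive model `value ~ species + tissue` is fit on cell means (one
value per species-tissue combination, complete cases only), and each
factor's share is its sum of squares adjusted for the other factor over
the total sum of squares. The source analyses this follows do not pin down
sequential versus adjusted sums of squares; adjusted (type-II-style) SS
were chosen because sequential SS make the result depend on factor order,
and the two coincide on the balanced designs this analysis targets. Values
enter untransformed (TPM10K or TPM10K ratios directly). SVG/TVG labels
require combined variance > 0.75 and a two-fold dominance of one factor.

## The simulator

The generator provides the package's study conditions: a fixed synthetic
seven-species ultrametric tree (root age 1, shortest branch 0.15, twelve
lettered branches), duplication–loss gene families simulated inside it
(defaults 0.5 duplications and 0.3 losses per unit time — enough complex
histories to exercise every annotation path while most families survive),
Brownian log-expression per tissue with family roots drawn around 1.5
(sd 1) on the log-TPM10K scale, a background of single-copy genes with
lognormal expression (sd 1.25 in log units) filling the reference,
lognormal gene-by-species counting-efficiency factors (sd 0.5 in log
units), and reads drawn multinomially so library sizes are conserved
exactly (`library_size = NULL` returns expected counts, the infinite-depth
limit). Substitution lengths are true times multiplied by Gamma(10, 10)
factors, a mild departure from the clock. All generators are reproducible
bit-for-bit under a seed.

What the simulator does *not* emulate: sequence-level mapping noise,
within-species biological replicate dispersion beyond multinomial
sampling, correlated efficiencies between related species, gene
conversion, and incomplete lineage sorting. Passing tests therefore show
the pipeline's internal consistency and its behavior under the stated
generative model, not robustness to every artifact of real libraries.

Problem sizes used by the checks (chosen as the package's standard desk
scale): 25 sets of four random libraries for the normalization identities;
50 random trees of up to 8 tips against the least-squares oracle; 200
duplication-loss trees for event labels; 40 families over a 4,000-gene
background for the zero-rate neutrality run; 500 multinomial simulations
of 400 genes for the cancellation-in-expectation check; 1,000 planted
genes on a 4 x 4 design (noise sd 0.1) for SVG/TVG recovery; 10,000
replicates for the Brownian tip moments.

## Known limitations

* The calibration rule is a reproducible stand-in for penalized-likelihood
  dating; numerical agreement with any particular smoothing model is not
  expected, only the shared constraint contract. A hook for plugging in an
  optimizer is the natural extension.
* Null-node demotion depends on the order of the root-to-tip scan in ties;
  the deterministic preorder makes results reproducible but alternative
  tie-breaks are conceivable.
* The per-library TPM normalizer leaves a small species-by-tissue offset
  in ratio traits for finite references (see above); with very small
  simulated references this offset can push scaled changes away from zero.
* Efficiency cancellation is exact only without a pseudocount; analyses of
  sparse data that need a pseudocount trade exactness for zero-handling.
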