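---
title: "Methods: reconstructing and quantifying post-polyploid diploidization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing and quantifying post-polyploid diploidization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppdtools)
```

`ppdtools` reconstructs post-polyploid diploidization (PPD) — the return of
a polyploid genome toward diploid-like structure through gene loss and
chromosome fusion — from gene orders and pairwise homology. This vignette
is the package's account of the models behind each stage, the parameters
that matter, and the choices made where the design was genuinely open.

## The synteny model

All collinearity is computed on gene *ranks* (order indices within a
chromosome), never on base-pair coordinates: at the timescales of ancient
WGDs, gene order is the conserved signal while intergenic distances are
not. `chain_anchors()` finds blocks by an O(n²) dynamic program over anchor
rank pairs: a block is a maximal-cardinality chain strictly increasing in
the first genome's rank and strictly monotone in the second's, with
consecutive anchors at most `max_gap` ranks apart on both sides. Chains are
peeled best-first, so each homology pair belongs to at most one block.

Two parameters shape the blocks:

* `min_block_size` (anchors per block, default **5**): shorter runs are
  indistinguishable from chance collinearity.
* `max_gap` (ranks, default **25**): tolerates fractionation holes without
  chaining across genuine breakpoints.

These follow common practice for gene-level collinearity detection; the
clean simulations used for validation are insensitive to moderate changes,
and both are exposed in every calling function.

Orthologous and out-paralogous synteny are separated by the **orthology
index** (OI): the fraction of a block's anchors whose pair is in the
ortholog set. Orthologs are called by *reciprocal near-best hit*
(`call_orthologs()`): a cross-genome pair is kept when its score reaches
`1 - tol` (default `tol = 0.1`) of both members' best scores against the
partner genome. Strict reciprocal best hit (`tol = 0`) is deliberately not
the default: an unduplicated outgroup gene is equally close to *all*
homoeologous copies of a polyploid, and exactly this many-to-one
co-orthology is what makes orthologous synteny depth readable as ploidy. A
10% tolerance keeps co-orthologs (score differences dominated by noise)
while excluding out-paralogs from a shared WGD, whose divergence excess
translates into a clearly larger score deficit. OI cutoffs used downstream
follow the stage: 0.5 for subgenome phasing and general filtering, 0.4 for
karyotype projection (where partial, fractionated segments still carry
signal).

## Relative ploidy

`estimate_relative_ploidy()` reads p as the **mode** of the positive
windowed synteny depth over the reference (windows of 10 ranks,
non-overlapping; a block covers a window when its anchor span overlaps at
least half of it). The mode — rather than the mean — makes the estimate
robust to locally elevated depth (tandem or segmental artifacts) and to
fractionation holes; zero-depth windows are excluded because they carry no
ratio information. Ties are broken toward the *larger* depth, since
fractionation only ever biases depth downward. How ambiguous, between-
plateau windows should be resolved is not externally fixed anywhere; the
mode rule is this package's decision and is validated against simulated
tetraploids through decaploids with up to 30% per-subgenome gene loss.

Ks-peak detection (`detect_ks_peaks()`) evaluates a Gaussian kernel density
(Silverman's bandwidth by default, overridable) and reports local maxima
above 5% of the global maximum — enough to recover WGD peaks at 0.2–0.5
while suppressing boundary ripple. Fewer than 10 values is an error, not a
guess.

## Subgenome phasing

`match_subgenomes()` phases a polyploid against an already phased reference
by maximum-weight bipartite matching (weight = orthologous anchor count),
with each reference chromosome offering `ceiling(n_query/n_ref)` slots.
Matching is at whole-chromosome granularity because post-fusion chromosomes
are chimeric: the winning label is the majority anchor weight, while
per-reference-chromosome evidence is retained for segment-level inspection.
Ties break by higher OI, then lexicographic identifiers, keeping the
assignment deterministic and invariant under chromosome relabeling.

A/B polarity that synteny cannot decide is voted on by per-chromosome
neighbor-joining trees (`build_chromosome_tree()` on median block ks):
across chromosomes, the copy more often sister to the C-subgenome reference
is B (`resolve_ab_by_topology()`). NJ on median block divergences stands in
for maximum-likelihood chromosome trees — a method substitution that is
adequate at simulation scale, where the distances are nearly additive. An
exact 50/50 vote, or the absence of a C reference, yields relative labels
(X1/X2) rather than a forced polarity, mirroring how paleopolyploid
subgenomes without polarizing evidence are conventionally reported. The
majority rule is a proxy for what is, in practice, a manual reconciliation
step across methods; the vote fraction is reported so low-support calls are
visible. Usefully, high gene-tree discordance is *symmetric* noise: even at
40% discordant trees the majority vote recovers the correct polarity.

## Ancestral karyotype and the rearrangement grammar

`build_proto_karyotype()` takes the least-fused genome as a backbone and
splits its chromosomes wherever at least `min_support` (default 2) other
genomes independently show the same breakpoint — a position where a
chromosome's anchors switch from tiling one partner chromosome to tiling
another, each side being a syntenic unit of at least `min_segment` anchors.
Breakpoints are clustered within a 10-rank tolerance before counting
support. A fusion shared by *every* genome is indistinguishable from an
ancestral chromosome without outgroup evidence; it is retained unsplit,
and this parsimony limit should be kept in mind when no outgroup is
available.

`project_karyotype()` partitions each extant chromosome into maximal runs
of anchors to a single (proto-chromosome, subgenome) combination — the
subgenome is part of the run key so that a fusion joining two copies of the
same proto-chromosome from different subgenomes still yields two segments.
Runs below `min_segment` (default 10 anchors) are treated as noise and
absorbed into their flanks. Within-segment order is deliberately ignored:
inversions and other intra-chromosomal rearrangements are outside the
event grammar.

`classify_rearrangements()` reads each chromosome's segment pattern. A
segment is a **full body** when it carries ≥ 80% of the anchors its
(proto, subgenome) combination has genome-wide; the threshold
operationalizes what is otherwise a visual dot-plot judgment, and 80%
leaves room for fractionation while rejecting translocated fragments.
Patterns map to events: donor-between-host-halves → NCF (resolved
outermost-in when fusions nest); adjacent full bodies → EEJ; reciprocal
terminal partials → one RT; a split body without partner exchange →
fission; anything else → COMPLEX, with its chromosome-number effect taken
from arithmetic so that bookkeeping stays exact. Compound rearrangements
that reuse the same chromosomes (an EEJ landing on a fresh RT product) are
genuinely ambiguous under any segment grammar and may be absorbed into a
single event of equal net effect — Σ delta_n is conserved even then.

`place_events_on_tree()` is Dollo-style: an event signature present in all
descendants of an edge arose once on that edge; identical breakpoints are
not assumed to recur. Signatures carried by an incomplete, non-clade set of
genomes stay on terminal edges.

## PPD indices and comparative statistics

The chromosome- and gene-level indices are

$$d_C = 1 - \frac{x}{N\,p}, \qquad d_G = 1 - \frac{g}{G\,p},$$

evaluated in exact arithmetic with full precision retained; a 2-decimal
value is attached for reporting, matching conventional precision. Negative
$d_C$ (ascending dysploidy) is allowed but flagged, since it most often
signals assembly artifacts rather than biology. Substitution rates are
$\mu = L/T$ with $T$ the crown age in My.

`pgls_fit()` implements generalized least squares with Pagel's λ scaling
the off-diagonal shared-path covariance. λ is either fixed or profiled by
maximum likelihood over a 1000-point logarithmic grid on $[10^{-6}, 1]$;
the lower bound is the optimizer floor conventionally reported as
"λ = 1e-6" in comparative analyses. R² is computed in the whitened space
against the GLS intercept-only model, and the slope p-value is a two-sided
t test. At the λ floor the fit reproduces OLS to numerical precision; at
λ = 1 it equals standard phylogenetic GLS (cross-checked against direct
matrix algebra and `nlme::gls` with `ape::corPagel`). Non-ultrametric trees
are accepted with a warning; a singular covariance is an error. Richness is
log-transformed before regression by default (config-switchable) — the
transform is recorded in pipeline output metadata because the choice is not
externally fixed.

Rank-sum comparisons (retention bias, expression bias) are two-sided and
unpaired, exact for group sizes ≤ 20 and normal-approximated with
continuity correction above that. Homoeolog expression shares are computed
within ancestral-locus groups and groups below `min_sum = 1` summed
expression are discarded before testing. The quartet screen counts the
three resolutions of a branch's induced quartet across gene trees and
flags q2-vs-q3 imbalance by a two-sided exact binomial test at α = 0.05 —
an explicit proxy for dedicated ILS/introgression indices, whose exact
formulas live in external tooling and are not reimplemented here.

## The simulator: what it emulates, and what it does not

`evolve()` walks a guide tree from an `ancestor_n`-chromosome ancestor
(default **11** proto-chromosomes, `genes_per_chromosome = 200`), replaying
scheduled events per branch: allopolyploid mergers (partner diploids at a
stated progenitor divergence), EEJ/NCF/RT/fission, and per-branch,
per-subgenome fractionation. Events are *scheduled*, not drawn from rates,
because the histories worth replaying are specific; unspecified positions
(an NCF insertion point, an EEJ partner) are drawn uniformly from the
seeded generator. Homology emission covers **all and only** pairs of
surviving copies of the same ancestral locus, with
`score = round(1000·exp(−ks))` plus bounded integer noise — monotone in
divergence so that near-best-hit orthology is meaningful.

Divergence between copies comes from an augmented genealogy: a subgenome
joining at divergence *d* is a ghost lineage attached to the receiving
lineage's root path *d/2* earlier (possibly before the root). Two copies'
ks is the sum of their path lengths below their split point, plus Gaussian
noise (`ks_noise_sd`, default 0.03). One modeling consequence: simulated
histories should place the outgroup split *deeper* than progenitor
divergences — the biologically realistic configuration — so that all
subgenomes are equidistant co-orthologs of the outgroup. Bundled scenarios
use progenitor divergences of 0.30–0.42 ks against outgroup splits near
1.0, matching the relative spacing of WGD and speciation peaks in real
paralog/ortholog Ks distributions.

Not emulated: nucleotide sequences, selection on gene content
(fractionation is independent per gene), tandem duplication, TE dynamics, and
inversions. Passing tests therefore demonstrate correct recovery of
inter-chromosomal structure and dosage under idealized homology — they do
not certify robustness to assembly error, annotation noise, or
translocation-rich histories, which real analyses must assess separately.

## Problem sizes and numerical conventions

Unit and property tests run on scaled genomes (3–8 chromosomes, 15–60
genes each) chosen so the whole suite exercises every code path in under a
minute; the validation scenarios behind the headline numbers use the full
11 × 200 ancestor. The PGLS recovery properties use 24-taxon coalescent
trees: profiling λ on much smaller trees is anticonservative (the
confidence interval undercovers), which is a known small-sample property of
the estimator, not an implementation artifact — the λ = 1 fixed-λ fit
covers nominally at any size. The dysploidy–richness end-to-end property
uses 7 clades with rates spread over [0.05, 0.8] and lognormal richness
noise (σ = 0.5) around an increasing trend — a signal strength comparable
to the tight chromosome-level correlations this analysis is designed to
detect.

Determinism: a single integer seed drives every stochastic stage; reruns
with an identical config are byte-identical (pipeline outputs embed the
config hash and seed in their headers). All tabular artifacts are TSV with
`#`-prefixed headers; trees are Newick round-tripped through `ape` at
6-decimal precision.

## Known limitations

* The proto-karyotype backbone inherits any assembly error of the chosen
  reference; suspicious fissions are reported, never auto-corrected.
* COMPLEX events are counted with arithmetic Δn but not interpreted;
  histories dominated by overlapping rearrangements need manual curation.
* The phasing polarity vote assumes discordance is symmetric between the
  candidate copies; systematic biased introgression into one copy could
  defeat it.
* `d_G` depends on a fixed ancestral gene count G; errors in G shift all
  gene-loss rates by the same factor rather than canceling.
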