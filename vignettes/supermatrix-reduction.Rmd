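---
title: "Reducing sparse supermatrices to selected optimal subsets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing sparse supermatrices to selected optimal subsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sosreduce)
```

## The problem

Phylogenomic supermatrices concatenate hundreds of gene alignments over a
taxon set, and in practice most taxon/gene cells are empty: data coverage of
published matrices runs as low as 8–15%. Heavy missingness can bias maximum
likelihood tree inference and destroy bootstrap support, so practitioners
routinely discard taxa and genes below ad hoc coverage cutoffs. Coverage
alone, however, says nothing about whether the retained genes carry
phylogenetic signal; a well-covered but conserved gene contributes little.
`sosreduce` implements a formal alternative: score every gene by a
quartet-based estimate of its *potential signal*, combine that score with
data coverage into a per-cell information content, and search for a
*selected optimal subset* (SOS) of taxa and genes by deterministic hill
climbing.

## Information content of genes, taxa and matrices

A supermatrix of $N$ taxa and $n$ genes is summarised by the binary coverage
matrix $B = (b_{ij})$, $b_{ij} = 1$ when taxon $i$ has sequence data for
gene $j$. A gene counts as present when its site range holds at least one
unambiguous residue; the threshold is configurable (`min_residues`), since
fragmentary sequences of a handful of residues arguably carry no usable
signal. The characters `-`, `?`, `X`, `x` and `*` are treated as non-data by
default.

Contents are plain means:

$$q_j = \frac{1}{N}\sum_i b_{ij}, \qquad
  p_i = \frac{1}{n}\sum_j b_{ij}, \qquad
  P(B) = \frac{1}{Nn}\sum_{ij} b_{ij},$$

so $P$ equals both the mean of the $q_j$ and the mean of the $p_i$ — an
identity the test suite asserts to $10^{-12}$. On the signal-weighted matrix
$B^*$ with entries $b_{ij}\,\hat t_j$ (below), the same formulas yield
signal-discounted contents.

## Potential signal by quartet geometry mapping

For every gene, taxon quartets are mapped onto the 2-simplex of relative
topology supports. Sequence dissimilarity uses BLOSUM62 scores $s(a,b)$
transformed to a proper distance, $m(a,b) = s(a,a) + s(b,b) - 2s(a,b)$
(symmetric, non-negative, zero diagonal; a max-score-minus-score transform
is available). The distance between two aligned sequences is the mean of
$m$ over columns where both carry residues, and the number of comparable
columns is tracked.

For a quartet $(1,2,3,4)$ the three pairing sums are
$S_1 = d(1,2)+d(3,4)$, $S_2 = d(1,3)+d(2,4)$, $S_3 = d(1,4)+d(2,3)$.
Supports are shortfalls from the worst pairing, $\delta_i = \max_j S_j -
S_i$, normalised to $s_i = \delta_i / \sum_k \delta_k$ — the four-point
condition in support form: on additive (tree-metric) data the true topology
gets all the weight. Quartets with all sums equal, or with any pair below
the comparable-site minimum (`min_sites`, default 1), sit at the centre
$(1/3, 1/3, 1/3)$.

The simplex is tiled into seven regions: corners $T_1, T_2, T_3$ (max
support $\ge 2/3$; resolved), the centre $T_\ast$ (max support $< 1/2$, the
inner triangle spanned by the edge midpoints; star-like), and otherwise the
edge region of the two largest supports ($T_{12}, T_{13}, T_{23}$; partly
resolved). Ties break toward lower indices, so the tiling is total and
deterministic.

Per gene, all quartets over its covered taxa are enumerated when
$\binom{N_g}{4}$ does not exceed the cap (default 20,000), otherwise that
many distinct quartets are sampled uniformly with a seeded generator and
rejection of duplicates. Two estimates come out of the region tally:

$$t_j = \frac{T_1+T_2+T_3}{k}, \qquad
  \hat t_j = 1 - \frac{T_\ast}{k},$$

the strict fraction of resolved quartets and the relaxed fraction of
at-least-partly-resolved quartets. By construction $t_j \le \hat t_j$.
Genes covered by fewer than four taxa cannot be quartet-mapped;
`gene_signal()` refuses them, and `gene_signal_table()` records
$\hat t = 0$ for them — consistent with their automatic elimination during
reduction.

**A property worth knowing.** Because the supports are scale-free
normalised shortfalls, one coordinate of $s$ is always zero, so
non-degenerate quartets always land in a corner or an edge region — never
in the centre. $T_\ast$ therefore collects only degenerate quartets (exact
ties, near-invariant sequences, incomparable pairs). The practical effect:
$\hat t$ is a *generous* estimator that penalises mainly invariant or
data-poor genes, while the strict $t$ responds to noise (i.i.d.-random
residues produce spuriously part-resolved edge quartets, dropping $t$ but
not necessarily $\hat t$). The original geometry-mapping support formula
is not recoverable from our sources and is a pluggable point; the
four-point construction used here is deterministic, reduces correctly on
additive data, and is the natural distance-based choice.

## Selecting the optimal subset

`reduce()` hill-climbs on $B$ or $B^*$ (the caller chooses by passing one
or the other; signal weights are **not** recalculated as taxa drop out —
the deliberate simplification that keeps the heuristic fast). Each step:

1. recompute $p_i$ and $q_j$ on the current submatrix;
2. the elimination candidate is the minimal-content taxon or gene; a gene
   wins gene-versus-taxon ties, input order breaks ties within a class;
3. after removal, genes left with fewer than four covered taxa are dropped
   automatically;
4. the step must strictly increase $P$ and must not worsen connectivity:
   a taxon *violates* when it shares a gene with fewer than three other
   taxa or retains fewer than two genes, and a candidate is accepted only
   if the number of violating taxa does not grow. Otherwise the next-best
   candidate (ascending content) is tried; when none is acceptable the
   trajectory ends.

On a clean matrix the connectivity rule is exactly "every taxon overlaps
three others and keeps two genes". Requiring *non-increase* rather than
absence of violations is a deliberate choice: empirically sparse matrices
— precisely the method's target — almost always contain single-gene taxa
at the outset, and a rule that rejects any step while violations persist
would leave them irreducible. Under the count rule the violations are
worked off (violating taxa have minimal content and fall early), and the
selected SOS in practice satisfies the full constraint. An input so sparse
that no step is acceptable at all is returned whole with a warning.

Each accepted step records $P$, the size ratio
$\lambda = (N'n')/(Nn) \in (0,1]$, and the optimality

$$f = 1 - \left|\lambda - g(P)\right|,$$

where the target term $g$ shrinks with the scaling factor $\alpha$
(default 3), so larger $\alpha$ lets $\lambda$ fall further before $f$
peaks — the optimum arrives later and favours a smaller subset with higher
$P$. Two forms of $g$ are provided:

* `form = "product"` (default): $g(P) = P^\alpha (1-P)$;
* `form = "ratio"`: $g(P) = P / (\alpha (1-P))$.

The algebra of the original optimality function is ambiguous in our
sources, so the form is a registered strategy rather than a constant. The
product form is the default because, under the reference power-law study
conditions (below), it places the optimum at SOS coverages several-fold
above the input — the documented behaviour of the approach — whereas the
ratio form stops markedly earlier, at optima whose coverage gain stays
under 3-fold. Both forms show the documented $\alpha$ effect (the
$\alpha = 3$ optimum is never earlier than the $\alpha = 2$ optimum; the
suite property-tests this on 100 random matrices). The product form is
continuous at $P = 1$ (where $g \to 0$, $f \to 1 - \lambda$); the ratio
form diverges there and is restricted to $P < 1$.

Because the steps are discrete, $f = 1$ is generally skipped rather than
hit; the procedure records the full trajectory and returns its *first
local maximum* of $f$ — the discrete analogue of stopping where the
optimality peaks, with plateaus resolving to their earliest step so that
the larger matrix wins. A global argmax would behave differently under
the product form: since $g \to 0$ as $P \to 1$, the tail of a trajectory
that shrinks to a near-complete block re-approaches $f = 1$ and would
often win, collapsing the SOS to a tiny complete submatrix; the
first-peak rule keeps the moderate-size optimum the stopping description
intends. The whole procedure is deterministic: identical inputs give
byte-identical trajectory reports.

`threshold_reduce()` provides the conventional baseline: keep genes at or
above a coverage cutoff, optionally after first filtering taxa by their
own cutoff (gene coverage is then recomputed over the surviving taxa).
Taxa listed as protected (`protected_taxa`, the "all-taxa constraint" use
case) are never candidates for elimination.

## The synthetic study designs

`simulate_study()` reproduces the reference simulation geometry: 50 taxa
$\times$ 50 genes of 400 amino acids each, concatenated to 20,000 aligned
sites per taxon. Its pieces, and the choices behind the defaults:

* **Sequence evolution** (`simulate_gene()`): root drawn from the model's
  stationary frequencies, sites evolved independently along the tree under
  a reversible 20-state Markov model; branch lengths are multiplied by the
  gene's relative rate, and site rates are homogeneous within a gene. The
  default model is Poisson (uniform exchangeabilities and frequencies);
  empirical matrices load from PAML-format rate files
  (`read_paml_model()`). The qualitative behaviour studied here — signal
  heterogeneity among genes — is driven by the rate spread, not the exact
  exchangeabilities.
* **Among-gene rate heterogeneity**: per-gene relative rates drawn
  log-uniformly from $[0.001, 15]$, the stated range of the reference
  design. The log-uniform draw spreads genes evenly across the
  near-invariant, informative and saturated regimes.
* **Tree**: a user-supplied newick, or a seeded birth–death tree rescaled
  to root-to-tip depth 0.4 expected substitutions per site — a mid-range
  divergence at which rate-1 genes are clearly informative and the rate
  extremes degrade realistically. `stress_branches()` optionally
  multiplies a chosen number of branches (default 7) to provoke
  long-branch effects.
* **Bernoulli missingness**: each cell independently retained with
  probability `retain_prob`. The reference description pairs a retention
  probability of 0.7 with an average coverage of 0.29; the two numbers are
  mutually inconsistent, so the probability is left as a free parameter
  rather than silently "corrected".
* **Power-law missingness**: each cell's retention probability is drawn as
  $f(x) = 0.1\,x^{-1/2} - 0.1$ with $x \sim \mathrm{Uniform}(0,1]$,
  clamped to $[0,1]$ (the stated domain "$0 \le x \le \infty$" is not a
  proper uniform; the clamped draw has analytic mean $1/11 \approx
  0.091$). Every taxon is guaranteed at least one gene, and four
  designated "genome" taxa use a fixed retention probability instead. The
  magnitude of that boost is unstated in the reference; the default 0.7
  yields mean pattern coverage $\approx 0.14$, matching the reported 0.13
  within Monte-Carlo and specification error.

What the simulator does **not** emulate: insertions/deletions and
alignment error, among-site rate variation within genes, compositional
heterogeneity, correlated (clade-structured) missingness, and real
branch-length distributions. Tests passing on these synthetics show that
the machinery behaves as designed under controlled signal and coverage
regimes; they do not certify performance on any particular empirical
matrix.

## Tree comparison metrics

`quartet_distance()` restricts two trees to their shared leaves and
compares the induced topology of every 4-subset; the standardized distance
$d_{QD}$ is the differing fraction of all $\binom{\text{shared}}{4}$
quartets. Induced topologies are read off the four-point condition on
unit-branch-length path distances; a quartet crossing a polytomy has no
strict minimum and counts as unresolved. Matching is strict: two
unresolved quartets agree, resolved-versus-unresolved disagree — so a star
tree is at distance 1 from any resolved tree. Plain $O(\binom{N}{4})$
enumeration is the implementation; at $N = 50$ that is 230,300 quartets
and well under a second, so no sub-quadratic algorithm is warranted.

`resolution_score()` summarises support as
$RS = \sum \{s : s \ge 50\} / (N-3)$ over the internal-branch bootstrap
values, the cutoff being inclusive. It errors when the tree carries no
numeric supports.

## Numerical and degenerate-input conventions

* Simplex points are validated to $\sum s_i = 1$ within $10^{-9}$;
  region classification uses exact comparisons on the normalised values.
* $\hat t$ is computed as $(k - T_\ast)/k$ so that the identity
  $t \le \hat t$ holds exactly in floating point.
* Quartets with any pair sharing zero comparable columns (or fewer than
  `min_sites`) are star-like by convention.
* A fully covered matrix ($P = 1$) admits no elimination and is returned
  as step 0.
* Partition coordinates are 1-based inclusive in files (RAxML convention)
  and kept 1-based inclusive internally, matching R's string indexing.
* Empty kept-sets, overlapping or gapped partitions, unequal sequence
  lengths and duplicate labels raise errors naming the offending record.

## Problem sizes used by the test suite

The packaged checks run the full pipeline at the reference matrix geometry
(50 × 50 × 400 aa) over 20 replicates with the quartet cap at 2,000, plus
100-replicate calibrations of the pattern generators, 200 random tree
pairs against a brute-force quartet-distance oracle, and 50 random
matrices against an independent greedy-replay oracle of the reduction.
These sizes keep the whole suite in the minutes range on a single core
while leaving the estimators' Monte-Carlo error well inside the asserted
tolerances.

## Known limitations

* The hill climb is greedy and deterministic; it makes no claim of global
  optimality over taxon/gene subsets, and equally optimal alternative
  subsets are not enumerated.
* $\hat t$ does not penalise i.i.d. noise (see the boundary-point property
  above); under long-branch conditions distance-based quartet mapping can
  confidently support the wrong topology, inflating $\hat t$. No
  correction is applied.
* Signal weights are frozen at the start of reduction; iterative
  recalculation might select better subsets at higher cost.
* ML tree inference itself is out of scope: the package prepares reduced
  matrices (FASTA + charsets) for external programs and evaluates their
  output trees, nothing more.
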