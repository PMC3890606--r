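# sosreduce

Reduction of sparse phylogenomic supermatrices to **selected optimal
subsets** (SOS) of taxa and genes, combining data coverage with a
quartet-based estimate of per-gene phylogenetic signal.

Concatenated multi-gene alignments routinely have 70–90% of their
taxon×gene cells empty, which degrades the accuracy and robustness of
maximum-likelihood tree inference. The common remedy — discarding taxa and
genes below arbitrary coverage cutoffs — ignores whether the retained genes
actually carry signal. `sosreduce` replaces the cutoffs with a formal
optimisation, for anyone assembling phylogenomic matrices who wants a
defensible, reproducible reduction step before tree inference.

## The model

A supermatrix of *N* taxa and *n* genes is summarised by its coverage
matrix *B* = (*b<sub>ij</sub>*), *b<sub>ij</sub>* ∈ {0, 1}. Information
contents are means of *B*:

> q<sub>j</sub> = Σ<sub>i</sub> b<sub>ij</sub> / N,
> p<sub>i</sub> = Σ<sub>j</sub> b<sub>ij</sub> / n,
> P(B) = Σ<sub>ij</sub> b<sub>ij</sub> / (N·n).

Each gene's potential signal t̂<sub>j</sub> is estimated by geometry
mapping: up to 20,000 taxon quartets are drawn, each quartet's three
topology supports (from BLOSUM62-derived distances and the four-point
condition) are placed on the support simplex, and t̂<sub>j</sub> is the
fraction of quartets falling outside the star-like central region. Scaling
the columns of *B* by t̂ gives the weighted matrix *B\**, whose contents
combine coverage with signal.

A deterministic hill climb then eliminates, step by step, the taxon or gene
with the lowest content (gene on ties; genes left with <4 taxa drop
automatically; connectivity of the matrix is monitored), recording the
information content *P*, the size ratio λ = (N′n′)/(Nn), and the optimality

> f = 1 − |λ − g(P)|,  g(P) = P<sup>α</sup>(1 − P) (default, α = 3)

The SOS is the trajectory step at the first peak of *f*: larger α pushes
the optimum later, trading more taxa/genes for higher information content.
Companion tools simulate sparse supermatrices (sequence evolution along a
tree with among-gene rate heterogeneity; Bernoulli and power-law
missing-data regimes), and score trees by standardized quartet distance
d<sub>QD</sub> and the resolution score RS = Σ{support ≥ 50}/(N−3).

## Worked example

Simulate one replicate of the reference study design (50 taxa × 50 genes ×
400 aa, power-law missingness with four high-coverage taxa), estimate
signal, and reduce the weighted matrix:

```r
library(sosreduce)

design <- sim_design(n_replicates = 1, seed = 42)
study  <- simulate_study(design)
sm     <- study$replicates[[1]]$supermatrix
sm
#> Supermatrix: 50 taxa x 50 genes, 20000 aligned sites

b <- presence_matrix(sm)
b
#> Unweighted coverage matrix: 50 taxa x 50 genes, P = 0.1348

sig <- gene_signal_table(sm, max_quartets = 2000, seed = 42)
head(sig[, c("gene", "n_taxa", "k", "t_strict", "t_hat")], 4)
#>      gene n_taxa   k  t_strict     t_hat
#> 1 gene001     10 210 0.9095238 1.0000000
#> 2 gene002      7  35 0.6000000 0.6857143
#> 3 gene003      4   1 1.0000000 1.0000000
#> 4 gene004      8  70 0.8857143 1.0000000

bstar <- weight_matrix(b, sig)
sos   <- reduce(bstar, alpha = 3)
sos
#> SOS reduction (weighted matrix, alpha = 3)
#>   input : 50 taxa x 50 genes, P = 0.1017
#>   SOS   : 8 taxa x 19 genes, P = 0.5217 (step 47 of 53, f = 0.9929)
```

The input matrix holds data in 13.5% of its cells (weighted content
P = 0.10 after discounting by signal). The selected subset of 8 taxa and
19 genes raises coverage to 0.546 — a four-fold enrichment — at the first
peak of the optimality trade-off between matrix size and content:

```r
matrix_content(subset_coverage(b, sos$kept_taxa, sos$kept_genes))
#> [1] 0.5460526
write_reduced(sm, sos$kept_taxa, sos$kept_genes, "sos")   # FASTA + charsets
```

`plot(sos)` draws P, λ and f against the elimination step. Tree evaluation
works the same way from R or the CLI:

```r
tr <- ape::read.tree(text = "((A:1,B:1)95:0.2,((C:1,D:1)88:0.1,E:1)60:0.1,F:1);")
resolution_score(tr)
#> [1] 81
```

A command-line wrapper with subcommands `reduce`, `threshold`, `simulate`,
`compare` and `signal` is installed at `inst/cli/sosreduce`
(`sosreduce reduce --alignment aln.fas --partitions parts.txt --seed 1`).

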