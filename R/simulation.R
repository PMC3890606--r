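#' Reversible amino-acid substitution model
#'
#' Builds a time-reversible 20-state Markov model from an exchangeability
#' matrix and stationary frequencies, normalised so one time unit equals one
#' expected substitution per site. The default is the Poisson model (uniform
#' exchangeabilities and frequencies); empirical matrices (WAG, LG, ...)
#' can be loaded from PAML-format rate files with
#' \code{\link{read_paml_model}}.
#'
#' @param exchangeabilities symmetric 20 x 20 matrix of relative rates
#'   (diagonal ignored), or NULL for uniform.
#' @param freqs stationary frequencies summing to 1, or NULL for uniform.
#' @return object of class \code{aa_model} with the eigendecomposition used
#'   to compute transition matrices.
#' @export
aa_model <- function(exchangeabilities = NULL, freqs = NULL) {
  k <- length(.aa_alphabet)
  if (is.null(exchangeabilities))
    exchangeabilities <- matrix(1, k, k)
  if (is.null(freqs)) freqs <- rep(1 / k, k)
  if (abs(sum(freqs) - 1) > 1e-8) stop("frequencies must sum to 1")
  R <- (exchangeabilities + t(exchangeabilities)) / 2
  Q <- R %*% diag(freqs)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))        # expected substitutions per unit time
  Q <- Q / mu
  # reversible Q symmetrised by sqrt(pi) for a stable eigendecomposition
  sp <- sqrt(freqs)
  Sym <- diag(sp) %*% Q %*% diag(1 / sp)
  e <- eigen((Sym + t(Sym)) / 2, symmetric = TRUE)
  structure(list(freqs = freqs, values = e$values,
                 U = diag(1 / sp) %*% e$vectors,
                 Uinv = t(e$vectors) %*% diag(sp)),
            class = "aa_model")
}

# Transition probability matrix P(t) = U exp(L t) U^-1.
.transition_matrix <- function(model, t) {
  P <- model$U %*% (exp(model$values * t) * model$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Load a PAML-format amino-acid rate file
#'
#' Parses the standard PAML .dat layout: the lower triangle of the
#' exchangeability matrix (19 rows) followed by 20 stationary frequencies,
#' in the PAML amino-acid order (A R N D C Q E G H I L K M F P S T W Y V).
#'
#' @param path path to the rate file.
#' @return an \code{\link{aa_model}}.
#' @export
read_paml_model <- function(path) {
  nums <- scan(path, what = numeric(), quiet = TRUE, comment.char = "#")
  need <- 190L + 20L
  if (length(nums) < need)
    stop("expected at least ", need, " numbers (lower triangle + frequencies)")
  R <- matrix(0, 20, 20)
  R[lower.tri(R)] <- nums[1:190]
  R <- R + t(R)
  freqs <- nums[191:210]
  aa_model(R, freqs / sum(freqs))
}

#' Simulate one gene alignment along a tree
#'
#' Draws a root sequence from the model's stationary frequencies and evolves
#' it site-independently along the tree, with every branch length multiplied
#' by the gene's relative rate. Site rates are homogeneous within the gene.
#'
#' @param tree a \code{phylo} with branch lengths (expected substitutions per
#'   site at rate 1).
#' @param n_sites number of sites.
#' @param rate relative rate multiplier (> 0).
#' @param model an \code{\link{aa_model}}.
#' @param seed RNG seed (NULL uses the current RNG state).
#' @return named character vector: one aligned residue string per leaf.
#' @export
simulate_gene <- function(tree, n_sites, rate = 1, model = aa_model(),
                          seed = NULL) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (rate <= 0) stop("rate must be > 0")
  .with_seed(seed, {
    tree <- stats::reorder(tree, "cladewise")
    n_tip <- length(tree$tip.label)
    n_node <- tree$Nnode
    states <- matrix(NA_integer_, n_tip + n_node, n_sites)
    root <- n_tip + 1L
    states[root, ] <- sample.int(20L, n_sites, replace = TRUE,
                                 prob = model$freqs)
    for (ei in seq_len(nrow(tree$edge))) {
      par <- tree$edge[ei, 1L]; child <- tree$edge[ei, 2L]
      P <- .transition_matrix(model, tree$edge.length[ei] * rate)
      ps <- states[par, ]
      cs <- integer(n_sites)
      for (s in unique(ps)) {
        idx <- which(ps == s)
        cs[idx] <- sample.int(20L, length(idx), replace = TRUE,
                              prob = P[s, ])
      }
      states[child, ] <- cs
    }
    seqs <- apply(states[seq_len(n_tip), , drop = FALSE], 1L,
                  function(z) paste(.aa_alphabet[z], collapse = ""))
    names(seqs) <- tree$tip.label
    seqs
  })
}

#' Bernoulli (random) missing-data pattern
#'
#' Each taxon/gene cell independently retains data with probability
#' \code{retain_prob}.
#'
#' @param n_taxa,n_genes matrix dimensions.
#' @param retain_prob probability of retaining a cell, in (0, 1].
#' @param seed RNG seed.
#' @param taxa,genes optional dimension labels.
#' @return an unweighted \code{\link{coverage_matrix}} pattern.
#' @export
apply_bernoulli_missingness <- function(n_taxa, n_genes, retain_prob,
                                        seed = NULL,
                                        taxa = paste0("t", seq_len(n_taxa)),
                                        genes = paste0("g", seq_len(n_genes))) {
  if (retain_prob <= 0 || retain_prob > 1) stop("retain_prob must lie in (0, 1]")
  m <- .with_seed(seed, matrix(
    as.integer(stats::runif(n_taxa * n_genes) < retain_prob),
    n_taxa, n_genes))
  dimnames(m) <- list(taxa, genes)
  coverage_matrix(m, weighted = FALSE)
}

#' Power-law (non-random) missing-data pattern
#'
#' Emulates the strongly skewed coverage of empirical supermatrices: each
#' cell's retention probability is drawn as f(x) = 0.1 x^(-1/2) - 0.1 with
#' x ~ Uniform(0, 1], clamped to [0, 1] (analytic mean coverage 1/11, about
#' 0.091). Every taxon is guaranteed at least one gene, and a designated set
#' of high-coverage taxa (genome taxa) uses the fixed retention probability
#' \code{boost_prob} instead.
#'
#' @inheritParams apply_bernoulli_missingness
#' @param boosted_taxa indices or labels of the high-coverage taxa
#'   (default none).
#' @param boost_prob retention probability for boosted taxa (default 0.7).
#' @return an unweighted \code{\link{coverage_matrix}} pattern.
#' @export
apply_powerlaw_missingness <- function(n_taxa, n_genes,
                                       boosted_taxa = integer(0),
                                       boost_prob = 0.7, seed = NULL,
                                       taxa = paste0("t", seq_len(n_taxa)),
                                       genes = paste0("g", seq_len(n_genes))) {
  if (is.character(boosted_taxa)) boosted_taxa <- match(boosted_taxa, taxa)
  if (anyNA(boosted_taxa) || any(boosted_taxa < 1 | boosted_taxa > n_taxa))
    stop("boosted_taxa must identify taxa of the matrix")
  .with_seed(seed, {
    x <- stats::runif(n_taxa * n_genes)
    x[x == 0] <- .Machine$double.eps
    prob <- pmin(pmax(0.1 * x^(-0.5) - 0.1, 0), 1)
    dim(prob) <- c(n_taxa, n_genes)
    if (length(boosted_taxa)) prob[boosted_taxa, ] <- boost_prob
    m <- matrix(as.integer(stats::runif(n_taxa * n_genes) <
                             prob), n_taxa, n_genes)
    empty <- which(rowSums(m) == 0L)
    for (i in empty) m[i, sample.int(n_genes, 1L)] <- 1L
    dimnames(m) <- list(taxa, genes)
    coverage_matrix(m, weighted = FALSE)
  })
}

#' Random birth-death tree scaled to a given depth
#'
#' @param n_taxa number of leaves.
#' @param depth root-to-tip height in expected substitutions per site.
#' @param seed RNG seed.
#' @param birth,death birth and death rates of the generating process.
#' @return a \code{phylo} with branch lengths.
#' @export
random_phylo <- function(n_taxa, depth = 0.4, seed = NULL,
                         birth = 1, death = 0) {
  .with_seed(seed, {
    tr <- ape::rphylo(n_taxa, birth = birth, death = death)
    h <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * (depth / h)
    tr
  })
}

#' Lengthen a set of branches to stress long-branch attraction
#'
#' Multiplies the lengths of \code{k} randomly chosen branches by
#' \code{factor}, mimicking simulation designs that modify a handful of
#' branches to provoke long-branch artefacts.
#'
#' @param tree a \code{phylo} with branch lengths.
#' @param k number of branches to lengthen (default 7).
#' @param factor multiplier (default 5).
#' @param seed RNG seed.
#' @return the modified tree.
#' @export
stress_branches <- function(tree, k = 7L, factor = 5, seed = NULL) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  .with_seed(seed, {
    idx <- sample.int(nrow(tree$edge), min(k, nrow(tree$edge)))
    tree$edge.length[idx] <- tree$edge.length[idx] * factor
    tree
  })
}

#' Simulation design for sparse-supermatrix studies
#'
#' Defines the study conditions for \code{\link{simulate_study}}: a tree, the
#' matrix dimensions, gene length, among-gene rate heterogeneity and a
#' missing-data regime. Defaults follow the reference design: 50 taxa x 50
#' genes of 400 amino acids (20,000 aligned sites), per-gene relative rates
#' drawn log-uniformly between 0.001 and 15, and power-law non-random
#' missingness with four boosted high-coverage taxa.
#'
#' @param n_taxa,n_genes,gene_length matrix dimensions and sites per gene.
#' @param tree a \code{phylo} with branch lengths, or NULL for a seeded
#'   birth-death tree of depth \code{tree_depth}.
#' @param tree_depth root-to-tip height used when \code{tree} is NULL.
#' @param rates per-gene relative rates, or NULL to draw them log-uniformly
#'   from \code{rate_range}.
#' @param rate_range range of among-gene relative rates.
#' @param missingness \code{"powerlaw"} or \code{"bernoulli"}.
#' @param retain_prob Bernoulli retention probability.
#' @param boosted_taxa,boost_prob power-law high-coverage taxa (indices) and
#'   their retention probability.
#' @param model an \code{\link{aa_model}}.
#' @param n_replicates replicate count.
#' @param seed master seed; all per-replicate and per-gene seeds derive from
#'   it.
#' @return object of class \code{sim_design}.
#' @export
sim_design <- function(n_taxa = 50L, n_genes = 50L, gene_length = 400L,
                       tree = NULL, tree_depth = 0.4,
                       rates = NULL, rate_range = c(0.001, 15),
                       missingness = c("powerlaw", "bernoulli"),
                       retain_prob = 0.7,
                       boosted_taxa = 1:4, boost_prob = 0.7,
                       model = aa_model(), n_replicates = 1L, seed = NULL) {
  missingness <- match.arg(missingness)
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (!is.null(rates)) {
    if (length(rates) != n_genes) stop("need one rate per gene")
    if (any(rates <= 0)) stop("rates must be > 0")
  }
  structure(list(n_taxa = n_taxa, n_genes = n_genes,
                 gene_length = gene_length, tree = tree,
                 tree_depth = tree_depth, rates = rates,
                 rate_range = rate_range, missingness = missingness,
                 retain_prob = retain_prob, boosted_taxa = boosted_taxa,
                 boost_prob = boost_prob, model = model,
                 n_replicates = n_replicates, seed = seed),
            class = "sim_design")
}

#' Simulate a replicate bundle of sparse supermatrices
#'
#' For each replicate: simulates every gene along the design tree with its
#' relative rate, concatenates the genes (taxon-wise) to the full alignment,
#' draws a missing-data pattern and blanks absent taxon/gene blocks to
#' \code{'-'}. Optionally writes FASTA + charset + newick files per
#' replicate and a seed manifest.
#'
#' @param design a \code{\link{sim_design}}.
#' @param out_dir optional directory for on-disk output.
#' @return list with \code{tree}, \code{rates}, \code{manifest} (data frame
#'   of per-replicate seeds) and \code{replicates}, each holding
#'   \code{supermatrix} (a \code{\link{supermatrix}}), \code{pattern} (the
#'   realized \code{\link{coverage_matrix}}) and \code{coverage}.
#' @export
simulate_study <- function(design, out_dir = NULL) {
  d <- design
  seeds <- .with_seed(d$seed, matrix(
    sample.int(.Machine$integer.max, d$n_replicates * (d$n_genes + 1L)),
    nrow = d$n_replicates))
  tree <- d$tree
  if (is.null(tree))
    tree <- random_phylo(d$n_taxa,
                         depth = d$tree_depth,
                         seed = if (is.null(d$seed)) NULL else d$seed + 1L)
  if (length(tree$tip.label) != d$n_taxa)
    stop("tree has ", length(tree$tip.label), " leaves, design says ", d$n_taxa)
  rates <- d$rates
  if (is.null(rates))
    rates <- .with_seed(if (is.null(d$seed)) NULL else d$seed + 2L,
      exp(stats::runif(d$n_genes, log(d$rate_range[1L]),
                       log(d$rate_range[2L]))))
  taxa <- tree$tip.label
  genes <- sprintf("gene%03d", seq_len(d$n_genes))
  parts <- data.frame(gene = genes,
                      start = seq(1L, by = d$gene_length, length.out = d$n_genes),
                      end = seq_len(d$n_genes) * d$gene_length,
                      stringsAsFactors = FALSE)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reps <- vector("list", d$n_replicates)
  for (r in seq_len(d$n_replicates)) {
    blocks <- lapply(seq_len(d$n_genes), function(j)
      simulate_gene(tree, d$gene_length, rates[j], d$model,
                    seed = seeds[r, j])[taxa])
    pat <- switch(d$missingness,
      bernoulli = apply_bernoulli_missingness(
        d$n_taxa, d$n_genes, d$retain_prob,
        seed = seeds[r, d$n_genes + 1L], taxa = taxa, genes = genes),
      powerlaw = apply_powerlaw_missingness(
        d$n_taxa, d$n_genes, d$boosted_taxa, d$boost_prob,
        seed = seeds[r, d$n_genes + 1L], taxa = taxa, genes = genes))
    gap <- strrep("-", d$gene_length)
    for (j in seq_len(d$n_genes))
      blocks[[j]][pat$entries[, j] == 0] <- gap
    seqs <- do.call(paste0, blocks)
    names(seqs) <- taxa
    sm <- supermatrix(seqs, parts)
    reps[[r]] <- list(supermatrix = sm, pattern = pat,
                      coverage = matrix_content(pat))
    if (!is.null(out_dir)) {
      prefix <- file.path(out_dir, sprintf("rep%03d", r))
      write_reduced(sm, taxa, genes, prefix)
    }
  }
  manifest <- data.frame(replicate = seq_len(d$n_replicates),
                         pattern_seed = seeds[, d$n_genes + 1L],
                         coverage = vapply(reps, `[[`, numeric(1), "coverage"))
  if (!is.null(out_dir)) {
    write_phylo_tree(tree, file.path(out_dir, "true_tree.nwk"))
    utils::write.table(cbind(manifest,
                             as.data.frame(seeds[, seq_len(d$n_genes), drop = FALSE])),
                       file.path(out_dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(tree = tree, rates = rates, manifest = manifest, replicates = reps)
}
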