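test_that("BLOSUM62 dissimilarity is a proper distance table", {
  w <- blosum62_dissimilarity()
  expect_equal(dim(w), c(20L, 20L))
  expect_true(all(diag(w) == 0))
  expect_equal(unclass(w), t(unclass(w)), ignore_attr = TRUE)
  expect_true(all(w >= 0))
  # hand computation from the published scores: s(A,A)=4, s(R,R)=5, s(A,R)=-1
  expect_equal(w["A", "R"], 4 + 5 - 2 * (-1))
  w2 <- blosum62_dissimilarity("max_minus_score")
  expect_true(all(diag(w2) == 0))
  expect_true(all(w2 >= 0))
})

test_that("pairwise distance averages over comparable columns only", {
  w <- blosum62_dissimilarity()
  s <- random_seqs(1, 50, seed = 21)[[1]]
  expect_equal(pairwise_distance(s, s, w), list(distance = 0,
                                                comparable_sites = 50L))
  gap <- strrep("-", 50)
  expect_equal(pairwise_distance(gap, s, w),
               list(distance = NA_real_, comparable_sites = 0L))
  expect_equal(pairwise_distance("AR", "RA", w)$distance, 11)
  # gapped columns are excluded from the mean
  expect_equal(pairwise_distance("AR-D", "RA-D", w),
               list(distance = mean(c(11, 11, 0)), comparable_sites = 3L))
  expect_error(pairwise_distance("AR", "ARN", w), "equal length")
})

test_that("simplex classification tiles all regions deterministically", {
  expect_equal(classify_region(c(1, 0, 0)), "T1")
  expect_equal(classify_region(c(0, 1, 0)), "T2")
  expect_equal(classify_region(c(1, 1, 1) / 3), "Tstar")
  expect_equal(classify_region(c(0.6, 0.35, 0.05)), "T12")
  expect_equal(classify_region(c(0.05, 0.6, 0.35)), "T23")
  expect_equal(classify_region(c(0.35, 0.05, 0.6)), "T13")
  expect_equal(classify_region(c(2, 1, 0) / 3), "T1")  # corner boundary
  expect_equal(classify_region(c(0.49, 0.31, 0.20)), "Tstar")
  expect_equal(classify_region(c(0.5, 0.25, 0.25)), "T12")  # tie -> lower pair
  # scalar rule and vectorised rule agree on random simplex points
  set.seed(22)
  s <- matrix(rexp(3 * 500), ncol = 3)
  s <- s / rowSums(s)
  vec <- sosreduce:::.classify_regions(s)
  scl <- apply(s, 1, classify_region)
  expect_equal(vec, scl)
})

test_that("quartet support resolves clean splits and flags star quartets", {
  w <- blosum62_dissimilarity()
  # four identical sequences: degenerate star point
  qs <- quartet_support(rep(strrep("A", 30), 4), w)
  expect_equal(qs$s, rep(1 / 3, 3))
  expect_equal(qs$region, "Tstar")
  # clean (12|34) split: two identical pairs far apart
  qs2 <- quartet_support(c(strrep("A", 30), strrep("A", 30),
                           strrep("W", 30), strrep("W", 30)), w)
  expect_equal(qs2$s, c(1, 0, 0))
  expect_equal(qs2$region, "T1")
  # any pair with no comparable sites counts as star-like
  qs3 <- quartet_support(c(strrep("A", 30), strrep("-", 30),
                           strrep("W", 30), strrep("W", 30)), w)
  expect_equal(qs3$region, "Tstar")
})

test_that("gene signal separates identical-sequence and tree-like genes", {
  # all covered taxa identical: every quartet is star-like
  flat <- supermatrix(stats::setNames(rep(strrep("A", 30), 6),
                                      paste0("t", 1:6)),
                      data.frame(gene = "g1", start = 1L, end = 30L))
  gs <- gene_signal(flat, "g1")
  expect_equal(gs$k, choose(6, 4))
  expect_equal(gs$t_hat, 0)
  expect_equal(gs$t_strict, 0)
  # perfectly structured gene: every quartet lands in a corner
  tl <- treelike_supermatrix(8)
  gs2 <- gene_signal(tl, "g1")
  expect_equal(gs2$k, choose(8, 4))
  expect_equal(gs2$t_hat, 1)
  expect_equal(sum(gs2$tallies), gs2$k)
  expect_true(all(gs2$tallies[c("T12", "T13", "T23", "Tstar")] == 0))
  # fewer than 4 covered taxa is an error telling the caller to drop the gene
  small <- supermatrix(c(a = "AAAA", b = "AAAA", c = "AAAA", d = "----"),
                       data.frame(gene = "g1", start = 1L, end = 4L))
  expect_error(gene_signal(small, "g1"), "drop")
})

test_that("t_strict never exceeds t_hat and tallies account for every quartet", {
  set.seed(23)
  sm <- supermatrix(random_seqs(7, 60, seed = 23),
                    data.frame(gene = c("g1", "g2"), start = c(1L, 31L),
                               end = c(30L, 60L)))
  for (g in c("g1", "g2")) {
    gs <- gene_signal(sm, g)
    expect_equal(sum(gs$tallies), gs$k)
    expect_lte(gs$t_strict, gs$t_hat)
    expect_gte(gs$t_hat, 0); expect_lte(gs$t_hat, 1)
  }
})

test_that("signal is invariant under taxon reordering in census mode", {
  seqs <- simulate_gene(random_phylo(7, depth = 0.5, seed = 24), 80,
                        rate = 1, seed = 25)
  parts <- data.frame(gene = "g1", start = 1L, end = 80L)
  sm <- supermatrix(seqs, parts)
  smp <- supermatrix(seqs[sample(7)], parts)
  a <- gene_signal(smp, "g1"); b <- gene_signal(sm, "g1")
  expect_equal(a$t_hat, b$t_hat)
  expect_equal(a$t_strict, b$t_strict)
  # per-corner tallies permute with the taxa, but their sums do not
  expect_equal(sum(a$tallies[1:3]), sum(b$tallies[1:3]))
  expect_equal(a$tallies[["Tstar"]], b$tallies[["Tstar"]])
})

test_that("quartet sampling is seeded, duplication-free and census-consistent", {
  seqs <- simulate_gene(random_phylo(20, depth = 0.5, seed = 26), 100,
                        rate = 1, seed = 27)
  sm <- supermatrix(seqs, data.frame(gene = "g1", start = 1L, end = 100L))
  # census when the cap equals the quartet count
  census <- gene_signal(sm, "g1", max_quartets = choose(20, 4))
  expect_equal(census$k, choose(20, 4))
  # sampled runs: reproducible for a seed, k distinct quartets
  s1 <- gene_signal(sm, "g1", max_quartets = 1500, seed = 7)
  s2 <- gene_signal(sm, "g1", max_quartets = 1500, seed = 7)
  expect_identical(s1$tallies, s2$tallies)
  expect_equal(s1$k, 1500L)
  # across seeds the estimator tracks the census value (binomial error);
  # sd of t_hat at k=1500 is <= 0.013, so 5 sd ~ 0.065
  s3 <- gene_signal(sm, "g1", max_quartets = 1500, seed = 8)
  expect_lt(abs(s1$t_hat - census$t_hat), 0.065)
  expect_lt(abs(s3$t_hat - census$t_hat), 0.065)
})

test_that("random residues degrade signal relative to tree-like data", {
  # the additive-line gene resolves every quartet into a corner; i.i.d.
  # noise produces spuriously part-resolved (edge) quartets instead, so the
  # strict signal drops while the relaxed estimate can only stay or fall
  tl <- treelike_supermatrix(10)
  noise <- random_seqs(10, 50, seed = 30)
  names(noise) <- tl$taxa
  parts <- data.frame(gene = "g1", start = 1L, end = 50L)
  good <- gene_signal(tl, "g1")
  rand <- gene_signal(supermatrix(noise, parts), "g1")
  expect_lt(rand$t_strict, good$t_strict)
  expect_lte(rand$t_hat, good$t_hat)
})

test_that("the signal table covers every gene and flags unmappable ones", {
  sm <- tiny_supermatrix()  # both genes have 3 covered taxa: unmappable
  tab <- gene_signal_table(sm, seed = 31)
  expect_equal(tab$gene, c("g1", "g2"))
  expect_equal(tab$t_hat, c(0, 0))
  expect_equal(tab$k, c(0L, 0L))
  tl <- treelike_supermatrix(8)
  tab2 <- gene_signal_table(tl, seed = 32)
  expect_equal(tab2$t_hat, 1)
  expect_equal(tab2$n_taxa, 8)
})
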