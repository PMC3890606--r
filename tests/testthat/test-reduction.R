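test_that("optimality arithmetic matches both target forms", {
  # ratio form: P=0.5, lam=1, alpha=2 -> target 0.5/(2*0.5)=0.5, f=0.5
  expect_equal(optimality(0.5, 1, 2, form = "ratio"), 0.5)
  # f = 1 exactly where lambda meets the target term
  expect_equal(optimality(0.5, 0.5 / (2 * 0.5), 2, form = "ratio"), 1)
  expect_equal(optimality(0.4, 0.4^3 * 0.6, 3, form = "product"), 1)
  # product form arithmetic
  expect_equal(optimality(0.5, 1, 2, form = "product"),
               1 - abs(1 - 0.25 * 0.5))
  # domain checks: the ratio target diverges at P = 1, the product form
  # is continuous there
  expect_error(optimality(1, 0.5, 3, form = "ratio"), "P < 1")
  expect_equal(optimality(1, 0.5, 3, form = "product"), 0.5)
  expect_error(optimality(0.5, 0, 3), "lam")
  # larger alpha moves the f=1 crossing to smaller lambda (for both forms)
  lam_grid <- seq(0.01, 1, by = 0.01)
  for (form in c("product", "ratio")) {
    for (P in c(0.2, 0.5, 0.8)) {
      best2 <- lam_grid[which.max(optimality(P, lam_grid, 2, form))]
      best3 <- lam_grid[which.max(optimality(P, lam_grid, 3, form))]
      expect_lte(best3, best2)
    }
  }
})

test_that("a data-free taxon is eliminated first", {
  m <- rbind(matrix(1, 5, 4), 0)
  rownames(m) <- paste0("t", 1:6); colnames(m) <- paste0("g", 1:4)
  red <- reduce(coverage_matrix(m))
  expect_equal(red$trajectory$action[2], "drop_taxon")
  expect_equal(red$trajectory$label[2], "t6")
  expect_equal(red$kept_taxa, paste0("t", 1:5))
})

test_that("a fully populated matrix is returned untouched", {
  full <- coverage_matrix(matrix(1, 6, 5))
  red <- reduce(full)
  expect_equal(nrow(red$trajectory), 1L)
  expect_equal(red$opt_step, 0L)
  expect_equal(red$kept_taxa, rownames(as.matrix(full)))
  expect_equal(red$kept_genes, colnames(as.matrix(full)))
})

test_that("reduction agrees exactly with the greedy-replay oracle", {
  set.seed(41)
  for (i in 1:25) {
    pat <- random_pattern(10, 8, p = runif(1, 0.35, 0.8))
    red <- suppressWarnings(reduce(pat, alpha = 3))
    orc <- oracle_reduce(pat, alpha = 3, form = "product")
    expect_equal(red$trajectory$P, orc$P)
    expect_equal(red$trajectory$lambda, orc$lambda)
    expect_equal(red$opt_step, orc$opt_step)
    expect_equal(red$kept_taxa, orc$kept_taxa)
    expect_equal(red$kept_genes, orc$kept_genes)
  }
})

test_that("P rises and lambda falls strictly along every trajectory", {
  set.seed(42)
  for (i in 1:30) {
    pat <- random_pattern(12, 9, p = runif(1, 0.3, 0.8))
    red <- suppressWarnings(reduce(pat))
    tr <- red$trajectory
    if (nrow(tr) > 1) {
      expect_true(all(diff(tr$P) > 0))
      expect_true(all(diff(tr$lambda) < 0))
    }
    expect_equal(tr$lambda[1], 1)
  }
})

test_that("reduction is deterministic down to the written report", {
  pat <- random_pattern(15, 12, p = 0.45, seed = 43)
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.tsv"); f2 <- file.path(dir, "b.tsv")
  write_trajectory(reduce(pat), f1)
  write_trajectory(reduce(pat), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("protected taxa survive every reduction", {
  set.seed(44)
  for (i in 1:10) {
    pat <- random_pattern(10, 8, p = runif(1, 0.35, 0.7))
    prot <- sample(rownames(as.matrix(pat)), 3)
    red <- suppressWarnings(reduce(pat, protected_taxa = prot))
    expect_true(all(prot %in% red$kept_taxa))
    for (st in red$steps) expect_true(all(prot %in% st$taxa))
  }
  # with every taxon protected only genes are eliminated
  pat <- random_pattern(8, 10, p = 0.5, seed = 45)
  red <- suppressWarnings(reduce(pat,
    protected_taxa = rownames(as.matrix(pat))))
  expect_true(all(red$trajectory$action[-1] == "drop_gene"))
  expect_equal(red$trajectory$n_taxa,
               rep(8L, nrow(red$trajectory)))
})

test_that("genes covered by fewer than four taxa are dropped automatically", {
  # g5 is held by exactly 4 taxa incl. t1; dropping t1 must remove g5 too
  m <- matrix(1, 8, 5)
  m[5:8, 5] <- 0
  m[1, 1:4] <- 0   # t1 has only g5 -> minimal content, dropped first
  dimnames(m) <- list(paste0("t", 1:8), paste0("g", 1:5))
  red <- suppressWarnings(reduce(coverage_matrix(m)))
  tr <- red$trajectory
  expect_equal(tr$label[2], "t1")
  expect_equal(tr$auto_dropped[2], "g5")
  expect_equal(tr$n_genes[2], 4L)
})

test_that("sparse inputs reduce and connectivity violations never multiply", {
  for (i in 1:6) {
    pat <- apply_powerlaw_missingness(50, 50, boosted_taxa = 1:4,
                                      seed = 460 + i)
    red <- suppressWarnings(reduce(pat))
    expect_gt(nrow(red$trajectory), 1)  # reduction does proceed
    B <- as.matrix(pat)
    prev <- length(sosreduce:::.violating_taxa(B))
    for (st in red$steps[-1]) {
      cur <- length(sosreduce:::.violating_taxa(
        B[st$taxa, st$genes, drop = FALSE]))
      expect_lte(cur, prev)
      prev <- cur
    }
    # the selected SOS itself satisfies the constraint
    expect_length(sosreduce:::.violating_taxa(
      B[red$kept_taxa, red$kept_genes, drop = FALSE]), 0)
  }
})

test_that("an input too sparse to reduce is returned whole with a warning", {
  # nearly empty matrix: any elimination would strand taxa, so the
  # procedure records the violation and keeps the input
  m <- diag(1, 8, 8)
  dimnames(m) <- list(paste0("t", 1:8), paste0("g", 1:8))
  expect_warning(red <- reduce(coverage_matrix(m)), "connectivity")
  expect_equal(nrow(red$trajectory), 1L)
  expect_equal(red$kept_taxa, paste0("t", 1:8))
})

test_that("threshold reduction matches brute-force set selection", {
  cm <- content_matrix()
  # zero threshold keeps everything
  kept <- threshold_reduce(cm, 0)
  expect_equal(kept$kept_taxa, rownames(as.matrix(cm)))
  expect_equal(kept$kept_genes, colnames(as.matrix(cm)))
  # every gene has q = 0.75 < 0.8: empty result is an error
  expect_error(threshold_reduce(cm, 0.8), "every gene")
  # two-stage filter equals direct recomputation on a 6x4 fixture
  pat <- random_pattern(6, 4, p = 0.5, seed = 47)
  m <- as.matrix(pat)
  got <- threshold_reduce(pat, min_gene_cov = 0.5, min_taxon_cov = 0.3)
  taxa_bf <- rownames(m)[rowMeans(m) >= 0.3]
  genes_bf <- colnames(m)[colMeans(m[taxa_bf, , drop = FALSE]) >= 0.5]
  expect_equal(got$kept_taxa, taxa_bf)
  expect_equal(got$kept_genes, genes_bf)
})

test_that("reduction scales to study-sized matrices in seconds", {
  pat <- apply_powerlaw_missingness(60, 60, boosted_taxa = 1:4, seed = 48)
  elapsed <- system.time(reduce(pat))[["elapsed"]]
  expect_lt(elapsed, 30)
})
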