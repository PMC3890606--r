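# Shared fixtures, built in code at test time.

# A 4-taxon, 2-gene supermatrix (genes 4 sites each) with mixed missingness.
tiny_supermatrix <- function() {
  seqs <- c(ta = "ARNDARND",
            tb = "ARND----",
            tc = "----ARND",
            td = "A---AR-D")
  supermatrix(seqs, data.frame(gene = c("g1", "g2"),
                               start = c(1L, 5L), end = c(4L, 8L)))
}

# The 4 x 3 presence matrix used in the content worked examples.
content_matrix <- function() {
  m <- rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  dimnames(m) <- list(paste0("t", 1:4), paste0("g", 1:3))
  coverage_matrix(m)
}

# Write a FASTA + charset fixture pair; returns the two paths.
write_fixture_pair <- function(seqs, parts, dir = NULL) {
  if (is.null(dir)) dir <- withr::local_tempdir(.local_envir = parent.frame())
  if (missing(parts))
    parts <- data.frame(gene = c("g1", "g2"), start = c(1L, 401L),
                        end = c(400L, 800L))
  fas <- file.path(dir, "aln.fas")
  cs <- file.path(dir, "parts.txt")
  writeLines(paste0(">", names(seqs), "\n", seqs), fas)
  writeLines(sprintf("%s = %d-%d", parts$gene, parts$start, parts$end), cs)
  c(alignment = fas, partitions = cs)
}

# Random aligned residue strings (uniform over the 20 amino acids).
random_seqs <- function(n_taxa, n_sites, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  stats::setNames(
    vapply(seq_len(n_taxa), function(i)
      paste(sample(aa, n_sites, replace = TRUE), collapse = ""),
      character(1)),
    paste0("t", seq_len(n_taxa)))
}

# A supermatrix whose gene distances are additive on a line (caterpillar):
# taxon i carries i mutated blocks, so d(i, j) is proportional to |i - j|
# and every quartet resolves cleanly to the (i j | k l) corner.
treelike_supermatrix <- function(n_taxa = 8, block = 5) {
  n_sites <- block * n_taxa
  seqs <- vapply(seq_len(n_taxa), function(i)
    paste0(strrep("W", block * i), strrep("A", n_sites - block * i)),
    character(1))
  names(seqs) <- paste0("t", seq_len(n_taxa))
  supermatrix(seqs, data.frame(gene = "g1", start = 1L, end = n_sites))
}

# Random 0/1 coverage matrix that satisfies the initial connectivity
# constraint (retried until legal enough to reduce).
random_pattern <- function(n_taxa, n_genes, p = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    m <- matrix(rbinom(n_taxa * n_genes, 1, p), n_taxa, n_genes)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
      dimnames(m) <- list(paste0("t", seq_len(n_taxa)),
                          paste0("g", seq_len(n_genes)))
      return(coverage_matrix(m))
    }
  }
}
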