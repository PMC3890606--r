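# Independent oracles used by the equivalence tests. These deliberately
# re-derive results with different machinery than the package internals.

# Quartet topology of 4 tips in a tree, by pruning with ape and inspecting
# the cherry structure: returns 0 (unresolved) or the pairing index of the
# tip pairing {q1,q2}|{q3,q4} (1), {q1,q3}|{q2,q4} (2), {q1,q4}|{q2,q3} (3).
oracle_quartet_topology <- function(tree, tips) {
  tr <- ape::unroot(ape::keep.tip(tree, tips))
  if (tr$Nnode < 2L) return(0L)  # star quartet
  tipidx <- match(tips, tr$tip.label)
  parents <- tr$edge[match(tipidx, tr$edge[, 2L]), 1L]
  partner <- which(parents == parents[1L])  # tips sharing tip 1's parent
  partner <- setdiff(partner, 1L)
  if (length(partner) != 1L) return(0L)
  c(`2` = 1L, `3` = 2L, `4` = 3L)[[as.character(partner)]]
}

# Brute-force standardized quartet distance over all shared 4-subsets.
oracle_quartet_distance <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  qs <- utils::combn(shared, 4L)
  diff <- 0L
  for (i in seq_len(ncol(qs))) {
    a <- oracle_quartet_topology(t1, qs[, i])
    b <- oracle_quartet_topology(t2, qs[, i])
    if (a != b) diff <- diff + 1L
  }
  diff / ncol(qs)
}

# Greedy-replay oracle for the hill-climbing reduction: re-derives every
# elimination step and the optimum with plain loops, independent of the
# package implementation.
oracle_reduce <- function(pat, alpha = 3, form = "product") {
  B <- as.matrix(pat)
  N0 <- nrow(B); n0 <- ncol(B)
  violators <- function(M) {
    out <- character(0)
    for (i in seq_len(nrow(M))) {
      genes_i <- which(M[i, ] > 0)
      partners <- 0L
      for (i2 in seq_len(nrow(M))) {
        if (i2 == i) next
        if (any(M[i2, genes_i] > 0)) partners <- partners + 1L
      }
      if (length(genes_i) < 2L || partners < 3L)
        out <- c(out, rownames(M)[i])
    }
    out
  }
  target <- function(P) if (form == "product") P^alpha * (1 - P)
    else P / (alpha * (1 - P))
  cur_t <- rownames(B); cur_g <- colnames(B)
  P_hist <- mean(B); lam_hist <- 1
  sets <- list(list(taxa = cur_t, genes = cur_g))
  repeat {
    M <- B[cur_t, cur_g, drop = FALSE]
    P <- mean(M)
    if (P >= 1) break
    # candidate list: (content, is_taxon, input order); genes first on ties
    cand <- list()
    for (j in seq_along(cur_g))
      cand[[length(cand) + 1L]] <- list(lab = cur_g[j], taxon = FALSE,
                                        cont = mean(M[, j]), ord = j)
    for (i in seq_along(cur_t))
      cand[[length(cand) + 1L]] <- list(lab = cur_t[i], taxon = TRUE,
                                        cont = mean(M[i, ]), ord = i)
    cand <- cand[order(sapply(cand, `[[`, "cont"),
                       sapply(cand, `[[`, "taxon"),
                       sapply(cand, `[[`, "ord"))]
    done <- FALSE
    for (c0 in cand) {
      tt <- if (c0$taxon) setdiff(cur_t, c0$lab) else cur_t
      gg <- if (c0$taxon) cur_g else setdiff(cur_g, c0$lab)
      if (!length(tt) || !length(gg)) next
      M2 <- B[tt, gg, drop = FALSE]
      keep <- colSums(M2 > 0) >= 4
      gg <- gg[keep]
      if (!length(gg)) next
      M2 <- B[tt, gg, drop = FALSE]
      if (length(violators(M2)) > length(violators(M))) next
      if (mean(M2) <= P) next
      cur_t <- tt; cur_g <- gg
      P_hist <- c(P_hist, mean(M2))
      lam_hist <- c(lam_hist, length(tt) * length(gg) / (N0 * n0))
      sets[[length(sets) + 1L]] <- list(taxa = cur_t, genes = cur_g)
      done <- TRUE
      break
    }
    if (!done) break
  }
  f <- ifelse(P_hist < 1 | form == "product",
              1 - abs(lam_hist - target(P_hist)), NA_real_)
  # earliest local maximum (first non-increase stops the climb)
  opt <- length(f)
  for (i in seq_len(length(f) - 1L)) {
    if (is.na(f[i + 1L]) || f[i + 1L] <= f[i]) { opt <- i; break }
  }
  list(P = P_hist, lambda = lam_hist, f = f, opt_step = opt - 1L,
       kept_taxa = sets[[opt]]$taxa, kept_genes = sets[[opt]]$genes)
}
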