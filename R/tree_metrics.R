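#' Standardized quartet distance between two trees
#'
#' Restricts both trees to their shared leaves and compares the induced
#' topology of every 4-leaf subset; the distance is the fraction of quartets
#' whose topologies differ, out of all choose(shared, 4) quartets. The
#' induced quartet topology is read off the four-point condition on
#' topological (unit-branch-length) path distances: the pairing with the
#' strictly smallest path-length sum is the quartet's split; if no strict
#' minimum exists (the quartet passes through a polytomy) the quartet is
#' unresolved. Two unresolved quartets agree; a resolved quartet never
#' matches an unresolved one.
#'
#' @param t1,t2 \code{phylo} objects sharing at least 4 leaf labels.
#' @return list with \code{d_QD} (fraction in [0, 1]), \code{shared_taxa}
#'   and \code{n_quartets}.
#' @export
quartet_distance <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  ns <- length(shared)
  if (ns < 4L) stop("trees share only ", ns, " taxa (need >= 4)")
  top <- function(tr) {
    tr <- ape::keep.tip(tr, shared)
    tr$edge.length <- rep(1, nrow(tr$edge))
    D <- stats::cophenetic(tr)[shared, shared]
    D
  }
  D1 <- top(t1); D2 <- top(t2)
  qs <- t(utils::combn(ns, 4L))
  resolved_split <- function(D) {
    ix <- function(a, b) D[qs[, c(a, b), drop = FALSE]]
    S <- cbind(ix(1, 2) + ix(3, 4), ix(1, 3) + ix(2, 4), ix(1, 4) + ix(2, 3))
    mn <- pmin(S[, 1L], S[, 2L], S[, 3L])
    nmin <- (S[, 1L] == mn) + (S[, 2L] == mn) + (S[, 3L] == mn)
    split <- max.col(-S, ties.method = "first")
    split[nmin != 1L] <- 0L  # unresolved
    split
  }
  r1 <- resolved_split(D1); r2 <- resolved_split(D2)
  list(d_QD = mean(r1 != r2), shared_taxa = ns, n_quartets = nrow(qs))
}

#' Resolution score of a tree with bootstrap supports
#'
#' Summarises tree robustness as the sum of internal-branch support values
#' at or above \code{threshold}, divided by N - 3 (the number of internal
#' branches of an unrooted binary N-leaf tree).
#'
#' @param tree a \code{phylo} whose internal node labels carry percent
#'   bootstrap supports.
#' @param threshold inclusive support cutoff (default 50).
#' @return the resolution score (percent scale).
#' @export
resolution_score <- function(tree, threshold = 50) {
  n <- ape::Ntip(tree)
  if (n < 4L) stop("need at least 4 taxa")
  s <- tree_supports(tree)
  if (!length(s)) stop("tree has no numeric support values")
  if (any(s < 0 | s > 100)) stop("support values must lie in [0, 100]")
  sum(s[s >= threshold]) / (n - 3)
}
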