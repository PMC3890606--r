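#' Optimality of a reduction step
#'
#' Trades matrix information content P against the size ratio lambda of the
#' reduced matrix: f = 1 - |lambda - g(P)|, defined for P < 1, where g is a
#' target term that shrinks as alpha grows, so that larger alpha lets lambda
#' fall further before f peaks — the optimum is reached later and favours a
#' subset with higher P. Two target forms are provided:
#' \describe{
#'   \item{\code{"product"} (default)}{g(P) = P^alpha * (1 - P). This is
#'     the form used by \code{\link{reduce}}; on sparse power-law matrices
#'     it places the optimum at strongly enriched submatrices (several-fold
#'     coverage gain).}
#'   \item{\code{"ratio"}}{g(P) = P / (alpha * (1 - P)), an alternative
#'     reading that favours earlier (larger, sparser) optima.}
#' }
#' f reaches its maximum of 1 where the shrinking lambda meets g(P).
#'
#' @param P matrix information content, in [0, 1).
#' @param lam size ratio (N' n') / (N n), in (0, 1].
#' @param alpha scaling factor (> 0); default 3.
#' @param form target-term form, \code{"product"} or \code{"ratio"}.
#' @return the optimality value f (<= 1). Vectorised over \code{P} and
#'   \code{lam}. The ratio form is undefined at P = 1 (its target diverges)
#'   and raises an error there; the product form is continuous on [0, 1].
#' @export
optimality <- function(P, lam, alpha = 3, form = c("product", "ratio")) {
  form <- match.arg(form)
  if (form == "ratio" && any(P >= 1))
    stop("the ratio form is defined only for P < 1")
  if (any(P > 1)) stop("optimality is defined only for P < 1")
  if (any(P < 0) || any(lam <= 0) || any(lam > 1) || alpha <= 0)
    stop("require 0 <= P <= 1, 0 < lam <= 1, alpha > 0")
  target <- switch(form,
                   product = P^alpha * (1 - P),
                   ratio = P / (alpha * (1 - P)))
  1 - abs(lam - target)
}

# Present-taxon count per gene column (an entry > 0 means data present,
# whether or not the matrix is signal-weighted).
.genes_under_4 <- function(entries) which(colSums(entries > 0) < 4L)

# Earliest local maximum of the optimality sequence: the discrete analogue
# of stopping at the first f = 1 crossing. Plateaus resolve to their first
# step (favouring the larger matrix); NA entries terminate the climb.
.first_peak <- function(f) {
  if (all(is.na(f))) return(1L)
  for (i in seq_len(length(f) - 1L)) {
    if (is.na(f[i])) next
    nxt <- f[i + 1L]
    if (is.na(nxt) || nxt <= f[i]) return(i)
  }
  length(f)
}

# Taxa violating the connectivity constraint: fewer than `min_genes` genes,
# or sharing >= 1 gene with fewer than `min_overlap` other taxa.
.violating_taxa <- function(entries, min_overlap = 3L, min_genes = 2L) {
  bp <- entries > 0
  few_genes <- rowSums(bp) < min_genes
  overlap <- tcrossprod(bp) > 0
  few_overlap <- (rowSums(overlap) - 1L) < min_overlap
  rownames(entries)[few_genes | few_overlap]
}

#' Hill-climbing selection of an optimal taxon/gene subset (SOS)
#'
#' Starting from the full coverage matrix (B or its signal-weighted form B*),
#' repeatedly eliminates the taxon or gene with the lowest information
#' content (p_i or q_j recomputed on the current submatrix). Gene-versus-
#' taxon ties drop the gene; ties within a class drop the first in input
#' order. After each elimination, genes left with fewer than four covered
#' taxa are dropped automatically, and the candidate is rejected — moving on
#' to the next-lowest-content candidate — unless the resulting submatrix
#' strictly increases P and does not worsen connectivity: a taxon violates
#' the connectivity constraint when it shares a gene with fewer than
#' \code{min_overlap} other taxa or holds fewer than \code{min_genes}
#' genes, and a candidate is legal only if the number of violating taxa
#' does not grow (so a clean matrix stays clean, while violations present
#' in a sparse input are worked off rather than blocking reduction). Each accepted step records the matrix
#' content P, the size ratio lambda and the optimality f; the procedure is
#' fully deterministic. Per-gene signal weights are not recalculated during
#' reduction. The full trajectory is recorded, and the returned subset is
#' its first local maximum of f — the discrete analogue of stopping where
#' the optimality crosses its peak; on plateaus the earliest step wins,
#' favouring the larger matrix.
#'
#' @param cm a \code{\link{coverage_matrix}} (weighted or unweighted).
#' @param alpha scaling factor of the optimality function (default 3).
#' @param protected_taxa taxon labels that must never be eliminated.
#' @param min_overlap,min_genes connectivity constraint (defaults 3 and 2).
#' @param form optimality target form passed to \code{\link{optimality}}.
#' @return object of class \code{sos_reduction}: list with
#'   \code{trajectory} (data frame: step, action, label, n_taxa, n_genes,
#'   P, lambda, f), \code{steps} (surviving label sets per step),
#'   \code{opt_step}, \code{kept_taxa}, \code{kept_genes}, \code{alpha},
#'   \code{weighted}, \code{input_dim}.
#' @export
reduce <- function(cm, alpha = 3, protected_taxa = character(),
                   min_overlap = 3L, min_genes = 2L,
                   form = c("product", "ratio")) {
  form <- match.arg(form)
  B <- cm$entries
  taxa0 <- rownames(B); genes0 <- colnames(B)
  if (length(bad <- setdiff(protected_taxa, taxa0)))
    stop("protected taxa not in matrix: ", paste(bad, collapse = ", "))
  N0 <- nrow(B); n0 <- ncol(B)
  cur_t <- taxa0; cur_g <- genes0

  P0 <- mean(B)
  traj <- data.frame(step = 0L, action = "initial", label = NA_character_,
                     auto_dropped = "",
                     n_taxa = N0, n_genes = n0, P = P0, lambda = 1,
                     f = if (P0 < 1 || form == "product")
                       optimality(P0, 1, alpha, form) else NA_real_,
                     stringsAsFactors = FALSE)
  steps <- list(list(taxa = cur_t, genes = cur_g))
  warned <- NULL

  viol0 <- .violating_taxa(B, min_overlap, min_genes)
  if (P0 < 1) {
    repeat {
      sub <- B[cur_t, cur_g, drop = FALSE]
      P <- mean(sub)
      if (P >= 1) break
      p <- rowMeans(sub); q <- colMeans(sub)
      unprot <- !(cur_t %in% protected_taxa)
      cand <- data.frame(
        label = c(cur_g, cur_t[unprot]),
        type = c(rep("gene", length(cur_g)), rep("taxon", sum(unprot))),
        content = c(q, p[unprot]),
        ord = c(seq_along(cur_g), which(unprot)),
        stringsAsFactors = FALSE)
      # lowest content first; gene beats taxon on ties; then input order
      cand <- cand[order(cand$content, cand$type != "gene", cand$ord), ]
      cur_viol <- .violating_taxa(sub, min_overlap, min_genes)
      accepted <- FALSE
      for (ci in seq_len(nrow(cand))) {
        if (cand$type[ci] == "taxon") {
          new_t <- setdiff(cur_t, cand$label[ci]); new_g <- cur_g
        } else {
          new_t <- cur_t; new_g <- setdiff(cur_g, cand$label[ci])
        }
        if (!length(new_t) || !length(new_g)) next
        sub2 <- B[new_t, new_g, drop = FALSE]
        auto <- .genes_under_4(sub2)
        if (length(auto)) {
          new_g <- new_g[-auto]
          if (!length(new_g)) next
          sub2 <- B[new_t, new_g, drop = FALSE]
        }
        if (length(.violating_taxa(sub2, min_overlap, min_genes)) >
              length(cur_viol)) next
        P2 <- mean(sub2)
        if (P2 <= P) next
        lam <- (length(new_t) * length(new_g)) / (N0 * n0)
        auto_lab <- if (length(auto)) paste(setdiff(
          setdiff(cur_g, cand$label[ci]), new_g), collapse = ",") else ""
        traj <- rbind(traj, data.frame(
          step = nrow(traj), action = paste0("drop_", cand$type[ci]),
          label = cand$label[ci], auto_dropped = auto_lab,
          n_taxa = length(new_t),
          n_genes = length(new_g), P = P2, lambda = lam,
          f = if (P2 < 1 || form == "product")
            optimality(P2, lam, alpha, form) else NA_real_,
          stringsAsFactors = FALSE))
        steps[[length(steps) + 1L]] <- list(taxa = new_t, genes = new_g)
        cur_t <- new_t; cur_g <- new_g
        accepted <- TRUE
        break
      }
      if (!accepted) break
    }
  }

  if (nrow(traj) == 1L && length(viol0)) {
    warned <- "input matrix violates the minimal connectivity constraint and admits no legal elimination; returned unreduced"
    warning(warned)
  }
  opt <- .first_peak(traj$f)
  structure(list(trajectory = traj, steps = steps, opt_step = opt - 1L,
                 kept_taxa = steps[[opt]]$taxa,
                 kept_genes = steps[[opt]]$genes,
                 alpha = alpha, form = form, weighted = cm$weighted,
                 input_dim = c(N0, n0), warning = warned),
            class = "sos_reduction")
}

#' @export
print.sos_reduction <- function(x, ...) {
  tr <- x$trajectory
  opt <- x$opt_step + 1L
  cat(sprintf("SOS reduction (%s matrix, alpha = %g)\n",
              if (x$weighted) "weighted" else "unweighted", x$alpha))
  cat(sprintf("  input : %d taxa x %d genes, P = %.4f\n",
              x$input_dim[1L], x$input_dim[2L], tr$P[1L]))
  cat(sprintf("  SOS   : %d taxa x %d genes, P = %.4f (step %d of %d, f = %.4f)\n",
              length(x$kept_taxa), length(x$kept_genes), tr$P[opt],
              x$opt_step, nrow(tr) - 1L, tr$f[opt]))
  if (!is.null(x$warning)) cat("  note  :", x$warning, "\n")
  invisible(x)
}

#' @method summary sos_reduction
#' @export
summary.sos_reduction <- function(object, ...) {
  tr <- object$trajectory
  dropped_t <- setdiff(object$steps[[1L]]$taxa, object$kept_taxa)
  dropped_g <- setdiff(object$steps[[1L]]$genes, object$kept_genes)
  out <- list(trajectory = tr, opt_step = object$opt_step,
              kept_taxa = object$kept_taxa, kept_genes = object$kept_genes,
              dropped_taxa = dropped_t, dropped_genes = dropped_g,
              P_gain = tr$P[object$opt_step + 1L] / tr$P[1L])
  class(out) <- "summary.sos_reduction"
  out
}

#' @export
print.summary.sos_reduction <- function(x, ...) {
  cat(sprintf("Optimal step %d: kept %d taxa, %d genes; P gain %.2f-fold\n",
              x$opt_step, length(x$kept_taxa), length(x$kept_genes),
              x$P_gain))
  cat("Dropped taxa:", if (length(x$dropped_taxa))
    paste(x$dropped_taxa, collapse = ", ") else "(none)", "\n")
  cat("Dropped genes:", if (length(x$dropped_genes))
    paste(x$dropped_genes, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Plot a reduction trajectory
#'
#' Draws P (rising), lambda (falling) and f against elimination step, with
#' the selected optimum marked.
#'
#' @param x an \code{\link{sos_reduction}}.
#' @param ... passed to \code{matplot}.
#' @method plot sos_reduction
#' @export
plot.sos_reduction <- function(x, ...) {
  tr <- x$trajectory
  graphics::matplot(tr$step, cbind(tr$P, tr$lambda, tr$f), type = "l",
                    lty = c(1, 1, 2), lwd = c(2, 2, 1),
                    col = c("grey40", "black", "steelblue"),
                    xlab = "elimination step", ylab = "value", ...)
  graphics::abline(v = x$opt_step, col = "red", lty = 3)
  graphics::legend("right", c("P", "lambda", "f", "optimum"),
                   lty = c(1, 1, 2, 3), lwd = c(2, 2, 1, 1),
                   col = c("grey40", "black", "steelblue", "red"),
                   bty = "n")
  invisible(x)
}

#' Threshold-based baseline reduction
#'
#' The conventional alternative to hill climbing: keep genes whose data
#' coverage meets \code{min_gene_cov}; if \code{min_taxon_cov} is given,
#' first keep taxa whose coverage meets it, then filter genes by coverage
#' recomputed over the surviving taxa.
#'
#' @param cm a \code{\link{coverage_matrix}}.
#' @param min_gene_cov minimum per-gene coverage, in [0, 1].
#' @param min_taxon_cov optional minimum per-taxon coverage.
#' @return list with \code{kept_taxa} and \code{kept_genes}.
#' @export
threshold_reduce <- function(cm, min_gene_cov, min_taxon_cov = NULL) {
  if (min_gene_cov < 0 || min_gene_cov > 1) stop("thresholds must lie in [0, 1]")
  entries <- cm$entries
  kept_taxa <- rownames(entries)
  if (!is.null(min_taxon_cov)) {
    if (min_taxon_cov < 0 || min_taxon_cov > 1) stop("thresholds must lie in [0, 1]")
    kept_taxa <- kept_taxa[rowMeans(entries) >= min_taxon_cov]
    if (!length(kept_taxa)) stop("taxon threshold removed every taxon")
    entries <- entries[kept_taxa, , drop = FALSE]
  }
  kept_genes <- colnames(entries)[colMeans(entries) >= min_gene_cov]
  if (!length(kept_genes)) stop("gene threshold removed every gene")
  list(kept_taxa = kept_taxa, kept_genes = kept_genes)
}

#' Write a reduction trajectory report
#'
#' @param red an \code{\link{sos_reduction}}.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
write_trajectory <- function(red, path) {
  utils::write.table(red$trajectory, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
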