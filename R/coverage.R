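#' Data-coverage representation matrix
#'
#' The coverage matrix B of an N-taxon, n-gene supermatrix holds one entry
#' per taxon/gene cell: 1 (present) or 0 (absent) in the unweighted form, or
#' the gene's potential-signal estimate t-hat in the weighted form B*
#' (entry b_ij * t_hat_j).
#'
#' @param entries numeric N x n matrix with taxon rownames and gene colnames;
#'   values in [0, 1]. Unweighted matrices may contain only 0 and 1.
#' @param weighted logical; \code{TRUE} iff entries were scaled by t-hat.
#' @return an object of class \code{coverage_matrix}.
#' @export
coverage_matrix <- function(entries, weighted = FALSE) {
  entries <- as.matrix(entries)
  if (!nrow(entries) || !ncol(entries)) stop("empty coverage matrix")
  if (is.null(rownames(entries)))
    rownames(entries) <- paste0("t", seq_len(nrow(entries)))
  if (is.null(colnames(entries)))
    colnames(entries) <- paste0("g", seq_len(ncol(entries)))
  storage.mode(entries) <- "double"
  if (any(entries < 0 | entries > 1))
    stop("coverage entries must lie in [0, 1]")
  if (!weighted && !all(entries %in% c(0, 1)))
    stop("unweighted coverage matrices may contain only 0 and 1")
  structure(list(entries = entries, weighted = isTRUE(weighted)),
            class = "coverage_matrix")
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf("%s coverage matrix: %d taxa x %d genes, P = %.4f\n",
              if (x$weighted) "Weighted" else "Unweighted",
              nrow(x$entries), ncol(x$entries), matrix_content(x)))
  invisible(x)
}

#' @export
dim.coverage_matrix <- function(x) dim(x$entries)

#' @method as.matrix coverage_matrix
#' @export
as.matrix.coverage_matrix <- function(x, ...) x$entries

#' Per-gene, per-taxon and whole-matrix information content
#'
#' For an unweighted matrix these are plain data-coverage fractions: the
#' information content of gene j is q_j = sum_i b_ij / N, of taxon i is
#' p_i = sum_j b_ij / n, and of the matrix is P = sum_ij b_ij / (N n).
#' On a weighted matrix B* the same formulas give coverage scaled by
#' potential signal.
#'
#' @param cm a \code{\link{coverage_matrix}}.
#' @return \code{gene_content}: named numeric vector q (length n);
#'   \code{taxon_content}: named numeric vector p (length N);
#'   \code{matrix_content}: scalar P. All lie in [0, 1], and
#'   \code{mean(q) == mean(p) == P}.
#' @export
gene_content <- function(cm) colMeans(cm$entries)

#' @rdname gene_content
#' @export
taxon_content <- function(cm) rowMeans(cm$entries)

#' @rdname gene_content
#' @export
matrix_content <- function(cm) mean(cm$entries)

#' Scale a presence matrix by per-gene potential signal
#'
#' Builds the weighted coverage matrix B* with entries b_ij * t_hat_j.
#'
#' @param b an unweighted \code{\link{coverage_matrix}}.
#' @param signal per-gene t-hat values: a numeric vector (one per gene, in
#'   gene order or named by gene), or a signal table as returned by
#'   \code{\link{gene_signal_table}}.
#' @return a weighted \code{\link{coverage_matrix}}; \code{b} is unchanged.
#' @export
weight_matrix <- function(b, signal) {
  if (b$weighted) stop("input matrix is already weighted")
  if (is.data.frame(signal)) {
    t_hat <- signal$t_hat
    names(t_hat) <- signal$gene
  } else t_hat <- signal
  genes <- colnames(b$entries)
  if (!is.null(names(t_hat))) {
    if (!all(genes %in% names(t_hat)))
      stop("signal missing for gene(s): ",
           paste(setdiff(genes, names(t_hat)), collapse = ", "))
    t_hat <- t_hat[genes]
  } else if (length(t_hat) != length(genes)) {
    stop("signal length ", length(t_hat), " does not match gene count ",
         length(genes))
  }
  if (anyNA(t_hat) || any(t_hat < 0 | t_hat > 1))
    stop("t-hat values must lie in [0, 1]")
  coverage_matrix(sweep(b$entries, 2L, t_hat, `*`), weighted = TRUE)
}

#' Restrict a coverage matrix to a taxon/gene subset
#'
#' @param cm a \code{\link{coverage_matrix}}.
#' @param taxa,genes labels (or indices) to keep.
#' @return the induced \code{\link{coverage_matrix}}.
#' @export
subset_coverage <- function(cm, taxa = rownames(cm$entries),
                            genes = colnames(cm$entries)) {
  coverage_matrix(cm$entries[taxa, genes, drop = FALSE],
                  weighted = cm$weighted)
}

#' Export a coverage matrix and its content summaries
#'
#' Writes tab-separated files: the matrix itself, per-gene content q,
#' per-taxon content p, and the scalar P.
#'
#' @param cm a \code{\link{coverage_matrix}}.
#' @param out_prefix path prefix for \code{<prefix>_matrix.tsv},
#'   \code{<prefix>_gene_content.tsv}, \code{<prefix>_taxon_content.tsv},
#'   \code{<prefix>_summary.tsv}.
#' @return invisibly, the paths written.
#' @export
write_coverage_report <- function(cm, out_prefix) {
  paths <- paste0(out_prefix, c("_matrix.tsv", "_gene_content.tsv",
                                "_taxon_content.tsv", "_summary.tsv"))
  utils::write.table(cm$entries, paths[1L], sep = "\t", quote = FALSE,
                     col.names = NA)
  q <- gene_content(cm); p <- taxon_content(cm)
  utils::write.table(data.frame(gene = names(q), q = q), paths[2L],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(taxon = names(p), p = p), paths[3L],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(N = nrow(cm$entries), n = ncol(cm$entries),
                                weighted = cm$weighted,
                                P = matrix_content(cm)),
                     paths[4L], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
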