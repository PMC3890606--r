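.aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' BLOSUM62-derived residue dissimilarity matrix
#'
#' Transforms the BLOSUM62 substitution scores s(a, b) into a symmetric,
#' non-negative dissimilarity with zero diagonal. The default transform is
#' m(a, b) = s(a, a) + s(b, b) - 2 s(a, b); the alternative
#' \code{"max_minus_score"} uses m(a, b) = max(s) - s(a, b) off the diagonal.
#'
#' @param transform which score-to-distance transform to apply.
#' @return 20 x 20 numeric matrix over the standard amino acids, of class
#'   \code{residue_weight_matrix}.
#' @export
blosum62_dissimilarity <- function(transform = c("squared_diff", "max_minus_score")) {
  transform <- match.arg(transform)
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  s <- env$BLOSUM62[.aa_alphabet, .aa_alphabet]
  m <- switch(transform,
    squared_diff = outer(diag(s), diag(s), `+`) - 2 * s,
    max_minus_score = {
      mm <- max(s) - s
      diag(mm) <- 0
      mm
    })
  structure(m, class = c("residue_weight_matrix", class(m)))
}

# Encode residue strings as integer indices into the weight-matrix alphabet;
# gaps/ambiguities (anything not in the alphabet) become NA.
.encode_residues <- function(seqs, alphabet = .aa_alphabet) {
  chars <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  codes <- match(chars, alphabet)
  dim(codes) <- dim(chars)
  rownames(codes) <- names(seqs)
  codes
}

#' Mean per-site dissimilarity between two aligned sequences
#'
#' Averages the residue dissimilarity over the columns where both sequences
#' carry an unambiguous residue.
#'
#' @param x,y aligned residue strings of equal length.
#' @param w a \code{\link{blosum62_dissimilarity}}-style weight matrix.
#' @return list with \code{distance} (NA if no comparable column) and
#'   \code{comparable_sites}.
#' @export
pairwise_distance <- function(x, y, w = blosum62_dissimilarity()) {
  if (nchar(x) != nchar(y)) stop("sequences must have equal length")
  codes <- .encode_residues(c(a = x, b = y), rownames(w))
  ok <- !is.na(codes[1L, ]) & !is.na(codes[2L, ])
  n <- sum(ok)
  d <- if (n == 0L) NA_real_ else mean(w[cbind(codes[1L, ok], codes[2L, ok])])
  list(distance = d, comparable_sites = n)
}

# All pairwise distances among the rows of a code matrix (taxa x sites).
# Returns D (mean dissimilarity, NA if no shared column) and counts.
.distance_matrix <- function(codes, w) {
  nt <- nrow(codes)
  D <- matrix(0, nt, nt, dimnames = list(rownames(codes), rownames(codes)))
  Cnt <- matrix(0L, nt, nt, dimnames = dimnames(D))
  for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt) {
    ok <- !is.na(codes[i, ]) & !is.na(codes[j, ])
    n <- sum(ok)
    d <- if (n == 0L) NA_real_ else mean(w[cbind(codes[i, ok], codes[j, ok])])
    D[i, j] <- D[j, i] <- d
    Cnt[i, j] <- Cnt[j, i] <- n
  }
  list(D = D, counts = Cnt)
}

#' Classify a quartet-support point on the topology simplex
#'
#' The simplex of relative supports (s1, s2, s3), with s_i >= 0 summing to 1,
#' is tiled into seven regions: corners T1, T2, T3 (resolved; max support
#' >= 2/3, argmax breaking ties toward the lower index), the central region
#' Tstar (star-like; max support < 1/2 — the inner triangle spanned by the
#' edge midpoints), and otherwise the edge region of the two largest supports
#' (T12, T13 or T23; ties keep the lower indices).
#'
#' @param s numeric triple of relative supports.
#' @return one of \code{"T1" "T2" "T3" "T12" "T13" "T23" "Tstar"}.
#' @export
classify_region <- function(s) {
  if (length(s) != 3L || any(s < -1e-9) || abs(sum(s) - 1) > 1e-9)
    stop("s must be a non-negative triple summing to 1")
  mx <- max(s)
  if (mx >= 2 / 3) return(c("T1", "T2", "T3")[which.max(s)])
  if (mx < 0.5) return("Tstar")
  excl <- max(which(s == min(s)))  # drop the smallest; ties keep lower pair
  c("T23", "T13", "T12")[excl]
}

#' Relative topology supports for one taxon quartet
#'
#' For sequences (1, 2, 3, 4), the three pairing sums are
#' S1 = d(1,2) + d(3,4) for topology (12|34), S2 = d(1,3) + d(2,4), and
#' S3 = d(1,4) + d(2,3). Supports are the shortfalls from the worst pairing,
#' delta_i = max_j S_j - S_i, normalised to s_i = delta_i / sum(delta)
#' (four-point condition: the smallest pairing sum marks the best topology).
#' Degenerate quartets — all sums equal, or any pair with fewer than
#' \code{min_sites} comparable columns — get the star point (1/3, 1/3, 1/3).
#'
#' @param seqs four aligned residue strings.
#' @param w residue weight matrix.
#' @param min_sites minimum comparable columns required of every pair.
#' @return list with \code{s} (support triple) and \code{region}.
#' @export
quartet_support <- function(seqs, w = blosum62_dissimilarity(),
                            min_sites = 1L) {
  if (length(seqs) != 4L) stop("exactly four sequences required")
  dm <- .distance_matrix(.encode_residues(seqs, rownames(w)), w)
  D <- dm$D
  pairs <- rbind(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  if (anyNA(D[upper.tri(D)]) || any(dm$counts[upper.tri(dm$counts)] < min_sites)) {
    s <- rep(1 / 3, 3)
  } else {
    S <- D[pairs[, 1:2]] + D[pairs[, 3:4]]
    delta <- max(S) - S
    s <- if (sum(delta) == 0) rep(1 / 3, 3) else delta / sum(delta)
  }
  list(s = s, region = classify_region(s))
}

.region_levels <- c("T1", "T2", "T3", "T12", "T13", "T23", "Tstar")

# Vectorised region classification for a k x 3 support matrix.
.classify_regions <- function(s) {
  mx <- pmax(s[, 1L], s[, 2L], s[, 3L])
  out <- character(nrow(s))
  corner <- mx >= 2 / 3
  star <- !corner & mx < 0.5
  edge <- !corner & !star
  if (any(corner))
    out[corner] <- c("T1", "T2", "T3")[max.col(s[corner, , drop = FALSE],
                                               ties.method = "first")]
  out[star] <- "Tstar"
  if (any(edge)) {
    excl <- max.col(-s[edge, , drop = FALSE], ties.method = "last")
    out[edge] <- c("T23", "T13", "T12")[excl]
  }
  out
}

# Sample m distinct (sorted) 4-subsets of 1..n, assuming choose(n,4) > m.
.sample_quartets <- function(n, m) {
  seen <- new.env(hash = TRUE)
  out <- matrix(0L, m, 4L)
  got <- 0L
  while (got < m) {
    q <- sort(sample.int(n, 4L))
    key <- paste(q, collapse = ".")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      got <- got + 1L
      out[got, ] <- q
    }
  }
  out
}

#' Potential phylogenetic signal of one gene by geometry mapping
#'
#' Maps taxon quartets of a gene onto the topology-support simplex and
#' tallies the seven regions. The relaxed signal estimate is
#' t_hat = 1 - (Tstar tally)/k, the fraction of quartets that are at least
#' partly resolved; the strict estimate t = (T1 + T2 + T3)/k counts only
#' fully resolved quartets. If the number of quartets over the gene's covered
#' taxa, choose(N_g, 4), is at most \code{max_quartets}, all are enumerated;
#' otherwise \code{max_quartets} distinct quartets are sampled uniformly
#' without duplication.
#'
#' @param sm a \code{\link{supermatrix}}.
#' @param gene gene label or index.
#' @param w residue weight matrix.
#' @param max_quartets sampling cap (default 20000).
#' @param seed RNG seed for sampling mode (NULL uses the current RNG state).
#' @param min_sites minimum comparable columns per sequence pair; quartets
#'   failing it count as star-like.
#' @param min_residues,missing_chars presence rule (see
#'   \code{\link{presence_matrix}}).
#' @return object of class \code{gene_signal}: list with \code{gene},
#'   \code{k}, \code{tallies} (7 counts), \code{t_strict}, \code{t_hat},
#'   \code{seed}.
#' @export
gene_signal <- function(sm, gene, w = blosum62_dissimilarity(),
                        max_quartets = 20000L, seed = NULL,
                        min_sites = 1L, min_residues = 1L,
                        missing_chars = .default_missing_chars) {
  block <- gene_block(sm, gene)
  gname <- if (is.character(gene)) gene else sm$partitions$gene[gene]
  codes <- .encode_residues(block, rownames(w))
  present <- rowSums(!is.na(codes)) >= min_residues
  ng <- sum(present)
  if (ng < 4L)
    stop("gene '", gname, "' is covered by only ", ng,
         " taxa (< 4); drop it before signal estimation")
  codes <- codes[present, , drop = FALSE]
  dm <- .distance_matrix(codes, w)
  total <- choose(ng, 4)
  if (total <= max_quartets) {
    qs <- t(utils::combn(ng, 4L))
  } else {
    qs <- .with_seed(seed, .sample_quartets(ng, max_quartets))
  }
  k <- nrow(qs)
  ix <- function(m, a, b) m[qs[, c(a, b), drop = FALSE]]
  S1 <- ix(dm$D, 1, 2) + ix(dm$D, 3, 4)
  S2 <- ix(dm$D, 1, 3) + ix(dm$D, 2, 4)
  S3 <- ix(dm$D, 1, 4) + ix(dm$D, 2, 3)
  c12 <- ix(dm$counts, 1, 2); c34 <- ix(dm$counts, 3, 4)
  c13 <- ix(dm$counts, 1, 3); c24 <- ix(dm$counts, 2, 4)
  c14 <- ix(dm$counts, 1, 4); c23 <- ix(dm$counts, 2, 3)
  bad <- is.na(S1) | is.na(S2) | is.na(S3) |
    pmin(c12, c34, c13, c24, c14, c23) < min_sites
  S <- cbind(S1, S2, S3)
  S[bad, ] <- 1  # placeholder; forced to the star point below
  mx <- pmax(S[, 1L], S[, 2L], S[, 3L])
  delta <- mx - S
  tot <- rowSums(delta)
  s <- delta / ifelse(tot == 0, 1, tot)
  s[tot == 0 | bad, ] <- 1 / 3
  regions <- .classify_regions(s)
  tallies <- vapply(.region_levels, function(r) sum(regions == r), integer(1))
  structure(list(gene = gname, k = k, tallies = tallies,
                 t_strict = sum(tallies[c("T1", "T2", "T3")]) / k,
                 t_hat = (k - tallies[["Tstar"]]) / k,
                 seed = seed),
            class = "gene_signal")
}

#' @export
print.gene_signal <- function(x, ...) {
  cat(sprintf("Gene '%s': k = %d quartets, t = %.3f, t-hat = %.3f\n",
              x$gene, x$k, x$t_strict, x$t_hat))
  print(x$tallies)
  invisible(x)
}

#' Per-gene signal table for a whole supermatrix
#'
#' Runs \code{\link{gene_signal}} on every gene. Genes covered by fewer than
#' four taxa cannot be quartet-mapped; they are reported with k = 0 and
#' t_hat = 0 (they are eliminated automatically during reduction anyway).
#'
#' @inheritParams gene_signal
#' @param seed master seed; per-gene seeds are drawn from it and recorded.
#' @return data frame with one row per gene: \code{gene}, \code{n_taxa}
#'   (covered taxa), \code{k}, the seven region tallies, \code{t_strict},
#'   \code{t_hat}, \code{seed}.
#' @export
gene_signal_table <- function(sm, w = blosum62_dissimilarity(),
                              max_quartets = 20000L, seed = NULL,
                              min_sites = 1L, min_residues = 1L,
                              missing_chars = .default_missing_chars) {
  genes <- sm$partitions$gene
  b <- presence_matrix(sm, min_residues, missing_chars)
  ntax <- colSums(b$entries)
  gene_seeds <- .with_seed(seed,
    sample.int(.Machine$integer.max, length(genes)))
  rows <- lapply(seq_along(genes), function(j) {
    if (ntax[j] < 4) {
      tal <- stats::setNames(rep(0L, 7L), .region_levels)
      return(data.frame(gene = genes[j], n_taxa = ntax[j], k = 0L,
                        as.list(tal), t_strict = 0, t_hat = 0,
                        seed = gene_seeds[j]))
    }
    gs <- gene_signal(sm, genes[j], w, max_quartets, gene_seeds[j],
                      min_sites, min_residues, missing_chars)
    data.frame(gene = genes[j], n_taxa = ntax[j], k = gs$k,
               as.list(gs$tallies), t_strict = gs$t_strict,
               t_hat = gs$t_hat, seed = gene_seeds[j])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a per-gene signal report
#'
#' @param sig table from \code{\link{gene_signal_table}}.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
write_signal_table <- function(sig, path) {
  utils::write.table(sig, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
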