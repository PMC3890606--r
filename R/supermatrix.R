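#' @importFrom ape read.FASTA read.tree write.tree Ntip
NULL

# Characters treated as "no data" when deciding gene presence.
.default_missing_chars <- c("-", "?", "X", "x", "*")

#' Construct a supermatrix object
#'
#' A supermatrix is a concatenated multi-gene alignment: one aligned residue
#' string per taxon plus an ordered gene-partition table that tiles the
#' alignment columns without gaps or overlap.
#'
#' @param sequences named character vector of aligned sequences (one per
#'   taxon, equal lengths; 20-letter amino-acid alphabet plus gap/missing
#'   symbols).
#' @param partitions data frame with columns \code{gene}, \code{start},
#'   \code{end}; coordinates are 1-based inclusive and must tile
#'   \code{[1, alignment length]} in order.
#' @return An object of class \code{supermatrix} with elements \code{taxa},
#'   \code{sequences} and \code{partitions}.
#' @export
supermatrix <- function(sequences, partitions) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("all sequences must be named by taxon")
  taxa <- names(sequences)
  dup <- taxa[duplicated(taxa)]
  if (length(dup))
    stop("duplicate taxon label(s): ", paste(unique(dup), collapse = ", "))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("unequal sequence lengths; first offender: ",
         taxa[which(lens != lens[1L])[1L]])
  L <- lens[[1L]]
  partitions <- as.data.frame(partitions, stringsAsFactors = FALSE)
  if (!all(c("gene", "start", "end") %in% names(partitions)))
    stop("partitions must have columns gene, start, end")
  if (nrow(partitions) < 1L) stop("at least one partition required")
  if (anyDuplicated(partitions$gene))
    stop("duplicate gene label(s) in partitions")
  if (any(partitions$end < partitions$start))
    stop("partition with end < start: ",
         partitions$gene[which(partitions$end < partitions$start)[1L]])
  expect_start <- c(1L, head(partitions$end, -1L) + 1L)
  bad <- which(partitions$start != expect_start)
  if (length(bad))
    stop("partitions must tile the alignment without gaps or overlap; ",
         "offending charset: ", partitions$gene[bad[1L]])
  if (partitions$end[nrow(partitions)] != L)
    stop("partitions cover sites 1-", partitions$end[nrow(partitions)],
         " but the alignment has ", L, " columns (uncovered sites)")
  structure(list(taxa = taxa,
                 sequences = sequences,
                 partitions = partitions),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("Supermatrix:", length(x$taxa), "taxa x", nrow(x$partitions),
      "genes,", nchar(x$sequences[[1L]]), "aligned sites\n")
  invisible(x)
}

#' @export
dim.supermatrix <- function(x) c(length(x$taxa), nrow(x$partitions))

.sanitize_labels <- function(labels) {
  out <- gsub("[ \t]+", "_", trimws(labels))
  names(labels) <- out
  attr(out, "label_map") <- labels
  out
}

.read_fasta_aa <- function(path) {
  x <- ape::read.FASTA(path, type = "AA")
  if (length(x) == 0L) stop("no sequences found in ", path)
  seqs <- toupper(vapply(as.character(x), paste, character(1), collapse = ""))
  names(seqs) <- names(x)
  seqs
}

# Relaxed sequential PHYLIP: "N L" header, then one "name  sequence" record
# per taxon; the sequence may be wrapped over following lines.
.read_phylip_relaxed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty PHYLIP file: ", path)
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]))
  if (length(hdr) < 2L || anyNA(hdr[1:2]))
    stop("malformed PHYLIP header in ", path)
  n <- hdr[1L]; L <- hdr[2L]
  body <- lines[-1L]
  seqs <- character(0)
  i <- 1L
  while (i <= length(body) && length(seqs) < n) {
    parts <- strsplit(trimws(body[i]), "[ \t]+")[[1L]]
    name <- parts[1L]
    seq <- paste(parts[-1L], collapse = "")
    i <- i + 1L
    while (nchar(seq) < L) {
      if (i > length(body))
        stop("sequence for taxon '", name, "' shorter than header length ", L)
      seq <- paste0(seq, gsub("[ \t]", "", body[i]))
      i <- i + 1L
    }
    if (nchar(seq) != L)
      stop("sequence for taxon '", name, "' has ", nchar(seq),
           " sites, header says ", L)
    seqs[name] <- toupper(seq)
  }
  if (length(seqs) != n)
    stop("PHYLIP header promises ", n, " taxa, found ", length(seqs))
  seqs
}

#' Parse a RAxML-style partition (charset) file
#'
#' Accepts lines of the form \code{GENE = start-end}, optionally prefixed by a
#' model tag (\code{"AA, GENE = 1-400"}) or the keyword \code{charset}, with
#' an optional trailing semicolon. Blank lines and \code{#} comments are
#' ignored.
#'
#' @param path path to the partition file.
#' @return data frame with columns \code{gene}, \code{start}, \code{end} in
#'   file order.
#' @export
read_partitions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no charset lines found in ", path)
  pat <- "^(charset[ \t]+)?([^,=]+,[ \t]*)?([^=,]+?)[ \t]*=[ \t]*([0-9]+)[ \t]*-[ \t]*([0-9]+)[ \t]*;?$"
  m <- regmatches(lines, regexec(pat, lines, ignore.case = TRUE))
  bad <- which(vapply(m, length, 1L) == 0L)
  if (length(bad))
    stop("malformed charset line ", bad[1L], ": '", lines[bad[1L]], "'")
  data.frame(
    gene  = vapply(m, function(g) trimws(g[4L]), character(1)),
    start = vapply(m, function(g) as.integer(g[5L]), integer(1)),
    end   = vapply(m, function(g) as.integer(g[6L]), integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Read a supermatrix from an alignment plus a partition file
#'
#' @param alignment_path FASTA or relaxed sequential PHYLIP alignment of
#'   amino-acid sequences.
#' @param partition_path RAxML-style charset file (see
#'   \code{\link{read_partitions}}).
#' @param format \code{"auto"} (detect from the first non-blank character),
#'   \code{"fasta"}, or \code{"phylip"}.
#' @return A \code{\link{supermatrix}}. Taxon order follows the alignment,
#'   gene order follows the partition file. Whitespace inside taxon labels is
#'   replaced by underscores; the original labels are kept in the
#'   \code{"label_map"} attribute of \code{$taxa}.
#' @export
read_supermatrix <- function(alignment_path, partition_path,
                             format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(alignment_path, n = 50L, warn = FALSE)
    first <- first[nzchar(trimws(first))]
    format <- if (length(first) && startsWith(trimws(first[1L]), ">"))
      "fasta" else "phylip"
  }
  seqs <- switch(format,
                 fasta  = .read_fasta_aa(alignment_path),
                 phylip = .read_phylip_relaxed(alignment_path))
  labels <- .sanitize_labels(names(seqs))
  names(seqs) <- labels
  sm <- supermatrix(seqs, read_partitions(partition_path))
  attr(sm$taxa, "label_map") <- attr(labels, "label_map")
  sm
}

#' Extract the aligned block of one gene
#'
#' @param sm a \code{\link{supermatrix}}.
#' @param gene gene label or index.
#' @return named character vector of the gene's aligned sequences (all taxa).
#' @export
gene_block <- function(sm, gene) {
  p <- sm$partitions
  row <- if (is.character(gene)) match(gene, p$gene) else as.integer(gene)
  if (is.na(row) || row < 1L || row > nrow(p)) stop("unknown gene: ", gene)
  substring(sm$sequences, p$start[row], p$end[row])
}

#' Gene presence/absence matrix of a supermatrix
#'
#' A gene is scored present for a taxon when its site range contains at least
#' \code{min_residues} unambiguous residues (anything outside
#' \code{missing_chars}). The result is the 0/1 data-coverage representation
#' matrix of the supermatrix.
#'
#' @param sm a \code{\link{supermatrix}}.
#' @param min_residues minimum number of unambiguous residues for presence.
#' @param missing_chars characters counted as "no data".
#' @return an unweighted \code{\link{coverage_matrix}} (entries 0/1).
#' @export
presence_matrix <- function(sm, min_residues = 1L,
                            missing_chars = .default_missing_chars) {
  chars <- do.call(rbind, strsplit(sm$sequences, "", fixed = TRUE))
  isres <- !(chars %in% missing_chars)
  dim(isres) <- dim(chars)
  p <- sm$partitions
  b <- vapply(seq_len(nrow(p)), function(j) {
    as.integer(rowSums(isres[, p$start[j]:p$end[j], drop = FALSE]) >= min_residues)
  }, integer(length(sm$taxa)))
  dimnames(b) <- list(sm$taxa, p$gene)
  coverage_matrix(b, weighted = FALSE)
}

#' Write a reduced supermatrix
#'
#' Writes the submatrix induced by the kept taxa and genes as a FASTA
#' alignment plus a recomputed charset file. Reading the pair back yields the
#' induced submatrix.
#'
#' @param sm a \code{\link{supermatrix}}.
#' @param kept_taxa,kept_genes labels to keep (subsets of \code{sm}'s labels;
#'   original order is preserved).
#' @param out_prefix output path prefix; files are
#'   \code{<prefix>.fas} and \code{<prefix>_partitions.txt}.
#' @return invisibly, a character vector of the two paths written.
#' @export
write_reduced <- function(sm, kept_taxa, kept_genes, out_prefix) {
  kept_taxa <- sm$taxa[sm$taxa %in% kept_taxa]
  p <- sm$partitions
  keepg <- p$gene %in% kept_genes
  if (!length(kept_taxa)) stop("no taxa kept")
  if (!any(keepg)) stop("no genes kept")
  blocks <- lapply(which(keepg), function(j)
    substring(sm$sequences[kept_taxa], p$start[j], p$end[j]))
  seqs <- do.call(paste0, blocks)
  names(seqs) <- kept_taxa
  lens <- p$end[keepg] - p$start[keepg] + 1L
  ends <- cumsum(lens)
  parts <- data.frame(gene = p$gene[keepg],
                      start = c(1L, head(ends, -1L) + 1L),
                      end = ends, stringsAsFactors = FALSE)
  fas <- paste0(out_prefix, ".fas")
  cs <- paste0(out_prefix, "_partitions.txt")
  writeLines(paste0(">", names(seqs), "\n", seqs), fas)
  writeLines(sprintf("%s = %d-%d", parts$gene, parts$start, parts$end), cs)
  invisible(c(alignment = fas, partitions = cs))
}

#' Read and write trees with optional internal-branch supports
#'
#' Thin wrappers around \pkg{ape}'s newick parser. Support values (percent)
#' are taken from internal node labels.
#'
#' @param path newick file path.
#' @return \code{read_phylo_tree}: an \pkg{ape} \code{phylo} object.
#' @export
read_phylo_tree <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("malformed newick in '", path,
                                          "': ", conditionMessage(e)))
  if (is.null(tr)) stop("malformed newick in '", path, "'")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' @rdname read_phylo_tree
#' @param tree a \code{phylo} object.
#' @export
write_phylo_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Internal-branch support values of a tree
#'
#' @param tree a \code{phylo} object with node labels carrying percent
#'   supports.
#' @return numeric vector of parseable support values (non-numeric or empty
#'   labels, e.g. the arbitrary root node of an unrooted tree, are dropped).
#' @export
tree_supports <- function(tree) {
  if (is.null(tree$node.label)) return(numeric(0))
  s <- suppressWarnings(as.numeric(tree$node.label))
  s[!is.na(s)]
}
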