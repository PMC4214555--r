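#' Read a multiple alignment from aligned FASTA
#'
#' Reads an SSU rRNA alignment (or any gapped nucleotide alignment) into
#' a named character vector of equal-length upper-case rows. Ragged rows
#' are an error: the distance machinery assumes positional homology.
#'
#' @param path Path to an aligned FASTA file.
#' @return Named character vector, one gapped sequence per strain.
#' @export
read_alignment <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  rows <- toupper(as.character(seqs))
  names(rows) <- sub("\\s.*$", "", names(rows))
  validate_alignment(rows)
}

validate_alignment <- function(rows) {
  if (!length(rows)) stop("alignment is empty")
  if (is.null(names(rows)) || anyDuplicated(names(rows)))
    stop("alignment rows must carry unique strain identifiers")
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows have unequal lengths")
  rows
}

#' Write a multiple alignment to aligned FASTA
#'
#' @param rows Named character vector of equal-length gapped sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(rows, path) {
  validate_alignment(rows)
  Biostrings::writeXStringSet(Biostrings::BStringSet(rows), path)
  invisible(path)
}

#' Write a distance matrix in PHYLIP square format
#'
#' Emits the taxon count on the first line, then one row per taxon with
#' its name followed by the full row of distances (the square-matrix
#' layout produced by classic distance programs). Infinite entries,
#' which this package uses for saturated pairs, are written as `Inf`.
#'
#' @param m Symmetric numeric matrix with strain ids as dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(m, path) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), !is.null(rownames(m)))
  lines <- c(sprintf("%5d", nrow(m)),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(format(rownames(m)[i], width = 10),
                       sprintf("%.10g", m[i, ])), collapse = "  ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' @param path Path to a PHYLIP square-format distance matrix.
#' @return Symmetric numeric matrix with strain ids as dimnames.
#' @export
read_distance_matrix <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  if (is.na(n) || length(lines) < n + 1L)
    stop("malformed PHYLIP distance matrix: ", path)
  ids <- character(n)
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1L]]
    if (length(tok) != n + 1L)
      stop("malformed PHYLIP row ", i, " in ", path)
    ids[i] <- tok[1L]
    m[i, ] <- as.numeric(tok[-1L])
  }
  dimnames(m) <- list(ids, ids)
  m
}

#' Read and write trees in Newick format
#'
#' Thin wrappers over [ape::read.tree()] and [ape::write.tree()] so the
#' pipeline's file formats all have readers and writers in one place.
#'
#' @param path Path to a Newick file.
#' @return `read_newick` returns an [ape::phylo] tree; `write_newick`
#'   returns `path` invisibly.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @param tree A `phylo` tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a data frame as a TSV report
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV report written by this package
#'
#' @param path Path to a TSV file.
#' @return Data frame.
#' @export
read_tsv_report <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
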