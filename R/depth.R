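#' Construct a per-base read-depth track
#'
#' A `DepthTrack` stores strand-resolved per-base read depth for one
#' strain and one RNA-seq dataset as dense integer vectors. Unstranded
#' data keep the combined depth in the forward array and an all-zero
#' reverse array, so strand-aware operations can treat them uniformly as
#' strand `"both"`.
#'
#' @param strain_id,dataset_id Identifiers (single strings).
#' @param fwd Integer vector of forward-strand depth, one value per base.
#' @param rev Optional reverse-strand depth of the same length; omit (or
#'   pass `NULL`) for unstranded data.
#' @param total_reads,mapped_reads Optional read-count metadata produced
#'   upstream of this package (mapping itself is out of scope); used only
#'   for the fraction-mapped QC metric.
#' @return An object of class `DepthTrack`.
#' @export
depth_track <- function(strain_id, dataset_id, fwd, rev = NULL,
                        total_reads = NA_real_, mapped_reads = NA_real_) {
  stranded <- !is.null(rev)
  fwd <- as.integer(fwd)
  rev <- if (stranded) as.integer(rev) else integer(length(fwd))
  if (length(rev) != length(fwd))
    stop("forward and reverse depth arrays differ in length")
  if (anyNA(fwd) || anyNA(rev) || any(fwd < 0L) || any(rev < 0L))
    stop("depth values must be non-negative integers")
  structure(list(strain_id = strain_id, dataset_id = dataset_id,
                 stranded = stranded, fwd = fwd, rev = rev,
                 total_reads = total_reads, mapped_reads = mapped_reads),
            class = "DepthTrack")
}

#' @export
print.DepthTrack <- function(x, ...) {
  cat(sprintf("DepthTrack: %s / %s, %d nt, %s; mean depth %.2f\n",
              x$strain_id, x$dataset_id, length(x$fwd),
              if (x$stranded) "stranded" else "unstranded",
              mean(x$fwd + x$rev)))
  invisible(x)
}

genome_length <- function(track) length(track$fwd)

combined_depth <- function(track) track$fwd + track$rev

bedgraph_to_dense <- function(path, genome_length) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  depth <- integer(genome_length)
  if (length(gr) == 0L) return(depth)
  start0 <- BiocGenerics::start(gr) - 1L
  end <- BiocGenerics::end(gr)
  val <- gr$score
  if (any(val < 0)) stop("negative depth value in ", path)
  if (any(end > genome_length))
    stop("bedGraph interval beyond genome_length in ", path)
  o <- order(start0)
  if (any(start0[o][-1L] < end[o][-length(o)]))
    stop("overlapping bedGraph intervals in ", path)
  for (i in seq_along(gr))
    depth[(start0[i] + 1L):end[i]] <- as.integer(val[i])
  depth
}

#' Read a depth track from bedGraph
#'
#' Reads one bedGraph file per strand (0-based half-open intervals) into
#' dense per-base arrays. Positions not covered by any interval get depth
#' 0. Overlapping intervals, intervals past the genome end and negative
#' values are rejected. The resulting calls downstream are invariant to
#' how runs of equal depth are fragmented into intervals.
#'
#' @param path_fwd bedGraph file for the forward strand (or the combined
#'   depth of an unstranded dataset).
#' @param path_rev Optional bedGraph file for the reverse strand; omit
#'   for unstranded data.
#' @param genome_length Genome length in nucleotides.
#' @param strain_id,dataset_id Identifiers stored on the track.
#' @inheritParams depth_track
#' @return A `DepthTrack`.
#' @export
read_depth <- function(path_fwd, path_rev = NULL, genome_length,
                       strain_id = "strain", dataset_id = "dataset",
                       total_reads = NA_real_, mapped_reads = NA_real_) {
  fwd <- bedgraph_to_dense(path_fwd, genome_length)
  rev <- if (!is.null(path_rev)) bedgraph_to_dense(path_rev, genome_length)
  depth_track(strain_id, dataset_id, fwd, rev,
              total_reads = total_reads, mapped_reads = mapped_reads)
}

dense_to_bedgraph <- function(depth, seqname, path) {
  r <- rle(depth)
  end <- cumsum(r$lengths)
  start0 <- end - r$lengths
  keep <- r$values != 0L
  if (any(keep)) {
    gr <- GenomicRanges::GRanges(
      seqnames = seqname,
      ranges = IRanges::IRanges(start = start0[keep] + 1L, end = end[keep]),
      score = r$values[keep])
    rtracklayer::export(gr, path, format = "bedGraph")
  } else {
    writeLines(character(), path)
  }
  invisible(path)
}

#' Write a depth track to bedGraph
#'
#' Inverse of [read_depth()]: emits maximal runs of equal non-zero depth
#' as 0-based half-open bedGraph intervals, one file per strand for
#' stranded tracks. Zero-depth runs are left implicit.
#'
#' @param track A `DepthTrack`.
#' @param path_fwd,path_rev Output paths; `path_rev` is required for
#'   stranded tracks and ignored otherwise.
#' @return `path_fwd`, invisibly.
#' @export
write_depth <- function(track, path_fwd, path_rev = NULL) {
  stopifnot(inherits(track, "DepthTrack"))
  dense_to_bedgraph(track$fwd, track$strain_id, path_fwd)
  if (track$stranded) {
    if (is.null(path_rev)) stop("stranded track needs path_rev")
    dense_to_bedgraph(track$rev, track$strain_id, path_rev)
  }
  invisible(path_fwd)
}
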