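#' Mask annotated positions of a genome
#'
#' Marks which positions of each strand are free of annotated
#' protein-coding or RNA genes. Existing RUF-kind features do not mask:
#' the caller must be able to re-find them. For stranded tracks the
#' default is strand-aware masking (a `+` feature masks only `+`
#' positions; features with strand `"both"` mask both strands);
#' `strand_aware = FALSE` masks both strands under any feature, and
#' unstranded tracks are always treated that way.
#'
#' @param track A `DepthTrack` (supplies genome length and strandedness).
#' @param ann An `AnnotationSet` for the same genome.
#' @param strand_aware Mask per strand for stranded tracks.
#' @return List with logical vectors `fwd` and `rev`, `TRUE` where the
#'   position is unannotated on that strand.
#' @export
mask_annotated <- function(track, ann, strand_aware = TRUE) {
  stopifnot(inherits(track, "DepthTrack"), inherits(ann, "AnnotationSet"))
  gl <- genome_length(track)
  if (gl != ann$genome_length)
    stop("track and annotation genome lengths differ")
  open_fwd <- rep(TRUE, gl); open_rev <- rep(TRUE, gl)
  f <- ann$features[ann$features$kind %in% c("protein", "rna"), , drop = FALSE]
  per_strand <- strand_aware && track$stranded
  for (i in seq_len(nrow(f))) {
    idx <- (f$start[i] + 1L):f$end[i]
    if (!per_strand || f$strand[i] %in% c("+", "both")) open_fwd[idx] <- FALSE
    if (!per_strand || f$strand[i] %in% c("-", "both")) open_rev[idx] <- FALSE
  }
  list(fwd = open_fwd, rev = open_rev)
}

# Maximal runs of TRUE in `eligible`, merging runs separated by <= max_gap
# positions that are all `open` (unannotated); annotated positions always
# break a run.
merge_runs <- function(eligible, open, max_gap) {
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths   # 0-based half-open
  runs <- cbind(starts[r$values], ends[r$values])
  if (!nrow(runs)) return(runs)
  merged <- runs[1L, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1L]) {
    last <- nrow(merged)
    gap_start <- merged[last, 2L]; gap_end <- runs[i, 1L]
    gap_len <- gap_end - gap_start
    if (gap_len <= max_gap && all(open[(gap_start + 1L):gap_end]))
      merged[last, 2L] <- runs[i, 2L]
    else merged <- rbind(merged, runs[i, , drop = FALSE])
  }
  merged
}

call_rufs_strand <- function(depth, open, strand, min_depth, min_len,
                             max_len, max_gap) {
  eligible <- open & depth >= min_depth
  runs <- merge_runs(eligible, open, max_gap)
  if (!nrow(runs)) return(NULL)
  len <- runs[, 2L] - runs[, 1L]
  med <- vapply(seq_len(nrow(runs)), function(i)
    stats::median(depth[(runs[i, 1L] + 1L):runs[i, 2L]]), numeric(1))
  keep <- len >= min_len & len <= max_len & med >= min_depth
  if (!any(keep)) return(NULL)
  data.frame(start = runs[keep, 1L], end = runs[keep, 2L],
             strand = strand, length = len[keep], median_depth = med[keep],
             stringsAsFactors = FALSE)
}

#' Call RNAs of Unknown Function from a depth track
#'
#' A deterministic surrogate for manual inspection of coverage plots:
#' candidate regions are maximal runs of unannotated positions with
#' depth at or above `min_depth`, allowing internal gaps of up to
#' `max_gap` below-threshold (but still unannotated) positions; a
#' candidate is retained as a RUF call iff its length lies in
#' `[min_len, max_len]` and its median depth over the whole region
#' (gap positions included) is at least `min_depth`. Regions longer
#' than `max_len` are rejected whole, never trimmed — trimming would
#' invent boundaries the data do not support. For stranded tracks the
#' two strands are scanned independently, so overlapping calls on
#' opposite strands are reported separately.
#'
#' @param track A `DepthTrack`.
#' @param ann An `AnnotationSet` for the same genome.
#' @param min_depth Expression threshold in reads per base.
#' @param min_len,max_len Retained call length bounds in nt.
#' @param max_gap Longest tolerated internal below-threshold gap, nt.
#' @param strand_aware Passed to [mask_annotated()].
#' @return Data frame of calls (`strain_id`, `dataset_id`, `start`,
#'   `end`, `strand`, `length`, `median_depth`) sorted by coordinate.
#' @export
call_rufs <- function(track, ann, min_depth = 10, min_len = 50,
                      max_len = 400, max_gap = 10, strand_aware = TRUE) {
  stopifnot(min_depth > 0, min_len > 0, max_len >= min_len, max_gap >= 0)
  mask <- mask_annotated(track, ann, strand_aware = strand_aware)
  calls <- if (track$stranded) {
    rbind(call_rufs_strand(track$fwd, mask$fwd, "+", min_depth, min_len,
                           max_len, max_gap),
          call_rufs_strand(track$rev, mask$rev, "-", min_depth, min_len,
                           max_len, max_gap))
  } else {
    call_rufs_strand(track$fwd, mask$fwd, "both", min_depth, min_len,
                     max_len, max_gap)
  }
  if (is.null(calls))
    calls <- data.frame(start = integer(), end = integer(),
                        strand = character(), length = integer(),
                        median_depth = numeric(), stringsAsFactors = FALSE)
  calls <- cbind(strain_id = rep(track$strain_id, nrow(calls)),
                 dataset_id = rep(track$dataset_id, nrow(calls)),
                 calls, stringsAsFactors = FALSE)
  calls[order(calls$start, calls$strand), , drop = FALSE]
}

#' Pool depth tracks by summing per-base depths
#'
#' Sums the per-base depths of several datasets from the same strain,
#' for callers or rankings that should see pooled evidence.
#'
#' @param tracks List of `DepthTrack`s sharing strain and genome length.
#' @return A single pooled `DepthTrack` with `dataset_id = "pooled"`.
#' @export
pool_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  gl <- unique(vapply(tracks, function(t) length(t$fwd), integer(1)))
  if (length(gl) != 1L) stop("tracks differ in genome length")
  stranded <- tracks[[1L]]$stranded
  fwd <- Reduce(`+`, lapply(tracks, `[[`, "fwd"))
  rev <- Reduce(`+`, lapply(tracks, `[[`, "rev"))
  depth_track(tracks[[1L]]$strain_id, "pooled", fwd, if (stranded) rev,
              total_reads = sum(vapply(tracks, `[[`, numeric(1), "total_reads")),
              mapped_reads = sum(vapply(tracks, `[[`, numeric(1), "mapped_reads")))
}

#' Convert RUF calls into annotation features
#'
#' Gives each call a feature id and kind `"ruf"` so calls can be ranked
#' jointly with annotated genes, and optionally a family id from a
#' homology grouping.
#'
#' @param calls Data frame from [call_rufs()] (possibly several strains
#'   and datasets row-bound); duplicate intervals from different
#'   datasets of the same strain are collapsed.
#' @param family_ids Optional character vector of group labels, one per
#'   distinct call.
#' @return Feature data frame suitable for [annotation_set()].
#' @export
ruf_features <- function(calls, family_ids = NULL) {
  key <- !duplicated(calls[c("strain_id", "start", "end", "strand")])
  calls <- calls[key, , drop = FALSE]
  data.frame(
    feature_id = sprintf("%s_ruf_%05d_%05d_%s", calls$strain_id,
                         calls$start, calls$end,
                         ifelse(calls$strand == "+", "p",
                                ifelse(calls$strand == "-", "m", "b"))),
    family_id = if (is.null(family_ids)) rep(NA_character_, nrow(calls))
                else family_ids,
    kind = rep("ruf", nrow(calls)),
    start = calls$start, end = calls$end, strand = calls$strand,
    stringsAsFactors = FALSE)
}
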