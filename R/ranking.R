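#' Median read depth of a genomic interval
#'
#' Median of the per-base depth over a 0-based half-open interval on the
#' given strand. Features on `"+"` or `"-"` use that strand's array of a
#' stranded track; strand `"both"` — and every feature of an unstranded
#' track — uses the sum of both arrays. For even interval lengths the
#' median is the mean of the central pair.
#'
#' @param track A `DepthTrack`.
#' @param start,end 0-based half-open interval bounds.
#' @param strand `"+"`, `"-"` or `"both"`.
#' @return Median depth (numeric scalar).
#' @export
median_depth <- function(track, start, end, strand = "both") {
  stopifnot(inherits(track, "DepthTrack"))
  if (start >= end) stop("empty interval")
  if (end > genome_length(track)) stop("interval beyond genome end")
  idx <- (start + 1L):end
  depth <- if (!track$stranded || strand == "both") track$fwd[idx] + track$rev[idx]
           else if (strand == "+") track$fwd[idx]
           else track$rev[idx]
  stats::median(depth)
}

#' Is a feature expressed in any dataset?
#'
#' A feature counts as expressed when its median depth reaches the
#' threshold in at least one dataset (experiment).
#'
#' @param medians Numeric vector of per-dataset median depths.
#' @param threshold Expression threshold (reads).
#' @return Logical scalar.
#' @export
flag_expressed <- function(medians, threshold = 10) {
  stopifnot(length(medians) >= 1L)
  max(medians) >= threshold
}

#' Rank features of one strain by expression
#'
#' Ranks by a statistic in decreasing order: rank 1 is the most highly
#' expressed feature. Ties are broken by lexicographic feature id, so
#' ranks are a permutation of `1..n` invariant to input row order.
#'
#' @param stat Numeric vector of ranking statistics.
#' @param feature_id Character vector of ids, same length.
#' @return Integer vector of ranks aligned with the input.
#' @export
rank_strain <- function(stat, feature_id) {
  stopifnot(length(stat) == length(feature_id), length(stat) >= 1L)
  o <- order(-stat, feature_id)
  ranks <- integer(length(stat))
  ranks[o] <- seq_along(stat)
  ranks
}

#' Per-strain expression table
#'
#' Computes per-dataset median depths for every feature of a strain
#' (annotated genes plus RUF calls are ranked jointly when the caller
#' includes RUF features in `ann`), flags expression, and assigns ranks
#' from the ranking statistic: by default the maximum over datasets of
#' the per-dataset median depth, so a transcript abundant in any one
#' condition is treated as abundant; with `pool = TRUE` the datasets'
#' depths are summed first and ranked as one experiment.
#'
#' @param ann An `AnnotationSet` whose features to quantify.
#' @param tracks List of `DepthTrack`s for this strain (one per dataset).
#' @param threshold Expression threshold on the median depth.
#' @param pool Sum tracks before quantifying instead of taking the
#'   per-dataset maximum.
#' @return Data frame with one row per feature: `strain_id`,
#'   `feature_id`, `family_id`, `kind`, per-dataset `median_*` columns,
#'   `stat`, `expressed`, `rank`.
#' @export
expression_table <- function(ann, tracks, threshold = 10, pool = FALSE) {
  stopifnot(inherits(ann, "AnnotationSet"), length(tracks) >= 1L)
  f <- ann$features
  if (!nrow(f)) stop("no features to rank")
  if (pool) tracks <- list(pooled = pool_tracks(tracks))
  med <- vapply(tracks, function(tk)
    vapply(seq_len(nrow(f)), function(i)
      median_depth(tk, f$start[i], f$end[i], f$strand[i]), numeric(1)),
    numeric(nrow(f)))
  med <- matrix(med, nrow = nrow(f),
                dimnames = list(NULL, paste0("median_", vapply(tracks, `[[`,
                                             character(1), "dataset_id"))))
  stat <- apply(med, 1L, max)
  out <- data.frame(strain_id = ann$strain_id, feature_id = f$feature_id,
                    family_id = f$family_id, kind = f$kind,
                    stringsAsFactors = FALSE)
  out <- cbind(out, med)
  out$stat <- stat
  out$expressed <- apply(med, 1L, flag_expressed, threshold = threshold)
  out$rank <- rank_strain(stat, f$feature_id)
  out
}

#' Classification thresholds for expression and conservation
#'
#' Rank and distance cut-offs splitting features into High / Medium /
#' Low expression and conservation classes. The defaults are the upper
#' and lower quartiles of the comparative survey this package
#' re-implements: expression ranks 204 and 1660, conservation distances
#' 0.478 and 0.267 substitutions/site. Because those quartiles are
#' dataset-specific, [thresholds_from_data()] recomputes them from any
#' input distribution.
#'
#' @param expr_upper_q Rank at or below which expression is High.
#' @param expr_lower_q Rank above which expression is Low.
#' @param cons_upper_q Distance at or above which conservation is High.
#' @param cons_lower_q Distance at or below which conservation is Low.
#' @return List of class `class_thresholds`.
#' @export
class_thresholds <- function(expr_upper_q = 204, expr_lower_q = 1660,
                             cons_upper_q = 0.478, cons_lower_q = 0.267) {
  stopifnot(expr_upper_q < expr_lower_q, cons_lower_q < cons_upper_q)
  structure(list(expr_upper_q = expr_upper_q, expr_lower_q = expr_lower_q,
                 cons_upper_q = cons_upper_q, cons_lower_q = cons_lower_q),
            class = "class_thresholds")
}

#' @rdname class_thresholds
#' @param min_ranks Numeric vector of cross-strain minimum ranks.
#' @param max_distances Numeric vector of family conservation scores.
#' @export
thresholds_from_data <- function(min_ranks, max_distances) {
  rq <- stats::quantile(min_ranks, c(0.25, 0.75), names = FALSE, type = 1)
  dq <- stats::quantile(max_distances[is.finite(max_distances)],
                        c(0.25, 0.75), names = FALSE)
  class_thresholds(expr_upper_q = rq[1L], expr_lower_q = rq[2L],
                   cons_upper_q = dq[2L], cons_lower_q = dq[1L])
}

#' Aggregate expression across strains by minimum rank
#'
#' For each family (or RUF homology group) expressed in one or more
#' strains, takes the minimum of the member strains' ranks — the
#' relatively most abundant observation — so a transcript that is highly
#' abundant anywhere is treated as highly abundant, while transcripts
#' that are low abundance everywhere stay low. The minimum rank is then
#' classified: High iff `min_rank <= expr_upper_q`, Low iff
#' `min_rank > expr_lower_q`, else Medium.
#'
#' @param expr Row-bound per-strain [expression_table()]s; rows with
#'   `NA` family ids are dropped (nothing to aggregate across strains).
#' @param th A [class_thresholds()].
#' @param expressed_only Use only rows flagged expressed (default), so
#'   the aggregate reflects strains where the gene is actually seen.
#' @return Data frame: `family_id`, `n_strains_expressed`, `min_rank`,
#'   `expression_class`.
#' @export
aggregate_min_rank <- function(expr, th = class_thresholds(),
                               expressed_only = TRUE) {
  stopifnot(inherits(th, "class_thresholds"))
  rows <- expr[!is.na(expr$family_id), , drop = FALSE]
  if (expressed_only) rows <- rows[rows$expressed, , drop = FALSE]
  if (!nrow(rows)) stop("no expressed rows with family ids to aggregate")
  agg <- stats::aggregate(rows["rank"], by = rows["family_id"], FUN = min)
  nstr <- stats::aggregate(list(n_strains_expressed = rows$strain_id),
                           by = rows["family_id"],
                           FUN = function(x) length(unique(x)))
  out <- merge(agg, nstr, by = "family_id")
  names(out)[names(out) == "rank"] <- "min_rank"
  out$expression_class <- expression_class(out$min_rank, th)
  out[order(out$family_id), c("family_id", "n_strains_expressed",
                              "min_rank", "expression_class")]
}

#' @rdname aggregate_min_rank
#' @param min_rank Numeric vector of minimum ranks.
#' @export
expression_class <- function(min_rank, th = class_thresholds()) {
  ifelse(min_rank <= th$expr_upper_q, "High",
         ifelse(min_rank > th$expr_lower_q, "Low", "Medium"))
}
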