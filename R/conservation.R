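#' Family conservation scores from a distance matrix
#'
#' The conservation score of a family is the maximum pairwise F84
#' distance between any two strains carrying it; a family seen in fewer
#' than two strains scores 0. Scores are classified against the
#' conservation quartiles: High iff `score >= cons_upper_q`, Low iff
#' `score <= cons_lower_q`, else Medium (so singletons are Low, and a
#' saturated `Inf` score is High).
#'
#' @param presence Named list mapping `family_id` to the character
#'   vector of strains carrying the family, or a logical family x
#'   strain matrix with dimnames.
#' @param m Symmetric distance matrix with strain ids as dimnames.
#' @param th A [class_thresholds()].
#' @return Data frame: `family_id`, `n_strains`, `max_distance`,
#'   `conservation_class`.
#' @export
family_conservation <- function(presence, m, th = class_thresholds()) {
  stopifnot(inherits(th, "class_thresholds"))
  if (is.matrix(presence))
    presence <- apply(presence, 1L, function(r) colnames(presence)[r],
                      simplify = FALSE)
  stopifnot(is.list(presence), !is.null(names(presence)))
  unknown <- setdiff(unique(unlist(presence)), rownames(m))
  if (length(unknown))
    stop("strains absent from the distance matrix: ",
         paste(unknown, collapse = ", "))
  maxd <- vapply(presence, function(strains) {
    if (length(strains) < 2L) return(0)
    max(m[strains, strains])
  }, numeric(1))
  data.frame(family_id = names(presence),
             n_strains = lengths(presence),
             max_distance = unname(maxd),
             conservation_class = conservation_class(unname(maxd), th),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname family_conservation
#' @param max_distance Numeric vector of conservation scores.
#' @export
conservation_class <- function(max_distance, th = class_thresholds()) {
  ifelse(max_distance >= th$cons_upper_q, "High",
         ifelse(max_distance <= th$cons_lower_q, "Low", "Medium"))
}

#' Conserved-fraction curve over phylogenetic distance
#'
#' For each grid distance `d`, the fraction of families whose
#' conservation score (maximum pairwise distance) is at least `d` — the
#' share of families still conserved across that distance. All families
#' enter the denominator, including singletons (score 0); restrict with
#' `min_strains = 2` for the alternative convention.
#'
#' @param records Data frame from [family_conservation()].
#' @param grid Strictly increasing non-negative distance grid.
#' @param min_strains Drop families seen in fewer strains than this.
#' @return Data frame of class `conserved_fraction_curve` with columns
#'   `distance` and `fraction` (non-increasing).
#' @export
conserved_fraction_curve <- function(records, grid, min_strains = 1L) {
  if (!nrow(records)) stop("no family records")
  stopifnot(all(diff(grid) > 0), all(grid >= 0))
  records <- records[records$n_strains >= min_strains, , drop = FALSE]
  if (!nrow(records)) stop("no families left after min_strains filter")
  frac <- vapply(grid, function(d) mean(records$max_distance >= d), numeric(1))
  structure(data.frame(distance = grid, fraction = frac),
            class = c("conserved_fraction_curve", "data.frame"))
}

#' Distance at which a target fraction of families is still conserved
#'
#' Largest grid distance whose conserved fraction is at least `target`
#' (step-function convention). If even the first grid point falls below
#' the target the value is unreachable and `NA` is returned rather than
#' an error, so callers can flag it.
#'
#' @param curve A [conserved_fraction_curve()].
#' @param target Fraction in (0, 1).
#' @return Distance, or `NA_real_` when unreachable.
#' @export
distance_at_fraction <- function(curve, target = 0.8) {
  stopifnot(target > 0, target < 1)
  ok <- which(curve$fraction >= target)
  if (!length(ok)) return(NA_real_)
  curve$distance[max(ok)]
}

#' Enumerate within-domain strain pairs
#'
#' All unordered pairs of strains from the same domain; Bacteria vs
#' Archaea pairs are excluded because cross-domain SSU distances are
#' saturated and uninformative for zone analysis.
#'
#' @param domains Named character vector mapping strain id to
#'   `"Bacteria"` or `"Archaea"`.
#' @return Data frame with columns `strain1`, `strain2`, `domain`.
#' @export
enumerate_pairs <- function(domains) {
  stopifnot(length(domains) >= 2L, !is.null(names(domains)))
  out <- lapply(unique(domains), function(dom) {
    ids <- sort(names(domains)[domains == dom])
    if (length(ids) < 2L) return(NULL)
    idx <- utils::combn(length(ids), 2L)
    data.frame(strain1 = ids[idx[1L, ]], strain2 = ids[idx[2L, ]],
               domain = dom, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(strain1 = character(), strain2 = character(),
                      domain = character(), stringsAsFactors = FALSE)
  out
}

#' The Goldilocks Zone of phylogenetic distances
#'
#' The closed interval of pairwise SSU distances within which
#' comparative RNA analysis is informative: close enough that RNA
#' homologs are still detectable, distant enough that conservation is
#' distinguishable from ubiquitous sharing. Defaults are the surveyed
#' bounds 0.0118–0.0542 substitutions/site. [derived_zone()] instead
#' derives bounds from an RNA conserved-fraction curve, taking `d_max`
#' where 80% of RNA families are still conserved and `d_min` where 99%
#' are — a documented surrogate for bounds whose original derivation is
#' not specified.
#'
#' @param d_min,d_max Zone bounds, substitutions/site, `0 < d_min < d_max`.
#' @return List of class `goldilocks_zone`.
#' @export
goldilocks_zone <- function(d_min = 0.0118, d_max = 0.0542) {
  stopifnot(d_min > 0, d_min < d_max)
  structure(list(d_min = d_min, d_max = d_max), class = "goldilocks_zone")
}

#' @rdname goldilocks_zone
#' @param curve RNA-family [conserved_fraction_curve()].
#' @param hi_target Conserved fraction defining `d_max` (default 0.8).
#' @param lo_target Conserved fraction defining `d_min` (default 0.99).
#' @export
derived_zone <- function(curve, hi_target = 0.8, lo_target = 0.99) {
  d_max <- distance_at_fraction(curve, hi_target)
  d_min <- distance_at_fraction(curve, lo_target)
  if (is.na(d_min) || is.na(d_max))
    stop("conserved-fraction curve never reaches the zone targets")
  goldilocks_zone(d_min = d_min, d_max = d_max)
}

#' Classify strain pairs relative to the Goldilocks Zone
#'
#' A pair is `too_hot` below `d_min` (strains so close that everything
#' is shared and comparative power is lost), `goldilocks` inside the
#' closed interval `[d_min, d_max]`, and `too_cold` above `d_max`
#' (RNA homology no longer detectable). Vectorized over distances.
#'
#' @param d Non-negative pairwise distance(s).
#' @param zone A [goldilocks_zone()].
#' @return Character vector of zone labels.
#' @export
classify_pair <- function(d, zone = goldilocks_zone()) {
  stopifnot(all(d >= 0))
  ifelse(d < zone$d_min, "too_hot",
         ifelse(d <= zone$d_max, "goldilocks", "too_cold"))
}

#' Classify all within-domain pairs of a distance matrix
#'
#' @param m Distance matrix with strain ids as dimnames.
#' @param domains Named domain vector (see [enumerate_pairs()]).
#' @param zone A [goldilocks_zone()].
#' @return [enumerate_pairs()] output with `distance` and `zone_label`.
#' @export
classify_pairs <- function(m, domains, zone = goldilocks_zone()) {
  pairs <- enumerate_pairs(domains)
  pairs$distance <- m[cbind(pairs$strain1, pairs$strain2)]
  pairs$zone_label <- classify_pair(pairs$distance, zone)
  pairs
}

#' Integrate conservation, structure and cross-strain expression evidence
#'
#' Scores each RUF homology group on three binary criteria: conserved
#' (carried by at least two strains), structured (external secondary-
#' structure evidence flag) and expressed elsewhere (expressed, median
#' depth at threshold, in at least two strains). Expression in another
#' strain requires a homolog there, so `expressed_elsewhere` without
#' `conserved` violates the model and is an error. High-confidence
#' groups satisfy at least two criteria.
#'
#' @param records Data frame with columns `group_id`, `conserved`,
#'   `structured`, `expressed_elsewhere`; groups missing a flag should
#'   be entered as `FALSE`.
#' @return List with `records` (input plus `n_criteria` and
#'   `high_confidence`), `venn` (named counts of the seven non-empty
#'   criterion intersections plus `none`), `n_high_confidence` and
#'   `n_total`.
#' @export
evidence_integration <- function(records) {
  req <- c("group_id", "conserved", "structured", "expressed_elsewhere")
  stopifnot(all(req %in% names(records)))
  bad <- records$expressed_elsewhere & !records$conserved
  if (any(bad))
    stop("expressed_elsewhere without conserved for group(s): ",
         paste(records$group_id[bad], collapse = ", "))
  records$n_criteria <- records$conserved + records$structured +
    records$expressed_elsewhere
  records$high_confidence <- records$n_criteria >= 2L
  cat_of <- function(c1, c2, c3) {
    key <- paste0(ifelse(c1, "C", ""), ifelse(c2, "S", ""), ifelse(c3, "E", ""))
    ifelse(key == "", "none", key)
  }
  cats <- cat_of(records$conserved, records$structured,
                 records$expressed_elsewhere)
  all_cats <- c("C", "S", "E", "CS", "CE", "SE", "CSE", "none")
  venn <- vapply(all_cats, function(k) sum(cats == k), integer(1))
  list(records = records, venn = venn,
       n_high_confidence = sum(records$high_confidence),
       n_total = nrow(records))
}
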