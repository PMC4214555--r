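#' Empirical base frequencies of an alignment
#'
#' Frequencies of A, C, G, T pooled over all rows of the alignment,
#' ignoring gaps and ambiguity codes. Pooled frequencies (rather than
#' per-pair) match the convention of the classic distance programs; a
#' per-pair mode is available in [f84_distance_matrix()].
#'
#' @param rows Named character vector of equal-length gapped sequences
#'   (see [read_alignment()]).
#' @return Named numeric vector `c(A=, C=, G=, T=)` summing to 1.
#' @export
base_frequencies <- function(rows) {
  validate_alignment(rows)
  chars <- unlist(strsplit(rows, "", fixed = TRUE), use.names = FALSE)
  counts <- vapply(c("A", "C", "G", "T"), function(b) sum(chars == b), numeric(1))
  if (sum(counts) == 0) stop("alignment contains no unambiguous nucleotides")
  counts / sum(counts)
}

BASES <- c("A", "C", "G", "T")

#' Transition and transversion proportions between two aligned rows
#'
#' Sites where either row carries a gap or an ambiguity code are excluded
#' (pairwise deletion). Transitions are A<->G and C<->T; every other
#' difference is a transversion.
#'
#' @param row_i,row_j Equal-length gapped sequences (character scalars).
#' @return List with `P` (transition proportion), `Q` (transversion
#'   proportion) and `n_sites` (number of compared sites).
#' @export
count_PQ <- function(row_i, row_j) {
  a <- strsplit(toupper(row_i), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(row_j), "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) stop("rows have unequal lengths")
  ok <- a %in% BASES & b %in% BASES
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites after pairwise deletion")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  ts <- diff & ((a == "A" & b == "G") | (a == "G" & b == "A") |
                (a == "C" & b == "T") | (a == "T" & b == "C"))
  list(P = sum(ts) / n, Q = sum(diff & !ts) / n, n_sites = n)
}

#' F84 distance from transition/transversion proportions
#'
#' Closed-form maximum-likelihood distance under the F84 substitution
#' model, which allows unequal base frequencies and distinct transition
#' and transversion rates. With purine frequency \eqn{\pi_R}, pyrimidine
#' frequency \eqn{\pi_Y}, \eqn{A = \pi_C\pi_T/\pi_Y + \pi_A\pi_G/\pi_R},
#' \eqn{B = \pi_C\pi_T + \pi_A\pi_G} and \eqn{C = \pi_R\pi_Y}, the
#' distance in expected substitutions per site is
#' \deqn{d = -2A \ln(1 - P/(2A) - (A-B)Q/(2AC)) + 2(A-B-C)\ln(1 - Q/(2C)).}
#' When either logarithm argument is non-positive the sequences are
#' saturated and the distance is `Inf` (with a warning); downstream
#' maximum-distance logic stays total and `Inf` maps to high conservation
#' distance.
#'
#' @param P,Q Transition and transversion difference proportions.
#' @param pi Base-frequency vector `c(A, C, G, T)` summing to 1, all
#'   components positive.
#' @return Non-negative distance, possibly `Inf`.
#' @export
f84_distance <- function(P, Q, pi) {
  stopifnot(length(pi) == 4L, P >= 0, Q >= 0, P + Q <= 1)
  if (abs(sum(pi) - 1) > 1e-8) stop("base frequencies must sum to 1")
  if (any(pi <= 0) && (P > 0 || Q > 0))
    stop("zero base frequency with nonzero difference counts: F84 terms undefined")
  piA <- pi[[1L]]; piC <- pi[[2L]]; piG <- pi[[3L]]; piT <- pi[[4L]]
  piR <- piA + piG; piY <- piC + piT
  A <- piC * piT / piY + piA * piG / piR
  B <- piC * piT + piA * piG
  C <- piR * piY
  arg1 <- 1 - P / (2 * A) - (A - B) * Q / (2 * A * C)
  arg2 <- 1 - Q / (2 * C)
  if (arg1 <= 0 || arg2 <= 0) {
    warning("saturated sequence pair: F84 distance undefined, returning Inf")
    return(Inf)
  }
  d <- -2 * A * log(arg1) + 2 * (A - B - C) * log(arg2)
  max(d, 0)
}

#' Pairwise F84 distance matrix from an alignment
#'
#' Applies [count_PQ()] and [f84_distance()] to every pair of rows. The
#' pairwise distances estimate the total branch length separating each
#' pair of strains on the underlying phylogeny.
#'
#' @param rows Named character vector of aligned sequences.
#' @param per_pair If `TRUE`, base frequencies are recomputed from each
#'   pair of rows instead of pooled over the whole alignment.
#' @return Symmetric matrix of distances with zero diagonal; entries may
#'   be `Inf` for saturated pairs.
#' @export
f84_distance_matrix <- function(rows, per_pair = FALSE) {
  validate_alignment(rows)
  if (length(rows) < 2L) stop("need at least two rows")
  n <- length(rows)
  pi_pool <- base_frequencies(rows)
  m <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pq <- count_PQ(rows[[i]], rows[[j]])
      pi <- if (per_pair) base_frequencies(rows[c(i, j)]) else pi_pool
      m[i, j] <- m[j, i] <- f84_distance(pq$P, pq$Q, pi)
    }
  }
  m
}

#' F84 instantaneous rate matrix
#'
#' Rate matrix of the F84 process with base frequencies `pi` and
#' within-group (transition) bias `kappa`, scaled so one unit of branch
#' length equals one expected substitution per site at stationarity.
#' The transition rate from i to j is proportional to
#' \eqn{\pi_j (1 + \kappa/\Pi_j)} within a purine or pyrimidine group
#' (\eqn{\Pi_j} the group frequency) and to \eqn{\pi_j} between groups.
#'
#' @param pi Base-frequency vector `c(A, C, G, T)`.
#' @param kappa Non-negative transition bias; 0 collapses to the equal
#'   input rate (Felsenstein 1981) process.
#' @return 4x4 rate matrix with rows/columns `A,C,G,T`, zero row sums.
#' @export
f84_rate_matrix <- function(pi, kappa = 2) {
  stopifnot(length(pi) == 4L, all(pi > 0), kappa >= 0)
  pi <- pi / sum(pi)
  names(pi) <- BASES
  group <- c(A = "R", C = "Y", G = "R", T = "Y")
  group_freq <- c(R = pi[["A"]] + pi[["G"]], Y = pi[["C"]] + pi[["T"]])
  Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  for (i in BASES) for (j in BASES) {
    if (i == j) next
    Q[i, j] <- if (group[[i]] == group[[j]])
      pi[[j]] * (1 + kappa / group_freq[[group[[j]]]])
    else pi[[j]]
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q / scale
}

#' F84 transition-probability matrix for a branch
#'
#' Exact matrix exponential `P(t) = exp(Qt)` of the scaled F84 rate
#' matrix, computed through the symmetrized eigendecomposition that the
#' reversibility of F84 guarantees. Used by the sequence simulator so
#' that estimator-recovery checks are exact in expectation.
#'
#' @param t Branch length in expected substitutions per site.
#' @inheritParams f84_rate_matrix
#' @return 4x4 stochastic matrix.
#' @export
f84_transition_probs <- function(t, pi, kappa = 2) {
  stopifnot(t >= 0)
  Q <- f84_rate_matrix(pi, kappa)
  pi <- pi / sum(pi)
  D <- diag(sqrt(pi)); Dinv <- diag(1 / sqrt(pi))
  S <- D %*% Q %*% Dinv
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  P <- Dinv %*% e$vectors %*% diag(exp(e$values * t)) %*% t(e$vectors) %*% D
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(BASES, BASES)
  P
}
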