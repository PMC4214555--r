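# Small in-code fixtures shared across test files.

toy_features <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(feature_id = r[[1]], family_id = r[[2]], kind = r[[3]],
               start = as.integer(r[[4]]), end = as.integer(r[[5]]),
               strand = r[[6]], stringsAsFactors = FALSE)))
}

# A track with chosen depths; pad/truncate to genome_length
toy_track <- function(fwd, rev = NULL, genome_length = length(fwd),
                      strain = "s1", dataset = "d1") {
  pad <- function(x) c(x, integer(genome_length - length(x)))
  depth_track(strain, dataset, pad(fwd), if (!is.null(rev)) pad(rev))
}

# Uniform-depth interval on an otherwise empty genome
interval_track <- function(genome_length, start, end, depth,
                           strand = "+", stranded = TRUE) {
  fwd <- integer(genome_length); rev <- integer(genome_length)
  idx <- (start + 1):end
  if (strand == "-") rev[idx] <- depth else fwd[idx] <- depth
  depth_track("s1", "d1", fwd, if (stranded) rev)
}

small_sim_config <- function(...) {
  sim_config(n_strains = 4, n_protein_families = 15, n_rna_families = 10,
             genome_length = 30000, n_rufs_per_strain = 4,
             n_datasets = 1, ssu_length = 400, ...)
}

# Independent matrix exponential by scaling-and-squaring on a plain
# power series; used as an oracle for the F84 transition probabilities.
expm_series <- function(M) {
  k <- max(0L, ceiling(log2(max(1, norm(M, "1")))) + 8L)
  A <- M / 2^k
  P <- diag(nrow(M)); term <- diag(nrow(M))
  for (i in 1:30) {
    term <- term %*% A / i
    P <- P + term
  }
  for (i in seq_len(k)) P <- P %*% P
  P
}

# F84 rate matrix written out longhand (independent of the package's
# constructor) with rows/cols A,C,G,T, scaled to one substitution/site.
oracle_f84_rate <- function(pi, kappa) {
  piA <- pi[1]; piC <- pi[2]; piG <- pi[3]; piT <- pi[4]
  piR <- piA + piG; piY <- piC + piT
  Q <- rbind(
    c(0, piC, piG * (1 + kappa / piR), piT),
    c(piA, 0, piG, piT * (1 + kappa / piY)),
    c(piA * (1 + kappa / piR), piC, 0, piT),
    c(piA, piC * (1 + kappa / piY), piG, 0))
  diag(Q) <- -rowSums(Q)
  Q / sum(pi * -diag(Q))
}
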