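#' Configuration for the synthetic comparative RNA-seq generator
#'
#' Bundles and validates every tunable of the generator. The defaults
#' describe a small but realistic comparative design: a dozen strains, a
#' full-length SSU rRNA marker, more protein than RNA families, RNA
#' families lost an order of magnitude faster than protein families
#' along the tree, and sparse background depth typical of a well-made
#' bacterial RNA-seq library after rRNA depletion.
#'
#' @param n_strains Number of strains (>= 2).
#' @param tree_shape `"balanced"` (every edge `branch_scale` long) or
#'   `"coalescent"` (random coalescent shape with edges scaled by
#'   `branch_scale`).
#' @param branch_scale Edge length scale, expected substitutions/site.
#' @param ssu_length SSU rRNA length in nt (1500 matches 16S).
#' @param base_freqs Stationary base frequencies `c(A, C, G, T)`.
#' @param transition_bias F84 within-group bias `kappa` (>= 0).
#' @param n_protein_families,n_rna_families Family counts at the root.
#' @param loss_rate_protein,loss_rate_rna Irreversible per-branch family
#'   loss rates per unit branch length; the RNA rate must exceed the
#'   protein rate, matching the faster evolutionary turnover of
#'   noncoding RNA families.
#' @param genome_length Genome length in nt for every strain.
#' @param n_rufs_per_strain Expected number of planted RUFs per strain.
#' @param ruf_share_frac Probability that a strain carries a given RUF
#'   homology group.
#' @param ruf_expressed_frac Fraction of carrying strains in which a
#'   planted RUF is expressed above threshold.
#' @param ruf_level_range Range of per-group RUF expression levels
#'   (mean reads per base).
#' @param expression_law Rank-abundance decay exponent `alpha`: the
#'   k-th most abundant annotated gene has mean depth
#'   `peak_depth * k^-alpha`.
#' @param peak_depth Mean depth of the most abundant annotated gene.
#' @param noise_mean Mean background depth at unexpressed positions.
#' @param nb_size Negative-binomial size (inverse overdispersion) for
#'   all count noise; smaller is noisier, `Inf` gives deterministic
#'   depths equal to the rounded means.
#' @param n_datasets RNA-seq datasets simulated per strain.
#' @param stranded Whether tracks are strand-resolved.
#' @param structured_frac Fraction of RUF groups carrying simulated
#'   secondary-structure evidence.
#' @param protein_len_range,rna_len_range Gene length ranges (nt).
#' @param placement_margin Minimum gap kept between placed features.
#' @param seed Integer seed; every generator is reproducible from the
#'   configuration plus this seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 12, tree_shape = c("balanced", "coalescent"),
                       branch_scale = 0.02, ssu_length = 1500,
                       base_freqs = c(0.25, 0.23, 0.31, 0.21),
                       transition_bias = 2,
                       n_protein_families = 60, n_rna_families = 40,
                       loss_rate_protein = 0.5, loss_rate_rna = 5,
                       genome_length = 200000, n_rufs_per_strain = 8,
                       ruf_share_frac = 0.6, ruf_expressed_frac = 1,
                       ruf_level_range = c(30, 120),
                       expression_law = 0.7, peak_depth = 500,
                       noise_mean = 1, nb_size = 10, n_datasets = 2,
                       stranded = TRUE, structured_frac = 0.35,
                       protein_len_range = c(300, 900),
                       rna_len_range = c(80, 300),
                       placement_margin = 25, seed = 1L) {
  tree_shape <- match.arg(tree_shape)
  stopifnot(n_strains >= 2, branch_scale > 0, ssu_length > 0,
            length(base_freqs) == 4, all(base_freqs > 0),
            transition_bias >= 0,
            n_protein_families > 0, n_rna_families > 0,
            loss_rate_protein >= 0, loss_rate_rna > 0,
            loss_rate_rna > loss_rate_protein,
            genome_length > 0, n_rufs_per_strain >= 0,
            ruf_share_frac > 0, ruf_share_frac <= 1,
            ruf_expressed_frac >= 0, ruf_expressed_frac <= 1,
            expression_law > 0, peak_depth > 0, noise_mean >= 0,
            nb_size > 0, n_datasets >= 1)
  cfg <- list(n_strains = as.integer(n_strains), tree_shape = tree_shape,
              branch_scale = branch_scale, ssu_length = as.integer(ssu_length),
              base_freqs = base_freqs / sum(base_freqs),
              transition_bias = transition_bias,
              n_protein_families = as.integer(n_protein_families),
              n_rna_families = as.integer(n_rna_families),
              loss_rate_protein = loss_rate_protein,
              loss_rate_rna = loss_rate_rna,
              genome_length = as.integer(genome_length),
              n_rufs_per_strain = as.integer(n_rufs_per_strain),
              ruf_share_frac = ruf_share_frac,
              ruf_expressed_frac = ruf_expressed_frac,
              ruf_level_range = ruf_level_range,
              expression_law = expression_law, peak_depth = peak_depth,
              noise_mean = noise_mean, nb_size = nb_size,
              n_datasets = as.integer(n_datasets), stranded = stranded,
              structured_frac = structured_frac,
              protein_len_range = as.integer(protein_len_range),
              rna_len_range = as.integer(rna_len_range),
              placement_margin = as.integer(placement_margin),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

balanced_newick <- function(ids, bl) {
  build <- function(ids) {
    if (length(ids) == 1L) return(sprintf("%s:%g", ids, bl))
    half <- ceiling(length(ids) / 2)
    sprintf("(%s,%s):%g", build(ids[seq_len(half)]),
            build(ids[-seq_len(half)]), bl)
  }
  half <- ceiling(length(ids) / 2)
  sprintf("(%s,%s);", build(ids[seq_len(half)]), build(ids[-seq_len(half)]))
}

#' Simulate a strain phylogeny
#'
#' Balanced trees give every edge length `branch_scale` (two strains sit
#' at distance `2 * branch_scale`); coalescent trees draw a random
#' shape via [ape::rcoal()] and scale all edges by `branch_scale`. The
#' returned leaf-to-leaf path lengths are the ground-truth distances the
#' F84 estimator is later asked to recover.
#'
#' @param cfg A [sim_config()].
#' @return List with `tree` (rooted `phylo` with branch lengths) and
#'   `true_distances` (symmetric matrix of leaf path lengths).
#' @export
simulate_tree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_strains < 2) stop("need at least two strains")
  set.seed(cfg$seed)
  ids <- sprintf("strain_%02d", seq_len(cfg$n_strains))
  tree <- if (cfg$tree_shape == "balanced") {
    ape::read.tree(text = balanced_newick(ids, cfg$branch_scale))
  } else {
    t <- ape::rcoal(cfg$n_strains, tip.label = ids)
    t$edge.length <- t$edge.length * cfg$branch_scale
    t
  }
  d <- stats::cophenetic(tree)[ids, ids]
  list(tree = tree, true_distances = d)
}

evolve_along_edge <- function(states, P) {
  out <- integer(length(states))
  for (s in 1:4) {
    idx <- which(states == s)
    if (length(idx))
      out[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[s, ])
  }
  out
}

#' Evolve SSU rRNA sequences down a tree under F84
#'
#' Draws the root sequence from the stationary frequencies and applies,
#' on each branch, the exact F84 transition-probability matrix for that
#' branch length (see [f84_transition_probs()]). No indels are
#' introduced, so the leaf sequences are a valid alignment as they
#' stand; the estimator's gap handling is exercised with masked columns
#' in tests instead.
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param cfg A [sim_config()].
#' @return Named character vector of leaf sequences (an alignment).
#' @export
evolve_ssu <- function(tree, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  ntip <- length(tree$tip.label)
  tree <- stats::reorder(tree, "cladewise")
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- sample.int(4L, cfg$ssu_length, replace = TRUE,
                             prob = cfg$base_freqs)
  lens <- tree$edge.length
  pmats <- lapply(unique(lens), f84_transition_probs,
                  pi = cfg$base_freqs, kappa = cfg$transition_bias)
  names(pmats) <- format(unique(lens), digits = 15)
  for (k in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[k, 1L]; child <- tree$edge[k, 2L]
    P <- pmats[[format(lens[k], digits = 15)]]
    seqs[[child]] <- evolve_along_edge(seqs[[parent]], P)
  }
  tips <- vapply(seq_len(ntip),
                 function(i) paste(BASES[seqs[[i]]], collapse = ""),
                 character(1))
  names(tips) <- tree$tip.label
  tips
}

#' Simulate family presence/absence by irreversible loss on a tree
#'
#' Every family is present at the root and is lost on each branch with
#' probability `1 - exp(-loss_rate * branch_length)`, independently per
#' family and branch; loss is irreversible down-tree. RNA families use
#' `loss_rate_rna`, protein families `loss_rate_protein`, producing the
#' faster decay of RNA-family conservation with phylogenetic distance.
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param cfg A [sim_config()].
#' @return List with `presence` (family x strain logical matrix),
#'   `kind` and `loss_rate` (named per-family vectors).
#' @export
simulate_family_presence <- function(tree, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  fam_ids <- c(sprintf("PF%04d", seq_len(cfg$n_protein_families)),
               sprintf("RF%04d", seq_len(cfg$n_rna_families)))
  kind <- c(rep("protein", cfg$n_protein_families),
            rep("rna", cfg$n_rna_families))
  lambda <- ifelse(kind == "protein", cfg$loss_rate_protein, cfg$loss_rate_rna)
  names(kind) <- names(lambda) <- fam_ids
  nf <- length(fam_ids)
  ntip <- length(tree$tip.label)
  tree <- stats::reorder(tree, "cladewise")
  pres <- matrix(FALSE, nf, ntip + tree$Nnode)
  pres[, ntip + 1L] <- TRUE
  for (k in seq_len(nrow(tree$edge))) {
    surv <- stats::runif(nf) < exp(-lambda * tree$edge.length[k])
    pres[, tree$edge[k, 2L]] <- pres[, tree$edge[k, 1L]] & surv
  }
  presence <- pres[, seq_len(ntip), drop = FALSE]
  dimnames(presence) <- list(fam_ids, tree$tip.label)
  list(presence = presence, kind = kind, loss_rate = lambda)
}

place_intervals <- function(lengths, genome_length, occupied, margin) {
  # occupied: 2-column matrix of half-open intervals already taken
  placed <- matrix(integer(), 0L, 2L)
  for (len in lengths) {
    ok <- FALSE
    for (try in 1:500) {
      s <- sample.int(genome_length - len + 1L, 1L) - 1L
      e <- s + len
      all_iv <- rbind(occupied, placed)
      if (!nrow(all_iv) ||
          all(e + margin <= all_iv[, 1L] | s >= all_iv[, 2L] + margin)) {
        placed <- rbind(placed, c(s, e)); ok <- TRUE; break
      }
    }
    if (!ok) stop("genome too small to place features without overlap")
  }
  placed
}

# size = Inf gives noiseless (deterministic) depth, handy for exact checks
nb_draw <- function(n, mu, size) {
  if (mu <= 0) return(integer(n))
  if (!is.finite(size)) return(rep(as.integer(round(mu)), n))
  stats::rnbinom(n, size = size, mu = mu)
}

#' Simulate annotations and coverage tracks with planted RUFs
#'
#' For each strain, places one gene per present family and the strain's
#' planted RUF intervals uniformly at random without overlap, assigns
#' annotated genes mean depths following a rank-abundance law
#' (`peak_depth * k^-alpha`), gives each RUF homology group a shared
#' expression level, and draws per-base depths as overdispersed
#' (negative-binomial) counts around those means on the feature's
#' strand, on top of background noise with mean `noise_mean`.
#'
#' @param tree Rooted `phylo` tree (supplies strain ids).
#' @param fams Result of [simulate_family_presence()].
#' @param cfg A [sim_config()].
#' @return List with `annotations` (named list of `AnnotationSet`,
#'   annotated genes only), `tracks` (per strain, a list of
#'   `DepthTrack`s, one per dataset), `planted_rufs` (data frame of
#'   planted intervals with true levels and homology groups),
#'   `ruf_groups` (per-group length, level and structure flag) and
#'   `gene_levels` (the true mean depth assigned to every annotated
#'   gene, for recovery tests).
#' @export
simulate_tracks <- function(tree, fams, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 3L)
  strains <- tree$tip.label
  n_groups <- max(1L, round(cfg$n_rufs_per_strain / cfg$ruf_share_frac))
  if (cfg$n_rufs_per_strain == 0L) n_groups <- 0L
  ruf_groups <- if (n_groups) data.frame(
    group_id = sprintf("RUF%04d", seq_len(n_groups)),
    length = sample(50:400, n_groups, replace = TRUE),
    level = stats::runif(n_groups, cfg$ruf_level_range[1L], cfg$ruf_level_range[2L]),
    structured = stats::runif(n_groups) < cfg$structured_frac,
    stringsAsFactors = FALSE)
  else data.frame(group_id = character(), length = integer(),
                  level = numeric(), structured = logical())
  carry <- if (n_groups)
    matrix(stats::runif(n_groups * length(strains)) < cfg$ruf_share_frac,
           n_groups, length(strains), dimnames = list(ruf_groups$group_id, strains))
  else matrix(FALSE, 0L, length(strains))
  # guarantee every group is carried somewhere
  for (g in seq_len(n_groups))
    if (!any(carry[g, ])) carry[g, sample.int(length(strains), 1L)] <- TRUE

  annotations <- list(); tracks <- list()
  planted <- list(); gene_levels <- list()
  for (si in seq_along(strains)) {
    st <- strains[si]
    fam_here <- rownames(fams$presence)[fams$presence[, st]]
    kinds <- fams$kind[fam_here]
    glens <- ifelse(kinds == "protein",
                    sample(cfg$protein_len_range[1L]:cfg$protein_len_range[2L],
                           length(fam_here), replace = TRUE),
                    sample(cfg$rna_len_range[1L]:cfg$rna_len_range[2L],
                           length(fam_here), replace = TRUE))
    groups_here <- ruf_groups$group_id[carry[, st]]
    rlens <- ruf_groups$length[carry[, st]]
    iv <- place_intervals(c(glens, rlens), cfg$genome_length,
                          matrix(integer(), 0L, 2L), cfg$placement_margin)
    ng <- length(fam_here)
    strands <- sample(c("+", "-"), ng + length(groups_here), replace = TRUE)
    features <- data.frame(
      feature_id = if (ng) sprintf("%s_%s", st, fam_here) else character(),
      family_id = fam_here, kind = unname(kinds),
      start = iv[seq_len(ng), 1L], end = iv[seq_len(ng), 2L],
      strand = strands[seq_len(ng)], stringsAsFactors = FALSE)
    annotations[[st]] <- annotation_set(st, cfg$genome_length, features)

    # rank-abundance mean depths for annotated genes
    lev_order <- sample.int(ng)
    gene_level <- numeric(ng)
    gene_level[lev_order] <- cfg$peak_depth * seq_len(ng)^(-cfg$expression_law)
    if (ng) gene_levels[[st]] <- data.frame(
      strain_id = st, feature_id = features$feature_id,
      level = gene_level, stringsAsFactors = FALSE)
    ruf_level <- ruf_groups$level[carry[, st]]
    ruf_expr <- stats::runif(length(ruf_level)) < cfg$ruf_expressed_frac
    if (length(groups_here))
      planted[[st]] <- data.frame(
        strain_id = st, group_id = groups_here,
        start = iv[ng + seq_along(groups_here), 1L],
        end = iv[ng + seq_along(groups_here), 2L],
        strand = strands[ng + seq_along(groups_here)],
        level = ifelse(ruf_expr, ruf_level, 0),
        expressed = ruf_expr, stringsAsFactors = FALSE)

    starts <- iv[, 1L]; ends <- iv[, 2L]
    levels <- c(gene_level, ifelse(ruf_expr, ruf_level, 0))
    tracks[[st]] <- lapply(seq_len(cfg$n_datasets), function(ds) {
      fwd <- nb_draw(cfg$genome_length, cfg$noise_mean, cfg$nb_size)
      rev <- if (cfg$stranded) nb_draw(cfg$genome_length, cfg$noise_mean, cfg$nb_size)
             else integer(cfg$genome_length)
      for (k in seq_along(levels)) {
        if (levels[k] <= 0) next
        idx <- (starts[k] + 1L):ends[k]
        sig <- nb_draw(length(idx), levels[k], cfg$nb_size)
        if (!cfg$stranded || strands[k] == "+") fwd[idx] <- fwd[idx] + sig
        else rev[idx] <- rev[idx] + sig
      }
      mapped <- sum(fwd) + sum(rev)
      depth_track(st, sprintf("ds%02d", ds), fwd,
                  if (cfg$stranded) rev,
                  total_reads = round(mapped * 1.1), mapped_reads = mapped)
    })
    names(tracks[[st]]) <- sprintf("ds%02d", seq_len(cfg$n_datasets))
  }
  planted <- if (length(planted)) do.call(rbind, planted)
             else data.frame(strain_id = character(), group_id = character(),
                             start = integer(), end = integer(),
                             strand = character(), level = numeric(),
                             expressed = logical())
  rownames(planted) <- NULL
  gene_levels <- if (length(gene_levels)) do.call(rbind, gene_levels)
                 else data.frame(strain_id = character(),
                                 feature_id = character(), level = numeric())
  rownames(gene_levels) <- NULL
  list(annotations = annotations, tracks = tracks,
       planted_rufs = planted, ruf_groups = ruf_groups,
       gene_levels = gene_levels)
}

#' Generate a complete synthetic comparative RNA-seq study
#'
#' Runs [simulate_tree()], [evolve_ssu()], [simulate_family_presence()]
#' and [simulate_tracks()] and bundles their outputs with the ground
#' truth needed for recovery tests.
#'
#' @param cfg A [sim_config()].
#' @return List with `cfg`, `tree`, `true_distances`, `alignment`,
#'   `families`, `annotations`, `tracks`, `planted_rufs`, `ruf_groups`.
#' @export
simulate_dataset <- function(cfg) {
  tr <- simulate_tree(cfg)
  aln <- evolve_ssu(tr$tree, cfg)
  fams <- simulate_family_presence(tr$tree, cfg)
  tk <- simulate_tracks(tr$tree, fams, cfg)
  c(list(cfg = cfg, tree = tr$tree, true_distances = tr$true_distances,
         alignment = aln, families = fams), tk)
}

#' Write a simulated study to a directory of standard files
#'
#' Emits per-strain GFF3 and bedGraph files, the SSU alignment as
#' aligned FASTA, the tree as Newick, a family/homology TSV (one row
#' per family x strain, including planted RUF groups) and a truth JSON
#' with the simulation configuration, true distances and planted RUFs.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (st in names(sim$annotations))
    write_annotation(sim$annotations[[st]], file.path(dir, paste0(st, ".gff3")))
  for (st in names(sim$tracks))
    for (ds in names(sim$tracks[[st]])) {
      tk <- sim$tracks[[st]][[ds]]
      write_depth(tk, file.path(dir, sprintf("%s_%s_fwd.bedgraph", st, ds)),
                  if (tk$stranded) file.path(dir, sprintf("%s_%s_rev.bedgraph", st, ds)))
    }
  write_alignment(sim$alignment, file.path(dir, "ssu_alignment.fasta"))
  write_newick(sim$tree, file.path(dir, "tree.nwk"))
  pres <- sim$families$presence
  fam_rows <- data.frame(
    family_id = rep(rownames(pres), ncol(pres)),
    strain_id = rep(colnames(pres), each = nrow(pres)),
    kind = rep(unname(sim$families$kind[rownames(pres)]), ncol(pres)),
    present = as.vector(pres), start = NA_integer_, end = NA_integer_,
    strand = NA_character_, stringsAsFactors = FALSE)
  ruf_rows <- if (nrow(sim$planted_rufs)) data.frame(
    family_id = sim$planted_rufs$group_id,
    strain_id = sim$planted_rufs$strain_id,
    kind = "ruf", present = TRUE,
    start = sim$planted_rufs$start, end = sim$planted_rufs$end,
    strand = sim$planted_rufs$strand, stringsAsFactors = FALSE)
  else NULL
  write_tsv_report(rbind(fam_rows, ruf_rows), file.path(dir, "homology.tsv"))
  truth <- list(config = unclass(sim$cfg),
                true_distances = sim$true_distances,
                planted_rufs = sim$planted_rufs,
                ruf_groups = sim$ruf_groups)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
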