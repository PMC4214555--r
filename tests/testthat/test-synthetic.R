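test_that("tree simulation honours branch scale, seed and metric axioms", {
  cfg2 <- sim_config(n_strains = 2, branch_scale = 0.03, seed = 4)
  tr <- simulate_tree(cfg2)
  expect_equal(tr$true_distances["strain_01", "strain_02"], 0.06)

  cfg <- sim_config(n_strains = 9, tree_shape = "coalescent", seed = 8)
  tr1 <- simulate_tree(cfg)
  tr2 <- simulate_tree(cfg)
  expect_identical(tr1$true_distances, tr2$true_distances)

  d <- tr1$true_distances
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 9))
  trip <- combn(9, 3)
  for (k in seq_len(ncol(trip))) {
    i <- trip[1, k]; j <- trip[2, k]; l <- trip[3, k]
    expect_lte(d[i, j], d[i, l] + d[l, j] + 1e-12)
  }
})

test_that("sequence evolution is the generative twin of the F84 estimator", {
  # zero-length branches copy the root sequence
  cfg0 <- sim_config(n_strains = 4, seed = 2)
  tr <- simulate_tree(cfg0)$tree
  tr$edge.length[] <- 0
  aln0 <- evolve_ssu(tr, cfg0)
  expect_length(unique(unname(aln0)), 1L)

  # observed mismatch fraction between two leaves matches the analytic
  # F84 site-difference probability within 3 Monte-Carlo SE
  cfg <- sim_config(n_strains = 2, ssu_length = 10000, branch_scale = 0.08,
                    transition_bias = 3, seed = 31)
  aln <- evolve_ssu(simulate_tree(cfg)$tree, cfg)
  a <- strsplit(aln[[1]], "")[[1]]; b <- strsplit(aln[[2]], "")[[1]]
  p_obs <- mean(a != b)
  P <- expm_series(oracle_f84_rate(cfg$base_freqs, 3) * 0.08)
  # leaves sit 0.08 from the root on each side; mismatch prob marginalizes
  # over the root state drawn from the stationary frequencies
  p_exp <- sum(vapply(1:4, function(r)
    cfg$base_freqs[r] * (1 - sum(P[r, ]^2)), numeric(1)))
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("estimated distances recover true path lengths with slope near 1", {
  set.seed(17)
  d_true <- seq(0.02, 0.3, length.out = 50)
  d_est <- vapply(seq_along(d_true), function(i) {
    cfg <- sim_config(n_strains = 2, ssu_length = 5000,
                      branch_scale = d_true[i] / 2, seed = 1000L + i)
    aln <- evolve_ssu(simulate_tree(cfg)$tree, cfg)
    f84_distance_matrix(aln)[1, 2]
  }, numeric(1))
  slope <- coef(lm(d_est ~ 0 + d_true))[[1]]
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
})

test_that("family loss follows the exponential survival law on a two-leaf tree", {
  # loss rate ~0 keeps every family everywhere
  cfg0 <- sim_config(n_strains = 6, loss_rate_protein = 0,
                     loss_rate_rna = 1e-9, seed = 3)
  fams0 <- simulate_family_presence(simulate_tree(cfg0)$tree, cfg0)
  expect_true(all(fams0$presence))

  # extreme loss leaves each family in at most a single lineage
  cfg_hot <- sim_config(n_strains = 6, loss_rate_protein = 100,
                        loss_rate_rna = 200, seed = 3)
  fams_hot <- simulate_family_presence(simulate_tree(cfg_hot)$tree, cfg_hot)
  expect_lte(max(rowSums(fams_hot$presence)), 1L)

  # closed form on a 2-leaf tree: P(present in both) = exp(-lambda*(l1+l2))
  cfg <- sim_config(n_strains = 2, branch_scale = 0.1,
                    n_protein_families = 5000, n_rna_families = 5000,
                    loss_rate_protein = 2, loss_rate_rna = 6, seed = 23)
  fams <- simulate_family_presence(simulate_tree(cfg)$tree, cfg)
  for (kind in c("protein", "rna")) {
    lambda <- if (kind == "protein") 2 else 6
    pres <- fams$presence[fams$kind == kind, , drop = FALSE]
    p_both <- mean(rowSums(pres) == 2L)
    p_exp <- exp(-lambda * 0.2)
    se <- sqrt(p_exp * (1 - p_exp) / 5000)
    expect_lt(abs(p_both - p_exp), 3 * se)
  }
})

test_that("noiseless tracks place exact depths on planted features only", {
  cfg <- sim_config(n_strains = 2, n_protein_families = 4, n_rna_families = 2,
                    genome_length = 20000, n_rufs_per_strain = 3,
                    n_datasets = 1, noise_mean = 0, nb_size = Inf,
                    peak_depth = 50, seed = 12)
  tr <- simulate_tree(cfg)
  fams <- simulate_family_presence(tr$tree, cfg)
  tk <- simulate_tracks(tr$tree, fams, cfg)
  st <- "strain_01"
  track <- tk$tracks[[st]][[1]]
  ann <- tk$annotations[[st]]
  lev <- tk$gene_levels[tk$gene_levels$strain_id == st, ]
  for (i in seq_len(nrow(ann$features))) {
    f <- ann$features[i, ]
    expect_equal(median_depth(track, f$start, f$end, f$strand),
                 round(lev$level[lev$feature_id == f$feature_id]))
  }
  # the most abundant gene sits exactly at the rank-abundance peak
  expect_equal(max(round(lev$level)), 50)

  # coverage >= 10X footprint equals the expressed feature + RUF footprint
  planted <- tk$planted_rufs[tk$planted_rufs$strain_id == st, ]
  expressed_len <- sum((ann$features$end - ann$features$start)[
    round(lev$level[match(ann$features$feature_id, lev$feature_id)]) >= 10]) +
    sum((planted$end - planted$start)[round(planted$level) >= 10])
  expect_equal(sum(combined_depth(track) >= 10), expressed_len)
})

test_that("planted RUFs are recovered by the caller with default thresholds", {
  cfg <- sim_config(n_strains = 2, n_protein_families = 6, n_rna_families = 4,
                    genome_length = 30000, n_rufs_per_strain = 4,
                    n_datasets = 1, seed = 62)
  sim <- simulate_dataset(cfg)
  st <- "strain_01"
  calls <- call_rufs(sim$tracks[[st]][[1]], sim$annotations[[st]])
  planted <- sim$planted_rufs[sim$planted_rufs$strain_id == st &
                              sim$planted_rufs$expressed, ]
  for (i in seq_len(nrow(planted))) {
    ov <- pmin(calls$end, planted$end[i]) - pmax(calls$start, planted$start[i])
    span <- pmax(calls$end - calls$start, planted$end[i] - planted$start[i])
    expect_true(any(ov / span >= 0.5 & calls$strand == planted$strand[i]))
  }
})

test_that("the whole generator is reproducible bit-for-bit from (cfg, seed)", {
  cfg <- small_sim_config(seed = 77)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$alignment, s2$alignment)
  expect_identical(s1$families$presence, s2$families$presence)
  expect_identical(s1$planted_rufs, s2$planted_rufs)
  expect_identical(lapply(s1$tracks, lapply, `[[`, "fwd"),
                   lapply(s2$tracks, lapply, `[[`, "fwd"))
})

test_that("simulated RNA families decay faster than protein families", {
  cfg <- sim_config(n_strains = 8, tree_shape = "coalescent",
                    branch_scale = 0.15, n_protein_families = 1500,
                    n_rna_families = 1500, loss_rate_protein = 0.5,
                    loss_rate_rna = 5, seed = 41)
  tr <- simulate_tree(cfg)
  fams <- simulate_family_presence(tr$tree, cfg)
  presence <- apply(fams$presence, 1, function(r)
    colnames(fams$presence)[r], simplify = FALSE)
  fc <- family_conservation(presence, tr$true_distances)
  fc$kind <- fams$kind[fc$family_id]
  grid <- seq(0, max(tr$true_distances), length.out = 40)[-1]
  curves <- lapply(split(fc, fc$kind), conserved_fraction_curve, grid = grid)
  for (cv in curves) expect_true(all(diff(cv$fraction) <= 0))
  expect_true(all(curves$rna$fraction <= curves$protein$fraction))
})
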