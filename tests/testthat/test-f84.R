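test_that("base frequencies pool rows and ignore gaps and ambiguity", {
  expect_equal(unname(base_frequencies(c(a = "ACGT", b = "ACGT"))),
               rep(0.25, 4))
  expect_equal(base_frequencies(c(a = "AAAA", b = "AACC"))[["A"]], 0.75)
  expect_equal(base_frequencies(c(a = "AAAA", b = "AACC"))[["C"]], 0.25)
  expect_equal(base_frequencies(c(a = "A-", b = "AA"))[["A"]], 1)
  expect_error(base_frequencies(c(a = "--NN", b = "--NN")), "no unambiguous")
})

test_that("transition/transversion counting uses pairwise deletion", {
  expect_equal(count_PQ("ACGT", "ACGT"), list(P = 0, Q = 0, n_sites = 4L))
  pq <- count_PQ("AG", "GG")
  expect_equal(pq$P, 0.5)
  expect_equal(pq$Q, 0)
  expect_equal(pq$n_sites, 2L)
  # gap in either row removes the site from comparison
  pq <- count_PQ("AC-T", "ACG-")
  expect_equal(pq, list(P = 0, Q = 0, n_sites = 2L))
  expect_error(count_PQ("--", "AA"), "no comparable sites")
})

test_that("F84 distance matches the closed form and an independent ML fit", {
  eqpi <- rep(0.25, 4)
  expect_equal(f84_distance(0, 0, eqpi), 0)
  # hand-evaluated closed form: A=0.25, B=0.125, C=0.25 at equal frequencies
  d <- f84_distance(0.1, 0.1, eqpi)
  expect_equal(d, 0.2341, tolerance = 1e-3)

  # independent route: maximize the multinomial likelihood of the implied
  # site-pattern counts over branch length and transition bias, using a
  # series matrix exponential of a longhand F84 rate matrix
  n <- 1000; n_ts <- 100; n_tv <- 100; n_same <- n - n_ts - n_tv
  negll <- function(par) {
    P <- expm_series(oracle_f84_rate(eqpi, par[2]) * par[1])
    p_same <- sum(eqpi * diag(P))
    p_ts <- eqpi[1] * P[1, 3] + eqpi[3] * P[3, 1] +
            eqpi[2] * P[2, 4] + eqpi[4] * P[4, 2]
    p_tv <- 1 - p_same - p_ts
    -(n_same * log(p_same) + n_ts * log(p_ts) + n_tv * log(p_tv))
  }
  fit <- optim(c(0.3, 1), negll, method = "L-BFGS-B",
               lower = c(1e-4, 1e-4), upper = c(3, 50))
  expect_equal(fit$par[1], d, tolerance = 1e-3)
})

test_that("saturation yields +Inf with a warning, not an error", {
  expect_warning(d <- f84_distance(0.6, 0.4, rep(0.25, 4)), "saturat")
  expect_identical(d, Inf)
})

test_that("distance is strictly increasing in P below saturation", {
  pi <- c(0.3, 0.2, 0.3, 0.2)
  Q <- 0.05
  Ps <- seq(0, 0.4, by = 0.02)
  ds <- vapply(Ps, f84_distance, numeric(1), Q = Q, pi = pi)
  expect_true(all(diff(ds) > 0))
})

test_that("distance matrices are symmetric with zero diagonal and flag duplicates", {
  cfg <- small_sim_config(seed = 5)
  sim <- simulate_tree(cfg)
  aln <- evolve_ssu(sim$tree, cfg)
  aln <- c(aln, dup = unname(aln[1]))
  m <- f84_distance_matrix(aln)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, nrow(m)))
  expect_equal(m["strain_01", "dup"], 0)
})

test_that("F84 distances agree with an established implementation", {
  cfg <- sim_config(n_strains = 6, ssu_length = 2000, branch_scale = 0.05,
                    seed = 42)
  aln <- evolve_ssu(simulate_tree(cfg)$tree, cfg)
  m <- f84_distance_matrix(aln)
  bin <- ape::as.DNAbin(lapply(strsplit(aln, ""), tolower))
  ref <- as.matrix(ape::dist.dna(bin, model = "F84", pairwise.deletion = TRUE))
  expect_equal(m, ref[rownames(m), colnames(m)], tolerance = 1e-8)
})

test_that("estimates on data generated without transition bias match the
           equal-rate closed form", {
  cfg <- sim_config(n_strains = 2, ssu_length = 10000, branch_scale = 0.1,
                    base_freqs = rep(0.25, 4), transition_bias = 1e-9,
                    seed = 99)
  aln <- evolve_ssu(simulate_tree(cfg)$tree, cfg)
  pq <- count_PQ(aln[[1]], aln[[2]])
  p <- pq$P + pq$Q
  d_jc <- -0.75 * log(1 - 4 * p / 3)
  d_f84 <- f84_distance(pq$P, pq$Q, rep(0.25, 4))
  se <- sqrt(p * (1 - p) / pq$n_sites) / (1 - 4 * p / 3)
  expect_lt(abs(d_f84 - 0.2), 3 * se)
  expect_lt(abs(d_f84 - d_jc), 3 * se)
})

test_that("masked alignment columns are tolerated via pairwise deletion", {
  cfg <- sim_config(n_strains = 2, ssu_length = 5000, branch_scale = 0.05,
                    seed = 13)
  aln <- evolve_ssu(simulate_tree(cfg)$tree, cfg)
  d_full <- f84_distance_matrix(aln)[1, 2]
  set.seed(13)
  mask <- sample(5000, 1000)
  chars <- strsplit(aln[[1]], "")[[1]]
  chars[mask] <- "-"
  aln_masked <- c(aln[-1],
                  stats::setNames(paste(chars, collapse = ""), "masked"))
  d_masked <- f84_distance_matrix(aln_masked)["masked", "strain_02"]
  expect_true(is.finite(d_masked))
  expect_equal(d_masked, d_full, tolerance = 0.15)
})

test_that("family conservation takes the max pairwise distance and classifies it", {
  m <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  m["a", "b"] <- m["b", "a"] <- 0.1
  m["a", "c"] <- m["c", "a"] <- 0.3
  m["b", "c"] <- m["c", "b"] <- 0.2
  fc <- family_conservation(
    list(solo = "a", pairHigh = c("a", "c"), trio = c("a", "b", "c")),
    m * 5 / 3, class_thresholds())  # scale so a-c pair sits at 0.5
  expect_equal(fc$max_distance[fc$family_id == "solo"], 0)
  expect_equal(fc$conservation_class[fc$family_id == "solo"], "Low")
  expect_equal(fc$max_distance[fc$family_id == "pairHigh"], 0.5)
  expect_equal(fc$conservation_class[fc$family_id == "pairHigh"], "High")

  fc2 <- family_conservation(list(trio = c("a", "b", "c")), m,
                             class_thresholds())
  expect_equal(fc2$max_distance, 0.3)
  expect_equal(fc2$conservation_class, "Medium")
  expect_error(family_conservation(list(f = c("a", "zz")), m), "absent")
})

test_that("adding a strain to a family never decreases its score", {
  set.seed(21)
  ids <- letters[1:6]
  m <- matrix(runif(36, 0, 0.6), 6, 6, dimnames = list(ids, ids))
  m <- (m + t(m)) / 2; diag(m) <- 0
  for (rep in 1:20) {
    strains <- sample(ids, sample(2:5, 1))
    extra <- sample(setdiff(ids, strains), 1)
    d1 <- family_conservation(list(f = strains), m)$max_distance
    d2 <- family_conservation(list(f = c(strains, extra)), m)$max_distance
    expect_gte(d2, d1)
  }
})
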