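fam_records <- function(max_distances, n_strains = NULL) {
  data.frame(family_id = sprintf("f%03d", seq_along(max_distances)),
             n_strains = if (is.null(n_strains))
               ifelse(max_distances > 0, 2L, 1L) else n_strains,
             max_distance = max_distances,
             conservation_class = conservation_class(max_distances),
             stringsAsFactors = FALSE)
}

test_that("conserved-fraction curves count families at or beyond each distance", {
  cv <- conserved_fraction_curve(fam_records(c(0, 0, 0)), c(0.1, 0.2))
  expect_equal(cv$fraction, c(0, 0))

  cv <- conserved_fraction_curve(fam_records(c(0.1, 0.3, 0.5)),
                                 c(0.05, 0.2, 0.4))
  expect_equal(cv$fraction, c(1, 2 / 3, 1 / 3))
  expect_true(all(diff(cv$fraction) <= 0))
  expect_error(conserved_fraction_curve(fam_records(numeric()), c(0.1)),
               "no family records")
  # singletons stay in the denominator unless min_strains excludes them
  recs <- fam_records(c(0, 0.3), n_strains = c(1L, 2L))
  expect_equal(conserved_fraction_curve(recs, 0.2)$fraction, 0.5)
  expect_equal(conserved_fraction_curve(recs, 0.2, min_strains = 2)$fraction, 1)
})

test_that("distance_at_fraction follows the step-function convention", {
  cv <- structure(data.frame(distance = c(0.1, 0.2, 0.3),
                             fraction = c(1, 1, 1)),
                  class = c("conserved_fraction_curve", "data.frame"))
  expect_equal(distance_at_fraction(cv, 0.8), 0.3)
  cv2 <- structure(data.frame(distance = c(0.1, 0.2),
                              fraction = c(0.9, 0.7)),
                   class = c("conserved_fraction_curve", "data.frame"))
  expect_equal(distance_at_fraction(cv2, 0.8), 0.1)
  expect_true(is.na(distance_at_fraction(cv2, 0.95)))

  # result is non-increasing in the target over random monotone curves
  set.seed(71)
  for (rep in 1:20) {
    fr <- sort(runif(10), decreasing = TRUE)
    cv3 <- structure(data.frame(distance = seq(0.1, 1, length.out = 10),
                                fraction = fr),
                     class = c("conserved_fraction_curve", "data.frame"))
    targets <- sort(runif(5, min(fr) + 1e-9, max(fr)))
    res <- vapply(targets, distance_at_fraction, numeric(1), curve = cv3)
    expect_true(all(diff(res) <= 0))
  }
})

test_that("within-domain pair enumeration excludes cross-domain pairs", {
  doms <- c(setNames(rep("Bacteria", 32), sprintf("b%02d", 1:32)),
            setNames(rep("Archaea", 5), sprintf("a%02d", 1:5)))
  expect_equal(nrow(enumerate_pairs(doms)), 506L)
  expect_equal(nrow(enumerate_pairs(c(x = "Bacteria", y = "Bacteria",
                                      z = "Archaea"))), 1L)
  n <- 7
  only_b <- setNames(rep("Bacteria", n), sprintf("b%02d", 1:n))
  expect_equal(nrow(enumerate_pairs(only_b)), n * (n - 1) / 2)
})

test_that("zone classification partitions distances with closed bounds", {
  zone <- goldilocks_zone()
  expect_equal(classify_pair(0.03, zone), "goldilocks")
  expect_equal(classify_pair(0.005, zone), "too_hot")
  expect_equal(classify_pair(0.2, zone), "too_cold")
  expect_equal(classify_pair(0.0118, zone), "goldilocks")
  expect_equal(classify_pair(0.0542, zone), "goldilocks")
  set.seed(3)
  d <- c(0, runif(200, 0, 0.2), zone$d_min, zone$d_max)
  labels <- classify_pair(d, zone)
  expect_true(all(labels %in% c("too_hot", "goldilocks", "too_cold")))
  expect_equal(labels == "too_hot", d < zone$d_min)
  expect_equal(labels == "too_cold", d > zone$d_max)
})

test_that("derived zone bounds come from the RNA conserved-fraction curve", {
  recs <- fam_records(seq(0, 1, length.out = 101))
  cv <- conserved_fraction_curve(recs, seq(0.005, 1, by = 0.005))
  zone <- derived_zone(cv)
  expect_lt(zone$d_min, zone$d_max)
  expect_equal(zone$d_max, distance_at_fraction(cv, 0.8))
  expect_equal(zone$d_min, distance_at_fraction(cv, 0.99))
})

test_that("evidence integration counts criteria and fills the Venn diagram", {
  rec <- data.frame(group_id = "g1", conserved = TRUE, structured = TRUE,
                    expressed_elsewhere = TRUE)
  ev <- evidence_integration(rec)
  expect_equal(ev$records$n_criteria, 3L)
  expect_equal(unname(ev$venn["CSE"]), 1L)

  set.seed(14)
  n <- 200
  conserved <- runif(n) < 0.5
  structured <- runif(n) < 0.4
  expressed <- conserved & runif(n) < 0.6
  ev2 <- evidence_integration(data.frame(
    group_id = sprintf("g%03d", 1:n), conserved = conserved,
    structured = structured, expressed_elsewhere = expressed))
  expect_equal(sum(ev2$venn), n)
  expect_equal(ev2$n_high_confidence, sum(ev2$records$n_criteria >= 2))

  bad <- data.frame(group_id = "g1", conserved = FALSE, structured = FALSE,
                    expressed_elsewhere = TRUE)
  expect_error(evidence_integration(bad), "without conserved")
})
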