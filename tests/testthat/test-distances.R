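test_that("circular boundary-gap distance follows the shorter arc", {
  L <- 1e5
  expect_equal(circular_distance(10e3, 11e3, 90e3, 91e3, L), 19e3)
  expect_equal(circular_distance(90e3, 91e3, 10e3, 11e3, L), 19e3)
  expect_equal(circular_distance(0, 1000, 1000, 2000, L), 0)  # adjacent
  expect_equal(circular_distance(0, 1000, 500, 1500, L), 0)   # overlap
  expect_equal(circular_distance(0, 1000, 5000, 6000, L), 4000)
  ## wrap-encoded feature (end > L)
  expect_equal(circular_distance(99e3, 101e3, 2e3, 3e3, L), 1e3)
  ## vectorised
  expect_equal(circular_distance(c(0, 0), c(1e3, 1e3), c(2e3, 5e3),
                                 c(3e3, 6e3), L), c(1e3, 4e3))
})

test_that("midpoint distance is symmetric and bounded by half the circle", {
  L <- 1e5
  expect_equal(midpoint_distance(10e3, 11e3, 90e3, 91e3, L), 20e3)
  expect_equal(midpoint_distance(90e3, 91e3, 10e3, 11e3, L), 20e3)
  set.seed(83)
  s <- runif(50, 0, L); e <- s + runif(50, 100, 3000)
  d <- midpoint_distance(s, e, rev(s), rev(e), L)
  expect_true(all(d <= L / 2 + 1e-9))
})

test_that("allele-aware pair distances take the minimum allele pair", {
  L <- 1e5
  genes <- rbind(
    toy_genes(c(0, 5e3, 45e3), c(1e3, 6e3, 46e3), L, genome_id = "G1",
              family = c("FB", "FA", "FA")),       # FA has two alleles
    toy_genes(c(0, 20e3), c(1e3, 21e3), L, genome_id = "G2",
              family = c("FB", "FA")))
  d1 <- per_occurrence_distances("FA", "FB", genes, convention = "gap")
  expect_equal(length(d1), 2L)
  expect_equal(unname(d1["G1"]), 4e3)      # min over the two alleles
  expect_equal(unname(d1["G2"]), 19e3)
  expect_equal(min_family_distance("FA", "FB", genes, convention = "gap"),
               4e3)
  expect_equal(min(d1), min_family_distance("FA", "FB", genes,
                                            convention = "gap"))
  ## a pair never co-present is undefined
  expect_true(is.na(min_family_distance("FA", "FZ", genes)))
  ## adding a genome can only decrease or keep the minimum
  extra <- toy_genes(c(0, 2e3), c(1e3, 3e3), L, genome_id = "G3",
                     family = c("FB", "FA"))
  expect_lte(min_family_distance("FA", "FB", rbind(genes, extra),
                                 convention = "gap"),
             min_family_distance("FA", "FB", genes, convention = "gap"))
})

test_that("intervening genes are counted on the shorter arc", {
  L <- 1e5
  genes <- toy_genes(c(0, 2e3, 4e3, 6e3, 50e3),
                     c(1e3, 3e3, 5e3, 7e3, 51e3), L,
                     family = c("FA", "FP", "FN", "FB", "FZ"),
                     product = c("a", "phage protein", "normal", "b", "z"))
  status <- classify_phage(genes, data.frame(family_id = c("FN", "FZ"),
                                             go_term = "GO:0006096"))
  pairs <- data.frame(family_a = "FA", family_b = "FB")
  rec <- pair_distances(pairs, genes, status = status, intervening = TRUE)
  expect_equal(rec$n_intervening, 2L)              # FP and FN between
  expect_equal(rec$frac_intervening_phage, 0.5)
  ## adjacent pair: no genes between -> fraction undefined
  rec2 <- pair_distances(data.frame(family_a = "FA", family_b = "FP"),
                         genes, status = status, intervening = TRUE)
  expect_equal(rec2$n_intervening, 0L)
  expect_true(is.na(rec2$frac_intervening_phage))
})

test_that("close/distant intervening-phage comparison summarises groups", {
  rec <- data.frame(
    family_a = "a", family_b = "b", pair = "a|b",
    genome_id = paste0("G", 1:8),
    distance = c(1e3, 2e3, 3e3, 4e3, 6e3, 7e3, 8e3, 9e3),
    n_intervening = c(1L, 2L, 1L, 0L, 3L, 4L, 5L, 2L),
    frac_intervening_phage = c(0, 0, 0, NA, 1, 0.75, 1, 0.5))
  s <- intervening_phage_stats(rec, close_bound = 5e3, far_bound = 1e4)
  expect_equal(s$n_close, 3L)          # the zero-intervening row drops out
  expect_equal(s$n_distant, 4L)
  expect_equal(s$mean_close, 0)
  expect_equal(s$mean_distant, 100 * mean(c(1, 0.75, 1, 0.5)))
  expect_equal(s$frac_distant_with_phage, 1)
  expect_lt(s$p_value, 0.05)
  expect_error(intervening_phage_stats(rec[, 1:5], 5e3, 1e4), "intervening")
})

test_that("distance distributions filter, sort and majorize correctly", {
  rec <- data.frame(
    family_a = c("a", "a", "c"), family_b = c("b", "b", "d"),
    pair = c("a|b", "a|b", "c|d"), genome_id = c("G1", "G2", "G1"),
    distance = c(30, 10, 20))
  status <- c(a = "not_associated", b = "not_associated",
              c = "associated", d = "not_associated")
  dmin <- build_distance_distribution(rec, status, "all", "min")
  expect_equal(dmin$distances, c(10, 20))
  docc <- build_distance_distribution(rec, status, "all", "occurrence")
  expect_equal(docc$distances, c(10, 20, 30))
  expect_equal(dist_cdf(docc, 20), 2 / 3)
  expect_true(all(diff(dist_cdf(docc, seq(0, 40, 5))) >= 0))
  ## non-phage filter requires both members strictly not associated
  dnp <- build_distance_distribution(rec, status, "non_phage", "min")
  expect_equal(dnp$distances, 10)
  ## min-over-genomes CDF dominates the per-occurrence CDF pointwise
  grid <- seq(0, 40, 1)
  expect_true(all(dist_cdf(dmin, grid) >= dist_cdf(docc, grid) - 1e-12))
})
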