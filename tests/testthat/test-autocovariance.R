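test_that("autocovariance matches site-by-site enumeration on toy genomes", {
  ## two adjacent 1 kb genes, zero gap, on a 10 kb circle
  genes <- toy_genes(c(1000, 2000), c(2000, 3000), 1e4,
                     family = c("FA", "FB"))
  Q <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2,
              dimnames = list(c("FA", "FB"), c("FA", "FB")))
  qual <- structure(list(families = c("FA", "FB"), Q = Q),
                    class = "pair_qualifier")
  ac1 <- compute_ac(genes, qual, frame = 1L, x_max = 4000)
  oracle <- ac_oracle(genes, qual, frame = 1L, x_max = 4000)
  expect_equal(ac1$curve$G, oracle$G, tolerance = 1e-12)
  ## positive exactly for cross-gene offsets (0 < x < 2 kb, circularly)
  expect_true(all(ac1$curve$G[ac1$curve$x < 2000] > 0))
  expect_true(all(ac1$curve$G[ac1$curve$x >= 2000 & ac1$curve$x < 7000] == 0))
  ## frame 10 agrees with frame 1 within discretisation error
  ac10 <- compute_ac(genes, qual, frame = 10L, x_max = 4000)
  on_grid <- ac1$curve$x %in% ac10$curve$x
  expect_lt(max(abs(ac10$curve$G - ac1$curve$G[on_grid])), 0.02)
})

test_that("sparse and dense (FFT) computation paths agree exactly", {
  set.seed(101)
  starts <- sort(sample(seq(0, 48e3, by = 1000), 12))  # non-overlapping
  genes <- toy_genes(starts, starts + 800, 5e4)
  fams <- genes$family_id
  ## dense qualifier: every cross pair qualifies -> FFT path
  Qd <- matrix(TRUE, 12, 12, dimnames = list(fams, fams)); diag(Qd) <- FALSE
  ## sparse qualifier: a handful of pairs -> direct trapezoid path
  Qs <- matrix(FALSE, 12, 12, dimnames = list(fams, fams))
  Qs[1, 2] <- Qs[2, 1] <- Qs[3, 7] <- Qs[7, 3] <- TRUE
  for (Q in list(Qd, Qs)) {
    qual <- structure(list(families = fams, Q = Q), class = "pair_qualifier")
    got <- compute_ac(genes, qual, frame = 10L, x_max = 8000)
    oracle <- ac_oracle(genes, qual, frame = 10L, x_max = 8000)
    expect_equal(got$curve$G, oracle$G, tolerance = 1e-9)
  }
  ## no qualifying pairs: flat zero curve, rescaling refuses it
  Q0 <- matrix(FALSE, 12, 12, dimnames = list(fams, fams))
  qual0 <- structure(list(families = fams, Q = Q0),
                     class = "pair_qualifier")
  ac0 <- compute_ac(genes, qual0, frame = 10L, x_max = 8000)
  expect_true(all(ac0$curve$G == 0))
  expect_error(rescale_and_bin(ac0), "empty|flat")
})

test_that("rescaling peaks at one and recovers planted cluster support", {
  ## planted cluster: 5 genes spaced 1.2 kb apart on a 200 kb circle
  starts <- 10e3 + (0:4) * 1200
  genes <- toy_genes(starts, starts + 800, 2e5)
  fams <- genes$family_id
  Q <- matrix(TRUE, 5, 5, dimnames = list(fams, fams)); diag(Q) <- FALSE
  qual <- structure(list(families = fams, Q = Q), class = "pair_qualifier")
  soc <- rescale_and_bin(compute_ac(genes, qual, frame = 10L,
                                    x_max = 2e4), bins_per_decade = 25)
  expect_equal(max(soc$bins$value), 1)
  expect_equal(sum(soc$bins$mass), 1, tolerance = 1e-12)
  expect_true(all(diff(soc$bins$cdf) >= -1e-12))
  ## maximal intra-cluster site distance is (5-1)*1200 + 800 = 5600
  expect_lt(max(soc$bins$right), 5600 * 10^(2 / 25))  # within ~2 bins
  expect_gt(max(soc$bins$right), 4000)
})

test_that("distribution comparison yields KS and medians", {
  da <- structure(list(distances = c(10, 20, 30), filter = "all",
                       mode = "min", n = 3L), class = "distance_distribution")
  expect_equal(compare_distributions(da, da)$ks, 0)
  db <- structure(list(distances = c(100, 200), filter = "all",
                       mode = "min", n = 2L), class = "distance_distribution")
  cmp <- compare_distributions(da, db)
  expect_equal(cmp$ks, 1)            # disjoint supports
  expect_equal(cmp$median_a, 20)
  expect_equal(cmp$median_b, 150)
})

test_that("operon distance distributions pool within-operon pairs", {
  genes <- toy_genes(c(0, 1100, 5000), c(1000, 2100, 6000), 2e4,
                     family = c("FA", "FB", "FC"))
  operons <- data.frame(genome_id = "G1", operon_id = "OP1",
                        family_id = c("FA", "FB"))
  d <- operon_distance_distribution(operons, genes, convention = "gap")
  expect_equal(d$distances, 100)     # boundary gap of the adjacent pair
  ## k-gene operon: k(k-1)/2 pairs
  op3 <- data.frame(genome_id = "G1", operon_id = "OP1",
                    family_id = c("FA", "FB", "FC"))
  d3 <- operon_distance_distribution(op3, genes, convention = "gap")
  expect_equal(d3$n, 3L)
})

test_that("pair qualification enforces cutoffs and phage exclusion", {
  genes <- toy_genes(c(0, 2000, 4000), c(1000, 3000, 5000), 2e4,
                     family = c("FA", "FB", "FC"))
  status <- c(FA = "not_associated", FB = "not_associated",
              FC = "associated")
  mi <- matrix(0.9, 3, 3, dimnames = list(names(status), names(status)))
  q <- qualify_pairs(genes, "CO", mi = mi, status = status, mi_cutoff = 0.8)
  expect_setequal(q$families, c("FA", "FB"))     # FC excluded by status
  expect_true(q$Q["FA", "FB"])
  mi2 <- mi; mi2["FA", "FB"] <- mi2["FB", "FA"] <- 0.5
  q2 <- qualify_pairs(genes, "CO", mi = mi2, status = status,
                      mi_cutoff = 0.8)
  expect_false(q2$Q["FA", "FB"])                 # below the cutoff
  go_shared <- matrix(1L, 3, 3, dimnames = dimnames(mi))
  q3 <- qualify_pairs(genes, "GO", go_shared = go_shared, status = status,
                      n_go = 1)
  expect_true(q3$Q["FA", "FB"])
  q4 <- qualify_pairs(genes, "GO", go_shared = go_shared, status = status,
                      n_go = 2)
  expect_false(any(q4$Q))
})
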