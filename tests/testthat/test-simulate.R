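test_that("simulated trees are rooted, bifurcating, and the right size", {
  tr4 <- simulate_tree(sim_config(n_leaves = 4, seed = 3))
  expect_true(ape::is.rooted(tr4))
  expect_true(ape::is.binary(tr4))
  expect_equal(nrow(tr4$edge), 6L)      # 2n - 2 branches
  expect_equal(tr4$Nnode, 3L)           # n - 1 internal nodes
  expect_true(all(tr4$edge.length > 0))
  expect_equal(anyDuplicated(tr4$tip.label), 0L)

  tr53 <- simulate_tree(sim_config(n_leaves = 53, seed = 3))
  expect_equal(nrow(tr53$edge), 104L)
  expect_equal(tr53$Nnode, 52L)

  a <- ape::write.tree(simulate_tree(sim_config(seed = 9)))
  b <- ape::write.tree(simulate_tree(sim_config(seed = 9)))
  expect_identical(a, b)
})

test_that("config validation rejects inconsistent parameters", {
  expect_error(sim_config(n_leaves = 3), "n_leaves")
  expect_error(sim_config(segment_cap = 2e4, phage_segment_cap = 1e4),
               "segment_cap")
  expect_error(sim_config(phage_segment_cap = 2e6), "genome_length")
  expect_error(sim_config(gain_rate = -1), "rates")
})

test_that("root genome lays out clusters with recorded pair distances", {
  cfg <- small_config(seed = 5)
  root <- simulate_root_genome(cfg)
  truth <- root$truth
  k <- table(truth$cluster[truth$cluster > 0])
  expect_equal(length(truth$intra_cluster_distances),
               sum(k * (k - 1) / 2))
  ## distances bounded by the widest possible cluster span
  span_bound <- (max(k) - 1) *
    (cfg$intra_cluster_gap[["max"]] + max(root$families$length)) +
    max(root$families$length)
  expect_true(all(truth$intra_cluster_distances <= span_bound))
  expect_true(all(truth$intra_cluster_distances >= 0))
  ## coordinates respect the configured genome length to rounding
  expect_equal(socgain:::ring_genome_length(root$ring), cfg$genome_length,
               tolerance = 1e-3)

  root0 <- simulate_root_genome(small_config(seed = 5, n_clusters = 0))
  expect_equal(length(root0$truth$intra_cluster_distances), 0L)
  expect_true(all(root0$truth$cluster == 0))

  expect_error(simulate_root_genome(small_config(genome_length = 3e5)),
               "too small")
})

test_that("zero rates leave every leaf identical to the root", {
  cfg <- small_config(seed = 7, gain_rate = 0, loss_rate = 0)
  ds <- simulate_hgt_dataset(cfg)
  expect_true(all(ds$presence == 1L))
  for (g in unique(ds$genes$genome_id)) {
    leaf <- ds$genes[ds$genes$genome_id == g, ]
    expect_setequal(leaf$family_id, ds$root$families$family_id)
  }
  expect_equal(nrow(ds$truth$event_log), 0L)
})

test_that("event log respects segment caps and phage interleaving", {
  cfg <- small_config(seed = 7)
  ds <- simulate_hgt_dataset(cfg)
  el <- ds$truth$event_log
  expect_gt(nrow(el), 0)
  expect_true(all(el$length[!el$phage] <= cfg$segment_cap))
  expect_true(all(el$length <= cfg$phage_segment_cap))
  ## every co-transfer pair is backed by at least one event
  in_log <- unlist(lapply(el$families, function(f) {
    if (length(f) < 2) return(character(0))
    p <- combn(f, 2); socgain:::pair_key(p[1, ], p[2, ])
  }))
  expect_true(all(ds$truth$cotransfer_pairs %in% in_log))

  ## all-phage regime: every event carries phage genes between cargo genes
  cfg1 <- small_config(seed = 8, phage_event_fraction = 1)
  ds1 <- simulate_hgt_dataset(cfg1)
  el1 <- ds1$truth$event_log
  phage_fam <- ds1$truth$phage
  expect_gt(nrow(el1), 0)
  expect_true(all(vapply(el1$families, function(f) any(phage_fam[f]),
                         logical(1))))
  ## interleaving: with >= 2 cargo genes the phage genes are internal
  interleaved <- vapply(el1$families, function(f) {
    cargo <- which(!phage_fam[f])
    if (length(cargo) < 2) return(TRUE)
    ph <- which(phage_fam[f])
    all(ph > min(cargo) & ph < max(cargo))
  }, logical(1))
  expect_true(all(interleaved))
})

test_that("presence matrix is consistent with leaf annotations", {
  ds <- simulate_hgt_dataset(small_config(seed = 9))
  for (g in colnames(ds$presence)) {
    leaf <- unique(ds$genes$family_id[ds$genes$genome_id == g])
    expect_setequal(rownames(ds$presence)[ds$presence[, g] == 1L], leaf)
  }
  ## gene coordinates are valid half-open intervals
  expect_true(all(ds$genes$end > ds$genes$start))
  expect_true(all(ds$genes$start >= 0))
})

test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_hgt_dataset(small_config(seed = 13))
  b <- simulate_hgt_dataset(small_config(seed = 13))
  expect_identical(a$presence, b$presence)
  expect_identical(a$genes, b$genes)
  expect_identical(a$panel, b$panel)
  expect_identical(a$truth$event_log, b$truth$event_log)
  c2 <- simulate_hgt_dataset(small_config(seed = 14))
  expect_false(identical(a$presence, c2$presence))
})

test_that("panel profiles have cluster structure and the right shape", {
  cfg <- small_config(seed = 15)
  root <- simulate_root_genome(cfg)
  prof <- simulate_panel_profiles(root$truth, cfg)
  expect_equal(dim(prof), c(cfg$n_families, cfg$n_panel_species))
  expect_true(all(prof %in% c(0L, 1L)))

  ## noise-free panel: same-cluster profiles are identical
  cfg0 <- small_config(seed = 15, panel_block_flip = 0, panel_gene_flip = 0)
  prof0 <- simulate_panel_profiles(root$truth, cfg0)
  cl <- root$truth$cluster
  one <- names(cl)[cl == 1]
  expect_true(all(apply(prof0[one, , drop = FALSE], 2,
                        function(col) length(unique(col)) == 1)))
  expect_equal(profile_mi(prof0[one[1], ], prof0[one[2], ])$mi,
               profile_mi(prof0[one[1], ], prof0[one[1], ])$H_A)
})
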