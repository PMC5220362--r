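test_that("rates are recovered from model-simulated data within 25%", {
  tree <- simulate_tree(sim_config(n_leaves = 16, tree_depth = 1, seed = 2))
  M <- simulate_presence_matrix(tree, alpha = 0.5, beta = 1.0,
                                n_families = 2000, seed = 21)
  fit <- fit_gain_loss(tree, M)
  expect_lt(abs(fit$alpha - 0.5) / 0.5, 0.25)
  expect_lt(abs(fit$beta - 1.0) / 1.0, 0.25)

  ## symmetric rates give a fitted ratio near one
  Ms <- simulate_presence_matrix(tree, alpha = 0.8, beta = 0.8,
                                 n_families = 2000, seed = 22)
  fs <- fit_gain_loss(tree, Ms)
  expect_gt(fs$alpha / fs$beta, 0.8)
  expect_lt(fs$alpha / fs$beta, 1.25)
})

test_that("fitted rates sit at a likelihood maximum", {
  tree <- simulate_tree(sim_config(n_leaves = 8, tree_depth = 1, seed = 3))
  M <- simulate_presence_matrix(tree, 0.6, 0.9, 400, seed = 31)
  fit <- fit_gain_loss(tree, M)
  ll_hat <- socgain:::loglik_matrix(tree, socgain:::check_presence(
    socgain:::check_tree(tree), M), fit$alpha, fit$beta)
  expect_equal(ll_hat, fit$loglik, tolerance = 1e-8)
  for (f in c(0.7, 0.9, 1.1, 1.4)) {
    expect_gte(ll_hat, socgain:::loglik_matrix(
      tree, socgain:::check_presence(socgain:::check_tree(tree), M),
      fit$alpha * f, fit$beta))
    expect_gte(ll_hat, socgain:::loglik_matrix(
      tree, socgain:::check_presence(socgain:::check_tree(tree), M),
      fit$alpha, fit$beta * f))
  }
  expect_error(fit_gain_loss(tree, matrix(1L, 5, 8,
    dimnames = list(paste0("F", 1:5), tree$tip.label))), "constant")
})

test_that("two-leaf posteriors match the closed-form Bayes ratio", {
  tree <- ape::read.tree(text = "(A:0.4,B:0.7):0;")
  M <- matrix(c(1L, 1L), 1, 2, dimnames = list("F1", c("A", "B")))
  alpha <- 0.3; beta <- 0.9
  post <- posterior_presence(tree, M, list(alpha = alpha, beta = beta))
  p1 <- alpha / (alpha + beta)
  p11 <- function(t) p1 + (1 - p1) * exp(-(alpha + beta) * t)
  p01 <- function(t) p1 * (1 - exp(-(alpha + beta) * t))
  num <- p1 * p11(0.4) * p11(0.7)
  den <- num + (1 - p1) * p01(0.4) * p01(0.7)
  expect_equal(unname(post[1, 3]), num / den, tolerance = 1e-12)

  ## near-zero branch lengths pin the root to the shared leaf state
  tr0 <- ape::read.tree(text = "(A:1e-8,B:1e-8):0;")
  post0 <- posterior_presence(tr0, M, list(alpha = alpha, beta = beta))
  expect_equal(unname(post0[1, 3]), 1, tolerance = 1e-6)
})

test_that("posteriors match brute-force enumeration on small trees", {
  set.seed(41)
  for (n_tip in c(3, 4, 5)) {
    tree <- ape::rtree(n_tip)
    tree$edge.length <- runif(nrow(tree$edge), 0.1, 1.5)
    tree$node.label <- sprintf("N%02d", (n_tip + 1):(2 * n_tip - 1))
    M <- matrix(rbinom(20 * n_tip, 1L, 0.4), 20, n_tip,
                dimnames = list(sprintf("F%02d", 1:20), tree$tip.label))
    alpha <- runif(1, 0.2, 1); beta <- runif(1, 0.2, 1.5)
    post <- posterior_presence(tree, M, list(alpha = alpha, beta = beta))
    oracle <- posterior_oracle(tree, M, alpha, beta)
    expect_lt(max(abs(post - oracle[, colnames(post)])), 1e-9)
  }
})

test_that("event calling applies the inclusive and high thresholds", {
  tree <- simulate_tree(sim_config(n_leaves = 4, seed = 5))
  nn <- socgain:::node_names(tree)
  post <- matrix(0.5, 3, length(nn), dimnames = list(paste0("F", 1:3), nn))
  parent <- nn[tree$edge[1, 1]]; child <- nn[tree$edge[1, 2]]
  post["F1", parent] <- 0.1; post["F1", child] <- 0.9   # both tiers
  post["F2", parent] <- 0.4; post["F2", child] <- 0.6   # inclusive only
  post["F3", parent] <- 0.5; post["F3", child] <- 0.5   # no event
  inc <- call_events(post, tree, "inclusive")
  high <- call_events(post, tree, "high")
  expect_true(inc$gain["F1", child] && high$gain["F1", child])
  expect_true(inc$gain["F2", child] && !high$gain["F2", child])
  expect_false(inc$gain["F3", child] || inc$loss["F3", child])
  ## high-confidence calls are a subset of inclusive calls
  expect_true(all(inc$gain[high$gain]))
  expect_true(all(inc$loss[high$loss]))
})

test_that("inclusive calls track Fitch parsimony at low event rates", {
  tree <- simulate_tree(sim_config(n_leaves = 12, tree_depth = 1, seed = 6))
  M <- simulate_presence_matrix(tree, alpha = 0.1, beta = 0.15, 600,
                                seed = 61)
  keep <- rowSums(M) > 0 & rowSums(M) < ncol(M)
  M <- M[keep, , drop = FALSE]
  fit <- fit_gain_loss(tree, M)
  post <- posterior_presence(tree, M, fit)
  ev <- call_events(post, tree)
  fg <- fitch_gains(tree, M)
  agree <- mean(ev$gain == fg[, colnames(ev$gain)])
  expect_gte(agree, 0.9)
  ## total gains equal the 0 -> 1 flips of the thresholded states
  states <- post >= 0.5
  nn <- socgain:::node_names(tree)
  flips <- sum(!states[, nn[tree$edge[, 1]]] & states[, nn[tree$edge[, 2]]])
  expect_equal(sum(ev$gain), flips)
})

test_that("per-family rate scalars raise the likelihood and stay deterministic", {
  ds <- simulate_hgt_dataset(small_config(seed = 17))
  f0 <- fit_gain_loss(ds$tree, ds$presence)
  f1 <- fit_gain_loss(ds$tree, ds$presence, per_family = TRUE)
  expect_gte(f1$loglik, f0$loglik)
  expect_true(all(f1$alpha_scalar %in% f1$scalar_grid))
  f2 <- fit_gain_loss(ds$tree, ds$presence, per_family = TRUE)
  expect_identical(f1$alpha_scalar, f2$alpha_scalar)
})
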