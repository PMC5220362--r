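## Two-state (absent/present) continuous-time Markov model of gene gain and
## loss on a rooted tree, with maximum-likelihood rate fitting via the
## pruning algorithm and marginal posterior reconstruction of ancestral
## presence. Branch lengths are taken from the input tree as-is.

## transition probabilities over a branch of length t for rates
## alpha (0 -> 1, gain) and beta (1 -> 0, loss); stationary presence
## probability pi1 = alpha/(alpha+beta)
branch_probs <- function(alpha, beta, t) {
  p1 <- alpha / (alpha + beta)
  e <- exp(-(alpha + beta) * t)
  list(p00 = (1 - p1) + p1 * e,
       p01 = p1 * (1 - e),
       p10 = (1 - p1) * (1 - e),
       p11 = p1 + (1 - p1) * e)
}

## validate tree and return it in cladewise order with node labels
check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("tree must be a 'phylo' object")
  if (!ape::is.rooted(tree)) stopf("tree must be rooted")
  if (!ape::is.binary(tree)) stopf("tree must be fully bifurcating")
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0))
    stopf("tree must have strictly positive branch lengths")
  if (is.null(tree$node.label)) {
    n <- length(tree$tip.label)
    tree$node.label <- sprintf("N%02d", (n + 1L):(2L * n - 1L))
  }
  ape::reorder.phylo(tree, "cladewise")
}

check_presence <- function(tree, M) {
  if (is.null(rownames(M))) stopf("presence matrix needs family rownames")
  if (!all(tree$tip.label %in% colnames(M)))
    stopf("presence matrix is missing columns for some tips")
  M <- M[, tree$tip.label, drop = FALSE]
  if (!all(M %in% c(0L, 1L))) stopf("presence matrix must be binary")
  storage.mode(M) <- "integer"
  M
}

## pruning algorithm, vectorised over families: conditional likelihoods
## L0/L1 (families x nodes) plus per-child messages for the downward pass
prune_up <- function(tree, M, alpha, beta) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  nf <- nrow(M)
  L0 <- matrix(1, nf, n_node)
  L1 <- matrix(1, nf, n_node)
  L0[, seq_len(n_tip)] <- 1L - M
  L1[, seq_len(n_tip)] <- M
  m0 <- matrix(NA_real_, nf, n_node)  # message child -> parent, indexed by child
  m1 <- matrix(NA_real_, nf, n_node)
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    v <- po$edge[e, 1]; ch <- po$edge[e, 2]
    tp <- branch_probs(alpha, beta, po$edge.length[e])
    m0[, ch] <- tp$p00 * L0[, ch] + tp$p01 * L1[, ch]
    m1[, ch] <- tp$p10 * L0[, ch] + tp$p11 * L1[, ch]
    L0[, v] <- L0[, v] * m0[, ch]
    L1[, v] <- L1[, v] * m1[, ch]
  }
  list(L0 = L0, L1 = L1, m0 = m0, m1 = m1)
}

## per-family log-likelihood vector; alpha/beta may be scalars or
## per-family vectors (all pruning arithmetic is elementwise over families)
loglik_families <- function(tree, M, alpha, beta) {
  up <- prune_up(tree, M, alpha, beta)
  root <- length(tree$tip.label) + 1L
  p1 <- alpha / (alpha + beta)
  log((1 - p1) * up$L0[, root] + p1 * up$L1[, root])
}

loglik_matrix <- function(tree, M, alpha, beta) {
  sum(loglik_families(tree, M, alpha, beta))
}

#' Fit the two-state gain/loss model
#'
#' Maximises the product over families of pruning-algorithm likelihoods of
#' the binary presence/absence matrix under a two-state Markov model with
#' global gain rate `alpha` (absent to present) and loss rate `beta`
#' (present to absent), with the stationary distribution as root prior.
#' Optimisation is bounded in log-rate space with three fixed starting
#' points to avoid local optima.
#'
#' @param tree rooted binary `phylo` with positive branch lengths.
#' @param M binary matrix, families x genomes; column names must cover the
#'   tip labels.
#' @param per_family also estimate a per-family gain-rate scalar (see
#'   [estimate_rate_scalars()]); families differ enormously in their
#'   propensity for horizontal acquisition, and a single global gain/loss
#'   ratio systematically explains repeated independent acquisitions as
#'   ancestral presence followed by losses.
#' @param scalar_grid candidate gain-rate multipliers for `per_family`.
#' @return an object of class `gl_model`: list with `alpha`, `beta`,
#'   `root_prior` (P(absent), P(present)), `loglik`, and (if requested)
#'   `alpha_scalar` (named per-family multipliers).
#' @export
fit_gain_loss <- function(tree, M, per_family = FALSE,
                          scalar_grid = c(0.25, 1, 4, 16, 64)) {
  tree <- check_tree(tree)
  M <- check_presence(tree, M)
  rs <- rowSums(M)
  if (all(rs == 0L | rs == ncol(M)))
    stopf("all families are constant across genomes; rates are unidentifiable")
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    -loglik_matrix(tree, M, a, b)
  }
  starts <- list(log(c(0.5, 0.5)), log(c(0.1, 1)), log(c(2, 0.2)))
  best <- NULL
  for (s in starts) {
    fit <- optim(s, nll, method = "L-BFGS-B",
                 lower = c(-8, -8), upper = c(5, 5))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  alpha <- exp(best$par[1]); beta <- exp(best$par[2])
  p1 <- alpha / (alpha + beta)
  model <- structure(list(alpha = alpha, beta = beta,
                          root_prior = c(absent = 1 - p1, present = p1),
                          loglik = -best$value),
                     class = "gl_model")
  if (per_family) {
    model$scalar_grid <- scalar_grid
    model$alpha_scalar <- estimate_rate_scalars(tree, M, model)
    model$loglik <- loglik_matrix(tree, M, alpha * model$alpha_scalar, beta)
  }
  model
}

#' Per-family gain-rate scalars
#'
#' For each family, selects from `model$scalar_grid` the multiplier of the
#' global gain rate that maximises that family's pruning likelihood (loss
#' rate held global). This is a discrete empirical-Bayes analog of a
#' variable gain/loss-ratio mixture: horizontally mobile families obtain a
#' high gain/loss ratio, so their repeated independent acquisitions are
#' reconstructed as gains rather than as ancestral presence plus losses.
#'
#' @param tree rooted binary `phylo`.
#' @param M binary presence matrix.
#' @param model a fitted `gl_model` with a `scalar_grid` (or the default
#'   grid is used).
#' @return named numeric vector of per-family multipliers.
#' @export
estimate_rate_scalars <- function(tree, M, model) {
  tree <- check_tree(tree)
  M <- check_presence(tree, M)
  grid <- model$scalar_grid
  if (is.null(grid)) grid <- c(0.25, 1, 4, 16, 64)
  ll <- vapply(grid, function(s)
    loglik_families(tree, M, model$alpha * s, model$beta),
    numeric(nrow(M)))
  setNames(grid[max.col(ll, ties.method = "first")], rownames(M))
}

#' @export
print.gl_model <- function(x, ...) {
  cat(sprintf("Two-state gain/loss model: alpha = %.4g, beta = %.4g, logL = %.2f\n",
              x$alpha, x$beta, x$loglik))
  invisible(x)
}

#' Marginal posterior probability of presence at every node
#'
#' Computes, for each family and each node of the rooted tree, the marginal
#' posterior probability that the gene is present, by an upward (pruning)
#' pass followed by a downward pass. Leaf posteriors equal the observed 0/1
#' states.
#'
#' @param tree rooted binary `phylo`.
#' @param M binary presence matrix (families x genomes).
#' @param model a fitted [fit_gain_loss()] model (or any list with `alpha`
#'   and `beta`).
#' @return matrix families x nodes of P(present), columns named by tip and
#'   node labels, class `posterior_presence`.
#' @export
posterior_presence <- function(tree, M, model) {
  tree <- check_tree(tree)
  M <- check_presence(tree, M)
  alpha <- model$alpha; beta <- model$beta
  if (!is.null(model$alpha_scalar)) {
    sc <- model$alpha_scalar[rownames(M)]
    sc[is.na(sc)] <- 1
    alpha <- alpha * sc
  }
  up <- prune_up(tree, M, alpha, beta)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  nf <- nrow(M)
  p1 <- alpha / (alpha + beta)
  D0 <- matrix(NA_real_, nf, n_node)
  D1 <- matrix(NA_real_, nf, n_node)
  root <- n_tip + 1L
  D0[, root] <- 1 - p1
  D1[, root] <- p1
  ## cladewise edge order is a preorder: a child's D is computed only after
  ## its parent's, using the sibling subtree's upward message
  for (e in seq_len(nrow(tree$edge))) {
    v <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    sib <- tree$edge[tree$edge[, 1] == v, 2]
    sib <- sib[sib != ch]
    ex0 <- D0[, v]
    ex1 <- D1[, v]
    for (s in sib) {
      ex0 <- ex0 * up$m0[, s]
      ex1 <- ex1 * up$m1[, s]
    }
    tp <- branch_probs(alpha, beta, tree$edge.length[e])
    D0[, ch] <- ex0 * tp$p00 + ex1 * tp$p10
    D1[, ch] <- ex0 * tp$p01 + ex1 * tp$p11
  }
  w1 <- D1 * up$L1
  post <- w1 / (D0 * up$L0 + w1)
  post[, seq_len(n_tip)] <- M  # pin leaves to observations
  dimnames(post) <- list(rownames(M), node_names(tree))
  structure(post, class = c("posterior_presence", "matrix"))
}

#' Call gain and loss events on branches
#'
#' Thresholds posterior presence along every branch (parent -> child). In
#' the inclusive tier a gene is considered present at a node when its
#' posterior P >= 0.5, so a gain is called when P_parent < 0.5 and
#' P_child >= 0.5 (loss symmetric). In the high-confidence tier a gain
#' additionally requires near-certainty at both ends: P_parent <= 0.2 and
#' P_child >= 0.8 (loss symmetric). High-tier calls are a subset of
#' inclusive-tier calls.
#'
#' @param post a [posterior_presence()] matrix.
#' @param tree the same rooted binary `phylo`.
#' @param tier `"inclusive"` or `"high"`.
#' @return list of class `event_calls`: logical matrices `gain` and `loss`
#'   (families x branches, branch columns named by child node), `branches`,
#'   and `tier`.
#' @export
call_events <- function(post, tree, tier = c("inclusive", "high")) {
  tier <- match.arg(tier)
  tree <- check_tree(tree)
  nn <- node_names(tree)
  pa <- post[, nn[tree$edge[, 1]], drop = FALSE]
  pd <- post[, nn[tree$edge[, 2]], drop = FALSE]
  if (tier == "inclusive") {
    gain <- pa < 0.5 & pd >= 0.5
    loss <- pa >= 0.5 & pd < 0.5
  } else {
    gain <- pa <= 0.2 & pd >= 0.8
    loss <- pa >= 0.8 & pd <= 0.2
  }
  branches <- nn[tree$edge[, 2]]
  dimnames(gain) <- dimnames(loss) <- list(rownames(post), branches)
  structure(list(gain = gain, loss = loss, branches = branches, tier = tier),
            class = "event_calls")
}

#' Simulate a presence/absence matrix directly from the two-state model
#'
#' Evolves each family independently down the tree under the gain/loss
#' Markov model, starting from the stationary distribution at the root.
#' Used for parameter-recovery checks of [fit_gain_loss()].
#'
#' @param tree rooted binary `phylo`.
#' @param alpha,beta gain and loss rates per unit branch length.
#' @param n_families number of independent families.
#' @param seed RNG seed.
#' @return binary integer matrix, families x tips.
#' @export
simulate_presence_matrix <- function(tree, alpha, beta, n_families,
                                     seed = 1L) {
  tree <- check_tree(tree)
  set.seed(seed)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  p1 <- alpha / (alpha + beta)
  state <- matrix(NA_integer_, n_families, n_node)
  state[, n_tip + 1L] <- rbinom(n_families, 1L, p1)
  for (e in seq_len(nrow(tree$edge))) {
    v <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    tp <- branch_probs(alpha, beta, tree$edge.length[e])
    pr <- ifelse(state[, v] == 1L, tp$p11, tp$p01)
    state[, ch] <- rbinom(n_families, 1L, pr)
  }
  M <- state[, seq_len(n_tip), drop = FALSE]
  dimnames(M) <- list(sprintf("F%04d", seq_len(n_families)), tree$tip.label)
  M
}
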