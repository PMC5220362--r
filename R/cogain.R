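## Co-gain association scores: for every pair of gene families the branch-
## wise gain histories are cross-tabulated into a 2x2 contingency table and
## scored by the decadic logarithm of the right-tail Fisher exact p-value.
## Significance is assessed against a permutation null (leaf presences of
## each family shuffled independently) via an empirical false discovery
## rate FDR(t) = N_null(t) / N_data(t) over scores more significant than t.

#' Gain vectors for families with at least one gain
#'
#' Extracts, from called events, the binary gain-history vector of every
#' family over all branches (ordered as in the cladewise edge ordering of
#' the tree, i.e. branch = child node). Families never gained contribute
#' only the `[0,0]` pattern and a p-value of 1, so they are excluded from
#' the pair universe.
#'
#' @param events an [call_events()] result.
#' @return integer matrix families x branches, only rows with >= 1 gain.
#' @export
build_gain_vectors <- function(events) {
  stopifnot(inherits(events, "event_calls"))
  G <- events$gain * 1L
  G[rowSums(G) > 0L, , drop = FALSE]
}

#' Right-tail Fisher exact p-value of a 2x2 table
#'
#' Probability of observing at least `n11` joint gains given the table
#' margins, i.e. the upper tail of the hypergeometric distribution (the
#' one-sided Fisher exact test for positive association). Vectorised.
#'
#' @param n11,n10,n01,n00 counts of the branch-wise patterns
#'   `[1,1]`, `[1,0]`, `[0,1]`, `[0,0]`.
#' @param log10p return the decadic logarithm instead of the p-value.
#' @return p-values (or their decadic logs).
#' @export
fisher_right_tail <- function(n11, n10, n01, n00, log10p = FALSE) {
  if (any(c(n11, n10, n01, n00) < 0)) stopf("counts must be non-negative")
  ra <- n11 + n10           # gains of family A
  rb <- n11 + n01           # gains of family B
  nb <- n11 + n10 + n01 + n00
  lp <- phyper(n11 - 1, ra, nb - ra, rb, lower.tail = FALSE, log.p = TRUE)
  if (log10p) lp / log(10) else exp(lp)
}

#' Co-gain association score of two gain vectors
#'
#' Cross-tabulates two equal-length binary gain vectors over branches and
#' returns `t = log10` of the right-tail Fisher exact p-value; more
#' negative scores indicate stronger co-gain. Symmetric in its arguments.
#'
#' @param a,b binary vectors over the same branches.
#' @return the score t (<= 0).
#' @export
score_pair <- function(a, b) {
  if (length(a) != length(b)) stopf("gain vectors must have equal length")
  n11 <- sum(a == 1 & b == 1)
  n10 <- sum(a == 1 & b == 0)
  n01 <- sum(a == 0 & b == 1)
  n00 <- sum(a == 0 & b == 0)
  fisher_right_tail(n11, n10, n01, n00, log10p = TRUE)
}

#' Score all unordered pairs of gain vectors
#'
#' Vectorised scoring of every unordered pair of families in a gain-vector
#' matrix.
#'
#' @param G integer matrix families x branches from [build_gain_vectors()].
#' @return data.frame with `family_a`, `family_b`, `n11`, `t`.
#' @export
score_pairs <- function(G) {
  nf <- nrow(G)
  if (nf < 2) {
    return(data.frame(family_a = character(0), family_b = character(0),
                      n11 = integer(0), t = numeric(0)))
  }
  nb <- ncol(G)
  N11 <- tcrossprod(G)
  rs <- rowSums(G)
  ij <- which(upper.tri(N11), arr.ind = TRUE)
  n11 <- N11[ij]
  ra <- rs[ij[, 1]]
  rb <- rs[ij[, 2]]
  t <- phyper(n11 - 1, ra, nb - ra, rb, lower.tail = FALSE,
              log.p = TRUE) / log(10)
  data.frame(family_a = rownames(G)[ij[, 1]],
             family_b = rownames(G)[ij[, 2]],
             n11 = as.integer(n11), t = t, stringsAsFactors = FALSE)
}

#' Permutation null for co-gain scores
#'
#' Shuffles the presences and absences of each family independently across
#' the extant genomes (preserving per-family presence counts), reruns the
#' posterior reconstruction, event calling and pair scoring with the
#' already-fitted model, and collects the null score multiset. Replicates
#' use sub-seeds derived from `seed`.
#'
#' @param M binary presence matrix (families x genomes).
#' @param tree rooted binary `phylo`.
#' @param model fitted [fit_gain_loss()] model (reused, not refitted, so
#'   that only the association structure is destroyed; set `refit = TRUE`
#'   to refit per replicate).
#' @param tier event-call tier passed to [call_events()].
#' @param n_reps number of shuffle replicates (>= 1).
#' @param seed RNG seed.
#' @param refit refit the rate model on each shuffled matrix.
#' @return list of class `cogain_null`: `scores` (list of score vectors),
#'   `n_pairs` (pair-universe size per replicate).
#' @export
shuffle_null <- function(M, tree, model, tier = "inclusive", n_reps = 1L,
                         seed = 1L, refit = FALSE) {
  if (n_reps < 1) stopf("n_reps must be >= 1")
  tree <- check_tree(tree)
  M <- check_presence(tree, M)
  scores <- vector("list", n_reps)
  n_pairs <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(seed + r - 1L)
    Mp <- t(apply(M, 1L, sample))
    dimnames(Mp) <- dimnames(M)
    mod <- if (refit) {
      fit_gain_loss(tree, Mp, per_family = !is.null(model$alpha_scalar))
    } else if (!is.null(model$alpha_scalar)) {
      ## same reconstruction procedure as the data: global rates reused,
      ## per-family scalars re-estimated on the shuffled matrix
      m2 <- model
      m2$alpha_scalar <- estimate_rate_scalars(tree, Mp, model)
      m2
    } else {
      model
    }
    post <- posterior_presence(tree, Mp, mod)
    ev <- call_events(post, tree, tier = tier)
    G <- build_gain_vectors(ev)
    sc <- score_pairs(G)
    scores[[r]] <- sc$t
    n_pairs[r] <- nrow(sc)
  }
  structure(list(scores = scores, n_pairs = n_pairs), class = "cogain_null")
}

#' Empirical FDR curve over score thresholds
#'
#' For each candidate threshold t, counts the empirical pairs with score
#' strictly below t, `N_d(t)`, and the mean null count `N_n(t)` (rescaled
#' to the empirical pair-universe size when the null universes differ), and
#' forms FDR(t) = N_n(t)/N_d(t).
#'
#' @param emp_scores empirical score vector.
#' @param null a [shuffle_null()] result (or list with `scores`, `n_pairs`).
#' @param thresholds candidate thresholds; defaults to the sorted unique
#'   empirical scores.
#' @return data.frame `t`, `N_d`, `N_n`, `FDR`.
#' @export
fdr_curve <- function(emp_scores, null, thresholds = NULL) {
  if (length(emp_scores) == 0) stopf("no empirical scores")
  if (is.null(thresholds))
    thresholds <- sort(unique(emp_scores))
  n_emp <- length(emp_scores)
  Nd <- vapply(thresholds, function(t) sum(emp_scores < t), numeric(1))
  Nn <- rep(0, length(thresholds))
  for (r in seq_along(null$scores)) {
    scale <- n_emp / max(null$n_pairs[r], 1)
    Nn <- Nn + scale *
      vapply(thresholds, function(t) sum(null$scores[[r]] < t), numeric(1))
  }
  Nn <- Nn / length(null$scores)
  data.frame(t = thresholds, N_d = Nd, N_n = Nn,
             FDR = ifelse(Nd > 0, Nn / Nd, NA_real_))
}

#' Significant co-gained pairs at a target FDR
#'
#' Finds the largest (least stringent) threshold t* whose empirical
#' FDR(t*) does not exceed `alpha` and returns the pairs scoring strictly
#' below it.
#'
#' @param pairs a [score_pairs()] data.frame.
#' @param null a [shuffle_null()] result.
#' @param alpha target FDR (e.g. 0.05 or 0.005).
#' @return list of class `cogain_fdr`: `threshold` (t*), `alpha`,
#'   `pairs` (significant subset, with pair keys), `curve`.
#' @export
fdr_threshold <- function(pairs, null, alpha = 0.05) {
  curve <- fdr_curve(pairs$t, null)
  ok <- which(!is.na(curve$FDR) & curve$FDR <= alpha & curve$N_d > 0)
  if (length(ok) == 0) {
    warnf("no threshold reaches FDR <= %g; returning empty set", alpha)
    tstar <- -Inf
  } else {
    tstar <- max(curve$t[ok])
  }
  sig <- pairs[pairs$t < tstar, , drop = FALSE]
  if (nrow(sig) > 0)
    sig$pair <- pair_key(sig$family_a, sig$family_b)
  else
    sig$pair <- character(0)
  structure(list(threshold = tstar, alpha = alpha, pairs = sig,
                 curve = curve),
            class = "cogain_fdr")
}

#' Per-branch gain probabilities from posteriors
#'
#' The probability that a family was gained on a branch, approximated as
#' the positive part of the posterior presence increase from parent to
#' child, clipped to \[0,1\].
#'
#' @param post a [posterior_presence()] matrix.
#' @param tree the rooted binary `phylo`.
#' @return matrix families x branches of gain probabilities.
#' @export
gain_probabilities <- function(post, tree) {
  tree <- check_tree(tree)
  nn <- node_names(tree)
  g <- post[, nn[tree$edge[, 2]], drop = FALSE] -
    post[, nn[tree$edge[, 1]], drop = FALSE]
  g <- pmin(pmax(g, 0), 1)
  colnames(g) <- nn[tree$edge[, 2]]
  g
}

#' Probability-product association score (experimental)
#'
#' Alternative co-gain score: the product of the two families' per-branch
#' gain probabilities, summed over all branches. Retained for comparison;
#' it is less selective than the Fisher-based score and tends to pick up
#' weakly associated pairs.
#'
#' @param gA,gB per-branch gain-probability vectors of the two families.
#' @return the score (>= 0, bounded by `min(sum(gA), sum(gB))`).
#' @export
prob_product_score <- function(gA, gB) {
  if (length(gA) != length(gB)) stopf("gain-probability vectors must match")
  sum(gA * gB)
}
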