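## Independent brute-force oracles and shared fixtures for the test suite.

## small, fast simulation used by unit tests
small_config <- function(seed = 11, ...) {
  args <- list(n_leaves = 8, genome_length = 6e5, n_families = 400,
               n_clusters = 25, n_panel_species = 120, gain_rate = 20,
               seed = seed)
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

## reference study conditions (16 genomes, 2 Mb, 1500 families) run once and
## cached for the acceptance tests
.pipeline_cache <- new.env(parent = emptyenv())
reference_pipeline <- function() {
  if (is.null(.pipeline_cache$pl)) {
    t0 <- Sys.time()
    .pipeline_cache$pl <- suppressWarnings(run_pipeline(sim_config(seed = 1)))
    .pipeline_cache$elapsed <- as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs"))
  }
  .pipeline_cache$pl
}
reference_pipeline_elapsed <- function() {
  reference_pipeline()
  .pipeline_cache$elapsed
}

## exhaustive right-tail Fisher oracle: enumerate all placements of A's
## gains over the branches, with B's gains fixed, and count overlap >= n11
fisher_oracle <- function(n11, n10, n01, n00) {
  N <- n11 + n10 + n01 + n00
  ra <- n11 + n10
  rb <- n11 + n01
  if (n11 == 0) return(1)
  subs <- combn(N, ra)
  overlaps <- colSums(matrix(subs <= rb, nrow = ra))
  mean(overlaps >= n11)
}

## exact marginal posteriors by enumeration over all internal-state
## assignments (trees with <= 5 leaves)
posterior_oracle <- function(tree, M, alpha, beta) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  n_node <- n_tip + n_int
  p1 <- alpha / (alpha + beta)
  tp <- lapply(seq_len(nrow(tree$edge)), function(e) {
    t <- tree$edge.length[e]
    eb <- exp(-(alpha + beta) * t)
    matrix(c((1 - p1) + p1 * eb, p1 * (1 - eb),
             (1 - p1) * (1 - eb), p1 + (1 - p1) * eb),
           2, 2, byrow = TRUE)  # rows: from-state 0/1; cols: to-state 0/1
  })
  out <- matrix(NA_real_, nrow(M), n_node)
  M <- M[, tree$tip.label, drop = FALSE]
  for (f in seq_len(nrow(M))) {
    marg <- numeric(n_node)
    tot <- 0
    for (code in 0:(2^n_int - 1)) {
      st <- integer(n_node)
      st[seq_len(n_tip)] <- M[f, ]
      st[(n_tip + 1):n_node] <- bitwAnd(bitwShiftR(code, 0:(n_int - 1)), 1L)
      pr <- if (st[n_tip + 1] == 1) p1 else 1 - p1
      for (e in seq_len(nrow(tree$edge))) {
        pr <- pr * tp[[e]][st[tree$edge[e, 1]] + 1L, st[tree$edge[e, 2]] + 1L]
      }
      marg <- marg + pr * st
      tot <- tot + pr
    }
    out[f, ] <- marg / tot
  }
  colnames(out) <- c(tree$tip.label, tree$node.label)
  rownames(out) <- rownames(M)
  out
}

## site-by-site autocovariance oracle on a small genome
ac_oracle <- function(genes, qualifier, frame, x_max) {
  L <- genes$genome_length[1]
  fams <- qualifier$families
  g <- genes[genes$family_id %in% fams, , drop = FALSE]
  n_grid <- floor(L / frame)
  occ <- integer(n_grid)
  for (r in seq_len(nrow(g))) {
    ks <- ceiling(g$start[r] / frame):(ceiling(g$end[r] / frame) - 1L)
    occ[(ks %% n_grid) + 1L] <- r
  }
  fam_of <- match(g$family_id, fams)
  sites <- which(occ > 0L)
  n <- length(sites)
  xs <- frame * seq_len(floor(x_max / frame))
  G <- vapply(seq_along(xs), function(k) {
    tgt <- occ[((sites - 1L + k) %% n_grid) + 1L]
    src <- occ[sites]
    hit <- tgt > 0L & tgt != src
    if (!any(hit)) return(0)
    sum(qualifier$Q[cbind(fam_of[src[hit]], fam_of[tgt[hit]])]) / n
  }, numeric(1))
  data.frame(x = xs, G = G)
}

## Fitch parsimony gain calls (union/intersection up-pass, preorder
## down-pass resolving ties towards the parent state, root ties -> absent)
fitch_gains <- function(tree, M) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  M <- M[, tree$tip.label, drop = FALSE]
  po <- ape::reorder.phylo(tree, "postorder")
  gains <- matrix(FALSE, nrow(M), nrow(tree$edge))
  for (f in seq_len(nrow(M))) {
    sets <- vector("list", n_node)
    for (i in seq_len(n_tip)) sets[[i]] <- M[f, i]
    for (e in seq_len(nrow(po$edge))) {
      v <- po$edge[e, 1]; ch <- po$edge[e, 2]
      sets[[v]] <- if (is.null(sets[[v]])) sets[[ch]] else {
        inter <- intersect(sets[[v]], sets[[ch]])
        if (length(inter) > 0) inter else union(sets[[v]], sets[[ch]])
      }
    }
    st <- integer(n_node)
    root <- n_tip + 1L
    st[root] <- if (0L %in% sets[[root]]) 0L else 1L
    for (e in seq_len(nrow(tree$edge))) {
      v <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      st[ch] <- if (st[v] %in% sets[[ch]]) st[v] else sets[[ch]][1]
      gains[f, e] <- st[v] == 0L && st[ch] == 1L
    }
  }
  colnames(gains) <- socgain:::node_names(tree)[tree$edge[, 2]]
  rownames(gains) <- rownames(M)
  gains
}

## gene annotation row constructor for toy genomes
toy_genes <- function(starts, ends, genome_length, genome_id = "G1",
                      family = sprintf("F%02d", seq_along(starts)),
                      product = "hypothetical protein") {
  data.frame(family_id = family, genome_id = genome_id,
             start = starts, end = ends, strand = "+",
             product = product, genome_length = genome_length,
             stringsAsFactors = FALSE)
}

## precision of a significant pair set against the simulation ground truth
## (co-transferred in one event, or members of one cluster)
truth_precision <- function(fdr, truth) {
  p <- fdr$pairs
  if (nrow(p) == 0) return(NA_real_)
  cl <- truth$cluster
  same_cluster <- cl[p$family_a] > 0 & cl[p$family_a] == cl[p$family_b]
  mean(p$pair %in% truth$cotransfer_pairs | same_cluster)
}
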