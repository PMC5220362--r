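## End-to-end orchestration: simulate -> reconstruct -> associate ->
## distances -> MI -> autocovariance -> compare. All randomness derives
## from the configuration seed, so a rerun with the same configuration
## reproduces the result exactly.

#' Run the full co-gain / SOC analysis pipeline on simulated data
#'
#' Simulates a ground-truthed dataset, fits the gain/loss model,
#' reconstructs ancestral presence, calls gains, scores all family pairs,
#' assesses significance against the shuffle null at each `fdr_alphas`,
#' computes distance distributions and intervening-phage statistics for
#' the significant pairs, the profile MI matrix, the co-occurrence (CO-AC)
#' and co-functioning (GO-AC) autocovariance estimates of the SOC distance
#' distribution, the operon distance distribution, and the
#' Kolmogorov–Smirnov comparisons between them.
#'
#' @param config a [sim_config()].
#' @param fdr_alphas FDR levels, most permissive first (default 0.05,
#'   0.005); the first one drives the distance analysis.
#' @param tier event-call tier (`"inclusive"` or `"high"`).
#' @param n_null shuffle-null replicates.
#' @param per_family_rates use per-family gain-rate scalars in the
#'   reconstruction (a variable gain/loss-ratio analog; recommended, since
#'   horizontally mobile families need a higher gain/loss ratio than the
#'   genomic background for repeated acquisitions to be reconstructed).
#' @param mi_cutoff MI cutoff for CO-AC qualification.
#' @param n_go shared-GO cutoff for GO-AC qualification.
#' @param frame autocovariance lattice (bp).
#' @param bins_per_decade log-binning resolution.
#' @param x_max largest autocovariance offset (default genome/40).
#' @param close_bound,far_bound close/distant allele-pair boundaries
#'   (default: the configured segment caps).
#' @param reference_genome genome used for autocovariance (default: first
#'   tip).
#' @return an object of class `hgt_pipeline`; see the `summary` element
#'   for the headline numbers.
#' @export
run_pipeline <- function(config = sim_config(),
                         fdr_alphas = c(0.05, 0.005),
                         tier = "inclusive",
                         n_null = 3L,
                         per_family_rates = TRUE,
                         mi_cutoff = 0.05,
                         n_go = 1L,
                         frame = 10L,
                         bins_per_decade = 25L,
                         x_max = NULL,
                         close_bound = config$segment_cap,
                         far_bound = config$phage_segment_cap,
                         reference_genome = NULL) {
  ds <- simulate_hgt_dataset(config)
  tree <- ds$tree

  model <- fit_gain_loss(tree, ds$presence, per_family = per_family_rates)
  post <- posterior_presence(tree, ds$presence, model)
  events <- call_events(post, tree, tier = tier)
  G <- build_gain_vectors(events)
  pairs <- score_pairs(G)
  null <- shuffle_null(ds$presence, tree, model, tier = tier,
                       n_reps = n_null, seed = config$seed + 10000L)
  fdr <- lapply(fdr_alphas, function(a) fdr_threshold(pairs, null, a))
  names(fdr) <- paste0("alpha_", fdr_alphas)

  status <- classify_phage(ds$genes, ds$go)

  sig <- fdr[[1]]$pairs
  records <- pair_distances(sig, ds$genes, status = status,
                            intervening = TRUE)
  nonphage_rec <- records[
    status[records$family_a] == "not_associated" &
      status[records$family_b] == "not_associated", , drop = FALSE]
  dists <- list(
    min_all = build_distance_distribution(records, status, "all", "min"),
    min_nonphage = build_distance_distribution(records, status,
                                               "non_phage", "min"),
    occ_all = build_distance_distribution(records, status, "all",
                                          "occurrence"),
    occ_nonphage = build_distance_distribution(records, status,
                                               "non_phage", "occurrence"))
  ## truth-filtered analog of the sharp non-phage cutoff: significant
  ## pairs whose co-transfers were exclusively ordinary (non-phage) events
  truth_np <- records[records$pair %in% ds$truth$nonphage_cotransfer_pairs &
                        status[records$family_a] == "not_associated" &
                        status[records$family_b] == "not_associated", ,
                      drop = FALSE]
  dists$min_truth_nonphage <-
    build_distance_distribution(truth_np, status, "all", "min")
  phage_stats <- intervening_phage_stats(nonphage_rec, close_bound,
                                         far_bound)

  mi <- mi_matrix(ds$panel)
  go_shared <- shared_go_counts(ds$go)
  ## MI ~ shared-GO rank correlation over pairs sharing >= 1 term
  common <- intersect(rownames(mi), rownames(go_shared))
  Sg <- go_shared[common, common]
  Sm <- mi[common, common]
  ut <- upper.tri(Sg)
  gomi <- go_mi_correlation(Sg[ut], Sm[ut])

  if (is.null(reference_genome)) reference_genome <- tree$tip.label[1]
  ref_genes <- ds$genes[ds$genes$genome_id == reference_genome, ,
                        drop = FALSE]
  q_co <- qualify_pairs(ref_genes, "CO", mi = mi, status = status,
                        mi_cutoff = mi_cutoff)
  q_go <- qualify_pairs(ref_genes, "GO", go_shared = go_shared,
                        status = status, n_go = n_go)
  q_op <- qualify_pairs(ref_genes, "GO", go_shared = go_shared,
                        status = status, n_go = n_go,
                        operons = ds$operons, operon_restricted = TRUE)
  ac_co <- compute_ac(ref_genes, q_co, frame = frame, x_max = x_max)
  ac_go <- compute_ac(ref_genes, q_go, frame = frame, x_max = x_max)
  ac_op <- compute_ac(ref_genes, q_op, frame = frame, x_max = x_max)
  soc_co <- rescale_and_bin(ac_co, bins_per_decade)
  soc_go <- rescale_and_bin(ac_go, bins_per_decade)
  soc_op <- rescale_and_bin(ac_op, bins_per_decade)
  operon_dist <- operon_distance_distribution(ds$operons, ds$genes)

  ## the co-gained pair distance distribution, estimated through the same
  ## site-pair autocovariance as the SOC and operon estimates, so all
  ## compared curves share one representation
  q_cg <- qualifier_from_pairs(ref_genes, sig, status)
  soc_cogain <- if (sum(q_cg$Q) > 0) {
    rescale_and_bin(compute_ac(ref_genes, q_cg, frame = frame,
                               x_max = x_max), bins_per_decade)
  } else {
    NULL
  }

  na_cmp <- list(ks = NA_real_, median_a = NA_real_, median_b = NA_real_)
  cmp <- list(
    cogain_vs_soc_co = if (is.null(soc_cogain)) na_cmp else
      compare_distributions(soc_cogain, soc_co),
    cogain_vs_soc_go = if (is.null(soc_cogain)) na_cmp else
      compare_distributions(soc_cogain, soc_go),
    cogain_vs_operon = if (is.null(soc_cogain)) na_cmp else
      compare_distributions(soc_cogain, soc_op),
    soc_co_vs_soc_go = compare_distributions(soc_co, soc_go),
    operon_ac_vs_operon = compare_distributions(soc_op, operon_dist))

  counts <- lapply(fdr, function(f) {
    p <- f$pairs
    both_go <- p[p$family_a %in% ds$go$family_id &
                   p$family_b %in% ds$go$family_id, , drop = FALSE]
    both_np <- both_go[status[both_go$family_a] == "not_associated" &
                         status[both_go$family_b] == "not_associated", ,
                       drop = FALSE]
    d <- vapply(seq_len(nrow(both_np)), function(i)
      min_family_distance(both_np$family_a[i], both_np$family_b[i],
                          ds$genes), numeric(1))
    d <- d[!is.na(d)]
    c(total = nrow(p), both_go = nrow(both_go), both_nonphage = nrow(both_np),
      close = sum(d < close_bound), distant = sum(d >= close_bound))
  })

  summary <- list(
    alpha = model$alpha, beta = model$beta,
    n_branches = nrow(tree$edge),
    n_gained_families = nrow(G),
    n_pairs_scored = nrow(pairs),
    thresholds = vapply(fdr, function(f) f$threshold, numeric(1)),
    counts = counts,
    phage_stats = phage_stats,
    go_mi_rho = gomi$rho,
    median_operon = median(operon_dist),
    median_operon_ac = median(soc_op),
    median_soc_co = median(soc_co),
    median_soc_go = median(soc_go),
    median_cogain = median(dists$min_nonphage),
    median_cogain_ac = if (is.null(soc_cogain)) NA_real_ else
      median(soc_cogain),
    ks = vapply(cmp, function(x) x$ks, numeric(1)))

  structure(list(config = config, dataset = ds, model = model,
                 posterior = post, events = events, pairs = pairs,
                 null = null, fdr = fdr, status = status,
                 records = records, distributions = dists,
                 phage_stats = phage_stats, mi = mi,
                 go_shared = go_shared, go_mi = gomi,
                 reference_genome = reference_genome,
                 ac = list(co = ac_co, go = ac_go, operon = ac_op),
                 soc = list(co = soc_co, go = soc_go, operon = soc_op,
                            cogain = soc_cogain),
                 operon_dist = operon_dist, comparisons = cmp,
                 summary = summary),
            class = "hgt_pipeline")
}

#' @export
print.hgt_pipeline <- function(x, ...) {
  s <- x$summary
  cat("Co-gain / SOC pipeline\n")
  cat(sprintf("  gain/loss rates: alpha = %.3g, beta = %.3g\n",
              s$alpha, s$beta))
  cat(sprintf("  %d branches, %d gained families, %d pairs scored\n",
              s$n_branches, s$n_gained_families, s$n_pairs_scored))
  for (nm in names(x$fdr)) {
    cat(sprintf("  %s: t* = %.4f, significant pairs = %d\n", nm,
                x$fdr[[nm]]$threshold, nrow(x$fdr[[nm]]$pairs)))
  }
  cat(sprintf("  medians (bp): co-gain %.0f | SOC(CO) %.0f | SOC(GO) %.0f | operon %.0f\n",
              s$median_cogain, s$median_soc_co, s$median_soc_go,
              s$median_operon))
  cat(sprintf("  KS co-gain vs SOC(CO) %.3f | vs operon %.3f\n",
              s$ks[["cogain_vs_soc_co"]], s$ks[["cogain_vs_operon"]]))
  invisible(x)
}
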