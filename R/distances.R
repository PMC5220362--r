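## Genomic distances of gene pairs on circular chromosomes, minimum-over-
## genomes and per-occurrence distance distributions of co-gained pairs,
## and the intervening phage-gene comparison between close and distant
## allele pairs.

#' Circular boundary-gap distance between two genes
#'
#' Gap between the nearest boundaries of two features along the shorter arc
#' of a circular chromosome; 0 if the features overlap. Coordinates are
#' 0-based half-open; a feature wrapping the origin may be encoded with
#' `end > genome_length`. Vectorised and symmetric.
#'
#' @param start_a,end_a,start_b,end_b feature coordinates (bp).
#' @param genome_length circle length (bp).
#' @return distance(s) in bp, in `[0, genome_length/2]`.
#' @export
circular_distance <- function(start_a, end_a, start_b, end_b, genome_length) {
  L <- genome_length
  d_ab <- pmod(start_b - end_a, L)   # arc from A's end forward to B's start
  d_ba <- pmod(start_a - end_b, L)
  len_a <- end_a - start_a
  len_b <- end_b - start_b
  ## overlap on the circle: one start falls inside the other feature
  b_in_a <- pmod(start_b - start_a, L) < len_a
  a_in_b <- pmod(start_a - start_b, L) < len_b
  ifelse(b_in_a | a_in_b, 0, pmin(d_ab, d_ba))
}

#' Midpoint distance between two genes on a circle
#'
#' Distance between feature midpoints along the shorter arc. At distances
#' much larger than a gene length it coincides with the boundary-gap
#' distance; at cluster scale it matches the site-offset scale on which
#' autocovariance-based distributions live, which makes gene-pair and
#' site-pair distributions directly comparable.
#'
#' @inheritParams circular_distance
#' @return distance(s) in bp, in `[0, genome_length/2]`.
#' @export
midpoint_distance <- function(start_a, end_a, start_b, end_b, genome_length) {
  L <- genome_length
  ma <- pmod((start_a + end_a) / 2, L)
  mb <- pmod((start_b + end_b) / 2, L)
  d <- abs(ma - mb)
  pmin(d, L - d)
}

gene_distance_fun <- function(convention) {
  switch(convention, midpoint = midpoint_distance, gap = circular_distance,
         stopf("unknown distance convention '%s'", convention))
}

## per-genome minimum allele-pair distance for one family pair
pair_distance_in_genome <- function(ga, gb, L, convention = "midpoint") {
  dfun <- gene_distance_fun(convention)
  best <- Inf
  for (i in seq_len(nrow(ga)))
    for (j in seq_len(nrow(gb)))
      best <- min(best, dfun(ga$start[i], ga$end[i],
                             gb$start[j], gb$end[j], L))
  best
}

#' Per-occurrence distances of a family pair
#'
#' For every genome where both families are present, the minimum
#' circular distance over all allele (paralog) pairs in that genome.
#'
#' @param fam_a,fam_b family ids.
#' @param genes pooled annotation table (`family_id`, `genome_id`, `start`,
#'   `end`, `genome_length`).
#' @param convention `"midpoint"` (default) or `"gap"` (nearest-boundary
#'   gap along the shorter arc).
#' @return named numeric vector, one distance per co-occupied genome
#'   (length 0 if the families never co-occur).
#' @export
per_occurrence_distances <- function(fam_a, fam_b, genes,
                                     convention = "midpoint") {
  ga <- genes[genes$family_id == fam_a, , drop = FALSE]
  gb <- genes[genes$family_id == fam_b, , drop = FALSE]
  shared <- intersect(unique(ga$genome_id), unique(gb$genome_id))
  out <- vapply(shared, function(g) {
    a <- ga[ga$genome_id == g, , drop = FALSE]
    b <- gb[gb$genome_id == g, , drop = FALSE]
    pair_distance_in_genome(a, b, a$genome_length[1], convention)
  }, numeric(1))
  setNames(out, shared)
}

#' Minimum distance of a family pair over all genomes
#'
#' The minimum over genomes of the per-genome minimum allele-pair distance;
#' a lower bound on the pair's genomic distance at transfer time.
#'
#' @inheritParams per_occurrence_distances
#' @return single distance in bp, or `NA` if never co-present.
#' @export
min_family_distance <- function(fam_a, fam_b, genes,
                                convention = "midpoint") {
  d <- per_occurrence_distances(fam_a, fam_b, genes, convention)
  if (length(d) == 0) NA_real_ else min(d)
}

#' Distance records for a set of family pairs
#'
#' Computes, for every pair and every genome where both families occur,
#' the per-genome minimum allele distance, and optionally the intervening
#' genes on the shorter arc (count, and fraction phage-associated).
#'
#' @param pairs data.frame with `family_a`, `family_b`.
#' @param genes pooled annotation table.
#' @param status optional named phage-status vector from [classify_phage()]
#'   (required for intervening-gene fractions).
#' @param intervening compute intervening-gene statistics.
#' @param convention `"midpoint"` (default) or `"gap"`.
#' @return data.frame `family_a`, `family_b`, `pair`, `genome_id`,
#'   `distance`, and (if requested) `n_intervening`,
#'   `frac_intervening_phage` (`NA` when no genes lie between).
#' @export
pair_distances <- function(pairs, genes, status = NULL, intervening = FALSE,
                           convention = "midpoint") {
  dfun <- gene_distance_fun(convention)
  by_fam <- split(genes, genes$family_id)
  by_gen <- if (intervening) split(genes, genes$genome_id) else NULL
  rows <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    fa <- pairs$family_a[k]; fb <- pairs$family_b[k]
    ga <- by_fam[[fa]]; gb <- by_fam[[fb]]
    if (is.null(ga) || is.null(gb)) next
    shared <- intersect(unique(ga$genome_id), unique(gb$genome_id))
    if (length(shared) == 0) next
    recs <- lapply(shared, function(gid) {
      a <- ga[ga$genome_id == gid, , drop = FALSE]
      b <- gb[gb$genome_id == gid, , drop = FALSE]
      L <- a$genome_length[1]
      best <- Inf; bi <- 1L; bj <- 1L
      for (i in seq_len(nrow(a)))
        for (j in seq_len(nrow(b))) {
          d <- dfun(a$start[i], a$end[i], b$start[j], b$end[j], L)
          if (d < best) { best <- d; bi <- i; bj <- j }
        }
      out <- data.frame(family_a = fa, family_b = fb,
                        pair = pair_key(fa, fb), genome_id = gid,
                        distance = best, stringsAsFactors = FALSE)
      if (intervening) {
        iv <- intervening_genes(a[bi, ], b[bj, ], by_gen[[gid]], L)
        out$n_intervening <- length(iv)
        out$frac_intervening_phage <- if (length(iv) == 0) NA_real_ else
          mean(status[iv] == "associated", na.rm = TRUE)
      }
      out
    })
    rows[[k]] <- do.call(rbind, recs)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(family_a = character(0), family_b = character(0),
                      pair = character(0), genome_id = character(0),
                      distance = numeric(0))
    if (intervening) {
      out$n_intervening <- integer(0)
      out$frac_intervening_phage <- numeric(0)
    }
  }
  rownames(out) <- NULL
  out
}

## family ids of genes whose midpoint lies strictly inside the shorter-arc
## gap between two alleles
intervening_genes <- function(a, b, genome_genes, L) {
  d_ab <- pmod(b$start - a$end, L)
  d_ba <- pmod(a$start - b$end, L)
  if (d_ab <= d_ba) { from <- pmod(a$end, L); width <- d_ab }
  else { from <- pmod(b$end, L); width <- d_ba }
  if (width <= 0) return(character(0))
  mid <- pmod((genome_genes$start + genome_genes$end) / 2, L)
  off <- pmod(mid - from, L)
  hit <- off > 0 & off < width
  hit[genome_genes$family_id %in% c(a$family_id, b$family_id)] <- FALSE
  unique(genome_genes$family_id[hit])
}

#' Close vs distant allele pairs: intervening phage-gene comparison
#'
#' Splits per-occurrence records into close (`distance < close_bound`) and
#' distant (`close_bound <= distance < far_bound`) groups, keeps only
#' occurrences with at least one intervening gene, and compares the
#' fraction of intervening genes that are phage-associated between the two
#' groups with a two-sided Wilcoxon rank-sum test.
#'
#' @param records a [pair_distances()] result with intervening statistics.
#' @param close_bound,far_bound group boundaries in bp (analogs of the
#'   30 kb and 70 kb transfer-size bounds).
#' @return list: group means (`mean_close`, `mean_distant`, as
#'   percentages), occurrence counts, fraction of distant occurrences with
#'   at least one intervening phage gene, max distance among distant
#'   occurrences without one, and the rank-sum `p_value` (`NA` if a group
#'   is empty).
#' @export
intervening_phage_stats <- function(records, close_bound, far_bound) {
  if (!"frac_intervening_phage" %in% names(records))
    stopf("records lack intervening-gene statistics")
  r <- records[!is.na(records$frac_intervening_phage), , drop = FALSE]
  close <- r$frac_intervening_phage[r$distance < close_bound]
  distant_rows <- r$distance >= close_bound & r$distance < far_bound
  distant <- r$frac_intervening_phage[distant_rows]
  has_phage <- r$frac_intervening_phage[distant_rows] > 0
  p <- if (length(close) > 0 && length(distant) > 0)
    suppressWarnings(wilcox.test(distant, close)$p.value) else NA_real_
  list(mean_close = 100 * mean(close),
       mean_distant = 100 * mean(distant),
       n_close = length(close), n_distant = length(distant),
       frac_distant_with_phage =
         if (length(distant) > 0) mean(has_phage) else NA_real_,
       max_distant_without_phage =
         if (any(!has_phage)) max(r$distance[distant_rows][!has_phage])
         else NA_real_,
       p_value = p)
}

#' Empirical distance distribution of co-gained pairs
#'
#' Builds the (cumulative) distribution of pair distances, either the
#' minimum over genomes per pair (`mode = "min"`) or pooled per-occurrence
#' values (`mode = "occurrence"`), optionally restricted to pairs whose
#' members are both strictly `not_associated` with phages (uncertain
#' families excluded, mirroring a "known to be non-phage" filter).
#'
#' @param records a [pair_distances()] result.
#' @param status named phage-status vector (required for the filter).
#' @param filter `"all"` or `"non_phage"`.
#' @param mode `"min"` or `"occurrence"`.
#' @return object of class `distance_distribution`: sorted `distances`,
#'   `filter`, `mode`, `n`.
#' @export
build_distance_distribution <- function(records, status = NULL,
                                        filter = c("all", "non_phage"),
                                        mode = c("min", "occurrence")) {
  filter <- match.arg(filter)
  mode <- match.arg(mode)
  r <- records
  if (filter == "non_phage") {
    if (is.null(status)) stopf("status needed for the non-phage filter")
    ok <- status[r$family_a] == "not_associated" &
      status[r$family_b] == "not_associated"
    r <- r[ok, , drop = FALSE]
  }
  d <- if (mode == "min") {
    tapply(r$distance, r$pair, min)
  } else {
    r$distance
  }
  structure(list(distances = sort(as.numeric(d)), filter = filter,
                 mode = mode, n = length(d)),
            class = "distance_distribution")
}

#' Evaluate a cumulative distance distribution
#'
#' @param dist a `distance_distribution` or `soc_distribution` object.
#' @param x distances (bp) at which to evaluate the CDF.
#' @return CDF values in `[0,1]` (0s if the distribution is empty).
#' @export
dist_cdf <- function(dist, x) {
  UseMethod("dist_cdf")
}

#' @export
dist_cdf.distance_distribution <- function(dist, x) {
  if (dist$n == 0) return(rep(0, length(x)))
  vapply(x, function(q) mean(dist$distances <= q), numeric(1))
}

#' @export
median.distance_distribution <- function(x, ...) {
  if (x$n == 0) return(NA_real_)
  median(x$distances)
}
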