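## Delineation of supra-operonic cluster (SOC) distance distributions via
## genomic autocovariance. For nucleotide sites i on a sliding frame inside
## eligible genes, g_i(x) = 1 when site i lies in gene A and site i+x
## (circular) lies in a different gene B such that (A, B) is a qualifying
## pair — co-occurring (MI above a cutoff) or co-functioning (shared GO
## terms above a cutoff), both genes non-phage and outside mobile elements.
## G(x) is the mean of g_i(x) over the n qualifying sites; rescaling by the
## background level and log-binning turns G(x) into an estimate of the
## within-cluster pair distance distribution G_cluster(x).

#' Qualifying gene pairs for autocovariance
#'
#' Selects the unordered family pairs on one genome that qualify as
#' co-occurring (`mode = "CO"`: profile MI above `mi_cutoff`) or
#' co-functioning (`mode = "GO"`: at least `n_go` shared GO terms). Pairs
#' with a phage-associated member, or a member overlapping a mobile
#' element, are excluded; `operon_restricted` additionally requires both
#' genes in the same operon.
#'
#' @param genes annotation table of one genome.
#' @param mode `"CO"` or `"GO"`.
#' @param mi optional symmetric MI matrix (CO mode).
#' @param go_shared optional symmetric shared-GO-count matrix (GO mode).
#' @param status named phage-status vector from [classify_phage()].
#' @param mi_cutoff MI threshold (CO mode).
#' @param n_go minimum shared GO terms (GO mode).
#' @param operons optional operon table (`genome_id`, `operon_id`,
#'   `family_id`) used when `operon_restricted = TRUE`.
#' @param operon_restricted restrict to pairs within one operon.
#' @param mobile optional named logical of mobile-element overlap.
#' @return list of class `pair_qualifier`: `families` (eligible families on
#'   the genome) and `Q` (symmetric logical matrix of qualifying pairs,
#'   diagonal `FALSE`).
#' @export
qualify_pairs <- function(genes, mode = c("CO", "GO"), mi = NULL,
                          go_shared = NULL, status,
                          mi_cutoff = 1e-4, n_go = 1L,
                          operons = NULL, operon_restricted = FALSE,
                          mobile = NULL) {
  mode <- match.arg(mode)
  fams <- unique(genes$family_id)
  ok <- status[fams] == "not_associated"
  if (!is.null(mobile)) ok <- ok & !mobile[fams]
  fams <- fams[!is.na(ok) & ok]
  S <- if (mode == "CO") mi else go_shared
  if (is.null(S)) stopf("similarity matrix for mode %s missing", mode)
  fams <- fams[fams %in% rownames(S)]
  if (length(fams) < 2)
    return(structure(list(families = fams,
                          Q = matrix(FALSE, length(fams), length(fams),
                                     dimnames = list(fams, fams))),
                     class = "pair_qualifier"))
  cut <- if (mode == "CO") mi_cutoff else n_go
  Q <- S[fams, fams, drop = FALSE] >= cut
  diag(Q) <- FALSE
  if (operon_restricted) {
    if (is.null(operons)) stopf("operon table required when restricted")
    op <- operons[operons$genome_id == genes$genome_id[1], , drop = FALSE]
    fam_op <- setNames(op$operon_id, op$family_id)
    same <- outer(fam_op[fams], fam_op[fams], "==")
    same[is.na(same)] <- FALSE
    Q <- Q & same
  }
  structure(list(families = fams, Q = Q), class = "pair_qualifier")
}

## add, for one ordered gene-instance pair with lattice site ranges
## A=[a1,a2], B=[b1,b2], the count of site pairs (i in A, j in B) with
## circular lag (j - i) mod n_grid = m, for every m in 1..mmax, into H
add_pair_counts <- function(H, a1, a2, b1, b2, mmax, n_grid) {
  for (off in c(0L, n_grid, -n_grid)) {
    lo <- max(b1 - a2 + off, 1L)
    hi <- min(b2 - a1 + off, mmax)
    if (lo > hi) next
    ms <- lo:hi
    d <- ms - off
    cnt <- pmin(a2, b2 - d) - pmax(a1, b1 - d) + 1L
    H[ms] <- H[ms] + pmax(cnt, 0L)
  }
  H
}

#' Build a pair qualifier from an explicit pair list
#'
#' Wraps a set of family pairs (e.g. significant co-gained pairs) as a
#' `pair_qualifier`, so their genomic distance distribution can be
#' estimated through the same autocovariance machinery as the
#' co-occurrence and co-functioning cluster estimates — putting all
#' compared distributions on the same site-pair representation.
#'
#' @param genes annotation table of one genome.
#' @param pairs data.frame with `family_a`, `family_b`.
#' @param status named phage-status vector; pairs with a member not
#'   strictly `not_associated` are excluded.
#' @return a `pair_qualifier`.
#' @export
qualifier_from_pairs <- function(genes, pairs, status) {
  keep <- status[pairs$family_a] == "not_associated" &
    status[pairs$family_b] == "not_associated"
  pairs <- pairs[!is.na(keep) & keep, , drop = FALSE]
  fams <- intersect(unique(genes$family_id),
                    unique(c(pairs$family_a, pairs$family_b)))
  Q <- matrix(FALSE, length(fams), length(fams),
              dimnames = list(fams, fams))
  ok <- pairs$family_a %in% fams & pairs$family_b %in% fams
  Q[cbind(pairs$family_a[ok], pairs$family_b[ok])] <- TRUE
  Q <- Q | t(Q)
  structure(list(families = fams, Q = Q), class = "pair_qualifier")
}

#' Genomic autocovariance curve
#'
#' Evaluates G(x) on a sliding frame: sites i are taken every `frame` bp
#' within genes of the eligible families; for every offset x on the same
#' lattice up to `x_max`, G(x) is the fraction of sites i for which the
#' site i+x (circular) falls in a different gene forming a qualifying pair
#' with the gene at i. `frame = 1` gives the exact site-by-site curve.
#'
#' The curve is computed exactly from gene-pair geometry: every ordered
#' qualifying gene pair contributes a trapezoidal count profile over the
#' lag range it spans. When the qualifying pair set is dense, the total is
#' instead obtained from the FFT autocorrelation of the site-occupancy
#' indicator minus the (sparse) complement, which is algebraically
#' identical.
#'
#' @param genes annotation table of one genome.
#' @param qualifier a [qualify_pairs()] result.
#' @param frame lattice spacing in bp (default 10, which trades a little
#'   resolution for a large constant-factor speedup).
#' @param x_max largest offset evaluated (default `genome_length/40`,
#'   comfortably beyond the cluster length scale so the background level
#'   dominates the grid mean).
#' @return object of class `ac_curve`: data.frame `x`, `G`; plus `n`
#'   (number of sites), `frame`, `genome_length`.
#' @export
compute_ac <- function(genes, qualifier, frame = 10L, x_max = NULL) {
  L <- genes$genome_length[1]
  if (is.null(x_max)) x_max <- floor(L / 40)
  fams <- qualifier$families
  n_grid <- as.integer(floor(L / frame))
  mmax <- as.integer(floor(x_max / frame))
  if (n_grid < 4 || mmax < 1) stopf("frame too large for genome")
  if (mmax >= n_grid) mmax <- n_grid - 1L
  xs <- frame * seq_len(mmax)
  g <- genes[genes$family_id %in% fams, , drop = FALSE]
  ## lattice site ranges per gene instance (sites k*frame in [start, end))
  a1 <- as.integer(ceiling(g$start / frame))
  a2 <- as.integer(ceiling(g$end / frame) - 1L)
  keep <- a2 >= a1
  g <- g[keep, , drop = FALSE]; a1 <- a1[keep]; a2 <- a2[keep]
  n <- sum(a2 - a1 + 1L)
  H <- numeric(mmax)
  if (n > 0 && length(fams) >= 2 && nrow(g) >= 2) {
    fam_of <- match(g$family_id, fams)
    Q <- qualifier$Q
    Qg <- Q[fam_of, fam_of, drop = FALSE]   # instance-level qualification
    diag(Qg) <- FALSE
    n_qual <- sum(Qg)
    n_comp <- nrow(g) * (nrow(g) - 1L) - n_qual
    if (n_qual <= n_comp) {
      idx <- which(Qg, arr.ind = TRUE)
      for (k in seq_len(nrow(idx))) {
        r <- idx[k, 1]; s <- idx[k, 2]
        H <- add_pair_counts(H, a1[r], a2[r], a1[s], a2[s], mmax, n_grid)
      }
    } else {
      ## dense case: FFT autocorrelation of site occupancy, minus same-gene
      ## lags, minus the sparse non-qualifying complement
      f <- numeric(n_grid)
      for (r in seq_len(nrow(g)))
        f[pmod(a1[r]:a2[r], n_grid) + 1L] <- 1
      fh <- stats::fft(f)
      ac <- Re(stats::fft(fh * Conj(fh), inverse = TRUE)) / n_grid
      H <- ac[2:(mmax + 1L)]
      len <- a2 - a1 + 1L
      for (r in seq_len(nrow(g))) {
        m <- seq_len(min(len[r] - 1L, mmax))
        if (length(m) > 0) H[m] <- H[m] - (len[r] - m)
      }
      comp <- which(!Qg & !diag(TRUE, nrow(g)), arr.ind = TRUE)
      for (k in seq_len(nrow(comp))) {
        r <- comp[k, 1]; s <- comp[k, 2]
        Hc <- add_pair_counts(numeric(mmax), a1[r], a2[r], a1[s], a2[s],
                              mmax, n_grid)
        H <- H - Hc
      }
      H <- pmax(round(H), 0)
    }
  }
  structure(list(curve = data.frame(x = xs, G = H / max(n, 1L)), n = n,
                 frame = frame, genome_length = L),
            class = "ac_curve")
}

#' Rescale, log-bin and truncate an autocovariance curve
#'
#' Rescales G(x) to `(G - <G>)/(max G - <G>)` (so the background level maps
#' to 0 and the peak to 1), averages it in geometric (log-spaced) bins,
#' drops the low-distance bins before the first local maximum (cross-gene
#' site pairs are depleted at distances below typical gene length, which
#' only adds noise), truncates at the first non-positive bin after the
#' peak, and renormalises the remaining mass into a probability
#' distribution over pair distances — the estimate of G_cluster(x).
#'
#' @param ac an [compute_ac()] curve.
#' @param bins_per_decade geometric bin resolution (default 25).
#' @return object of class `soc_distribution`: data.frame `bins` with
#'   `left`, `right`, `mid`, `value` (peak-normalised binned curve),
#'   `mass`, `cdf`.
#' @export
rescale_and_bin <- function(ac, bins_per_decade = 25L) {
  cv <- ac$curve
  if (nrow(cv) == 0 || all(cv$G == 0)) stopf("empty autocovariance curve")
  g0 <- mean(cv$G)
  peak <- max(cv$G)
  if (peak <= g0) stopf("flat autocovariance curve; no cluster signal")
  gt <- (cv$G - g0) / (peak - g0)
  lo <- log10(min(cv$x))
  hi <- log10(max(cv$x))
  edges <- 10^seq(lo, hi + 1 / bins_per_decade,
                  by = 1 / bins_per_decade)
  bin <- findInterval(cv$x, edges, rightmost.closed = TRUE)
  val <- tapply(gt, bin, mean)
  cnt <- tapply(gt, bin, length)
  bidx <- as.integer(names(val))
  o <- order(bidx)                 # tapply orders factor levels as strings
  val <- val[o]; cnt <- cnt[o]; bidx <- bidx[o]
  bins <- data.frame(left = edges[bidx], right = edges[bidx + 1L],
                     mid = sqrt(edges[bidx] * edges[bidx + 1L]),
                     value = as.numeric(val), n_x = as.integer(cnt))
  ## drop leading low-distance noise: bins on the rising flank whose level
  ## is below a small fraction of the peak carry few legitimate cross-gene
  ## site pairs and are dominated by discretisation noise; the genuine
  ## flank above the floor is kept
  v <- bins$value
  first_ok <- which(v >= 0.05 * max(v))[1]
  bins <- bins[first_ok:nrow(bins), , drop = FALSE]
  ## peak-normalise the binned curve, then truncate after the peak at the
  ## first bin that is non-positive
  bins$value <- bins$value / max(bins$value)
  pk <- which.max(bins$value)
  after <- which(bins$value <= 0 & seq_len(nrow(bins)) > pk)
  if (length(after) > 0) bins <- bins[seq_len(min(after) - 1L), , drop = FALSE]
  bins$value[bins$value < 0] <- 0
  w <- bins$value * bins$n_x
  bins$mass <- w / sum(w)
  bins$cdf <- cumsum(bins$mass)
  rownames(bins) <- NULL
  structure(list(bins = bins), class = "soc_distribution")
}

#' @export
dist_cdf.soc_distribution <- function(dist, x) {
  b <- dist$bins
  ## piecewise-linear CDF across bins (mass spread within each bin)
  cdf_at <- function(q) {
    if (q < b$left[1]) return(0)
    if (q >= b$right[nrow(b)]) return(1)
    j <- max(which(b$left <= q))
    below <- if (j > 1) b$cdf[j - 1] else 0
    frac <- min(1, max(0, (q - b$left[j]) / (b$right[j] - b$left[j])))
    below + frac * b$mass[j]
  }
  vapply(x, cdf_at, numeric(1))
}

#' @export
median.soc_distribution <- function(x, ...) {
  b <- x$bins
  j <- which(b$cdf >= 0.5)[1]
  below <- if (j > 1) b$cdf[j - 1] else 0
  need <- 0.5 - below
  b$left[j] + (b$right[j] - b$left[j]) * need / b$mass[j]
}

#' Compare two distance distributions
#'
#' Two-sample Kolmogorov–Smirnov statistic between the cumulative
#' distributions, evaluated on the merged support grid, with both medians.
#' Works for empirical (`distance_distribution`) and autocovariance-derived
#' (`soc_distribution`) objects interchangeably.
#'
#' @param dist_a,dist_b distribution objects supporting [dist_cdf()] and
#'   `median`.
#' @return list `ks`, `median_a`, `median_b`.
#' @export
compare_distributions <- function(dist_a, dist_b) {
  grid_of <- function(d) {
    if (inherits(d, "soc_distribution")) c(d$bins$left, d$bins$right)
    else d$distances
  }
  grid <- sort(unique(c(grid_of(dist_a), grid_of(dist_b))))
  ## refine between breakpoints: piecewise-linear CDFs attain their maximum
  ## difference at breakpoints of either curve, so the merged grid suffices
  ks <- max(abs(dist_cdf(dist_a, grid) - dist_cdf(dist_b, grid)))
  list(ks = ks, median_a = median(dist_a), median_b = median(dist_b))
}

#' Pairwise distance distribution of genes within operons
#'
#' Pools, across genomes, the circular boundary-gap distances of all gene
#' pairs that share an operon.
#'
#' @param operons operon table (`genome_id`, `operon_id`, `family_id`).
#' @param genes pooled annotation table.
#' @param convention `"midpoint"` (default) or `"gap"`; see
#'   [per_occurrence_distances()].
#' @return a `distance_distribution` (mode `"operon"`).
#' @export
operon_distance_distribution <- function(operons, genes,
                                         convention = "midpoint") {
  dfun <- gene_distance_fun(convention)
  dists <- numeric(0)
  key <- paste(genes$genome_id, genes$family_id)
  for (gid in unique(operons$genome_id)) {
    op <- operons[operons$genome_id == gid, , drop = FALSE]
    for (oid in unique(op$operon_id)) {
      fams <- op$family_id[op$operon_id == oid]
      if (length(fams) < 2) next
      rows <- genes[match(paste(gid, fams), key), , drop = FALSE]
      L <- rows$genome_length[1]
      prs <- combn(nrow(rows), 2)
      d <- dfun(rows$start[prs[1, ]], rows$end[prs[1, ]],
                rows$start[prs[2, ]], rows$end[prs[2, ]], L)
      dists <- c(dists, d)
    }
  }
  structure(list(distances = sort(dists), filter = "operon",
                 mode = "operon", n = length(dists)),
            class = "distance_distribution")
}
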