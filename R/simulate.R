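## Forward simulator of gene-content evolution with segmental co-transfer.
##
## The generator emulates the data a co-gain / SOC analysis consumes: a
## rooted bifurcating phylogeny, a circular ancestral genome organised into
## supra-operonic clusters (SOCs) subdivided into operon-scale blocks,
## per-branch gene loss, segmental acquisitions bounded by `segment_cap`,
## phage-mediated acquisitions bounded by the larger `phage_segment_cap`
## with phage-flagged genes interleaved between cargo genes, GO terms shared
## within clusters/operons, and a multi-species co-occurrence panel.

#' Simulation configuration
#'
#' Bundles and validates all parameters of the synthetic-data generator.
#' Defaults define the package's reference study conditions: 16 genomes, a
#' 2 Mb circular chromosome carrying 1500 gene families, 40 clusters, a
#' 5 kb cap on ordinarily transferred segments and a 12 kb cap on
#' phage-mediated segments (scaled-down analogs of the 30 kb / 70 kb bounds
#' observed for enterobacterial transfers and phage genomes).
#'
#' @param n_leaves number of extant genomes (>= 4).
#' @param tree_depth expected root-to-tip branch-length sum.
#' @param genome_length circular chromosome length in bp.
#' @param n_families number of orthologous gene families in the pan-genome.
#' @param n_clusters number of supra-operonic clusters; remaining families
#'   are singletons.
#' @param cluster_size_range integer range `c(min, max)` of genes per cluster.
#' @param operon_size_range integer range of genes per operon-scale block
#'   within a cluster.
#' @param intra_cluster_gap `c(mean, max)` bp of the (truncated exponential)
#'   gap distribution between neighbouring genes of one cluster.
#' @param gain_rate segmental acquisition events per unit branch length.
#' @param loss_rate per-family loss rate per unit branch length; losses are
#'   realised as contiguous block deletions of geometric mean length
#'   `loss_block_mean` genes, as mutational deletions remove multi-gene
#'   stretches.
#' @param loss_block_mean mean genes removed per deletion event.
#' @param cluster_transfer_weight relative weight of clustered families
#'   when seeding an acquisition segment; values > 1 make SOC units the
#'   preferred cargo of transfer, the regime the analysis is designed to
#'   detect.
#' @param segment_cap bp cap on non-phage transferred segments.
#' @param phage_segment_cap bp cap on phage-mediated segments.
#' @param phage_event_fraction probability an acquisition is phage-mediated.
#' @param phage_family_fraction fraction of families that are phage genes.
#' @param uncertain_fraction fraction of non-phage singleton families whose
#'   GO annotation is withheld (their phage status becomes uncertain).
#' @param go_terms_per_cluster GO terms shared by all members of a cluster.
#' @param go_terms_per_operon extra GO terms shared within an operon block.
#' @param n_panel_species species in the cross-species co-occurrence panel.
#' @param panel_cluster_prob probability a cluster is present in a panel
#'   species.
#' @param panel_block_flip probability an operon block deviates from its
#'   cluster's presence state in a panel species.
#' @param panel_gene_flip per-gene flip noise in the panel.
#' @param seed integer RNG seed (< 2^31 - 16).
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_leaves = 16,
                       tree_depth = 2.5,
                       genome_length = 2e6,
                       n_families = 1500,
                       n_clusters = 90,
                       cluster_size_range = c(4L, 4L),
                       operon_size_range = c(2L, 2L),
                       intra_cluster_gap = c(mean = 200, max = 1500),
                       gain_rate = 50,
                       loss_rate = 2.6,
                       loss_block_mean = 4,
                       cluster_transfer_weight = 100,
                       segment_cap = 5000,
                       phage_segment_cap = 12000,
                       phage_event_fraction = 0.25,
                       phage_family_fraction = 0.08,
                       uncertain_fraction = 0.15,
                       go_terms_per_cluster = 2L,
                       go_terms_per_operon = 5L,
                       n_panel_species = 200L,
                       panel_cluster_prob = 0.5,
                       panel_block_flip = 0.15,
                       panel_gene_flip = 0.01,
                       seed = 1L) {
  cfg <- list(n_leaves = as.integer(n_leaves), tree_depth = tree_depth,
              genome_length = genome_length,
              n_families = as.integer(n_families),
              n_clusters = as.integer(n_clusters),
              cluster_size_range = as.integer(cluster_size_range),
              operon_size_range = as.integer(operon_size_range),
              intra_cluster_gap = intra_cluster_gap,
              gain_rate = gain_rate, loss_rate = loss_rate,
              loss_block_mean = loss_block_mean,
              cluster_transfer_weight = cluster_transfer_weight,
              segment_cap = segment_cap,
              phage_segment_cap = phage_segment_cap,
              phage_event_fraction = phage_event_fraction,
              phage_family_fraction = phage_family_fraction,
              uncertain_fraction = uncertain_fraction,
              go_terms_per_cluster = as.integer(go_terms_per_cluster),
              go_terms_per_operon = as.integer(go_terms_per_operon),
              n_panel_species = as.integer(n_panel_species),
              panel_cluster_prob = panel_cluster_prob,
              panel_block_flip = panel_block_flip,
              panel_gene_flip = panel_gene_flip,
              seed = as.integer(seed))
  if (cfg$n_leaves < 4L)
    stopf("n_leaves must be >= 4 (got %d)", cfg$n_leaves)
  if (!(cfg$segment_cap < cfg$phage_segment_cap))
    stopf("segment_cap must be < phage_segment_cap")
  if (!(cfg$phage_segment_cap < cfg$genome_length / 2))
    stopf("phage_segment_cap must be < genome_length/2")
  if (cfg$gain_rate < 0 || cfg$loss_rate < 0 || cfg$tree_depth <= 0)
    stopf("rates must be >= 0 and tree_depth > 0")
  if (cfg$loss_block_mean < 1 || cfg$cluster_transfer_weight <= 0)
    stopf("loss_block_mean must be >= 1 and cluster_transfer_weight > 0")
  if (cfg$n_clusters > 0 &&
      (cfg$cluster_size_range[1] < 2L ||
       cfg$cluster_size_range[2] < cfg$cluster_size_range[1]))
    stopf("invalid cluster_size_range")
  for (p in c("phage_event_fraction", "phage_family_fraction",
              "uncertain_fraction", "panel_cluster_prob",
              "panel_block_flip", "panel_gene_flip"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stopf("%s must be in [0,1]", p)
  if (is.na(cfg$seed) || abs(seed) >= 2^31 - 16)
    stopf("seed must be an integer below 2^31 - 16")
  structure(cfg, class = "sim_config")
}

## sample() without the scalar-x surprise
resample <- function(x, size = 1, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

## truncated-exponential intergenic gap sampler
sample_gap <- function(n, cfg) {
  g <- rexp(n, rate = 1 / cfg$intra_cluster_gap[["mean"]])
  round(pmin(g, cfg$intra_cluster_gap[["max"]]))
}

#' Simulate a rooted bifurcating phylogeny
#'
#' Draws a random rooted, fully bifurcating topology and assigns branch
#' lengths with the shape typical of a bacterial strain phylogeny: long
#' basal branches below the root, a rapid radiation of short internal
#' branches, and long terminal branches (relative weights 2 : 0.1 : 1).
#' Lengths are rescaled so the mean root-to-tip path equals `tree_depth`.
#' Leaves are labelled `G01, G02, ...` and internal nodes `N<ape index>`;
#' branches are identified by their child node throughout the package.
#'
#' @param config a [sim_config()].
#' @return an [ape::rtree()]-style `phylo` object, rooted and binary.
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_leaves
  tr <- ape::rtree(n, rooted = TRUE,
                   tip.label = sprintf("G%02d", seq_len(n)))
  is_tip <- tr$edge[, 2] <= n
  is_basal <- tr$edge[, 1] == n + 1L
  w <- ifelse(is_basal, 2, ifelse(is_tip, 1, 0.1))
  tr$edge.length <- w * runif(nrow(tr$edge), 0.8, 1.2)
  depth <- mean(ape::node.depth.edgelength(tr)[seq_len(n)])
  tr$edge.length <- tr$edge.length * config$tree_depth / depth
  tr$node.label <- sprintf("N%02d", (n + 1L):(2L * n - 1L))
  ape::reorder.phylo(tr, "cladewise")
}

## node labels in ape numbering order (tips then internals)
node_names <- function(tree) {
  c(tree$tip.label, tree$node.label)
}

## ring representation of one circular genome: ordered genes with the gap
## to the next gene; coordinates are derived 0-based half-open
ring_coords <- function(ring) {
  if (nrow(ring) == 0)
    return(cbind(start = numeric(0), end = numeric(0)))
  step <- ring$length + ring$gap_after
  start <- cumsum(c(0, step[-length(step)]))
  cbind(start = start, end = start + ring$length)
}

ring_genome_length <- function(ring) sum(ring$length + ring$gap_after)

## ring -> per-gene annotation table for one genome
ring_annotation <- function(ring, genome_id, fam) {
  co <- ring_coords(ring)
  data.frame(family_id = fam$family_id[ring$family],
             genome_id = genome_id,
             start = co[, "start"], end = co[, "end"],
             strand = fam$strand[ring$family],
             product = fam$product[ring$family],
             genome_length = ring_genome_length(ring),
             stringsAsFactors = FALSE)
}

#' Simulate the ancestral (root) genome
#'
#' Lays `n_families` genes on a circular chromosome. Cluster members are
#' contiguous, separated by truncated-exponential gaps, and subdivided into
#' operon-scale blocks; singleton and phage families fill the remaining
#' space. Each cluster shares `go_terms_per_cluster` GO terms and each
#' operon block shares `go_terms_per_operon` additional terms, so that the
#' number of shared terms increases with organisational tightness. All
#' intra-cluster pairwise distances are recorded as ground truth.
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_root` with elements `ring` (gene order and
#'   gaps), `genes` (annotation table), `families` (per-family metadata),
#'   and `truth` (cluster/operon membership, phage flags, GO assignments,
#'   intra-cluster distance samples).
#' @export
simulate_root_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_families
  fam_id <- sprintf("F%04d", seq_len(n))

  ## cluster / operon membership over family indices
  cluster <- integer(n)
  operon <- integer(n)
  if (config$n_clusters > 0) {
    sizes <- resample(seq(config$cluster_size_range[1],
                          config$cluster_size_range[2]),
                      config$n_clusters, replace = TRUE)
    if (sum(sizes) > floor(0.8 * n))
      stopf("cluster genes (%d) exceed 80%% of n_families", sum(sizes))
    idx <- 1L
    op_id <- 0L
    for (cl in seq_along(sizes)) {
      members <- idx:(idx + sizes[cl] - 1L)
      cluster[members] <- cl
      left <- members
      while (length(left) > 0) {
        k <- min(length(left),
                 resample(seq(config$operon_size_range[1],
                              config$operon_size_range[2])))
        op_id <- op_id + 1L
        operon[left[seq_len(k)]] <- op_id
        left <- left[-seq_len(k)]
      }
      idx <- idx + sizes[cl]
    }
  }
  singletons <- which(cluster == 0L)
  n_phage <- round(config$phage_family_fraction * n)
  if (n_phage > length(singletons))
    stopf("not enough singleton families for phage_family_fraction")
  phage <- logical(n)
  phage[resample(singletons, n_phage)] <- TRUE

  ## GO assignment: cluster-wide + operon-level terms; private terms for
  ## ordinary singletons; a viral-process term for phage genes; withheld
  ## entirely for the `uncertain` fraction of ordinary singletons
  go <- vector("list", n)
  for (f in seq_len(n)) {
    terms <- character(0)
    if (cluster[f] > 0) {
      terms <- c(sprintf("GO:C%03d_%d", cluster[f],
                         seq_len(config$go_terms_per_cluster)),
                 sprintf("GO:O%04d_%d", operon[f],
                         seq_len(config$go_terms_per_operon)))
    } else if (phage[f]) {
      terms <- "GO:0016032"
    } else {
      terms <- sprintf("GO:S%04d", f)
    }
    go[[f]] <- terms
  }
  plain <- which(cluster == 0L & !phage)
  uncertain <- resample(plain, round(config$uncertain_fraction * length(plain)))
  go[uncertain] <- list(character(0))

  product <- ifelse(phage, paste("putative phage protein", fam_id),
                    paste("hypothetical protein", fam_id))
  ## keyword evidence must not leak into non-phage families, and uncertain
  ## families must carry neither GO nor keyword evidence (holds: products of
  ## non-phage families never contain "phage")
  length_bp <- pmax(150, round(rlnorm(n, log(900), 0.22)))
  strand <- sample(c("+", "-"), n, replace = TRUE)

  families <- data.frame(family_id = fam_id, length = length_bp,
                         strand = strand, product = product,
                         cluster = cluster, operon = operon,
                         phage = phage, stringsAsFactors = FALSE)

  ## layout: clusters as contiguous units, singletons as their own units,
  ## unit order shuffled, inter-unit gaps absorb the remaining length
  units <- c(lapply(seq_len(max(cluster, 0)), function(cl) which(cluster == cl)),
             as.list(singletons))
  units <- units[lengths(units) > 0]
  units <- units[sample(length(units))]
  ord <- unlist(units)
  gap_after <- numeric(n)
  pos <- 0L
  for (u in units) {
    k <- length(u)
    if (k > 1) gap_after[pos + seq_len(k - 1L)] <- sample_gap(k - 1L, config)
    pos <- pos + k
  }
  used <- sum(length_bp) + sum(gap_after)
  spare <- config$genome_length - used
  n_units <- length(units)
  if (spare < 100 * n_units)
    stopf("genome_length %g too small for gene content (%g bp used)",
          config$genome_length, used)
  ## inter-unit gaps: every gap flanking a cluster gets a guaranteed
  ## minimum of 0.3 * segment_cap so that clusters are spatially isolated
  ## transfer units (a segment cannot bridge from one unit into the next
  ## within the cap); the remaining spare length is spread at random
  unit_last <- cumsum(lengths(units))
  is_cluster_unit <- lengths(units) > 1
  flanks_cluster <- is_cluster_unit |
    c(is_cluster_unit[-1], is_cluster_unit[1])  # right or left flank
  min_gap <- ifelse(flanks_cluster, 0.3 * config$segment_cap, 0)
  if (sum(min_gap) > 0.8 * spare)
    min_gap <- min_gap * (0.8 * spare / sum(min_gap))
  w <- rexp(n_units)
  gap_after[unit_last] <- round(min_gap +
                                  (spare - sum(min_gap)) * w / sum(w))

  ring <- data.frame(family = ord, length = length_bp[ord],
                     gap_after = gap_after, stringsAsFactors = FALSE)

  ## ground-truth intra-cluster pairwise distances on the root layout
  co <- ring_coords(ring)
  L <- ring_genome_length(ring)
  dists <- numeric(0)
  if (config$n_clusters > 0) {
    for (cl in seq_len(config$n_clusters)) {
      rows <- which(cluster[ring$family] == cl)
      if (length(rows) < 2) next
      prs <- combn(rows, 2)
      d <- circular_distance(co[prs[1, ], "start"], co[prs[1, ], "end"],
                             co[prs[2, ], "start"], co[prs[2, ], "end"], L)
      dists <- c(dists, d)
    }
  }

  truth <- list(cluster = setNames(cluster, fam_id),
                operon = setNames(operon, fam_id),
                phage = setNames(phage, fam_id),
                go = setNames(go, fam_id),
                uncertain = fam_id[uncertain],
                intra_cluster_distances = dists)
  structure(list(ring = ring, families = families,
                 genes = ring_annotation(ring, "root", families),
                 truth = truth),
            class = "sim_root")
}

## extract a contiguous run of absent families from the donor (root) layout,
## starting at `seed_fam` and extending rightwards while the running span
## stays within `cap` (and close to `target`); returns family indices
## grow a contiguous donor interval outwards from `seed_fam`, always
## crossing the smaller flanking gap next (recombination breakpoints fall
## preferentially in long intergenic stretches, so gap-delimited units are
## transferred intact). Families already present in the recipient are
## passed over (no duplicate insertion, no gain) but their donor span still
## counts towards the cap and merges into the neighbouring gap, so the
## inserted block keeps the donor's geometry.
segment_from_pool <- function(seed_fam, absent, root_pos, root_ord,
                              root_gap, fam_len, cap, target) {
  n <- length(root_ord)
  segment <- seed_fam
  gaps <- numeric(0)            # gaps between consecutive segment members
  span <- fam_len[seed_fam]
  ## cumulative cost (gaps + passed-over gene lengths) to reach the next
  ## absent family on each side, scanned lazily
  scan_next <- function(p, dir, taken) {
    cost <- 0
    steps <- 0L
    while (steps < n - 1L) {
      steps <- steps + 1L
      gp <- if (dir > 0) root_gap[p] else root_gap[if (p == 1L) n else p - 1L]
      p <- if (dir > 0) (if (p == n) 1L else p + 1L) else
        (if (p == 1L) n else p - 1L)
      nxt <- root_ord[p]
      if (nxt %in% taken) return(NULL)
      if (absent[nxt])
        return(list(fam = nxt, pos = p, add = cost + gp + fam_len[nxt],
                    gap = cost + gp))
      cost <- cost + gp + fam_len[nxt]
    }
    NULL
  }
  pR <- root_pos[seed_fam]
  pL <- root_pos[seed_fam]
  nr <- scan_next(pR, 1L, segment)
  nl <- scan_next(pL, -1L, segment)
  while (span < target) {
    pickR <- !is.null(nr) && span + nr$add <= cap &&
      (is.null(nl) || span + nl$add > cap || nr$gap <= nl$gap)
    pickL <- !pickR && !is.null(nl) && span + nl$add <= cap
    if (pickR) {
      segment <- c(segment, nr$fam)
      gaps <- c(gaps, nr$gap)
      span <- span + nr$add
      pR <- nr$pos
      nr <- scan_next(pR, 1L, segment)
    } else if (pickL) {
      segment <- c(nl$fam, segment)
      gaps <- c(nl$gap, gaps)
      span <- span + nl$add
      pL <- nl$pos
      nl <- scan_next(pL, -1L, segment)
    } else {
      break
    }
  }
  list(fams = segment, gaps = gaps, span = span)
}

#' Evolve genomes along the tree
#'
#' Walks the tree from the root, applying per-family losses at `loss_rate`
#' and segmental acquisitions at `gain_rate` per unit branch length.
#' Acquisition events insert a contiguous run of currently absent families
#' sampled from the donor (pan-genome) layout, so cluster adjacency is
#' respected; non-phage segments span at most `segment_cap` bp, while
#' phage-mediated events span up to `phage_segment_cap` bp with
#' phage-flagged genes interleaved between the cargo genes (emulating
#' imprecise prophage excision). Every event is recorded in a ground-truth
#' log.
#'
#' @param tree a rooted binary `phylo` from [simulate_tree()].
#' @param root a `sim_root` from [simulate_root_genome()].
#' @param config the [sim_config()].
#' @return a list of class `sim_evolved`: `presence` (families x leaves 0/1
#'   matrix), `genes` (pooled leaf annotation table), `event_log`
#'   (data.frame with branch, families, phage flag, segment length),
#'   `cotransfer_pairs` / `nonphage_cotransfer_pairs` (pair-key character
#'   sets), and `n_skipped_events`.
#' @export
evolve_genomes <- function(tree, root, config) {
  stopifnot(inherits(root, "sim_root"), inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  fam <- root$families
  n <- nrow(fam)
  n_tip <- length(tree$tip.label)
  nname <- node_names(tree)
  root_ord <- root$ring$family
  root_pos <- integer(n)
  root_pos[root_ord] <- seq_along(root_ord)
  root_gap <- root$ring$gap_after    # gap after ring position p
  fam_len <- fam$length

  rings <- vector("list", 2L * n_tip - 1L)
  rings[[n_tip + 1L]] <- root$ring
  ev_branch <- character(0); ev_fams <- list()
  ev_phage <- logical(0); ev_len <- numeric(0)
  skipped <- 0L

  edges <- tree$edge
  for (e in seq_len(nrow(edges))) {
    v <- edges[e, 1]; ch <- edges[e, 2]; bl <- tree$edge.length[e]
    ring <- rings[[v]]

    ## losses: block deletions removing contiguous runs of genes; the event
    ## rate is chosen so the per-gene loss rate stays at loss_rate
    if (config$loss_rate > 0 && nrow(ring) > 0) {
      n_del <- rpois(1, config$loss_rate * bl * nrow(ring) /
                       config$loss_block_mean)
      lose <- logical(nrow(ring))
      for (d in seq_len(n_del)) {
        run <- 1L + stats::rgeom(1L, 1 / config$loss_block_mean)
        from <- sample.int(nrow(ring), 1)
        lose[pmod(from - 1L + seq_len(run) - 1L, nrow(ring)) + 1L] <- TRUE
      }
      ## cluster losses are all-or-none: a deletion clipping part of a
      ## co-functioning cluster removes the unit's function, so surviving
      ## deletions cover whole clusters
      hit <- unique(fam$cluster[ring$family[lose]])
      hit <- hit[hit > 0]
      if (length(hit) > 0) lose[fam$cluster[ring$family] %in% hit] <- TRUE
      if (all(lose)) lose[sample(nrow(ring), 1)] <- FALSE
      if (any(lose)) {
        keep <- which(!lose)
        lab <- cumsum(!lose)          # preceding kept row (0 -> wrap to last)
        drop <- which(lose)
        tgt <- lab[drop]
        tgt[tgt == 0L] <- length(keep)
        extra <- tapply(ring$length[drop] + ring$gap_after[drop], tgt, sum)
        ring2 <- ring[keep, , drop = FALSE]
        ring2$gap_after[as.integer(names(extra))] <-
          ring2$gap_after[as.integer(names(extra))] + as.numeric(extra)
        ring <- ring2
      }
    }

    ## segmental acquisitions
    n_ev <- if (config$gain_rate > 0) rpois(1, config$gain_rate * bl) else 0L
    if (n_ev > 0) {
      for (k in seq_len(n_ev)) {
        absent <- rep(TRUE, n)
        absent[ring$family] <- FALSE
        is_phage_ev <- runif(1) < config$phage_event_fraction
        pool <- which(absent & !fam$phage)
        if (length(pool) == 0) { skipped <- skipped + 1L; next }
        target <- config$segment_cap   # take the donor run that fits the cap
        w <- ifelse(fam$cluster[pool] > 0, config$cluster_transfer_weight, 1)
        seed_fam <- pool[sample.int(length(pool), 1, prob = w)]
        cargo <- segment_from_pool(seed_fam, absent, root_pos, root_ord,
                                   root_gap, fam_len, config$segment_cap,
                                   target)
        if (is_phage_ev) {
          ## phage-mediated: cargo flanks an excised prophage block, so
          ## phage genes sit between the two cargo halves
          ppool <- which(absent & fam$phage)
          if (length(ppool) == 0) { skipped <- skipped + 1L; next }
          total_target <- runif(1, 0.55, 1) * config$phage_segment_cap
          span <- cargo$span
          pg <- integer(0); pgaps <- numeric(0)
          while (length(ppool) > 0) {
            cand <- ppool[sample.int(length(ppool), 1)]
            g <- sample_gap(1L, config)
            if (length(pg) > 0 &&
                span + g + fam_len[cand] > config$phage_segment_cap) break
            pg <- c(pg, cand); pgaps <- c(pgaps, g)
            span <- span + g + fam_len[cand]
            ppool <- setdiff(ppool, cand)
            if (span >= total_target) break
          }
          nc <- length(cargo$fams)
          s <- if (nc >= 2) sample.int(nc - 1L, 1) else nc
          seg <- c(cargo$fams[seq_len(s)], pg,
                   if (s < nc) cargo$fams[(s + 1L):nc])
          gaps_int <- c(cargo$gaps[seq_len(s - 1L)], pgaps,
                        if (s <= length(cargo$gaps))
                          cargo$gaps[s:length(cargo$gaps)])
        } else {
          seg <- cargo$fams
          gaps_int <- cargo$gaps
          span <- cargo$span
        }
        m <- length(seg)
        if (is_phage_ev && !any(fam$phage[seg])) { skipped <- skipped + 1L; next }
        ## insert the block into a random intergenic gap
        j <- sample.int(nrow(ring), 1)
        host_gap <- ring$gap_after[j]
        u <- round(runif(1) * host_gap)
        block <- data.frame(family = seg, length = fam_len[seg],
                            gap_after = c(gaps_int, host_gap - u),
                            stringsAsFactors = FALSE)
        ring$gap_after[j] <- u
        ring <- rbind(ring[seq_len(j), , drop = FALSE], block,
                      if (j < nrow(ring))
                        ring[(j + 1L):nrow(ring), , drop = FALSE])
        ev_branch <- c(ev_branch, nname[ch])
        ev_fams <- c(ev_fams, list(fam$family_id[seg]))
        ev_phage <- c(ev_phage, is_phage_ev)
        ev_len <- c(ev_len, span)
      }
    }
    rings[[ch]] <- ring
  }
  if (skipped > 0)
    warnf("%d acquisition event(s) skipped for lack of donor families", skipped)

  presence <- matrix(0L, n, n_tip,
                     dimnames = list(fam$family_id, tree$tip.label))
  genes <- vector("list", n_tip)
  for (i in seq_len(n_tip)) {
    presence[rings[[i]]$family, i] <- 1L
    genes[[i]] <- ring_annotation(rings[[i]], tree$tip.label[i], fam)
  }
  genes <- do.call(rbind, genes)
  rownames(genes) <- NULL

  pair_set <- function(fams_list) {
    keys <- unlist(lapply(fams_list, function(f) {
      if (length(f) < 2) return(character(0))
      prs <- combn(f, 2)
      pair_key(prs[1, ], prs[2, ])
    }))
    unique(keys)
  }
  event_log <- data.frame(branch = ev_branch, phage = ev_phage,
                          length = ev_len, stringsAsFactors = FALSE)
  event_log$families <- ev_fams

  nonphage <- setdiff(pair_set(ev_fams[!ev_phage]),
                      pair_set(ev_fams[ev_phage]))
  structure(list(presence = presence, genes = genes, event_log = event_log,
                 cotransfer_pairs = pair_set(ev_fams),
                 ## pairs co-transferred exclusively by ordinary (non-phage)
                 ## events: their distances are bounded by segment_cap
                 nonphage_cotransfer_pairs = nonphage,
                 n_skipped_events = skipped),
            class = "sim_evolved")
}

#' Simulate a cross-species co-occurrence panel
#'
#' Generates the binary presence/absence profile of every family across an
#' independent panel of species. A cluster is present in a species with
#' probability `panel_cluster_prob`; operon blocks deviate from their
#' cluster with probability `panel_block_flip`, genes flip independently
#' with probability `panel_gene_flip`, and unclustered families are
#' independent coin flips. Same-cluster families therefore co-occur, with
#' tighter co-occurrence within operon blocks.
#'
#' @param truth the `truth` element of a [simulate_root_genome()] result.
#' @param config the [sim_config()].
#' @return integer matrix (families x species) with dimnames.
#' @export
simulate_panel_profiles <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  cl <- truth$cluster
  op <- truth$operon
  n <- length(cl)
  n_sp <- config$n_panel_species
  ops <- sort(unique(op[op > 0]))
  op_cluster <- vapply(ops, function(o) cl[match(o, op)], numeric(1))
  prof <- matrix(0L, n, n_sp,
                 dimnames = list(names(cl), sprintf("S%03d", seq_len(n_sp))))
  n_cl <- max(cl, 0)
  for (s in seq_len(n_sp)) {
    base <- rbinom(n, 1L, 0.5)
    if (n_cl > 0) {
      cl_pres <- rbinom(n_cl, 1L, config$panel_cluster_prob)
      blk <- rbinom(length(ops), 1L, config$panel_block_flip)
      op_state <- as.integer(xor(cl_pres[op_cluster], blk))
      in_cl <- op > 0
      base[in_cl] <- op_state[match(op[in_cl], ops)]
    }
    flip <- rbinom(n, 1L, config$panel_gene_flip)
    prof[, s] <- as.integer(xor(base, flip))
  }
  prof
}

#' Simulate a complete ground-truthed dataset
#'
#' Runs [simulate_tree()], [simulate_root_genome()], [evolve_genomes()] and
#' [simulate_panel_profiles()] under one configuration and assembles the
#' tables the analysis modules read: presence/absence matrix, pooled leaf
#' gene annotations, GO table, per-genome operon table, panel profiles, and
#' the full ground truth (event log, co-transfer pair sets, cluster
#' membership, intra-cluster distances). Deterministic: the same config
#' (including seed) reproduces the dataset exactly.
#'
#' @param config a [sim_config()].
#' @return an object of class `hgt_sim`.
#' @export
simulate_hgt_dataset <- function(config) {
  tree <- simulate_tree(config)
  root <- simulate_root_genome(config)
  evo <- evolve_genomes(tree, root, config)
  panel <- simulate_panel_profiles(root$truth, config)

  go_list <- root$truth$go
  go <- data.frame(
    family_id = rep(names(go_list), lengths(go_list)),
    go_term = unlist(go_list, use.names = FALSE),
    stringsAsFactors = FALSE)

  ## per-genome operon table: an operon instance exists only where >= 2 of
  ## its member families sit at consecutive genomic positions (operons are
  ## co-transcribed units, so scattered re-acquired copies do not qualify)
  op <- root$truth$operon
  operons <- do.call(rbind, lapply(split(evo$genes, evo$genes$genome_id),
    function(g) {
      g <- g[order(g$start), , drop = FALSE]
      g$op <- op[g$family_id]
      g$op[is.na(g$op)] <- 0L
      run <- c(TRUE, g$op[-1] != g$op[-nrow(g)])   # runs of equal operon id
      g$inst <- cumsum(run)
      g <- g[g$op > 0, , drop = FALSE]
      cnt <- table(g$inst)
      g <- g[g$inst %in% names(cnt)[cnt >= 2], , drop = FALSE]
      if (nrow(g) == 0) return(NULL)
      ## keep one (the first) intact instance per operon and genome
      first <- tapply(g$inst, g$op, min)
      g <- g[g$inst == first[as.character(g$op)], , drop = FALSE]
      data.frame(genome_id = g$genome_id,
                 operon_id = sprintf("OP%04d", g$op),
                 family_id = g$family_id, stringsAsFactors = FALSE)
    }))
  rownames(operons) <- NULL

  truth <- c(root$truth,
             list(event_log = evo$event_log,
                  cotransfer_pairs = evo$cotransfer_pairs,
                  nonphage_cotransfer_pairs = evo$nonphage_cotransfer_pairs))

  structure(list(config = config, tree = tree, root = root,
                 presence = evo$presence, genes = evo$genes,
                 go = go, operons = operons, panel = panel,
                 truth = truth),
            class = "hgt_sim")
}
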