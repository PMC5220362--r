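## Plain-text dialects read and written by the pipeline: Newick tree,
## presence/absence TSV (families x genomes), gene table TSV, GO TSV,
## operon TSV, panel profile TSV, ground-truth JSON, and a GFF3 mirror of
## the gene table.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a binary matrix TSV (families x columns)
#'
#' Used for both the presence/absence matrix over genomes and the
#' cross-species profile panel: first column = family id, remaining
#' columns 0/1.
#'
#' @param path TSV file path.
#' @return integer matrix with family rownames.
#' @export
read_presence_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  if (!all(M %in% c(0L, 1L))) stopf("%s: matrix entries must be 0/1", path)
  storage.mode(M) <- "integer"
  M
}

#' @rdname read_presence_matrix
#' @export
read_profile_matrix <- read_presence_matrix

#' Read and validate a gene table TSV
#'
#' Expects columns `family_id`, `genome_id`, `start`, `end`, `strand`,
#' `product`, `genome_length`. Coordinates are 0-based half-open on a
#' circular chromosome; a feature wrapping the origin has
#' `end > genome_length` but `end - start < genome_length`. Rows violating
#' the coordinate invariants, and duplicated `(family, genome, start)`
#' rows, are rejected with their line numbers.
#'
#' @param path TSV file path.
#' @return validated data.frame.
#' @export
read_gene_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("family_id", "genome_id", "start", "end", "strand",
            "product", "genome_length")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stopf("%s: missing columns: %s", path, paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$start < 0 | df$start >= df$genome_length |
                 df$end <= df$start |
                 df$end - df$start >= df$genome_length)
  if (length(bad) > 0)
    stopf("%s: malformed coordinates at line(s) %s", path,
          paste(head(bad + 1L, 5), collapse = ", "))
  dup <- duplicated(df[, c("family_id", "genome_id", "start")])
  if (any(dup))
    stopf("%s: duplicate (family, genome, start) at line(s) %s", path,
          paste(head(which(dup) + 1L, 5), collapse = ", "))
  df
}

#' Read a GO annotation TSV (`family_id`, `go_term`)
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_go_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("family_id", "go_term") %in% names(df)))
    stopf("%s: need columns family_id, go_term", path)
  df
}

#' Read an operon membership TSV (`genome_id`, `operon_id`, `family_id`)
#'
#' An empty file (header only) yields an empty operon set. A gene may
#' belong to at most one operon per genome.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_operon_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("genome_id", "operon_id", "family_id") %in% names(df)))
    stopf("%s: need columns genome_id, operon_id, family_id", path)
  dup <- duplicated(df[, c("genome_id", "family_id")])
  if (any(dup))
    stopf("%s: gene assigned to more than one operon at line(s) %s", path,
          paste(head(which(dup) + 1L, 5), collapse = ", "))
  df
}

#' Write a gene table as GFF3
#'
#' Emits one `gene` feature per row with `ID`, `family`, `product` and
#' `genome_length` attributes. GFF3 is 1-based inclusive, so `start + 1`
#' and `end` are written.
#'
#' @param genes gene table data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genes, path) {
  esc <- function(x) gsub("([,=;])", " ", x)
  attr_col <- sprintf("ID=%s.%s;family=%s;product=%s;genome_length=%s",
                      genes$genome_id, seq_len(nrow(genes)),
                      genes$family_id, esc(genes$product),
                      format(genes$genome_length, scientific = FALSE,
                             trim = TRUE))
  lines <- c("##gff-version 3",
             paste(genes$genome_id, "socgain", "gene",
                   format(genes$start + 1, scientific = FALSE, trim = TRUE),
                   format(genes$end, scientific = FALSE, trim = TRUE),
                   ".", genes$strand, ".", attr_col, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 gene table (via rtracklayer)
#'
#' Inverse of [write_genes_gff3()]; requires the `rtracklayer` package.
#'
#' @param path GFF3 file path.
#' @return gene table data.frame in the TSV dialect.
#' @export
read_genes_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stopf("reading GFF3 requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    family_id = as.character(gr$family),
    genome_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    product = as.character(gr$product),
    genome_length = as.numeric(gr$genome_length),
    stringsAsFactors = FALSE)
  df[order(df$genome_id, df$start), , drop = FALSE]
}

## md5 of the serialised configuration, for provenance headers
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(config),
                   vapply(config, function(x) paste(format(x), collapse = ","),
                          character(1)), sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

#' Write pipeline result tables
#'
#' Emits the significant-pair table, the null score table, the distance
#' CDF tables and a summary JSON. Every table carries a provenance header
#' line with the configuration hash and seed, so outputs can be matched to
#' the run that produced them.
#'
#' @param pl an [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_results <- function(pl, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# socgain config_hash=%s seed=%d",
                 config_hash(pl$config), pl$config$seed)
  write_hdr_tsv <- function(df, path) {
    con <- file(path, "w")
    writeLines(hdr, con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  pairs <- pl$pairs
  for (nm in names(pl$fdr)) {
    pairs[[paste0("significant_", sub("alpha_", "", nm))]] <-
      pair_key(pairs$family_a, pairs$family_b) %in% pl$fdr[[nm]]$pairs$pair
  }
  write_hdr_tsv(pairs[order(pairs$t), ], file.path(dir, "cogain_pairs.tsv"))
  null_df <- do.call(rbind, lapply(seq_along(pl$null$scores), function(r)
    data.frame(replicate = r, t = pl$null$scores[[r]])))
  write_hdr_tsv(null_df, file.path(dir, "null_scores.tsv"))
  for (nm in names(pl$distributions)) {
    d <- pl$distributions[[nm]]
    if (d$n == 0) next
    write_hdr_tsv(data.frame(distance = d$distances,
                             cdf = seq_along(d$distances) / d$n),
                  file.path(dir, sprintf("cdf_%s.tsv", nm)))
  }
  for (nm in names(pl$soc)) {
    if (is.null(pl$soc[[nm]])) next
    write_hdr_tsv(pl$soc[[nm]]$bins, file.path(dir, sprintf("soc_%s.tsv", nm)))
  }
  summary <- pl$summary
  summary$config_hash <- unname(config_hash(pl$config))
  summary$seed <- pl$config$seed
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Write a simulated dataset to a directory
#'
#' Emits all files the analysis modules read: `tree.nwk`, `presence.tsv`,
#' `genes.tsv` (+ `genes.gff3`), `go.tsv`, `operons.tsv`, `panel.tsv`, and
#' `truth.json`.
#'
#' @param ds an [simulate_hgt_dataset()] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_hgt_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(ds$tree, file.path(dir, "tree.nwk"))
  pres <- data.frame(family_id = rownames(ds$presence), ds$presence,
                     check.names = FALSE)
  write_tsv(pres, file.path(dir, "presence.tsv"))
  write_tsv(ds$genes, file.path(dir, "genes.tsv"))
  write_genes_gff3(ds$genes, file.path(dir, "genes.gff3"))
  write_tsv(ds$go, file.path(dir, "go.tsv"))
  write_tsv(ds$operons, file.path(dir, "operons.tsv"))
  panel <- data.frame(family_id = rownames(ds$panel), ds$panel,
                      check.names = FALSE)
  write_tsv(panel, file.path(dir, "panel.tsv"))
  truth <- ds$truth
  truth$go <- NULL
  truth$event_log <- list(branch = truth$event_log$branch,
                          phage = truth$event_log$phage,
                          length = truth$event_log$length,
                          families = truth$event_log$families)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
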