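## Family-level phage classification and annotation helpers.

#' Default phage-associated GO term list
#'
#' Reads the small synthetic default list of phage/mobile-element GO terms
#' shipped with the package (`extdata/phage_go_terms.tsv`). It stands in
#' for a curated phage GO vocabulary and should be replaced with a curated
#' list for real data.
#'
#' @return character vector of GO ids.
#' @export
default_phage_go_terms <- function() {
  path <- system.file("extdata", "phage_go_terms.tsv", package = "socgain")
  read.delim(path, stringsAsFactors = FALSE)$go_term
}

#' Classify families by phage association
#'
#' A family is `associated` if any of its alleles carries a phage-related
#' GO term or the keyword (default `"phage"`, case-insensitive substring)
#' in its product/description text; `not_associated` if it has GO terms
#' assigned but no phage evidence; and `uncertain` if it has neither GO
#' terms nor keyword evidence. The classification is at the family level
#' (evidence from any allele in any genome counts), total and exclusive,
#' and monotone: adding evidence can only move a family towards
#' `associated`.
#'
#' @param genes gene annotation data.frame with `family_id` and `product`.
#' @param go data.frame with `family_id`, `go_term` (may be empty).
#' @param phage_go_terms character vector of phage-related GO ids; defaults
#'   to [default_phage_go_terms()].
#' @param keyword text whose presence in the product marks phage
#'   association.
#' @return named character vector family -> status, one of
#'   `"associated"`, `"not_associated"`, `"uncertain"`.
#' @export
classify_phage <- function(genes, go,
                           phage_go_terms = default_phage_go_terms(),
                           keyword = "phage") {
  fams <- sort(unique(c(genes$family_id, go$family_id)))
  kw <- tapply(grepl(keyword, genes$product, ignore.case = TRUE, fixed = FALSE),
               genes$family_id, any)
  has_kw <- setNames(rep(FALSE, length(fams)), fams)
  has_kw[names(kw)] <- kw
  go_hit <- tapply(go$go_term %in% phage_go_terms, go$family_id, any)
  has_pgo <- setNames(rep(FALSE, length(fams)), fams)
  has_pgo[names(go_hit)] <- go_hit
  has_go <- setNames(rep(FALSE, length(fams)), fams)
  has_go[unique(go$family_id)] <- TRUE
  status <- ifelse(has_kw | has_pgo, "associated",
                   ifelse(has_go, "not_associated", "uncertain"))
  setNames(status, fams)
}

#' Shared-GO-term counts for family pairs
#'
#' Number of GO terms two families have in common, computed for all
#' unordered pairs of the given families via the GO incidence matrix.
#'
#' @param go data.frame with `family_id`, `go_term`.
#' @param families families to include (default: all annotated ones).
#' @return symmetric integer matrix of shared-term counts (diagonal = own
#'   term count).
#' @export
shared_go_counts <- function(go, families = NULL) {
  if (is.null(families)) families <- sort(unique(go$family_id))
  go <- go[go$family_id %in% families, , drop = FALSE]
  terms <- sort(unique(go$go_term))
  B <- matrix(0L, length(families), length(terms),
              dimnames = list(families, terms))
  B[cbind(match(go$family_id, families), match(go$go_term, terms))] <- 1L
  tcrossprod(B)
}
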