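## Mutual information of phylogenetic profiles: the joint presence pattern
## of two families across a species panel is tabulated into the four
## patterns [0,0], [1,0], [0,1], [1,1]; plug-in probabilities and base-2
## entropies give I(A:B) = H(A) + H(B) - H(A,B), which for binary profiles
## is bounded in [0,1] (base 2 is the only base making that bound tight).

h2 <- function(p) {
  # entropy contribution with the 0*log(0) := 0 convention
  out <- numeric(length(p))
  nz <- p > 0
  out[nz] <- -p[nz] * log2(p[nz])
  out
}

#' Mutual information of two binary profiles
#'
#' @param a,b binary vectors over the same species panel (length >= 2).
#' @return list: pattern probabilities `p` (p00, p10, p01, p11), marginal
#'   presence `qA`, `qB`, entropies `H_A`, `H_B`, `H_AB`, and `mi`.
#' @export
profile_mi <- function(a, b) {
  if (length(a) != length(b)) stopf("profiles must have equal length")
  if (length(a) < 2) stopf("profiles must have length >= 2")
  n <- length(a)
  n11 <- sum(a == 1 & b == 1)
  n10 <- sum(a == 1 & b == 0)
  n01 <- sum(a == 0 & b == 1)
  n00 <- n - n11 - n10 - n01
  p <- c(p00 = n00, p10 = n10, p01 = n01, p11 = n11) / n
  qA <- p[["p10"]] + p[["p11"]]
  qB <- p[["p01"]] + p[["p11"]]
  H_A <- sum(h2(c(qA, 1 - qA)))
  H_B <- sum(h2(c(qB, 1 - qB)))
  H_AB <- sum(h2(p))
  list(p = p, qA = qA, qB = qB, H_A = H_A, H_B = H_B, H_AB = H_AB,
       mi = max(H_A + H_B - H_AB, 0))
}

#' Pairwise mutual-information matrix of a profile panel
#'
#' Vectorised MI for all family pairs of a binary profile matrix; the
#' diagonal holds the marginal entropies.
#'
#' @param profiles binary matrix, families x species.
#' @return symmetric numeric matrix of MI values in `[0,1]`.
#' @export
mi_matrix <- function(profiles) {
  if (ncol(profiles) < 2) stopf("need >= 2 species")
  P <- profiles
  storage.mode(P) <- "double"
  n <- ncol(P)
  N11 <- tcrossprod(P)
  rs <- rowSums(P)
  N10 <- outer(rs, rs, function(x, y) x) - N11
  N01 <- t(N10)
  N00 <- n - N11 - N10 - N01
  H_AB <- (h2(N11 / n) + h2(N10 / n) + h2(N01 / n) + h2(N00 / n))
  dim(H_AB) <- dim(N11)
  q <- rs / n
  H <- h2(q) + h2(1 - q)
  I <- outer(H, H, "+") - H_AB
  I[I < 0] <- 0
  diag(I) <- H
  dimnames(I) <- list(rownames(profiles), rownames(profiles))
  I
}

#' Rank correlation between shared-GO counts and co-occurrence MI
#'
#' Spearman correlation (mid-rank ties) between the number of shared GO
#' terms and the profile MI over family pairs, restricted to pairs sharing
#' at least one term.
#'
#' @param n_go integer vector of shared-GO counts per pair.
#' @param mi MI values for the same pairs.
#' @return list `rho`, `p_value`, `n` (pairs used), or `NA`s if < 3 pairs
#'   remain.
#' @export
go_mi_correlation <- function(n_go, mi) {
  if (length(n_go) != length(mi)) stopf("n_go and mi must have equal length")
  keep <- n_go > 0
  n_go <- n_go[keep]; mi <- mi[keep]
  if (length(n_go) < 3)
    return(list(rho = NA_real_, p_value = NA_real_, n = length(n_go)))
  ct <- suppressWarnings(cor.test(n_go, mi, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(n_go))
}
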