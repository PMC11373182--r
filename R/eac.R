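#' Expected allele count (EAC)
#'
#' Linearises each individual's genotype distribution as the posterior
#' mean number of copies of allele A:
#' `EAC = 0*p(aa) + 1*p(aA) + 1*p(Aa) + 2*p(AA)`, in `[0, 2]`. The EAC is
#' additive by construction and is the response variable of the
#' segregation GWAS.
#'
#' @param probs a `genotype_probabilities`.
#' @return named numeric vector (names = individual ids).
#' @export
compute_eac <- function(probs) {
  stopifnot(inherits(probs, "genotype_probabilities"))
  o <- probs$ordered
  stats::setNames(o[, 2L] + o[, 3L] + 2 * o[, 4L], probs$id)
}

#' Genotype probability index (GPI)
#'
#' A 0-100 score of how informative an individual's genotype distribution
#' is, computed as an entropy ratio against the Hardy-Weinberg prior:
#' `GPI = 100 * max(0, 1 - H_i / H_HW)`, where `H_i` is the Shannon
#' entropy of the individual's unordered class distribution and `H_HW`
#' the entropy of `((1-q)^2, 2q(1-q), q^2)`. A point-mass distribution
#' scores 100; a distribution equal to the Hardy-Weinberg prior scores 0
#' (distributions more entropic than the prior are clamped to 0). The
#' population mean GPI tracks the EAC-true-genotype correlation
#' approximately linearly.
#'
#' @param probs a `genotype_probabilities`.
#' @param q model allele frequency defining the Hardy-Weinberg reference.
#' @param subset optional ids over which the mean is taken (default all).
#' @return list with `gpi` (named vector) and `mean_gpi`.
#' @export
compute_gpi <- function(probs, q, subset = NULL) {
  stopifnot(inherits(probs, "genotype_probabilities"), q > 0, q < 1)
  H <- apply(probs$unordered, 1L, shannon_entropy)
  H_hw <- shannon_entropy(c((1 - q)^2, 2 * q * (1 - q), q^2))
  gpi <- stats::setNames(100 * pmax(0, 1 - H / H_hw), probs$id)
  keep <- if (is.null(subset)) gpi else gpi[as.character(subset)]
  list(gpi = gpi, mean_gpi = mean(keep))
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}
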