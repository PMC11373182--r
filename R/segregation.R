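## Ordered genotype coding used throughout: 1=aa, 2=aA, 3=Aa, 4=AA
## (paternal allele written first). Unordered classes 0/1/2 collapse the
## two heterozygote states. "A" is the allele counted by the EAC; its
## meaning is fixed by the orientation of the penetrance matrix.

CLASS_OF_ORDERED <- c(0L, 1L, 1L, 2L)

#' Segregation model: founder allele frequency + penetrance
#'
#' @param q frequency of the counted allele A in the founder population,
#'   strictly inside (0, 1).
#' @param penetrance a [penetrance_matrix()].
#' @export
seg_model <- function(q, penetrance) {
  stopifnot(is.numeric(q), length(q) == 1L, q > 0, q < 1,
            inherits(penetrance, "penetrance_matrix"))
  structure(list(q = q, penetrance = penetrance), class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cat("segregation model: q(A) =", signif(x$q, 6), "\n")
  print(x$penetrance)
  invisible(x)
}

# ordered Hardy-Weinberg founder prior (aa, aA, Aa, AA)
hw_prior <- function(q) c((1 - q)^2, (1 - q) * q, q * (1 - q), q^2)

#' Allele transmission probabilities from a parent
#'
#' Given a parent's distribution over ordered genotypes, the probability
#' that a transmitted gamete carries allele a or A:
#' `P(A) = p(AA) + (p(aA) + p(Aa)) / 2`.
#'
#' @param parent_p numeric length-4 distribution over (aa, aA, Aa, AA).
#' @return named numeric `c(a = , A = )`.
#' @export
mendelian_transmission <- function(parent_p) {
  stopifnot(length(parent_p) == 4L, abs(sum(parent_p) - 1) < 1e-8)
  pA <- parent_p[4L] + 0.5 * (parent_p[2L] + parent_p[3L])
  c(a = unname(1 - pA), A = unname(pA))
}

# transmission tensor T[go, gs, gd] = P(offspring go | sire gs, dam gd)
transmission_tensor <- function() {
  pA <- c(0, 0.5, 0.5, 1)
  Tm <- array(0, c(4, 4, 4))
  for (gs in 1:4) for (gd in 1:4) {
    Tm[1, gs, gd] <- (1 - pA[gs]) * (1 - pA[gd])
    Tm[2, gs, gd] <- (1 - pA[gs]) * pA[gd]
    Tm[3, gs, gd] <- pA[gs] * (1 - pA[gd])
    Tm[4, gs, gd] <- pA[gs] * pA[gd]
  }
  Tm
}

# per-individual likelihood over the 4 ordered genotypes; 1 where the
# phenotype is missing. phenotype_error mixes each likelihood with a
# uniform miscoding term, (1-e)*pen + e/K, which tolerates records that
# contradict structural zeros of the penetrance matrix. Errors if some
# individual's phenotype has zero penetrance under every genotype.
penetrance_factors <- function(ped, phen, penetrance,
                               phenotype_error = 0) {
  y <- align_phenotypes(phen, ped)
  n <- length(ped$id)
  pen <- matrix(1, n, 4)
  obs <- which(!is.na(y))
  if (length(obs)) {
    if (any(y[obs] + 1L > nrow(penetrance)))
      stop("phenotype class exceeds penetrance matrix rows")
    for (g in 1:4)
      pen[obs, g] <- penetrance[y[obs] + 1L, CLASS_OF_ORDERED[g] + 1L]
    if (phenotype_error > 0)
      pen[obs, ] <- (1 - phenotype_error) * pen[obs, , drop = FALSE] +
        phenotype_error / nrow(penetrance)
    dead <- obs[rowSums(pen[obs, , drop = FALSE]) == 0]
    if (length(dead))
      stop("model-data contradiction: phenotype of individual ",
           ped$id[dead[1L]], " has zero penetrance under every genotype")
  }
  pen
}

# nuclear-family structure for peeling (0-based indices for the C++ core)
build_families <- function(ped) {
  n <- length(ped$id)
  nonf <- which(!is.na(ped$sire_idx))
  key <- paste(ped$sire_idx[nonf], ped$dam_idx[nonf])
  fam_id <- match(key, unique(key))
  F <- max(c(fam_id, 0L))
  fs <- fd <- integer(F)
  off <- vector("list", max(F, 1L))
  if (F > 0) {
    for (f in seq_len(F)) {
      members <- nonf[fam_id == f]
      fs[f] <- ped$sire_idx[members[1L]]
      fd[f] <- ped$dam_idx[members[1L]]
      off[[f]] <- members - 1L
    }
  } else off <- list()
  natal <- rep(-1L, n)
  natal[nonf] <- fam_id - 1L
  parfams <- vector("list", n)
  for (i in seq_len(n)) parfams[[i]] <- integer(0)
  for (f in seq_len(F)) {
    parfams[[fs[f]]] <- c(parfams[[fs[f]]], f - 1L)
    parfams[[fd[f]]] <- c(parfams[[fd[f]]], f - 1L)
  }
  # process families in order of their first offspring's topological rank
  topo_rank <- integer(n)
  topo_rank[ped$order] <- seq_len(n)
  ford <- if (F > 0) order(vapply(seq_len(F), function(f)
    min(topo_rank[off[[f]] + 1L]), 1L)) - 1L else integer(0)
  list(fs = fs - 1L, fd = fd - 1L, off = off, parfams = parfams,
       natal = natal, fam_order = as.integer(ford))
}

#' Posterior genotype probabilities by iterative peeling
#'
#' Computes, for every individual, the posterior distribution over the
#' four ordered genotypes at a single biallelic locus given the pedigree,
#' the categorical phenotypes, the penetrance matrix and a founder allele
#' frequency. Founders carry an ordered Hardy-Weinberg prior; phenotype
#' likelihoods enter through the penetrance matrix (missing phenotypes
#' contribute no information); messages between nuclear families are
#' iterated to a fixed point, which makes the result exact on loop-free
#' pedigrees and a standard approximation on looped ones.
#'
#' @param ped a `seg_pedigree`.
#' @param phen a `seg_phenotypes` table (ids matched against the
#'   pedigree; individuals without a record are treated as missing).
#' @param model a [seg_model()].
#' @param tol convergence tolerance on the maximum absolute change of any
#'   individual's probability between sweeps.
#' @param max_sweeps maximum number of forward+backward sweeps; if reached
#'   without convergence the last iterate is returned with a warning.
#' @param phenotype_error probability that a record is miscoded: each
#'   phenotype likelihood is evaluated as
#'   `(1 - e) * pen(y | g) + e / K`. The default 0 applies the penetrance
#'   matrix exactly, in which case records incompatible with its zeros
#'   raise the model-data contradiction error.
#' @return object of class `genotype_probabilities`: list with `id`,
#'   `ordered` (n x 4 matrix over aa/aA/Aa/AA), `unordered` (n x 3 over
#'   classes 0/1/2), `converged`, `sweeps`.
#' @export
peel_genotype_probabilities <- function(ped, phen, model,
                                        tol = 1e-8, max_sweeps = 200L,
                                        phenotype_error = 0) {
  stopifnot(inherits(ped, "seg_pedigree"), inherits(model, "seg_model"),
            tol > 0)
  pen <- penetrance_factors(ped, phen, model$penetrance, phenotype_error)
  fam <- build_families(ped)
  res <- peel_cpp(pen, hw_prior(model$q), fam$fs, fam$fd, fam$off,
                  fam$parfams, fam$natal, fam$fam_order,
                  tol, as.integer(max_sweeps))
  if (res$err_ind > 0)
    stop("model-data contradiction: zero posterior probability ",
         "encountered at individual ", ped$id[res$err_ind])
  if (!res$converged)
    warning("peeling did not converge in ", max_sweeps,
            " sweeps; returning last iterate")
  new_genotype_probabilities(res$p, ped$id,
                             converged = res$converged, sweeps = res$sweeps)
}

new_genotype_probabilities <- function(ordered, id, converged = TRUE,
                                       sweeps = NA_integer_) {
  dimnames(ordered) <- list(id, c("aa", "aA", "Aa", "AA"))
  unord <- cbind(g0 = ordered[, 1L],
                 g1 = ordered[, 2L] + ordered[, 3L],
                 g2 = ordered[, 4L])
  rownames(unord) <- id
  structure(list(id = id, ordered = ordered, unordered = unord,
                 converged = converged, sweeps = sweeps),
            class = "genotype_probabilities")
}

#' @export
print.genotype_probabilities <- function(x, ...) {
  cat("genotype probabilities for", length(x$id), "individuals",
      if (isTRUE(x$converged)) "(converged" else "(NOT converged",
      "after", x$sweeps, "sweeps)\n")
  print(utils::head(round(x$unordered, 4)))
  invisible(x)
}

#' Exact genotype probabilities by full enumeration
#'
#' Test oracle: sums the joint probability of every ordered-genotype
#' configuration (founder Hardy-Weinberg priors x Mendelian transmission x
#' penetrance of observed phenotypes) and marginalises per individual.
#' Cost is 4^n, so pedigrees are limited to 12 individuals.
#'
#' @inheritParams peel_genotype_probabilities
#' @return a `genotype_probabilities` (with attribute `loglik`, the exact
#'   observed-data log-likelihood).
#' @export
brute_force_probabilities <- function(ped, phen, model) {
  stopifnot(inherits(ped, "seg_pedigree"))
  n <- length(ped$id)
  if (n > 12L)
    stop("brute-force enumeration refused for pedigrees larger than 12")
  pen <- penetrance_factors(ped, phen, model$penetrance)
  Tm <- transmission_tensor()
  prior <- hw_prior(model$q)
  N <- 4^n
  cfg <- seq_len(N) - 1
  gidx <- lapply(seq_len(n), function(i) (cfg %/% 4^(i - 1)) %% 4 + 1)
  joint <- rep(1, N)
  for (i in seq_len(n)) {
    gi <- gidx[[i]]
    if (is.na(ped$sire_idx[i])) {
      joint <- joint * prior[gi]
    } else {
      joint <- joint * Tm[cbind(gi, gidx[[ped$sire_idx[i]]],
                                gidx[[ped$dam_idx[i]]])]
    }
    joint <- joint * pen[i, ][gi]
  }
  tot <- sum(joint)
  if (tot <= 0)
    stop("model-data contradiction: zero likelihood for the whole pedigree")
  p <- matrix(0, n, 4)
  for (i in seq_len(n))
    for (g in 1:4) p[i, g] <- sum(joint[gidx[[i]] == g])
  p <- p / tot
  out <- new_genotype_probabilities(p, ped$id)
  attr(out, "loglik") <- log(tot)
  out
}

#' Exact observed-data log-likelihood by enumeration (test oracle)
#' @inheritParams peel_genotype_probabilities
#' @export
brute_force_loglik <- function(ped, phen, model) {
  attr(brute_force_probabilities(ped, phen, model), "loglik")
}
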