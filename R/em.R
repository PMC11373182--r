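#' M-step estimate of the penetrance matrix
#'
#' `entries[k][g] = sum over phenotyped i with y_i = k of p_i(g), divided
#' by the total posterior mass on g across all phenotyped individuals.`
#' Genotype classes with negligible total mass (`< min_weight`) keep their
#' previous column, so the estimate never divides by (near) zero.
#'
#' @param probs a `genotype_probabilities`.
#' @param phen a `seg_phenotypes` table (matched by id).
#' @param prev previous `penetrance_matrix` used for empty columns; if
#'   `NULL`, empty columns fall back to a uniform column.
#' @param min_weight column-mass threshold below which `prev` is kept.
#' @param lock optional logical K x 3 mask of structural zeros: locked
#'   cells are held at exactly 0 and each column is renormalised over its
#'   unlocked cells. Used to preserve the inheritance-model zeros of a
#'   starting matrix when likelihoods are evaluated with a miscoding
#'   tolerance.
#' @return a `penetrance_matrix`.
#' @export
estimate_penetrance <- function(probs, phen, prev = NULL,
                                min_weight = 1e-8, lock = NULL) {
  y <- phen$phenotype[match(probs$id, phen$id)]
  obs <- which(!is.na(y))
  if (!length(obs)) stop("all phenotypes missing; cannot estimate penetrance")
  K <- if (!is.null(prev)) nrow(prev) else length(attr(phen, "labels"))
  labels <- if (!is.null(prev)) rownames(prev) else attr(phen, "labels")
  U <- probs$unordered[obs, , drop = FALSE]
  num <- matrix(0, K, 3)
  for (k in seq_len(K) - 1L) {
    rows <- y[obs] == k
    if (any(rows)) num[k + 1L, ] <- colSums(U[rows, , drop = FALSE])
  }
  if (!is.null(lock)) num[lock] <- 0
  denom <- colSums(num)
  out <- matrix(1 / K, K, 3)
  for (g in 1:3) {
    if (denom[g] >= min_weight) out[, g] <- num[, g] / denom[g]
    else if (!is.null(prev)) out[, g] <- prev[, g]
  }
  penetrance_matrix(out, labels = labels)
}

#' M-step estimate of the founder allele frequency
#'
#' `q = sum of founder EACs / (2 * number of founders)`, clamped away from
#' the boundary so Hardy-Weinberg priors stay proper.
#'
#' @param probs a `genotype_probabilities`.
#' @param ped the `seg_pedigree` the probabilities were computed on.
#' @param q_min clamp: q is kept in `[q_min, 1 - q_min]`.
#' @export
estimate_allele_frequency <- function(probs, ped, q_min = 1e-6) {
  stopifnot(length(ped$founders) > 0)
  eac <- compute_eac(probs)
  q <- sum(eac[ped$founders]) / (2 * length(ped$founders))
  min(max(q, q_min), 1 - q_min)
}

#' Fit the segregation model by expectation-maximisation
#'
#' Alternates the peeling E-step (posterior genotype probabilities under
#' the current penetrance and allele frequency) with M-step updates of the
#' penetrance matrix ([estimate_penetrance()]) and founder allele
#' frequency ([estimate_allele_frequency()]), until the largest absolute
#' change in any penetrance entry and in q falls below `em_tol`.
#'
#' Penetrance entries are never floored: exact zeros in the starting
#' matrix act as structural constraints of the inheritance model (zero
#' posterior mass never re-enters them), which is how complete-penetrance
#' runs recover exact-zero fitted entries. When those zeros contradict
#' the observed data outright (e.g. a start that forces horned animals to
#' be AA, faced with two horned parents and a polled offspring), the fit
#' is restarted once with a small miscoding tolerance: likelihoods are
#' evaluated as `(1-e)*pen + e/K` (`retry_error`) while the starting
#' zeros stay locked in the M-step, so the fitted matrix keeps its
#' structural zeros and the remaining entries are estimated freely.
#'
#' @param ped a `seg_pedigree`.
#' @param phen a `seg_phenotypes` table.
#' @param init starting [seg_model()].
#' @param em_tol EM convergence tolerance (max of |dPenetrance|, |dq|).
#' @param max_em_iter maximum EM iterations; non-convergence is flagged,
#'   not fatal.
#' @param phenotype_error miscoding tolerance used when evaluating
#'   phenotype likelihoods (see [peel_genotype_probabilities()]); 0
#'   applies the penetrance matrix exactly.
#' @param retry_error tolerance used for the single automatic restart
#'   after a model-data contradiction under `phenotype_error = 0`
#'   (0 disables the retry and propagates the error).
#' @param peel_tol,max_sweeps passed to [peel_genotype_probabilities()].
#' @return object of class `fitted_segregation`: `model` (at
#'   convergence), `probs`, `eac`, `gpi`, `mean_gpi`, `n_em_iterations`,
#'   `converged`, and `trace` (per-iteration q, penetrance, max change).
#' @export
fit_segregation_model <- function(ped, phen, init, em_tol = 1e-5,
                                  max_em_iter = 500L, phenotype_error = 0,
                                  retry_error = 1e-3,
                                  peel_tol = 1e-8, max_sweeps = 200L) {
  stopifnot(inherits(init, "seg_model"))
  if (phenotype_error == 0 && retry_error > 0) {
    out <- tryCatch(
      fit_segregation_model(ped, phen, init, em_tol = em_tol,
                            max_em_iter = max_em_iter,
                            phenotype_error = 0, retry_error = 0,
                            peel_tol = peel_tol, max_sweeps = max_sweeps),
      error = function(e) {
        if (!grepl("contradiction", conditionMessage(e))) stop(e)
        message("records contradict the starting penetrance zeros; ",
                "refitting with miscoding tolerance ", retry_error)
        fit_segregation_model(ped, phen, init, em_tol = em_tol,
                              max_em_iter = max_em_iter,
                              phenotype_error = retry_error,
                              retry_error = 0, peel_tol = peel_tol,
                              max_sweeps = max_sweeps)
      })
    return(out)
  }
  pen <- init$penetrance
  # structural zeros of the starting matrix stay zero; only relevant when
  # a miscoding tolerance lets posterior mass leak into locked cells
  lock <- if (phenotype_error > 0) unclass(pen) == 0 else NULL
  q <- init$q
  trace <- list()
  converged <- FALSE
  probs <- NULL
  it <- 0L
  for (it in seq_len(max_em_iter)) {
    model <- seg_model(q, pen)
    probs <- suppressWarnings(
      peel_genotype_probabilities(ped, phen, model,
                                  tol = peel_tol, max_sweeps = max_sweeps,
                                  phenotype_error = phenotype_error))
    pen_new <- estimate_penetrance(probs, phen, prev = pen, lock = lock)
    q_new <- estimate_allele_frequency(probs, ped)
    delta <- max(max(abs(unclass(pen_new) - unclass(pen))), abs(q_new - q))
    pen <- pen_new
    q <- q_new
    trace[[it]] <- list(iter = it, q = q, penetrance = pen, delta = delta)
    if (delta < em_tol) { converged <- TRUE; break }
  }
  model <- seg_model(q, pen)
  # final E-step under the converged parameters
  probs <- suppressWarnings(
    peel_genotype_probabilities(ped, phen, model,
                                tol = peel_tol, max_sweeps = max_sweeps,
                                phenotype_error = phenotype_error))
  if (!converged)
    warning("EM did not converge in ", max_em_iter, " iterations")
  eac <- compute_eac(probs)
  gpi <- compute_gpi(probs, q)
  structure(list(model = model, probs = probs, eac = eac, gpi = gpi$gpi,
                 mean_gpi = gpi$mean_gpi, n_em_iterations = it,
                 converged = converged, trace = trace),
            class = "fitted_segregation")
}

#' @export
print.fitted_segregation <- function(x, ...) {
  cat("fitted segregation model (",
      if (x$converged) "converged" else "NOT converged", " after ",
      x$n_em_iterations, " EM iterations)\n", sep = "")
  cat("q(A) =", signif(x$model$q, 6), "  mean GPI =",
      round(x$mean_gpi, 2), "\n")
  print(x$model$penetrance)
  invisible(x)
}

#' Write per-individual EAC/GPI results and a model summary sidecar
#'
#' TSV columns `id p_aa p_het p_AA eac gpi` (6 decimal places); the
#' converged model, iteration count and convergence flag go to
#' `<path>.json`.
#'
#' @param fit a `fitted_segregation`.
#' @param path output TSV path.
#' @export
write_eacgpi <- function(fit, path) {
  u <- fit$probs$unordered
  df <- data.frame(id = fit$probs$id,
                   p_aa = sprintf("%.6f", u[, 1L]),
                   p_het = sprintf("%.6f", u[, 2L]),
                   p_AA = sprintf("%.6f", u[, 3L]),
                   eac = sprintf("%.6f", fit$eac),
                   gpi = sprintf("%.6f", fit$gpi))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(q = fit$model$q,
         penetrance = unclass(fit$model$penetrance),
         phenotype_labels = rownames(fit$model$penetrance),
         n_em_iterations = fit$n_em_iterations,
         converged = fit$converged,
         mean_gpi = fit$mean_gpi),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
    matrix = "rowmajor")
  invisible(path)
}
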