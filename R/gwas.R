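#' Per-SNP quality control
#'
#' Removes SNPs failing any of: minor allele frequency below `maf_min`;
#' Hardy-Weinberg goodness-of-fit chi-square (1 df, expected counts from
#' the sample allele frequency) above `hwe_chi2_max`; call rate below
#' `call_rate_min`; non-autosomal chromosome code (anything that is not a
#' positive integer string) when `autosomes_only`.
#'
#' @param gm a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_chi2_max maximum HWE chi-square (default 600).
#' @param call_rate_min minimum per-SNP call rate (default 0.90).
#' @param autosomes_only drop non-autosomal SNPs?
#' @return list with `gm` (filtered matrix) and `report` (per-rule
#'   removal counts plus per-SNP pass/fail table).
#' @export
qc_filter <- function(gm, maf_min = 0.01, hwe_chi2_max = 600,
                      call_rate_min = 0.90, autosomes_only = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  X <- gm$counts
  n <- nrow(X)
  obs <- !is.na(X)
  n_called <- colSums(obs)
  call_rate <- n_called / n
  n2 <- colSums(X == 2, na.rm = TRUE)
  n1 <- colSums(X == 1, na.rm = TRUE)
  n0 <- n_called - n1 - n2
  p <- ifelse(n_called > 0, (n1 + 2 * n2) / (2 * n_called), NA_real_)
  maf <- pmin(p, 1 - p)
  e0 <- n_called * (1 - p)^2
  e1 <- n_called * 2 * p * (1 - p)
  e2 <- n_called * p^2
  chi2 <- ifelse(p > 0 & p < 1,
                 (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2,
                 0)
  autosome <- grepl("^[0-9]+$", gm$map$chrom) &
    suppressWarnings(as.numeric(gm$map$chrom)) > 0
  fail_maf <- is.na(maf) | maf < maf_min
  fail_hwe <- !is.na(chi2) & chi2 > hwe_chi2_max
  fail_cr <- call_rate < call_rate_min
  fail_auto <- autosomes_only & !autosome
  keep <- !(fail_maf | fail_hwe | fail_cr | fail_auto)
  report <- list(
    n_input = ncol(X), n_kept = sum(keep),
    removed = c(maf = sum(fail_maf), hwe = sum(fail_hwe),
                call_rate = sum(fail_cr), non_autosome = sum(fail_auto)),
    per_snp = data.frame(snp = gm$map$snp, maf = maf, hwe_chi2 = chi2,
                         call_rate = call_rate, kept = keep))
  if (!any(keep)) warning("no SNPs pass QC; returning an empty matrix")
  list(gm = gm[, which(keep)], report = report)
}

new_association_table <- function(df) {
  structure(df, class = c("association_table", "data.frame"))
}

#' Additive GWAS on the expected allele count
#'
#' Ordinary least squares of EAC on allele count, one SNP at a time, with
#' pairwise deletion of missing genotypes. The two-sided p-value comes
#' from the slope t-statistic and is computed entirely in log space, so
#' `neglog10p` stays finite and exact far beyond the usual floating-point
#' floor of p = 1e-308. A residual-variance floor at machine precision
#' keeps perfect fits (SNP identical to EAC) at a large finite ceiling.
#'
#' @param eac named numeric vector of expected allele counts.
#' @param gm a [genotype_matrix()]; individuals are matched to `eac` by
#'   name, unmatched individuals are dropped.
#' @param min_n minimum non-missing pairs per SNP.
#' @return `association_table` data frame with columns
#'   `snp chrom pos n beta se stat neglog10p r2 flag`.
#' @export
eac_gwas <- function(eac, gm, min_n = 3L) {
  stopifnot(inherits(gm, "genotype_matrix"), !is.null(names(eac)))
  ids <- intersect(names(eac), rownames(gm$counts))
  if (!length(ids)) stop("no overlapping ids between EAC and genotypes")
  y <- unname(eac[ids])
  X <- gm$counts[ids, , drop = FALSE]
  M <- !is.na(X)
  X0 <- X; X0[!M] <- 0
  n <- colSums(M)
  Sx <- colSums(X0)
  Sxx <- colSums(X0^2)
  Sy <- as.vector(crossprod(M, y))
  Syy <- as.vector(crossprod(M, y^2))
  Sxy <- as.vector(crossprod(X0, y))
  Sxx_c <- Sxx - Sx^2 / n
  Syy_c <- Syy - Sy^2 / n
  Sxy_c <- Sxy - Sx * Sy / n
  ok <- n >= min_n & Sxx_c > 1e-12 & Syy_c > 0
  beta <- ifelse(ok, Sxy_c / Sxx_c, NA_real_)
  sse <- Syy_c - beta^2 * Sxx_c
  sse <- pmax(sse, .Machine$double.eps * Syy_c)  # perfect-fit guard
  df <- n - 2
  se <- ifelse(ok & df > 0, sqrt(sse / df / Sxx_c), NA_real_)
  tstat <- beta / se
  neglog10p <- neglog10_t(tstat, df)
  r2 <- ifelse(ok, Sxy_c^2 / (Sxx_c * Syy_c), NA_real_)
  flag <- ifelse(ok, "", "monomorphic")
  flag[n < min_n] <- "too_few"
  new_association_table(data.frame(
    snp = gm$map$snp, chrom = gm$map$chrom, pos = gm$map$pos,
    n = n, beta = beta, se = se, stat = tstat,
    neglog10p = neglog10p, r2 = r2, flag = flag,
    stringsAsFactors = FALSE))
}

# -log10 two-sided p from a t statistic, in log space
neglog10_t <- function(tstat, df) {
  out <- rep(NA_real_, length(tstat))
  ok <- !is.na(tstat) & df > 0
  out[ok] <- -(log(2) + stats::pt(-abs(tstat[ok]), df[ok],
                                  log.p = TRUE)) / log(10)
  out
}

#' Logistic GWAS on a binary phenotype
#'
#' Per-SNP logistic regression of a 0/1 phenotype (e.g. horned vs
#' non-horned, or polled vs non-polled) on allele count. The p-value is a
#' likelihood-ratio test against the intercept-only model (chosen over
#' Wald, which degenerates under the near-separation a monogenic trait
#' produces). Complete or quasi-complete separation is detected and
#' flagged; the LRT at the iteration cap is still reported.
#'
#' @param y named 0/1 vector.
#' @param gm a [genotype_matrix()].
#' @param min_n minimum non-missing pairs per SNP.
#' @return `association_table` data frame (columns as [eac_gwas()]).
#' @export
binary_gwas <- function(y, gm, min_n = 3L) {
  stopifnot(inherits(gm, "genotype_matrix"), !is.null(names(y)))
  if (!all(y %in% c(0, 1))) stop("y must be a 0/1 vector")
  ids <- intersect(names(y), rownames(gm$counts))
  if (!length(ids)) stop("no overlapping ids between phenotype and genotypes")
  yv <- unname(y[ids])
  if (length(unique(yv)) < 2L) stop("binary phenotype is constant")
  X <- gm$counts[ids, , drop = FALSE]
  m <- ncol(X)
  beta <- se <- stat <- nlp <- rep(NA_real_, m)
  nvec <- integer(m)
  flag <- character(m)
  for (j in seq_len(m)) {
    x <- X[, j]
    use <- !is.na(x)
    nvec[j] <- sum(use)
    xj <- x[use]; yj <- yv[use]
    if (nvec[j] < min_n || length(unique(xj)) < 2L ||
        length(unique(yj)) < 2L) {
      flag[j] <- "monomorphic"
      next
    }
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, xj), yj, family = stats::binomial()))
    dev_diff <- fit$null.deviance - fit$deviance
    beta[j] <- fit$coefficients[2L]
    eta <- fit$linear.predictors
    sep <- !fit$converged || max(abs(eta)) > 25 || abs(beta[j]) > 15
    flag[j] <- if (sep) "separation" else ""
    # Wald SE for reporting only; the test is the LRT
    w <- fit$weights
    XtWX <- crossprod(cbind(1, xj) * sqrt(w))
    v <- tryCatch(solve(XtWX)[2L, 2L], error = function(e) NA_real_)
    se[j] <- sqrt(v)
    stat[j] <- max(dev_diff, 0)
    nlp[j] <- -stats::pchisq(stat[j], df = 1, lower.tail = FALSE,
                             log.p = TRUE) / log(10)
  }
  new_association_table(data.frame(
    snp = gm$map$snp, chrom = gm$map$chrom, pos = gm$map$pos,
    n = nvec, beta = beta, se = se, stat = stat,
    neglog10p = nlp, r2 = NA_real_, flag = flag,
    stringsAsFactors = FALSE))
}

#' Most significant SNP of an association table
#'
#' Maximum `neglog10p`; ties broken by larger `|beta|`, then genome order
#' (chromosome, position).
#'
#' @param tab an `association_table`.
#' @return single-row data frame.
#' @export
top_snp <- function(tab) {
  stopifnot(nrow(tab) > 0)
  usable <- which(!is.na(tab$neglog10p))
  if (!length(usable)) stop("association table has no usable statistics")
  t2 <- tab[usable, , drop = FALSE]
  chrom_num <- suppressWarnings(as.numeric(t2$chrom))
  chrom_ord <- ifelse(is.na(chrom_num), Inf, chrom_num)
  o <- order(-t2$neglog10p, -abs(t2$beta), chrom_ord, t2$pos)
  t2[o[1L], , drop = FALSE]
}

#' Pearson correlation between EAC and a SNP's allele counts
#'
#' @param eac named EAC vector.
#' @param snp named allele-count vector (e.g. one column of a genotype
#'   matrix); pairs with missing values are dropped.
#' @return Pearson r, or `NA` with a warning if either vector is constant
#'   or fewer than 3 pairs remain.
#' @export
eac_snp_correlation <- function(eac, snp) {
  ids <- intersect(names(eac), names(snp))
  x <- snp[ids]; y <- eac[ids]
  use <- !is.na(x) & !is.na(y)
  x <- x[use]; y <- y[use]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant or too-short vectors; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Remove the top SNP's effect from the EAC
#'
#' Residualises the EAC on the allele count of the lead SNP (OLS with
#' intercept) and restores the original EAC mean, so the output can be
#' re-used directly as the response of a second GWAS scan to look for
#' secondary peaks.
#'
#' @param eac named EAC vector.
#' @param top_counts named allele counts of the lead SNP.
#' @return adjusted EAC (same names/order as `eac`); individuals with a
#'   missing lead genotype get `NA`.
#' @export
adjust_eac_for_top_snp <- function(eac, top_counts) {
  ids <- intersect(names(eac), names(top_counts))
  if (!length(ids)) stop("no overlapping ids")
  x <- top_counts[ids]; y <- eac[ids]
  use <- !is.na(x)
  if (stats::sd(x[use]) == 0) stop("top SNP is monomorphic; cannot adjust")
  fit <- stats::lm(y[use] ~ x[use])
  out <- rep(NA_real_, length(eac))
  names(out) <- names(eac)
  out[ids[use]] <- stats::residuals(fit) + mean(y[use])
  out
}

#' Run the four analysis subsets of a segregation GWAS
#'
#' Fits the segregation model and runs the EAC GWAS for: (i) females only
#' and (ii) males only (the full pedigree is kept for relationship
#' information, the other sex's phenotypes are masked to missing);
#' (iii) both sexes pooled under a single penetrance matrix; and
#' (iv) the EAC vectors from (i) and (ii) concatenated into one GWAS,
#' which preserves sex-specific penetrance in the response.
#'
#' @param ped a `seg_pedigree` with sex labels (needed for i, ii, iv).
#' @param phen a `seg_phenotypes` table.
#' @param init starting [seg_model()].
#' @param gm a [genotype_matrix()].
#' @param subsets which subsets to run.
#' @param ... passed to [fit_segregation_model()].
#' @return named list per subset: `fit` (or `fits` for
#'   `combined_separate`), `eac`, `gwas` (association table).
#' @export
run_subsets <- function(ped, phen, init, gm,
                        subsets = c("female", "male", "combined",
                                    "combined_separate"), ...) {
  subsets <- match.arg(subsets, several.ok = TRUE)
  out <- list()
  fit_sex <- list()
  need_sex <- intersect(subsets, c("female", "male", "combined_separate"))
  for (s in c("female", "male")) {
    if (!(s %in% subsets) &&
        !("combined_separate" %in% subsets)) next
    if (!length(need_sex)) next
    masked <- mask_phenotypes_by_sex(phen, ped, keep = s)
    if (all(is.na(masked$phenotype)))
      stop("no phenotyped ", s, "s in the data")
    fit_sex[[s]] <- fit_segregation_model(ped, masked, init, ...)
    if (s %in% subsets) {
      keep_ids <- ped$id[ped$sex == s]
      eac <- fit_sex[[s]]$eac[names(fit_sex[[s]]$eac) %in% keep_ids]
      out[[s]] <- list(fit = fit_sex[[s]], eac = eac,
                       gwas = eac_gwas(eac, gm))
    }
  }
  if ("combined" %in% subsets) {
    fit <- fit_segregation_model(ped, phen, init, ...)
    out$combined <- list(fit = fit, eac = fit$eac,
                         gwas = eac_gwas(fit$eac, gm))
  }
  if ("combined_separate" %in% subsets) {
    eac_f <- fit_sex$female$eac[names(fit_sex$female$eac) %in%
                                  ped$id[ped$sex == "female"]]
    eac_m <- fit_sex$male$eac[names(fit_sex$male$eac) %in%
                                ped$id[ped$sex == "male"]]
    eac <- c(eac_f, eac_m)
    out$combined_separate <- list(fits = fit_sex, eac = eac,
                                  gwas = eac_gwas(eac, gm))
  }
  out
}

#' Manhattan plot of an association table
#'
#' Chromosome-alternating colours, -log10 p on the y axis, optional
#' Bonferroni reference line (for display only).
#'
#' @param tab an `association_table`.
#' @param path optional PNG path; when given the plot is written there.
#' @param bonferroni draw the 0.05/m Bonferroni line?
#' @export
manhattan_plot <- function(tab, path = NULL, bonferroni = TRUE) {
  tab <- tab[!is.na(tab$neglog10p), , drop = FALSE]
  chrom_num <- suppressWarnings(as.numeric(tab$chrom))
  chrom_ord <- order(ifelse(is.na(chrom_num), Inf, chrom_num), tab$pos)
  tab <- tab[chrom_ord, , drop = FALSE]
  chr <- factor(tab$chrom, levels = unique(tab$chrom))
  xpos <- seq_len(nrow(tab))
  if (!is.null(path)) {
    grDevices::png(path, width = 1200, height = 500)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(xpos, tab$neglog10p,
                 col = c("grey30", "steelblue")[as.integer(chr) %% 2 + 1],
                 pch = 20, xlab = "genome position (SNP index)",
                 ylab = expression(-log[10](p)), xaxt = "n")
  mid <- tapply(xpos, chr, mean)
  graphics::axis(1, at = mid, labels = levels(chr))
  if (bonferroni)
    graphics::abline(h = -log10(0.05 / nrow(tab)), lty = 2, col = "red")
  invisible(tab)
}
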