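#' Gene-drop simulation configuration
#'
#' Parameters of the SNP-dropping protocol: a founder population of
#' `founders_n` evolves by pure drift for `burnin_generations`;
#' `n_candidate_snps` unlinked biallelic loci are generated, of which
#' `singleton_fraction` are singletons (a single heterozygous copy in one
#' pedigree founder); genotypes are then dropped through a pedigree and
#' one segregating locus is picked as the causative mutation.
#'
#' @param founders_n burn-in population size (default 100).
#' @param burnin_generations drift generations before the drop (100).
#' @param n_candidate_snps unlinked candidate loci (1000).
#' @param singleton_fraction fraction of loci that are singletons (0.5).
#' @param replicates independent replicates (10).
#' @param seed base RNG seed.
#' @param causal_snp_rule `"any_segregating"` or `"maf_at_least"`.
#' @param causal_maf_min MAF threshold for `"maf_at_least"`.
#' @export
sim_config <- function(founders_n = 100L, burnin_generations = 100L,
                       n_candidate_snps = 1000L, singleton_fraction = 0.5,
                       replicates = 10L, seed = 1L,
                       causal_snp_rule = c("any_segregating",
                                           "maf_at_least"),
                       causal_maf_min = 0.4) {
  causal_snp_rule <- match.arg(causal_snp_rule)
  stopifnot(founders_n > 0, burnin_generations >= 0, n_candidate_snps > 0,
            singleton_fraction >= 0, singleton_fraction <= 1,
            replicates > 0)
  structure(list(founders_n = as.integer(founders_n),
                 burnin_generations = as.integer(burnin_generations),
                 n_candidate_snps = as.integer(n_candidate_snps),
                 singleton_fraction = singleton_fraction,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed),
                 causal_snp_rule = causal_snp_rule,
                 causal_maf_min = causal_maf_min),
            class = "sim_config")
}

#' Founder SNP genotypes from a Wright-Fisher burn-in
#'
#' Non-singleton loci start at a frequency drawn uniform(0.05, 0.95) and
#' drift for `burnin_generations` in a population of `founders_n`
#' diploids (binomial resampling of 2N gametes per generation); loci that
#' fix are redrawn. Pedigree founders then receive Hardy-Weinberg
#' genotypes at the final frequencies. Singleton loci place exactly one
#' heterozygous copy in one random founder. Loci are mutually
#' independent (no linkage).
#'
#' @param cfg a [sim_config()].
#' @param founder_ids ids of the pedigree founders to genotype.
#' @return matrix founders x loci of allele counts, with attributes
#'   `singleton` (logical per locus) and `freq` (post-burn-in frequency).
#' @export
simulate_founder_snps <- function(cfg, founder_ids) {
  nf <- length(founder_ids)
  L <- cfg$n_candidate_snps
  n_single <- round(cfg$singleton_fraction * L)
  n_drift <- L - n_single
  drift_freq <- numeric(0)
  if (n_drift > 0) {
    need <- n_drift
    drift_freq <- numeric(n_drift)
    filled <- 0L
    tries <- 0L
    while (need > 0 && tries < 50L) {
      p <- stats::runif(need, 0.05, 0.95)
      for (g in seq_len(cfg$burnin_generations))
        p <- stats::rbinom(need, 2L * cfg$founders_n, p) /
          (2 * cfg$founders_n)
      seg <- p > 0 & p < 1
      k <- sum(seg)
      if (k) drift_freq[filled + seq_len(k)] <- p[seg]
      filled <- filled + k
      need <- need - k
      tries <- tries + 1L
    }
    if (need > 0)  # pathological drift settings: fall back to fresh draws
      drift_freq[filled + seq_len(need)] <- stats::runif(need, 0.05, 0.95)
  }
  counts <- matrix(0, nf, L)
  singleton <- rep(FALSE, L)
  if (n_single > 0) {
    idx <- seq_len(n_single)
    singleton[idx] <- TRUE
    carrier <- sample.int(nf, n_single, replace = TRUE)
    counts[cbind(carrier, idx)] <- 1
  }
  if (n_drift > 0) {
    idx <- n_single + seq_len(n_drift)
    counts[, idx] <- matrix(stats::rbinom(nf * n_drift, 2L,
                                          rep(drift_freq, each = nf)),
                            nf, n_drift)
  }
  rownames(counts) <- founder_ids
  colnames(counts) <- paste0("snp", seq_len(L))
  freq <- rep(NA_real_, L)
  freq[!singleton] <- if (n_drift > 0) drift_freq else numeric(0)
  attr(counts, "singleton") <- singleton
  attr(counts, "freq") <- freq
  counts
}

#' Drop founder alleles through a pedigree
#'
#' Founder allele counts are phased once at random; every non-founder then
#' inherits one allele from each parent, sampled uniformly from that
#' parent's two alleles, independently per locus. Deterministic given the
#' RNG state.
#'
#' @param ped a `seg_pedigree`.
#' @param founder_genotypes matrix founders x loci of counts (rownames
#'   must cover `ped$founders`).
#' @param seed optional seed (`set.seed` is called when non-NULL).
#' @return object of class `true_genotypes`: list with `counts`
#'   (individuals x loci), and phased allele matrices `pat`, `mat`.
#' @export
gene_drop <- function(ped, founder_genotypes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(ped$founders %in% rownames(founder_genotypes)))
  n <- length(ped$id)
  L <- ncol(founder_genotypes)
  pat <- mat <- matrix(0L, n, L)
  rownames(pat) <- rownames(mat) <- ped$id
  f_idx <- match(ped$founders, ped$id)
  fg <- founder_genotypes[ped$founders, , drop = FALSE]
  # random phasing of founder counts: het -> one allele on a random strand
  het <- fg == 1
  flip <- matrix(stats::runif(length(fg)) < 0.5, nrow(fg), ncol(fg))
  pat[f_idx, ] <- (fg == 2) + (het & flip)
  mat[f_idx, ] <- (fg == 2) + (het & !flip)
  for (i in ped$order) {
    s <- ped$sire_idx[i]
    if (is.na(s)) next
    d <- ped$dam_idx[i]
    from_pat_s <- stats::runif(L) < 0.5
    from_pat_d <- stats::runif(L) < 0.5
    pat[i, ] <- ifelse(from_pat_s, pat[s, ], mat[s, ])
    mat[i, ] <- ifelse(from_pat_d, pat[d, ], mat[d, ])
  }
  counts <- pat + mat
  colnames(counts) <- colnames(founder_genotypes)
  structure(list(counts = counts, pat = pat, mat = mat,
                 id = ped$id), class = "true_genotypes")
}

#' Choose the causative locus among segregating SNPs
#'
#' @param tg a `true_genotypes` from [gene_drop()].
#' @param rule `"any_segregating"` (uniform over all segregating loci) or
#'   `"maf_at_least"` (uniform over loci with population MAF at least
#'   `maf_min`).
#' @param maf_min threshold for `"maf_at_least"`.
#' @param seed optional seed.
#' @return list `locus` (column index), `maf` (population MAF).
#' @export
choose_causal_snp <- function(tg, rule = c("any_segregating",
                                           "maf_at_least"),
                              maf_min = 0.4, seed = NULL) {
  rule <- match.arg(rule)
  if (!is.null(seed)) set.seed(seed)
  p <- colMeans(tg$counts) / 2
  maf <- pmin(p, 1 - p)
  qualifying <- which(if (rule == "any_segregating") maf > 0
                      else maf >= maf_min)
  if (!length(qualifying)) stop("no segregating locus qualifies under rule ",
                                rule)
  locus <- unname(qualifying[sample.int(length(qualifying), 1L)])
  list(locus = locus, maf = unname(maf[locus]))
}

#' Assign phenotypes from the causal genotype and a penetrance matrix
#'
#' Each individual's phenotype class is drawn from the penetrance column
#' of its causal genotype class.
#'
#' @param causal_counts named vector of causal allele counts (0/1/2).
#' @param pen a [penetrance_matrix()].
#' @param seed optional seed.
#' @param phenotyped_ids optional subset of ids that receive a record
#'   (others are set missing); default all.
#' @return a `seg_phenotypes` table.
#' @export
assign_phenotypes <- function(causal_counts, pen, seed = NULL,
                              phenotyped_ids = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(pen, "penetrance_matrix"),
            !is.null(names(causal_counts)))
  K <- nrow(pen)
  u <- stats::runif(length(causal_counts))
  ph <- integer(length(causal_counts))
  for (g in 0:2) {
    idx <- which(causal_counts == g)
    if (!length(idx)) next
    cum <- cumsum(pen[, g + 1L])
    ph[idx] <- findInterval(u[idx], cum, left.open = TRUE)
  }
  ph <- pmin(ph, K - 1L)  # guard against rounding at the top boundary
  if (!is.null(phenotyped_ids))
    ph[!names(causal_counts) %in% phenotyped_ids] <- NA_integer_
  seg_phenotypes(names(causal_counts), ph, labels = rownames(pen))
}

#' Multi-generation half-sib pedigree generator
#'
#' Stands in for a real livestock pedigree: per generation,
#' `sires_per_generation` sires are each mated to `dams_per_sire` dams,
#' every dam producing `offspring_per_dam` offspring. Parents of later
#' generations are sampled from the previous generation's offspring
#' (creating loops through shared grandparents, as in real data); when too
#' few candidates of a sex exist, new unrelated founders are added.
#'
#' @param generations number of offspring generations.
#' @param sires_per_generation,dams_per_sire,offspring_per_dam family
#'   structure counts.
#' @param seed RNG seed (offspring sex and parent selection).
#' @return a `seg_pedigree`; its summary counts (individuals, sires,
#'   dams) are available through [pedigree_summary()].
#' @export
synthesize_pedigree <- function(generations = 3L, sires_per_generation = 5L,
                                dams_per_sire = 10L, offspring_per_dam = 2L,
                                seed = 1L) {
  stopifnot(generations >= 1, sires_per_generation >= 1,
            dams_per_sire >= 1, offspring_per_dam >= 1)
  set.seed(seed)
  n_dams <- sires_per_generation * dams_per_sire
  rows <- list()
  counter <- 0L
  new_id <- function(prefix) {
    counter <<- counter + 1L
    paste0(prefix, counter)
  }
  add <- function(id, sire, dam, sex)
    rows[[length(rows) + 1L]] <<- data.frame(id = id, sire = sire,
                                             dam = dam, sex = sex,
                                             stringsAsFactors = FALSE)
  pool_m <- character(0)
  pool_f <- character(0)
  for (gen in seq_len(generations)) {
    take <- function(pool, k, sex) {
      if (length(pool) >= k) {
        sample(pool, k)
      } else {
        extra <- replicate(k - length(pool), new_id("F"))
        for (e in extra) add(e, "0", "0", sex)
        c(pool, extra)
      }
    }
    sires <- take(pool_m, sires_per_generation, "male")
    dams <- take(pool_f, n_dams, "female")
    pool_m <- character(0)
    pool_f <- character(0)
    for (si in seq_along(sires)) {
      my_dams <- dams[(si - 1L) * dams_per_sire + seq_len(dams_per_sire)]
      for (dm in my_dams) {
        for (o in seq_len(offspring_per_dam)) {
          oid <- new_id("I")
          sex <- if (stats::runif(1) < 0.5) "male" else "female"
          add(oid, sires[si], dm, sex)
          if (sex == "male") pool_m <- c(pool_m, oid)
          else pool_f <- c(pool_f, oid)
        }
      }
    }
  }
  seg_pedigree(do.call(rbind, rows))
}

#' Summary counts of a pedigree
#' @param ped a `seg_pedigree`.
#' @return list: individuals, sires, dams, founders.
#' @export
pedigree_summary <- function(ped) {
  list(n_individuals = length(ped$id),
       n_sires = length(unique(ped$sire_idx[!is.na(ped$sire_idx)])),
       n_dams = length(unique(ped$dam_idx[!is.na(ped$dam_idx)])),
       n_founders = length(ped$founders))
}

#' Run a penetrance scenario end to end
#'
#' Per replicate: simulate founder SNPs, gene-drop them through the
#' pedigree, choose a causative locus, assign phenotypes under the
#' scenario's penetrance matrix, fit the segregation model (from the
#' standard horn-status starting values), and record the Pearson
#' correlation between the EAC and the causal allele count together with
#' the mean GPI. The across-replicate mean and standard error of the mean
#' are attached as attributes.
#'
#' @param ped a `seg_pedigree`.
#' @param pen generating [penetrance_matrix()] for the scenario.
#' @param cfg a [sim_config()].
#' @param init starting model for the EM fit (default: the standard
#'   horn-status start at q = 0.5).
#' @param phenotyped_ids optional ids that receive phenotype records.
#' @param ... passed to [fit_segregation_model()].
#' @return data frame of class `replicate_summary` with columns
#'   `replicate corr_eac_causal mean_gpi causal_maf status`; attributes
#'   `mean` and `se` hold the aggregate row.
#' @export
run_scenario <- function(ped, pen, cfg, init = NULL,
                         phenotyped_ids = NULL, ...) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(init))
    init <- seg_model(0.5, penetrance_start_horn())
  res <- vector("list", cfg$replicates)
  for (r in seq_len(cfg$replicates)) {
    set.seed(cfg$seed + 7919L * r)
    row <- tryCatch({
      fg <- simulate_founder_snps(cfg, ped$founders)
      tg <- gene_drop(ped, fg)
      causal <- choose_causal_snp(tg, rule = cfg$causal_snp_rule,
                                  maf_min = cfg$causal_maf_min)
      cc <- stats::setNames(tg$counts[, causal$locus], ped$id)
      phen <- assign_phenotypes(cc, pen,
                                phenotyped_ids = phenotyped_ids)
      fit <- fit_segregation_model(ped, phen, init, ...)
      data.frame(replicate = r,
                 corr_eac_causal = stats::cor(fit$eac[ped$id], cc),
                 mean_gpi = fit$mean_gpi,
                 causal_maf = causal$maf,
                 status = "ok", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(replicate = r, corr_eac_causal = NA_real_,
                 mean_gpi = NA_real_, causal_maf = NA_real_,
                 status = paste("failed:", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    res[[r]] <- row
  }
  out <- do.call(rbind, res)
  ok <- out$status == "ok"
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  attr(out, "mean") <- c(corr_eac_causal = mean(out$corr_eac_causal[ok]),
                         mean_gpi = mean(out$mean_gpi[ok]))
  attr(out, "se") <- c(corr_eac_causal = sem(out$corr_eac_causal[ok]),
                       mean_gpi = sem(out$mean_gpi[ok]))
  class(out) <- c("replicate_summary", "data.frame")
  out
}

#' @export
print.replicate_summary <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  m <- attr(x, "mean"); s <- attr(x, "se")
  cat(sprintf("mean corr(EAC, causal) = %.4f (SE %.4f); mean GPI = %.2f (SE %.2f)\n",
              m[1L], s[1L], m[2L], s[2L]))
  invisible(x)
}

#' Write a replicate summary TSV with an aggregate row
#' @param rs a `replicate_summary`.
#' @param path output path.
#' @export
write_replicate_summary <- function(rs, path) {
  utils::write.table(rs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  m <- attr(rs, "mean"); s <- attr(rs, "se")
  cat(sprintf("# mean\t%.6f\t%.6f\n# se\t%.6f\t%.6f\n",
              m[1L], m[2L], s[1L], s[2L]),
      file = path, append = TRUE)
  invisible(path)
}
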