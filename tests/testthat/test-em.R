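# build a genotype_probabilities object directly from an unordered matrix
probs_from_unordered <- function(u, id) {
  ordered <- cbind(u[, 1], u[, 2] / 2, u[, 2] / 2, u[, 3])
  seggwas:::new_genotype_probabilities(ordered, id)
}

test_that("penetrance M-step is the posterior-weighted class frequency", {
  # two animals certain genotype class 2, phenotypes horned and scurs
  u <- rbind(c(0, 0, 1), c(0, 0, 1))
  probs <- probs_from_unordered(u, c("a", "b"))
  phen <- seg_phenotypes(c("a", "b"), c(2L, 1L))
  est <- estimate_penetrance(probs, phen,
                             prev = penetrance_start_horn())
  expect_equal(unname(est[, 3]), c(0, 0.5, 0.5))
  # empty columns keep the previous values
  expect_equal(unname(est[, 1]), c(1, 0, 0))

  # point masses matching a truth table reproduce empirical frequencies
  u2 <- diag(3)[c(1, 1, 2, 2, 3, 3, 3), ]
  y2 <- c(0L, 0L, 1L, 0L, 2L, 2L, 1L)
  est2 <- estimate_penetrance(probs_from_unordered(u2, paste0("i", 1:7)),
                              seg_phenotypes(paste0("i", 1:7), y2))
  expect_equal(unname(est2[, 2]), c(0.5, 0.5, 0))
  expect_equal(unname(est2[, 3]), c(0, 1 / 3, 2 / 3))

  # fuzzy probabilities: hand-computed weighted ratios on 5 animals
  u3 <- rbind(c(0.6, 0.3, 0.1), c(0.2, 0.5, 0.3), c(0.1, 0.1, 0.8),
              c(0.4, 0.4, 0.2), c(0.3, 0.3, 0.4))
  y3 <- c(0L, 1L, 2L, 0L, 1L)
  est3 <- estimate_penetrance(probs_from_unordered(u3, paste0("a", 1:5)),
                              seg_phenotypes(paste0("a", 1:5), y3))
  num <- sapply(0:2, function(k) colSums(u3[y3 == k, , drop = FALSE]))
  expect_equal(unclass(est3), t(num) / rep(colSums(u3), each = 3),
               ignore_attr = TRUE)
})

test_that("allele frequency M-step averages founder EACs with clamping", {
  ped <- seg_pedigree(data.frame(id = paste0("f", 1:4),
                                 sire = "0", dam = "0"))
  u <- rbind(c(0, 0, 1), c(0, 1, 0), c(0, 1, 0), c(1, 0, 0))
  probs <- probs_from_unordered(u, ped$id)
  expect_equal(estimate_allele_frequency(probs, ped), 0.5)
  # all founders certain aa clamps at q_min instead of 0
  all_aa <- probs_from_unordered(matrix(rep(c(1, 0, 0), 4), 4,
                                        byrow = TRUE), ped$id)
  expect_equal(estimate_allele_frequency(all_aa, ped), 1e-6)
  # founders at exact HW with q = 0.3 return 0.3
  hw <- probs_from_unordered(matrix(rep(c(0.49, 0.42, 0.09), 4), 4,
                                    byrow = TRUE), ped$id)
  expect_equal(estimate_allele_frequency(hw, ped), 0.3)
})

test_that("EM recovers identity penetrance from fully informative data", {
  ped <- synthesize_pedigree(generations = 3, sires_per_generation = 4,
                             dams_per_sire = 6, offspring_per_dam = 3,
                             seed = 11)
  cfg <- sim_config(n_candidate_snps = 50, replicates = 1, seed = 11,
                    causal_snp_rule = "maf_at_least", causal_maf_min = 0.3)
  set.seed(11)
  fg <- simulate_founder_snps(cfg, ped$founders)
  tg <- gene_drop(ped, fg)
  causal <- choose_causal_snp(tg, "maf_at_least", maf_min = 0.3)
  cc <- setNames(tg$counts[, causal$locus], ped$id)
  phen <- assign_phenotypes(cc, penetrance_identity())
  fit <- fit_segregation_model(ped, phen,
                               seg_model(0.5, penetrance_start_horn()))
  expect_true(fit$converged)
  expect_equal(unclass(fit$model$penetrance), diag(3),
               ignore_attr = TRUE, tolerance = 0.01)
  # with complete information the EAC reproduces the true allele count
  expect_equal(unname(fit$eac[ped$id]), unname(cc), tolerance = 1e-3)
})

test_that("different admissible starts converge to the same penetrance", {
  ped <- synthesize_pedigree(generations = 3, sires_per_generation = 4,
                             dams_per_sire = 6, offspring_per_dam = 3,
                             seed = 7)
  cfg <- sim_config(n_candidate_snps = 50, replicates = 1, seed = 7,
                    causal_snp_rule = "maf_at_least", causal_maf_min = 0.3)
  set.seed(7)
  fg <- simulate_founder_snps(cfg, ped$founders)
  tg <- gene_drop(ped, fg)
  causal <- choose_causal_snp(tg, "maf_at_least", maf_min = 0.3)
  cc <- setNames(tg$counts[, causal$locus], ped$id)
  phen <- assign_phenotypes(cc, penetrance_scenarios()$moderate, seed = 7)
  # two admissible (all-positive) starts; zero cells in a start are
  # structural constraints, not starting values, so both starts here are
  # unconstrained
  alt_start <- penetrance_matrix(rbind(c(0.8, 0.3, 0.1),
                                       c(0.15, 0.4, 0.2),
                                       c(0.05, 0.3, 0.7)))
  alt2 <- penetrance_matrix(rbind(c(0.5, 0.3, 0.2),
                                  c(0.3, 0.4, 0.3),
                                  c(0.2, 0.3, 0.5)))
  f1 <- fit_segregation_model(ped, phen, seg_model(0.5, alt2))
  f2 <- fit_segregation_model(ped, phen, seg_model(0.3, alt_start))
  expect_equal(unclass(f1$model$penetrance), unclass(f2$model$penetrance),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(f1$model$q, f2$model$q, tolerance = 1e-3)
})

test_that("EM never decreases the exact observed-data likelihood", {
  # exact E-step on a loop-free pedigree => textbook EM monotonicity,
  # checked against the enumeration oracle at every recorded iterate
  ped <- tree_pedigree(depth = 2, seed = 3)
  phen <- random_phenotypes(ped, seed = 3, miss = 0.2)
  start <- penetrance_matrix(rbind(c(0.6, 0.3, 0.1), c(0.3, 0.4, 0.3),
                                   c(0.1, 0.3, 0.6)))
  fit <- suppressWarnings(
    fit_segregation_model(ped, phen, seg_model(0.4, start),
                          max_em_iter = 40))  # capped run; trace is what matters
  lls <- vapply(fit$trace, function(tr)
    brute_force_loglik(ped, phen, seg_model(tr$q, tr$penetrance)),
    numeric(1))
  expect_true(all(diff(lls) > -1e-9))
})

test_that("an added phenotype record increases expected own-GPI", {
  # realisation-wise the GPI can drop; the information inequality holds
  # in expectation over the new record's predictive distribution
  for (s in 1:6) {
    ped <- tree_pedigree(depth = 2, seed = s)
    pen <- random_penetrance(s + 300)
    m <- seg_model(runif(1, 0.2, 0.8), pen)
    y <- random_phenotypes(ped, seed = s + 600, miss = 0.5)
    target <- ped$id[which(is.na(align_phen <- y$phenotype[match(ped$id, y$id)]))][1]
    if (is.na(target)) next
    base <- brute_force_probabilities(ped, y, m)
    gpi0 <- compute_gpi(base, m$q)$gpi[target]
    pred <- as.vector(unclass(pen) %*% base$unordered[target, ])
    egpi <- 0
    for (k in which(pred > 0)) {
      y2 <- y
      y2$phenotype[y2$id == target] <- k - 1L
      attributes(y2) <- attributes(y)
      p2 <- brute_force_probabilities(ped, y2, m)
      egpi <- egpi + pred[k] * compute_gpi(p2, m$q)$gpi[target]
    }
    expect_gte(egpi, gpi0 - 1e-8)
  }
})
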