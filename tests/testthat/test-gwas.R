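make_gm <- function(counts, chrom = NULL, pos = NULL) {
  m <- ncol(counts)
  map <- data.frame(snp = paste0("s", seq_len(m)),
                    chrom = if (is.null(chrom)) rep("1", m) else chrom,
                    pos = if (is.null(pos)) seq_len(m) else pos,
                    counted = "A")
  colnames(counts) <- map$snp
  genotype_matrix(counts, map)
}

test_that("QC removes low-MAF, HWE-deviant, low-call and non-autosomal SNPs", {
  n <- 1000
  set.seed(1)
  good <- rbinom(n, 2, 0.3)                   # ~HW, MAF 0.3
  rare <- c(rep(1, 10), rep(0, n - 10))       # MAF 0.005
  allhet <- rep(1, n)                         # chi2 = n = 1000 > 600
  holey <- good; holey[1:150] <- NA           # call rate 0.85
  sexchr <- good
  counts <- cbind(good, rare, allhet, holey, sexchr)
  rownames(counts) <- paste0("i", 1:n)
  gm <- make_gm(counts, chrom = c("1", "1", "1", "1", "X"))
  res <- qc_filter(gm)
  expect_equal(res$gm$map$snp, "s1")
  expect_equal(unname(res$report$removed["maf"]), 1)
  expect_equal(unname(res$report$removed["hwe"]), 1)
  expect_equal(unname(res$report$removed["call_rate"]), 1)
  expect_equal(unname(res$report$removed["non_autosome"]), 1)
  # the all-heterozygote chi-square is exactly n
  expect_equal(res$report$per_snp$hwe_chi2[3], 1000)
})

test_that("EAC regression matches closed-form OLS on a printed toy", {
  x <- c(0, 1, 2, 1, 0, 2)
  y <- c(0.1, 0.9, 1.8, 1.1, 0.3, 1.7)
  counts <- matrix(x, 6, 1)
  rownames(counts) <- paste0("i", 1:6)
  names(y) <- rownames(counts)
  tab <- eac_gwas(y, make_gm(counts))
  ref <- summary(lm(y ~ x))
  expect_equal(tab$beta, unname(coef(ref)[2, 1]))
  expect_equal(tab$se, unname(coef(ref)[2, 2]))
  expect_equal(tab$neglog10p, -log10(coef(ref)[2, 4]), ignore_attr = TRUE)
  expect_equal(tab$r2, ref$r.squared)
  expect_equal(tab$n, 6L)
})

test_that("a SNP identical to the EAC reaches the numeric ceiling", {
  set.seed(2)
  x <- rbinom(500, 2, 0.4)
  counts <- cbind(x, mono = rep(1, 500))
  rownames(counts) <- paste0("i", 1:500)
  eac <- setNames(as.numeric(x), rownames(counts))
  tab <- eac_gwas(eac, make_gm(counts))
  expect_equal(tab$beta[1], 1)
  expect_equal(tab$r2[1], 1)
  expect_gt(tab$neglog10p[1], 321)        # beyond the double floor
  expect_true(is.finite(tab$neglog10p[1]))
  expect_equal(tab$flag[2], "monomorphic")
  expect_true(is.na(tab$beta[2]))
})

test_that("the null distribution of EAC-GWAS p-values is uniform", {
  set.seed(3)
  n <- 400; m <- 2000
  counts <- matrix(rbinom(n * m, 2, 0.3), n, m)
  rownames(counts) <- paste0("i", 1:n)
  eac <- setNames(runif(n, 0, 2), rownames(counts))
  tab <- eac_gwas(eac, make_gm(counts))
  p <- 10^(-tab$neglog10p)
  frac <- mean(p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / m))
  expect_lt(abs(mean(tab$beta)), 0.02)
  # R^2 equals the squared EAC-SNP correlation
  r <- eac_snp_correlation(eac, setNames(counts[, 1], rownames(counts)))
  expect_equal(tab$r2[1], r^2, tolerance = 1e-10)
})

test_that("logistic GWAS: null calibration, separation flag, information", {
  set.seed(4)
  n <- 600
  x <- rbinom(n, 2, 0.4)
  ids <- paste0("i", 1:n)
  # null: y independent of x
  m0 <- matrix(rbinom(n * 300, 2, 0.3), n, 300)
  rownames(m0) <- ids
  y0 <- setNames(rbinom(n, 1, 0.4), ids)
  tab0 <- binary_gwas(y0, make_gm(m0))
  p0 <- 10^(-tab0$neglog10p)
  expect_lt(abs(mean(p0 < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 300) + 0.01)
  # deterministic y from the SNP: separation flagged, signal dominates
  counts <- matrix(x, n, 1)
  rownames(counts) <- ids
  ydet <- setNames(as.numeric(x >= 1), ids)
  tabd <- binary_gwas(ydet, make_gm(counts))
  expect_equal(tabd$flag[1], "separation")
  yhalf <- ydet
  yhalf[1:(n / 2)] <- sample(yhalf[1:(n / 2)])
  tabh <- binary_gwas(yhalf, make_gm(counts))
  expect_gt(tabd$neglog10p[1], tabh$neglog10p[1])
  expect_error(binary_gwas(setNames(rep(1, n), ids), make_gm(counts)),
               "constant")
})

test_that("top SNP selection breaks ties by |beta| then genome order", {
  tab <- seggwas:::new_association_table(data.frame(
    snp = c("a", "b", "c"), chrom = c("2", "1", "1"), pos = c(5, 9, 2),
    n = 10, beta = c(0.9, 1.1, -1.1), se = 0.1, stat = 1,
    neglog10p = c(330, 330, 2), r2 = 0.5, flag = ""))
  expect_equal(top_snp(tab)$snp, "b")
  tab$neglog10p <- c(330, 330, 330)
  tab$beta <- c(1.1, 1.1, 0.9)
  expect_equal(top_snp(tab)$snp, "b")  # chrom 1 before chrom 2
  empty <- tab[0, ]
  expect_error(top_snp(empty))
})

test_that("EAC-SNP correlation endpoints and formula", {
  eac <- setNames(c(0, 1, 2, 1, 0.5), paste0("i", 1:5))
  expect_equal(eac_snp_correlation(eac, eac), 1)
  expect_equal(eac_snp_correlation(eac, 2 - eac), -1)
  snp <- setNames(c(0, 2, 1, 1, 0), paste0("i", 1:5))
  direct <- sum((eac - mean(eac)) * (snp - mean(snp))) /
    sqrt(sum((eac - mean(eac))^2) * sum((snp - mean(snp))^2))
  expect_equal(eac_snp_correlation(eac, snp), direct)
  expect_warning(r <- eac_snp_correlation(eac, setNames(rep(1, 5),
                                                        names(eac))))
  expect_true(is.na(r))
})

test_that("adjusting the EAC for the lead SNP moves the signal on", {
  set.seed(5)
  n <- 1500
  ids <- paste0("i", 1:n)
  snpA <- rbinom(n, 2, 0.5)
  snpB <- rbinom(n, 2, 0.5)
  noise <- matrix(rbinom(n * 20, 2, 0.3), n, 20)
  counts <- cbind(snpA, snpB, noise)
  rownames(counts) <- ids
  gm <- make_gm(counts)
  eac <- setNames(snpA + 0.3 * snpB, ids)
  tab1 <- eac_gwas(eac, gm)
  lead <- top_snp(tab1)
  expect_equal(lead$snp, "s1")
  adj <- adjust_eac_for_top_snp(eac, setNames(counts[, 1], ids))
  expect_equal(mean(adj), mean(eac))
  tab2 <- eac_gwas(adj, gm)
  expect_equal(top_snp(tab2)$snp, "s2")
  # perfectly explained EAC leaves no residual signal anywhere
  adj0 <- adjust_eac_for_top_snp(setNames(as.numeric(snpA), ids),
                                 setNames(counts[, 1], ids))
  expect_lt(suppressWarnings(max(eac_gwas(adj0, gm)$neglog10p,
                                 na.rm = TRUE)), 321)
  expect_error(adjust_eac_for_top_snp(eac, setNames(rep(2, n), ids)),
               "monomorphic")
})

test_that("PLINK binary and TSV readers agree and round-trip", {
  set.seed(6)
  counts <- matrix(rbinom(60, 2, 0.4), 10, 6)
  counts[2, 3] <- NA
  rownames(counts) <- paste0("ind", 1:10)
  gm <- make_gm(counts, chrom = c(1, 1, 2, 2, 3, 3), pos = 101:106)
  prefix <- tempfile()
  write_plink(gm, prefix)
  back <- read_plink(prefix)
  expect_equal(back$counts, gm$counts)
  expect_equal(back$map$chrom, as.character(gm$map$chrom))
  expect_equal(back$map$pos, gm$map$pos)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes_tsv(gm, f)
  expect_equal(read_genotypes_tsv(f)$counts, gm$counts)
  unlink(paste0(prefix, c(".bed", ".bim", ".fam")))
})
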