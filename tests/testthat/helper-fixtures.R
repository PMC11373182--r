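# Fixtures are built in code; no binary data ships with the package.

trio_df <- function() {
  data.frame(id = c("sire1", "dam1", "kid1"),
             sire = c("0", "0", "sire1"),
             dam = c("0", "0", "dam1"),
             sex = c("male", "female", "male"),
             stringsAsFactors = FALSE)
}

# random pedigree with matings among earlier individuals; loops arise
# naturally through shared ancestors
random_pedigree <- function(n, seed) {
  set.seed(seed)
  id <- paste0("i", seq_len(n))
  sire <- dam <- rep("0", n)
  sex <- rep(c("male", "female"), length.out = n)
  nf <- max(2L, floor(n / 3))
  for (i in (nf + 1L):n) {
    males <- which(sex[1:(i - 1L)] == "male")
    females <- which(sex[1:(i - 1L)] == "female")
    if (!length(males) || !length(females)) next
    sire[i] <- id[sample(males, 1L)]
    dam[i] <- id[sample(females, 1L)]
  }
  seg_pedigree(data.frame(id = id, sire = sire, dam = dam, sex = sex,
                          stringsAsFactors = FALSE))
}

# loop-free pedigree: disjoint founder couples, each child mates a fresh
# founder; every family shares at most one individual with any other
tree_pedigree <- function(depth, seed) {
  set.seed(seed)
  rows <- data.frame(id = c("m1", "f1"), sire = c("0", "0"),
                     dam = c("0", "0"), sex = c("male", "female"),
                     stringsAsFactors = FALSE)
  cur_m <- "m1"; cur_f <- "f1"
  for (d in seq_len(depth)) {
    kid <- paste0("k", d)
    mate <- paste0("s", d)
    kid_sex <- if (d %% 2 == 0) "male" else "female"
    rows <- rbind(rows,
      data.frame(id = kid, sire = cur_m, dam = cur_f, sex = kid_sex),
      data.frame(id = paste0("k", d, "b"), sire = cur_m, dam = cur_f,
                 sex = "female"),
      data.frame(id = mate, sire = "0", dam = "0",
                 sex = if (kid_sex == "male") "female" else "male"))
    if (kid_sex == "male") { cur_m <- kid; cur_f <- mate }
    else { cur_m <- mate; cur_f <- kid }
  }
  seg_pedigree(rows)
}

# does the individual-family bipartite graph contain a cycle?
pedigree_has_loop <- function(ped) {
  fam <- seggwas:::build_families(ped)
  F <- length(fam$fs)
  if (F < 2L) return(FALSE)
  nv <- length(ped$id) + F
  parent <- seq_len(nv)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (f in seq_len(F)) {
    members <- c(fam$fs[f], fam$fd[f], fam$off[[f]]) + 1L
    for (m in members) {
      a <- find(m); b <- find(length(ped$id) + f)
      if (a == b) return(TRUE)
      parent[a] <- b
    }
  }
  FALSE
}

random_penetrance <- function(seed, K = 3) {
  set.seed(seed)
  pm <- matrix(stats::rgamma(K * 3, 1), K, 3)
  pm <- sweep(pm, 2, colSums(pm), "/")
  penetrance_matrix(pm, labels = paste0("ph", seq_len(K) - 1L))
}

random_phenotypes <- function(ped, seed, miss = 0.25) {
  set.seed(seed)
  y <- sample(0:2, length(ped$id), replace = TRUE)
  y[stats::runif(length(y)) < miss] <- NA_integer_
  seg_phenotypes(ped$id, y)
}

table4_male_penetrance <- function() {
  penetrance_matrix(rbind(c(1, 0.23, 0),
                          c(0, 0.76, 0),
                          c(0, 0.01, 1)))
}
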