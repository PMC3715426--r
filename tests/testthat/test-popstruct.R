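test_that("derived-allele frequencies exclude missing genotypes", {
  g <- genotype_panel(matrix(c(0L, 1L, 2L), 3, 1), "p1")
  expect_equal(unname(derived_freqs(g)$freq[1, 1]), 0.5)

  # 42 individuals, one heterozygote
  g2 <- genotype_panel(matrix(c(1L, rep(0L, 41)), 42, 1), "p1")
  expect_equal(unname(derived_freqs(g2)$freq[1, 1]), 1 / 84)

  # an all-missing SNP in one population is NA-flagged with zero count
  geno <- matrix(c(NA, NA, 1L, 1L, 2L, 0L), 3, 2)
  ft <- derived_freqs(genotype_panel(geno, c("a", "a", "b")))
  expect_true(is.na(ft$freq["a", 1]))
  expect_equal(unname(ft$n["a", 1]), 0L)
  expect_equal(unname(ft$freq["b", 1]), 0.5)

  # population with no genotyped individuals anywhere is an error
  allna <- matrix(NA_integer_, 2, 3)
  allna <- rbind(allna, matrix(1L, 2, 3))
  expect_error(derived_freqs(genotype_panel(allna, c("x", "x", "y", "y"))),
               "population x")
})

test_that("LD pruning drops the later SNP of an offending pair", {
  set.seed(42)
  base <- rbinom(40, 2, 0.5)
  geno <- cbind(base, base, rbinom(40, 2, 0.5))  # duplicated column
  storage.mode(geno) <- "integer"
  keep <- ld_prune(genotype_panel(geno))
  expect_equal(keep, c(1L, 3L))

  # mutually independent SNPs are all retained
  set.seed(7)
  ind <- matrix(rbinom(40 * 6, 2L, 0.5), 40, 6)
  expect_equal(ld_prune(genotype_panel(ind)), 1:6)
})

test_that("LD pruning matches the exhaustive-pair oracle on 5-SNP fixtures", {
  set.seed(11)
  for (rep in 1:40) {
    base <- matrix(rbinom(30 * 5, 2L, 0.5), 30, 5)
    # induce correlation by copying noisy columns
    j <- sample(4, 1)
    base[, j + 1] <- ifelse(runif(30) < 0.9, base[, j], rbinom(30, 2, 0.5))
    storage.mode(base) <- "integer"
    expect_equal(ld_prune(genotype_panel(base)), oracle_ld_keep(base))
  }
})

test_that("LD pruning is invariant to column scaling of dosages", {
  set.seed(3)
  g <- matrix(rbinom(50 * 8, 2L, 0.4), 50, 8)
  g[, 2] <- g[, 1]
  k1 <- ld_prune(g)
  k2 <- ld_prune(sweep(g, 2, c(1, 2, 5, 1, 3, 1, 1, 2), `*`))
  expect_equal(k1, k2)
})

test_that("allele-sharing distance follows the 0 / 0.5 / 1 convention", {
  g <- rbind(c(0L, 2L, 1L), c(0L, 2L, 1L))
  expect_equal(allele_sharing_distance(genotype_panel(g))[1, 2], 0)
  g2 <- rbind(c(0L, 0L), c(2L, 2L))
  expect_equal(allele_sharing_distance(genotype_panel(g2))[1, 2], 1)
  g3 <- rbind(c(0L, 0L), c(1L, 1L))
  expect_equal(allele_sharing_distance(genotype_panel(g3))[1, 2], 0.5)
  # a pair with no co-genotyped SNP errors
  g4 <- rbind(c(0L, NA), c(NA, 1L))
  expect_error(allele_sharing_distance(genotype_panel(g4)), "share no genotyped")
  # symmetry and zero diagonal
  set.seed(2)
  g5 <- matrix(rbinom(5 * 20, 2L, 0.5), 5, 20)
  D <- allele_sharing_distance(genotype_panel(g5))
  expect_equal(D, t(D))
  expect_equal(diag(D), setNames(rep(0, 5), rownames(D)))
})

test_that("Hudson F_ST matches its closed form and is symmetric", {
  # single SNP, huge n: (0.2-0.8)^2 / (0.2*0.2 + 0.8*0.8)
  ft <- freq_table(rbind(a = 0.2, b = 0.8),
                   rbind(a = 1e9, b = 1e9))
  M <- pairwise_fst(ft)
  expect_equal(M["a", "b"], 0.36 / 0.68, tolerance = 1e-6)
  expect_identical(M["a", "b"], M["b", "a"])

  # identical frequency vectors, large n: near zero
  set.seed(4)
  p <- runif(30, 0.1, 0.9)
  ft2 <- freq_table(rbind(a = p, b = p), matrix(200L, 2, 30))
  expect_lt(abs(pairwise_fst(ft2)["a", "b"]), 1 / 100)

  # a population with sample size <= 1 everywhere is an error
  ft3 <- freq_table(rbind(a = p, b = p),
                    rbind(a = rep(1L, 30), b = rep(200L, 30)))
  expect_error(pairwise_fst(ft3), "sample size")
})

test_that("Balding-Nichols F_ST recovery at reduced scale", {
  bn <- sim_balding_nichols(n_pops = 2, F = 0.10, n_snps = 8000,
                            n_per_pop = 50, seed = 101)
  expect_lt(abs(pairwise_fst(bn$freqs)[1, 2] - 0.10), 0.02)
})

test_that("classical PCA reports sane variance decomposition", {
  # three collinear points: PC1 explains everything
  x <- matrix(c(0, 1, 3), dimnames = list(c("a", "b", "c"), NULL))
  D <- as.matrix(dist(x))
  expect_warning(res <- pca_from_distances(D, k = 2), "truncating")
  expect_equal(res$var_explained[1], 100, tolerance = 1e-8)

  # general case: percentages non-increasing, sum <= 100, distances
  # reproduced for a Euclidean-embeddable matrix
  set.seed(5)
  pts <- matrix(rnorm(8 * 3), 8, 3)
  D2 <- as.matrix(dist(pts))
  res2 <- pca_from_distances(D2, k = 3)
  expect_true(all(diff(res2$var_explained) <= 1e-8))
  expect_lte(sum(res2$var_explained), 100 + 1e-8)
  expect_equal(as.matrix(dist(res2$coords)), D2, ignore_attr = TRUE,
               tolerance = 1e-8)

  # two well-separated populations: PC1 splits the labels cleanly
  bn <- sim_balding_nichols(n_pops = 2, F = 0.2, n_snps = 2000,
                            n_per_pop = 20, seed = 6)
  D3 <- allele_sharing_distance(bn$panel)
  pc <- pca_from_distances(D3, k = 2)$coords[, 1]
  g1 <- pc[bn$panel$population == "pop1"]
  g2 <- pc[bn$panel$population == "pop2"]
  expect_true(max(g1) < min(g2) || max(g2) < min(g1))
})

test_that("neighbor joining solves the three-taxon path equations", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(len[["A"]], 1)
  expect_equal(len[["B"]], 1)
  expect_equal(len[["C"]], 3)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("neighbor joining reproduces additive distances and ignores taxon order", {
  set.seed(8)
  rt <- random_additive_tree(4)
  tr <- nj_tree(rt$D)
  back <- ape::cophenetic.phylo(tr)
  expect_equal(back[rownames(rt$D), colnames(rt$D)], rt$D, tolerance = 1e-9)

  perm <- sample(nrow(rt$D))
  tr2 <- nj_tree(rt$D[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2))[1], 0)
})
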