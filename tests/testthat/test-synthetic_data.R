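test_that("Balding-Nichols draws have the stated mean and variance structure", {
  # F = 0: population frequencies equal the ancestral ones exactly
  bn0 <- sim_balding_nichols(n_pops = 2, F = 0, n_snps = 200, n_per_pop = 10,
                             seed = 71)
  expect_equal(attr(bn0, "true_freq")[1, ], attr(bn0, "ancestral_freq"))
  expect_equal(attr(bn0, "true_freq")[2, ], attr(bn0, "ancestral_freq"))

  # F = 0.1: Var(pop - ancestral) tracks F p (1 - p) within 5%
  bn <- sim_balding_nichols(n_pops = 1, F = 0.1, n_snps = 50000,
                            n_per_pop = 2, seed = 72)
  p <- attr(bn, "ancestral_freq")
  d2 <- (attr(bn, "true_freq")[1, ] - p)^2 / (p * (1 - p))
  expect_lt(abs(mean(d2) - 0.1), 0.005)

  # fixed seed: byte-identical outputs
  a <- sim_balding_nichols(n_pops = 2, F = 0.1, n_snps = 100, n_per_pop = 5,
                           seed = 73)
  b <- sim_balding_nichols(n_pops = 2, F = 0.1, n_snps = 100, n_per_pop = 5,
                           seed = 73)
  expect_identical(a$panel$geno, b$panel$geno)
  expect_identical(attr(a, "true_freq"), attr(b, "true_freq"))
})

test_that("neutral Wright-Fisher evolution preserves expected frequencies", {
  set.seed(74)
  drift <- replicate(200, {
    sim <- sim_wf_haplotypes(seed = sample.int(1e6, 1), s = 0, n_haps = 60,
                             n_sites = 120, chrom_length = 1e6,
                             burnin_gens = 30, n_founders = 10)
    mean(colMeans(sim$panel$haps))
  })
  # founder allele counts are uniform on 1..9 of 10, so E[freq] = 0.5
  expect_lt(abs(mean(drift) - 0.5), 0.01)
})

test_that("without recombination and mutation haplotypes stay founder copies", {
  sim0 <- sim_wf_haplotypes(seed = 75, s = 0, n_haps = 40, n_sites = 150,
                            chrom_length = 2e6, burnin_gens = 0,
                            n_founders = 8, rec_rate = 0, mut_rate = 0)
  simG <- sim_wf_haplotypes(seed = 75, s = 0, n_haps = 40, n_sites = 150,
                            chrom_length = 2e6, burnin_gens = 40,
                            n_founders = 8, rec_rate = 0, mut_rate = 0)
  founders <- unique(apply(sim0$panel$haps, 1, paste, collapse = ""))
  finals <- unique(apply(simG$panel$haps, 1, paste, collapse = ""))
  expect_true(all(finals %in% founders))
})

test_that("a conditioned sweep reaches its target with a recorded truth", {
  sim <- sim_wf_haplotypes(seed = 76, n_haps = 300, n_sites = 800,
                           chrom_length = 4e6, s = 0.08, target_freq = 0.6)
  f <- mean(sim$panel$haps[, sim$truth$core_site])
  expect_gte(f, 0.6)
  expect_equal(sim$sites$pos[sim$truth$core_site], sim$truth$core_pos)
  w <- sim$truth$window
  expect_true(sim$truth$core_pos >= w["start"] && sim$truth$core_pos < w["end"])
  expect_equal(unname(w["end"] - w["start"]), 200000)
  # an unreachable target within a tiny restart budget reports attempts
  expect_error(sim_wf_haplotypes(seed = 77, n_haps = 200, n_sites = 300,
                                 chrom_length = 2e6, s = 0.001,
                                 target_freq = 0.95, sweep_gens = 10,
                                 max_restarts = 3),
               "3 attempts")
})

test_that("sweep carriers carry longer haplotypes than neutral ones", {
  ehh_at <- function(sim, dist) {
    cls <- if (is.null(sim$truth)) "combined" else "derived"
    core <- if (is.null(sim$truth)) {
      which.min(abs(sim$sites$pos - 2.5e6))
    } else {
      sim$truth$core_site
    }
    cv <- ehh_curve(sim$panel, sim$sites, core, cls, "right")
    i <- which(cv$pos - cv$pos[1] >= dist)[1]
    if (is.na(i)) 0 else cv$ehh[i]
  }
  sw <- vapply(1:5, function(s) {
    ehh_at(sim_wf_haplotypes(seed = 80 + s, n_haps = 400, n_sites = 1200,
                             chrom_length = 5e6), 5e4)
  }, 0)
  ne <- vapply(1:5, function(s) {
    ehh_at(sim_wf_haplotypes(seed = 90 + s, n_haps = 400, n_sites = 1200,
                             chrom_length = 5e6, s = 0), 5e4)
  }, 0)
  expect_gt(mean(sw), mean(ne))
})

test_that("phenotype simulation is linear in copies at the noiseless limit", {
  cp <- data.frame(individual = sprintf("i%d", 1:40),
                   copies = rep(0:2, length.out = 40))
  ph <- sim_phenotypes(cp, beta = 0.8, hb_sd = 1e-9, age_beta = 0, seed = 78)
  expect_equal(ph$hb, 13.5 + 0.8 * cp$copies, tolerance = 1e-6)
  expect_error(sim_phenotypes(cp, hb_sd = 0), "hb_sd")

  # beta = 0: association p-values show no systematic signal
  set.seed(79)
  ps <- replicate(200, {
    ph0 <- sim_phenotypes(cp, beta = 0, hb_sd = 1, age_beta = 0,
                          seed = sample.int(1e6, 1))
    summary(lm(ph0$hb ~ cp$copies))$coefficients[2, 4]
  })
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
})

test_that("the MR testbed honours its stated linear-combination structure", {
  tb <- make_mr_testbed(n_refs = 4, n_snps = 1000, noise_sd = 0,
                        n_divergent = 5, delta = 0.25, seed = 81)
  fr <- tb$freqs$freq
  null_snps <- setdiff(seq_len(1000), tb$truth$divergent)
  recon <- drop(tb$truth$weights %*% fr[-1, ])
  expect_equal(fr["target", null_snps], recon[null_snps])
  expect_equal(max(abs(fr["target", tb$truth$divergent] -
                       recon[tb$truth$divergent])), 0.25)
  expect_error(make_mr_testbed(n_refs = 2), "at least 3")
})

test_that("simulated panels survive a VCF round-trip without loss", {
  sim <- sim_wf_haplotypes(seed = 82, n_haps = 20, n_sites = 120,
                           chrom_length = 5e5, s = 0)
  path <- tempfile(fileext = ".vcf")
  write_phased_vcf(sim$sites, sim$panel, path,
                   header = paste0("seed=", attr(sim, "seed")))
  back <- read_phased_vcf(path, ancestral_source = "AA")
  expect_identical(back$panel$haps, sim$panel$haps)
  expect_equal(back$sites$pos, sim$sites$pos)
  expect_equal(back$sites$ancestral, sim$sites$ancestral)
})
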