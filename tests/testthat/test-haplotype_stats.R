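test_that("EHH pair counting matches hand-derived values", {
  # all carriers identical over the window: EHH stays 1
  h <- matrix(1L, 4, 5)
  fx <- panel_fixture(h)
  cv <- ehh_curve(fx$panel, fx$sites, 1, "derived", "right")
  expect_equal(cv$ehh, rep(1, 5))

  # 4 carriers splitting 2/1/1 at the first flanking marker: C(2,2)/C(4,2)
  h2 <- cbind(rep(1L, 4), c(0L, 0L, 1L, NA))
  fx2 <- panel_fixture(h2)
  cv2 <- ehh_curve(fx2$panel, fx2$sites, 1, "derived", "right")
  expect_equal(cv2$ehh[2], 1 / 6)

  # fewer than 2 carriers: invalid curve
  h3 <- cbind(c(1L, 0L, 0L, 0L), c(1L, 1L, 0L, 0L))
  fx3 <- panel_fixture(h3)
  expect_false(ehh_curve(fx3$panel, fx3$sites, 1, "derived", "right")$valid)
})

test_that("EHH equals the exhaustive pair-counting oracle on random panels", {
  set.seed(99)
  for (rep in 1:300) {
    h <- random_small_panel(2L * sample(2:8, 1), sample(3:12, 1))
    fx <- panel_fixture(h)
    core <- sample(ncol(h), 1)
    cls <- sample(c("derived", "ancestral", "combined"), 1)
    dir <- sample(c("left", "right"), 1)
    carriers <- switch(cls,
      derived = which(!is.na(h[, core]) & h[, core] == 1L),
      ancestral = which(!is.na(h[, core]) & h[, core] == 0L),
      combined = seq_len(nrow(h)))
    cv <- ehh_curve(fx$panel, fx$sites, core, cls, dir)
    if (length(carriers) < 2) {
      expect_false(cv$valid)
      next
    }
    expect_identical(cv$ehh[-1], oracle_ehh(h, core, carriers, dir))
    # monotone non-increasing along the curve
    expect_true(all(diff(cv$ehh) <= 0))
  }
})

test_that("iHH integration follows the inclusive-truncation trapezoid rule", {
  curve <- structure(list(pos = c(0, 10000, 20000), gmap_cm = NULL,
                          ehh = c(1, 0.5, 0.05), n_carriers = 10,
                          allele_class = "derived", direction = "right",
                          valid = TRUE), class = "ehh_curve")
  expect_equal(integrate_ihh(curve, 0.10, units = "bp"), 10250)
  expect_equal(integrate_ihh(curve, 0.10), 0.01025)  # 1 cM/Mb scaling

  # constant EHH to the chromosome end: invalid (flagged as NA)
  flat <- structure(list(pos = c(0, 1e4, 2e4), gmap_cm = NULL,
                         ehh = c(1, 1, 1), n_carriers = 10,
                         allele_class = "derived", direction = "right",
                         valid = TRUE), class = "ehh_curve")
  expect_true(is.na(integrate_ihh(flat, 0.10)))

  # inserting denser markers with linearly interpolated EHH leaves the
  # trapezoid integral unchanged
  dense <- structure(list(pos = c(0, 5000, 10000, 15000, 20000), gmap_cm = NULL,
                          ehh = c(1, 0.75, 0.5, 0.275, 0.05), n_carriers = 10,
                          allele_class = "derived", direction = "right",
                          valid = TRUE), class = "ehh_curve")
  expect_equal(integrate_ihh(dense, 0.10, units = "bp"), 10250)

  # a supplied genetic map overrides the physical 1 cM/Mb scaling
  mapped <- structure(list(pos = c(0, 10000, 20000), gmap_cm = c(0, 0.5, 0.6),
                           ehh = c(1, 0.5, 0.05), n_carriers = 10,
                           allele_class = "derived", direction = "right",
                           valid = TRUE), class = "ehh_curve")
  expect_equal(integrate_ihh(mapped, 0.10),
               0.5 * (1 + 0.5) / 2 + 0.1 * (0.5 + 0.05) / 2)
})

test_that("raw iHS is antisymmetric under ancestral/derived relabeling", {
  set.seed(12)
  h <- random_small_panel(20, 30, p_na = 0)
  fx <- panel_fixture(h)
  tr <- ihs_scan(fx$panel, fx$sites, min_maf = 0.05)
  core <- which(tr$valid)[1]
  # flip the core column: ancestral and derived classes swap
  h2 <- h
  h2[, core] <- 1L - h2[, core]
  fx2 <- panel_fixture(h2)
  tr2 <- ihs_scan(fx2$panel, fx2$sites, min_maf = 0.05)
  expect_equal(tr2$raw[core], -tr$raw[core])

  # a panel symmetric under swapping the labels scores exactly 0
  hs <- rbind(h[1:10, ], 1L - h[1:10, ])
  fxs <- panel_fixture(hs)
  trs <- ihs_scan(fxs$panel, fxs$sites, min_maf = 0.05)
  expect_true(all(abs(trs$raw[trs$valid]) < 1e-12))
})

test_that("iHS applies the MAF floor and the polarity requirement", {
  set.seed(13)
  h <- random_small_panel(50, 12, p_na = 0)
  h[, 3] <- c(1L, rep(0L, 49))               # MAF 0.02
  sites <- site_table("chr1", 1000L * (1:12), "A", "G",
                      ancestral = c(rep("A", 10), NA, NA))
  panel <- haplotype_panel(h)
  tr <- ihs_scan(panel, sites)
  expect_equal(tr$reason[3], "maf")
  expect_false(tr$valid[3])
  expect_equal(tr$reason[11], "unpolarized")
  expect_equal(tr$reason[12], "unpolarized")
})

test_that("score standardization is exact within frequency bins", {
  set.seed(14)
  n <- 4000
  track <- data.frame(chrom = "chr1", pos = seq_len(n),
                      freq_derived = runif(n, 0.02, 0.98),
                      raw = rnorm(n), valid = TRUE,
                      reason = NA_character_)
  std <- standardize_scores(track, "ihs")
  bins <- steppescan:::freq_bins(std$freq_derived, std$valid)
  for (b in unique(bins[!is.na(bins)])) {
    sel <- which(bins == b & std$valid)
    expect_gte(length(sel), 20)
    expect_lt(abs(mean(std$std[sel])), 1e-8)
    expect_lt(abs(sd(std$std[sel]) - 1), 1e-8)
  }

  # adding a constant to every raw score within a bin leaves std unchanged
  track2 <- track
  track2$raw <- track2$raw + 5
  expect_equal(standardize_scores(track2, "ihs")$std, std$std)

  # identical scores in a degenerate bin are invalidated, not divided by 0
  deg <- data.frame(chrom = "chr1", pos = 1:30, freq_derived = 0.5,
                    raw = 1, valid = TRUE, reason = NA_character_)
  out <- standardize_scores(deg, "ihs")
  expect_true(all(!out$valid))
  expect_true(all(is.na(out$std)))
})

test_that("XP-EHH is zero on identical panels and antisymmetric under swap", {
  set.seed(15)
  h <- random_small_panel(24, 40, p_na = 0)
  fx <- panel_fixture(h)
  same <- xpehh_scan(fx$panel, fx$panel, fx$sites)
  expect_true(all(abs(same$raw[same$valid]) < 1e-12))
  expect_gt(sum(same$valid), 0)

  h2 <- random_small_panel(24, 40, p_na = 0)
  p2 <- haplotype_panel(h2)
  ab <- xpehh_scan(fx$panel, p2, fx$sites)
  ba <- xpehh_scan(p2, fx$panel, fx$sites)
  expect_equal(ab$raw, -ba$raw)
})

test_that("XP-EHH concentrates positive scores at a target-only sweep", {
  sim_t <- sim_wf_haplotypes(seed = 21, n_haps = 600, n_sites = 2500,
                             chrom_length = 8e6)
  sim_r <- sim_wf_haplotypes(seed = 21, n_haps = 600, n_sites = 2500,
                             chrom_length = 8e6, s = 0)
  expect_identical(sim_t$sites$pos, sim_r$sites$pos)
  xp <- standardize_scores(xpehh_scan(sim_t$panel, sim_r$panel, sim_t$sites),
                           "xpehh")
  near <- abs(sim_t$sites$pos - sim_t$truth$core_pos) < 1e5
  expect_gt(mean(xp$std[near], na.rm = TRUE), 1)
  expect_lt(abs(mean(xp$std[!near], na.rm = TRUE)), 0.5)
})
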