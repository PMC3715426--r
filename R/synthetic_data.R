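# Seed-deterministic generators emulating the statistical structure the
# scans assume: drift-structured allele frequencies (Balding-Nichols) for
# F_ST/PBS/MR, a forward Wright-Fisher haplotype simulator with an
# optional conditioned selective sweep for the EHH family, phenotype
# simulation for the [Hb] association stage, and an MR regression testbed.
# All generators record their seed and parameters as attributes; writers
# can emit them as `#` header lines.

#' Simulation configuration
#'
#' Collects and validates generator parameters; every generator accepts
#' one (or individual arguments).  Defaults are desk-scale values chosen
#' to mimic array-SNP data: a SNP every ~3 kb with common-variant
#' ascertainment, and a recombination rate rescaled upward (1e-7 per bp
#' per generation) so that the few-hundred-generation simulated genealogy
#' reproduces the LD decay scale that a human-depth genealogy (~1e4
#' generations at 1e-8, i.e. 1 cM/Mb) would show; EHH then decays within
#' tens to a few hundred kb as in real array data.
#'
#' @param seed RNG seed recorded in all outputs.
#' @param n_pops,F,n_snps,n_per_pop Balding-Nichols block: number of
#'   populations, drift parameter in `[0,1)`, SNP count, diploid sample
#'   size per population.
#' @param n_haps,n_sites,chrom_length,rec_rate,mut_rate Haplotype block:
#'   haplotype count (even), segregating sites, chromosome length (bp),
#'   per-bp per-generation recombination rate, per-site per-haplotype
#'   per-generation mutation (toggle) rate.
#' @param n_founders,burnin_gens Founder haplotype count (the bottleneck
#'   that creates long-range LD) and neutral burn-in generations.
#' @param s,target_freq,sweep_gens,max_restarts Sweep block: selection
#'   coefficient (>= 0; 0 disables the sweep), derived target frequency
#'   at the core, generation cap for the selected phase, and the restart
#'   budget for conditioning on the target being reached.  The selected
#'   allele is injected as a single new copy at the segregating site
#'   nearest the chromosome midpoint (a hard sweep); most injections are
#'   lost to drift and restarted cheaply.
#' @param beta,hb_mean,hb_sd,age_beta Phenotype block: [Hb] shift per
#'   haplotype copy (g/dL), baseline mean and residual sd (g/dL), age
#'   effect (g/dL per year).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_pops = 2L, F = 0.10, n_snps = 50000L,
                       n_per_pop = 50L, n_haps = 1000L, n_sites = 5000L,
                       chrom_length = 15e6, rec_rate = 1e-7, mut_rate = 2e-6,
                       n_founders = 40L, burnin_gens = 60L, s = 0.05,
                       target_freq = 0.7, sweep_gens = 300L,
                       max_restarts = 500L,
                       beta = 0, hb_mean = 13.5, hb_sd = 1.4,
                       age_beta = 0.03) {
  cfg <- as.list(environment())
  if (F < 0 || F >= 1) stop("F must lie in [0,1)")
  if (s < 0) stop("s must be >= 0")
  if (rec_rate < 0 || mut_rate < 0) stop("rates must be >= 0")
  if (n_haps %% 2L != 0L) stop("n_haps must be even")
  if (n_sites < 100L) stop("need at least 100 sites")
  structure(cfg, class = "sim_config")
}

#' Balding-Nichols drift-structured frequencies and genotypes
#'
#' Per SNP an ancestral frequency is drawn uniform on (0.05, 0.95); each
#' population's frequency comes from the Beta distribution with mean p
#' and variance `F p (1-p)` (for `F = 0` the ancestral frequency is used
#' exactly); genotypes are binomial(2, freq) dosages.
#'
#' @param config A [sim_config] (or `NULL` to use the other arguments).
#' @param n_pops,F,n_snps,n_per_pop,seed Override individual parameters.
#' @return A list: `sites` ([site_table]), `freqs` (observed sample
#'   [freq_table]), `panel` ([genotype_panel]); attributes `true_freq`
#'   (population frequencies), `ancestral_freq`, `seed`.
#' @export
sim_balding_nichols <- function(config = NULL, n_pops = NULL, F = NULL,
                                n_snps = NULL, n_per_pop = NULL, seed = NULL) {
  cfg <- config %||% sim_config()
  n_pops <- n_pops %||% cfg$n_pops
  F <- F %||% cfg$F
  n_snps <- n_snps %||% cfg$n_snps
  n_per_pop <- n_per_pop %||% cfg$n_per_pop
  seed <- seed %||% cfg$seed
  set.seed(seed)
  p_anc <- runif(n_snps, 0.05, 0.95)
  pops <- sprintf("pop%d", seq_len(n_pops))
  pf <- matrix(NA_real_, n_pops, n_snps, dimnames = list(pops, NULL))
  for (k in seq_len(n_pops)) {
    if (F == 0) {
      pf[k, ] <- p_anc
    } else {
      shape <- (1 - F) / F
      pf[k, ] <- rbeta(n_snps, p_anc * shape, (1 - p_anc) * shape)
    }
  }
  geno <- matrix(NA_integer_, n_pops * n_per_pop, n_snps)
  poplab <- rep(pops, each = n_per_pop)
  for (k in seq_len(n_pops)) {
    rows <- which(poplab == pops[k])
    geno[rows, ] <- matrix(rbinom(n_per_pop * n_snps, 2L,
                                  rep(pf[k, ], each = n_per_pop)),
                           n_per_pop, n_snps)
  }
  sites <- site_table(chrom = "chr1", pos = 3000L * seq_len(n_snps),
                      ref = "A", alt = "G", ancestral = "A")
  panel <- genotype_panel(geno, poplab)
  out <- list(sites = sites, freqs = derived_freqs(panel), panel = panel)
  attr(out, "true_freq") <- pf
  attr(out, "ancestral_freq") <- p_anc
  attr(out, "seed") <- seed
  out
}

# Founder haplotypes with a uniform derived-allele count per site,
# mimicking the common-variant ascertainment of genotyping arrays (the
# neutral 1/k SFS would leave most sites below a 5% MAF floor).
make_founders <- function(n_founders, n_sites) {
  k <- sample.int(n_founders - 1L, n_sites, replace = TRUE)
  F <- matrix(0L, n_founders, n_sites)
  for (j in seq_len(n_sites))
    F[sample.int(n_founders, k[j]), j] <- 1L
  F
}

#' Forward Wright-Fisher haplotype simulation with an optional sweep
#'
#' A panel of `n_haps` haplotypes over `n_sites` SNPs evolves under
#' random mating with recombination and mutation.  The panel starts as
#' copies of a small founder set (a bottleneck that creates realistic
#' long-range LD) and is burned in neutrally; when `s > 0` the derived
#' allele at the core SNP nearest the chromosome midpoint is re-seeded as
#' a single new copy with multiplicative fitness `1 + s` (a hard sweep)
#' and the run is conditioned, by restarting the selected phase, on that
#' allele reaching `target_freq`.  Restarts reuse the burned-in panel and
#' only re-inject the mutation, so drift losses are cheap.
#'
#' @param config A [sim_config]; individual fields may be overridden via
#'   `...` (passed to [sim_config] when `config` is `NULL`).
#' @param seed Override the config seed.
#' @return A list: `sites` ([site_table], ancestral = REF by
#'   construction), `panel` ([haplotype_panel]), `truth` (core site
#'   index/position, the 200-kb window containing it, s, target, attempt
#'   count; `NULL` core for neutral runs).  Attribute `seed`.
#' @export
sim_wf_haplotypes <- function(config = NULL, seed = NULL, ...) {
  cfg <- config %||% sim_config(...)
  seed <- seed %||% cfg$seed
  set.seed(seed)
  pos <- sort(sample.int(cfg$chrom_length, cfg$n_sites))
  run_burnin <- function() {
    founders <- make_founders(cfg$n_founders, cfg$n_sites)
    init <- t(founders[sample.int(cfg$n_founders, cfg$n_haps, replace = TRUE), ,
                       drop = FALSE])  # sites x haplotypes for the C++ core
    cpp_wf_evolve(init, as.numeric(pos), cfg$rec_rate, cfg$mut_rate,
                  cfg$burnin_gens, -1L, 0, -1)$haps
  }

  core <- NA_integer_
  attempts <- 0L
  sweep_gens_used <- NA_integer_
  if (cfg$s > 0) {
    base <- run_burnin()
    core <- which.min(abs(pos - cfg$chrom_length / 2))
    repeat {
      attempts <- attempts + 1L
      if (attempts > cfg$max_restarts)
        stop("sweep failed to reach target frequency in ", cfg$max_restarts,
             " attempts")
      start <- base
      start[core, ] <- 0L                       # core becomes a de novo allele
      start[core, sample.int(cfg$n_haps, 1L)] <- 1L
      res <- cpp_wf_evolve(start, as.numeric(pos), cfg$rec_rate, cfg$mut_rate,
                           cfg$sweep_gens, core - 1L, cfg$s, cfg$target_freq,
                           abort_gen = 80L, abort_freq = 0.02)
      if (res$reached) { mat <- res$haps; sweep_gens_used <- res$generations; break }
    }
  } else {
    mat <- run_burnin()
  }

  haps <- t(mat)
  sites <- site_table(chrom = "chr1", pos = pos, ref = "A", alt = "G",
                      ancestral = "A")
  panel <- haplotype_panel(haps, population = "sim")
  truth <- if (cfg$s > 0) {
    w0 <- pos[core] %/% 200000L * 200000L
    list(core_site = core, core_pos = pos[core],
         window = c(start = w0, end = w0 + 200000L),
         s = cfg$s, target_freq = cfg$target_freq, attempts = attempts,
         sweep_generations = sweep_gens_used)
  } else NULL
  out <- list(sites = sites, panel = panel, truth = truth)
  attr(out, "seed") <- seed
  out
}

#' Simulate [Hb] phenotypes from haplotype copies
#'
#' `[Hb] = mean + beta * copies + age_beta * (age - mean age) + noise`,
#' noise Normal(0, sd).  All individuals are simulated as non-smoking
#' females aged uniformly in 16-60, mirroring the phenotype-collection
#' design the association stage expects.
#'
#' @param copy_table `data.frame` with `individual` and one or more copy
#'   columns (e.g. from [haplotype_copies]), or a numeric vector.
#' @param beta Effect per haplotype copy (g/dL); scalar or one per copy
#'   column.
#' @param hb_mean,hb_sd Baseline mean and residual sd (g/dL; sd > 0).
#' @param age_beta Age effect in g/dL per year.
#' @param seed RNG seed.
#' @return A `data.frame`: id, sex, age, hb, smoking; attribute `params`.
#' @export
sim_phenotypes <- function(copy_table, beta = 0, hb_mean = 13.5, hb_sd = 1.4,
                           age_beta = 0.03, seed = 1L) {
  if (hb_sd <= 0) stop("hb_sd must be > 0")
  if (is.numeric(copy_table))
    copy_table <- data.frame(individual = sprintf("ind%d", seq_along(copy_table)),
                             copies = copy_table)
  copies <- as.matrix(copy_table[, setdiff(colnames(copy_table),
                                           c("individual", "unknown", "flagged")),
                                 drop = FALSE])
  n <- nrow(copies)
  beta <- rep_len(beta, ncol(copies))
  set.seed(seed)
  age <- round(runif(n, 16, 60))
  hb <- hb_mean + drop(copies %*% beta) + age_beta * (age - mean(age)) +
    rnorm(n, 0, hb_sd)
  hb <- pmax(hb, 0.1)
  out <- data.frame(id = copy_table$individual, sex = "F", age = age,
                    hb = hb, smoking = "no", stringsAsFactors = FALSE)
  attr(out, "params") <- list(beta = beta, hb_mean = hb_mean, hb_sd = hb_sd,
                              age_beta = age_beta, seed = seed)
  out
}

#' Build an MR-scan testbed with known divergent SNPs
#'
#' Reference-population frequencies are Balding-Nichols draws around a
#' shared ancestral frequency; the target is a stated linear combination
#' of the references plus Normal noise; a chosen subset of SNPs receives
#' an added divergence of magnitude `delta` (random sign, clipped into
#' `[0,1]` with a warning).
#'
#' @param n_refs Number of reference populations (>= 3).
#' @param n_snps SNP count.
#' @param F Drift parameter of the reference populations.
#' @param weights Combination weights (default equal, summing to 1).
#' @param noise_sd Residual sd of the target frequency around the
#'   combination.
#' @param n_divergent,delta Number of divergent SNPs and their shift.
#' @param n_alleles Nominal allele sample count recorded in the table.
#' @param seed RNG seed.
#' @return A list: `freqs` ([freq_table], rows `target`, `ref1`, ...),
#'   `sites` ([site_table]), `truth` (divergent indices, delta, weights).
#' @export
make_mr_testbed <- function(n_refs = 6L, n_snps = 20000L, F = 0.05,
                            weights = NULL, noise_sd = 0.02,
                            n_divergent = 10L, delta = 0.3,
                            n_alleles = 100L, seed = 1L) {
  if (n_refs < 3L) stop("need at least 3 reference populations")
  weights <- weights %||% rep(1 / n_refs, n_refs)
  stopifnot(length(weights) == n_refs)
  set.seed(seed)
  p_anc <- runif(n_snps, 0.05, 0.95)
  shape <- (1 - F) / F
  refs <- matrix(NA_real_, n_refs, n_snps,
                 dimnames = list(sprintf("ref%d", seq_len(n_refs)), NULL))
  for (k in seq_len(n_refs))
    refs[k, ] <- rbeta(n_snps, p_anc * shape, (1 - p_anc) * shape)
  target <- drop(weights %*% refs) + rnorm(n_snps, 0, noise_sd)
  divergent <- sort(sample.int(n_snps, n_divergent))
  shift <- delta * sample(c(-1, 1), n_divergent, replace = TRUE)
  target[divergent] <- target[divergent] + shift
  clipped <- target < 0 | target > 1
  if (any(clipped))
    warning(sum(clipped), " target frequencies clipped into [0,1]")
  target <- pmin(pmax(target, 0), 1)
  fr <- rbind(target = target, refs)
  nn <- matrix(n_alleles, nrow(fr), n_snps, dimnames = dimnames(fr))
  sites <- site_table("chr1", 3000L * seq_len(n_snps), "A", "G", "A")
  out <- list(freqs = freq_table(fr, nn), sites = sites,
              truth = list(divergent = divergent, delta = delta,
                           weights = weights, noise_sd = noise_sd))
  attr(out, "seed") <- seed
  out
}
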