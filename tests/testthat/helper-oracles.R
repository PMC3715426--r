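# Independent oracles and fixture builders used across the suite.

# Exhaustive pair-counting EHH: for each marker outward from the core,
# EHH = (number of carrier pairs identical and non-missing over every
# site from the first flanking marker through m) / C(n_c, 2).
oracle_ehh <- function(haps, core, carriers, direction) {
  step <- if (direction == "right") 1L else -1L
  nc <- length(carriers)
  if (nc < 2L) return(numeric(0))
  pairs <- utils::combn(carriers, 2L)
  alive <- rep(TRUE, ncol(pairs))
  denom <- nc * (nc - 1) / 2
  out <- numeric(0)
  m <- core + step
  while (m >= 1L && m <= ncol(haps)) {
    a <- haps[pairs[1, ], m]
    b <- haps[pairs[2, ], m]
    alive <- alive & !is.na(a) & !is.na(b) & a == b
    out <- c(out, sum(alive) / denom)
    m <- m + step
  }
  out
}

# Random small phased panel with optional missingness.
random_small_panel <- function(n_hap, n_site, p_na = 0.05) {
  h <- matrix(rbinom(n_hap * n_site, 1L, runif(1, 0.2, 0.8)), n_hap, n_site)
  if (p_na > 0)
    h[runif(length(h)) < p_na] <- NA_integer_
  storage.mode(h) <- "integer"
  h
}

# Independent single-window greedy LD pruning for small fixtures: scan
# left to right, drop any SNP whose r^2 with a retained earlier SNP
# exceeds the threshold.
oracle_ld_keep <- function(geno, r2_max = 0.2) {
  keep <- integer(0)
  for (j in seq_len(ncol(geno))) {
    ok <- TRUE
    for (i in keep) {
      r <- suppressWarnings(cor(geno[, i], geno[, j],
                                use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 > r2_max) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, j)
  }
  keep
}

# Leave-one-out externally studentized residuals by explicit refitting.
oracle_studentized <- function(y, X) {
  n <- length(y)
  out <- numeric(n)
  for (i in seq_len(n)) {
    fit <- lm(y[-i] ~ X[-i, , drop = FALSE])
    beta <- coef(fit)
    pred <- beta[1] + drop(X[i, , drop = FALSE] %*% beta[-1])
    s2 <- sum(fit$residuals^2) / fit$df.residual
    Zi <- cbind(1, X[-i, , drop = FALSE])
    xi <- c(1, X[i, ])
    lever <- drop(t(xi) %*% solve(crossprod(Zi)) %*% xi)
    out[i] <- (y[i] - pred) / sqrt(s2 * (1 + lever))
  }
  out
}

# Random additive (ultrametric-free) tree distances: build a random
# topology with positive branch lengths via ape, return its cophenetic
# distances together with the tree.
random_additive_tree <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), 0.1, 2)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# Minimal phased VCF text fixture.
write_vcf_fixture <- function(path, body_lines, samples = c("S1", "S2")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body_lines), path)
  path
}

# Small phased panel wrapped in package containers.
panel_fixture <- function(haps, pos = NULL, chrom = "chr1") {
  pos <- pos %||% (1000L * seq_len(ncol(haps)))
  sites <- site_table(chrom, pos, "A", "G", "A")
  list(sites = sites, panel = haplotype_panel(haps))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
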