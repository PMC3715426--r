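# Population-structure computations on genotype dosages: per-population
# derived-allele frequencies, LD pruning, allele-sharing distances,
# pairwise F_ST (Hudson ratio-of-averages by default, Weir-Cockerham
# behind a flag), classical PCA from distances, and neighbor-joining.

#' Per-population derived-allele frequencies
#'
#' @param panel A [genotype_panel] or [haplotype_panel].
#' @return A [freq_table]: frequencies and allele sample counts (missing
#'   genotypes excluded from denominators; an all-missing SNP in a
#'   population yields `NA` frequency with count 0).
#' @export
derived_freqs <- function(panel) {
  if (inherits(panel, "haplotype_panel")) panel <- haplotypes_to_genotypes(panel)
  stopifnot(inherits(panel, "genotype_panel"))
  pops <- unique(panel$population)
  L <- ncol(panel$geno)
  fr <- matrix(NA_real_, length(pops), L, dimnames = list(pops, NULL))
  nn <- matrix(0L, length(pops), L, dimnames = list(pops, NULL))
  for (p in seq_along(pops)) {
    g <- panel$geno[panel$population == pops[p], , drop = FALSE]
    typed <- colSums(!is.na(g))
    if (all(typed == 0L))
      stop("population ", pops[p], " has no genotyped individuals at any SNP")
    nn[p, ] <- 2L * typed
    s <- colSums(g, na.rm = TRUE)
    fr[p, ] <- ifelse(typed > 0L, s / (2 * typed), NA_real_)
  }
  freq_table(fr, nn)
}

#' LD pruning by pairwise r-squared in sliding SNP windows
#'
#' Scans left to right in windows of `window_snps` SNPs advanced by half a
#' window; within a window, for every retained pair with squared genotype
#' correlation above `r2_max` the later SNP is dropped.  Deterministic;
#' monomorphic SNPs have r-squared defined as 0.
#'
#' @param panel A [genotype_panel] (or dosage matrix).
#' @param window_snps Window size in SNPs.
#' @param r2_max Maximum tolerated squared correlation.
#' @return Integer vector of retained site indices (increasing).
#' @export
ld_prune <- function(panel, window_snps = 50, r2_max = 0.2) {
  geno <- if (inherits(panel, "genotype_panel")) panel$geno else as.matrix(panel)
  L <- ncol(geno)
  if (L < 2L) stop("panel must have at least 2 sites")
  keep <- rep(TRUE, L)
  step <- max(1L, window_snps %/% 2L)
  starts <- seq(1L, max(1L, L - 1L), by = step)
  for (w0 in starts) {
    w1 <- min(L, w0 + window_snps - 1L)
    idx <- (w0:w1)[keep[w0:w1]]
    if (length(idx) < 2L) next
    r <- suppressWarnings(cor(geno[, idx, drop = FALSE],
                              use = "pairwise.complete.obs"))
    r[is.na(r)] <- 0  # monomorphic or no shared observations
    r2 <- r^2
    for (a in seq_along(idx)) {
      if (!keep[idx[a]]) next
      for (b in seq_along(idx)) {
        if (b <= a || !keep[idx[b]]) next
        if (r2[a, b] > r2_max) keep[idx[b]] <- FALSE
      }
    }
    if (w1 == L) break
  }
  which(keep)
}

#' Pairwise allele-sharing distance between individuals
#'
#' Per-SNP distance is `1 - shared/2`: identical genotypes 0, het vs hom
#' 0.5, opposite homozygotes 1; averaged over SNPs genotyped in both
#' individuals.
#'
#' @param panel A [genotype_panel].
#' @return Square symmetric distance matrix over individuals.
#' @export
allele_sharing_distance <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  g <- panel$geno
  n <- nrow(g)
  if (n < 2L) stop("need at least 2 individuals")
  labs <- rownames(g) %||% sprintf("ind%d", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    xi <- g[i, ]
    for (j in (i + 1L):n) {
      d <- abs(xi - g[j, ]) / 2
      ok <- !is.na(d)
      if (!any(ok))
        stop("individuals ", labs[i], " and ", labs[j],
             " share no genotyped SNPs")
      D[i, j] <- D[j, i] <- mean(d[ok])
    }
  }
  D
}

# Hudson per-SNP F_ST components (Bhatia et al. ratio-of-averages form).
hudson_components <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = num, den = den)
}

# Weir-Cockerham two-population theta components (no inbreeding term).
wc_components <- function(p1, p2, n1, n2) {
  # n1, n2 are allele counts; WC formulas use individuals-equivalents n/2?
  # Work on allele counts directly (haploid-sample form of the estimator).
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- 0  # haploid-allele form: no heterozygosity correction term
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  list(num = a, den = a + b)
}

#' Pairwise F_ST between populations
#'
#' Hudson's estimator in ratio-of-averages form by default: the mean over
#' SNPs of the sample-size-corrected numerator divided by the mean of the
#' between-population heterozygosity.  SNPs with undefined frequency in
#' either population are excluded from that pair.
#'
#' @param ft A [freq_table].
#' @param estimator `"hudson"` (default) or `"wc"` (Weir-Cockerham).
#' @return Symmetric matrix of pairwise F_ST values (zero diagonal).
#' @export
pairwise_fst <- function(ft, estimator = c("hudson", "wc")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(ft, "freq_table"))
  pops <- rownames(ft$freq)
  if (length(pops) < 2L) stop("need at least 2 populations")
  P <- length(pops)
  for (p in seq_len(P))
    if (all(ft$n[p, ] <= 1)) stop("population ", pops[p], " has sample size <= 1")
  M <- matrix(0, P, P, dimnames = list(pops, pops))
  comp <- if (estimator == "hudson") hudson_components else wc_components
  for (i in seq_len(P - 1L)) {
    for (j in (i + 1L):P) {
      p1 <- ft$freq[i, ]; p2 <- ft$freq[j, ]
      n1 <- ft$n[i, ]; n2 <- ft$n[j, ]
      ok <- !is.na(p1) & !is.na(p2) & n1 > 1 & n2 > 1
      if (!any(ok))
        stop("no jointly defined SNPs for ", pops[i], " and ", pops[j])
      cc <- comp(p1[ok], p2[ok], n1[ok], n2[ok])
      M[i, j] <- M[j, i] <- mean(cc$num) / mean(cc$den)
    }
  }
  M
}

#' Classical PCA (metric MDS) from a distance matrix
#'
#' Double-centering plus eigendecomposition; variance explained is
#' reported per axis as a percentage of the total positive-eigenvalue
#' mass.
#'
#' @param D Square symmetric distance matrix.
#' @param k Number of axes requested (truncated with a warning if it
#'   exceeds the number of positive eigenvalues).
#' @return List with `coords` (n x k matrix), `var_explained`
#'   (percentages, non-increasing), and `eig` (all eigenvalues).
#' @export
pca_from_distances <- function(D, k = 2) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  mds <- cmdscale(as.dist(D), k = min(k, nrow(D) - 1L), eig = TRUE)
  pos <- mds$eig[mds$eig > 1e-12 * max(abs(mds$eig))]
  if (k > length(pos)) {
    warning("k = ", k, " exceeds the ", length(pos),
            " positive eigenvalue(s); truncating")
    k <- length(pos)
  }
  coords <- mds$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- sprintf("PC%d", seq_len(k))
  ve <- 100 * pos[seq_len(k)] / sum(pos)
  list(coords = coords, var_explained = ve, eig = mds$eig)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}) with two determinism /
#' sanity post-passes: taxa are canonically ordered by label before
#' joining, and any negative branch length is clamped to zero with the
#' deficit moved onto its sibling branch so sums across the parent node
#' are preserved.
#'
#' @param D Square symmetric distance matrix with labelled rows.
#' @return An `ape::phylo` unrooted tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-10)) stop("distance matrix must be symmetric")
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  labs <- rownames(D) %||% sprintf("t%d", seq_len(nrow(D)))
  rownames(D) <- colnames(D) <- labs
  ord <- order(labs)
  D <- D[ord, ord]
  tr <- ape::nj(as.dist(D))
  # clamp negative branches: zero the edge, move the deficit to a sibling
  repeat {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    e <- neg[which.min(tr$edge.length[neg])]
    parent <- tr$edge[e, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), e)
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sibs)) {
      s <- sibs[which.min(tr$edge[sibs, 2])]
      tr$edge.length[s] <- tr$edge.length[s] + deficit
    }
  }
  tr
}
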