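# Population branch statistic.  F_ST values are transformed into
# divergence times T = -ln(1 - F_ST); the branch length private to the
# target population A against references B and C is
# PBS = (T_AB + T_AC - T_BC) / 2.

FST_CLAMP_EPS <- 1e-9

#' Population branch statistic from three F_ST values
#'
#' `PBS = (T_ab + T_ac - T_bc) / 2` with `T = -ln(1 - F)`.  Inputs are
#' clamped into `[0, 1 - 1e-9]` (negative estimator values to 0) before
#' the log.  Vectorized.
#'
#' @param f_ab,f_ac F_ST between the target and each reference.
#' @param f_bc F_ST between the two references.
#' @return PBS value(s); negative values are legal.
#' @export
pbs_from_fst <- function(f_ab, f_ac, f_bc) {
  if (!all(is.finite(f_ab), is.finite(f_ac), is.finite(f_bc)))
    stop("non-finite F_ST input")
  tt <- function(f) -log(1 - pmin(pmax(f, 0), 1 - FST_CLAMP_EPS))
  (tt(f_ab) + tt(f_ac) - tt(f_bc)) / 2
}

# single-SNP Hudson F_ST (sample-size corrected), NA when the denominator
# vanishes (both populations fixed for the same allele)
fst_single_snp <- function(p1, p2, n1, n2) {
  cc <- hudson_components(p1, p2, n1, n2)
  ifelse(cc$den > 0, cc$num / cc$den, NA_real_)
}

#' Per-SNP PBS scan
#'
#' Computes the three single-SNP Hudson F_ST values per SNP, clamps them,
#' transforms to branch lengths, and combines into PBS.  SNPs with an
#' undefined frequency (or empty sample) in any of the three populations,
#' or with all three pairs degenerate, are flagged invalid.
#'
#' @param ft A [freq_table] containing the three populations.
#' @param target,ref1,ref2 Population labels (rows of `ft`).
#' @param sites Optional [site_table] supplying chrom/pos columns.
#' @return A `data.frame` (PBS track): per SNP the three F_ST values,
#'   branch lengths, `pbs`, and `valid`.
#' @export
pbs_scan <- function(ft, target, ref1, ref2, sites = NULL) {
  stopifnot(inherits(ft, "freq_table"))
  pops <- c(target, ref1, ref2)
  if (length(unique(pops)) < 3L || !all(pops %in% rownames(ft$freq)))
    stop("need three distinct populations present in the frequency table")
  p <- ft$freq[pops, , drop = FALSE]
  n <- ft$n[pops, , drop = FALSE]
  ok <- colSums(is.na(p)) == 0L & colSums(n <= 1) == 0L
  f_ab <- f_ac <- f_bc <- rep(NA_real_, ncol(p))
  f_ab[ok] <- fst_single_snp(p[1, ok], p[2, ok], n[1, ok], n[2, ok])
  f_ac[ok] <- fst_single_snp(p[1, ok], p[3, ok], n[1, ok], n[3, ok])
  f_bc[ok] <- fst_single_snp(p[2, ok], p[3, ok], n[2, ok], n[3, ok])
  valid <- ok & !is.na(f_ab) & !is.na(f_ac) & !is.na(f_bc)
  tt <- function(f) -log(1 - pmin(pmax(f, 0), 1 - FST_CLAMP_EPS))
  pbs <- rep(NA_real_, ncol(p))
  pbs[valid] <- pbs_from_fst(f_ab[valid], f_ac[valid], f_bc[valid])
  out <- data.frame(fst_t_r1 = f_ab, fst_t_r2 = f_ac, fst_r1_r2 = f_bc,
                    t_t_r1 = ifelse(valid, tt(f_ab), NA_real_),
                    t_t_r2 = ifelse(valid, tt(f_ac), NA_real_),
                    t_r1_r2 = ifelse(valid, tt(f_bc), NA_real_),
                    pbs = pbs, valid = valid)
  if (!is.null(sites))
    out <- cbind(data.frame(chrom = sites$chrom, pos = sites$pos,
                            stringsAsFactors = FALSE), out)
  out
}
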