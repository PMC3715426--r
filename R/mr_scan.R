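# Multiple-regression divergence scan.  The target population's
# derived-allele frequencies are regressed (OLS, intercept included) on
# the frequencies of a set of reference populations, SNPs being the
# observations.  The MR Score of a SNP is the externally studentized
# residual of observed vs predicted frequency; gene-level MR Factors
# measure enrichment of tail-scoring SNPs in a gene's span (transcribed
# region plus a 10-kb flank) relative to all gene regions.

#' Fit the MR frequency-prediction model
#'
#' @param target_freqs Numeric vector of target-population frequencies
#'   (one per SNP; `NA` allowed, such SNPs are skipped).
#' @param reference_freq_matrix SNPs x reference-populations matrix of
#'   frequencies.
#' @return A list of class `mr_model`: `coefficients`, `fitted`,
#'   `residuals`, `scores` (externally studentized residuals, `NA` at
#'   skipped SNPs), `used` (logical per SNP).
#' @export
fit_mr_model <- function(target_freqs, reference_freq_matrix) {
  X <- as.matrix(reference_freq_matrix)
  y <- as.numeric(target_freqs)
  stopifnot(nrow(X) == length(y))
  if (is.null(colnames(X))) colnames(X) <- sprintf("ref%d", seq_len(ncol(X)))
  used <- !is.na(y) & rowSums(is.na(X)) == 0L
  if (sum(used) < ncol(X) + 2L)
    stop("need at least ", ncol(X) + 2L, " SNPs with defined frequencies")
  Xu <- X[used, , drop = FALSE]
  Z <- cbind(`(Intercept)` = 1, Xu)
  qrx <- qr(Z)
  if (qrx$rank < ncol(Z)) {
    aliased <- colnames(Z)[qrx$pivot[(qrx$rank + 1L):ncol(Z)]]
    stop("collinear reference columns: ", paste(aliased, collapse = ", "))
  }
  dat <- data.frame(.y = y[used], Xu, check.names = FALSE)
  fit <- lm(.y ~ ., data = dat)
  scores <- fitted <- resid <- rep(NA_real_, length(y))
  sigma <- sqrt(sum(fit$residuals^2) / fit$df.residual)
  if (sigma < 1e-12) {
    scores[used] <- 0  # exact fit: every residual is 0, so is every score
  } else {
    scores[used] <- rstudent(fit)
  }
  fitted[used] <- fit$fitted.values
  resid[used] <- fit$residuals
  structure(list(coefficients = coef(fit), fitted = fitted,
                 residuals = resid, scores = scores, used = used,
                 model = fit),
            class = "mr_model")
}

#' Gene-level MR Factors
#'
#' A SNP belongs to a gene region when it falls within the transcribed
#' span extended by `flank` bp on either side (clipped at position 0).
#' Tail membership is two-sided on `|MR Score|`: for tail level `q`, the
#' SNPs whose absolute score reaches the upper `q`-quantile of all
#' gene-region SNP scores.  Per gene and level,
#' `MR Factor = (gene tail proportion) / (all-gene-region tail proportion)`.
#'
#' @param mr_scores Numeric vector of MR Scores (one per SNP; `NA` for
#'   SNPs not scored).
#' @param genes A [gene_annotation].
#' @param sites The [site_table] positioning the scores.
#' @param tail_levels Tail levels of the score distribution.
#' @param flank Flank in bp added to each side of the transcribed span.
#' @return A `data.frame` of class `mr_factor_table`: gene, level,
#'   n_snps, n_tail, factor.
#' @export
mr_factor <- function(mr_scores, genes, sites,
                      tail_levels = c(0.05, 0.01, 0.005), flank = 10000) {
  stopifnot(length(mr_scores) == nrow(sites))
  scored <- which(!is.na(mr_scores))
  span_start <- pmax(genes$start - flank, 0L)  # 0-based half-open
  span_end <- genes$end + flank
  gr_genes <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(span_start + 1L, span_end))
  gr_snps <- GenomicRanges::GRanges(sites$chrom[scored],
                                    IRanges::IRanges(sites$pos[scored], width = 1L))
  hits <- GenomicRanges::findOverlaps(gr_snps, gr_genes)
  snp_of <- scored[S4Vectors::queryHits(hits)]
  gene_of <- S4Vectors::subjectHits(hits)

  empty <- setdiff(seq_len(nrow(genes)), unique(gene_of))
  if (length(empty))
    message(length(empty), " gene(s) with no scored SNPs excluded")

  region_snps <- sort(unique(snp_of))  # each SNP counted once globally
  abs_all <- abs(mr_scores[region_snps])
  out <- list()
  for (q in tail_levels) {
    thr <- quantile(abs_all, probs = 1 - q, names = FALSE, type = 7)
    in_tail <- abs(mr_scores) >= thr
    global_prop <- mean(in_tail[region_snps])
    for (g in setdiff(seq_len(nrow(genes)), empty)) {
      sel <- unique(snp_of[gene_of == g])
      n_tail <- sum(in_tail[sel])
      out[[length(out) + 1L]] <-
        data.frame(gene = genes$gene[g], level = q, n_snps = length(sel),
                   n_tail = n_tail,
                   factor = (n_tail / length(sel)) / global_prop,
                   stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("mr_factor_table", "data.frame")
  res
}

#' Empirical p-values for gene-level MR Factors
#'
#' Within each tail level, genes with at least `min_snps` scored SNPs are
#' ranked by MR Factor (row order ties broken by gene tail count, then by
#' label); the empirical p of a gene is its maximum rank among genes with
#' an equal factor divided by the number of ranked genes, and genes with
#' `p <= top_fraction` are flagged.
#'
#' @param factor_table An `mr_factor_table` from [mr_factor].
#' @param min_snps Minimum scored SNPs for a gene to be ranked.
#' @param top_fraction Candidate flagging threshold on the empirical p.
#' @return The eligible rows, ordered, with `p` and `candidate` columns.
#' @export
mr_gene_pvalues <- function(factor_table, min_snps = 10, top_fraction = 0.02) {
  ft <- factor_table[factor_table$n_snps >= min_snps, , drop = FALSE]
  res <- list()
  for (q in unique(ft$level)) {
    sub <- ft[ft$level == q, , drop = FALSE]
    if (nrow(sub) < 50L)
      warning("only ", nrow(sub), " eligible genes at level ", q,
              "; the top ", 100 * top_fraction, "% may be empty")
    ord <- order(-sub$factor, -sub$n_tail, sub$gene)
    sub <- sub[ord, , drop = FALSE]
    n <- nrow(sub)
    # maximum rank among genes sharing the factor value (conservative p)
    maxrank <- vapply(sub$factor, function(f) sum(sub$factor >= f), 0L)
    sub$p <- maxrank / n
    sub$candidate <- sub$p <= top_fraction
    res[[as.character(q)]] <- sub
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
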