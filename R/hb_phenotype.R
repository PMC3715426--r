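# Hemoglobin genotype-phenotype stage: two-sample t-tests reconstructed
# from published group summaries, counting copies of a selected core-SNP
# haplotype per individual, and stepwise linear regression of [Hb] on
# per-region haplotype copies.

#' Group summary for a summary-level t-test
#'
#' @param label Group label.
#' @param mean Group mean (e.g. [Hb] in g/dL).
#' @param sd Group standard deviation.
#' @param n Group size (>= 2).
#' @return A list of class `group_summary`.
#' @export
group_summary <- function(label, mean, sd, n) {
  if (sd < 0) stop("sd must be >= 0")
  if (n < 2) stop("n must be >= 2 in group ", label)
  structure(list(label = label, mean = mean, sd = sd, n = n),
            class = "group_summary")
}

#' Two-sample t-test from group summaries
#'
#' Welch (default) uses the Welch-Satterthwaite degrees of freedom;
#' `"pooled"` assumes equal variances with `n1 + n2 - 2` df.  Two-sided p.
#'
#' @param g1,g2 [group_summary] objects (or lists with mean/sd/n).
#' @param method `"welch"` or `"pooled"`.
#' @return A list: t, df, p.
#' @export
ttest_from_summary <- function(g1, g2, method = c("welch", "pooled")) {
  method <- match.arg(method)
  if (g1$n < 2 || g2$n < 2) stop("both groups need n >= 2")
  d <- g1$mean - g2$mean
  if (method == "welch") {
    v1 <- g1$sd^2 / g1$n
    v2 <- g2$sd^2 / g2$n
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  } else {
    sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / (g1$n + g2$n - 2)
    se <- sqrt(sp2 * (1 / g1$n + 1 / g2$n))
    df <- g1$n + g2$n - 2
  }
  t <- if (se == 0) 0 else d / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Count copies of a selected core-SNP haplotype per individual
#'
#' The selected haplotype is defined by the alleles at three core SNPs; an
#' individual's copy number (0-2) is the number of its phased haplotypes
#' matching the selected allele at all three.  A haplotype with a missing
#' allele at any core SNP contributes "unknown" and flags the individual.
#'
#' @param panel A phased [haplotype_panel].
#' @param sites The matching [site_table].
#' @param core_pos Positions (1-based bp) of the three core SNPs; a
#'   position absent from `sites` is an error naming it.
#' @param selected_alleles Alleles (0/1 on the panel coding) defining the
#'   selected haplotype, one per core SNP.
#' @param chrom Optional chromosome label to disambiguate positions.
#' @return A `data.frame`: individual, copies (known matches), unknown
#'   (haplotypes unresolvable), flagged.
#' @export
haplotype_copies <- function(panel, sites, core_pos, selected_alleles,
                             chrom = NULL) {
  stopifnot(length(core_pos) == length(selected_alleles))
  idx <- vapply(core_pos, function(p) {
    hit <- which(sites$pos == p & (is.null(chrom) | sites$chrom == (chrom %||% sites$chrom)))
    if (!length(hit)) stop("core SNP at position ", p, " absent from panel")
    hit[1]
  }, 0L)
  H <- panel$haps[, idx, drop = FALSE]
  match_row <- rowSums(H == rep(selected_alleles, each = nrow(H))) ==
    length(idx)
  unknown_row <- rowSums(is.na(H)) > 0L
  inds <- unique(panel$individual)
  out <- data.frame(individual = inds, copies = 0L, unknown = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(inds)) {
    rows <- which(panel$individual == inds[i])
    out$unknown[i] <- sum(unknown_row[rows])
    out$copies[i] <- sum(match_row[rows] & !unknown_row[rows], na.rm = TRUE)
  }
  out$flagged <- out$unknown > 0L
  out
}

#' Stepwise linear regression with forward selection / backward elimination
#'
#' Forward step: among candidate predictors not in the model, add the one
#' with the smallest partial-F p-value if it is below `p_enter` (ties by
#' column order).  Backward step: drop the selected term with the largest
#' partial-F p-value above `p_remove`.  Iterates to convergence;
#' deterministic.  `covariates` are always kept in the model.
#'
#' @param phenotype Numeric response vector.
#' @param predictor_table `data.frame`/matrix of candidate predictors
#'   (e.g. per-region haplotype copies).
#' @param p_enter,p_remove Entry / removal thresholds.
#' @param covariates Optional `data.frame` of forced-in covariates.
#' @return A list: `selected` (character), `model` (`lm` fit on the final
#'   terms), `coefficients`, `p_values` (partial-F p per selected term).
#' @export
stepwise_regression <- function(phenotype, predictor_table,
                                p_enter = 0.05, p_remove = 0.10,
                                covariates = NULL) {
  X <- as.data.frame(predictor_table)
  if (ncol(X) > 0 && is.null(colnames(predictor_table)))
    colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  dat <- data.frame(.y = phenotype, X, check.names = FALSE)
  forced <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    forced <- colnames(covariates)
    dat <- cbind(dat, covariates)
  }
  cc <- complete.cases(dat)
  if (!any(cc)) stop("no complete cases")
  dat <- dat[cc, , drop = FALSE]
  candidates <- colnames(X)
  selected <- character(0)

  fit_terms <- function(terms) {
    rhs <- if (length(c(forced, terms))) paste(sprintf("`%s`", c(forced, terms)),
                                               collapse = " + ") else "1"
    lm(as.formula(paste(".y ~", rhs)), data = dat)
  }
  partial_p <- function(fit, term) {
    a <- drop1(fit, scope = as.formula(paste("~", sprintf("`%s`", term))),
               test = "F")
    a[["Pr(>F)"]][2]
  }

  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 100L) break  # cycling guard; practically unreachable
    changed <- FALSE
    # forward
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      fit0 <- fit_terms(selected)
      pvals <- vapply(pool, function(tm) {
        a <- add1(fit0, scope = as.formula(paste("~ . +", sprintf("`%s`", tm))),
                  test = "F")
        a[["Pr(>F)"]][2]
      }, 0)
      best <- which.min(pvals)  # first index on ties = column order
      if (is.finite(pvals[best]) && pvals[best] < p_enter) {
        selected <- c(selected, pool[best])
        changed <- TRUE
      }
    }
    # backward
    if (length(selected)) {
      fit1 <- fit_terms(selected)
      pv <- vapply(selected, function(tm) partial_p(fit1, tm), 0)
      worst <- which.max(pv)
      if (is.finite(pv[worst]) && pv[worst] > p_remove) {
        selected <- selected[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  fit <- fit_terms(selected)
  pvals <- if (length(selected))
    vapply(selected, function(tm) partial_p(fit, tm), 0) else numeric(0)
  list(selected = selected, model = fit, coefficients = coef(fit),
       p_values = pvals, n = nrow(dat))
}
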