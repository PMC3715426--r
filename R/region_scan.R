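# 200-kb region aggregation of per-SNP score tracks, genome-wide empirical
# p-values, candidate calling at the 0.02 level, and the
# independence-null simulation for cross-population candidate overlap.

#' Tile chromosomes into fixed-width windows
#'
#' Windows are 0-based half-open `[0,w), [w,2w), ...` anchored at position
#' 0 on every chromosome; a final partial window is retained and flagged.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param width Window width in bp (default 200,000).
#' @return A `data.frame`: chrom, start, end, partial.
#' @export
tile_windows <- function(chrom_lengths, width = 200000) {
  stopifnot(all(chrom_lengths > 0))
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- sprintf("chr%d", seq_along(chrom_lengths))
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = width)
    ends <- pmin(starts + width, len)
    data.frame(chrom = ch, start = as.integer(starts), end = as.integer(ends),
               partial = ends - starts < width, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Region test statistics over tiled windows
#'
#' `mode = "max"` (XP-EHH / PBS): the maximum valid score in each window;
#' windows without any valid SNP are excluded.  `mode = "ihs_fraction"`:
#' the fraction of valid SNPs with `|score| > abs_threshold`; windows with
#' fewer than `min_snps` valid SNPs are excluded.  A SNP with 1-based
#' position p is assigned to the window with `start <= p < end`
#' (`floor(p / width)`), so the boundary SNP at p = width falls in the
#' second window.
#'
#' @param track A score track with chrom, pos, valid, and a score column
#'   (`std` when present, else `raw` or `pbs`).
#' @param windows Window table from [tile_windows].
#' @param mode `"max"` or `"ihs_fraction"`.
#' @param min_snps Minimum valid SNPs per window in `ihs_fraction` mode.
#' @param abs_threshold |score| threshold in `ihs_fraction` mode.
#' @param score_col Name of the score column; default picks `std`, then
#'   `pbs`, then `raw`.
#' @param use_abs In `max` mode, take the maximum of |score| instead of
#'   the signed maximum.
#' @return The window table with `n_snps`, `stat`, `scored` columns.
#' @export
region_statistics <- function(track, windows, mode = c("max", "ihs_fraction"),
                              min_snps = 5, abs_threshold = 2.0,
                              score_col = NULL, use_abs = FALSE) {
  mode <- match.arg(mode)
  score_col <- score_col %||%
    intersect(c("std", "pbs", "raw"), colnames(track))[1]
  if (is.na(score_col)) stop("no score column found in track")
  sc <- track[[score_col]]
  ok <- track$valid & !is.na(sc)
  win_id <- rep(NA_integer_, nrow(track))
  for (ch in unique(windows$chrom)) {
    wsel <- which(windows$chrom == ch)
    tsel <- which(track$chrom == ch & ok)
    if (!length(tsel)) next
    idx <- findInterval(track$pos[tsel], windows$start[wsel])
    inside <- idx >= 1L & track$pos[tsel] < windows$end[wsel][pmax(idx, 1L)]
    win_id[tsel[inside]] <- wsel[idx[inside]]
  }
  n_snps <- integer(nrow(windows))
  stat <- rep(NA_real_, nrow(windows))
  tab <- table(factor(win_id, levels = seq_len(nrow(windows))))
  n_snps <- as.integer(tab)
  for (w in which(n_snps > 0L)) {
    s <- sc[which(win_id == w)]
    stat[w] <- if (mode == "max") {
      if (use_abs) max(abs(s)) else max(s)
    } else {
      mean(abs(s) > abs_threshold)
    }
  }
  scored <- if (mode == "ihs_fraction") n_snps >= min_snps else n_snps > 0L
  stat[!scored] <- NA_real_
  cbind(windows, data.frame(n_snps = n_snps, stat = stat, scored = scored))
}

#' Empirical p-values and candidate flags for scored regions
#'
#' One-sided high empirical p: the fraction of scored regions genome-wide
#' whose statistic is at least the observed one (ties share the maximal
#' count, so equal statistics share a p and all-equal statistics give
#' p = 1).  A region is a candidate when `p < alpha`.
#'
#' @param region_table Output of [region_statistics].
#' @param alpha Candidate significance level (default 0.02).
#' @return The table with `p` and `candidate` columns (NA for unscored
#'   regions).
#' @export
empirical_p_candidates <- function(region_table, alpha = 0.02) {
  sc <- which(region_table$scored)
  if (!length(sc)) stop("no scored regions")
  st <- region_table$stat[sc]
  p <- vapply(st, function(x) mean(st >= x), 0)
  region_table$p <- NA_real_
  region_table$p[sc] <- p
  region_table$candidate <- NA
  region_table$candidate[sc] <- p < alpha
  region_table
}

#' Cross-population candidate overlap against an independence null
#'
#' Observed statistic: the number of regions shared by every candidate
#' set.  Null: each simulation redraws, for each population, a uniform
#' random subset of the region universe of that population's candidate
#' count, and records the intersection size.  The p-value uses the
#' add-one convention `(r + 1) / (n_sims + 1)` so it is never zero.
#'
#' @param candidate_sets List of candidate region index vectors (or any
#'   identifiers drawn from a universe of `n_regions` coded 1..n).
#' @param n_regions Size of the region universe.
#' @param n_sims Number of simulations (default 100,000).
#' @param seed Optional RNG seed recorded in the result.
#' @return A list of class `overlap_result`: observed, expectation, sd,
#'   p, n_sims, seed.
#' @export
overlap_and_null <- function(candidate_sets, n_regions, n_sims = 100000,
                             seed = NULL) {
  k <- vapply(candidate_sets, length, 0L)
  if (any(k > n_regions))
    stop("candidate count exceeds the region universe")
  if (!is.null(seed)) set.seed(seed)
  observed <- length(Reduce(intersect, candidate_sets))
  npop <- length(candidate_sets)
  sims <- integer(n_sims)
  for (s in seq_len(n_sims)) {
    cnt <- tabulate(unlist(lapply(k, function(ki) sample.int(n_regions, ki))),
                    n_regions)
    sims[s] <- sum(cnt == npop)
  }
  structure(list(observed = observed, expectation = mean(sims),
                 sd = sd(sims),
                 p = (sum(sims >= observed) + 1) / (n_sims + 1),
                 n_sims = n_sims, seed = seed, sims_summary = table(sims)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: observed %d shared regions; null expectation %.3f (sd %.3f); p = %.3g [%d sims]\n",
              x$observed, x$expectation, x$sd, x$p, x$n_sims))
  invisible(x)
}
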