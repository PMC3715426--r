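# EHH-family statistics.  EHH at marker m, among the n_c carriers of a core
# allele class, is sum_h C(n_h,2) / C(n_c,2) over the distinct extended
# haplotypes h spanning core..m; a missing allele breaks identity.  iHH is
# the trapezoidal integral of the decay curve out to (and including) the
# first marker at or below the truncation threshold, summed over both
# directions.  iHS = ln(iHH_ancestral / iHH_derived), standardized within
# derived-allele-frequency bins; XP-EHH = ln(iHH_target / iHH_reference)
# on unsplit panels, truncated where the pooled-panel EHH drops to 0.05,
# standardized genome-wide.

carrier_rows <- function(haps, core, allele_class) {
  switch(allele_class,
         derived = which(!is.na(haps[, core]) & haps[, core] == 1L),
         ancestral = which(!is.na(haps[, core]) & haps[, core] == 0L),
         combined = seq_len(nrow(haps)),
         stop("unknown allele class '", allele_class, "'"))
}

#' EHH decay curve on one side of a core SNP
#'
#' @param panel A [haplotype_panel].
#' @param sites The matching [site_table].
#' @param core_site Site index (column) of the core SNP.
#' @param allele_class `"derived"`, `"ancestral"`, or `"combined"` (no
#'   allele split; used by XP-EHH).
#' @param direction `"left"` or `"right"` of the core.
#' @param truncate Stop extending once EHH falls to this value (the
#'   stopping marker is included); `NULL` returns the full side.
#' @param max_markers Optional hard bound on the number of flanking
#'   markers visited (used by XP-EHH to integrate all panels over the
#'   pooled-panel truncation span).
#' @return A list of class `ehh_curve`: `pos` (bp, first entry the core),
#'   `gmap_cm` (when the site table has a map), `ehh` (first entry 1),
#'   `n_carriers`, `valid` (`FALSE` when there are fewer than 2 carriers).
#' @export
ehh_curve <- function(panel, sites, core_site,
                      allele_class = c("derived", "ancestral", "combined"),
                      direction = c("right", "left"), truncate = NULL,
                      max_markers = NULL) {
  allele_class <- match.arg(allele_class)
  direction <- match.arg(direction)
  carriers <- carrier_rows(panel$haps, core_site, allele_class)
  step <- if (direction == "right") 1L else -1L
  if (length(carriers) < 2L) {
    return(structure(list(pos = sites$pos[core_site], gmap_cm = NULL,
                          ehh = 1, n_carriers = length(carriers),
                          allele_class = allele_class, direction = direction,
                          valid = FALSE), class = "ehh_curve"))
  }
  e <- cpp_ehh_side(panel$haps, core_site - 1L, carriers - 1L, step,
                    if (is.null(truncate)) -1 else truncate,
                    if (is.null(max_markers)) -1L else as.integer(max_markers))
  idx <- core_site + step * (0:length(e))
  idx <- idx[idx >= 1L & idx <= nrow(sites)]
  structure(list(pos = sites$pos[idx],
                 gmap_cm = if (!is.null(sites$gmap_cm)) sites$gmap_cm[idx] else NULL,
                 ehh = c(1, e), n_carriers = length(carriers),
                 allele_class = allele_class, direction = direction,
                 valid = TRUE), class = "ehh_curve")
}

# Trapezoidal area over |distance| with an explicit stopping index
# (inclusive); distances in cM.
trapz_to <- function(dist_cm, ehh, stop_idx) {
  if (stop_idx < 2L) return(0)
  d <- abs(diff(dist_cm[seq_len(stop_idx)]))
  sum(d * (head(ehh[seq_len(stop_idx)], -1) + tail(ehh[seq_len(stop_idx)], -1)) / 2)
}

curve_dist_cm <- function(curve, units = "cM") {
  if (units == "bp") return(as.numeric(curve$pos))
  if (!is.null(curve$gmap_cm)) curve$gmap_cm else curve$pos * 1e-6  # 1 cM/Mb
}

#' Integrate an EHH curve into an iHH value
#'
#' Trapezoidal integral of EHH over genetic distance from the core up to
#' and including the first marker whose EHH is at or below `truncation`;
#' no interpolation beyond observed markers.  Distance is in cM when the
#' site table carries a genetic map, otherwise physical distance scaled at
#' 1 cM/Mb.
#'
#' @param curve An [ehh_curve].
#' @param truncation Decay threshold (0.10 for iHS, 0.05 for XP-EHH).
#' @param units `"cM"` (default) or `"bp"` (unscaled physical distance).
#' @return iHH scalar, or `NA` when the curve never decays to the
#'   threshold before the chromosome end (site invalid) or the curve
#'   itself is invalid.
#' @export
integrate_ihh <- function(curve, truncation = 0.10, units = c("cM", "bp")) {
  units <- match.arg(units)
  if (!isTRUE(curve$valid)) return(NA_real_)
  hit <- which(curve$ehh <= truncation)
  if (!length(hit)) return(NA_real_)
  trapz_to(curve_dist_cm(curve, units), curve$ehh, hit[1])
}

ihh_both_sides <- function(panel, sites, core, allele_class, truncation) {
  l <- ehh_curve(panel, sites, core, allele_class, "left", truncate = truncation)
  r <- ehh_curve(panel, sites, core, allele_class, "right", truncate = truncation)
  if (!l$valid || !r$valid) return(NA_real_)
  il <- integrate_ihh(l, truncation)
  ir <- integrate_ihh(r, truncation)
  il + ir
}

#' Genome scan of raw iHS scores
#'
#' For every polarized site passing the MAF floor, integrates EHH decay in
#' both directions for each core allele class and reports
#' `ln(iHH_ancestral / iHH_derived)`.  Sites failing the MAF, polarity,
#' carrier-count, or decay checks are flagged invalid (never dropped from
#' the table).
#'
#' @param panel A [haplotype_panel] (ancestral/derived coded).
#' @param sites The matching [site_table]; sites with unknown ancestral
#'   state are invalid for iHS.
#' @param min_maf Minor-allele-frequency floor (default 0.05).
#' @param truncation EHH decay threshold (default 0.10).
#' @return A score-track `data.frame`: chrom, pos, freq_derived, raw,
#'   valid, reason.
#' @export
ihs_scan <- function(panel, sites, min_maf = 0.05, truncation = 0.10) {
  L <- ncol(panel$haps)
  stopifnot(nrow(sites) == L)
  raw <- rep(NA_real_, L)
  reason <- rep(NA_character_, L)
  p_der <- colMeans(panel$haps, na.rm = TRUE)
  polarized <- !is.na(sites$ancestral)
  for (j in seq_len(L)) {
    if (!polarized[j]) { reason[j] <- "unpolarized"; next }
    maf <- min(p_der[j], 1 - p_der[j])
    if (is.na(maf) || maf < min_maf) { reason[j] <- "maf"; next }
    ihh_a <- ihh_both_sides(panel, sites, j, "ancestral", truncation)
    ihh_d <- ihh_both_sides(panel, sites, j, "derived", truncation)
    if (is.na(ihh_a) || is.na(ihh_d)) { reason[j] <- "no_decay"; next }
    if (ihh_a <= 0 || ihh_d <= 0) { reason[j] <- "zero_ihh"; next }
    raw[j] <- log(ihh_a / ihh_d)
  }
  data.frame(chrom = sites$chrom, pos = sites$pos, freq_derived = p_der,
             raw = raw, valid = !is.na(raw), reason = reason,
             stringsAsFactors = FALSE)
}

# Derived-frequency bin assignment: fixed-width bins over (0,1), bins with
# fewer than `min_bin` valid scores merged into their right neighbour
# (the last occupied bin merges leftward), repeated until stable.
freq_bins <- function(freq, valid, bin_width = 0.025, min_bin = 20) {
  edges <- seq(0, 1, by = bin_width)
  bin <- findInterval(freq, edges, rightmost.closed = TRUE, left.open = TRUE)
  bin[!valid] <- NA_integer_
  repeat {
    occupied <- sort(unique(bin[!is.na(bin)]))
    if (length(occupied) <= 1L) break
    cnt <- table(factor(bin, levels = occupied))
    small <- occupied[cnt < min_bin]
    if (!length(small)) break
    b <- small[1]
    nb <- occupied[occupied > b]
    to <- if (length(nb)) nb[1] else occupied[max(which(occupied < b))]
    bin[!is.na(bin) & bin == b] <- to
  }
  bin
}

#' Standardize raw haplotype scores
#'
#' `mode = "ihs"`: scores are grouped into derived-allele-frequency bins of
#' width `bin_width` over (0,1); bins holding fewer than `min_bin` scores
#' are merged with neighbours; within each (merged) bin the mean is
#' subtracted and the standard deviation divided out.  `mode = "xpehh"`: a
#' single genome-wide standardization.  A bin with zero variance renders
#' its scores invalid.
#'
#' @param track A raw score track (from [ihs_scan] or [xpehh_scan]).
#' @param mode `"ihs"` or `"xpehh"`.
#' @param bin_width,min_bin Frequency-bin scheme for `mode = "ihs"`.
#' @return The track with columns `std` and updated `valid`.
#' @export
standardize_scores <- function(track, mode = c("ihs", "xpehh"),
                               bin_width = 0.025, min_bin = 20) {
  mode <- match.arg(mode)
  if (!any(track$valid)) stop("no valid raw scores to standardize")
  std <- rep(NA_real_, nrow(track))
  if (mode == "xpehh") {
    bin <- ifelse(track$valid, 1L, NA_integer_)
  } else {
    bin <- freq_bins(track$freq_derived, track$valid, bin_width, min_bin)
  }
  for (b in unique(bin[!is.na(bin)])) {
    sel <- which(!is.na(bin) & bin == b)
    m <- mean(track$raw[sel]); s <- sd(track$raw[sel])
    if (!is.finite(s) || s == 0) next  # zero-variance bin: stays invalid
    std[sel] <- (track$raw[sel] - m) / s
  }
  track$std <- std
  track$valid <- track$valid & !is.na(std)
  track$reason[is.na(std) & is.na(track$reason)] <- "degenerate_bin"
  track
}

#' Cross-population XP-EHH scan
#'
#' Per site, EHH is computed over all haplotypes (no allele split) within
#' each population; the integration for both is truncated at the first
#' marker where the pooled-population EHH falls to `truncation` (0.05).
#' Raw score is `ln(iHH_target / iHH_reference)`; positive values indicate
#' longer haplotypes in the target.  Standardize with
#' `standardize_scores(mode = "xpehh")`.
#'
#' @param panel_target,panel_reference [haplotype_panel]s sharing `sites`.
#' @param sites The shared [site_table].
#' @param truncation Pooled-EHH decay threshold (default 0.05).
#' @return A raw score-track `data.frame`.
#' @export
xpehh_scan <- function(panel_target, panel_reference, sites,
                       truncation = 0.05) {
  L <- ncol(panel_target$haps)
  stopifnot(ncol(panel_reference$haps) == L, nrow(sites) == L)
  pooled <- haplotype_panel(rbind(panel_target$haps, panel_reference$haps),
                            c(panel_target$individual,
                              paste0("ref_", panel_reference$individual)),
                            "pooled")
  raw <- rep(NA_real_, L)
  reason <- rep(NA_character_, L)
  for (j in seq_len(L)) {
    ihh <- xpehh_site(panel_target, panel_reference, pooled, sites, j, truncation)
    if (is.na(ihh$t) || is.na(ihh$r)) { reason[j] <- "no_decay"; next }
    if (ihh$t <= 0 || ihh$r <= 0) { reason[j] <- "zero_ihh"; next }
    raw[j] <- log(ihh$t / ihh$r)
  }
  p_der <- colMeans(panel_target$haps, na.rm = TRUE)
  data.frame(chrom = sites$chrom, pos = sites$pos, freq_derived = p_der,
             raw = raw, valid = !is.na(raw), reason = reason,
             stringsAsFactors = FALSE)
}

xpehh_site <- function(pt, pr, pooled, sites, core, truncation) {
  it <- ir <- 0
  for (dir in c("left", "right")) {
    cp <- ehh_curve(pooled, sites, core, "combined", dir, truncate = truncation)
    last <- length(cp$ehh)
    if (cp$ehh[last] > truncation)  # side exhausted before decay
      return(list(t = NA_real_, r = NA_real_))
    nmark <- last - 1L  # flanking markers out to the pooled stop
    ct <- ehh_curve(pt, sites, core, "combined", dir, max_markers = nmark)
    cr <- ehh_curve(pr, sites, core, "combined", dir, max_markers = nmark)
    if (!ct$valid || !cr$valid) return(list(t = NA_real_, r = NA_real_))
    it <- it + trapz_to(curve_dist_cm(ct), ct$ehh, last)
    ir <- ir + trapz_to(curve_dist_cm(cr), cr$ehh, last)
  }
  list(t = it, r = ir)
}
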