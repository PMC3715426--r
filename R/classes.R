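# Lightweight S3 containers shared by all scan modules.  Coordinate
# conventions: SNP positions are 1-based physical bp (as in VCF); all
# interval types (gene spans, scan windows) are 0-based half-open (as in
# BED).  Haplotype/genotype matrices are coded on the ancestral/derived
# axis: 0 = ancestral, 1 = derived (dosage 0..2 for genotypes); NA =
# missing.  When the ancestral state of a site is unknown the column keeps
# the REF-as-0 coding and the site is flagged via `ancestral = NA`.

#' Per-SNP site metadata table
#'
#' Builds the site table shared by every scan: one row per biallelic SNP
#' with chromosome, 1-based position, REF/ALT alleles, the ancestral allele
#' (or `NA` when unknown), and an optional genetic-map position.
#'
#' @param chrom Character vector of chromosome labels.
#' @param pos Integer vector of 1-based physical positions, strictly
#'   increasing within each chromosome.
#' @param ref,alt Nucleotide codes of the reference and alternate allele.
#' @param ancestral Nucleotide code of the ancestral allele, `NA` when
#'   unknown.  When known it must equal `ref` or `alt`.
#' @param gmap_cm Optional genetic-map position in centimorgans,
#'   non-decreasing with `pos` within a chromosome.
#' @return A `data.frame` of class `site_table`.
#' @export
site_table <- function(chrom, pos, ref, alt, ancestral = NA, gmap_cm = NULL) {
  n <- length(pos)
  st <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   ancestral = as.character(rep_len(ancestral, n)),
                   stringsAsFactors = FALSE)
  if (!is.null(gmap_cm)) st$gmap_cm <- as.numeric(gmap_cm)
  validate_site_table(st)
  class(st) <- c("site_table", "data.frame")
  st
}

validate_site_table <- function(st) {
  for (ch in unique(st$chrom)) {
    p <- st$pos[st$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
    if (!is.null(st$gmap_cm)) {
      g <- st$gmap_cm[st$chrom == ch]
      if (any(diff(g) < 0))
        stop("genetic-map positions must be non-decreasing within chromosome ", ch)
    }
  }
  known <- !is.na(st$ancestral)
  bad <- known & st$ancestral != st$ref & st$ancestral != st$alt
  if (any(bad))
    stop("ancestral allele matches neither REF nor ALT at ",
         st$chrom[bad][1], ":", st$pos[bad][1])
  invisible(st)
}

#' Phased haplotype panel
#'
#' A haplotypes-by-sites matrix of ancestral(0)/derived(1) alleles with the
#' haplotype-to-individual and individual-to-population maps.  Each
#' individual contributes exactly two haplotype rows.
#'
#' @param haps Integer matrix, haplotypes x sites, entries 0/1/NA.
#' @param individual Character vector, one entry per haplotype row, naming
#'   the individual each haplotype belongs to.
#' @param population Either a single label, a vector with one entry per
#'   individual (named by individual), or one entry per haplotype row.
#' @return A list of class `haplotype_panel` with elements `haps`,
#'   `individual`, `population` (per haplotype row).
#' @export
haplotype_panel <- function(haps, individual = NULL, population = "pop1") {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  if (!all(haps %in% c(0L, 1L, NA_integer_)))
    stop("haplotype entries must be 0, 1 or NA")
  nh <- nrow(haps)
  if (is.null(individual)) {
    if (nh %% 2L != 0L) stop("odd haplotype count with no individual map")
    individual <- rep(sprintf("ind%d", seq_len(nh / 2L)), each = 2L)
  }
  individual <- as.character(individual)
  if (length(individual) != nh)
    stop("individual map length must equal haplotype count")
  if (any(table(individual) != 2L))
    stop("each individual must contribute exactly 2 haplotypes")
  pop <- expand_pop_labels(population, individual)
  structure(list(haps = haps, individual = individual, population = pop),
            class = "haplotype_panel")
}

expand_pop_labels <- function(population, individual) {
  n <- length(individual)
  if (length(population) == 1L) return(rep(as.character(population), n))
  if (!is.null(names(population))) {
    miss <- setdiff(unique(individual), names(population))
    if (length(miss))
      stop("no population label for individual ", miss[1])
    return(as.character(population[individual]))
  }
  if (length(population) == n) return(as.character(population))
  if (length(population) == length(unique(individual)))
    return(as.character(population[match(individual, unique(individual))]))
  stop("population labels do not match individuals")
}

#' Genotype dosage panel
#'
#' Individuals-by-sites matrix of derived-allele dosages in `{0,1,2,NA}`
#' plus the individual-to-population map.
#'
#' @param geno Integer matrix, individuals x sites, dosage 0/1/2/NA.
#' @param population Population label(s): scalar or one per individual.
#' @return A list of class `genotype_panel` with elements `geno`,
#'   `population`.
#' @export
genotype_panel <- function(geno, population = "pop1") {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (!all(geno %in% c(0L, 1L, 2L, NA_integer_)))
    stop("genotype dosages must be 0, 1, 2 or NA")
  pop <- rep_len(as.character(population), nrow(geno))
  structure(list(geno = geno, population = pop), class = "genotype_panel")
}

#' Collapse a phased haplotype panel to genotype dosages
#'
#' Sums the two haplotypes of each individual; an individual is missing at
#' a site if either haplotype allele is missing there.
#'
#' @param panel A `haplotype_panel`.
#' @return A `genotype_panel` with one row per individual.
#' @export
haplotypes_to_genotypes <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  inds <- unique(panel$individual)
  geno <- matrix(NA_integer_, length(inds), ncol(panel$haps))
  pop <- character(length(inds))
  for (i in seq_along(inds)) {
    rows <- which(panel$individual == inds[i])
    geno[i, ] <- panel$haps[rows[1], ] + panel$haps[rows[2], ]
    pop[i] <- panel$population[rows[1]]
  }
  rownames(geno) <- inds
  genotype_panel(geno, pop)
}

#' Per-population derived-allele frequency table
#'
#' @param freq Numeric matrix, populations x SNPs, derived-allele
#'   frequencies in `[0,1]` (`NA` where no individual was genotyped).
#' @param n Integer matrix of the same shape: number of successfully typed
#'   alleles (2 x genotyped individuals).
#' @return A list of class `freq_table` with elements `freq`, `n`.
#' @export
freq_table <- function(freq, n) {
  freq <- as.matrix(freq); n <- as.matrix(n)
  if (!identical(dim(freq), dim(n)))
    stop("freq and n must have identical dimensions")
  if (any(freq < 0 | freq > 1, na.rm = TRUE))
    stop("frequencies must lie in [0,1]")
  if (any(n < 0)) stop("allele sample counts must be >= 0")
  if (is.null(rownames(freq)))
    rownames(freq) <- sprintf("pop%d", seq_len(nrow(freq)))
  dimnames(n) <- dimnames(freq)
  structure(list(freq = freq, n = n), class = "freq_table")
}

#' Gene annotation table
#'
#' Gene spans stored 0-based half-open (BED convention).
#'
#' @param gene Unique gene identifiers.
#' @param chrom Chromosome labels.
#' @param start,end 0-based half-open span, `start < end`.
#' @return A `data.frame` of class `gene_annotation`.
#' @export
gene_annotation <- function(gene, chrom, start, end) {
  ga <- data.frame(gene = as.character(gene), chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(ga$gene))
    stop("duplicate gene id: ", ga$gene[duplicated(ga$gene)][1])
  if (any(ga$start >= ga$end))
    stop("gene with start >= end: ", ga$gene[ga$start >= ga$end][1])
  class(ga) <- c("gene_annotation", "data.frame")
  ga
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes (%d individuals) x %d sites; populations: %s\n",
              nrow(x$haps), length(unique(x$individual)), ncol(x$haps),
              paste(unique(x$population), collapse = ", ")))
  invisible(x)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d individuals x %d sites; populations: %s\n",
              nrow(x$geno), ncol(x$geno),
              paste(unique(x$population), collapse = ", ")))
  invisible(x)
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("freq_table: %d populations x %d SNPs\n",
              nrow(x$freq), ncol(x$freq)))
  invisible(x)
}
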