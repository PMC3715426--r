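# On-disk formats.  VCF parsing goes through VariantAnnotation; BED through
# rtracklayer; trees through ape.  The small tabular formats (dosage TSV,
# PLINK-style text, score/region tables) are plain write.table/read.table
# with a fixed layout so that writes are byte-stable.

#' Read a phased VCF into a site table and haplotype panel
#'
#' Retains biallelic SNPs only (multiallelic and indel records are skipped
#' and counted in a message).  Alleles are recoded onto the
#' ancestral/derived axis: when the ancestral allele equals ALT the column
#' coding is flipped relative to the GT field.  Sites whose ancestral state
#' cannot be resolved are retained with `ancestral = NA` (REF-as-0 coding);
#' such sites are usable by unpolarized statistics (XP-EHH, F_ST) but are
#' skipped by iHS.
#'
#' @param path Path to an uncompressed or bgzipped VCF with phased GT.
#' @param ancestral_source Either `"ref"` (treat REF as ancestral) or the
#'   name of an INFO tag (conventionally `"AA"`) holding the ancestral
#'   allele.
#' @param population Population label(s) for the samples (scalar, or named
#'   by sample).
#' @return A list with elements `sites` (a [site_table]) and `panel`
#'   (a [haplotype_panel]); attribute `n_skipped` counts skipped records.
#' @export
read_phased_vcf <- function(path, ancestral_source = "ref",
                            population = "pop1") {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  is_snp <- n_alt == 1L & nchar(ref) == 1L & nchar(alt1) == 1L &
    alt1 %in% c("A", "C", "G", "T") & ref %in% c("A", "C", "G", "T")
  n_skipped <- sum(!is_snp)
  if (n_skipped > 0)
    message(n_skipped, " non-biallelic-SNP record(s) skipped")
  keep <- which(is_snp)
  if (!length(keep)) stop("no biallelic SNPs in ", path)

  chrom <- as.character(GenomicRanges::seqnames(rr))[keep]
  pos <- GenomicRanges::start(rr)[keep]
  ref <- ref[keep]; alt <- alt1[keep]

  gt <- VariantAnnotation::geno(vcf)$GT[keep, , drop = FALSE]
  unphased <- grepl("/", gt, fixed = TRUE) & gt != "./."
  if (any(unphased)) {
    w <- which(unphased, arr.ind = TRUE)[1, ]
    stop("unphased genotype at ", chrom[w[1]], ":", pos[w[1]],
         " (sample ", colnames(gt)[w[2]], ")")
  }

  # ancestral state
  if (identical(ancestral_source, "ref")) {
    anc <- ref
  } else {
    aa <- VariantAnnotation::info(vcf)[[ancestral_source]]
    if (is.null(aa))
      stop("INFO tag '", ancestral_source, "' not present in ", path)
    aa <- toupper(as.character(aa))[keep]
    anc <- ifelse(!is.na(aa) & (aa == ref | aa == alt), aa, NA_character_)
  }

  # parse "a|b" strings into two haplotype rows per sample; "." alleles
  # (or a bare "." / "./." genotype) become missing
  nsamp <- ncol(gt); nsite <- nrow(gt)
  haps <- matrix(NA_integer_, 2L * nsamp, nsite)
  bad <- !(grepl("^[01.]\\|[01.]$", gt) | gt %in% c(".", "./."))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("unparseable GT '", gt[w[1], w[2]], "' at ", chrom[w[1]], ":", pos[w[1]])
  }
  c1 <- substr(gt, 1L, 1L); c2 <- substr(gt, 3L, 3L)
  c1[!grepl("|", gt, fixed = TRUE)] <- "."
  c2[!grepl("|", gt, fixed = TRUE)] <- "."
  a1 <- suppressWarnings(matrix(as.integer(c1), nsite, nsamp))
  a2 <- suppressWarnings(matrix(as.integer(c2), nsite, nsamp))
  for (s in seq_len(nsamp)) {
    haps[2L * s - 1L, ] <- a1[, s]
    haps[2L * s, ] <- a2[, s]
  }
  # recode to ancestral = 0 where the ancestral allele is the ALT; REF/ALT
  # keep their VCF identity, only the 0/1 coding flips
  flip <- !is.na(anc) & anc == alt
  if (any(flip)) haps[, flip] <- 1L - haps[, flip]

  st <- site_table(chrom, pos, ref, alt, ancestral = anc)
  individual <- rep(colnames(gt), each = 2L)
  panel <- haplotype_panel(haps, individual, population)
  structure(list(sites = st, panel = panel), n_skipped = n_skipped)
}

#' Read a genotype dosage table
#'
#' Two dialects are supported.  `"tsv-dosage"`: a TSV with columns `id`,
#' `pop`, then one column per SNP named `chrom:pos:ref:alt`, entries being
#' derived-allele dosages (0/1/2, `NA` for missing).  `"plink-text"`: a
#' PLINK-style `.ped`/`.map` pair (pass the `.ped` path); since the text
#' format carries no REF/ALT designation, the lexicographically smaller
#' allele is stored as REF and dosage counts the larger allele; ancestral
#' states are unknown.
#'
#' @param path File path (`.ped` for the plink-text dialect).
#' @param dialect `"tsv-dosage"` or `"plink-text"`.
#' @return A list with elements `sites` ([site_table]) and `panel`
#'   ([genotype_panel]).
#' @export
read_genotype_table <- function(path, dialect = c("tsv-dosage", "plink-text")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv-dosage") read_tsv_dosage(path) else read_plink_text(path)
}

read_tsv_dosage <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("id", "pop") %in% colnames(tab)[1:2]))
    stop("tsv-dosage requires leading 'id' and 'pop' columns")
  snp_cols <- colnames(tab)[-(1:2)]
  parts <- strsplit(snp_cols, ":", fixed = TRUE)
  if (any(lengths(parts) != 4L))
    stop("SNP columns must be named chrom:pos:ref:alt")
  pm <- do.call(rbind, parts)
  geno <- as.matrix(tab[, -(1:2), drop = FALSE])
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(tab))
    stop("row count mismatch against header")
  rownames(geno) <- tab$id
  st <- site_table(pm[, 1], as.integer(pm[, 2]), pm[, 3], pm[, 4])
  list(sites = st, panel = genotype_panel(geno, tab$pop))
}

read_plink_text <- function(ped_path) {
  map_path <- sub("\\.ped$", ".map", ped_path)
  if (identical(map_path, ped_path)) stop("plink-text expects a .ped path")
  map <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  colnames(map)[1:4] <- c("chrom", "snp", "cm", "pos")
  ped <- read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  nsnp <- nrow(map)
  if (ncol(ped) != 6L + 2L * nsnp)
    stop("column count mismatch: .ped has ", ncol(ped), " columns, expected ",
         6L + 2L * nsnp, " for ", nsnp, " SNPs")
  al1 <- as.matrix(ped[, 6L + 2L * seq_len(nsnp) - 1L, drop = FALSE])
  al2 <- as.matrix(ped[, 6L + 2L * seq_len(nsnp), drop = FALSE])
  al1[al1 == "0"] <- NA; al2[al2 == "0"] <- NA
  ref <- alt <- character(nsnp)
  geno <- matrix(NA_integer_, nrow(ped), nsnp)
  for (j in seq_len(nsnp)) {
    obs <- sort(unique(stats::na.omit(c(al1[, j], al2[, j]))))
    if (length(obs) > 2L) stop("more than 2 alleles at SNP ", map$snp[j])
    ref[j] <- obs[1]
    alt[j] <- if (length(obs) == 2L) obs[2] else "N"
    cnt <- (al1[, j] == alt[j]) + (al2[, j] == alt[j])
    geno[, j] <- as.integer(cnt)
  }
  rownames(geno) <- ped[, 2]
  st <- site_table(map$chrom, as.integer(map$pos), ref, alt)
  list(sites = st, panel = genotype_panel(geno, "pop1"))
}

#' Read gene annotation from BED
#'
#' BED4 with the gene name in column 4; coordinates are kept 0-based
#' half-open.  Duplicate gene ids and non-positive-width spans are
#' rejected.
#'
#' @param path Path to a BED file.
#' @return A [gene_annotation].
#' @export
read_gene_annotation <- function(path) {
  raw <- readLines(path)
  raw <- raw[nzchar(raw) & !startsWith(raw, "#") & !startsWith(raw, "track")]
  fld <- strsplit(raw, "\t", fixed = TRUE)
  if (any(lengths(fld) < 4L))
    stop("BED line ", which(lengths(fld) < 4L)[1], " has fewer than 4 fields")
  start <- as.integer(vapply(fld, `[`, "", 2L))
  end <- as.integer(vapply(fld, `[`, "", 3L))
  bad <- which(start >= end)
  if (length(bad))
    stop("start >= end on BED line ", bad[1], " (", raw[bad[1]], ")")
  gr <- rtracklayer::import(path, format = "BED")
  gene_annotation(gr$name, as.character(GenomicRanges::seqnames(gr)),
                  GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
}

# ---- writers ---------------------------------------------------------------

write_header_lines <- function(con, header) {
  if (!is.null(header)) writeLines(paste0("# ", header), con)
}

#' Write a per-SNP score track as TSV
#'
#' Columns: chrom, pos, raw, std (when present), freq_derived, valid.
#' `header` lines (e.g. the simulation seed) are written as `# ` comments.
#'
#' @param track A score-track `data.frame` (from [ihs_scan], [xpehh_scan],
#'   [pbs_scan]).
#' @param path Output path.
#' @param header Optional character vector of comment lines.
#' @export
write_score_track <- function(track, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  write_header_lines(con, header)
  write.table(format(track, digits = 15, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a score track written by [write_score_track]
#' @param path Input path.
#' @return A `data.frame`.
#' @export
read_score_track <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Write a region score table as BED plus TSV
#'
#' The BED carries `chrom start end name` with 0-based half-open windows;
#' the TSV carries the full table (statistic, SNP count, empirical p,
#' candidate flag).
#'
#' @param regions A region score `data.frame` (see [region_statistics]).
#' @param bed_path,tsv_path Output paths (either may be `NULL` to skip).
#' @param header Optional comment lines for the TSV.
#' @export
write_region_table <- function(regions, bed_path = NULL, tsv_path = NULL,
                               header = NULL) {
  if (!is.null(bed_path)) {
    name <- sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
    bed <- data.frame(regions$chrom, regions$start, regions$end, name)
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    con <- file(tsv_path, "w")
    on.exit(close(con))
    write_header_lines(con, header)
    write.table(format(regions, digits = 15, trim = TRUE), con, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(regions)
}

#' Write a tree in Newick format
#' @param tree An `ape::phylo` object.
#' @param path Output path.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a site table + haplotype panel as a phased VCF
#'
#' Minimal VCF 4.2 output with an `AA` INFO tag carrying the ancestral
#' allele (`.` when unknown) and phased GT fields.  Round-trips through
#' [read_phased_vcf].
#'
#' @param sites A [site_table].
#' @param panel A [haplotype_panel] over the same sites.
#' @param path Output path.
#' @param header Optional extra `##`-style header lines (written verbatim
#'   after `##` prefixing).
#' @export
write_phased_vcf <- function(sites, panel, path, header = NULL) {
  stopifnot(nrow(sites) == ncol(panel$haps))
  inds <- unique(panel$individual)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  if (!is.null(header)) writeLines(paste0("##", header), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", inds), collapse = "\t"), con)
  h1 <- panel$haps[match(inds, panel$individual), , drop = FALSE]
  rows2 <- vapply(inds, function(i) which(panel$individual == i)[2], 0L)
  h2 <- panel$haps[rows2, , drop = FALSE]
  for (j in seq_len(nrow(sites))) {
    flip <- !is.na(sites$ancestral[j]) && sites$ancestral[j] == sites$alt[j]
    v1 <- if (flip) 1L - h1[, j] else h1[, j]
    v2 <- if (flip) 1L - h2[, j] else h2[, j]
    a <- ifelse(is.na(v1), ".", v1)
    b <- ifelse(is.na(v2), ".", v2)
    gts <- paste0(a, "|", b)
    aa <- if (is.na(sites$ancestral[j])) "." else sites$ancestral[j]
    writeLines(paste(c(sites$chrom[j], sites$pos[j], ".", sites$ref[j],
                       sites$alt[j], ".", "PASS", paste0("AA=", aa), "GT",
                       gts), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a genotype panel in the tsv-dosage dialect
#' @param sites A [site_table].
#' @param panel A [genotype_panel].
#' @param path Output path.
#' @param header Optional comment lines.
#' @export
write_genotype_table <- function(sites, panel, path, header = NULL) {
  stopifnot(nrow(sites) == ncol(panel$geno))
  ids <- rownames(panel$geno) %||% sprintf("ind%d", seq_len(nrow(panel$geno)))
  cols <- sprintf("%s:%d:%s:%s", sites$chrom, sites$pos, sites$ref, sites$alt)
  tab <- data.frame(id = ids, pop = panel$population,
                    panel$geno, check.names = FALSE)
  colnames(tab)[-(1:2)] <- cols
  con <- file(path, "w")
  on.exit(close(con))
  write_header_lines(con, header)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
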