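#' Construct a haplotype matrix
#'
#' The substrate of every statistic in the package: a samples x sites
#' matrix of allele codes for one chromosome, with physical positions and
#' a population label per sample.
#'
#' @param chrom Chromosome identifier (length-1 character).
#' @param positions Integer vector of 0-based physical coordinates,
#'   strictly increasing, one per site (column).
#' @param alleles Integer matrix, samples x sites; allele codes in
#'    0..3 (0 = reference/first allele), `NA` = missing.
#' @param sample_ids Character vector of sample names (rows).
#' @param pops Character vector, one population label per sample.
#'
#' @return An object of class `haplotype_matrix`: a list with elements
#'   `chrom`, `positions`, `alleles`, `sample_ids`, `pops`.
#' @export
haplotype_matrix <- function(chrom, positions, alleles, sample_ids, pops) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  positions <- as.integer(positions)
  if (length(chrom) != 1L) stop("chrom must be a single identifier")
  if (ncol(alleles) != length(positions))
    stop("ncol(alleles) must equal length(positions)")
  if (nrow(alleles) != length(sample_ids))
    stop("nrow(alleles) must equal length(sample_ids)")
  if (length(pops) != length(sample_ids))
    stop("every sample needs exactly one population label")
  if (length(positions) > 1L && any(diff(positions) <= 0L))
    stop("positions must be strictly increasing")
  ok <- is.na(alleles) | (alleles >= 0L & alleles <= 3L)
  if (!all(ok)) stop("allele codes must be in 0..3 or NA")
  dimnames(alleles) <- list(sample_ids, NULL)
  structure(
    list(chrom = as.character(chrom), positions = positions,
         alleles = alleles, sample_ids = as.character(sample_ids),
         pops = as.character(pops)),
    class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  tab <- table(x$pops)
  cat("haplotype_matrix: ", length(x$sample_ids), " haplotypes x ",
      length(x$positions), " sites on ", x$chrom, "\n", sep = "")
  cat("populations:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.haplotype_matrix <- function(x) dim(x$alleles)

# row indices of a population; errors on unknown labels
pop_rows <- function(hap, pop) {
  idx <- which(hap$pops == pop)
  if (length(idx) == 0L)
    stop("no samples in population '", pop, "'")
  idx
}

# column indices of sites inside [start, end), optionally restricted to
# mask-passing positions
site_cols <- function(hap, start = NULL, end = NULL, keep = NULL) {
  sel <- rep(TRUE, length(hap$positions))
  if (!is.null(start)) sel <- sel & hap$positions >= start
  if (!is.null(end)) sel <- sel & hap$positions < end
  if (!is.null(keep)) sel <- sel & keep
  which(sel)
}

#' Load haplotypes from a VCF and a population panel
#'
#' Reads SNP records from a VCF (plain or bgzipped), retains the samples
#' listed in a panel file, and collapses diploid genotypes to one
#' haplotype per sample. Non-SNP records (indels, symbolic alleles) are
#' skipped; the skip count is attached as attribute `n_skipped`.
#'
#' @param vcf_path Path to the VCF.
#' @param panel_path Path to a two-column TSV (`sample_id`, `population`),
#'   no header, listing every sample to retain.
#' @param ploidy_policy How to collapse diploid genotypes:
#'   `"first_allele"` (default) takes the first allele of each genotype
#'   and counts heterozygous calls in attribute `n_het_collapsed`;
#'   `"strict"` errors on any heterozygous call. Inbred-line data are
#'   expected, so heterozygotes are treated as noise.
#'
#' @return A [haplotype_matrix()] (positions converted to 0-based).
#' @export
load_haplotypes <- function(vcf_path, panel_path,
                            ploidy_policy = c("first_allele", "strict")) {
  ploidy_policy <- match.arg(ploidy_policy)
  panel <- read_panel(panel_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  alt_split <- strsplit(ifelse(is.na(alt), "", alt), ",", fixed = TRUE)
  is_snp <- nchar(ref) == 1L & ref %in% c("A", "C", "G", "T") &
    vapply(alt_split, function(a)
      length(a) >= 1L && all(nchar(a) == 1L & a %in% c("A", "C", "G", "T")),
      logical(1))
  n_skipped <- sum(!is_snp)

  gt <- v@gt[, -1, drop = FALSE]
  vcf_samples <- colnames(gt)
  missing_samples <- setdiff(panel$sample_id, vcf_samples)
  if (length(missing_samples) > 0L)
    stop("panel sample(s) absent from VCF: ",
         paste(missing_samples, collapse = ", "))

  if (sum(is_snp) == 0L) stop("zero SNP sites retained from ", vcf_path)
  fix <- fix[is_snp, , drop = FALSE]
  gt <- gt[is_snp, panel$sample_id, drop = FALSE]

  # strip FORMAT payload beyond GT
  gt_only <- sub(":.*$", "", gt)
  first <- sub("[/|].*$", "", gt_only)
  second <- ifelse(grepl("[/|]", gt_only), sub("^[^/|]*[/|]", "", gt_only), first)
  het <- first != second & first != "." & second != "."
  n_het <- sum(het)
  if (n_het > 0L) {
    if (ploidy_policy == "strict")
      stop(n_het, " heterozygous genotype(s) under ploidy_policy='strict'")
    warning(n_het, " heterozygous genotype(s) collapsed to the first allele")
  }
  codes <- suppressWarnings(matrix(as.integer(first), nrow = nrow(gt_only)))
  alleles <- t(codes) # samples x sites
  chrom <- unique(fix[, "CHROM"])
  if (length(chrom) > 1L)
    stop("VCF spans multiple chromosomes; load one chromosome at a time")
  hap <- haplotype_matrix(
    chrom = chrom,
    positions = as.integer(fix[, "POS"]) - 1L,
    alleles = alleles,
    sample_ids = panel$sample_id,
    pops = panel$population)
  attr(hap, "n_skipped") <- n_skipped
  attr(hap, "n_het_collapsed") <- n_het
  hap
}

#' Read a sample-to-population panel file
#'
#' @param path Two-column TSV (`sample_id`, `population`), no header.
#' @return A data frame with columns `sample_id` and `population`.
#' @export
read_panel <- function(path) {
  panel <- read.table(path, header = FALSE, sep = "\t",
                      col.names = c("sample_id", "population"),
                      colClasses = "character")
  if (anyDuplicated(panel$sample_id))
    stop("duplicated sample in panel: ",
         panel$sample_id[duplicated(panel$sample_id)][1])
  panel
}

#' Write / read the internal haplotype text format
#'
#' A plain-text round-trip format: header lines carry the chromosome,
#' sample ids and population labels; one line per site carries the 0-based
#' position and the allele codes (`.` for missing).
#'
#' @param hap A [haplotype_matrix()].
#' @param path File path.
#' @return `write_haplotypes()` returns `path` invisibly;
#'   `read_haplotypes()` returns a [haplotype_matrix()].
#' @export
write_haplotypes <- function(hap, path) {
  stopifnot(inherits(hap, "haplotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#chrom\t", hap$chrom),
    paste0("#samples\t", paste(hap$sample_ids, collapse = "\t")),
    paste0("#pops\t", paste(hap$pops, collapse = "\t"))), con)
  if (length(hap$positions) > 0L) {
    al <- hap$alleles
    al[is.na(al)] <- -1L
    body <- vapply(seq_along(hap$positions), function(s) {
      codes <- al[, s]
      paste0(hap$positions[s], "\t",
             paste(ifelse(codes < 0L, ".", as.character(codes)),
                   collapse = ""))
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}

#' @rdname write_haplotypes
#' @export
read_haplotypes <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get_hdr <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("#", key, "\t"))]
    if (length(ln) != 1L) stop("malformed header: missing #", key)
    strsplit(ln, "\t", fixed = TRUE)[[1]][-1]
  }
  chrom <- get_hdr("chrom")
  samples <- get_hdr("samples")
  pops <- get_hdr("pops")
  if (length(body) == 0L) {
    return(haplotype_matrix(chrom, integer(0),
                            matrix(integer(0), nrow = length(samples)),
                            samples, pops))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  positions <- as.integer(vapply(parts, `[`, character(1), 1))
  allele_str <- vapply(parts, `[`, character(1), 2)
  chars <- do.call(rbind, strsplit(allele_str, "", fixed = TRUE)) # sites x samples
  ints <- suppressWarnings(as.integer(chars))
  ints[as.vector(chars) == "."] <- NA_integer_
  alleles <- t(matrix(ints, nrow = nrow(chars))) # samples x sites
  haplotype_matrix(chrom, positions, alleles, samples, pops)
}

#' Write a haplotype matrix as a minimal haploid VCF
#'
#' Allele codes are rendered as nucleotides (0 = A, 1 = C, 2 = G, 3 = T)
#' purely for format compliance; positions are converted to 1-based.
#'
#' @param hap A [haplotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(hap, path) {
  stopifnot(inherits(hap, "haplotype_matrix"))
  nt <- c("A", "C", "G", "T")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", hap$chrom, ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", hap$sample_ids), collapse = "\t")), con)
  for (s in seq_along(hap$positions)) {
    codes <- hap$alleles[, s]
    obs <- sort(unique(codes[!is.na(codes)]))
    ref_code <- if (0L %in% obs) 0L else obs[1]
    alt_codes <- setdiff(obs, ref_code)
    if (length(alt_codes) == 0L) alt_codes <- integer(0)
    idx <- match(codes, c(ref_code, alt_codes)) - 1L
    gt <- ifelse(is.na(idx), ".", as.character(idx))
    alt_field <- if (length(alt_codes)) paste(nt[alt_codes + 1L],
                                              collapse = ",") else "."
    writeLines(paste(c(hap$chrom, hap$positions[s] + 1L, ".",
                       nt[ref_code + 1L], alt_field, ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}
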