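write_test_vcf <- function(path, records, samples) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    records), path)
}

write_test_panel <- function(path, samples, pops) {
  writeLines(paste(samples, pops, sep = "\t"), path)
}

test_that("VCF loading encodes SNPs, skips indels, collapses diploids", {
  vcf <- tempfile(fileext = ".vcf")
  panel <- tempfile()
  write_test_vcf(vcf, c(
    "chr1\t101\t.\tA\tG\t.\tPASS\t.\tGT\t0\t1",
    "chr1\t201\t.\tC\tT\t.\tPASS\t.\tGT\t1\t1",
    "chr1\t301\t.\tG\tA\t.\tPASS\t.\tGT\t0\t0"), c("s1", "s2"))
  write_test_panel(panel, c("s1", "s2"), c("A", "B"))
  hap <- load_haplotypes(vcf, panel)
  expect_s3_class(hap, "haplotype_matrix")
  expect_equal(dim(hap), c(2L, 3L))
  expect_equal(sort(unique(hap$pops)), c("A", "B"))
  expect_equal(hap$positions, c(100L, 200L, 300L)) # 0-based
  expect_equal(unname(hap$alleles[2, ]), c(1L, 1L, 0L))

  # indel record skipped with a count
  write_test_vcf(vcf, c(
    "chr1\t101\t.\tA\tG\t.\tPASS\t.\tGT\t0\t1",
    "chr1\t150\t.\tAT\tA\t.\tPASS\t.\tGT\t0\t1"), c("s1", "s2"))
  hap <- load_haplotypes(vcf, panel)
  expect_equal(attr(hap, "n_skipped"), 1L)
  expect_equal(ncol(hap$alleles), 1L)

  # diploid het: first_allele policy takes allele 0 and warns; strict errors
  write_test_vcf(vcf, c(
    "chr1\t101\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1"), c("s1", "s2"))
  expect_warning(hap <- load_haplotypes(vcf, panel), "heterozygous")
  expect_equal(unname(hap$alleles[, 1]), c(0L, 1L))
  expect_equal(attr(hap, "n_het_collapsed"), 1L)
  expect_error(load_haplotypes(vcf, panel, ploidy_policy = "strict"),
               "heterozygous")

  # panel sample absent from the VCF is a hard error naming it
  write_test_panel(panel, c("s1", "s9"), c("A", "B"))
  expect_error(load_haplotypes(vcf, panel), "s9")
})

test_that("window tiling covers chromosomes exactly", {
  w <- make_windows(c(chr1 = 25000), 10000)
  expect_equal(w$start, c(0, 10000, 20000))
  expect_equal(w$end, c(10000, 20000, 25000))
  expect_equal(nrow(make_windows(c(chr1 = 10000), 10000)), 1L)
  expect_equal(nrow(make_windows(c(chr1 = 21e6), 10000)), 2100L)
  expect_error(make_windows(c(chr1 = 1e5), 10000, step = 20000), "gaps")

  # every base covered exactly once for step = size
  w <- make_windows(c(a = 12345, b = 9999), 1000)
  for (ch in c("a", "b")) {
    d <- w[w$chrom == ch, ]
    expect_equal(d$start[-1], d$end[-nrow(d)]) # contiguous
    expect_equal(sum(d$end - d$start), c(a = 12345, b = 9999)[[ch]])
  }
})

test_that("callable-fraction filter is boundary-inclusive and monotone", {
  lens <- c(chr1 = 10000)
  w <- make_windows(lens, 10000)
  half <- site_mask(data.frame(chrom = "chr1", start = 0, end = 5000), lens)
  just_under <- site_mask(data.frame(chrom = "chr1", start = 0, end = 4999),
                          lens)
  expect_true(window_passes_filter(w, half)$pass)
  expect_equal(window_passes_filter(w, half)$callable_fraction, 0.5)
  expect_false(window_passes_filter(w, just_under)$pass)

  # raising min_fraction never adds windows
  set.seed(11)
  lens <- c(chr1 = 2e5)
  w <- make_windows(lens, 1e4)
  iv <- do.call(rbind, lapply(seq_len(nrow(w)), function(i) {
    keep <- runif(1, 0.2, 1)
    data.frame(chrom = "chr1", start = w$start[i],
               end = w$start[i] + round(keep * 1e4))
  }))
  m <- site_mask(iv, lens)
  passed <- vapply(c(0.3, 0.5, 0.7, 0.9), function(f)
    sum(window_passes_filter(w, m, f)$pass), numeric(1))
  expect_true(all(diff(passed) <= 0))

  # window outside mask coverage errors
  expect_error(window_passes_filter(
    data.frame(chrom = "chrX", start = 0, end = 100), m), "coverage")
})

test_that("a scan-scale retention count matches a direct oracle", {
  # 11,083 windows of 1 kb with per-window pass fractions drawn so that
  # exactly 640 fall below 0.5; the filter must retain the other 10,443
  set.seed(101)
  n <- 11083L
  size <- 1000L
  frac <- runif(n, 0.5, 1)
  frac[sample.int(n, 640)] <- runif(640, 0, 0.4999)
  lens <- c(chr1 = n * size)
  w <- make_windows(lens, size)
  n_pass_sites <- round(frac * size)
  iv <- data.frame(chrom = "chr1", start = w$start,
                   end = w$start + n_pass_sites)
  iv <- iv[iv$end > iv$start, ]
  m <- site_mask(iv, lens)
  filt <- window_passes_filter(w, m, 0.5)
  expect_equal(sum(filt$pass), sum(round(frac * size) / size >= 0.5))
  expect_equal(sum(filt$pass), 10443L)
})

test_that("internal haplotype text format round-trips bit-exactly", {
  set.seed(5)
  al <- matrix(sample(c(0:3, NA), 60, replace = TRUE), nrow = 5)
  hap <- haplotype_matrix("chr2", sort(sample.int(500, 12)) - 1L, al,
                          sprintf("s%d", 1:5),
                          c("A", "A", "A", "B", "B"))
  f <- tempfile()
  write_haplotypes(hap, f)
  hap2 <- read_haplotypes(f)
  expect_identical(hap$positions, hap2$positions)
  expect_identical(unname(hap$alleles), unname(hap2$alleles))
  expect_identical(hap$pops, hap2$pops)
  expect_identical(hap$sample_ids, hap2$sample_ids)
  expect_identical(hap$chrom, hap2$chrom)
})

test_that("haplotype matrices written as VCF reload identically", {
  tf <- toy_fixture()
  vcf <- tempfile(fileext = ".vcf")
  panel <- tempfile()
  write_vcf(tf$hap, vcf)
  write_test_panel(panel, tf$hap$sample_ids, tf$hap$pops)
  hap2 <- load_haplotypes(vcf, panel)
  expect_equal(hap2$positions, tf$hap$positions)
  d <- dxy(hap2, "A", "B", min_overlap = 1)
  expect_equal(unname(d["dxy"]), tf$expected$dxy)
})

test_that("haplotype_matrix enforces its invariants", {
  expect_error(haplotype_matrix("c", c(3L, 1L), matrix(0L, 1, 2), "s", "A"),
               "increasing")
  expect_error(haplotype_matrix("c", 0L, matrix(5L, 1, 1), "s", "A"),
               "allele codes")
  expect_error(haplotype_matrix("c", 0L, matrix(0L, 2, 1), c("a", "b"), "A"),
               "population")
})
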