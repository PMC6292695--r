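# Independent brute-force oracles. These deliberately share no code with
# the package internals: plain loops over explicit pair enumerations.

# build a haplotype_matrix from strings like c("0010", "0110")
hap_from_strings <- function(strings, pops, chrom = "t",
                             positions = NULL) {
  mat <- do.call(rbind, lapply(strsplit(strings, "", fixed = TRUE),
                               function(x) {
                                 out <- suppressWarnings(as.integer(x))
                                 out[x == "."] <- NA_integer_
                                 out
                               }))
  if (is.null(positions)) positions <- seq_len(ncol(mat)) - 1L
  haplotype_matrix(chrom, positions, mat,
                   sprintf("s%02d", seq_len(nrow(mat))), pops)
}

# mean per-site pairwise difference within a matrix (rows = haplotypes),
# pairwise-complete, each pair normalized by its own comparable length
brute_pi <- function(mat, L) {
  n <- nrow(mat)
  if (n < 2) return(NA_real_)
  vals <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- 0; miss <- 0
    for (s in seq_len(ncol(mat))) {
      if (is.na(mat[i, s]) || is.na(mat[j, s])) miss <- miss + 1
      else if (mat[i, s] != mat[j, s]) d <- d + 1
    }
    if (L - miss >= 1) vals <- c(vals, d / (L - miss))
  }
  if (length(vals) == 0) NA_real_ else mean(vals)
}

brute_dxy <- function(A, B, L, min_overlap = 1) {
  vals <- c()
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d <- 0; miss <- 0
    for (s in seq_len(ncol(A))) {
      if (is.na(A[i, s]) || is.na(B[j, s])) miss <- miss + 1
      else if (A[i, s] != B[j, s]) d <- d + 1
    }
    if (L - miss >= min_overlap) vals <- c(vals, d / (L - miss))
  }
  if (length(vals) == 0) return(c(NA_real_, NA_real_))
  c(mean(vals), min(vals))
}

# textbook Tajima (1989) D, complete data, rows = haplotypes
brute_tajd <- function(mat) {
  n <- nrow(mat)
  seg <- which(apply(mat, 2, function(x) length(unique(x)) > 1))
  S <- length(seg)
  if (S == 0 || n < 2) return(NA_real_)
  k <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    k <- k + sum(mat[i, ] != mat[j, ])
  k <- k / choose(n, 2)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# mean r^2 over non-singleton biallelic site pairs, complete data
brute_zns <- function(mat) {
  keep <- which(apply(mat, 2, function(x) {
    tab <- table(x)
    length(tab) == 2 && min(tab) >= 2
  }))
  if (length(keep) < 2) return(NA_real_)
  r2 <- c()
  for (a in 1:(length(keep) - 1)) for (b in (a + 1):length(keep)) {
    x <- as.integer(mat[, keep[a]] != mat[1, keep[a]])
    y <- as.integer(mat[, keep[b]] != mat[1, keep[b]])
    # allele labels arbitrary; r^2 is invariant to flips
    pA <- mean(x); pB <- mean(y); pAB <- mean(x & y)
    r2 <- c(r2, (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB)))
  }
  mean(r2)
}

# single-site Weir & Cockerham (1984) theta-hat for haploid samples,
# written from the published variance-component definitions
brute_wc_fst_site <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  p1 <- mean(x); p2 <- mean(y)
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r)
  c(a = a, ab = a + b)
}

# exhaustive integer-start enumeration for the placement test
enumerate_placement_p <- function(chrom_length, segment_length, loci) {
  starts <- 0:(chrom_length - segment_length)
  hits <- sum(vapply(starts, function(s)
    all(loci >= s & loci < s + segment_length), logical(1)))
  hits / length(starts)
}

# random small haplotype matrix (complete data) for property loops
random_small_matrix <- function(n, S, n_alleles = 2) {
  matrix(sample.int(n_alleles, n * S, replace = TRUE) - 1L, nrow = n)
}
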