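# Within- and between-population summary statistics. All statistics use
# pairwise-complete sites: a site where either member of a haplotype pair
# is missing is treated as uncallable for that pair, and the pair's
# distance is normalized by its own comparable-site count.

# per-pair difference counts and comparable lengths between rows of A and
# rows of B (or within A when B is NULL); callable_len is the number of
# mask-passing bases in the window (variant and invariant)
pair_distance_table <- function(A, B = NULL, callable_len) {
  within <- is.null(B)
  if (within) B <- A
  nA <- nrow(A); nB <- nrow(B)
  pairs <- if (within) {
    if (nA < 2L) return(NULL)
    t(utils::combn(nA, 2L))
  } else {
    as.matrix(expand.grid(i = seq_len(nA), j = seq_len(nB)))
  }
  diffs <- numeric(nrow(pairs))
  comp <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    x <- A[pairs[k, 1], ]
    y <- B[pairs[k, 2], ]
    ok <- !is.na(x) & !is.na(y)
    diffs[k] <- sum(x[ok] != y[ok])
    comp[k] <- callable_len - sum(!ok) # pair-missing variant sites uncallable
  }
  data.frame(i = pairs[, 1], j = pairs[, 2], diffs = diffs, comparable = comp)
}

# extract the in-window, mask-passing allele submatrix for a population
window_submatrix <- function(hap, pop = NULL, start = NULL, end = NULL,
                             mask = NULL) {
  keep <- mask_pass_positions(mask, hap$chrom, hap$positions)
  cols <- site_cols(hap, start, end, keep)
  rows <- if (is.null(pop)) seq_along(hap$sample_ids) else pop_rows(hap, pop)
  hap$alleles[rows, cols, drop = FALSE]
}

window_callable_len <- function(hap, start, end, mask) {
  if (is.null(start)) start <- 0L
  if (is.null(end)) end <- max(hap$positions) + 1L
  mask_pass_count(mask, hap$chrom, start, end)
}

#' Nucleotide diversity (pi) in a window
#'
#' Mean per-site pairwise difference among the haplotypes of one
#' population: the sum over haplotype pairs of the pairwise-complete
#' difference count divided by that pair's comparable length, averaged
#' over pairs.
#'
#' @param hap A [haplotype_matrix()].
#' @param pop Population label.
#' @param start,end Window bounds (0-based half-open); `NULL` = all sites.
#' @param mask Optional [site_mask()].
#' @param min_overlap Minimum comparable sites for a pair to contribute.
#' @return Per-site diversity, or `NA` with fewer than 2 haplotypes.
#' @export
nuc_div <- function(hap, pop, start = NULL, end = NULL, mask = NULL,
                    min_overlap = 1L) {
  A <- window_submatrix(hap, pop, start, end, mask)
  if (nrow(A) < 2L) return(NA_real_)
  L <- window_callable_len(hap, start, end, mask)
  tab <- pair_distance_table(A, NULL, L)
  tab <- tab[tab$comparable >= min_overlap, , drop = FALSE]
  if (nrow(tab) == 0L) return(NA_real_)
  mean(tab$diffs / tab$comparable)
}

# Tajima (1989) constants for sample size n
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D in a window
#'
#' Normalized difference between mean pairwise diversity and Watterson's
#' theta, computed from the segregating-site count S and the per-site
#' unbiased heterozygosity summed over sites. Sites with missing data use
#' their observed sample size for the heterozygosity term; the variance
#' constants use the population sample size.
#'
#' @inheritParams nuc_div
#' @return Tajima's D; `NA` if no segregating sites or fewer than 2
#'   haplotypes.
#' @export
tajimas_d <- function(hap, pop, start = NULL, end = NULL, mask = NULL) {
  A <- window_submatrix(hap, pop, start, end, mask)
  n <- nrow(A)
  if (n < 2L) return(NA_real_)
  seg <- apply(A, 2, function(x) length(unique(x[!is.na(x)])) > 1L)
  S <- sum(seg)
  if (S == 0L) return(NA_real_)
  khat <- sum(apply(A[, seg, drop = FALSE], 2, function(x) {
    x <- x[!is.na(x)]
    ns <- length(x)
    if (ns < 2L) return(0)
    counts <- table(x)
    (1 - sum((counts / ns)^2)) * ns / (ns - 1)
  }))
  k <- tajima_constants(n)
  denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  if (denom == 0) return(NA_real_)
  (khat - S / k$a1) / denom
}

# r^2 between two 0/1-coded site vectors over complete observations
r_squared <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  pA <- mean(x); pB <- mean(y)
  vv <- pA * (1 - pA) * pB * (1 - pB)
  if (vv == 0) return(NA_real_)
  (mean(x * y) - pA * pB)^2 / vv
}

#' ZnS: mean pairwise r-squared linkage disequilibrium
#'
#' Unweighted mean of r^2 over all pairs of biallelic segregating sites in
#' the window, excluding singletons (minor-allele count 1 within the
#' analyzed population).
#'
#' @inheritParams nuc_div
#' @return ZnS in `[0, 1]`; `NA` with fewer than 2 retained sites.
#' @export
zns <- function(hap, pop, start = NULL, end = NULL, mask = NULL) {
  A <- window_submatrix(hap, pop, start, end, mask)
  if (nrow(A) < 2L) return(NA_real_)
  keep <- apply(A, 2, function(x) {
    x <- x[!is.na(x)]
    counts <- table(x)
    length(counts) == 2L && min(counts) >= 2L
  })
  A <- A[, keep, drop = FALSE]
  if (ncol(A) < 2L) return(NA_real_)
  # recode to 0/1 by first observed allele
  B <- apply(A, 2, function(x) as.integer(x != x[which(!is.na(x))[1]]))
  B[is.na(A)] <- NA_integer_
  pairs <- utils::combn(ncol(A), 2L)
  r2 <- apply(pairs, 2, function(p) r_squared(B[, p[1]], B[, p[2]]))
  if (all(is.na(r2))) return(NA_real_)
  mean(r2, na.rm = TRUE)
}

#' Between-population divergence D_XY and minimum pairwise distance
#'
#' Per-site sequence distance over all cross-population haplotype pairs:
#' the mean (D_XY) and the minimum (min D_XY), the two ingredients of the
#' G_min ratio. Pairs with fewer than `min_overlap` comparable sites are
#' dropped.
#'
#' @inheritParams nuc_div
#' @param popA,popB The two population labels.
#' @param min_overlap Minimum comparable sites per pair (default 100).
#' @return Named numeric `c(dxy, min_dxy)`; both `NA` if every pair is
#'   dropped.
#' @export
dxy <- function(hap, popA, popB, start = NULL, end = NULL, mask = NULL,
                min_overlap = 100L) {
  A <- window_submatrix(hap, popA, start, end, mask)
  B <- window_submatrix(hap, popB, start, end, mask)
  if (nrow(A) < 1L || nrow(B) < 1L)
    stop("need at least one haplotype per population")
  L <- window_callable_len(hap, start, end, mask)
  tab <- pair_distance_table(A, B, L)
  tab <- tab[tab$comparable >= min_overlap, , drop = FALSE]
  if (nrow(tab) == 0L) return(c(dxy = NA_real_, min_dxy = NA_real_))
  d <- tab$diffs / tab$comparable
  c(dxy = mean(d), min_dxy = min(d))
}

#' Net divergence D_A
#'
#' `D_A = D_XY - (pi_A + pi_B) / 2`. Can be negative when within-population
#' diversity exceeds between-population divergence (expected for very
#' recently diverged populations retaining ancestral variation).
#'
#' @param dxy_value Mean between-population per-site distance.
#' @param piA,piB Within-population diversities.
#' @return Net divergence; `NA` if any input is `NA`.
#' @export
da <- function(dxy_value, piA, piB) {
  dxy_value - (piA + piB) / 2
}

#' Window F_ST between two populations
#'
#' Ratio-of-sums fixation index over biallelic sites. Two estimators:
#' `"wc"` (default), a Weir-Cockerham-type variance-components estimator
#' for haploid samples, and `"hudson"`, `1 - pi_within / pi_between` with
#' window-level ratio of sums.
#'
#' @inheritParams dxy
#' @param estimator `"wc"` or `"hudson"`.
#' @return F_ST (clamped to at most 1); `NA` when no site segregates
#'   between the pooled samples.
#' @export
fst <- function(hap, popA, popB, start = NULL, end = NULL, mask = NULL,
                estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  A <- window_submatrix(hap, popA, start, end, mask)
  B <- window_submatrix(hap, popB, start, end, mask)
  if (nrow(A) < 2L || nrow(B) < 2L) return(NA_real_)
  if (estimator == "hudson") {
    L <- window_callable_len(hap, start, end, mask)
    piw <- c(nuc_div(hap, popA, start, end, mask),
             nuc_div(hap, popB, start, end, mask))
    tabB <- pair_distance_table(A, B, L)
    pib <- mean(tabB$diffs / tabB$comparable)
    if (is.na(pib) || pib == 0) return(NA_real_)
    return(min(1, 1 - mean(piw) / pib))
  }
  num <- 0; den <- 0
  for (s in seq_len(ncol(A))) {
    x <- A[, s]; y <- B[, s]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    n1 <- length(x); n2 <- length(y)
    if (n1 < 2L || n2 < 2L) next
    all_alleles <- c(x, y)
    alleles <- unique(all_alleles)
    if (length(alleles) != 2L) next # monomorphic or multiallelic site
    p1 <- mean(x == alleles[2]); p2 <- mean(y == alleles[2])
    comp <- wc_site_components(n1, n2, p1, p2)
    num <- num + comp[1]
    den <- den + comp[2]
  }
  if (den == 0) return(NA_real_)
  min(1, num / den)
}

# Weir & Cockerham (1984) variance components for haploid samples at one
# biallelic site; returns c(a, a + b)
wc_site_components <- function(n1, n2, p1, p2) {
  r <- 2
  n <- c(n1, n2); p <- c(p1, p2)
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r)
  c(a, a + b)
}

#' Coalescence-time ratio implied by F_ST
#'
#' Under the two-population island/split relation `F_ST = (T_b - T_w) /
#' (T_b + T_w)` (Slatkin), the ratio of mean between- to within-population
#' coalescence times is `(1 + F_ST) / (1 - F_ST)`.
#'
#' @param fst_value F_ST value(s).
#' @return The fold-depth ratio; `Inf` (with a warning) for `F_ST >= 1`,
#'   `NA` for `NA` input.
#' @export
coalescence_time_ratio <- function(fst_value) {
  out <- (1 + fst_value) / (1 - fst_value)
  if (any(fst_value >= 1, na.rm = TRUE)) {
    warning("F_ST >= 1: infinite coalescence-time ratio")
    out[!is.na(fst_value) & fst_value >= 1] <- Inf
  }
  out
}

#' Polarize SNPs against an outgroup by parsimony
#'
#' A site is polarized when the outgroup carries a single observed allele
#' that matches one of the focal alleles: that allele is called ancestral
#' and the other focal allele derived. Sites where the outgroup is missing,
#' polymorphic, or carries an allele absent from the focal sample, and
#' focal sites that are not biallelic, are left unpolarized and excluded
#' from the ancestral/derived tallies.
#'
#' Each population's polymorphisms are then partitioned: a polymorphism
#' whose derived allele is also observed in the other population is
#' counted as a retained ancestral (shared) polymorphism; one whose
#' derived allele is private is counted as a new, lineage-specific derived
#' polymorphism.
#'
#' @param hap Focal [haplotype_matrix()] (two populations).
#' @param outgroup A [haplotype_matrix()] of outgroup haplotypes on the
#'   same coordinates.
#' @return A list with `sites` (per-site data frame: position, polarized,
#'   ancestral/derived codes, per-population derived frequencies) and
#'   `counts` (per-population polymorphism partition with percentages).
#' @export
polarize <- function(hap, outgroup) {
  stopifnot(inherits(hap, "haplotype_matrix"),
            inherits(outgroup, "haplotype_matrix"))
  og_idx <- match(hap$positions, outgroup$positions)
  pops <- unique(hap$pops)
  S <- length(hap$positions)
  anc <- rep(NA_integer_, S)
  der <- rep(NA_integer_, S)
  freq <- matrix(NA_real_, S, length(pops), dimnames = list(NULL, pops))
  for (s in seq_len(S)) {
    x <- hap$alleles[, s]
    focal <- sort(unique(x[!is.na(x)]))
    if (length(focal) > 2L) next
    o <- if (is.na(og_idx[s])) integer(0) else {
      oo <- outgroup$alleles[, og_idx[s]]
      unique(oo[!is.na(oo)])
    }
    if (length(o) != 1L || !(o %in% focal)) next
    anc[s] <- o
    der[s] <- if (length(focal) == 2L) setdiff(focal, o) else NA_integer_
    for (p in pops) {
      xp <- x[hap$pops == p]
      xp <- xp[!is.na(xp)]
      if (length(xp) == 0L) next
      freq[s, p] <- if (is.na(der[s])) 0 else mean(xp == der[s])
    }
  }
  polarized <- !is.na(anc)
  sites <- data.frame(position = hap$positions, polarized = polarized,
                      ancestral = anc, derived = der)
  sites <- cbind(sites, as.data.frame(freq))
  counts <- lapply(seq_along(pops), function(k) {
    other <- freq[, -k, drop = FALSE]
    f <- freq[, k]
    poly <- polarized & !is.na(f) & f > 0 & f < 1 & !is.na(der)
    shared <- poly & apply(other, 1, function(z) any(z > 0, na.rm = TRUE))
    n_poly <- sum(poly)
    n_shared <- sum(shared)
    c(n_polymorphic = n_poly, n_ancestral_shared = n_shared,
      n_derived_private = n_poly - n_shared,
      pct_ancestral = if (n_poly) 100 * n_shared / n_poly else NA_real_,
      pct_derived = if (n_poly) 100 * (n_poly - n_shared) / n_poly
                    else NA_real_)
  })
  names(counts) <- pops
  list(sites = sites, counts = counts)
}

#' Windowed summary-statistic table
#'
#' Computes the full per-window statistic vector for a two-population
#' haplotype matrix: callable fraction, pi / Tajima's D / ZnS per
#' population, D_XY, min D_XY, D_A, F_ST and G_min. Statistics are
#' computed only for windows whose callable fraction meets
#' `min_fraction`; failing windows keep `NA` statistics.
#'
#' @param hap A [haplotype_matrix()].
#' @param windows Data frame from [make_windows()] (this chromosome only).
#' @param popA,popB Population labels; default the first two label values.
#' @param mask Optional [site_mask()].
#' @param min_fraction Callable-fraction retention threshold (default 0.5).
#' @param min_overlap Minimum comparable sites per haplotype pair.
#' @param fst_estimator Passed to [fst()].
#' @param statistics `"full"` (default) computes every column;
#'   `"divergence"` computes only the distance-based columns (pi, D_XY,
#'   min D_XY, D_A, F_ST, G_min), leaving Tajima's D and ZnS `NA` — much
#'   faster for large scans that only feed the G_min test.
#' @return Data frame, one row per window, columns `chrom, start, end,
#'   callable_fraction, pi_pop1, pi_pop2, tajd_pop1, tajd_pop2, zns_pop1,
#'   zns_pop2, dxy, min_dxy, da, fst, gmin`.
#' @export
window_stats <- function(hap, windows, popA = NULL, popB = NULL, mask = NULL,
                         min_fraction = 0.5, min_overlap = 100L,
                         fst_estimator = "wc",
                         statistics = c("full", "divergence")) {
  statistics <- match.arg(statistics)
  upops <- unique(hap$pops)
  if (is.null(popA)) popA <- upops[1]
  if (is.null(popB)) popB <- upops[2]
  windows <- windows[windows$chrom == hap$chrom, , drop = FALSE]
  windows <- window_passes_filter(windows, mask, min_fraction)
  n <- nrow(windows)
  cols <- c("pi_pop1", "pi_pop2", "tajd_pop1", "tajd_pop2", "zns_pop1",
            "zns_pop2", "dxy", "min_dxy", "da", "fst", "gmin")
  stats <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  for (i in seq_len(n)) {
    if (!windows$pass[i]) next
    s <- windows$start[i]; e <- windows$end[i]
    p1 <- nuc_div(hap, popA, s, e, mask, min_overlap)
    p2 <- nuc_div(hap, popB, s, e, mask, min_overlap)
    dd <- dxy(hap, popA, popB, s, e, mask, min_overlap)
    full <- statistics == "full"
    stats[i, ] <- c(
      p1, p2,
      if (full) tajimas_d(hap, popA, s, e, mask) else NA_real_,
      if (full) tajimas_d(hap, popB, s, e, mask) else NA_real_,
      if (full) zns(hap, popA, s, e, mask) else NA_real_,
      if (full) zns(hap, popB, s, e, mask) else NA_real_,
      dd["dxy"], dd["min_dxy"], da(dd[["dxy"]], p1, p2),
      fst(hap, popA, popB, s, e, mask, fst_estimator),
      gmin(dd[["min_dxy"]], dd[["dxy"]]))
  }
  out <- cbind(windows[, c("chrom", "start", "end", "callable_fraction")],
               as.data.frame(stats))
  attr(out, "pops") <- c(popA, popB)
  attr(out, "min_fraction") <- min_fraction
  out
}

#' Write a window-statistic table as TSV
#'
#' Fixed column order, `NA` for undefined values.
#'
#' @param stats Data frame from [window_stats()].
#' @param path Output path.
#' @export
write_window_stats <- function(stats, path) {
  cols <- c("chrom", "start", "end", "callable_fraction", "pi_pop1",
            "pi_pop2", "tajd_pop1", "tajd_pop2", "zns_pop1", "zns_pop2",
            "dxy", "min_dxy", "da", "fst", "gmin")
  write.table(stats[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
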