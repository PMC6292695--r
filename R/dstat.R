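#' Frequency-weighted ABBA / BABA site patterns
#'
#' Probabilistic contribution of a site to the two discordant patterns,
#' from derived-allele frequencies in the four populations
#' (((P1, P2), P3), Outgroup) with derived = B:
#' `abba = (1 - p1) p2 p3 (1 - p4)` and `baba = p1 (1 - p2) p3 (1 - p4)`.
#' Sites polarized against the outgroup but with residual derived alleles
#' in it (`p4 > 0`) are down-weighted by `1 - p4` rather than discarded.
#'
#' @param p1,p2,p3,p4 Derived-allele frequencies (vectors) in P1, P2, P3
#'   and the outgroup.
#' @return Data frame with columns `abba`, `baba`; rows with any `NA`
#'   frequency are `NA` (skipped by downstream sums).
#' @export
site_patterns <- function(p1, p2, p3, p4) {
  stopifnot(length(p1) == length(p2), length(p2) == length(p3),
            length(p3) == length(p4))
  rng_ok <- function(p) all(p >= 0 & p <= 1, na.rm = TRUE)
  if (!rng_ok(p1) || !rng_ok(p2) || !rng_ok(p3) || !rng_ok(p4))
    stop("frequencies must be in [0, 1]")
  data.frame(abba = (1 - p1) * p2 * p3 * (1 - p4),
             baba = p1 * (1 - p2) * p3 * (1 - p4))
}

#' Patterson's D statistic
#'
#' `D = (sum ABBA - sum BABA) / (sum ABBA + sum BABA)`.
#'
#' @param abba_sum,baba_sum Weighted pattern sums.
#' @return D in `[-1, 1]`; `NA` when both sums are zero.
#' @export
patterson_d <- function(abba_sum, baba_sum) {
  denom <- abba_sum + baba_sum
  ifelse(denom == 0, NA_real_, (abba_sum - baba_sum) / denom)
}

#' Construct a four-population frequency panel
#'
#' Per-site derived-allele frequencies for populations (P1, P2, P3,
#' Outgroup), with genomic positions and jackknife block assignment on
#' fixed physical tiles (default 1 Mb). A terminal partial block is kept
#' if it contains at least one site.
#'
#' @param p1,p2,p3,p4 Derived-allele frequency vectors.
#' @param chrom Chromosome per site (recycled if length 1).
#' @param positions Physical positions (bp, 0-based).
#' @param block_size Jackknife block size in bp (default 1e6).
#' @return Data frame of class `quad_panel` with columns `chrom`,
#'   `position`, `p1..p4`, `block`.
#' @export
quad_freq_panel <- function(p1, p2, p3, p4, chrom, positions,
                            block_size = 1e6) {
  n <- length(positions)
  chrom <- rep_len(as.character(chrom), n)
  panel <- data.frame(chrom = chrom, position = positions,
                      p1 = p1, p2 = p2, p3 = p3, p4 = p4)
  panel$block <- paste0(chrom, ":", floor(positions / block_size))
  class(panel) <- c("quad_panel", "data.frame")
  panel
}

#' Fit Patterson's D with a block jackknife
#'
#' Computes the frequency-weighted ABBA/BABA sums over all complete
#' sites, Patterson's D, the delete-one-block jackknife standard error,
#' and `Z = D / SE`.
#'
#' @param panel A [quad_freq_panel()].
#' @return Object of class `dstat`: list with `abba_sum`, `baba_sum`,
#'   `D`, `se`, `Z`, `n_blocks`, `n_sites`.
#' @export
d_stat <- function(panel) {
  w <- site_patterns(panel$p1, panel$p2, panel$p3, panel$p4)
  ok <- complete.cases(w)
  w <- w[ok, , drop = FALSE]
  blocks <- panel$block[ok]
  A <- sum(w$abba); B <- sum(w$baba)
  se <- jackknife_se(w$abba, w$baba, blocks)
  D <- patterson_d(A, B)
  structure(list(abba_sum = A, baba_sum = B, D = D, se = se,
                 Z = if (!is.na(se) && se > 0) D / se else NA_real_,
                 n_blocks = length(unique(blocks)), n_sites = nrow(w)),
            class = "dstat")
}

#' @export
print.dstat <- function(x, ...) {
  cat(sprintf("Patterson's D = %.4f (ABBA = %.1f, BABA = %.1f)\n",
              x$D, x$abba_sum, x$baba_sum))
  cat(sprintf("  block jackknife SE = %s over %d blocks (Z = %s); %d sites\n",
              formatC(x$se, digits = 4, format = "g"), x$n_blocks,
              formatC(x$Z, digits = 3, format = "g"), x$n_sites))
  invisible(x)
}

#' Delete-one-block jackknife standard error for Patterson's D
#'
#' Removes each block in turn, recomputes D from the remaining pattern
#' sums, and applies the standard jackknife variance formula
#' `SE^2 = ((B - 1) / B) * sum (D_(i) - mean D_(i))^2`.
#'
#' @param abba,baba Per-site weighted pattern contributions.
#' @param blocks Block identifier per site.
#' @return The jackknife SE; `NA` with fewer than 2 non-empty blocks.
#' @export
jackknife_se <- function(abba, baba, blocks) {
  a_by <- tapply(abba, blocks, sum)
  b_by <- tapply(baba, blocks, sum)
  B <- length(a_by)
  if (B < 2L) return(NA_real_)
  A <- sum(a_by); Btot <- sum(b_by)
  d_i <- vapply(seq_len(B), function(i)
    patterson_d(A - a_by[i], Btot - b_by[i]), numeric(1))
  if (anyNA(d_i)) return(NA_real_)
  sqrt((B - 1) / B * sum((d_i - mean(d_i))^2))
}

#' Contrast ABBA/BABA composition between a region and its background
#'
#' Pearson chi-square test (1 df, no continuity correction) on the 2x2
#' table `[[abba_r, baba_r], [abba_b, baba_b]]`. Weighted sums are used
#' as-is (possibly fractional) unless `round = TRUE`. If any expected
#' cell is below 1, the test falls back to Fisher's exact test on rounded
#' counts with a warning.
#'
#' @param region_sums Numeric `c(abba, baba)` for the region.
#' @param background_sums Numeric `c(abba, baba)` for the background.
#' @param round Round sums to integers before testing.
#' @return List with `statistic`, `df`, `p.value`, `method`.
#' @export
region_contrast <- function(region_sums, background_sums, round = FALSE) {
  tab <- rbind(region_sums, background_sums)
  if (round) tab <- round(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    warning("expected cell count < 1; using Fisher's exact test on ",
            "rounded counts")
    ft <- fisher.test(round(tab))
    return(list(statistic = NA_real_, df = NA_integer_,
                p.value = ft$p.value, method = "fisher"))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value, method = "chisq")
}

#' Per-chromosome and per-region D-statistic report
#'
#' @param panel A [quad_freq_panel()].
#' @param regions Optional data frame (`chrom`, `start`, `end`) of
#'   regions to report separately.
#' @return Data frame with one row for the genome, one per chromosome,
#'   and one per region: scope, ABBA/BABA sums, D, SE, Z.
#' @export
dstat_report <- function(panel, regions = NULL) {
  row_for <- function(scope, sub) {
    fit <- d_stat(sub)
    data.frame(scope = scope, abba = fit$abba_sum, baba = fit$baba_sum,
               D = fit$D, se = fit$se, Z = fit$Z, n_sites = fit$n_sites)
  }
  out <- list(row_for("genome", panel))
  for (ch in unique(panel$chrom))
    out <- c(out, list(row_for(ch, panel[panel$chrom == ch, ])))
  if (!is.null(regions)) {
    for (k in seq_len(nrow(regions))) {
      sel <- panel$chrom == regions$chrom[k] &
        panel$position >= regions$start[k] & panel$position < regions$end[k]
      out <- c(out, list(row_for(
        sprintf("%s:%d-%d", regions$chrom[k], regions$start[k],
                regions$end[k]), panel[sel, ])))
    }
  }
  do.call(rbind, out)
}
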