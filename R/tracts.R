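#' Merge significant windows into introgression tracts
#'
#' Significant windows on the same chromosome are merged into maximal
#' runs, bridging up to `gap_tolerance` consecutive non-significant
#' windows ("semi-contiguous" runs); tract ends coincide with the
#' outermost significant windows. Window adjacency is taken from row
#' order within each chromosome, so the input should contain every tested
#' window in genomic order.
#'
#' @param results Data frame with columns `chrom`, `start`, `end`,
#'   `significant`, and (optionally) `gmin`, `min_dxy`, `rho_mean` for
#'   tract summaries — e.g. the `results` of a [gmin_scan()] merged with
#'   the window statistics.
#' @param gap_tolerance Maximum number of consecutive non-significant
#'   windows bridged inside a tract (default 1).
#' @return Data frame of tracts: `chrom`, `start`, `end`, `length`,
#'   `n_windows` (significant members), plus `mean_gmin`, `min_min_dxy`,
#'   `mean_rho` when the inputs carry those columns.
#' @export
merge_tracts <- function(results, gap_tolerance = 1L) {
  stopifnot(all(c("chrom", "start", "end", "significant") %in%
                  names(results)))
  out <- list()
  for (ch in unique(results$chrom)) {
    d <- results[results$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    sig_idx <- which(d$significant)
    if (length(sig_idx) == 0L) next
    run_id <- cumsum(c(1L, diff(sig_idx) > gap_tolerance + 1L))
    for (g in split(sig_idx, run_id)) {
      members <- d[g, , drop = FALSE]
      tract <- data.frame(chrom = ch, start = min(members$start),
                          end = max(members$end))
      tract$length <- tract$end - tract$start
      tract$n_windows <- nrow(members)
      if ("gmin" %in% names(members)) tract$mean_gmin <- mean(members$gmin)
      if ("min_dxy" %in% names(members))
        tract$min_min_dxy <- min(members$min_dxy)
      if ("rho_mean" %in% names(members))
        tract$mean_rho <- mean(members$rho_mean)
      out <- c(out, list(tract))
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      n_windows = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract introgression tracts from a scan
#'
#' @param x A [gmin_scan()] object (or anything with `merge_tracts()`
#'   columns).
#' @param gap_tolerance Passed to [merge_tracts()].
#' @param ... Unused.
#' @export
tracts <- function(x, ...) UseMethod("tracts")

#' @rdname tracts
#' @export
tracts.gmin_scan <- function(x, gap_tolerance = 1L, ...) {
  merge_tracts(x$results, gap_tolerance)
}

#' @rdname tracts
#' @export
tracts.data.frame <- function(x, gap_tolerance = 1L, ...) {
  merge_tracts(x, gap_tolerance)
}

#' Spearman correlates of tract length
#'
#' Rank correlations (average-rank ties) of tract length against mean
#' G_min, minimum min[D_XY], and mean local recombination rate, with
#' two-sided permutation p-values (labels of the second variable
#' permuted). Longer tracts are expected to be younger, hence to carry
#' lower G_min; long tracts are also expected in low-recombination
#' environments.
#'
#' @param tract_table Data frame from [merge_tracts()].
#' @param n_perm Number of permutations for the p-values.
#' @param seed RNG seed.
#' @return Data frame with columns `variable`, `rho`, `p`, `n`; `NA` rho
#'   with fewer than 3 tracts.
#' @export
tract_correlations <- function(tract_table, n_perm = 1000L, seed = 1L) {
  vars <- intersect(c("mean_gmin", "min_min_dxy", "mean_rho"),
                    names(tract_table))
  set.seed(seed)
  out <- lapply(vars, function(v) {
    x <- tract_table$length
    y <- tract_table[[v]]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L)
      return(data.frame(variable = v, rho = NA_real_, p = NA_real_,
                        n = length(x)))
    rho <- cor(x, y, method = "spearman")
    perm <- replicate(n_perm, abs(cor(x, sample(y), method = "spearman")))
    p <- (1 + sum(perm >= abs(rho))) / (1 + n_perm)
    data.frame(variable = v, rho = rho, p = p, n = length(x))
  })
  do.call(rbind, out)
}

#' Segment-placement permutation test
#'
#' Estimates the probability that a randomly placed segment of length
#' `segment_length` on a chromosome of length `chrom_length` contains all
#' of a set of loci: segment starts are uniform on `[0, L - W]` and a
#' placement is a hit iff every locus falls inside the half-open segment.
#' Used to ask whether an observed introgression's overlap with specific
#' loci is surprising.
#'
#' @param chrom_length Chromosome length (bp).
#' @param segment_length Segment length W (bp), `< chrom_length`.
#' @param locus_positions Positions (bp) that must all be covered.
#' @param n_perm Number of random placements (default 1e5).
#' @param seed RNG seed.
#' @param add_one Use the add-one p-value estimator instead of the raw
#'   hit proportion.
#' @return List with `hits`, `n_perm`, `p`, `seed`.
#' @export
placement_test <- function(chrom_length, segment_length, locus_positions,
                           n_perm = 1e5, seed = 1L, add_one = FALSE) {
  if (segment_length >= chrom_length)
    stop("segment_length must be smaller than chrom_length")
  if (length(locus_positions) < 1L) stop("need at least one locus")
  if (any(locus_positions < 0 | locus_positions >= chrom_length))
    stop("locus outside chromosome")
  set.seed(seed)
  lo <- min(locus_positions)
  hi <- max(locus_positions)
  starts <- runif(n_perm, 0, chrom_length - segment_length)
  hits <- sum(starts <= lo & hi < starts + segment_length)
  p <- if (add_one) (1 + hits) / (1 + n_perm) else hits / n_perm
  list(hits = hits, n_perm = as.integer(n_perm), p = p,
       seed = as.integer(seed))
}

#' Write tracts as a BED file
#'
#' Columns: chrom, start, end, name, mean G_min (score slot).
#'
#' @param tract_table Data frame from [merge_tracts()].
#' @param path Output path.
#' @export
write_tracts_bed <- function(tract_table, path) {
  n <- nrow(tract_table)
  bed <- data.frame(chrom = tract_table$chrom, start = tract_table$start,
                    end = tract_table$end,
                    name = sprintf("tract_%03d", seq_len(max(n, 0))),
                    score = if ("mean_gmin" %in% names(tract_table))
                      signif(tract_table$mean_gmin, 4) else ".")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
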