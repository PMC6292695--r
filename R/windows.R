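#' Tile chromosomes into analysis windows
#'
#' Generates 0-based half-open windows covering each chromosome from 0 to
#' its length. The terminal window may be shorter than `size`. With
#' `step = size` (the default) the windows are non-overlapping and tile
#' every base exactly once; `step < size` gives sliding windows.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param size Window size in bp (default 10 kb, the standard scan scale).
#' @param step Step between window starts; defaults to `size`. `step >
#'   size` would leave gaps and is an error.
#'
#' @return Data frame with columns `chrom`, `start`, `end`.
#' @export
make_windows <- function(chrom_lengths, size = 10000L, step = size) {
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == ""))
    stop("chrom_lengths must be a named vector")
  size <- as.integer(size)
  step <- as.integer(step)
  if (size <= 0L) stop("size must be positive")
  if (step <= 0L) stop("step must be positive")
  if (step > size) stop("step > size would leave gaps between windows")
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- as.integer(chrom_lengths[[ch]])
    if (len <= 0L) stop("chromosome length must be positive: ", ch)
    starts <- seq.int(0L, len - 1L, by = step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + size, len))
  })
  do.call(rbind, out)
}

#' Construct a callable-site mask
#'
#' A mask records which reference positions pass site-quality filters, as
#' a set of 0-based half-open passing intervals per chromosome.
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open passing intervals).
#' @param chrom_lengths Named vector giving the coordinate span the mask
#'   covers.
#' @return An object of class `site_mask`.
#' @export
site_mask <- function(intervals, chrom_lengths) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$end <= intervals$start))
    stop("mask intervals must have end > start")
  bad <- !(intervals$chrom %in% names(chrom_lengths))
  if (any(bad))
    stop("mask interval on chromosome absent from chrom_lengths: ",
         intervals$chrom[bad][1])
  over <- intervals$end > chrom_lengths[intervals$chrom]
  if (any(over)) stop("mask interval extends past chromosome end")
  intervals <- intervals[order(intervals$chrom, intervals$start), ,
                         drop = FALSE]
  structure(list(intervals = intervals, chrom_lengths = chrom_lengths),
            class = "site_mask")
}

#' @export
print.site_mask <- function(x, ...) {
  cat("site_mask:", nrow(x$intervals), "passing intervals on",
      length(x$chrom_lengths), "chromosome(s)\n")
  invisible(x)
}

#' Read a mask from a BED file of passing intervals
#'
#' @param path BED file (chrom, start, end; 0-based half-open).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return A [site_mask()].
#' @export
read_mask_bed <- function(path, chrom_lengths) {
  bed <- read.table(path, header = FALSE, sep = "\t")[, 1:3]
  names(bed) <- c("chrom", "start", "end")
  bed$chrom <- as.character(bed$chrom)
  site_mask(bed, chrom_lengths)
}

#' @rdname read_mask_bed
#' @param mask A [site_mask()] to write.
#' @export
write_mask_bed <- function(mask, path) {
  write.table(mask$intervals, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# number of mask-passing bases within [start, end) on chrom
mask_pass_count <- function(mask, chrom, start, end) {
  if (is.null(mask)) return(end - start)
  if (!(chrom %in% names(mask$chrom_lengths)))
    stop("window on chromosome outside mask coverage: ", chrom)
  if (start < 0 || end > mask$chrom_lengths[[chrom]])
    stop("window [", start, ",", end, ") outside mask coverage on ", chrom)
  iv <- mask$intervals[mask$intervals$chrom == chrom, , drop = FALSE]
  if (nrow(iv) == 0L) return(0L)
  sum(pmax(0L, pmin(iv$end, end) - pmax(iv$start, start)))
}

# logical: does each position pass the mask
mask_pass_positions <- function(mask, chrom, positions) {
  if (is.null(mask)) return(rep(TRUE, length(positions)))
  iv <- mask$intervals[mask$intervals$chrom == chrom, , drop = FALSE]
  if (nrow(iv) == 0L) return(rep(FALSE, length(positions)))
  # findInterval on sorted starts; check position < corresponding end
  idx <- findInterval(positions, iv$start)
  pass <- idx >= 1L
  pass[pass] <- positions[pass] < iv$end[idx[pass]]
  pass
}

#' Window callable fraction and retention filter
#'
#' Computes, per window, the fraction of sites passing the mask, and
#' whether the window is retained at the `min_fraction` threshold
#' (boundary inclusive: a window at exactly the threshold passes). The
#' standard scan retains windows with at least half their sites callable.
#'
#' @param windows Data frame from [make_windows()].
#' @param mask A [site_mask()], or `NULL` for no masking (all sites pass).
#' @param min_fraction Minimum callable fraction to retain a window
#'   (default 0.5).
#'
#' @return `windows` with added columns `callable_fraction` and `pass`.
#' @export
window_passes_filter <- function(windows, mask, min_fraction = 0.5) {
  if (is.null(mask)) {
    windows$callable_fraction <- 1
    windows$pass <- TRUE
    return(windows)
  }
  frac <- numeric(nrow(windows))
  for (ch in unique(windows$chrom)) {
    sel <- windows$chrom == ch
    if (!(ch %in% names(mask$chrom_lengths)))
      stop("window on chromosome outside mask coverage: ", ch)
    if (any(windows$start[sel] < 0) ||
        any(windows$end[sel] > mask$chrom_lengths[[ch]]))
      stop("window outside mask coverage on ", ch)
    iv <- mask$intervals[mask$intervals$chrom == ch, , drop = FALSE]
    if (nrow(iv) == 0L) { frac[sel] <- 0; next }
    # cumulative passing coverage strictly before a position x
    # (intervals are sorted and assumed non-overlapping)
    cum <- c(0, cumsum(iv$end - iv$start))
    cov_before <- function(x) {
      idx <- findInterval(x, iv$start)
      out <- cum[idx + 1L]
      out - pmax(0, iv$end[pmax(idx, 1L)] - x) * (idx >= 1L)
    }
    n_pass <- cov_before(windows$end[sel]) - cov_before(windows$start[sel])
    frac[sel] <- n_pass / (windows$end[sel] - windows$start[sel])
  }
  windows$callable_fraction <- frac
  windows$pass <- frac >= min_fraction
  windows
}
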