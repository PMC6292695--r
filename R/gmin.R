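#' The G_min statistic
#'
#' Ratio of the minimum to the mean pairwise sequence distance between
#' populations in a window: `G_min = min[D_XY] / mean[D_XY]`. Values near
#' 1 indicate reciprocal monophyly; small values flag a recently shared
#' (introgressed) haplotype.
#'
#' @param min_dxy Minimum cross-population pairwise distance(s).
#' @param dxy_mean Mean cross-population pairwise distance(s).
#' @return G_min in `[0, 1]`; `NA` where the mean distance is 0 or `NA`.
#' @export
gmin <- function(min_dxy, dxy_mean) {
  out <- ifelse(is.na(dxy_mean) | dxy_mean == 0, NA_real_,
                min_dxy / dxy_mean)
  out
}

#' Monte Carlo p-value from a simulated null
#'
#' Add-one estimator (Davison-Hinkley): `p = (1 + #{null <= obs}) /
#' (1 + R)`, which cannot be zero and yields valid tests.
#'
#' @param obs Observed statistic.
#' @param null_values Simulated null draws (small values significant).
#' @return p-value in `(0, 1]`; `NA` for `NA` observations.
#' @export
mc_pvalue <- function(obs, null_values) {
  if (length(null_values) == 0L) stop("null_values must be nonempty")
  null_values <- null_values[!is.na(null_values)]
  vapply(obs, function(o) {
    if (is.na(o)) return(NA_real_)
    (1 + sum(null_values <= o)) / (1 + length(null_values))
  }, numeric(1))
}

#' Plug-in false discovery rate for a scan
#'
#' Estimates the proportion of true nulls pi0 (Storey's estimator at
#' `lambda`, capped at 1) unless a fixed `pi0` is supplied, then the
#' plug-in FDR at threshold `alpha`: `FDR = pi0 * m * alpha / max(R, 1)`.
#'
#' @param pvalues Vector of per-window p-values (may be omitted when `m`
#'   and `R` are given directly).
#' @param alpha Significance threshold.
#' @param pi0 Fixed null proportion; `NULL` (default) estimates it.
#' @param lambda Storey tuning parameter (default 0.5).
#' @param m Number of tests (default `length(pvalues)`).
#' @param R Number of rejections (default `#{p <= alpha}`).
#' @return List with `m`, `alpha`, `R`, `pi0`, `fdr`.
#' @export
estimate_fdr <- function(pvalues = NULL, alpha = 0.001, pi0 = NULL,
                         lambda = 0.5, m = NULL, R = NULL) {
  if (is.null(pvalues) && (is.null(m) || is.null(R)))
    stop("supply pvalues, or m and R")
  if (!is.null(pvalues)) pvalues <- pvalues[!is.na(pvalues)]
  if (is.null(m)) m <- length(pvalues)
  if (is.null(R)) R <- sum(pvalues <= alpha)
  if (is.null(pi0)) {
    if (is.null(pvalues))
      stop("pi0 estimation needs pvalues; otherwise supply pi0")
    pi0 <- min(1, sum(pvalues > lambda) / ((1 - lambda) * m))
  }
  if (R == 0) {
    warning("no rejections at alpha = ", alpha, "; FDR reported as 0")
    fdr <- 0
  } else {
    fdr <- pi0 * m * alpha / R
  }
  list(m = m, alpha = alpha, R = R, pi0 = pi0, fdr = fdr)
}

#' Scan windows for significantly low G_min
#'
#' The central fitting function. For each retained window it calibrates
#' the null mutation rate from the window's observed D_XY
#' ([calibrate_theta()]), draws a recombination rate per replicate from a
#' truncated-normal prior (when one is supplied), simulates the
#' clean-split coalescent null, and assigns the observed G_min an add-one
#' Monte Carlo p-value from the simulated cumulative distribution.
#' Windows at or below `alpha` are flagged significant. When populations
#' differ in effective size (e.g. X vs autosomes), run separate scans
#' with appropriately calibrated priors.
#'
#' @param stats Window-statistic table from [window_stats()] (needs
#'   columns `chrom`, `start`, `end`, `callable_fraction`, `dxy`,
#'   `min_dxy`, `gmin`).
#' @param spec A [null_model_spec()]; its `theta` is overridden per
#'   window by the D_XY calibration, its `replicates`, `tau`, `n1`, `n2`
#'   and `locus_length` define the null.
#' @param rho_prior `NULL` for no recombination, a single
#'   [recomb_prior()] used for every window, or a data frame with columns
#'   `chrom`, `window_start`, `mean`, `variance` (rho units) matched to
#'   windows by start coordinate.
#' @param alpha Significance threshold (default 0.001, the standard
#'   genome-scan choice corresponding to a ~5\% plug-in FDR).
#' @param seed Root seed; per-window child seeds are derived from it so
#'   scans are reproducible.
#' @param backend Simulation backend ([simulate_split_locus()]):
#'   `"internal"` (rho = 0 only) or `"msprime"`.
#' @param theta_mode Passed to [calibrate_theta()].
#' @param pi0 Fixed null-proportion override for the FDR summary;
#'   `NULL` estimates it from the scan's p-values.
#' @param min_fraction Callable-fraction retention threshold.
#'
#' @return An object of class `gmin_scan` with components `results` (one
#'   row per tested window: `chrom, start, end, gmin, theta, rho_mean, p,
#'   significant`), `summary` (from [estimate_fdr()]), `spec`, `seed`,
#'   `backend`, `alpha`, and `n_skipped` (windows with undefined G_min).
#' @export
gmin_scan <- function(stats, spec = null_model_spec(), rho_prior = NULL,
                      alpha = 0.001, seed = 1L,
                      backend = c("internal", "msprime"),
                      theta_mode = "expectation_matched", pi0 = NULL,
                      min_fraction = 0.5) {
  backend <- match.arg(backend)
  stopifnot(inherits(spec, "null_model_spec"))
  keep <- stats$callable_fraction >= min_fraction & !is.na(stats$gmin) &
    !is.na(stats$dxy) & stats$dxy > 0
  n_skipped <- sum(stats$callable_fraction >= min_fraction & !keep)
  sc <- stats[keep, , drop = FALSE]
  nw <- nrow(sc)
  if (nw == 0L) stop("no windows with defined G_min to scan")

  theta <- calibrate_theta(sc$dxy, spec$locus_length, spec$tau, theta_mode)
  priors <- window_priors(rho_prior, sc)
  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, nw)

  p <- numeric(nw)
  rho_mean <- vapply(priors, function(pr)
    if (is.null(pr)) 0 else pr$mean, numeric(1))
  for (i in seq_len(nw)) {
    wspec <- spec
    wspec$theta <- theta[i]
    set.seed(child_seeds[i])
    rhos <- if (is.null(priors[[i]])) NULL
            else sample_rho(priors[[i]], spec$replicates)
    if (backend == "internal" && !is.null(rhos) && any(rhos > 0))
      stop("internal backend supports rho = 0 only; use backend='msprime' ",
           "or a zero prior")
    nulls <- cross_pair_null(wspec, rhos, seed = child_seeds[i])
    null_gmin <- gmin(nulls[, 1], nulls[, 2])
    p[i] <- mc_pvalue(sc$gmin[i], null_gmin)
  }

  results <- data.frame(chrom = sc$chrom, start = sc$start, end = sc$end,
                        gmin = sc$gmin, min_dxy = sc$min_dxy, theta = theta,
                        rho_mean = rho_mean, p = p, significant = p <= alpha)
  smry <- estimate_fdr(p, alpha = alpha, pi0 = pi0)
  structure(list(results = results, summary = smry, spec = spec,
                 alpha = alpha, seed = seed, backend = backend,
                 n_skipped = n_skipped),
            class = "gmin_scan")
}

# resolve the rho prior argument into one recomb_prior (or NULL) per window
window_priors <- function(rho_prior, sc) {
  if (is.null(rho_prior)) return(vector("list", nrow(sc)))
  if (inherits(rho_prior, "recomb_prior"))
    return(rep(list(rho_prior), nrow(sc)))
  stopifnot(is.data.frame(rho_prior),
            all(c("chrom", "window_start", "mean", "variance") %in%
                  names(rho_prior)))
  key <- paste(sc$chrom, sc$start)
  idx <- match(key, paste(rho_prior$chrom, rho_prior$window_start))
  if (anyNA(idx)) stop("rho_prior is missing windows: ",
                       key[is.na(idx)][1])
  lapply(seq_along(idx), function(k)
    recomb_prior(rho_prior$mean[idx[k]], rho_prior$variance[idx[k]]))
}

#' @export
print.gmin_scan <- function(x, ...) {
  s <- x$summary
  cat("G_min introgression scan\n")
  cat(sprintf("  windows tested: %d (skipped: %d)\n", s$m, x$n_skipped))
  cat(sprintf("  significant at alpha = %g: %d (pi0 = %.3f, FDR = %.3f)\n",
              x$alpha, s$R, s$pi0, s$fdr))
  cat(sprintf("  null: tau = %g, n = %d + %d, %d replicates/window (%s)\n",
              x$spec$tau, x$spec$n1, x$spec$n2, x$spec$replicates,
              x$backend))
  invisible(x)
}

#' @export
summary.gmin_scan <- function(object, ...) {
  r <- object$results
  by_chr <- do.call(rbind, lapply(split(r, r$chrom), function(d)
    data.frame(chrom = d$chrom[1], windows = nrow(d),
               significant = sum(d$significant),
               median_gmin = median(d$gmin))))
  rownames(by_chr) <- NULL
  out <- list(per_chromosome = by_chr, fdr = object$summary,
              alpha = object$alpha)
  class(out) <- "summary.gmin_scan"
  out
}

#' @export
print.summary.gmin_scan <- function(x, ...) {
  cat("Per-chromosome breakdown:\n")
  print(x$per_chromosome, row.names = FALSE)
  s <- x$fdr
  cat(sprintf("\nOverall: %d/%d significant at alpha = %g; pi0 = %.3f; FDR = %.3f\n",
              s$R, s$m, x$alpha, s$pi0, s$fdr))
  invisible(x)
}

#' @export
plot.gmin_scan <- function(x, ...) {
  r <- x$results
  chroms <- unique(r$chrom)
  op <- graphics::par(mfrow = c(length(chroms), 1),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (ch in chroms) {
    d <- r[r$chrom == ch, ]
    mid <- (d$start + d$end) / 2
    graphics::plot(mid / 1e6, d$gmin, pch = 16, cex = 0.6,
                   col = ifelse(d$significant, "red", "grey40"),
                   xlab = "position (Mb)", ylab = expression(G[min]),
                   main = ch, ylim = c(0, 1), ...)
    graphics::abline(h = median(d$gmin), lty = 2, col = "grey70")
  }
  invisible(x)
}

#' Write scan results as TSV and the summary as JSON
#'
#' @param scan A `gmin_scan` object.
#' @param tsv_path,json_path Output paths (either may be `NULL`).
#' @export
write_scan <- function(scan, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(scan, "gmin_scan"))
  if (!is.null(tsv_path))
    write.table(scan$results, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(json_path)) {
    s <- scan$summary
    jsonlite::write_json(
      list(m = s$m, alpha = s$alpha, R = s$R, pi0 = s$pi0, fdr = s$fdr,
           seed = scan$seed, backend = scan$backend,
           null_spec = unclass(scan$spec)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(scan)
}
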