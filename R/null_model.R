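#' Specify the two-population clean-split coalescent null
#'
#' The null model for the G_min scan: two populations of equal, constant
#' size that split `tau` time units ago (units of 4N generations) with no
#' subsequent migration, neutral infinite-sites mutation at per-locus rate
#' `theta` (4*N*mu*L) and crossover at per-locus rate `rho` (4*N*c*(L-1)).
#' Defaults mirror the standard scan design: 10 + 20 haploid samples,
#' split time 0.61, a 10,001-site locus, 1e5 replicates.
#'
#' @param tau Split time in units of 4N generations.
#' @param n1,n2 Haploid sample sizes of the two populations.
#' @param theta Per-locus population mutation rate.
#' @param rho Per-locus population recombination rate.
#' @param locus_length Number of sites in the simulated locus.
#' @param replicates Number of Monte Carlo replicates.
#' @return An object of class `null_model_spec`.
#' @export
null_model_spec <- function(tau = 0.61, n1 = 10L, n2 = 20L, theta = 50,
                            rho = 0, locus_length = 10001L,
                            replicates = 1e5) {
  if (tau <= 0) stop("tau must be positive")
  if (theta < 0 || rho < 0) stop("rates must be non-negative")
  if (n1 < 1L || n2 < 1L) stop("sample sizes must be at least 1")
  if (replicates < 1) stop("replicates must be at least 1")
  structure(list(tau = tau, n1 = as.integer(n1), n2 = as.integer(n2),
                 theta = theta, rho = rho,
                 locus_length = as.integer(locus_length),
                 replicates = as.integer(replicates)),
            class = "null_model_spec")
}

#' @export
print.null_model_spec <- function(x, ...) {
  cat(sprintf(
    "clean-split coalescent null: n = %d + %d, tau = %g (4N gens),\n",
    x$n1, x$n2, x$tau))
  cat(sprintf("  theta = %g, rho = %g over %d sites; %d replicates\n",
              x$theta, x$rho, x$locus_length, x$replicates))
  invisible(x)
}

#' Calibrate the null theta from observed divergence
#'
#' Under the clean split, the expected per-site between-population
#' distance is `theta * (2 tau + 1) / L`. The default
#' `"expectation_matched"` mode inverts this so the null reproduces the
#' observed local D_XY in expectation: `theta = dxy * L / (2 tau + 1)`.
#' `"direct"` mode uses `theta = dxy * L`.
#'
#' @param observed_dxy Observed per-site D_XY value(s).
#' @param locus_length Simulated locus length (sites).
#' @param tau Split time (4N units).
#' @param mode `"expectation_matched"` (default) or `"direct"`.
#' @return Per-locus theta value(s); `NA` input propagates.
#' @export
calibrate_theta <- function(observed_dxy, locus_length, tau = 0.61,
                            mode = c("expectation_matched", "direct")) {
  mode <- match.arg(mode)
  if (any(observed_dxy < 0, na.rm = TRUE)) stop("observed_dxy must be >= 0")
  if (mode == "expectation_matched")
    observed_dxy * locus_length / (2 * tau + 1)
  else
    observed_dxy * locus_length
}

#' Truncated-normal prior on the recombination rate
#'
#' Models uncertainty in the local crossover rate: per simulated
#' replicate, rho is drawn from Normal(mean, variance) truncated at zero.
#' The mean comes from a genetic-map estimate for the window; the variance
#' is typically the arm-level variance of the crossover estimates.
#'
#' @param mean Prior mean (rho units, i.e. 4Nc per locus).
#' @param variance Prior variance (rho units squared).
#' @return An object of class `recomb_prior`.
#' @export
recomb_prior <- function(mean, variance) {
  if (variance < 0) stop("variance must be non-negative")
  if (mean < 0) stop("prior mean must be non-negative")
  structure(list(mean = mean, variance = variance), class = "recomb_prior")
}

#' Draw recombination rates from a truncated-normal prior
#'
#' Rejection sampling from Normal(mean, variance) truncated at zero; with
#' zero variance every draw equals the mean.
#'
#' @param prior A [recomb_prior()].
#' @param n Number of draws.
#' @return Numeric vector of `n` non-negative rho draws.
#' @export
sample_rho <- function(prior, n) {
  stopifnot(inherits(prior, "recomb_prior"))
  if (prior$variance == 0) return(rep(prior$mean, n))
  sdv <- sqrt(prior$variance)
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    draw <- rnorm(length(need), prior$mean, sdv)
    ok <- draw >= 0
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Convert a genetic-map estimate from cM to rho
#'
#' `rho = 4 * N_sim * c`, with `c = cM / 100` the crossover probability
#' for the window and `N_sim` the effective size used for the conversion
#' (default 1e6).
#'
#' @param cm Crossover estimate in centimorgans per window.
#' @param n_sim Effective population size used for scaling.
#' @return rho per window.
#' @export
cm_to_rho <- function(cm, n_sim = 1e6) {
  if (any(cm < 0, na.rm = TRUE)) stop("cM estimates must be non-negative")
  4 * n_sim * cm / 100
}

# build a haplotype_matrix from one cpp replicate
rep_to_hap <- function(rep, n1, n2, chrom = "sim") {
  n <- n1 + n2
  ids <- c(sprintf("pop1_%02d", seq_len(n1)), sprintf("pop2_%02d", seq_len(n2)))
  hap <- haplotype_matrix(chrom, rep$positions, rep$alleles, ids,
                          c(rep("pop1", n1), rep("pop2", n2)))
  attr(hap, "migrant") <- rep$migrant
  hap
}

#' Self-contained coalescent simulator (no recombination)
#'
#' Hudson-style coalescent for the clean two-population split:
#' exponential coalescence within demes, deme merger at `tau`, Poisson
#' mutations on branches under infinite sites on a discrete lattice.
#' Serves as the validation backend so the whole test suite runs without
#' an external simulator; requires `rho = 0`.
#'
#' @param spec A [null_model_spec()] with `rho = 0`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param reps Number of replicates (default `spec$replicates`).
#' @return List of `reps` [haplotype_matrix()] objects with populations
#'   `pop1`, `pop2`.
#' @export
internal_coalescent <- function(spec, seed = NULL, reps = spec$replicates) {
  stopifnot(inherits(spec, "null_model_spec"))
  if (spec$rho != 0)
    stop("internal coalescent has no recombination; set rho = 0 ",
         "or use backend = 'msprime'")
  if (!is.null(seed)) set.seed(seed)
  events <- matrix(c(spec$tau, 0, 0, 1, 0), nrow = 1)
  raw <- cpp_sim_haplotypes(c(spec$n1, spec$n2), events, spec$theta,
                            spec$locus_length, as.integer(reps))
  lapply(raw, rep_to_hap, n1 = spec$n1, n2 = spec$n2)
}

#' Simulate replicate loci under the clean-split null
#'
#' Backend contract: sample `n1 + n2` lineages in two demes merging at
#' `tau`, equal constant sizes, infinite-sites mutation at rate `theta`,
#' crossover at rate `rho`. The `"internal"` backend (default) is the
#' package's own coalescent and supports `rho = 0` only; the `"msprime"`
#' backend shells out to the msprime library through `python` and supports
#' recombination.
#'
#' @inheritParams internal_coalescent
#' @param backend `"internal"` or `"msprime"`.
#' @return List of [haplotype_matrix()] replicates.
#' @export
simulate_split_locus <- function(spec, seed = NULL,
                                 backend = c("internal", "msprime"),
                                 reps = spec$replicates) {
  backend <- match.arg(backend)
  if (backend == "internal") return(internal_coalescent(spec, seed, reps))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  raw <- msprime_split(spec$n1, spec$n2, spec$tau, spec$theta,
                       rep(spec$rho, reps), spec$locus_length, seed)
  lapply(raw, function(r) {
    pos <- as.integer(floor(r$positions * spec$locus_length))
    # de-duplicate lattice collisions from fractional positions
    while (anyDuplicated(pos)) pos[duplicated(pos)] <- pos[duplicated(pos)] + 1L
    o <- order(pos)
    rep_to_hap(list(alleles = r$alleles[, o, drop = FALSE],
                    positions = pos[o],
                    migrant = rep(FALSE, spec$n1 + spec$n2)),
               spec$n1, spec$n2)
  })
}

#' Is the external msprime backend available?
#'
#' @return `TRUE` if `python` with an importable `msprime` is on the PATH.
#' @export
msprime_available <- function() {
  py <- Sys.which("python")
  if (py == "") return(FALSE)
  code <- suppressWarnings(system2(py, c("-c", shQuote("import msprime")),
                                   stdout = FALSE, stderr = FALSE))
  identical(code, 0L)
}

# run the msprime helper: one replicate per entry of rhos; returns a list
# of list(alleles, positions) with positions as locus fractions in [0,1)
msprime_split <- function(n1, n2, tau, theta, rhos, locus_length, seed) {
  script <- system.file("python", "split_backend.py", package = "gminscan")
  if (script == "") stop("msprime backend script not found")
  cfg <- jsonlite::toJSON(list(n1 = n1, n2 = n2, tau = tau, theta = theta,
                               rhos = rhos, L = locus_length,
                               seed = as.integer(seed)),
                          auto_unbox = TRUE, digits = NA)
  out <- system2(Sys.which("python"), script, input = as.character(cfg),
                 stdout = TRUE)
  if (!is.null(attr(out, "status")))
    stop("msprime backend failed: ", paste(utils::tail(out, 3),
                                           collapse = " / "))
  parse_ms_blocks(out)
}

# null distribution of per-replicate (min, mean) cross-population
# difference counts; dispatches to the fast compiled path when rho = 0
cross_pair_null <- function(spec, rhos = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rhos) || all(rhos == 0)) {
    m <- cpp_cross_pair_null(spec$n1, spec$n2, spec$tau, spec$theta,
                             if (is.null(rhos)) spec$replicates
                             else length(rhos))
    return(m)
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  raw <- msprime_split(spec$n1, spec$n2, spec$tau, spec$theta, rhos,
                       spec$locus_length, seed)
  t(vapply(raw, function(r) {
    A <- r$alleles[seq_len(spec$n1), , drop = FALSE]
    B <- r$alleles[spec$n1 + seq_len(spec$n2), , drop = FALSE]
    if (ncol(A) == 0L) return(c(0, 0))
    D <- A %*% (1 - t(B)) + (1 - A) %*% t(B)
    c(min(D), mean(D))
  }, numeric(2)))
}
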