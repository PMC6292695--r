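test_that("G_min is the min/mean ratio with its limiting values", {
  # all cross distances equal (reciprocal monophyly limit)
  expect_equal(gmin(0.4, 0.4), 1)
  # shared identical haplotype
  expect_equal(gmin(0, 0.3), 0)
  # cross distances {2,4,4,6} per 10 sites
  d <- c(2, 4, 4, 6) / 10
  expect_equal(gmin(min(d), mean(d)), 0.5)
  # undefined when the mean distance is zero
  expect_true(is.na(gmin(0, 0)))
  h <- hap_from_strings(c("00", "01", "11"), c("A", "A", "B"))
  dd <- dxy(h, "A", "B", min_overlap = 1)
  expect_equal(gmin(dd[["min_dxy"]], dd[["dxy"]]), 2 / 3)
})

test_that("add-one Monte Carlo p-values behave as order statistics", {
  # observed below every null draw
  expect_equal(mc_pvalue(-1, seq_len(999)), 1 / 1000)
  # observed at the null maximum
  expect_equal(mc_pvalue(999, seq_len(999)), 1)
  expect_true(is.na(mc_pvalue(NA_real_, 1:10)))
  expect_error(mc_pvalue(1, numeric(0)), "nonempty")

  # observed at the empirical null median -> p ~ 0.5
  set.seed(12)
  nulls <- rnorm(1e4)
  expect_equal(mc_pvalue(median(nulls), nulls), 0.5, tolerance = 0.02)

  # p-values always in (0, 1]
  obs <- rnorm(50)
  p <- mc_pvalue(obs, nulls)
  expect_true(all(p > 0 & p <= 1))
})

test_that("plug-in FDR reproduces the printed-count arithmetic", {
  # fixed pi0 with the genome-scan counts: FDR = 5% to the nearest percent
  f <- estimate_fdr(alpha = 0.001, pi0 = 0.982, m = 10443, R = 196)
  expect_equal(f$fdr, 0.982 * 10443 * 0.001 / 196)
  expect_equal(round(100 * f$fdr), 5)

  # uniform-null consistency: pi0 = 1, alpha = 0.05, m = 1000, R = 50
  f <- estimate_fdr(alpha = 0.05, pi0 = 1, m = 1000, R = 50)
  expect_equal(f$fdr, 1)

  # Storey estimate caps at 1 when all p-values are 1
  f <- suppressWarnings(estimate_fdr(rep(1, 100), alpha = 0.05))
  expect_equal(f$pi0, 1)
  expect_warning(estimate_fdr(rep(1, 10), alpha = 0.01), "no rejections")
})

make_null_stats <- function(n_windows, spec, seed, theta = 45) {
  # observed windows drawn from the null itself; distances as counts per
  # locus_length sites (complete data, so G_min is scale-free)
  set.seed(seed)
  obs <- gminscan:::cpp_cross_pair_null(spec$n1, spec$n2, spec$tau, theta,
                                        n_windows)
  data.frame(chrom = "chr1",
             start = (seq_len(n_windows) - 1L) * spec$locus_length,
             end = seq_len(n_windows) * spec$locus_length,
             callable_fraction = 1,
             dxy = obs[, 2] / spec$locus_length,
             min_dxy = obs[, 1] / spec$locus_length,
             gmin = obs[, 1] / obs[, 2])
}

test_that("scans are deterministic, monotone in alpha, and respect alpha=0", {
  spec <- null_model_spec(replicates = 300)
  st <- make_null_stats(15, spec, seed = 200)
  s1 <- suppressWarnings(gmin_scan(st, spec, seed = 5, alpha = 0.05))
  s2 <- suppressWarnings(gmin_scan(st, spec, seed = 5, alpha = 0.05))
  expect_identical(s1$results, s2$results)

  # significance count monotone non-increasing in alpha
  counts <- vapply(c(0.2, 0.1, 0.05, 0.01),
                   function(a) sum(s1$results$p <= a), numeric(1))
  expect_true(all(diff(counts) <= 0))

  # alpha = 0 flags nothing
  expect_warning(s0 <- gmin_scan(st, spec, seed = 5, alpha = 0),
                 "no rejections")
  expect_equal(sum(s0$results$significant), 0)

  # windows with undefined G_min are skipped and counted
  st$gmin[3] <- NA
  s3 <- suppressWarnings(gmin_scan(st, spec, seed = 5, alpha = 0.05))
  expect_equal(nrow(s3$results), 14)
  expect_equal(s3$n_skipped, 1L)
})

test_that("null windows yield well-calibrated Monte Carlo p-values", {
  # 200 windows simulated under the scan's own null; the rejection rate
  # at alpha = 0.05 must sit inside the binomial 99% CI
  spec <- null_model_spec(replicates = 400)
  st <- make_null_stats(200, spec, seed = 300)
  sc <- suppressWarnings(gmin_scan(st, spec, seed = 6, alpha = 0.05))
  rate <- mean(sc$results$p <= 0.05)
  ci <- 2.576 * sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(rate - 0.05), ci + 1e-9)
})

test_that("a recently introgressed haplotype is detected above the null rate", {
  # windows carrying a migrant haplotype at intermediate frequency should
  # reach small p far more often than alpha
  cfg <- sim_config(chrom_lengths = c(chr1 = 3e5),
                    pulses = list(list(source = "pop2", dest = "pop1",
                                       time = 0.05, proportion = 0.3)))
  ds <- generate_dataset(cfg, seed = 404)
  st <- window_stats(ds$haplotypes$chr1, ds$windows, mask = ds$mask,
                     min_overlap = 50, statistics = "divergence")
  spec <- null_model_spec(replicates = 2000)
  sc <- gmin_scan(st, spec, seed = 7, alpha = 0.001)
  lab <- ds$truth$labels$introgressed[match(sc$results$start,
                                            ds$truth$labels$start)]
  tpr <- mean(sc$results$significant[lab])
  expect_gt(tpr, 0.05) # far above the 0.001 null rate
})

test_that("scan priors can come from a genetic map data frame", {
  spec <- null_model_spec(replicates = 100)
  st <- make_null_stats(4, spec, seed = 11)
  pri <- data.frame(chrom = "chr1", window_start = st$start,
                    mean = 0, variance = 0)
  sc <- suppressWarnings(gmin_scan(st, spec, rho_prior = pri, seed = 2, alpha = 0.05))
  expect_equal(sc$results$rho_mean, rep(0, 4))
  # a missing window in the prior map is an error
  expect_error(gmin_scan(st, spec, rho_prior = pri[-2, ], seed = 2),
               "missing windows")
  # nonzero rho needs the msprime backend
  pri$mean <- 5
  expect_error(gmin_scan(st, spec, rho_prior = pri, seed = 2), "msprime")
})

test_that("scan summaries and tract extraction are consistent", {
  spec <- null_model_spec(replicates = 200)
  st <- make_null_stats(25, spec, seed = 12)
  sc <- suppressWarnings(gmin_scan(st, spec, seed = 3, alpha = 0.2))
  sm <- summary(sc)
  expect_equal(sum(sm$per_chromosome$windows), sc$summary$m)
  expect_equal(sum(sm$per_chromosome$significant), sc$summary$R)
  tr <- tracts(sc, gap_tolerance = 0)
  expect_equal(sum(tr$n_windows), sum(sc$results$significant))
  expect_output(print(sc), "introgression scan")
})
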