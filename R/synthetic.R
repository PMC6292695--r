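# Synthetic two-population datasets with known introgression truth.
# Windows are simulated as independent, non-recombining loci under the
# clean-split coalescent, with introgression modeled as mass-migration
# pulses; a pulse leaves an unambiguous truth label per window (does any
# destination-sample lineage trace through a migrant at the pulse?).

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate the standard study design this package targets: 10 +
#' 20 haploid samples from two populations that split 0.61 x 4N
#' generations ago, 10-kb windows, and a per-site between-population
#' divergence target of 0.01. Desk-scale default genome: two 2-Mb
#' chromosomes (400 windows).
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param window_size Window size (bp).
#' @param n1,n2 Haploid sample sizes (`pop1`, `pop2`).
#' @param tau Split time in 4N units.
#' @param dxy_target Expected per-site between-population divergence;
#'   sets the per-window theta as `dxy_target * L / (2 tau + 1)`.
#' @param pulses List of introgression pulses, each a list with elements
#'   `source`, `dest` (population labels), `time` (4N units, must predate
#'   the split looking backwards, i.e. `time < tau`) and `proportion`.
#' @param mask_beta Shape parameters of the Beta distribution from which
#'   per-window callable fractions are drawn (default `c(8, 2)`, mean
#'   0.8, a realistic mix of mostly-callable windows with a tail failing
#'   the 50\% retention rule).
#' @param map_mean_cm,map_sd_cm Mean and SD of the per-window crossover
#'   estimate (cM); draws are truncated at zero.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                       window_size = 1e4, n1 = 10L, n2 = 20L, tau = 0.61,
                       dxy_target = 0.01, pulses = list(),
                       mask_beta = c(8, 2), map_mean_cm = 0.02,
                       map_sd_cm = 0.01) {
  for (p in pulses) {
    stopifnot(all(c("source", "dest", "time", "proportion") %in% names(p)))
    if (p$time >= tau)
      stop("pulse time must predate the split (time < tau)")
    if (p$proportion < 0 || p$proportion > 1)
      stop("pulse proportion must be in [0, 1]")
    if (!all(c(p$source, p$dest) %in% c("pop1", "pop2")))
      stop("pulse populations must be 'pop1'/'pop2'")
  }
  structure(list(chrom_lengths = chrom_lengths,
                 window_size = as.integer(window_size),
                 n1 = as.integer(n1), n2 = as.integer(n2), tau = tau,
                 dxy_target = dxy_target, pulses = pulses,
                 mask_beta = mask_beta, map_mean_cm = map_mean_cm,
                 map_sd_cm = map_sd_cm),
            class = "sim_config")
}

# event matrix (time, kind, from, to, prob) for the two-population model;
# pulses act backwards in time: lineages in the destination deme jump to
# the source deme with probability `proportion`
split_events <- function(config) {
  deme <- c(pop1 = 0, pop2 = 1)
  ev <- lapply(config$pulses, function(p)
    c(p$time, 1, deme[[p$dest]], deme[[p$source]], p$proportion))
  ev <- c(ev, list(c(config$tau, 0, 0, 1, 0)))
  m <- do.call(rbind, ev)
  m[order(m[, 1]), , drop = FALSE]
}

#' Generate a synthetic two-population dataset with known truth
#'
#' Simulates every window of the configured genome as an independent
#' coalescent locus (clean split plus any configured pulses), and builds
#' the companion inputs the scan pipeline consumes: a callable-site mask,
#' a genetic map of per-window crossover estimates, and per-window truth
#' labels (`TRUE` where the realized genealogy carries at least one
#' migrant-derived lineage in the pulse destination).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; output is a pure function of
#'   `(config, seed)`.
#' @return List with `haplotypes` (one [haplotype_matrix()] per
#'   chromosome), `mask` ([site_mask()]), `map` (genetic-map data frame),
#'   `windows`, and `truth` (list: `seed`, `config`, `labels` data frame
#'   with per-window `introgressed` flags).
#' @export
generate_dataset <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  events <- split_events(config)
  wins <- make_windows(config$chrom_lengths, config$window_size)
  n <- config$n1 + config$n2
  ids <- c(sprintf("pop1_%02d", seq_len(config$n1)),
           sprintf("pop2_%02d", seq_len(config$n2)))
  pops <- c(rep("pop1", config$n1), rep("pop2", config$n2))

  haps <- list()
  mask_iv <- list()
  introgressed <- logical(nrow(wins))
  cm <- numeric(nrow(wins))
  for (ch in names(config$chrom_lengths)) {
    wi <- which(wins$chrom == ch)
    allele_parts <- list()
    pos_parts <- list()
    for (k in seq_along(wi)) {
      i <- wi[k]
      len <- wins$end[i] - wins$start[i]
      theta <- config$dxy_target * len / (2 * config$tau + 1)
      rep1 <- cpp_sim_haplotypes(c(config$n1, config$n2), events, theta,
                                 len, 1L)[[1]]
      allele_parts[[k]] <- rep1$alleles
      pos_parts[[k]] <- rep1$positions + wins$start[i]
      introgressed[i] <- any(rep1$migrant)

      # mask: one failing chunk per window sized by a Beta draw
      frac <- rbeta(1, config$mask_beta[1], config$mask_beta[2])
      fail_len <- round((1 - frac) * len)
      if (fail_len >= len) fail_len <- len - 1L
      if (fail_len > 0) {
        off <- floor(runif(1, 0, len - fail_len + 1))
        fs <- wins$start[i] + off
        fe <- fs + fail_len
        pass <- data.frame(chrom = ch,
                           start = c(wins$start[i], fe),
                           end = c(fs, wins$end[i]))
        pass <- pass[pass$end > pass$start, , drop = FALSE]
      } else {
        pass <- data.frame(chrom = ch, start = wins$start[i],
                           end = wins$end[i])
      }
      mask_iv[[length(mask_iv) + 1L]] <- pass

      cm[i] <- max(0, rnorm(1, config$map_mean_cm, config$map_sd_cm))
    }
    haps[[ch]] <- haplotype_matrix(ch, unlist(pos_parts),
                                   do.call(cbind, allele_parts), ids, pops)
  }
  mask <- site_mask(do.call(rbind, mask_iv), config$chrom_lengths)
  map <- data.frame(chrom = wins$chrom, window_start = wins$start, cm = cm)
  labels <- cbind(wins, introgressed = introgressed)
  list(haplotypes = haps, mask = mask, map = map, windows = wins,
       truth = list(seed = as.integer(seed), config = config,
                    labels = labels))
}

#' Configuration for the four-population frequency panel generator
#'
#' Topology (((P1, P2), P3), Outgroup); an optional P3 -> P2 pulse of
#' proportion `f` generates an ABBA excess (positive Patterson's D).
#'
#' @param n Haploid sample sizes for P1, P2, P3, Outgroup.
#' @param t12,t13,t_out Split times (4N units) of P1+P2, (P1,P2)+P3 and
#'   the outgroup.
#' @param t_pulse Pulse time (must be `< t12`).
#' @param f P3 -> P2 pulse proportion in `[0, 1]`.
#' @param theta Per-locus mutation rate.
#' @param n_loci,locus_length,locus_spacing Number of independent loci,
#'   their length (sites) and genomic spacing (bp) — spacing spreads the
#'   loci over multiple jackknife blocks.
#' @return A list of class `quad_config`.
#' @export
quad_config <- function(n = c(4L, 20L, 10L, 2L), t12 = 0.5, t13 = 1.0,
                        t_out = 10, t_pulse = 0.05, f = 0,
                        theta = 20, n_loci = 400L, locus_length = 2000L,
                        locus_spacing = 2e4) {
  if (f < 0 || f > 1) stop("f must be in [0, 1]")
  if (!(t12 < t13 && t13 < t_out)) stop("need t12 < t13 < t_out")
  if (f > 0 && t_pulse >= t12) stop("pulse must postdate the P1+P2 split")
  structure(list(n = as.integer(n), t12 = t12, t13 = t13, t_out = t_out,
                 t_pulse = t_pulse, f = f, theta = theta,
                 n_loci = as.integer(n_loci),
                 locus_length = as.integer(locus_length),
                 locus_spacing = locus_spacing),
            class = "quad_config")
}

#' Generate a four-population derived-allele frequency panel
#'
#' Simulates independent loci under the (((P1, P2), P3), O) coalescent
#' with an optional P3 -> P2 pulse, and returns per-site derived-allele
#' frequencies (ancestral state known from the simulation; the outgroup
#' frequency `p4` is nonzero only for mutations on the outgroup lineage).
#'
#' @param config A [quad_config()].
#' @param seed Integer seed.
#' @return List with `panel` (a [quad_freq_panel()]) and `truth` (list
#'   `f`, `seed`, `config`).
#' @export
generate_quad_panel <- function(config, seed = 1L) {
  stopifnot(inherits(config, "quad_config"))
  set.seed(seed)
  ev <- list()
  if (config$f > 0) # backwards: P2 lineages jump into the P3 deme
    ev <- c(ev, list(c(config$t_pulse, 1, 1, 2, config$f)))
  ev <- c(ev,
          list(c(config$t12, 0, 0, 1, 0)),
          list(c(config$t13, 0, 1, 2, 0)),
          list(c(config$t_out, 0, 2, 3, 0)))
  events <- do.call(rbind, ev)
  events <- events[order(events[, 1]), , drop = FALSE]

  reps <- cpp_sim_haplotypes(config$n, events, config$theta,
                             config$locus_length, config$n_loci)
  grp <- rep(seq_len(4), config$n)
  parts <- lapply(seq_along(reps), function(i) {
    r <- reps[[i]]
    if (ncol(r$alleles) == 0L) return(NULL)
    freq <- sapply(seq_len(4), function(g)
      colMeans(r$alleles[grp == g, , drop = FALSE]))
    if (is.null(dim(freq))) freq <- matrix(freq, nrow = 1)
    data.frame(position = (i - 1) * config$locus_spacing + r$positions,
               p1 = freq[, 1], p2 = freq[, 2], p3 = freq[, 3],
               p4 = freq[, 4])
  })
  sites <- do.call(rbind, parts)
  panel <- quad_freq_panel(sites$p1, sites$p2, sites$p3, sites$p4,
                           chrom = "chrQ", positions = sites$position)
  list(panel = panel,
       truth = list(f = config$f, seed = as.integer(seed), config = config))
}

#' Tiny hand-checkable fixture
#'
#' Three haplotypes at two sites: popA = \{00, 01\}, popB = \{11\}. The
#' cross-population distances are \{1, 0.5\}, so D_XY = 0.75,
#' min D_XY = 0.5 and G_min = 2/3; pi(popA) = 0.5.
#'
#' @return List with `hap` (a [haplotype_matrix()]) and `expected`
#'   (named list of the hand-enumerated statistic values).
#' @export
toy_fixture <- function() {
  hap <- haplotype_matrix(
    chrom = "toy", positions = c(0L, 1L),
    alleles = rbind(c(0L, 0L), c(0L, 1L), c(1L, 1L)),
    sample_ids = c("A1", "A2", "B1"),
    pops = c("A", "A", "B"))
  list(hap = hap,
       expected = list(dxy = 0.75, min_dxy = 0.5, gmin = 2 / 3,
                       pi_A = 0.5, da = 0.75 - 0.25))
}
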