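test_that("nucleotide diversity matches hand enumeration", {
  # 2 haplotypes differing at 1 of 10 callable sites
  h <- hap_from_strings(c("1000000000", "0000000000"), c("A", "A"))
  expect_equal(nuc_div(h, "A"), 0.1)

  # monomorphic window
  h <- hap_from_strings(c("0000", "0000", "0000"), rep("A", 3))
  expect_equal(nuc_div(h, "A"), 0)

  # 4 haplotypes {000,001,011,111}: pair-diff sum 10 over 6 pairs, L = 3
  h <- hap_from_strings(c("000", "001", "011", "111"), rep("A", 4))
  expect_equal(nuc_div(h, "A"), (10 / 6) / 3)

  # <2 haplotypes undefined
  h <- hap_from_strings(c("000", "001"), c("A", "B"))
  expect_true(is.na(nuc_div(h, "A")))
})

test_that("Tajima's D matches the textbook formula", {
  h <- hap_from_strings(c("000", "001", "011", "111"), rep("A", 4))
  mat <- h$alleles
  expect_equal(tajimas_d(h, "A"), brute_tajd(mat))
  expect_equal(tajimas_d(h, "A"), 0.1677, tolerance = 1e-3)

  # S = 0 is undefined
  h0 <- hap_from_strings(c("000", "000"), c("A", "A"))
  expect_true(is.na(tajimas_d(h0, "A")))

  # sign(D) = sign(khat - S/a1) on random matrices
  set.seed(21)
  for (k in 1:20) {
    mat <- random_small_matrix(sample(4:6, 1), sample(2:6, 1))
    h <- haplotype_matrix("c", seq_len(ncol(mat)) - 1L, mat,
                          sprintf("s%d", seq_len(nrow(mat))),
                          rep("A", nrow(mat)))
    d <- tajimas_d(h, "A")
    if (is.na(d)) next
    n <- nrow(mat)
    seg <- apply(mat, 2, function(x) length(unique(x)) > 1)
    khat <- sum(apply(mat[, seg, drop = FALSE], 2, function(x) {
      p <- mean(x == x[1]); 2 * p * (1 - p) * n / (n - 1)
    }))
    expect_equal(sign(d), sign(khat - sum(seg) / sum(1 / (1:(n - 1)))))
  }
})

test_that("ZnS averages r^2 over non-singleton biallelic pairs", {
  # perfect LD
  h <- hap_from_strings(c("00", "00", "11", "11"), rep("A", 4))
  expect_equal(zns(h, "A"), 1)

  # a singleton site is excluded: only the non-singleton pair contributes
  h <- hap_from_strings(c("001", "000", "110", "110"), rep("A", 4))
  # site 3 is a singleton; sites 1-2 in perfect LD
  expect_equal(zns(h, "A"), 1)

  # all four gametes equally frequent: r^2 = 0
  h <- hap_from_strings(c("00", "01", "10", "11"), rep("A", 4))
  expect_equal(zns(h, "A"), 0)

  # <2 retained sites undefined
  h <- hap_from_strings(c("01", "00", "00", "00"), rep("A", 4))
  expect_true(is.na(zns(h, "A")))
})

test_that("D_XY returns mean and minimum over cross pairs", {
  h <- hap_from_strings(c("00", "11"), c("A", "B"))
  expect_equal(unname(dxy(h, "A", "B", min_overlap = 1)), c(1, 1))

  h <- hap_from_strings(c("00", "01", "11"), c("A", "A", "B"))
  d <- dxy(h, "A", "B", min_overlap = 1)
  expect_equal(unname(d), c(0.75, 0.5))

  # shared identical haplotype across populations
  h <- hap_from_strings(c("01", "01", "10"), c("A", "B", "B"))
  expect_equal(unname(dxy(h, "A", "B", min_overlap = 1)["min_dxy"]), 0)

  # min_overlap drops sparse pairs; all dropped -> NA
  h <- hap_from_strings(c("0.", ".1"), c("A", "B"))
  expect_true(all(is.na(dxy(h, "A", "B", min_overlap = 2))))
})

test_that("net divergence D_A follows its definition and bounds", {
  expect_equal(da(0.010, 0.010, 0.010), 0)
  expect_equal(da(0.013, 0.0152, 0.0116), -0.0004)
  expect_true(is.na(da(NA, 0.01, 0.01)))
  # D_A <= D_XY whenever pi >= 0
  set.seed(3)
  d <- runif(50); pa <- runif(50); pb <- runif(50)
  expect_true(all(da(d, pa, pb) <= d))
})

test_that("F_ST behaves at its endpoints and matches a per-site oracle", {
  # no true differentiation: mean F_ST over panmictic replicates ~ 0
  set.seed(90)
  reps <- internal_coalescent(null_model_spec(tau = 1e-9, n1 = 10L,
                                              n2 = 10L, theta = 5,
                                              replicates = 200))
  f <- vapply(reps, function(hp) {
    if (length(hp$positions) < 1) return(NA_real_)
    fst(hp, "pop1", "pop2")
  }, numeric(1))
  expect_lt(abs(mean(f, na.rm = TRUE)), 0.05)

  # fixed difference, no within-population variation -> 1
  h <- hap_from_strings(c("00", "00", "11", "11"), c("A", "A", "B", "B"))
  expect_equal(fst(h, "A", "B"), 1)
  expect_equal(fst(h, "A", "B", estimator = "hudson"), 1)

  # ratio-of-sums equals the sum of independent per-site WC components
  set.seed(31)
  A <- random_small_matrix(10, 2)
  B <- random_small_matrix(10, 2)
  h <- haplotype_matrix("c", 0:1, rbind(A, B), sprintf("s%d", 1:20),
                        rep(c("A", "B"), each = 10))
  comp <- rbind(brute_wc_fst_site(A[, 1], B[, 1]),
                brute_wc_fst_site(A[, 2], B[, 2]))
  seg <- apply(rbind(A, B), 2, function(x) length(unique(x)) > 1)
  expected <- sum(comp[seg, "a"]) / sum(comp[seg, "ab"])
  expect_equal(fst(h, "A", "B"), expected)
})

test_that("the Slatkin relation converts F_ST to coalescence-time depth", {
  expect_equal(round(coalescence_time_ratio(0.378), 1), 2.2)
  expect_equal(coalescence_time_ratio(0.378), 2.2154, tolerance = 1e-4)
  expect_equal(round(coalescence_time_ratio(0.279), 1), 1.8)
  expect_equal(coalescence_time_ratio(0.279), 1.7739, tolerance = 1e-4)
  expect_equal(coalescence_time_ratio(0), 1)
  expect_true(is.na(coalescence_time_ratio(NA)))
  expect_warning(r <- coalescence_time_ratio(1), "infinite")
  expect_identical(r, Inf)
})

test_that("parsimony polarization assigns ancestral/derived states", {
  # focal {A,G} coded 0/2; outgroup carries 0 -> 0 ancestral, 2 derived
  h <- hap_from_strings(c("00", "20", "22", "22"),
                        c("A", "A", "B", "B"))
  og <- hap_from_strings(c("03"), "O")
  pol <- polarize(h, og)
  expect_true(pol$sites$polarized[1])
  expect_equal(pol$sites$ancestral[1], 0L)
  expect_equal(pol$sites$derived[1], 2L)
  # outgroup allele 3 not among focal {0,2} -> unpolarized, excluded
  expect_false(pol$sites$polarized[2])
  # pop A polymorphism at site 1 shares its derived allele with pop B
  expect_equal(unname(pol$counts$A["n_ancestral_shared"]), 1)

  # simulated truth: internal coalescent uses 0 as the ancestral state,
  # so an all-zero outgroup must recover >= 99% of sites
  set.seed(77)
  reps <- internal_coalescent(null_model_spec(theta = 20, replicates = 20))
  agree <- vapply(reps, function(hp) {
    if (length(hp$positions) == 0) return(NA_real_)
    og <- haplotype_matrix(hp$chrom, hp$positions,
                           matrix(0L, 1, length(hp$positions)), "og", "O")
    pol <- polarize(hp, og)
    ok <- pol$sites$polarized
    mean(pol$sites$ancestral[ok] == 0L)
  }, numeric(1))
  expect_gte(mean(agree, na.rm = TRUE), 0.99)
})

test_that("statistics match brute-force enumeration on small matrices", {
  set.seed(42)
  for (k in 1:150) {
    n <- sample(2:6, 1)
    S <- sample(1:6, 1)
    mat <- random_small_matrix(n, S, n_alleles = sample(2:3, 1))
    # sprinkle missing data in a third of the cases
    if (k %% 3 == 0) mat[sample(length(mat), 1)] <- NA_integer_
    L <- S + sample(0:5, 1) # callable length >= number of variant sites
    h <- haplotype_matrix("c", seq_len(S) - 1L, mat,
                          sprintf("s%d", seq_len(n)), rep("A", n))
    expect_equal(nuc_div(h, "A", end = L), brute_pi(mat, L),
                 info = sprintf("pi case %d", k))
    if (n >= 4 && !anyNA(mat))
      expect_equal(tajimas_d(h, "A"), brute_tajd(mat),
                   info = sprintf("tajd case %d", k))
    if (!anyNA(mat)) {
      z1 <- zns(h, "A")
      z2 <- brute_zns(mat)
      if (!is.na(z1) || !is.na(z2))
        expect_equal(z1, z2, info = sprintf("zns case %d", k))
    }
    # split the same matrix into two populations for dxy
    if (n >= 2) {
      nA <- sample(1:(n - 1), 1)
      pops <- c(rep("X", nA), rep("Y", n - nA))
      h2 <- haplotype_matrix("c", seq_len(S) - 1L, mat,
                             sprintf("s%d", seq_len(n)), pops)
      got <- dxy(h2, "X", "Y", end = L, min_overlap = 1)
      want <- brute_dxy(mat[seq_len(nA), , drop = FALSE],
                        mat[-seq_len(nA), , drop = FALSE], L)
      expect_equal(unname(got), want, info = sprintf("dxy case %d", k))
    }
  }
})

test_that("statistics are invariant to sample order and allele labels", {
  set.seed(7)
  mat <- random_small_matrix(6, 5)
  pops <- rep(c("A", "B"), each = 3)
  h <- haplotype_matrix("c", 0:4, mat, sprintf("s%d", 1:6), pops)
  perm <- sample(6)
  hp <- haplotype_matrix("c", 0:4, mat[perm, ], sprintf("s%d", 1:6),
                         pops[perm])
  expect_equal(nuc_div(h, "A"), nuc_div(hp, "A"))
  expect_equal(dxy(h, "A", "B", min_overlap = 1),
               dxy(hp, "A", "B", min_overlap = 1))
  expect_equal(fst(h, "A", "B"), fst(hp, "A", "B"))
  # allele relabeling (0 <-> 1)
  hf <- haplotype_matrix("c", 0:4, 1L - mat, sprintf("s%d", 1:6), pops)
  expect_equal(nuc_div(h, "A"), nuc_div(hf, "A"))
  expect_equal(tajimas_d(h, "A"), tajimas_d(hf, "A"))
  expect_equal(zns(h, "A"), zns(hf, "A"))
})

test_that("mean Tajima's D is near zero under neutral panmixia", {
  set.seed(1234)
  spec <- null_model_spec(tau = 1e-9, n1 = 5L, n2 = 5L, theta = 10,
                          replicates = 500)
  reps <- internal_coalescent(spec)
  d <- vapply(reps, function(hp) {
    if (length(hp$positions) == 0) return(NA_real_)
    brute_tajd(hp$alleles)
  }, numeric(1))
  d <- d[!is.na(d)]
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 3 * se)
})
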