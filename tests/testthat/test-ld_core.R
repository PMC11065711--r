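test_that("haplotype LD statistics match hand evaluation", {
  complete <- haplotype_ld(0.5, 0.5, 0.5)
  expect_equal(complete$d, 0.25)
  expect_equal(complete$d_prime, 1)
  expect_equal(complete$r2, 1)

  le <- haplotype_ld(0.2 * 0.3, 0.2, 0.3)   # linkage equilibrium
  expect_equal(le$d, 0)
  expect_equal(le$r2, 0)

  h <- haplotype_ld(0.10, 0.2, 0.3)
  expect_equal(h$d, 0.04)
  expect_equal(h$r2, 0.04^2 / (0.2 * 0.8 * 0.3 * 0.7))

  expect_error(haplotype_ld(0.5, 1, 0.5), "monomorphic")
})

test_that("dosage r2 is exact, coding-invariant and missing-aware", {
  a <- c(0L, 1L, 2L, 2L, 0L, 1L, 2L, 0L)
  expect_equal(dosage_r2(a, a)$r2, 1)
  expect_equal(dosage_r2(a, 2L - a)$r2, 1)       # allele-coding swap

  b <- c(0L, 2L, 1L, 2L, 1L, 0L, 2L, 0L)         # hand-written table
  expect_equal(dosage_r2(a, b)$r2, brute_r2(a, b), tolerance = 1e-14)

  # property: random coding flips never change r2
  set.seed(5)
  for (i in 1:20) {
    x <- sample(0:2, 15, replace = TRUE)
    y <- sample(0:2, 15, replace = TRUE)
    if (var(x) == 0 || var(y) == 0) next
    base <- dosage_r2(x, y)$r2
    expect_equal(dosage_r2(2L - x, y)$r2, base, tolerance = 1e-12)
    expect_equal(dosage_r2(x, 2L - y)$r2, base, tolerance = 1e-12)
    expect_equal(dosage_r2(2L - x, 2L - y)$r2, base, tolerance = 1e-12)
  }

  # pairwise-complete deletion and skip reasons
  miss <- c(NA, 1L, 2L, NA, 0L, 1L, 2L, 0L)
  r <- dosage_r2(miss, b)
  expect_identical(r$n_obs, 6L)
  expect_equal(r$r2, brute_r2(miss, b), tolerance = 1e-14)
  expect_identical(dosage_r2(c(1L, 1L, 1L, 1L), c(0L, 1L, 2L, 0L))$reason,
                   "monomorphic")
  expect_identical(dosage_r2(c(1L, NA, NA, NA), c(0L, 1L, 2L, 0L))$reason,
                   "insufficient_obs")
})

test_that("EM haplotype frequencies: closed form, symmetry and grid optimality", {
  # no double heterozygotes: EM equals the direct gamete tally
  a <- c(2L, 2L, 0L, 1L, 0L)
  b <- c(2L, 1L, 0L, 0L, 2L)
  f <- em_haplotype_freqs(a, b)
  tally <- c(2 + 1, 1 + 1, 2, 2 + 1) / 10        # AB, Ab, aB, ab gametes
  expect_equal(unname(f[1:4]), tally, tolerance = 1e-12)

  # all double heterozygotes: symmetric fixed point at 0.25 each
  f2 <- em_haplotype_freqs(rep(1L, 8), rep(1L, 8))
  expect_equal(unname(f2[1:4]), rep(0.25, 4), tolerance = 1e-9)

  # EM fixed point beats a 100-point grid over the free pAB parameter
  set.seed(8)
  for (i in 1:5) {
    x <- sample(0:2, 10, replace = TRUE, prob = c(0.3, 0.4, 0.3))
    y <- sample(0:2, 10, replace = TRUE, prob = c(0.3, 0.4, 0.3))
    if (var(x) == 0 || var(y) == 0) next
    fhat <- em_haplotype_freqs(x, y)
    llhat <- geno_loglik(x, y, fhat)
    pA <- mean(x) / 2
    pB <- mean(y) / 2
    lo <- max(0, pA + pB - 1)
    hi <- min(pA, pB)
    grid <- seq(lo + 1e-9, hi - 1e-9, length.out = 100)
    llgrid <- vapply(grid, function(pab) {
      geno_loglik(x, y, c(pab, pA - pab, pB - pab, 1 - pA - pB + pab))
    }, numeric(1))
    expect_gte(llhat + 1e-8, max(llgrid))
  }
})

test_that("pair scan emits exactly the in-window pairs in order", {
  calls <- rbind(c(0L, 0L, 2L), c(1L, 2L, 1L), c(2L, 1L, 0L),
                 c(1L, 0L, 2L))
  ds <- toy_dataset(calls, pos = c(1, 400001, 800001))
  pairs <- pairwise_ld_scan(ds, max_dist_bp = 500000)
  expect_identical(nrow(pairs), 2L)              # 1-2 and 2-3, never 1-3
  expect_identical(pairs$snp_a, c("snp1", "snp2"))
  expect_identical(pairs$snp_b, c("snp2", "snp3"))
  expect_identical(pairs$dist_bp, c(400000, 400000))
  expect_identical(nrow(pairwise_ld_scan(ds, max_dist_bp = 0)), 0L)

  # m equally spaced SNPs fully inside the window: m(m-1)/2 pairs
  set.seed(3)
  m <- 12
  wide <- toy_dataset(matrix(sample(0:2, m * 30, TRUE), 30, m),
                      pos = seq_len(m) * 100)
  allp <- pairwise_ld_scan(wide, max_dist_bp = 500000)
  n_all <- as.integer(m * (m - 1) / 2)
  expect_identical(nrow(allp) + as.integer(sum(attr(allp, "n_skipped"))),
                   n_all)
  expect_identical(attr(allp, "n_candidate_pairs"), n_all)

  # distances never exceed the cap; matches brute-force double loop
  sc <- pairwise_ld_scan(wide, max_dist_bp = 450)
  expect_true(all(sc$dist_bp <= 450 & sc$dist_bp > 0))
  brute <- sum(outer(seq_len(m) * 100, seq_len(m) * 100,
                     function(x, y) y - x) > 0 &
               outer(seq_len(m) * 100, seq_len(m) * 100,
                     function(x, y) y - x) <= 450)
  expect_identical(attr(sc, "n_candidate_pairs"), as.integer(brute))

  expect_error(
    pairwise_ld_scan(structure(list(
      calls = matrix(0L, 2, 2),
      variants = data.frame(chrom = "1", id = c("a", "b"),
                            pos_bp = c(200, 100), a1 = "A", a2 = "G"),
      samples = c("s1", "s2")), class = "genotype_dataset")),
    "sort")
})

test_that("haplotype and dosage r2 agree on phased-unambiguous data", {
  # gametes with no double heterozygotes when paired in order
  h1a <- c(1, 1, 0, 0, 1, 0, 1, 0)
  h2a <- c(1, 0, 0, 1, 1, 0, 0, 0)
  h1b <- c(1, 1, 0, 0, 1, 0, 1, 0)
  h2b <- c(1, 0, 0, 1, 1, 0, 0, 0)   # locus b perfectly coupled to a
  a <- as.integer(h1a + h2a)
  b <- as.integer(h1b + h2b)
  pA <- mean(c(h1a, h2a))
  pB <- mean(c(h1b, h2b))
  pAB <- mean(c(h1a * h1b, h2a * h2b))
  expect_equal(dosage_r2(a, b)$r2, haplotype_ld(pAB, pA, pB)$r2,
               tolerance = 1e-12)
})
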