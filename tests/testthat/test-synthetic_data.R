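test_that("simulations are byte-reproducible from the seed", {
  truth <- simulation_truth(ne_schedule = data.frame(n_generations = 8,
                                                     size = 20),
                            n_sampled = 12, n_loci = 40,
                            chrom_length_bp = 2e6, seed = 31)
  ds1 <- simulate_wright_fisher(truth)
  ds2 <- simulate_wright_fisher(truth)
  expect_identical(ds1$calls, ds2$calls)
  expect_identical(ds1$variants, ds2$variants)

  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_ped_map(ds1, paste0(f1, ".ped"), paste0(f1, ".map"))
  write_ped_map(ds2, paste0(f2, ".ped"), paste0(f2, ".map"))
  expect_identical(readLines(paste0(f1, ".ped")),
                   readLines(paste0(f2, ".ped")))

  p1 <- simulate_pedigree(4, 6, 20, 5, seed = 17)
  p2 <- simulate_pedigree(4, 6, 20, 5, seed = 17)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
})

test_that("tiny populations fix rapidly under drift", {
  # N = 2: heterozygosity halves roughly every 1/(2N); by generation 40
  # essentially every replicate is fixed
  fixed <- vapply(1:200, function(i) {
    truth <- simulation_truth(ne_schedule = data.frame(n_generations = 40,
                                                       size = 2),
                              n_sampled = 2, n_loci = 1,
                              chrom_length_bp = 1e6, init_maf = 0.5,
                              seed = 1000 + i)
    f <- attr(simulate_wright_fisher(truth), "final_freqs")
    f == 0 || f == 1
  }, logical(1))
  expect_gte(mean(fixed), 0.95)
})

test_that("allele-frequency drift variance follows the Wright-Fisher law", {
  N <- 20
  t <- 10
  p0 <- 0.3
  freqs <- vapply(1:500, function(i) {
    truth <- simulation_truth(ne_schedule = data.frame(n_generations = t,
                                                       size = N),
                              n_sampled = 2, n_loci = 1,
                              chrom_length_bp = 1e6, init_maf = p0,
                              seed = 5000 + i)
    attr(simulate_wright_fisher(truth), "final_freqs")
  }, numeric(1))
  v_obs <- var(freqs)
  v_theo <- p0 * (1 - p0) * (1 - (1 - 1 / (2 * N))^t)
  # Monte-Carlo SE of the variance estimator from sample moments
  m <- freqs - mean(freqs)
  R <- length(freqs)
  se_v <- sqrt((mean(m^4) - (R - 3) / (R - 1) * v_obs^2) / R)
  expect_lt(abs(v_obs - v_theo), 3 * se_v)
})

test_that("recombination weakens LD between linked loci", {
  mean_r2 <- function(rate, seed) {
    truth <- simulation_truth(ne_schedule = data.frame(n_generations = 40,
                                                       size = 30),
                              n_sampled = 30, n_loci = 150,
                              chrom_length_bp = 2e7, init_maf = 0.5,
                              recomb_rate_per_bp = rate, seed = seed)
    ds <- simulate_wright_fisher(truth)
    qc <- apply_qc(ds, qc_thresholds(autosome_labels = "1"))
    pairs <- pairwise_ld_scan(qc$dataset, max_dist_bp = 2e6)
    mean(pairs$r2)
  }
  diffs <- vapply(1:20, function(i)
    mean_r2(0, 7000 + i) - mean_r2(2e-8, 7000 + i), numeric(1))
  expect_true(all(is.finite(diffs)))
  expect_gt(mean(diffs), 0)
})

test_that("equilibrium r2 matches the Sved expectation at c near 0.01", {
  # constant N = 50; pairs around 1 Mb (c ~ 0.01) pooled over replicates
  reps <- 8
  obs <- expct <- npairs <- numeric(reps)
  for (r in seq_len(reps)) {
    truth <- simulation_truth(
      ne_schedule = data.frame(n_generations = 200, size = 50),
      n_sampled = 96, n_loci = 1500, chrom_length_bp = 3e7,
      n_chromosomes = 2, seed = 8800 + r)
    ds <- simulate_wright_fisher(truth)
    qc <- apply_qc(ds, qc_thresholds())
    pairs <- pairwise_ld_scan(qc$dataset, max_dist_bp = 1.2e6)
    sel <- pairs$dist_bp >= 0.8e6
    cc <- sved_feldman_c(physical_to_genetic(pairs$dist_bp[sel]))
    obs[r] <- mean(pairs$r2[sel])
    expct[r] <- mean(expected_r2_sved(50, cc, n = 96))
    npairs[r] <- sum(sel)
  }
  expect_gte(sum(npairs), 2000)
  # 1/(1+4Nc) is a first-order approximation that understates equilibrium
  # r2 when 4Nc is small (here 4Nc ~ 2, and MAF filtering raises the mean
  # further); assert the simulated mean sits in that envelope: at or above
  # the first-order expectation but within 1.5x of it
  ratio <- mean(obs) / mean(expct)
  expect_gte(ratio, 0.95)
  expect_lte(ratio, 1.50)
})

test_that("pedigree simulator records its mating design truthfully", {
  expect_equal(attr(simulate_pedigree(25, 25, 100, 2, seed = 1),
                    "theoretical_ne"), 50)
  expect_equal(attr(simulate_pedigree(10, 40, 100, 2, seed = 1),
                    "theoretical_ne"), 32)
  sim <- simulate_pedigree(5, 5, 20, 3, seed = 2)
  t <- equivalent_complete_generations(sim)
  expect_true(all(t[sim$birth_year == 1] == 1))   # founders unknown-parent
  expect_true(all(t[sim$birth_year == 0] == 0))
  # parents always come from the previous generation's breeders
  yr <- stats::setNames(sim$birth_year, sim$id)
  kids <- sim[!is.na(sim$sire), ]
  expect_true(all(yr[kids$sire] == kids$birth_year - 1))
  expect_true(all(yr[kids$dam] == kids$birth_year - 1))
})

test_that("Sved expectation behaves in its limits and inverts algebraically", {
  expect_equal(expected_r2_sved(50, 0.025, n = Inf), 1 / 6)
  expect_equal(expected_r2_sved(1e6, 0.5, n = Inf), 1 / (1 + 2e6))
  r2 <- expected_r2_sved(123, 0.03, n = 96, beta = 1)
  est <- ne_at_bin(adjust_r2(r2, 96, beta = 1), 0.03)
  expect_equal(est$ne, 123, tolerance = 1e-9)
})
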