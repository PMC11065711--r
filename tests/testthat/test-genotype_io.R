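test_that("PED/MAP round-trips preserve the dosage matrix and metadata", {
  set.seed(42)
  ds <- toy_dataset(rbind(c(2L, 1L), c(1L, 0L), c(0L, NA)), pos = c(500, 1500))
  ds <- popne:::canonicalize_coding(ds)
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  write_ped_map(ds, ped, map)
  ds2 <- read_ped_map(ped, map)
  expect_identical(ds2$calls, ds$calls)
  expect_identical(ds2$variants$id, ds$variants$id)
  expect_identical(ds2$variants$pos_bp, as.numeric(ds$variants$pos_bp))
  expect_identical(ds2$samples, ds$samples)

  # simulated panel round-trips too, and re-reading is bit-reproducible
  truth <- simulation_truth(ne_schedule = data.frame(n_generations = 5,
                                                     size = 20),
                            n_sampled = 10, n_loci = 30,
                            chrom_length_bp = 1e6, seed = 7)
  sim <- simulate_wright_fisher(truth)
  write_ped_map(sim, ped, map)
  back <- read_ped_map(ped, map)
  expect_identical(back$calls, sim$calls)
  back2 <- read_ped_map(ped, map)
  expect_identical(back2$calls, back$calls)
})

test_that("half-missing genotypes are missing and counted-allele coding is deterministic", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  writeLines(c("1 snp1 0 100", "1 snp2 0 200"), map)
  writeLines(c("f1 s1 0 0 0 -9 0 A G G",   # snp1 half-missing? no: "0 A"
               "f2 s2 0 0 0 -9 A A A G",
               "f3 s3 0 0 0 -9 G G A A"), ped)
  ds <- read_ped_map(ped, map)
  expect_true(is.na(ds$calls[1, 1]))          # "0 A" is missing
  # snp1: first non-missing is "A A" (s2) -> counted allele A
  expect_identical(ds$variants$a1[1], "A")
  expect_identical(ds$calls[, 1], c(NA, 2L, 0L))
  # snp2: first genotype "G G" -> counted allele G, "A G" het
  expect_identical(ds$variants$a1[2], "G")
  expect_identical(ds$calls[, 2], c(2L, 1L, 0L))
})

test_that("heterozygous first genotype breaks the tie lexicographically", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  writeLines("1 snp1 0 100", map)
  writeLines(c("f1 s1 0 0 0 -9 G A",
               "f2 s2 0 0 0 -9 G G"), ped)
  ds <- read_ped_map(ped, map)
  expect_identical(ds$variants$a1[1], "A")    # lexicographically smaller
  expect_identical(ds$calls[, 1], c(1L, 0L))  # "G G" has zero A copies
})

test_that("malformed genotype files raise informative format errors", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  writeLines(c("1 snp1 0 100", "1 snp2 0"), map)    # 3 columns on line 2
  expect_error(read_ped_map(ped, map), "line 2")
  writeLines("1 snp1 0 100", map)
  writeLines(c("f1 s1 0 0 0 -9 A A",
               "f2 s2 0 0 0 -9 A"), ped)            # wrong column count
  expect_error(read_ped_map(ped, map), "line 2")
  writeLines(c("f1 s1 0 0 0 -9 A A",
               "f2 s2 0 0 0 -9 C G"), ped)          # 3 alleles at snp1
  expect_error(read_ped_map(ped, map), "allele")
})

test_that("empty dataset writes a valid empty PED and full MAP", {
  ds <- genotype_dataset(matrix(integer(0), nrow = 0, ncol = 2),
                         data.frame(chrom = "1", id = c("a", "b"),
                                    pos_bp = c(10, 20), a1 = "A", a2 = "G"),
                         character(0))
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  write_ped_map(ds, ped, map)
  expect_identical(length(readLines(ped)), 0L)
  expect_identical(length(readLines(map)), 2L)
})

test_that("pedigree files parse, validate and round-trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sire,dam", "S1,0,0", "D1,0,0", "X,S1,D1"), f)
  ped <- read_pedigree(f)
  expect_s3_class(ped, "pedigree_table")
  expect_identical(nrow(ped), 3L)
  expect_identical(sum(is.na(ped$sire) & is.na(ped$dam)), 2L)  # 2 founders

  # self-parentage is reported as a cycle
  writeLines(c("id,sire,dam", "A,A,0"), f)
  expect_error(read_pedigree(f), "cycle")
  # duplicated ids are a data error
  writeLines(c("id,sire,dam", "A,0,0", "A,0,0"), f)
  expect_error(read_pedigree(f), "duplicate")

  # multi-generation simulated pedigree round-trips (tab/whitespace too)
  sim <- simulate_pedigree(3, 4, 10, 5, seed = 9)
  write_pedigree(sim, f)
  back <- read_pedigree(f)
  expect_identical(back$id, sim$id)
  expect_identical(back$sire, sim$sire)
  expect_identical(back$dam, sim$dam)
  expect_identical(back$birth_year, sim$birth_year)
})

test_that("unsorted or duplicated variant tables are rejected", {
  expect_error(toy_dataset(rbind(c(0L, 1L)), pos = c(200, 100)), "sorted")
  expect_error(
    genotype_dataset(rbind(c(0L, 1L)),
                     data.frame(chrom = "1", id = c("a", "a"),
                                pos_bp = c(5, 5), a1 = "A", a2 = "G"),
                     "s1"),
    "duplicate")
})
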