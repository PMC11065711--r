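#' Ground-truth record for a genotype simulation
#'
#' Captures every parameter of a Wright-Fisher forward simulation so that
#' downstream estimates can be checked against known truth.
#'
#' @param ne_schedule data.frame with columns `n_generations` and `size`
#'   (diploid census = effective size under random mating), epochs in
#'   past-to-present order.
#' @param n_sampled number of genotyped individuals: a cohort of offspring
#'   drawn from the final-generation population (so it may exceed the
#'   population size, as when 96 animals of a herd bred from ~50 parents
#'   are genotyped).
#' @param n_loci number of SNPs per chromosome.
#' @param chrom_length_bp chromosome length in bp.
#' @param recomb_rate_per_bp per-bp recombination rate (Morgan/bp);
#'   1e-8 is the conventional 1 cM/Mb.
#' @param init_maf allele-frequency law at initialisation: a length-2
#'   vector gives a uniform range, a single value a fixed frequency.
#' @param n_chromosomes chromosomes are simulated as independent
#'   replicates concatenated with distinct labels.
#' @param seed RNG seed, recorded in every output.
#' @return A list of class `simulation_truth`.
#' @export
simulation_truth <- function(ne_schedule = data.frame(n_generations = 100,
                                                      size = 50),
                             n_sampled = 50, n_loci = 500,
                             chrom_length_bp = 5e7,
                             recomb_rate_per_bp = 1e-8,
                             init_maf = c(0.05, 0.5),
                             n_chromosomes = 1, seed = 1) {
  stopifnot(all(ne_schedule$n_generations > 0), all(ne_schedule$size > 0),
            n_sampled > 0, n_loci > 0, chrom_length_bp > 0,
            recomb_rate_per_bp >= 0, n_chromosomes >= 1)
  structure(list(ne_schedule = ne_schedule, n_sampled = n_sampled,
                 n_loci = n_loci, chrom_length_bp = chrom_length_bp,
                 recomb_rate_per_bp = recomb_rate_per_bp,
                 init_maf = init_maf, n_chromosomes = n_chromosomes,
                 seed = as.integer(seed)),
            class = "simulation_truth")
}

# one meiosis: recombine the two parental haplotypes at Poisson crossovers
.gamete <- function(h1, h2, pos, rate_bp, len_bp) {
  k <- stats::rpois(1, rate_bp * len_bp)
  start <- sample.int(2L, 1L)
  if (k == 0L) return(if (start == 1L) h1 else h2)
  x <- sort(stats::runif(k, 0, len_bp))
  use2 <- (start + findInterval(pos, x)) %% 2L == 0L
  out <- h1
  out[use2] <- h2[use2]
  out
}

#' Forward-in-time Wright-Fisher genotype simulation
#'
#' Discrete generations; each offspring draws two parents uniformly with
#' replacement (selfing allowed, the classical neutral model); gametes are
#' formed with crossovers as a Poisson process along the chromosome; loci
#' are initialised independently (linkage equilibrium) at frequencies from
#' the configured law and experience no mutation afterwards. After the
#' scheduled generations, the genotyped sample is a cohort of `n_sampled`
#' offspring of the final-generation population. Monomorphic loci are
#' retained (QC removes them downstream). Fully reproducible from the seed.
#'
#' @param truth a [simulation_truth()].
#' @return A [genotype_dataset()] in canonical allele coding, with
#'   attributes `truth` and `final_freqs` (per-locus allele-1 frequencies in
#'   the final population, before cohort sampling).
#' @export
simulate_wright_fisher <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  set.seed(truth$seed)
  per_chrom <- lapply(seq_len(truth$n_chromosomes), function(ch)
    .simulate_wf_chrom(truth, chrom = as.character(ch)))
  calls <- do.call(cbind, lapply(per_chrom, `[[`, "calls"))
  variants <- do.call(rbind, lapply(per_chrom, `[[`, "variants"))
  samples <- sprintf("sim%03d", seq_len(truth$n_sampled))
  ds <- structure(list(calls = calls, variants = variants,
                       samples = samples),
                  class = "genotype_dataset")
  ds <- canonicalize_coding(ds)
  validate_genotype_dataset(ds)
  attr(ds, "truth") <- truth
  attr(ds, "final_freqs") <- unlist(lapply(per_chrom, `[[`, "freqs"),
                                    use.names = FALSE)
  ds
}

.simulate_wf_chrom <- function(truth, chrom) {
  L <- truth$n_loci
  len <- truth$chrom_length_bp
  rate <- truth$recomb_rate_per_bp
  pos <- sort(sample.int(len, L))
  p0 <- if (length(truth$init_maf) == 2)
    stats::runif(L, truth$init_maf[1], truth$init_maf[2])
  else rep(truth$init_maf, L)

  N <- truth$ne_schedule$size[1]
  H <- matrix(stats::rbinom(2 * N * L, 1L, rep(p0, each = 2 * N)),
              nrow = 2 * N, ncol = L)
  next_gen <- function(H, N_cur, N_next) {
    out <- matrix(0L, nrow = 2 * N_next, ncol = ncol(H))
    for (i in seq_len(N_next)) {
      p1 <- sample.int(N_cur, 1L)
      p2 <- sample.int(N_cur, 1L)
      out[2L * i - 1L, ] <- .gamete(H[2L * p1 - 1L, ], H[2L * p1, ],
                                    pos, rate, len)
      out[2L * i, ] <- .gamete(H[2L * p2 - 1L, ], H[2L * p2, ],
                               pos, rate, len)
    }
    out
  }
  for (e in seq_len(nrow(truth$ne_schedule))) {
    N_next <- truth$ne_schedule$size[e]
    for (g in seq_len(truth$ne_schedule$n_generations[e])) {
      H <- next_gen(H, nrow(H) %/% 2L, N_next)
    }
  }
  freqs <- colMeans(H)
  S <- next_gen(H, nrow(H) %/% 2L, truth$n_sampled)   # genotyped cohort
  calls <- S[seq(1, nrow(S), by = 2), , drop = FALSE] +
           S[seq(2, nrow(S), by = 2), , drop = FALSE]
  storage.mode(calls) <- "integer"
  variants <- data.frame(chrom = chrom,
                         id = sprintf("chr%s_snp%05d", chrom, seq_len(L)),
                         pos_bp = pos, a1 = "A", a2 = "G",
                         stringsAsFactors = FALSE)
  list(calls = calls, variants = variants, freqs = freqs)
}

#' Simulate a hierarchical random-mating pedigree
#'
#' Discrete generations with `n_sires` breeding males and `n_dams` breeding
#' females per generation; each offspring's sire and dam are drawn
#' uniformly from the previous generation's breeders; sexes are assigned to
#' maintain the breeder counts; birth year = generation index. The
#' theoretical effective size `4 Ns Nd / (Ns + Nd)` is recorded as an
#' attribute.
#'
#' @param n_sires,n_dams breeding males/females per generation.
#' @param offspring_per_generation cohort size per generation (must allow
#'   both breeder counts).
#' @param n_generations number of offspring generations after the founders.
#' @param seed RNG seed.
#' @return A [pedigree_table()] with columns id, sire, dam, birth_year and
#'   attributes `sex`, `theoretical_ne`, `seed`.
#' @export
simulate_pedigree <- function(n_sires = 25, n_dams = 25,
                              offspring_per_generation = 100,
                              n_generations = 10, seed = 1) {
  stopifnot(n_sires > 0, n_dams > 0, offspring_per_generation > 0,
            n_generations > 0)
  set.seed(seed)
  id <- c(sprintf("G00_S%03d", seq_len(n_sires)),
          sprintf("G00_D%03d", seq_len(n_dams)))
  sex <- c(rep("M", n_sires), rep("F", n_dams))
  sire <- dam <- rep(NA_character_, length(id))
  year <- rep(0, length(id))
  prev_ids <- id
  prev_sex <- sex
  for (g in seq_len(n_generations)) {
    males <- prev_ids[prev_sex == "M"]
    females <- prev_ids[prev_sex == "F"]
    breed_s <- if (length(males) > n_sires)
      sample(males, n_sires) else males
    breed_d <- if (length(females) > n_dams)
      sample(females, n_dams) else females
    no <- offspring_per_generation
    oid <- sprintf("G%02d_%03d", g, seq_len(no))
    # alternate sexes, then shuffle, so both breeder counts are available
    osex <- sample(rep_len(c("M", "F"), no))
    if (sum(osex == "M") < n_sires || sum(osex == "F") < n_dams)
      stop("offspring_per_generation too small for the breeder counts")
    osire <- sample(breed_s, no, replace = TRUE)
    odam <- sample(breed_d, no, replace = TRUE)
    id <- c(id, oid); sex <- c(sex, osex)
    sire <- c(sire, osire); dam <- c(dam, odam)
    year <- c(year, rep(g, no))
    prev_ids <- oid
    prev_sex <- osex
  }
  ped <- pedigree_table(id, sire, dam, birth_year = year)
  attr(ped, "sex") <- sex
  attr(ped, "theoretical_ne") <- 4 * n_sires * n_dams / (n_sires + n_dams)
  attr(ped, "seed") <- as.integer(seed)
  ped
}

#' Sved's drift-recombination equilibrium expectation of r-squared
#'
#' `E[r2] = 1/(alpha + 4 N c) + 1/(beta n)`: the equilibrium LD for an
#' ideal population of effective size N at recombination rate c, plus the
#' finite-sample contribution of n genotyped individuals. Used as the
#' independent oracle for the LD-based Ne estimator (the estimator is its
#' algebraic inverse).
#'
#' @param N effective population size.
#' @param c recombination rate, in `(0, 0.5]`.
#' @param n sample size (`Inf` drops the sampling term).
#' @param beta phase factor (1 unphased, 2 phased).
#' @param alpha mutation correction.
#' @return Expected r-squared.
#' @export
expected_r2_sved <- function(N, c, n = Inf, beta = 1, alpha = 1) {
  stopifnot(N >= 1, all(c > 0), all(c <= 0.5))
  1 / (alpha + 4 * N * c) + if (is.finite(n)) 1 / (beta * n) else 0
}
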