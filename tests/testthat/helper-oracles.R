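# Independent oracles and fixture builders used across the suite.

# Pearson r^2 from first principles (sums only, no cor())
brute_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  sxy <- sum(a * b) - sum(a) * sum(b) / n
  sxx <- sum(a^2) - sum(a)^2 / n
  syy <- sum(b^2) - sum(b)^2 / n
  (sxy / sqrt(sxx * syy))^2
}

# Exact HWE p by direct log-factorial enumeration of the conditional
# distribution of the heterozygote count given the allele counts.
hwe_oracle <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  nA <- 2 * n_hom1 + n_het
  na <- 2 * n_hom2 + n_het
  hets <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- (na - h) / 2
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp)
  obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

# Kinship by common-ancestor path counting: f(i,j) = sum over common
# ancestors A and over ancestor-path pairs meeting only at A of
# (1/2)^(len1+len2+1) (1+F_A); F_A is the path-counting kinship of A's
# parents. Exponential, only for tiny pedigrees.
kinship_pc <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), NA_integer_, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), NA_integer_, idx[ped$dam])
  paths_memo <- vector("list", n)
  paths_up <- function(x) {            # all ancestor paths, incl. (x) itself
    if (!is.null(paths_memo[[x]])) return(paths_memo[[x]])
    out <- list(x)
    for (p in c(si[x], di[x])) {
      if (!is.na(p))
        out <- c(out, lapply(paths_up(p), function(pp) c(x, pp)))
    }
    paths_memo[[x]] <<- out
    out
  }
  F_memo <- rep(NA_real_, n)
  inbreeding <- function(x) {
    if (!is.na(F_memo[x])) return(F_memo[x])
    f <- if (!is.na(si[x]) && !is.na(di[x])) coan(si[x], di[x]) else 0
    F_memo[x] <<- f
    f
  }
  coan <- function(i, j) {
    if (i == j) return((1 + inbreeding(i)) / 2)
    tot <- 0
    for (p1 in paths_up(i)) for (p2 in paths_up(j)) {
      A <- p1[length(p1)]
      if (p2[length(p2)] != A) next
      if (length(intersect(p1, p2)) != 1) next
      tot <- tot + 0.5^(length(p1) + length(p2) - 1) * (1 + inbreeding(A))
    }
    tot
  }
  C <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) C[i, j] <- C[j, i] <- coan(i, j)
  C
}

# Random acyclic pedigree: parents always have smaller construction index;
# rows are then shuffled so order-independence is exercised too.
random_pedigree <- function(n, p_known = 0.7) {
  id <- sprintf("I%02d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (x in 2:n) {
    pool <- seq_len(x - 1)
    if (stats::runif(1) < p_known)
      sire[x] <- id[sample(pool, 1)]
    if (stats::runif(1) < p_known) {
      cand <- setdiff(pool, match(sire[x], id))
      if (length(cand)) dam[x] <- id[sample(cand, 1)]
    }
  }
  ord <- sample.int(n)
  pedigree_table(id[ord], sire[ord], dam[ord])
}

# Multinomial log-likelihood of a two-locus genotype sample given
# haplotype frequencies (random union of gametes).
geno_loglik <- function(a, b, f) {
  pAB <- f[1]; pAb <- f[2]; paB <- f[3]; pab <- f[4]
  P <- matrix(0, 3, 3)   # [dosA+1, dosB+1]
  P[3, 3] <- pAB^2;       P[3, 2] <- 2 * pAB * pAb; P[3, 1] <- pAb^2
  P[2, 3] <- 2 * pAB * paB
  P[2, 2] <- 2 * pAB * pab + 2 * pAb * paB
  P[2, 1] <- 2 * pAb * pab
  P[1, 3] <- paB^2;       P[1, 2] <- 2 * paB * pab; P[1, 1] <- pab^2
  ok <- !is.na(a) & !is.na(b)
  sum(log(P[cbind(a[ok] + 1, b[ok] + 1)]))
}

# Tiny genotype dataset built in code
toy_dataset <- function(calls, pos = NULL, chrom = "1") {
  calls <- as.matrix(calls)
  L <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(L) * 1000
  genotype_dataset(
    calls,
    data.frame(chrom = chrom, id = paste0("snp", seq_len(L)), pos_bp = pos,
               a1 = "A", a2 = "G", stringsAsFactors = FALSE),
    sprintf("s%02d", seq_len(nrow(calls))))
}
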