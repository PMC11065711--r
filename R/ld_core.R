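#' LD statistics from gamete (haplotype) frequencies
#'
#' For two biallelic loci with allele frequencies `pA`, `pB` and gamete
#' frequency `pAB`, the disequilibrium coefficient is `D = pAB - pA*pB`;
#' `D'` is `|D|` scaled by its maximum given the allele frequencies, and
#' `r2 = D^2 / (pA(1-pA) pB(1-pB))` is the squared correlation of the
#' all-or-none allele indicators.
#'
#' @param pAB gamete frequency of the A-B haplotype.
#' @param pA,pB allele frequencies at the two loci, both in `(0, 1)`.
#' @return A list with elements `d`, `d_prime`, `r2`.
#' @export
haplotype_ld <- function(pAB, pA, pB) {
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("LD undefined at a monomorphic locus")
  if (pAB < max(0, pA + pB - 1) - 1e-12 || pAB > min(pA, pB) + 1e-12)
    stop("pAB outside the feasible region for the given allele frequencies")
  d <- pAB - pA * pB
  dmax <- if (d > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  d_prime <- if (d == 0) 0 else abs(d) / dmax
  r2 <- d^2 / (pA * (1 - pA) * pB * (1 - pB))
  list(d = d, d_prime = d_prime, r2 = r2)
}

#' Genotype-dosage r-squared for one SNP pair
#'
#' The squared Pearson correlation of genotype dosages over
#' pairwise-complete samples (the PLINK `--r2` default for unphased data).
#' Invariant to swapping which allele is counted at either locus.
#'
#' @param a,b dosage vectors in `{0, 1, 2, NA}` of equal length.
#' @return A list with `r2`, `n_obs` (pairwise-complete samples) and
#'   `reason` (`NA` if computed; `"insufficient_obs"` or `"monomorphic"`
#'   when the pair is skipped, with `r2 = NA`).
#' @export
dosage_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  n_obs <- sum(ok)
  if (n_obs < 2)
    return(list(r2 = NA_real_, n_obs = n_obs, reason = "insufficient_obs"))
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0)
    return(list(r2 = NA_real_, n_obs = n_obs, reason = "monomorphic"))
  list(r2 = stats::cor(a, b)^2, n_obs = n_obs, reason = NA_character_)
}

#' EM estimate of two-locus haplotype frequencies from unphased genotypes
#'
#' Only the double heterozygote is phase-ambiguous; the EM iteration
#' reassigns its two possible gamete pairs (AB/ab vs Ab/aB) in proportion to
#' their current frequency products, starting from linkage equilibrium
#' (product of sample allele frequencies).
#'
#' @param a,b dosage vectors in `{0, 1, 2, NA}`.
#' @param tol convergence tolerance on the maximum frequency change.
#' @param max_iter iteration cap; non-convergence warns and flags the result.
#' @return Numeric vector `c(pAB, pAb, paB, pab)` with attributes
#'   `iterations` and `converged`.
#' @export
em_haplotype_freqs <- function(a, b, tol = 1e-10, max_iter = 1000) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2) stop("need at least two pairwise-complete samples")
  # unambiguous gamete counts
  cAB <- sum((a == 2) * (b == 2) * 2 + (a == 2) * (b == 1) +
             (a == 1) * (b == 2))
  cAb <- sum((a == 2) * (b == 0) * 2 + (a == 2) * (b == 1) +
             (a == 1) * (b == 0))
  caB <- sum((a == 0) * (b == 2) * 2 + (a == 0) * (b == 1) +
             (a == 1) * (b == 2))
  cab <- sum((a == 0) * (b == 0) * 2 + (a == 0) * (b == 1) +
             (a == 1) * (b == 0))
  ndh <- sum(a == 1 & b == 1)          # double heterozygotes
  tot <- 2 * n

  pA <- mean(a) / 2
  pB <- mean(b) / 2
  f <- c(AB = pA * pB, Ab = pA * (1 - pB),
         aB = (1 - pA) * pB, ab = (1 - pA) * (1 - pB))
  it <- 0L
  converged <- TRUE
  if (ndh == 0) {
    f <- c(cAB, cAb, caB, cab) / tot
  } else {
    repeat {
      it <- it + 1L
      num <- f["AB"] * f["ab"]
      den <- num + f["Ab"] * f["aB"]
      w <- if (den > 0) num / den else 0.5   # P(coupling | double het)
      f_new <- c(cAB + ndh * w, cAb + ndh * (1 - w),
                 caB + ndh * (1 - w), cab + ndh * w) / tot
      names(f_new) <- names(f)
      delta <- max(abs(f_new - f))
      f <- f_new
      if (delta < tol) break
      if (it >= max_iter) {
        warning("EM for haplotype frequencies did not converge in ",
                max_iter, " iterations")
        converged <- FALSE
        break
      }
    }
  }
  names(f) <- c("pAB", "pAb", "paB", "pab")
  attr(f, "iterations") <- it
  attr(f, "converged") <- converged
  f
}

#' Scan all same-chromosome SNP pairs within a distance window
#'
#' Emits every pair with `0 < pos_b - pos_a <= max_dist_bp` exactly once,
#' ordered by (chromosome block, left index, right index). Pairs where a
#' locus is monomorphic among pairwise-complete samples (or with fewer than
#' two such samples) are skipped; skip counts are attached as attributes.
#'
#' @param ds a QC'd `genotype_dataset`, sorted by position.
#' @param max_dist_bp maximum inter-marker physical distance (default the
#'   500 kb window beyond which r2 is typically below useful levels).
#' @param want_dprime if `TRUE`, also estimate haplotype frequencies by EM
#'   per pair and report `d` and `d_prime` (slower).
#' @return A data.frame with columns `chrom`, `snp_a`, `pos_a`, `snp_b`,
#'   `pos_b`, `dist_bp`, `n_obs`, `r2` (plus `d`, `d_prime` when requested),
#'   with attributes `n_candidate_pairs` and `n_skipped`.
#' @export
pairwise_ld_scan <- function(ds, max_dist_bp = 500000, want_dprime = FALSE) {
  validate_genotype_dataset(ds)
  v <- ds$variants
  out <- list()
  n_cand <- 0L
  n_skip <- c(insufficient_obs = 0L, monomorphic = 0L)
  for (ch in rle(v$chrom)$values) {
    jj <- which(v$chrom == ch)
    pos <- v$pos_bp[jj]
    if (is.unsorted(pos))
      stop("variants on chromosome ", ch,
           " are not sorted by position; sort the dataset first")
    if (length(jj) < 2 || max_dist_bp <= 0) next
    hi <- findInterval(pos + max_dist_bp, pos)
    ia <- ib <- integer(0)
    for (k in seq_along(jj)) {
      if (hi[k] > k) {
        right <- (k + 1):hi[k]
        right <- right[pos[right] > pos[k]]   # dist must be > 0
        ia <- c(ia, rep.int(k, length(right)))
        ib <- c(ib, right)
      }
    }
    if (!length(ia)) next
    n_cand <- n_cand + length(ia)
    X <- ds$calls[, jj, drop = FALSE]
    res <- .pair_r2(X, ia, ib)
    keep <- is.na(res$reason)
    n_skip["insufficient_obs"] <- n_skip[["insufficient_obs"]] +
      sum(res$reason == "insufficient_obs", na.rm = TRUE)
    n_skip["monomorphic"] <- n_skip[["monomorphic"]] +
      sum(res$reason == "monomorphic", na.rm = TRUE)
    if (!any(keep)) next
    df <- data.frame(chrom = ch,
                     snp_a = v$id[jj][ia[keep]], pos_a = pos[ia[keep]],
                     snp_b = v$id[jj][ib[keep]], pos_b = pos[ib[keep]],
                     dist_bp = pos[ib[keep]] - pos[ia[keep]],
                     n_obs = res$n_obs[keep], r2 = res$r2[keep],
                     stringsAsFactors = FALSE)
    if (want_dprime) {
      dd <- t(vapply(which(keep), function(q) {
        f <- em_haplotype_freqs(X[, ia[q]], X[, ib[q]])
        pA <- f[["pAB"]] + f[["pAb"]]
        pB <- f[["pAB"]] + f[["paB"]]
        hl <- haplotype_ld(f[["pAB"]], pA, pB)
        c(hl$d, hl$d_prime)
      }, numeric(2)))
      df$d <- dd[, 1]
      df$d_prime <- dd[, 2]
    }
    out[[ch]] <- df
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), snp_a = character(0),
               pos_a = numeric(0), snp_b = character(0), pos_b = numeric(0),
               dist_bp = numeric(0), n_obs = integer(0), r2 = numeric(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "n_candidate_pairs") <- n_cand
  attr(res, "n_skipped") <- n_skip
  res
}

# Vectorised r2 over index pairs when the matrix is complete; falls back to
# per-pair pairwise-complete correlation in the presence of missing calls.
.pair_r2 <- function(X, ia, ib) {
  if (!anyNA(X)) {
    n <- nrow(X)
    sd0 <- apply(X, 2, stats::sd) == 0
    Z <- scale(X)
    r2 <- rep(NA_real_, length(ia))
    reason <- rep(NA_character_, length(ia))
    bad <- sd0[ia] | sd0[ib]
    reason[bad] <- "monomorphic"
    if (any(!bad)) {
      chunk <- 50000L
      idx <- which(!bad)
      for (s in split(idx, ceiling(seq_along(idx) / chunk))) {
        r <- colSums(Z[, ia[s], drop = FALSE] * Z[, ib[s], drop = FALSE]) /
          (n - 1)
        r2[s] <- r^2
      }
    }
    list(r2 = r2, n_obs = rep.int(n, length(ia)), reason = reason)
  } else {
    res <- mapply(function(p, q) dosage_r2(X[, p], X[, q]), ia, ib,
                  SIMPLIFY = FALSE)
    list(r2 = vapply(res, `[[`, numeric(1), "r2"),
         n_obs = vapply(res, `[[`, numeric(1), "n_obs"),
         reason = vapply(res, `[[`, character(1), "reason"))
  }
}
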