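#' Additive kinship (coancestry) matrix by the tabular method
#'
#' In topological order, `C(x, y) = (C(sire_x, y) + C(dam_x, y)) / 2` for
#' individuals y processed before x (an unknown parent contributes 0), and
#' `C(x, x) = (1 + C(sire_x, dam_x)) / 2`, so the diagonal carries
#' `(1 + F_x) / 2` with F the inbreeding coefficient.
#'
#' @param ped a [pedigree_table()].
#' @return Symmetric matrix with `ped$id` dimnames, in the pedigree's row
#'   order.
#' @export
kinship_matrix <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), NA_integer_, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), NA_integer_, idx[ped$dam])
  C <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  ord <- attr(ped, "topo_order")
  if (is.null(ord)) ord <- pedigree_topo_order(ped)
  done <- integer(0)
  for (x in ord) {
    cs <- if (!is.na(si[x])) C[si[x], done] else rep(0, length(done))
    cd <- if (!is.na(di[x])) C[di[x], done] else rep(0, length(done))
    row <- (cs + cd) / 2
    C[x, done] <- row
    C[done, x] <- row
    fx <- if (!is.na(si[x]) && !is.na(di[x])) C[si[x], di[x]] else 0
    C[x, x] <- (1 + fx) / 2
    done <- c(done, x)
  }
  C
}

#' Inbreeding coefficients from a pedigree
#'
#' `F_i` is the coancestry of i's parents (0 when either parent is
#' unknown).
#'
#' @param ped a [pedigree_table()].
#' @param C optional precomputed [kinship_matrix()].
#' @return Named numeric vector of inbreeding coefficients.
#' @export
inbreeding_coefficients <- function(ped, C = kinship_matrix(ped)) {
  stats::setNames(2 * diag(C) - 1, ped$id)
}

#' Equivalent complete generations
#'
#' The pedigree-depth measure `t_i = sum over known ancestors of (1/2)^g`
#' with g the number of generation steps to the ancestor; founders have
#' `t = 0`. Computed by the recursion
#' `t_i = (1 + t_sire)/2 + (1 + t_dam)/2` over known parents.
#'
#' @param ped a [pedigree_table()].
#' @return Named numeric vector of `t_i`.
#' @export
equivalent_complete_generations <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), NA_integer_, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), NA_integer_, idx[ped$dam])
  t <- numeric(n)
  ord <- attr(ped, "topo_order")
  if (is.null(ord)) ord <- pedigree_topo_order(ped)
  for (x in ord) {
    t[x] <- (if (!is.na(si[x])) (1 + t[si[x]]) / 2 else 0) +
            (if (!is.na(di[x])) (1 + t[di[x]]) / 2 else 0)
  }
  stats::setNames(t, ped$id)
}

#' Pairwise increase in coancestry
#'
#' `dC_ij = 1 - (1 - C_ij)^(2 / (t_i + t_j))`: the per-generation rate of
#' coancestry accumulation for a pair, referenced to the pair's mean
#' pedigree depth. Undefined (NA) for founder pairs with `t_i + t_j = 0`.
#'
#' @param c_ij coancestry coefficient(s), in `[0, 1)`.
#' @param t_i,t_j equivalent complete generations of the two individuals.
#' @return Increase in coancestry, in `[0, 1)`; vectorised.
#' @export
delta_coancestry <- function(c_ij, t_i, t_j) {
  stopifnot(all(c_ij >= 0 & c_ij < 1))
  tt <- t_i + t_j
  out <- 1 - (1 - c_ij)^(2 / tt)
  out[tt == 0] <- NA_real_
  out
}

default_reference_set <- function(ped) {
  ped$id[!is.na(ped$sire) | !is.na(ped$dam)]  # all non-founders
}

#' Coancestry-based effective population size
#'
#' `NeCi = 1 / (2 * mean dC_ij)` over all unordered pairs of distinct
#' individuals in the reference set (default: all non-founders). Pairs with
#' `t_i + t_j = 0` are excluded and counted.
#'
#' @param ped a [pedigree_table()].
#' @param reference optional character vector of reference individual ids.
#' @return A list with `ne_ci`, `mean_dc`, `se` (standard error of the mean
#'   dC), `n_pairs`, `n_excluded` and `reason` (NA on success;
#'   `"no_coancestry_accumulation"` when mean dC is 0, with `ne_ci = NA`).
#' @export
ne_coancestry <- function(ped, reference = NULL) {
  if (is.null(reference)) reference <- default_reference_set(ped)
  keep <- ped$id %in% reference
  if (sum(keep) < 2)
    return(list(ne_ci = NA_real_, mean_dc = NA_real_, se = NA_real_,
                n_pairs = 0L, n_excluded = 0L, reason = "reference_too_small"))
  C <- kinship_matrix(ped)[keep, keep, drop = FALSE]
  t <- equivalent_complete_generations(ped)[keep]
  ut <- upper.tri(C)
  tt <- outer(t, t, "+")[ut]
  cc <- C[ut]
  ok <- tt > 0
  dc <- 1 - (1 - cc[ok])^(2 / tt[ok])
  n_pairs <- sum(ok)
  n_excluded <- sum(!ok)
  if (!n_pairs || mean(dc) <= 0)
    return(list(ne_ci = NA_real_, mean_dc = if (n_pairs) mean(dc) else NA_real_,
                se = NA_real_, n_pairs = n_pairs, n_excluded = n_excluded,
                reason = "no_coancestry_accumulation"))
  list(ne_ci = 1 / (2 * mean(dc)), mean_dc = mean(dc),
       se = stats::sd(dc) / sqrt(n_pairs), n_pairs = n_pairs,
       n_excluded = n_excluded, reason = NA_character_)
}

#' Inbreeding-based effective population size
#'
#' Per individual with pedigree depth `t_i > 1`, the individual rate of
#' inbreeding is `dF_i = 1 - (1 - F_i)^(1 / (t_i - 1))`; then
#' `NeFi = 1 / (2 * mean dF_i)` over the eligible reference individuals.
#'
#' @param ped a [pedigree_table()].
#' @param reference optional character vector of reference individual ids.
#' @return A list with `ne_fi`, `mean_df`, `n_used`, `n_excluded` and
#'   `reason` (NA on success; `"no_inbreeding_accumulation"` when mean dF
#'   is 0, `"no_eligible_individuals"` when no reference individual has
#'   `t > 1`).
#' @export
ne_inbreeding <- function(ped, reference = NULL) {
  if (is.null(reference)) reference <- default_reference_set(ped)
  keep <- ped$id %in% reference
  f <- inbreeding_coefficients(ped)[keep]
  t <- equivalent_complete_generations(ped)[keep]
  ok <- t > 1
  n_excluded <- sum(!ok)
  if (!any(ok))
    return(list(ne_fi = NA_real_, mean_df = NA_real_, n_used = 0L,
                n_excluded = n_excluded, reason = "no_eligible_individuals"))
  df <- 1 - (1 - f[ok])^(1 / (t[ok] - 1))
  if (mean(df) <= 0)
    return(list(ne_fi = NA_real_, mean_df = mean(df), n_used = sum(ok),
                n_excluded = n_excluded,
                reason = "no_inbreeding_accumulation"))
  list(ne_fi = 1 / (2 * mean(df)), mean_df = mean(df), n_used = sum(ok),
       n_excluded = n_excluded, reason = NA_character_)
}

#' Number of equivalent subpopulations
#'
#' `S = NeCi / NeFi`. Both Ne measures track the same accumulated drift, so
#' S near 1 signals panmixia while S below 1 indicates that coancestry
#' accumulates faster than inbreeding (subdivision-avoiding mating).
#'
#' @param ne_ci coancestry-based Ne.
#' @param ne_fi inbreeding-based Ne.
#' @return The ratio, or `NA` if either input is undefined.
#' @export
equivalent_subpopulations <- function(ne_ci, ne_fi) {
  if (is.null(ne_ci) || is.null(ne_fi) || is.na(ne_ci) || is.na(ne_fi))
    return(NA_real_)
  stopifnot(ne_ci > 0, ne_fi > 0)
  ne_ci / ne_fi
}

#' Full pedigree-based Ne analysis
#'
#' Convenience wrapper computing NeCi, NeFi and S for one reference set.
#'
#' @param ped a [pedigree_table()].
#' @param reference optional reference ids; default all non-founders.
#' @param reference_year optional birth year; when given, the reference set
#'   is the cohort born that year.
#' @return A list with components `ne_ci` ([ne_coancestry()] result),
#'   `ne_fi` ([ne_inbreeding()] result) and `s_ratio`.
#' @export
pedigree_ne <- function(ped, reference = NULL, reference_year = NULL) {
  if (!is.null(reference_year)) {
    if (is.null(ped$birth_year))
      stop("config error: reference_year given but pedigree has no birth_year")
    reference <- ped$id[!is.na(ped$birth_year) &
                        ped$birth_year == reference_year]
  }
  nc <- ne_coancestry(ped, reference)
  nf <- ne_inbreeding(ped, reference)
  list(ne_ci = nc, ne_fi = nf,
       s_ratio = equivalent_subpopulations(nc$ne_ci, nf$ne_fi))
}
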