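#' Configuration for LD-based historical Ne estimation
#'
#' @param k_morgan_per_bp physical-to-genetic map scaling (Morgan per bp);
#'   the conventional 1 cM/Mb corresponds to 1e-8.
#' @param alpha mutation correction in the drift-recombination expectation
#'   (1 = no mutation).
#' @param beta phase factor of the sampling-bias adjustment: 1 when the
#'   gametic phase is unknown (genotype data), 2 when known.
#' @param n_bins number of equal-width distance bins.
#' @param min_dist_bp,max_dist_bp distance window; shorter distances probe
#'   older generations, so widening `max_dist_bp` reaches more recent
#'   generations.
#' @param mapping_f mapping applied to the bin recombination rate inside
#'   `1/(4 f(c))`; identity by default.
#' @return A list of class `ne_ld_config`.
#' @export
ne_ld_config <- function(k_morgan_per_bp = 1e-8, alpha = 1, beta = 1,
                         n_bins = 30, min_dist_bp = 10000,
                         max_dist_bp = 4e6, mapping_f = identity) {
  stopifnot(k_morgan_per_bp > 0, alpha >= 1, beta %in% c(1, 2),
            n_bins >= 1, min_dist_bp >= 0, min_dist_bp < max_dist_bp)
  structure(list(k_morgan_per_bp = k_morgan_per_bp, alpha = alpha,
                 beta = beta, n_bins = n_bins, min_dist_bp = min_dist_bp,
                 max_dist_bp = max_dist_bp, mapping_f = mapping_f),
            class = "ne_ld_config")
}

#' Physical to genetic map distance
#'
#' `d = k * delta`: bp to Morgans at a constant per-bp recombination rate.
#'
#' @param delta_bp physical distance in bp (>= 0).
#' @param k Morgan per bp.
#' @return Genetic distance in Morgans.
#' @export
physical_to_genetic <- function(delta_bp, k = 1e-8) {
  stopifnot(all(delta_bp >= 0))
  k * delta_bp
}

#' Sved-Feldman recombination modifier
#'
#' `c = d (1 - d/2)`, mapping genetic map distance d (Morgans) to a
#' recombination fraction; on `[0, 1]` it is bounded by the free
#' recombination ceiling 0.5.
#'
#' @param d genetic distance in Morgans.
#' @return Recombination fraction.
#' @export
sved_feldman_c <- function(d) {
  if (any(d < 0 | d > 1))
    warning("Sved-Feldman modifier applied outside its intended range [0, 1]")
  d * (1 - d / 2)
}

#' Sampling-bias adjustment of mean r-squared
#'
#' `r2_adj = r2 - 1/(beta n)`, removing the expected contribution of the
#' finite sample of n genotyped individuals. The result may be non-positive
#' for weak LD; callers must drop such bins.
#'
#' @param mean_r2 bin mean r-squared.
#' @param n number of genotyped individuals.
#' @param beta 1 for unphased data, 2 for phased.
#' @return Adjusted r-squared.
#' @export
adjust_r2 <- function(mean_r2, n, beta = 1) {
  stopifnot(n >= 2, beta %in% c(1, 2))
  mean_r2 - 1 / (beta * n)
}

#' Point estimate of historical Ne from one distance bin
#'
#' `Ne = (1/(4 f(c))) (1/r2_adj - alpha)` evaluated at the bin's
#' recombination rate c, attributed to `t = 1/(2c)` generations ago. Bins
#' whose adjusted r-squared is non-positive ("over_corrected") or at least
#' `1/alpha` ("saturated", Ne would be non-positive) are flagged dropped.
#'
#' @param r2_adj adjusted mean r-squared of the bin.
#' @param c recombination rate of the bin (> 0).
#' @param alpha mutation correction.
#' @param mapping_f mapping f applied to c (identity by default).
#' @return A list with `t_generations`, `ne` and `status` (`"ok"`,
#'   `"over_corrected"` or `"saturated"`).
#' @export
ne_at_bin <- function(r2_adj, c, alpha = 1, mapping_f = identity) {
  stopifnot(c > 0)
  t_gen <- 1 / (2 * c)
  if (r2_adj <= 0)
    return(list(t_generations = t_gen, ne = NA_real_,
                status = "over_corrected"))
  if (r2_adj >= 1 / alpha)
    return(list(t_generations = t_gen, ne = NA_real_, status = "saturated"))
  list(t_generations = t_gen,
       ne = (1 / (4 * mapping_f(c))) * (1 / r2_adj - alpha),
       status = "ok")
}

#' Historical Ne trajectory from distance-binned LD
#'
#' Pairs within the configured distance window are partitioned into
#' `n_bins` equal-width bins; per bin the arithmetic mean pair distance is
#' mapped to genetic distance (`d = k * dist`), then to a recombination rate
#' by the Sved-Feldman modifier, and the bin mean r-squared, adjusted for
#' sampling bias, yields one `(t, Ne)` point with `t = 1/(2c)`.
#'
#' @param pairs a data.frame from [pairwise_ld_scan()].
#' @param n number of genotyped individuals (the single n of the
#'   sampling-bias adjustment).
#' @param config an [ne_ld_config()].
#' @return A data.frame with columns `t_gen`, `ne`, `c`, `r2_adj`,
#'   `n_pairs`, sorted by `t_gen` ascending, with attribute `dropped` (a
#'   data.frame of dropped bins and reasons).
#' @export
ne_trajectory <- function(pairs, n, config = ne_ld_config()) {
  stopifnot(n >= 2)
  cf <- config
  sel <- pairs$dist_bp >= cf$min_dist_bp & pairs$dist_bp <= cf$max_dist_bp
  d <- pairs$dist_bp[sel]
  r2 <- pairs$r2[sel]
  if (!length(d)) {
    out <- data.frame(t_gen = numeric(0), ne = numeric(0), c = numeric(0),
                      r2_adj = numeric(0), n_pairs = integer(0))
    attr(out, "dropped") <- data.frame(t_gen = numeric(0),
                                       reason = character(0))
    warning("no SNP pairs inside the configured distance window")
    return(out)
  }
  edges <- seq(cf$min_dist_bp, cf$max_dist_bp, length.out = cf$n_bins + 1)
  bi <- pmin(pmax(findInterval(d, edges, left.open = TRUE), 1L), cf$n_bins)
  rows <- lapply(seq_len(cf$n_bins), function(i) {
    sel_i <- bi == i
    np <- sum(sel_i)
    if (!np) return(NULL)
    md <- mean(d[sel_i])
    cc <- sved_feldman_c(physical_to_genetic(md, cf$k_morgan_per_bp))
    ra <- adjust_r2(mean(r2[sel_i]), n, cf$beta)
    est <- ne_at_bin(ra, cc, cf$alpha, cf$mapping_f)
    data.frame(t_gen = est$t_generations, ne = est$ne, c = cc, r2_adj = ra,
               n_pairs = np, status = est$status, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  dropped <- res[res$status != "ok", c("t_gen", "status"), drop = FALSE]
  names(dropped) <- c("t_gen", "reason")
  rownames(dropped) <- NULL
  out <- res[res$status == "ok",
             c("t_gen", "ne", "c", "r2_adj", "n_pairs"), drop = FALSE]
  out <- out[order(out$t_gen), , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out))
    warning("all distance bins dropped (",
            paste(unique(dropped$reason), collapse = ", "), ")")
  attr(out, "dropped") <- dropped
  out
}
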