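#' Default distance-bin edges for LD decay summaries (bp)
#'
#' 0-10, 10-25, 25-50, 50-100, 100-200 and 200-500 kb — the standard bins
#' for cattle SNP-array LD decay tables.
#'
#' @export
default_bin_edges_bp <- function() c(0, 10, 25, 50, 100, 200, 500) * 1000

#' Aggregate pairwise r-squared into distance bins
#'
#' Bins are half-open intervals `(lo, hi]`; every pair with distance in
#' `(edges[1], edges[last]]` is counted in exactly one bin. An "Overall" row
#' aggregates all binned pairs.
#'
#' @param pairs a data.frame from [pairwise_ld_scan()] (needs `dist_bp`,
#'   `r2`).
#' @param edges_bp strictly increasing bin bounds in bp.
#' @return A data.frame of class `ld_bins` with columns `bin`, `lo_bp`,
#'   `hi_bp`, `n_pairs`, `mean_r2`, `sd_r2`, `mean_dist_bp`.
#' @export
bin_ld <- function(pairs, edges_bp = default_bin_edges_bp()) {
  stopifnot(!is.unsorted(edges_bp, strictly = TRUE), length(edges_bp) >= 2)
  k <- length(edges_bp) - 1
  lab <- sprintf("%g-%g kb", edges_bp[-length(edges_bp)] / 1000,
                 edges_bp[-1] / 1000)
  inside <- pairs$dist_bp > edges_bp[1] & pairs$dist_bp <= edges_bp[k + 1]
  d <- pairs$dist_bp[inside]
  r2 <- pairs$r2[inside]
  # (lo, hi]: findInterval with left-open intervals
  bi <- findInterval(d, edges_bp, left.open = TRUE)
  agg <- function(sel) {
    n <- sum(sel)
    c(n_pairs = n,
      mean_r2 = if (n) mean(r2[sel]) else NA_real_,
      sd_r2 = if (n > 1) stats::sd(r2[sel]) else NA_real_,
      mean_dist_bp = if (n) mean(d[sel]) else NA_real_)
  }
  rows <- t(vapply(seq_len(k), function(i) agg(bi == i), numeric(4)))
  overall <- agg(rep(TRUE, length(d)))
  out <- data.frame(bin = c(lab, "Overall"),
                    lo_bp = c(edges_bp[-(k + 1)], edges_bp[1]),
                    hi_bp = c(edges_bp[-1], edges_bp[k + 1]),
                    rbind(rows, overall),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ld_bins", "data.frame")
  out
}

#' Distance at which mean r-squared falls below a threshold
#'
#' The headline crossing distance is obtained by linear interpolation
#' between consecutive bin summary points `(mean_dist_bp, mean_r2)`; a
#' coarse statement at 10 kb granularity (the largest 10 kb multiple still
#' at or above the threshold on the interpolated curve) is reported
#' alongside. A useful-LD threshold of r2 = 0.2 is the conventional level
#' for genomic selection accuracy around 0.85.
#'
#' @param bins an `ld_bins` data.frame from [bin_ld()] (the "Overall" row is
#'   ignored).
#' @param r2_threshold the useful-LD level.
#' @return A list with `status` (`"ok"`, `"not_reached_below_min"`,
#'   `"not_reached_within_window"`), `crossing_bp`, `coarse_bp` and
#'   `threshold`.
#' @export
decay_crossing <- function(bins, r2_threshold = 0.2) {
  b <- bins[bins$bin != "Overall" & bins$n_pairs > 0, , drop = FALSE]
  b <- b[order(b$mean_dist_bp), , drop = FALSE]
  if (!nrow(b)) stop("no populated bins")
  if (any(diff(b$mean_r2) > 0))
    warning("bin mean r2 is not monotonically decreasing with distance")
  if (r2_threshold <= 0 || all(b$mean_r2 >= r2_threshold))
    return(list(status = "not_reached_within_window", crossing_bp = NA_real_,
                coarse_bp = NA_real_, threshold = r2_threshold))
  if (b$mean_r2[1] < r2_threshold)
    return(list(status = "not_reached_below_min", crossing_bp = NA_real_,
                coarse_bp = NA_real_, threshold = r2_threshold))
  k <- which(b$mean_r2 < r2_threshold)[1]
  x0 <- b$mean_dist_bp[k - 1]; y0 <- b$mean_r2[k - 1]
  x1 <- b$mean_dist_bp[k];     y1 <- b$mean_r2[k]
  crossing <- x0 + (y0 - r2_threshold) * (x1 - x0) / (y0 - y1)
  list(status = "ok", crossing_bp = crossing,
       coarse_bp = 10000 * floor(crossing / 10000),
       threshold = r2_threshold)
}

#' Number of markers in an equidistant SNP panel
#'
#' `floor(genome_len_kb / spacing_kb)`: the count of markers placed at a
#' fixed inter-marker distance along the genome (a fractional marker is
#' meaningless). With the 2,510,605 kb cattle autosomal genome and 40 kb
#' spacing this gives 62,765 markers.
#'
#' @param genome_len_kb genome length in kb.
#' @param spacing_kb inter-marker distance in kb.
#' @return Integer marker count.
#' @export
panel_size <- function(genome_len_kb, spacing_kb) {
  stopifnot(genome_len_kb > 0, spacing_kb > 0)
  as.integer(floor(genome_len_kb / spacing_kb))
}

#' Equidistant SNP panel design
#'
#' @param genome_len_kb genome length in kb (default: cattle autosomes).
#' @param spacing_kb inter-marker distance in kb.
#' @param r2_threshold the useful-LD level the spacing was derived from.
#' @return A list of class `panel_design` with `genome_len_kb`,
#'   `spacing_kb`, `n_markers`, `r2_threshold`.
#' @export
panel_design <- function(genome_len_kb = 2510605, spacing_kb,
                         r2_threshold = 0.2) {
  structure(list(genome_len_kb = genome_len_kb, spacing_kb = spacing_kb,
                 n_markers = panel_size(genome_len_kb, spacing_kb),
                 r2_threshold = r2_threshold),
            class = "panel_design")
}

#' @export
print.panel_design <- function(x, ...) {
  cat(sprintf(
    "panel design: %s markers (%s kb genome at %g kb spacing, r2 >= %g)\n",
    format(x$n_markers, big.mark = ","),
    format(x$genome_len_kb, big.mark = ","), x$spacing_kb, x$r2_threshold))
  invisible(x)
}
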