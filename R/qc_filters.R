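#' Marker QC thresholds
#'
#' Defaults follow routine SNP-array practice for cattle diversity panels:
#' per-marker call rate >= 0.90, minor allele frequency >= 0.05, exact
#' Hardy-Weinberg test p >= 1e-5, and restriction to the 29 bovine autosomes
#' with a known map position.
#'
#' @param min_call_rate minimum fraction of non-missing calls (inclusive).
#' @param min_maf minimum minor allele frequency (inclusive).
#' @param hwe_p_floor markers with exact HWE p below this are removed.
#' @param autosome_labels chromosome labels retained.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.90, min_maf = 0.05,
                          hwe_p_floor = 1e-5,
                          autosome_labels = as.character(1:29)) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 0.5,
            hwe_p_floor >= 0, hwe_p_floor <= 1)
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 hwe_p_floor = hwe_p_floor,
                 autosome_labels = as.character(autosome_labels)),
            class = "qc_thresholds")
}

#' Per-variant call rate
#'
#' @param ds a `genotype_dataset`.
#' @param j variant index.
#' @return Fraction of samples with a non-missing call, in `[0, 1]`.
#' @export
snp_call_rate <- function(ds, j) {
  if (n_samples(ds) == 0) stop("call rate undefined: zero samples")
  mean(!is.na(ds$calls[, j]))
}

#' Per-variant minor allele frequency
#'
#' @param ds a `genotype_dataset`.
#' @param j variant index.
#' @return `min(p, 1 - p)` over non-missing dosages, in `[0, 0.5]`.
#' @export
minor_allele_frequency <- function(ds, j) {
  d <- ds$calls[, j]
  d <- d[!is.na(d)]
  if (!length(d)) stop("MAF undefined: variant ", j, " has no calls")
  p <- sum(d) / (2 * length(d))
  min(p, 1 - p)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditioning on the observed allele counts: the
#' p-value is the total conditional probability of heterozygote counts whose
#' probability does not exceed that of the observed count (no mid-p
#' correction). Probabilities are computed with the standard stable
#' recurrence from the modal heterozygote count.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return Exact p-value in `(0, 1]`. A monomorphic table returns 1.
#' @export
hwe_exact_p <- function(n_hom1, n_het, n_hom2) {
  stopifnot(n_hom1 >= 0, n_het >= 0, n_hom2 >= 0)
  n <- n_hom1 + n_het + n_hom2
  if (n < 1) stop("HWE test needs at least one genotype")
  rare <- 2L * min(n_hom1, n_hom2) + n_het
  if (rare == 0L) return(1)

  # heterozygote counts share the parity of the rare-allele count
  hets <- seq(rare %% 2L, rare, by = 2L)
  probs <- numeric(length(hets))
  # start at the mode of the conditional distribution
  mid <- floor(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2L != rare %% 2L) mid <- mid + 1L
  k0 <- match(mid, hets)
  probs[k0] <- 1
  # downward recurrence: P(h-2)/P(h) = h(h-1) / (4 (nr-h+2)/2 * (nc-h+2)/2)
  h <- mid
  k <- k0
  while (h >= 2) {
    hom_r <- (rare - h) / 2          # rare homozygotes at h
    hom_c <- n - h - hom_r           # common homozygotes at h
    probs[k - 1L] <- probs[k] * h * (h - 1) /
      (4 * (hom_r + 1) * (hom_c + 1))
    h <- h - 2L
    k <- k - 1L
  }
  # upward recurrence: P(h+2)/P(h) = 4 hom_r hom_c / ((h+2)(h+1))
  h <- mid
  k <- k0
  while (h + 2L <= rare) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    probs[k + 1L] <- probs[k] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
    h <- h + 2L
    k <- k + 1L
  }
  probs <- probs / sum(probs)
  obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= obs * (1 + 1e-10)]))
}

#' Apply marker quality control
#'
#' Evaluation order per marker: autosome/known-position, then call rate,
#' then MAF, then the exact HWE test; each failing marker is attributed to
#' the first rule it fails. Retained markers satisfy all four rules.
#'
#' @param ds a `genotype_dataset`.
#' @param thresholds a [qc_thresholds()] object.
#' @return A list with elements `dataset` (the filtered
#'   `genotype_dataset`) and `report` (a `qc_report`).
#' @export
apply_qc <- function(ds, thresholds = qc_thresholds()) {
  validate_genotype_dataset(ds)
  th <- thresholds
  L <- n_variants(ds)
  v <- ds$variants

  fail <- rep(NA_character_, L)
  auto_ok <- v$chrom %in% th$autosome_labels & !is.na(v$pos_bp)
  fail[!auto_ok] <- "autosome"

  for (j in which(is.na(fail))) {
    cr <- snp_call_rate(ds, j)
    if (cr < th$min_call_rate) { fail[j] <- "call_rate"; next }
    d <- ds$calls[, j]
    d <- d[!is.na(d)]
    if (th$min_maf > 0) {
      if (!length(d)) { fail[j] <- "maf"; next }
      p <- sum(d) / (2 * length(d))
      if (min(p, 1 - p) < th$min_maf) { fail[j] <- "maf"; next }
    }
    if (th$hwe_p_floor > 0 && length(d)) {
      p_hwe <- hwe_exact_p(sum(d == 2L), sum(d == 1L), sum(d == 0L))
      if (p_hwe < th$hwe_p_floor) { fail[j] <- "hwe"; next }
    }
  }

  keep <- is.na(fail)
  report <- qc_report(
    n_input = L, n_pass = sum(keep),
    n_fail_by_rule = c(autosome = sum(fail == "autosome", na.rm = TRUE),
                       call_rate = sum(fail == "call_rate", na.rm = TRUE),
                       maf = sum(fail == "maf", na.rm = TRUE),
                       hwe = sum(fail == "hwe", na.rm = TRUE)))
  if (!sum(keep)) warning("QC removed every variant")
  out <- structure(list(calls = ds$calls[, keep, drop = FALSE],
                        variants = ds$variants[keep, , drop = FALSE],
                        samples = ds$samples),
                   class = "genotype_dataset")
  rownames(out$variants) <- NULL
  list(dataset = out, report = report)
}

#' QC report
#'
#' Book-keeping of marker counts through QC: input count, retained count,
#' failures attributed to the first failing rule, and the retained
#' proportion.
#'
#' @param n_input,n_pass counts of input and retained markers.
#' @param n_fail_by_rule named integer vector of first-rule failures.
#' @return A list of class `qc_report`.
#' @export
qc_report <- function(n_input, n_pass, n_fail_by_rule) {
  stopifnot(n_pass + sum(n_fail_by_rule) == n_input)
  structure(list(n_input = n_input, n_pass = n_pass,
                 n_fail_by_rule = n_fail_by_rule,
                 pass_proportion = n_pass / n_input),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("marker QC:", x$n_pass, "of", x$n_input, "retained",
      sprintf("(%.2f%%)\n", 100 * x$pass_proportion))
  for (r in names(x$n_fail_by_rule))
    cat(sprintf("  failed %-10s %d\n", r, x$n_fail_by_rule[[r]]))
  invisible(x)
}

#' @export
as.data.frame.qc_report <- function(x, ...) {
  data.frame(rule = c("input", "pass", names(x$n_fail_by_rule)),
             n = c(x$n_input, x$n_pass, unname(x$n_fail_by_rule)),
             stringsAsFactors = FALSE)
}
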