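#' @keywords internal
"_PACKAGE"

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[", name, "] ", conditionMessage(e), call. = FALSE))
}

log_stage <- function(name, ...) {
  message("[", name, "] ", ...)
}

run_manifest <- function(config, inputs, outputs, seed = NULL) {
  digests <- if (length(inputs)) {
    d <- as.list(unname(tools::md5sum(unlist(inputs))))
    names(d) <- basename(unlist(inputs))
    d
  } else list()
  list(tool = "popne",
       version = as.character(utils::packageVersion("popne")),
       config = config,
       input_md5 = digests,
       seed = seed,
       outputs = as.list(basename(unlist(outputs))))
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Run the full genomic analysis pipeline
#'
#' Ingest (or simulate) a genotype panel, apply marker QC, scan pairwise LD
#' within the distance window, summarise LD decay over distance bins, find
#' the useful-LD crossing distance and size an equidistant SNP panel, and
#' estimate the historical Ne trajectory from distance-binned LD. Writes
#' `qc_report.tsv`, `ld_pairs.tsv`, `decay_bins.tsv`, `panel.tsv`,
#' `ne_trajectory.tsv` and `manifest.json` under `out_dir`. Reruns with
#' identical inputs and config are byte-identical. Stage progress is
#' logged to standard error; results never are.
#'
#' @param ped_path,map_path input PED/MAP paths (omit when `truth` given).
#' @param truth optional [simulation_truth()]: simulate the panel instead
#'   of reading one.
#' @param out_dir output directory (created if needed).
#' @param thresholds [qc_thresholds()].
#' @param max_dist_bp LD scan window.
#' @param edges_bp decay bin edges.
#' @param r2_threshold useful-LD level.
#' @param genome_len_kb genome length for panel sizing (default: cattle
#'   autosomes, 2,510,605 kb).
#' @param ne_config [ne_ld_config()] for the trajectory.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_genomic <- function(ped_path = NULL, map_path = NULL, truth = NULL,
                        out_dir, thresholds = qc_thresholds(),
                        max_dist_bp = 500000,
                        edges_bp = default_bin_edges_bp(),
                        r2_threshold = 0.2, genome_len_kb = 2510605,
                        ne_config = ne_ld_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- list()
  if (!is.null(truth)) {
    log_stage("simulate", "Wright-Fisher panel, seed ", truth$seed)
    ds <- stage("simulate", simulate_wright_fisher(truth))
    seed <- truth$seed
  } else {
    if (is.null(ped_path) || is.null(map_path))
      stop("config error: need ped_path and map_path (or a simulation truth)")
    log_stage("ingest", "reading ", ped_path, " / ", map_path)
    ds <- stage("ingest", read_ped_map(ped_path, map_path))
    inputs <- list(ped_path, map_path)
    seed <- NULL
  }

  log_stage("qc", "filtering ", n_variants(ds), " variants")
  qc <- stage("qc", apply_qc(ds, thresholds))
  log_stage("qc", qc$report$n_pass, " of ", qc$report$n_input, " retained")

  log_stage("ld", "pair scan within ", max_dist_bp, " bp")
  scan_max <- max(max_dist_bp, ne_config$max_dist_bp)
  pairs <- stage("ld", pairwise_ld_scan(qc$dataset, scan_max))
  log_stage("ld", nrow(pairs), " informative pairs")

  decay_pairs <- pairs[pairs$dist_bp <= max_dist_bp, , drop = FALSE]
  bins <- stage("decay", bin_ld(decay_pairs, edges_bp))
  crossing <- stage("decay", decay_crossing(bins, r2_threshold))
  spacing_kb <- if (crossing$status == "ok") crossing$coarse_bp / 1000
                else NA_real_
  panel <- if (!is.na(spacing_kb))
    stage("panel", panel_design(genome_len_kb, spacing_kb, r2_threshold))
  else NULL

  log_stage("ne-ld", "trajectory over ", ne_config$n_bins, " bins")
  traj <- stage("ne-ld",
                ne_trajectory(pairs, n_samples(qc$dataset), ne_config))

  out_files <- file.path(out_dir,
                         c("qc_report.tsv", "ld_pairs.tsv", "decay_bins.tsv",
                           "panel.tsv", "ne_trajectory.tsv"))
  write_tsv(as.data.frame(qc$report), out_files[1])
  ld_out <- pairs
  names(ld_out) <- c("CHR", "SNP_A", "BP_A", "SNP_B", "BP_B", "DIST_BP",
                     "N_OBS", "R2")[seq_along(ld_out)]
  write_tsv(ld_out, out_files[2])
  write_tsv(as.data.frame(bins), out_files[3])
  panel_df <- data.frame(
    genome_len_kb = genome_len_kb,
    r2_threshold = r2_threshold,
    crossing_status = crossing$status,
    crossing_bp = crossing$crossing_bp,
    coarse_bp = crossing$coarse_bp,
    spacing_kb = spacing_kb,
    n_markers = if (is.null(panel)) NA_integer_ else panel$n_markers)
  write_tsv(panel_df, out_files[4])
  traj_out <- traj
  names(traj_out) <- c("T_GEN", "NE", "C", "R2_ADJ", "N_PAIRS")
  write_tsv(traj_out, out_files[5])

  config <- list(
    qc = unclass(thresholds),
    ld = list(max_dist_bp = max_dist_bp),
    decay = list(edges_bp = edges_bp, r2_threshold = r2_threshold,
                 genome_len_kb = genome_len_kb),
    ne_ld = list(k_morgan_per_bp = ne_config$k_morgan_per_bp,
                 alpha = ne_config$alpha, beta = ne_config$beta,
                 n_bins = ne_config$n_bins,
                 min_dist_bp = ne_config$min_dist_bp,
                 max_dist_bp = ne_config$max_dist_bp))
  if (!is.null(truth))
    config$simulation <- unclass(truth)[c("n_sampled", "n_loci",
                                          "chrom_length_bp",
                                          "recomb_rate_per_bp",
                                          "n_chromosomes", "seed")]
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- run_manifest(config, inputs, out_files, seed = seed)
  write_manifest(manifest, manifest_path)

  invisible(list(dataset = qc$dataset, qc_report = qc$report, pairs = pairs,
                 bins = bins, crossing = crossing, panel = panel,
                 trajectory = traj, manifest = manifest,
                 files = c(out_files, manifest_path)))
}

#' Run the pedigree analysis pipeline
#'
#' Reads (or accepts) a pedigree, computes the coancestry- and
#' inbreeding-based effective population sizes and the equivalent
#' subpopulation ratio, and writes `pedigree_ne.tsv` and `manifest.json`.
#'
#' @param pedigree_path path to a pedigree file, or `NULL` when `ped` is
#'   given.
#' @param ped optional [pedigree_table()] (e.g. from
#'   [simulate_pedigree()]).
#' @param out_dir output directory.
#' @param reference_year optional birth-year cohort for the reference set.
#' @return Invisibly, a list with the [pedigree_ne()] result and manifest.
#' @export
run_pedigree <- function(pedigree_path = NULL, ped = NULL, out_dir,
                         reference_year = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- list()
  if (is.null(ped)) {
    if (is.null(pedigree_path))
      stop("config error: need pedigree_path or a pedigree_table")
    log_stage("ingest", "reading ", pedigree_path)
    ped <- stage("ingest", read_pedigree(pedigree_path))
    inputs <- list(pedigree_path)
  }
  log_stage("ne-ped", nrow(ped), " individuals")
  res <- stage("ne-ped", pedigree_ne(ped, reference_year = reference_year))

  out <- data.frame(
    NE_CI = res$ne_ci$ne_ci, SE = res$ne_ci$se,
    MEAN_DC = res$ne_ci$mean_dc, N_PAIRS = res$ne_ci$n_pairs,
    NE_FI = res$ne_fi$ne_fi, MEAN_DF = res$ne_fi$mean_df,
    N_USED_FI = res$ne_fi$n_used,
    N_EXCLUDED = res$ne_ci$n_excluded + res$ne_fi$n_excluded,
    S = res$s_ratio,
    NOTE = paste(stats::na.omit(c(res$ne_ci$reason, res$ne_fi$reason)),
                 collapse = ";"))
  theo <- attr(ped, "theoretical_ne")
  if (!is.null(theo)) out$THEORETICAL_NE <- theo
  out_file <- file.path(out_dir, "pedigree_ne.tsv")
  write_tsv(out, out_file)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- run_manifest(list(reference_year = reference_year),
                           inputs, list(out_file),
                           seed = attr(ped, "seed"))
  write_manifest(manifest, manifest_path)
  invisible(list(result = res, table = out, manifest = manifest,
                 files = c(out_file, manifest_path)))
}
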