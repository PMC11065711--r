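#' Construct a genotype dataset
#'
#' A `genotype_dataset` is the substrate of all LD work: an ordered variant
#' table, an ordered vector of sample ids, and a samples x variants matrix of
#' diploid genotypes coded as counted-allele dosage (0, 1, 2) with `NA` for
#' missing calls. `a1` is the counted allele (dosage = number of `a1` copies);
#' `a2` is the other observed allele (`NA` if the variant is monomorphic in
#' the data).
#'
#' @param calls integer matrix, samples in rows, variants in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param variants data.frame with columns `chrom` (character), `id`,
#'   `pos_bp` (1-based physical position), `a1`, `a2`.
#' @param samples character vector of sample ids.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(calls, variants, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.character(samples)
  ds <- structure(list(calls = calls, variants = variants, samples = samples),
                  class = "genotype_dataset")
  validate_genotype_dataset(ds)
  ds
}

#' Validate genotype dataset invariants
#'
#' Checks matrix/list dimension agreement, dosage range, positivity of
#' positions, sorting by (chromosome block, position) and absence of
#' duplicate (chrom, pos_bp, id) triples.
#'
#' @param ds a `genotype_dataset`.
#' @return `ds`, invisibly; stops on violation.
#' @export
validate_genotype_dataset <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  v <- ds$variants
  need <- c("chrom", "id", "pos_bp", "a1", "a2")
  if (!all(need %in% names(v)))
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  if (nrow(ds$calls) != length(ds$samples))
    stop("calls has ", nrow(ds$calls), " rows but there are ",
         length(ds$samples), " samples")
  if (ncol(ds$calls) != nrow(v))
    stop("calls has ", ncol(ds$calls), " columns but there are ",
         nrow(v), " variants")
  if (nrow(v) > 0) {
    if (any(is.na(v$chrom) | !nzchar(v$chrom)))
      stop("chromosome labels must be non-empty")
    ok_pos <- is.na(v$pos_bp) | v$pos_bp >= 1
    if (!all(ok_pos)) stop("positions must be >= 1 (or NA for unmapped)")
    bad <- ds$calls[!is.na(ds$calls) & !(ds$calls %in% 0:2)]
    if (length(bad)) stop("dosages must be 0, 1, 2 or NA")
    # variants sorted: chromosomes form contiguous blocks, positions
    # non-decreasing within each block
    blocks <- rle(v$chrom)$values
    if (anyDuplicated(blocks))
      stop("variants of one chromosome must be contiguous")
    for (ch in blocks) {
      p <- v$pos_bp[v$chrom == ch]
      p <- p[!is.na(p)]
      if (is.unsorted(p)) stop("positions not sorted on chromosome ", ch)
    }
    if (anyDuplicated(v[, c("chrom", "pos_bp", "id")]))
      stop("duplicate (chrom, pos_bp, id) variant")
    same <- !is.na(v$a2) & v$a1 == v$a2
    if (any(same)) stop("alleles of a variant must be distinct")
  }
  invisible(ds)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", length(x$samples), "samples x",
      nrow(x$variants), "variants on",
      length(unique(x$variants$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

n_variants <- function(ds) nrow(ds$variants)
n_samples <- function(ds) length(ds$samples)

read_lines_tokens <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  strsplit(trimws(lines), "[ \t]+")
}

#' Read a PLINK text PED/MAP genotype panel
#'
#' The MAP file has 4 whitespace-separated columns (chrom, id, cM, bp); the
#' PED file has 6 leading columns (family, individual, sire, dam, sex,
#' phenotype) followed by two allele tokens per variant, with "0" marking a
#' missing allele. A genotype with one missing allele is treated as missing.
#'
#' Dosages are counted against the first non-missing allele seen in file
#' order for each variant; when the first non-missing genotype is
#' heterozygous the lexicographically smaller allele is counted. The counted
#' allele is recorded as `a1` in the variant table, so re-reading a file is
#' bit-reproducible. r-squared is invariant to this choice; it only fixes
#' the sign of D.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @return A [genotype_dataset()].
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_tok <- read_lines_tokens(map_path)
  nfield <- lengths(map_tok)
  if (any(nfield != 4L))
    stop("MAP format error: line ", which(nfield != 4L)[1],
         " has ", nfield[nfield != 4L][1], " columns, expected 4")
  map <- do.call(rbind, map_tok)
  variants <- data.frame(chrom = map[, 1], id = map[, 2],
                         pos_bp = suppressWarnings(as.numeric(map[, 4])),
                         a1 = NA_character_, a2 = NA_character_,
                         stringsAsFactors = FALSE)
  L <- nrow(variants)

  ped_tok <- read_lines_tokens(ped_path)
  nfield <- lengths(ped_tok)
  want <- 6L + 2L * L
  if (any(nfield != want))
    stop("PED format error: line ", which(nfield != want)[1],
         " has ", nfield[nfield != want][1], " columns, expected ", want)
  n <- length(ped_tok)
  samples <- vapply(ped_tok, `[[`, character(1), 2L)
  calls <- matrix(NA_integer_, nrow = n, ncol = L)
  if (n > 0 && L > 0) {
    tok <- do.call(rbind, ped_tok)
    for (j in seq_len(L)) {
      x <- tok[, 6L + 2L * j - 1L]
      y <- tok[, 6L + 2L * j]
      miss <- x == "0" | y == "0"      # half-missing counts as missing
      obs <- sort(unique(c(x[!miss], y[!miss])))
      if (length(obs) > 2L)
        stop("data error: variant ", variants$id[j], " has ",
             length(obs), " alleles (", paste(obs, collapse = "/"), ")")
      if (length(obs) > 0L) {
        first <- which(!miss)[1]
        counted <- if (x[first] == y[first]) x[first]
                   else min(x[first], y[first])
        other <- setdiff(obs, counted)
        variants$a1[j] <- counted
        variants$a2[j] <- if (length(other)) other else NA_character_
        calls[, j] <- (x == counted) + (y == counted)
        calls[miss, j] <- NA_integer_
      }
    }
  }
  genotype_dataset(calls, variants, samples)
}

#' Write a genotype dataset as PLINK text PED/MAP
#'
#' Missing calls are written as "0 0". Files written here round-trip through
#' [read_ped_map()] reproducing the dosage matrix exactly, provided the
#' dataset's allele coding is canonical (as produced by [read_ped_map()] or
#' [simulate_wright_fisher()]).
#'
#' @param ds a `genotype_dataset`.
#' @param ped_path,map_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_ped_map <- function(ds, ped_path, map_path) {
  validate_genotype_dataset(ds)
  v <- ds$variants
  map <- paste(v$chrom, v$id, 0, ifelse(is.na(v$pos_bp), 0, v$pos_bp),
               sep = "\t")
  writeLines(map, map_path)

  L <- nrow(v)
  n <- length(ds$samples)
  lines <- character(n)
  a1 <- v$a1
  a2 <- ifelse(is.na(v$a2), "0", v$a2)
  for (i in seq_len(n)) {
    d <- ds$calls[i, ]
    g <- character(L)
    if (L > 0) {
      g[!is.na(d) & d == 2L] <- paste(a1, a1)[!is.na(d) & d == 2L]
      g[!is.na(d) & d == 1L] <- paste(a1, a2)[!is.na(d) & d == 1L]
      g[!is.na(d) & d == 0L] <- paste(a2, a2)[!is.na(d) & d == 0L]
      g[is.na(d)] <- "0 0"
    }
    lines[i] <- paste(c(ds$samples[i], ds$samples[i], "0", "0", "0", "-9", g),
                      collapse = " ")
  }
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

# Flip per-variant dosage coding so the dataset is a fixed point of
# write_ped_map + read_ped_map (counted allele = first-seen, lexicographic
# tie-break on a first heterozygote).
canonicalize_coding <- function(ds) {
  for (j in seq_len(n_variants(ds))) {
    d <- ds$calls[, j]
    first <- which(!is.na(d))[1]
    if (is.na(ds$variants$a2[j]) || is.na(first)) next
    flip <- FALSE
    if (d[first] == 0L) flip <- TRUE
    if (d[first] == 1L && ds$variants$a2[j] < ds$variants$a1[j]) flip <- TRUE
    if (flip) {
      ds$calls[, j] <- 2L - d
      tmp <- ds$variants$a1[j]
      ds$variants$a1[j] <- ds$variants$a2[j]
      ds$variants$a2[j] <- tmp
    }
  }
  ds
}

#' Construct and validate a pedigree table
#'
#' @param id,sire,dam character vectors; `NA` marks an unknown parent.
#' @param birth_year optional numeric vector.
#' @return A data.frame of class `pedigree_table` with an attribute
#'   `topo_order` giving a topological ordering (ancestors first).
#' @export
pedigree_table <- function(id, sire, dam, birth_year = NULL) {
  id <- as.character(id)
  sire <- as.character(sire)
  dam <- as.character(dam)
  unk <- function(x) is.na(x) | x == "0" | x == ""
  sire[unk(sire)] <- NA_character_
  dam[unk(dam)] <- NA_character_
  if (anyDuplicated(id))
    stop("data error: duplicate individual id '", id[duplicated(id)][1], "'")
  known <- c(sire[!is.na(sire)], dam[!is.na(dam)])
  missing_parent <- setdiff(known, id)
  if (length(missing_parent))
    stop("data error: parent id(s) not in pedigree: ",
         paste(utils::head(missing_parent, 5), collapse = ", "))
  ped <- data.frame(id = id, sire = sire, dam = dam,
                    stringsAsFactors = FALSE)
  if (!is.null(birth_year)) ped$birth_year <- as.numeric(birth_year)
  attr(ped, "topo_order") <- pedigree_topo_order(ped)
  class(ped) <- c("pedigree_table", "data.frame")
  ped
}

# Kahn topological sort; on a cycle, reports one cycle by parent-walking.
pedigree_topo_order <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- which(!placed &
                   (si == 0L | placed[pmax(si, 1L)]) &
                   (di == 0L | placed[pmax(di, 1L)]))
    if (!length(ready)) break
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  if (length(ord) < n) {
    start <- which(!placed)[1]
    cyc <- start
    cur <- start
    repeat {
      cur <- if (si[cur] != 0L && !placed[si[cur]]) si[cur] else di[cur]
      if (cur %in% cyc) {
        cyc <- c(cyc[which(cyc == cur):length(cyc)], cur)
        break
      }
      cyc <- c(cyc, cur)
    }
    stop("data error: pedigree cycle detected: ",
         paste(ped$id[cyc], collapse = " -> "))
  }
  ord
}

#' Read a pedigree file
#'
#' Delimited text (comma, tab or whitespace, auto-detected) with columns
#' id, sire, dam and optionally birth_year; "0" or an empty field marks an
#' unknown parent. A header line is detected by the presence of the tokens
#' "id"/"sire"/"dam". Acyclicity is verified at read time.
#'
#' @param path file path.
#' @return A [pedigree_table()].
#' @export
read_pedigree <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("data error: empty pedigree file")
  delim <- if (grepl(",", lines[1])) "," else "[ \t]+"
  tok <- strsplit(trimws(lines), delim)
  tok <- lapply(tok, trimws)
  nf <- lengths(tok)
  if (any(nf < 3L))
    stop("data error: pedigree line ", which(nf < 3L)[1],
         " has ", nf[nf < 3L][1], " fields, expected >= 3")
  hdr <- any(tolower(tok[[1]][1:3]) %in% c("id", "animal", "sire", "dam"))
  if (hdr) tok <- tok[-1]
  if (!length(tok)) stop("data error: pedigree file has no rows")
  m <- do.call(rbind, lapply(tok, function(t) t[1:min(4, length(t))]))
  by <- if (ncol(m) >= 4) suppressWarnings(as.numeric(m[, 4])) else NULL
  pedigree_table(m[, 1], m[, 2], m[, 3], birth_year = by)
}

#' Write a pedigree table as CSV
#'
#' Unknown parents are written as "0"; round-trips through
#' [read_pedigree()].
#'
#' @param ped a `pedigree_table`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(id = ped$id,
                    sire = ifelse(is.na(ped$sire), "0", ped$sire),
                    dam = ifelse(is.na(ped$dam), "0", ped$dam),
                    stringsAsFactors = FALSE)
  if (!is.null(ped$birth_year)) out$birth_year <- ped$birth_year
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a data.frame as tab-separated text with a header row
#'
#' The common output format of the pipeline stages.
#'
#' @param df data.frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
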