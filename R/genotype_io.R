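#' Read a diploid genotype matrix from a VCF file
#'
#' Parses the GT field of a VCF (v4.x) into a 3-class [genotype_matrix]:
#' `0|0 -> 1`, `0|1` or `1|0 -> 2`, `1|1 -> 3`, missing (`./.` or `.|.`)
#' `-> 0`. Phased (`|`) and unphased (`/`) separators are treated
#' identically: the class encoding is unordered. Multiallelic and
#' non-diploid records are skipped with a warning; markers are kept in file
#' order, one column per retained biallelic record.
#'
#' @param path path to a VCF file.
#' @return a [genotype_matrix] with `n_classes = 3`, `ploidy_mode = "diploid"`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || nrow(gt) == 0L) stop("VCF has no GT genotypes: ", path)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    warning(sprintf("skipping %d multiallelic record(s)", sum(multi)))
    gt <- gt[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(gt) == 0L) stop("no biallelic records retained from ", path)

  enc <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  g <- gsub("/", "|", gt, fixed = TRUE)
  enc[g == "0|0"] <- 1L
  enc[g == "0|1" | g == "1|0"] <- 2L
  enc[g == "1|1"] <- 3L
  enc[is.na(g) | g == ".|." | g == "."] <- 0L
  nondip <- which(rowSums(is.na(enc)) > 0L)
  if (length(nondip)) {
    warning(sprintf("skipping %d non-diploid/non-biallelic GT record(s)",
                    length(nondip)))
    enc <- enc[-nondip, , drop = FALSE]
    fix <- fix[-nondip, , drop = FALSE]
  }
  if (nrow(enc) == 0L) stop("no usable records retained from ", path)

  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  genotype_matrix(t(enc), n_classes = 3L,
                  sample_ids = colnames(gt), marker_ids = ids,
                  ploidy_mode = "diploid")
}

#' Write a diploid genotype matrix as a minimal VCF
#'
#' Emits a plain-text VCF v4.2 with GT-only FORMAT, inverting the
#' 1/2/3 class encoding (`1 -> 0|0`, `2 -> 0|1`, `3 -> 1|1`, `0 -> ./.`).
#' Positions are written 1-based in marker order on a single placeholder
#' chromosome with placeholder alleles; the file round-trips through
#' [read_vcf()] to the identical encoded matrix.
#'
#' @param gm a diploid [genotype_matrix] (`n_classes = 3`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (gm$n_classes != 3L)
    stop("write_vcf requires a diploid 3-class genotype_matrix")
  gtmap <- c("./.", "0|0", "0|1", "1|1")  # index = class + 1
  v <- gm$values
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##contig=<ID=1>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_ids), collapse = "\t"))
  body <- vapply(seq_len(ncol(v)), function(j) {
    paste(c("1", j, gm$marker_ids[j], "A", "G", ".", "PASS", ".", "GT",
            gtmap[v[, j] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read / write a genotype matrix as delimited text
#'
#' Tab-separated layout: header row of marker ids, first column sample ids,
#' one row per sample, genotype classes as integers (0 = missing).
#'
#' @param path file path.
#' @param n_classes,ploidy_mode class count and mode for the resulting
#'   [genotype_matrix] (defaults infer 2 classes / cross when no entry
#'   exceeds 2, else 3 / diploid).
#' @return [read_geno_table()] returns a [genotype_matrix];
#'   [write_geno_table()] returns `path` invisibly.
#' @export
read_geno_table <- function(path, n_classes = NULL, ploidy_mode = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  if (is.null(n_classes)) n_classes <- if (max(m) <= 2L) 2L else 3L
  if (is.null(ploidy_mode)) ploidy_mode <- if (n_classes == 2L) "cross" else "diploid"
  genotype_matrix(m, n_classes = n_classes, sample_ids = rownames(df),
                  marker_ids = colnames(df), ploidy_mode = ploidy_mode)
}

#' @rdname read_geno_table
#' @param gm a [genotype_matrix] to serialize.
#' @export
write_geno_table <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  df <- as.data.frame(gm$values)
  colnames(df) <- gm$marker_ids
  rownames(df) <- gm$sample_ids
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Recode a two-parent cross matrix from -1/1 to class codes
#'
#' Cross genotype tables commonly code the two parental origins as -1 and 1.
#' The model requires non-negative class codes, so -1 is recoded to class 2
#' and 1 stays class 1; an optional missing sentinel becomes 0.
#'
#' @param raw integer matrix with entries in `{-1, 1}` (plus the optional
#'   missing sentinel).
#' @param missing_code optional scalar marking missing entries in `raw`.
#' @param sample_ids,marker_ids optional names passed to [genotype_matrix()].
#' @return a 2-class [genotype_matrix] with `ploidy_mode = "cross"`.
#' @export
recode_cross <- function(raw, missing_code = NULL,
                         sample_ids = NULL, marker_ids = NULL) {
  raw <- as.matrix(raw)
  ok <- raw == -1 | raw == 1
  if (!is.null(missing_code)) ok <- ok | raw == missing_code
  bad <- which(!ok)
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(raw))
    stop(sprintf("invalid cross genotype value %s at [%d, %d]",
                 format(raw[bad[1L]]), rc[1L], rc[2L]))
  }
  v <- matrix(0L, nrow(raw), ncol(raw))
  v[raw == 1] <- 1L
  v[raw == -1] <- 2L
  genotype_matrix(v, n_classes = 2L, sample_ids = sample_ids,
                  marker_ids = marker_ids, ploidy_mode = "cross")
}

#' Randomly mask observed genotypes to missing
#'
#' Sets `round(fraction * n_observed)` uniformly sampled observed entries to
#' the missing code 0, recording the coordinates and original classes so the
#' corruption is exactly reversible. Pre-existing missing entries are
#' excluded from the sampling pool. Benchmarks corrupt at fractions of
#' 0.05, 0.10 and 0.20.
#'
#' @param gm a [genotype_matrix].
#' @param fraction fraction in (0, 1) of observed entries to mask.
#' @param seed integer RNG seed; identical seeds give identical masks.
#' @return a list with elements `masked` (corrupted copy of `gm`) and
#'   `mask` (a `mask_index`: 0-based `coords`, `original_values`, `fraction`).
#' @export
mask_random <- function(gm, fraction, seed) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop("fraction must be a single number in (0, 1)")
  pool <- which(gm$values != 0L)
  n_mask <- round(fraction * length(pool))
  if (n_mask > length(pool))
    stop("fewer non-missing entries than requested for masking")
  if (n_mask < 1L) stop("fraction too small: no entries would be masked")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  picked <- sort(sample(pool, n_mask, replace = FALSE))
  rc <- arrayInd(picked, dim(gm$values))
  mask <- structure(
    list(coords = cbind(sample = rc[, 1L] - 1L, marker = rc[, 2L] - 1L),
         original_values = gm$values[picked],
         fraction = fraction),
    class = "mask_index")
  masked <- gm
  masked$values[picked] <- 0L
  list(masked = masked, mask = mask)
}

#' Restore masked entries from a mask index
#'
#' Exact inverse of [mask_random()]: writes the recorded original classes
#' back at the recorded coordinates.
#'
#' @param gm corrupted [genotype_matrix].
#' @param mask a `mask_index` from [mask_random()].
#' @return the restored [genotype_matrix].
#' @export
unmask <- function(gm, mask) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(mask, "mask_index"))
  idx <- mask$coords[, 1L] + 1L + nrow(gm$values) * mask$coords[, 2L]
  gm$values[idx] <- mask$original_values
  gm
}

#' @export
print.mask_index <- function(x, ...) {
  cat(sprintf("mask_index: %d masked entries (fraction %.3f)\n",
              nrow(x$coords), x$fraction))
  invisible(x)
}

#' Serialize / read a mask index as TSV
#'
#' Three 0-based columns: `sample_idx`, `marker_idx`, `original_class`.
#' The masking fraction is kept in a `# fraction=` comment line.
#'
#' @param mask a `mask_index`.
#' @param path file path.
#' @return reading returns a `mask_index`; writing returns `path` invisibly.
#' @export
write_mask_index <- function(mask, path) {
  stopifnot(inherits(mask, "mask_index"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fraction=%.17g", mask$fraction), con)
  writeLines("sample_idx\tmarker_idx\toriginal_class", con)
  writeLines(sprintf("%d\t%d\t%d", mask$coords[, 1L], mask$coords[, 2L],
                     mask$original_values), con)
  invisible(path)
}

#' @rdname write_mask_index
#' @export
read_mask_index <- function(path) {
  first <- readLines(path, n = 1L)
  frac <- as.numeric(sub("# fraction=", "", first, fixed = TRUE))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  structure(
    list(coords = cbind(sample = as.integer(df$sample_idx),
                        marker = as.integer(df$marker_idx)),
         original_values = as.integer(df$original_class),
         fraction = frac),
    class = "mask_index")
}

#' Split samples into training / validation / test sets
#'
#' Sample-wise (whole-individual) partition. The validation and test sets
#' receive `floor(frac * n_samples)` samples each and the remainder goes to
#' training, so the three sets always partition the input; with the default
#' 0.65/0.15/0.20 fractions and 100 samples this gives 65/15/20.
#'
#' @param gm a [genotype_matrix] with at least 3 samples.
#' @param train_frac,val_frac,test_frac positive fractions summing to 1.
#' @param seed integer RNG seed for the random assignment.
#' @return named list of three [genotype_matrix] objects
#'   (`train`, `val`, `test`) plus an attribute `indices` giving the 1-based
#'   row indices of each split in the input.
#' @export
split_samples <- function(gm, train_frac = 0.65, val_frac = 0.15,
                          test_frac = 0.20, seed = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  fr <- c(train_frac, val_frac, test_frac)
  if (any(fr <= 0) || abs(sum(fr) - 1) > 1e-9)
    stop("split fractions must be positive and sum to 1")
  n <- nrow(gm$values)
  if (n < 3L) stop("need at least 3 samples to split")
  n_val <- floor(val_frac * n)
  n_test <- floor(test_frac * n)
  n_train <- n - n_val - n_test
  if (min(n_train, n_val, n_test) < 1L)
    stop("split produces an empty set; use more samples")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  perm <- sample.int(n)
  idx <- list(train = sort(perm[seq_len(n_train)]),
              val = sort(perm[n_train + seq_len(n_val)]),
              test = sort(perm[n_train + n_val + seq_len(n_test)]))
  take <- function(i) genotype_matrix(
    gm$values[i, , drop = FALSE], gm$n_classes,
    sample_ids = gm$sample_ids[i], marker_ids = gm$marker_ids,
    ploidy_mode = gm$ploidy_mode)
  out <- lapply(idx, take)
  attr(out, "indices") <- idx
  out
}

# Seed handling: save/restore the global RNG state so seeded operations do
# not perturb the caller's random stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
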