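#' Simulate a two-parent haploid cross genotype matrix
#'
#' Emulates the genotype structure of offspring from a cross between two
#' inbred strains (e.g. a yeast BY x RM cross): each offspring genome is a
#' mosaic of the two parental genotypes with long identical runs. Each
#' sample row is generated as a two-state Markov chain over classes
#' \{1, 2\}: the first marker is uniform, and each subsequent marker switches
#' parental origin with probability `switch_rate`, so parental run lengths
#' are geometric with parameter `switch_rate`.
#'
#' @param n_samples,n_markers matrix dimensions (both >= 2).
#' @param switch_rate per-adjacent-marker switch probability in (0, 0.5).
#'   The default 0.01 yields the strong local correlation typical of dense
#'   marker maps in a cross.
#' @param seed integer RNG seed.
#' @return a fully observed 2-class [genotype_matrix]
#'   (`ploidy_mode = "cross"`).
#' @export
simulate_cross <- function(n_samples, n_markers, switch_rate = 0.01,
                           seed = 1L) {
  if (n_samples < 2L || n_markers < 2L)
    stop("need n_samples >= 2 and n_markers >= 2")
  if (!is.numeric(switch_rate) || switch_rate <= 0 || switch_rate > 0.5)
    stop("switch_rate must be in (0, 0.5]")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  start <- sample(0:1, n_samples, replace = TRUE)
  # switches[i, j]: does sample i switch parent between marker j and j+1
  switches <- matrix(
    stats::rbinom(n_samples * (n_markers - 1L), 1L, switch_rate),
    nrow = n_samples)
  state <- (start + cbind(0L, t(apply(switches, 1L, cumsum)))) %% 2L
  genotype_matrix(state + 1L, n_classes = 2L, ploidy_mode = "cross")
}

#' Simulate diploid population genotypes with haplotype-block LD
#'
#' Emulates heterogeneous diploid genotype data (an HLA-like region): markers
#' are organised in blocks; within each block a small pool of haplotypes is
#' drawn once and shared by all individuals, which produces genuine linkage
#' disequilibrium within blocks and independence between blocks. Each
#' individual draws two haplotypes per block (with replacement,
#' block-independent) and the genotype class is the allele sum plus one
#' (0 alt alleles -> class 1, 1 -> 2, 2 -> 3), so a strong `ref_allele_bias`
#' makes class 1 (`0|0`) dominate as in real population data.
#'
#' @param n_samples,n_markers matrix dimensions.
#' @param block_length markers per LD block (the last block may be short).
#' @param haplotypes_per_block size of the shared haplotype pool per block
#'   (>= 2).
#' @param ref_allele_bias per-marker reference-allele probability in
#'   (0.5, 1) used when drawing pool haplotypes; the default 0.97 gives the
#'   skewed genotype frequencies seen in population variant data.
#' @param seed integer RNG seed.
#' @return a fully observed 3-class [genotype_matrix]
#'   (`ploidy_mode = "diploid"`). The realized haplotype pools are attached
#'   as attribute `haplotype_pools` (list of 0/1 matrices, one per block)
#'   so expected class frequencies can be computed from what was drawn.
#' @export
simulate_population <- function(n_samples, n_markers, block_length = 16L,
                                haplotypes_per_block = 4L,
                                ref_allele_bias = 0.97, seed = 1L) {
  if (n_samples < 2L || n_markers < 2L)
    stop("need n_samples >= 2 and n_markers >= 2")
  if (block_length < 1L) stop("block_length must be >= 1")
  if (haplotypes_per_block < 2L) stop("haplotypes_per_block must be >= 2")
  if (ref_allele_bias <= 0.5 || ref_allele_bias >= 1)
    stop("ref_allele_bias must be in (0.5, 1)")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  starts <- seq(1L, n_markers, by = block_length)
  vals <- matrix(0L, n_samples, n_markers)
  pools <- vector("list", length(starts))
  p_alt <- 1 - ref_allele_bias
  for (b in seq_along(starts)) {
    len <- min(block_length, n_markers - starts[b] + 1L)
    pool <- matrix(stats::rbinom(haplotypes_per_block * len, 1L, p_alt),
                   nrow = haplotypes_per_block)
    h1 <- sample.int(haplotypes_per_block, n_samples, replace = TRUE)
    h2 <- sample.int(haplotypes_per_block, n_samples, replace = TRUE)
    cols <- starts[b]:(starts[b] + len - 1L)
    vals[, cols] <- pool[h1, , drop = FALSE] + pool[h2, , drop = FALSE] + 1L
    pools[[b]] <- pool
  }
  gm <- genotype_matrix(vals, n_classes = 3L, ploidy_mode = "diploid")
  attr(gm, "haplotype_pools") <- pools
  gm
}

#' Build a corrupted imputation benchmark on disk
#'
#' For each missing level: simulates a genotype matrix, masks that fraction
#' of entries to 0, splits samples 65/15/20 into train/validation/test, and
#' writes all artifacts (truth, corrupted splits, mask indices) as delimited
#' text together with a YAML manifest recording seeds, configuration and
#' file paths. Running twice with the same seed reproduces the files
#' byte for byte.
#'
#' @param dataset_kind `"cross"` or `"population"`.
#' @param missing_levels numeric vector of masking fractions in (0, 1);
#'   the benchmark protocol uses `c(0.05, 0.10, 0.20)`.
#' @param out_dir output directory (created if needed).
#' @param seed integer base seed; per-level seeds are derived from it.
#' @param n_samples,n_markers benchmark scale. The default 1000 x 1024 is
#'   chosen to be trainable on a single CPU while preserving the LD
#'   structure the model exploits.
#' @param ... further arguments passed to the simulator
#'   ([simulate_cross()] or [simulate_population()]).
#' @return path to the manifest YAML, invisibly.
#' @export
make_benchmark <- function(dataset_kind = c("cross", "population"),
                           missing_levels = c(0.05, 0.10, 0.20),
                           out_dir = "benchmark", seed = 1L,
                           n_samples = 1000L, n_markers = 1024L, ...) {
  dataset_kind <- match.arg(dataset_kind)
  if (any(missing_levels <= 0 | missing_levels >= 1))
    stop("missing_levels must lie in (0, 1)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  simulator <- switch(dataset_kind, cross = simulate_cross,
                      population = simulate_population)
  entries <- list()
  for (i in seq_along(missing_levels)) {
    level <- missing_levels[i]
    sim_seed <- as.integer(seed) + 1000L * i
    truth <- simulator(n_samples, n_markers, seed = sim_seed, ...)
    mk <- mask_random(truth, level, seed = sim_seed + 1L)
    splits <- split_samples(mk$masked, seed = sim_seed + 2L)
    idx <- attr(splits, "indices")
    tag <- sprintf("%s_miss%02d", dataset_kind, round(100 * level))
    # manifest stores names relative to its own directory so identical
    # seeds give byte-identical manifests wherever the benchmark lands
    paths <- list(
      truth = paste0(tag, "_truth.tsv"), mask = paste0(tag, "_mask.tsv"),
      train = paste0(tag, "_train.tsv"), val = paste0(tag, "_val.tsv"),
      test = paste0(tag, "_test.tsv"))
    write_geno_table(truth, file.path(out_dir, paths$truth))
    write_mask_index(mk$mask, file.path(out_dir, paths$mask))
    write_geno_table(splits$train, file.path(out_dir, paths$train))
    write_geno_table(splits$val, file.path(out_dir, paths$val))
    write_geno_table(splits$test, file.path(out_dir, paths$test))
    entries[[i]] <- list(
      missing_level = level, sim_seed = sim_seed, mask_seed = sim_seed + 1L,
      split_seed = sim_seed + 2L, files = paths,
      split_indices = lapply(idx, as.integer))
  }
  manifest <- list(
    dataset_kind = dataset_kind, base_seed = as.integer(seed),
    n_samples = as.integer(n_samples), n_markers = as.integer(n_markers),
    simulator_args = lapply(list(...), function(x) x),
    levels = entries)
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(manifest_path)
}
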