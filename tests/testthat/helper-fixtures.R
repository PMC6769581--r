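# shared fixture builders for the test suite

# shorthand genotype_matrix from a plain matrix
gm_of <- function(values, n_classes = max(values),
                  mode = if (n_classes <= 2) "cross" else "diploid") {
  genotype_matrix(values, n_classes = n_classes, ploidy_mode = mode)
}

# random fully observed genotype matrix
random_gm <- function(n, m, n_classes = 2, seed = 1) {
  set.seed(seed)
  gm_of(matrix(sample.int(n_classes, n * m, replace = TRUE), n, m),
        n_classes = n_classes)
}

# small diploid VCF written as text: 3 samples x 2 biallelic markers,
# plus optional extra records for skip-path tests
write_tiny_vcf <- function(path, extra_records = character(0)) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##contig=<ID=1>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "sampA", "sampB", "sampC", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0|0", "0|1", "1|1", sep = "\t"),
    paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "1|0", "./.", "0/0", sep = "\t"),
    extra_records)
  writeLines(lines, path)
  path
}

# brute-force triple-loop evaluation of the same-padded 1-D convolution,
# independent of the package's im2col path
conv_brute <- function(input, filters, biases, activation = identity) {
  k <- dim(filters)[1]; D <- dim(filters)[2]; n <- dim(filters)[3]
  L <- nrow(input); h <- (k - 1) / 2
  out <- matrix(0, L, n)
  for (m in seq_len(n)) for (i in seq_len(L)) {
    s <- biases[m]
    for (u in seq_len(k)) for (d in seq_len(D)) {
      j <- i + u - h - 1
      if (j >= 1 && j <= L) s <- s + filters[u, d, m] * input[j, d]
    }
    out[i, m] <- s
  }
  activation(out)
}

# tiny deterministic cross benchmark pieces used by training tests
tiny_cross_benchmark <- function(n = 120, m = 64, level = 0.1, seed = 9) {
  truth <- simulate_cross(n, m, switch_rate = 0.02, seed = seed)
  mk <- mask_random(truth, level, seed = seed + 1)
  splits <- split_samples(mk$masked, seed = seed + 2)
  idx <- attr(splits, "indices")
  take <- function(r) genotype_matrix(
    truth$values[r, , drop = FALSE], truth$n_classes,
    ploidy_mode = truth$ploidy_mode)
  list(truth = truth, mask = mk$mask, splits = splits, idx = idx,
       train_target = take(idx$train), val_target = take(idx$val),
       test_target = take(idx$test))
}
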