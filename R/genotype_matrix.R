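#' Genotype matrix container
#'
#' A `genotype_matrix` holds a samples-by-markers integer matrix of genotype
#' classes. Classes are coded `1..n_classes`; `0` always means missing. For
#' two-parent cross data (`ploidy_mode = "cross"`) there are two classes
#' (parent 1 / parent 2); for diploid population data
#' (`ploidy_mode = "diploid"`) there are three (hom-ref `0|0` = 1,
#' het `0|1`/`1|0` = 2, hom-alt `1|1` = 3).
#'
#' @param values integer matrix, samples in rows, markers in columns. Entries
#'   must lie in `0..n_classes`.
#' @param n_classes number of valid genotype classes (2 for cross data,
#'   3 for diploid data).
#' @param sample_ids,marker_ids optional character vectors naming rows and
#'   columns; defaults are generated.
#' @param ploidy_mode `"cross"` or `"diploid"`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, n_classes,
                            sample_ids = NULL, marker_ids = NULL,
                            ploidy_mode = c("cross", "diploid")) {
  ploidy_mode <- match.arg(ploidy_mode)
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (length(n_classes) != 1L || n_classes < 1L)
    stop("n_classes must be a single positive integer")
  n_classes <- as.integer(n_classes)
  bad <- which(values < 0L | values > n_classes)
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(values))
    stop(sprintf(
      "invalid genotype code %d at [%d, %d]; entries must be in 0..%d",
      values[bad[1L]], rc[1L], rc[2L], n_classes))
  }
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(ncol(values)))
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length does not match row count")
  if (length(marker_ids) != ncol(values))
    stop("marker_ids length does not match column count")
  dimnames(values) <- NULL
  structure(
    list(values = values, n_classes = n_classes,
         sample_ids = as.character(sample_ids),
         marker_ids = as.character(marker_ids),
         ploidy_mode = ploidy_mode),
    class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' @export
print.genotype_matrix <- function(x, ...) {
  nmiss <- sum(x$values == 0L)
  cat(sprintf(
    "genotype_matrix: %d samples x %d markers, %d classes (%s), %d missing (%.2f%%)\n",
    nrow(x$values), ncol(x$values), x$n_classes, x$ploidy_mode,
    nmiss, 100 * nmiss / length(x$values)))
  invisible(x)
}

#' One-hot encoding of genotype classes
#'
#' Expands a genotype matrix into a samples x markers x classes array in
#' which class `c` maps to a unit vector at channel `c` and a missing entry
#' (code 0) maps to the all-zero vector. This is the input/target
#' representation used by the autoencoder: the all-zero vector for missing
#' entries lets the network treat missingness as corruption to be denoised.
#'
#' @param gm a [genotype_matrix].
#' @return numeric array `[n_samples, n_markers, n_classes]`.
#' @seealso [decode_argmax()] for the inverse on fully observed data.
#' @export
one_hot <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  v <- gm$values
  out <- array(0, dim = c(nrow(v), ncol(v), gm$n_classes))
  for (c in seq_len(gm$n_classes)) out[, , c] <- (v == c) * 1
  out
}

#' Decode class-probability (or one-hot) arrays to genotype classes
#'
#' Takes the per-channel argmax; ties are broken toward the lowest class
#' index, deterministically.
#'
#' @param probs numeric array `[n_samples, n_markers, n_classes]`.
#' @return integer matrix of classes in `1..n_classes`.
#' @export
decode_argmax <- function(probs) {
  stopifnot(is.array(probs), length(dim(probs)) == 3L)
  d <- dim(probs)
  flat <- matrix(probs, nrow = d[1L] * d[2L], ncol = d[3L])
  # max.col ties.method "first" == lowest class index
  cls <- max.col(flat, ties.method = "first")
  matrix(as.integer(cls), nrow = d[1L], ncol = d[2L])
}

#' Imputation result container
#'
#' @param completed [genotype_matrix] with missing entries filled in.
#' @param probabilities optional `[n_samples, n_markers, n_classes]` array of
#'   per-entry class probabilities (methods that do not produce them pass
#'   `NULL`).
#' @param mask_used optional [mask_index] that produced the corruption.
#' @param method name of the imputation method.
#' @param info free-form list of method diagnostics (e.g. convergence flags).
#' @return object of class `imputation_result`.
#' @export
imputation_result <- function(completed, probabilities = NULL,
                              mask_used = NULL, method = "unknown",
                              info = list()) {
  stopifnot(inherits(completed, "genotype_matrix"))
  if (!is.null(probabilities)) {
    d <- dim(probabilities)
    stopifnot(length(d) == 3L,
              all(d == c(dim(completed$values), completed$n_classes)))
  }
  structure(
    list(completed = completed, probabilities = probabilities,
         mask_used = mask_used, method = method, info = info),
    class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("imputation_result (%s): %d x %d matrix, %s\n",
              x$method, nrow(x$completed$values), ncol(x$completed$values),
              if (is.null(x$probabilities)) "no probabilities"
              else "with class probabilities"))
  invisible(x)
}
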