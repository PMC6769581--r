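#' Column mean/mode imputation
#'
#' Fills every missing entry with a per-marker central statistic of the
#' observed entries: the most frequent class (`"mode"`) or the mean rounded
#' to the nearest valid class (`"mean_rounded"`). All ties (including the
#' half-way rounding case) break toward the lower class index. A column
#' with no observed entries is filled with the global statistic and flagged
#' in `info$fallback_columns`.
#'
#' @param gm corrupted [genotype_matrix].
#' @param statistic `"mode"` (default) or `"mean_rounded"`.
#' @return an [imputation_result()] (no probabilities).
#' @export
impute_column_central <- function(gm, statistic = c("mode", "mean_rounded")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  statistic <- match.arg(statistic)
  v <- gm$values
  C <- gm$n_classes
  fill <- integer(ncol(v))
  empty <- logical(ncol(v))
  for (j in seq_len(ncol(v))) {
    obs <- v[v[, j] > 0L, j]
    if (!length(obs)) { empty[j] <- TRUE; next }
    fill[j] <- column_central(obs, C, statistic)
  }
  if (any(empty)) {
    allobs <- v[v > 0L]
    g <- column_central(allobs, C, statistic)
    fill[empty] <- g
    warning(sprintf("%d fully missing column(s) filled with global %s",
                    sum(empty), statistic))
  }
  out <- gm
  miss <- which(v == 0L)
  out$values[miss] <- fill[((miss - 1L) %/% nrow(v)) + 1L]
  imputation_result(out, method = paste0("column_", statistic),
                    info = list(fallback_columns = which(empty)))
}

# central statistic of observed classes; ties toward the lower class
column_central <- function(obs, n_classes, statistic) {
  if (statistic == "mode") {
    counts <- tabulate(obs, nbins = n_classes)
    which.max(counts)  # first max = lowest class on ties
  } else {
    round_to_class(mean(obs), n_classes)
  }
}

# nearest valid class; exact .5 rounds down; clamped to 1..n_classes
round_to_class <- function(x, n_classes) {
  cls <- ceiling(x - 0.5)
  as.integer(pmin(pmax(cls, 1L), n_classes))
}

#' K-nearest-neighbour genotype imputation
#'
#' For each missing entry (i, j), candidate neighbours are the samples
#' observed at marker j; distances to sample i are computed over markers
#' observed in both rows and normalized by the number of shared observed
#' markers (so rows with more missingness are not favoured). The k nearest
#' candidates vote for a class, either uniformly or weighted by inverse
#' distance (zero distances capped at weight 1/1e-8); the imputed class is
#' the (weighted) mode with ties toward the lower class. If no candidate
#' exists the column mode is used.
#'
#' @param gm corrupted [genotype_matrix].
#' @param k number of neighbours (default 10); gracefully truncated when
#'   fewer candidates exist.
#' @param metric `"euclidean"` (default; root mean squared difference over
#'   shared markers), `"pearson"` (1 - correlation) or `"cosine"`
#'   (1 - cosine similarity).
#' @param weighting `"inverse_distance"` (default) or `"uniform"`.
#' @return an [imputation_result()] (no probabilities).
#' @export
impute_knn <- function(gm, k = 10L, metric = c("euclidean", "pearson",
                                               "cosine"),
                       weighting = c("inverse_distance", "uniform")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  metric <- match.arg(metric)
  weighting <- match.arg(weighting)
  v <- gm$values
  n <- nrow(v)
  if (k < 1L) stop("k must be >= 1")
  if (k > n - 1L) k <- n - 1L
  C <- gm$n_classes
  D <- knn_distances(v, metric)
  out <- gm
  fallbacks <- 0L
  col_modes <- NULL
  for (j in seq_len(ncol(v))) {
    miss_rows <- which(v[, j] == 0L)
    if (!length(miss_rows)) next
    cand <- which(v[, j] > 0L)
    for (i in miss_rows) {
      d <- D[i, cand]
      usable <- cand[is.finite(d)]
      d <- d[is.finite(d)]
      if (!length(usable)) {
        if (is.null(col_modes))
          col_modes <- impute_column_central(gm, "mode")$completed$values
        out$values[i, j] <- col_modes[i, j]
        fallbacks <- fallbacks + 1L
        next
      }
      ord <- order(d)
      take <- ord[seq_len(min(k, length(ord)))]
      w <- if (weighting == "uniform") rep(1, length(take))
           else 1 / pmax(d[take], 1e-8)
      votes <- numeric(C)
      cls <- v[usable[take], j]
      for (t in seq_along(take)) votes[cls[t]] <- votes[cls[t]] + w[t]
      out$values[i, j] <- which.max(votes)
    }
  }
  imputation_result(out, method = "knn",
                    info = list(k = k, metric = metric,
                                weighting = weighting,
                                fallbacks = fallbacks))
}

# Pairwise sample distances, missing-aware, normalized by the number of
# markers observed in both rows. Computed with dense matrix products.
knn_distances <- function(v, metric) {
  O <- (v > 0L) * 1
  X <- v * O  # missing as 0
  shared <- tcrossprod(O)
  if (metric == "euclidean") {
    X2 <- X * X
    S <- tcrossprod(X2, O) + tcrossprod(O, X2) - 2 * tcrossprod(X)
    D <- sqrt(pmax(S, 0) / pmax(shared, 1))
  } else if (metric == "cosine") {
    num <- tcrossprod(X)
    X2 <- X * X
    na <- sqrt(tcrossprod(X2, O))
    nb <- sqrt(tcrossprod(O, X2))
    D <- 1 - num / pmax(na * nb, 1e-12)
  } else {  # pearson over shared markers
    sx <- tcrossprod(X, O)
    sy <- tcrossprod(O, X)
    X2 <- X * X
    sxx <- tcrossprod(X2, O)
    syy <- tcrossprod(O, X2)
    sxy <- tcrossprod(X)
    ns <- pmax(shared, 1)
    cov <- sxy - sx * sy / ns
    vx <- sxx - sx * sx / ns
    vy <- syy - sy * sy / ns
    D <- 1 - cov / pmax(sqrt(pmax(vx * vy, 0)), 1e-12)
  }
  D[shared == 0] <- Inf
  diag(D) <- Inf
  D
}

#' Low-rank SVD imputation fitted by EM-style iteration
#'
#' Initializes missing entries with column means of the observed classes,
#' then alternates (E-step) replacing missing entries with the rank-`rank`
#' truncated-SVD reconstruction of the filled matrix and (M-step)
#' recomputing that SVD, until the largest absolute change at missing
#' entries falls below `tol` or `max_iter` is reached. The continuous
#' estimates at missing entries are finally rounded to the nearest valid
#' class (clamped to `[1, n_classes]`, half-way ties toward the lower
#' class).
#'
#' @param gm corrupted [genotype_matrix].
#' @param rank SVD rank (default 10); must be below `min(dim)`.
#' @param max_iter maximum EM iterations (default 100).
#' @param tol convergence tolerance on missing-entry change (default 1e-4).
#' @return an [imputation_result()]; `info` carries `converged`,
#'   `iterations`, the per-iteration observed-entry Frobenius `objective`
#'   (non-increasing), and the continuous `fitted_missing` values before
#'   rounding.
#' @export
impute_svd_em <- function(gm, rank = 10L, max_iter = 100L, tol = 1e-4) {
  stopifnot(inherits(gm, "genotype_matrix"))
  v <- gm$values
  if (rank < 1L || rank >= min(dim(v)))
    stop("rank must satisfy 1 <= rank < min(n_samples, n_markers)")
  miss <- v == 0L
  X <- v * 1.0
  cm <- colMeans_obs(v)
  X[miss] <- cm[((which(miss) - 1L) %/% nrow(v)) + 1L]
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    sv <- svd(X, nu = rank, nv = rank)
    recon <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
    objective[iter] <- sqrt(sum(((X - recon)[!miss])^2))
    delta <- max(abs(recon[miss] - X[miss]))
    X[miss] <- recon[miss]
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged)
    warning(sprintf("SVD-EM did not converge in %d iterations (last change %.3g)",
                    iter, delta))
  out <- gm
  out$values[miss] <- round_to_class(X[miss], gm$n_classes)
  imputation_result(out, method = "svd_em",
                    info = list(rank = rank, converged = converged,
                                iterations = iter, objective = objective,
                                fitted_missing = X[miss]))
}

# per-column means of observed (non-zero) classes; global mean fallback
colMeans_obs <- function(v) {
  obs <- v > 0L
  cnt <- colSums(obs)
  s <- colSums(v * obs)
  cm <- ifelse(cnt > 0, s / pmax(cnt, 1), NA_real_)
  if (anyNA(cm)) cm[is.na(cm)] <- mean(v[obs])
  cm
}
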