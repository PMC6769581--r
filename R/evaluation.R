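#' Masked-entry imputation accuracy
#'
#' Fraction of deliberately masked coordinates at which the imputed class
#' equals the held-out truth. This is the score reported throughout the
#' benchmark: only entries hidden by the corruption protocol enter the
#' denominator.
#'
#' @param result an [imputation_result()] (or a [genotype_matrix] of
#'   completed values).
#' @param truth the uncorrupted [genotype_matrix].
#' @param mask the `mask_index` describing the corruption.
#' @return accuracy in `[0, 1]`.
#' @export
masked_accuracy <- function(result, truth, mask) {
  completed <- if (inherits(result, "imputation_result"))
    result$completed else result
  stopifnot(inherits(completed, "genotype_matrix"),
            inherits(truth, "genotype_matrix"),
            inherits(mask, "mask_index"))
  if (nrow(mask$coords) == 0L) stop("mask is empty: nothing to score")
  n <- nrow(truth$values)
  idx <- mask$coords[, 1L] + 1L + n * mask$coords[, 2L]
  mean(completed$values[idx] == truth$values[idx])
}

# restrict a whole-matrix mask to a subset of (1-based) sample rows,
# remapping sample indices to the subset's row order
subset_mask <- function(mask, rows) {
  keep <- which((mask$coords[, 1L] + 1L) %in% rows)
  structure(
    list(coords = cbind(
           sample = match(mask$coords[keep, 1L] + 1L, rows) - 1L,
           marker = mask$coords[keep, 2L]),
         original_values = mask$original_values[keep],
         fraction = mask$fraction),
    class = "mask_index")
}

# ---- method plug-ins -------------------------------------------------------

#' Imputation method plug-ins for the evaluation harness
#'
#' Each constructor returns a function taking an evaluation context `ctx`
#' (fields `train_corrupt`, `train_target`, `val_corrupt`, `val_target`,
#' `test_corrupt`, `test_target`, `seed`) and returning an
#' [imputation_result()] for the corrupted test matrix. The classical
#' baselines are training-free and use only `test_corrupt`; the SCDA method
#' trains on the corrupted/clean training pair with validation-based early
#' stopping before imputing the test matrix. `test_target` exists so that
#' reference oracles can be expressed in tests; real methods must not read
#' it.
#'
#' @param statistic,k,metric,weighting,rank,max_iter,tol passed through to
#'   the corresponding baseline.
#' @param config an [scda_config()].
#' @param tcfg a [train_config()]; its seed is replaced by the per-run seed.
#' @name method_plugins
NULL

#' @rdname method_plugins
#' @export
column_method <- function(statistic = "mode") {
  force(statistic)
  function(ctx) impute_column_central(ctx$test_corrupt, statistic)
}

#' @rdname method_plugins
#' @export
knn_method <- function(k = 10L, metric = "euclidean",
                       weighting = "inverse_distance") {
  function(ctx) impute_knn(ctx$test_corrupt, k = k, metric = metric,
                           weighting = weighting)
}

#' @rdname method_plugins
#' @export
svd_method <- function(rank = 10L, max_iter = 100L, tol = 1e-4) {
  function(ctx) impute_svd_em(ctx$test_corrupt, rank = rank,
                              max_iter = max_iter, tol = tol)
}

#' @rdname method_plugins
#' @export
scda_method <- function(config = scda_config(), tcfg = train_config()) {
  function(ctx) {
    tcfg$seed <- ctx$seed
    model <- build_scda(config, n_markers = ncol(ctx$train_corrupt$values),
                        n_classes = ctx$train_corrupt$n_classes,
                        seed = ctx$seed)
    model <- scda_train(model, ctx$train_corrupt, ctx$train_target,
                        ctx$val_corrupt, ctx$val_target, tcfg)
    scda_impute(model, ctx$test_corrupt)
  }
}

# ---- repeated-split experiment ---------------------------------------------

#' Repeated-split imputation benchmark
#'
#' Reproduces the benchmark protocol: for every missing level and repeat, a
#' fresh corruption mask is drawn and the samples are split 65/15/20 into
#' train/validation/test; each method imputes the corrupted test matrix and
#' is scored by [masked_accuracy()] on the test-split masked entries only.
#' Per-repeat seeds are `base_seed + repeat - 1`, so any single run can be
#' reproduced in isolation. A `"total"` row per method averages the
#' per-level means (and standard deviations) over the levels.
#'
#' @param data_source the uncorrupted [genotype_matrix], or a function
#'   `function(seed)` returning one (a simulator closure; called once per
#'   repeat so repeats see independent data draws).
#' @param methods named list of method plug-ins (see [method_plugins]).
#' @param missing_levels masking fractions, default `c(0.05, 0.10, 0.20)`.
#' @param n_repeats repeats per (method, level), default 10.
#' @param base_seed integer base seed.
#' @return a data.frame of class `eval_summary` with columns `method`,
#'   `level` (character; includes `"total"`), `n_repeats`, `mean_accuracy`,
#'   `sd_accuracy`; attribute `per_run` is a named list
#'   (`"method|level"`) of per-run accuracies, and attribute `failures`
#'   records failed runs.
#' @export
run_experiment <- function(data_source, methods,
                           missing_levels = c(0.05, 0.10, 0.20),
                           n_repeats = 10L, base_seed = 1L) {
  if (!length(methods) || is.null(names(methods)) ||
      any(names(methods) == ""))
    stop("methods must be a non-empty named list")
  if (any(missing_levels <= 0 | missing_levels >= 1))
    stop("missing_levels must lie in (0, 1)")
  per_run <- list()
  failures <- list()
  for (level in missing_levels) {
    for (rep_i in seq_len(n_repeats)) {
      seed_r <- as.integer(base_seed) + rep_i - 1L
      truth <- if (is.function(data_source)) data_source(seed_r)
               else data_source
      mk <- mask_random(truth, level, seed = seed_r)
      splits <- split_samples(mk$masked, seed = seed_r)
      idx <- attr(splits, "indices")
      take_truth <- function(rows) genotype_matrix(
        truth$values[rows, , drop = FALSE], truth$n_classes,
        sample_ids = truth$sample_ids[rows], marker_ids = truth$marker_ids,
        ploidy_mode = truth$ploidy_mode)
      ctx <- list(
        train_corrupt = splits$train, train_target = take_truth(idx$train),
        val_corrupt = splits$val, val_target = take_truth(idx$val),
        test_corrupt = splits$test, test_target = take_truth(idx$test),
        seed = seed_r)
      test_mask <- subset_mask(mk$mask, idx$test)
      for (mname in names(methods)) {
        key <- paste(mname, format(level), sep = "|")
        res <- tryCatch(methods[[mname]](ctx), error = function(e) e)
        if (inherits(res, "error")) {
          warning(sprintf("method '%s' failed at level %s repeat %d: %s",
                          mname, format(level), rep_i, conditionMessage(res)))
          failures[[length(failures) + 1L]] <-
            list(method = mname, level = level, repeat_ = rep_i,
                 message = conditionMessage(res))
          next
        }
        acc <- masked_accuracy(res, ctx$test_target, test_mask)
        per_run[[key]] <- c(per_run[[key]], acc)
      }
    }
  }
  rows <- list()
  for (mname in names(methods)) {
    lv_means <- c(); lv_sds <- c()
    for (level in missing_levels) {
      key <- paste(mname, format(level), sep = "|")
      acc <- per_run[[key]]
      if (is.null(acc)) next
      m <- mean(acc)
      s <- if (length(acc) > 1L) stats::sd(acc) else 0
      lv_means <- c(lv_means, m); lv_sds <- c(lv_sds, s)
      rows[[length(rows) + 1L]] <- data.frame(
        method = mname, level = format(level), n_repeats = length(acc),
        mean_accuracy = m, sd_accuracy = s, stringsAsFactors = FALSE)
    }
    if (length(lv_means)) {
      rows[[length(rows) + 1L]] <- data.frame(
        method = mname, level = "total", n_repeats = n_repeats,
        mean_accuracy = mean(lv_means), sd_accuracy = mean(lv_sds),
        stringsAsFactors = FALSE)
      per_run[[paste(mname, "total", sep = "|")]] <- lv_means
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "per_run") <- per_run
  attr(out, "failures") <- failures
  class(out) <- c("eval_summary", class(out))
  out
}

# ---- architecture sweep ----------------------------------------------------

#' Grid sweep over SCDA depth, filter size and kernel counts
#'
#' Trains one model per grid point at a reduced epoch budget and records
#' the validation masked-entry accuracy, returning the grid with the best
#' configuration flagged. Seven-layer kernel grids `(a, b, c, c, b)` are
#' mapped to `(a, b, a)` for the five-layer variant.
#'
#' @param train_corrupt,train_target,val_corrupt,val_target corrupted and
#'   clean training/validation [genotype_matrix] pairs.
#' @param depths depth variants to try.
#' @param filter_sizes odd filter sizes to try (the canonical sweep covers
#'   3 to 19).
#' @param kernel_grids list of seven-layer hidden kernel-count vectors.
#' @param tcfg a [train_config()] (use a small `max_epochs` here).
#' @param l1_lambda,dropout_p fixed regularization settings for the sweep.
#' @return data.frame of class `sweep_result` with one row per grid point
#'   (`depth_variant`, `filter_size`, `kernels`, `val_accuracy`, `best`).
#' @export
sweep_architecture <- function(train_corrupt, train_target,
                               val_corrupt, val_target,
                               depths = c("seven_layer", "five_layer"),
                               filter_sizes = seq(3L, 19L, by = 2L),
                               kernel_grids = list(c(32L, 64L, 128L, 128L, 64L)),
                               tcfg = train_config(max_epochs = 5L,
                                                   early_stop_patience = 5L),
                               l1_lambda = 1e-4, dropout_p = 0.25) {
  rows <- list()
  val_missing_mask <- val_corrupt$values == 0L & val_target$values > 0L
  if (!any(val_missing_mask))
    stop("validation split has no masked entries to score")
  for (depth in depths) {
    for (fs in filter_sizes) {
      for (kg in kernel_grids) {
        kc <- if (depth == "five_layer") c(kg[1L], kg[2L], kg[1L]) else kg
        cfg <- scda_config(kernel_counts = kc, filter_size = fs,
                           l1_lambda = l1_lambda, dropout_p = dropout_p,
                           depth_variant = depth)
        acc <- tryCatch({
          model <- build_scda(cfg, ncol(train_corrupt$values),
                              train_corrupt$n_classes, seed = tcfg$seed)
          model <- scda_train(model, train_corrupt, train_target,
                              val_corrupt, val_target, tcfg)
          res <- scda_impute(model, val_corrupt)
          mean(res$completed$values[val_missing_mask] ==
                 val_target$values[val_missing_mask])
        }, error = function(e) {
          warning(sprintf("sweep point (%s, k=%d) failed: %s", depth, fs,
                          conditionMessage(e)))
          NA_real_
        })
        rows[[length(rows) + 1L]] <- data.frame(
          depth_variant = depth, filter_size = fs,
          kernels = paste(kc, collapse = "-"), val_accuracy = acc,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$best <- FALSE
  if (any(is.finite(out$val_accuracy)))
    out$best[which.max(out$val_accuracy)] <- TRUE
  class(out) <- c("sweep_result", class(out))
  out
}

# ---- reporting -------------------------------------------------------------

#' Write an evaluation summary to disk
#'
#' Serializes the per-level and total rows to
#' `<out_dir>/accuracy_summary.csv` with columns `method`, `level`, `mean`,
#' `sd`, `total_mean`, `total_sd` (the totals repeated on each of the
#' method's rows), and optionally draws a violin plot of the per-run
#' accuracies per method.
#'
#' @param summaries an `eval_summary` from [run_experiment()].
#' @param out_dir output directory (created if needed).
#' @param plot if `TRUE` and ggplot2 is available, also writes
#'   `accuracy_violin.pdf`.
#' @return path of the CSV, invisibly.
#' @export
report <- function(summaries, out_dir, plot = FALSE) {
  if (is.null(summaries) || !nrow(summaries))
    stop("summaries is empty: nothing to report")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tot <- summaries[summaries$level == "total", ]
  df <- summaries[summaries$level != "total", ]
  df <- rbind(df, summaries[summaries$level == "total", ])
  ord <- order(match(df$method, unique(summaries$method)),
               df$level == "total", df$level)
  df <- df[ord, ]
  out <- data.frame(
    method = df$method, level = df$level,
    mean = df$mean_accuracy, sd = df$sd_accuracy,
    total_mean = tot$mean_accuracy[match(df$method, tot$method)],
    total_sd = tot$sd_accuracy[match(df$method, tot$method)])
  # full-precision formatting so the CSV re-parses to the in-memory values
  for (col in c("mean", "sd", "total_mean", "total_sd"))
    out[[col]] <- sprintf("%.17g", out[[col]])
  path <- file.path(out_dir, "accuracy_summary.csv")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (plot && requireNamespace("ggplot2", quietly = TRUE)) {
    per_run <- attr(summaries, "per_run")
    keys <- names(per_run)
    keep <- !grepl("\\|total$", keys)
    long <- do.call(rbind, lapply(keys[keep], function(k) {
      parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
      data.frame(method = parts[1L], level = parts[2L],
                 accuracy = per_run[[k]])
    }))
    p <- ggplot2::ggplot(long, ggplot2::aes(
           x = method, y = accuracy, fill = method)) +
      ggplot2::geom_violin(scale = "width") +
      ggplot2::facet_wrap(~level) +
      ggplot2::theme_bw() + ggplot2::guides(fill = "none") +
      ggplot2::labs(x = NULL, y = "masked-entry accuracy")
    ggplot2::ggsave(file.path(out_dir, "accuracy_violin.pdf"), p,
                    width = 7, height = 4)
  }
  invisible(path)
}
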