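oracle_method <- function() function(ctx)
  imputation_result(ctx$test_target, method = "oracle")

failing_method <- function() function(ctx) stop("deliberate failure")

test_that("masked accuracy counts matches over masked coordinates only", {
  truth <- random_gm(10, 10, n_classes = 2, seed = 41)
  mk <- mask_random(truth, 0.1, seed = 42)  # 10 masked entries
  # perfect imputer
  expect_equal(masked_accuracy(truth, truth, mk$mask), 1.0)
  # imputer wrong at every masked coordinate (flip the two classes)
  wrong <- truth
  idx <- mk$mask$coords[, 1] + 1 + 10 * mk$mask$coords[, 2]
  wrong$values[idx] <- 3L - wrong$values[idx]
  expect_equal(masked_accuracy(wrong, truth, mk$mask), 0.0)
  # 7 of 10 correct
  part <- truth
  part$values[idx[1:3]] <- 3L - part$values[idx[1:3]]
  expect_equal(masked_accuracy(part, truth, mk$mask), 0.7)
  empty <- mk$mask
  empty$coords <- empty$coords[0, , drop = FALSE]
  expect_error(masked_accuracy(truth, truth, empty), "empty")
})

test_that("a perfect oracle scores 1.0 with zero spread at every level", {
  truth <- random_gm(40, 30, n_classes = 2, seed = 43)
  summ <- run_experiment(truth, list(oracle = oracle_method()),
                         missing_levels = c(0.05, 0.10, 0.20),
                         n_repeats = 3, base_seed = 7)
  expect_equal(nrow(summ), 4)  # three levels + total
  expect_true(all(summ$mean_accuracy == 1.0))
  expect_true(all(summ$sd_accuracy == 0.0))
  expect_true("total" %in% summ$level)
  per_run <- attr(summ, "per_run")
  lv <- summ[summ$level != "total", ]
  expect_true(all(lv$n_repeats == 3))
  expect_true(all(vapply(per_run[paste0("oracle|", lv$level)],
                         length, numeric(1)) == 3))
})

test_that("the total row averages per-level means and sds", {
  # stub method with deterministic, level-dependent accuracy: imputes the
  # truth at a fixed fraction of masked entries via a wrapped oracle
  set.seed(44)
  truth <- random_gm(40, 30, n_classes = 2, seed = 44)
  noisy <- function() function(ctx) {
    out <- ctx$test_target
    imputation_result(out, method = "noisy")
  }
  summ <- run_experiment(truth, list(a = noisy(), b = oracle_method()),
                         missing_levels = c(0.05, 0.1), n_repeats = 2,
                         base_seed = 1)
  for (m in c("a", "b")) {
    lv <- summ[summ$method == m & summ$level != "total", ]
    tot <- summ[summ$method == m & summ$level == "total", ]
    expect_equal(tot$mean_accuracy, mean(lv$mean_accuracy))
    expect_equal(tot$sd_accuracy, mean(lv$sd_accuracy))
  }
  # single repeat: sd is defined as 0
  s1 <- run_experiment(truth, list(oracle = oracle_method()),
                       missing_levels = 0.1, n_repeats = 1, base_seed = 2)
  expect_true(all(s1$sd_accuracy == 0))
})

test_that("summary mean/sd are consistent with the per-run accuracies", {
  truth <- simulate_cross(60, 40, switch_rate = 0.05, seed = 45)
  summ <- run_experiment(truth, list(mode = column_method("mode"),
                                     knn = knn_method(k = 3)),
                         missing_levels = c(0.1, 0.2), n_repeats = 3,
                         base_seed = 5)
  per_run <- attr(summ, "per_run")
  lv <- summ[summ$level != "total", ]
  for (r in seq_len(nrow(lv))) {
    acc <- per_run[[paste(lv$method[r], lv$level[r], sep = "|")]]
    expect_equal(length(acc), lv$n_repeats[r])
    expect_equal(mean(acc), lv$mean_accuracy[r], tolerance = 1e-12)
    expect_equal(stats::sd(acc), lv$sd_accuracy[r], tolerance = 1e-12)
  }
})

test_that("repeated runs are reproducible for deterministic methods", {
  truth <- simulate_cross(50, 30, switch_rate = 0.05, seed = 46)
  a <- run_experiment(truth, list(mode = column_method()),
                      missing_levels = 0.1, n_repeats = 2, base_seed = 9)
  b <- run_experiment(truth, list(mode = column_method()),
                      missing_levels = 0.1, n_repeats = 2, base_seed = 9)
  expect_identical(attr(a, "per_run"), attr(b, "per_run"))
})

test_that("method failures are recorded and excluded with a warning", {
  truth <- random_gm(30, 20, n_classes = 2, seed = 47)
  expect_warning(
    summ <- run_experiment(truth, list(bad = failing_method(),
                                       oracle = oracle_method()),
                           missing_levels = 0.1, n_repeats = 1,
                           base_seed = 1),
    "deliberate failure")
  expect_false("bad" %in% summ$method)
  expect_equal(length(attr(summ, "failures")), 1L)
})

test_that("the column-mode baseline sits near chance on balanced cross data", {
  truth <- simulate_cross(1000, 1024, switch_rate = 0.01, seed = 48)
  summ <- run_experiment(truth, list(mode = column_method("mode")),
                         missing_levels = 0.1, n_repeats = 1, base_seed = 3)
  acc <- summ$mean_accuracy[summ$level != "total"]
  expect_lt(abs(acc - 0.5), 0.03)
})

test_that("report writes a CSV whose values round-trip exactly", {
  truth <- simulate_cross(60, 40, switch_rate = 0.05, seed = 49)
  summ <- run_experiment(truth,
                         list(mode = column_method(), knn = knn_method(k = 3),
                              svd = svd_method(rank = 3),
                              oracle = oracle_method()),
                         missing_levels = c(0.05, 0.1, 0.2), n_repeats = 2,
                         base_seed = 4)
  dir <- withr::local_tempdir()
  path <- report(summ, dir)
  csv <- utils::read.csv(path)
  expect_equal(nrow(csv), 4 * (3 + 1))  # 4 methods x (3 levels + total)
  expect_equal(sort(unique(csv$level)), sort(c("0.05", "0.1", "0.2", "total")))
  key <- paste(summ$method, summ$level)
  expect_identical(csv$mean[match(key, paste(csv$method, csv$level))],
                   summ$mean_accuracy)
  expect_error(report(summ[0, ], dir), "empty")
})

test_that("the architecture sweep covers the grid and flags the best point", {
  bench <- tiny_cross_benchmark(n = 60, m = 32, seed = 50)
  sw <- sweep_architecture(
    bench$splits$train, bench$train_target,
    bench$splits$val, bench$val_target,
    depths = c("seven_layer", "five_layer"), filter_sizes = c(3L, 5L),
    kernel_grids = list(c(8L, 16L, 32L, 32L, 16L)),
    tcfg = train_config(max_epochs = 3, early_stop_patience = 3, seed = 1))
  expect_equal(nrow(sw), 4)  # 2 depths x 2 filter sizes x 1 grid
  expect_equal(sum(sw$best), 1)
  expect_true(all(is.finite(sw$val_accuracy)))
  # the canonical default (seven_layer, k = 5) is a valid grid member of
  # the full sweep specification
  full_grid <- expand.grid(depth = c("seven_layer", "five_layer"),
                           k = seq(3, 19, 2))
  expect_true(any(full_grid$depth == "seven_layer" & full_grid$k == 5))
})
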