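test_that("zero-one accuracy counts exact matches", {
  expect_equal(zero_one_accuracy(1:5, 1:5), 1.0)
  expect_equal(zero_one_accuracy(1:4, 5:8), 0.0)
  expect_equal(zero_one_accuracy(c(1, 2, 3, 9), c(1, 2, 3, 4)), 0.75)
  expect_error(zero_one_accuracy(1:3, 1:4), "mismatch")
})

test_that("hamming loss follows the truth-size normalization literally", {
  expect_equal(hamming_loss(list(c(1L, 2L)), list(c(1L, 2L))), 0)
  # truth {a,b,c}, prediction {b,d}: |{a,c,d}| / 3 = 1 (can reach/top 1)
  expect_equal(hamming_loss(list(c(2L, 4L)), list(c(1L, 2L, 3L))), 1.0)
  # empty prediction against k truth labels misses all k: loss 1
  expect_equal(hamming_loss(list(integer(0)), list(c(1L, 5L, 9L))), 1.0)
  # literal normalization can exceed 1 for oversized predictions
  expect_gt(hamming_loss(list(1:6), list(1L)), 1.0)
  # conventional universe normalization stays in [0, 1]
  expect_equal(hamming_loss(list(1:6), list(1L), normalize = "universe",
                            universe_size = 10L), 0.5)
  expect_error(hamming_loss(list(1L), list(integer(0))), "empty truth")
  # matrix interface agrees with the set interface
  pm <- rbind(c(1L, 0L, 1L), c(0L, 1L, 0L))
  tm <- rbind(c(1L, 1L, 0L), c(0L, 1L, 0L))
  expect_equal(hamming_loss(pm, tm),
               hamming_loss(list(c(1L, 3L), 2L), list(c(1L, 2L), 2L)))
  expect_equal(hamming_accuracy(pm, tm), 1 - hamming_loss(pm, tm))
})

test_that("fold assignments partition every repeat with near-equal sizes", {
  plan <- cv_plan(n_folds = 10L, n_repeats = 20L, seed = 3L)
  folds <- make_folds(2835L, plan)
  expect_length(folds, 20L)
  for (f in folds[c(1L, 7L, 20L)]) {
    sizes <- tabulate(f, nbins = 10L)
    expect_equal(sum(sizes), 2835L)
    expect_lte(max(sizes) - min(sizes), 1L)
    expect_true(setequal(sort(unique(tabulate(f))), c(283L, 284L)))
  }
  expect_identical(make_folds(2835L, plan), folds)  # seed determinism
  expect_error(make_folds(5L, plan), "n >= n_folds")
})

perfect_trainer <- function(train_ds, seed) {
  function(test_ds) list(
    tuple = data.frame(icd10 = icd10_index(test_ds), tcm = test_ds$tcm,
                       stringsAsFactors = FALSE),
    acupoints = test_ds$acupoints)
}

test_that("the repeated ten-fold protocol executes exactly 200 runs", {
  res <- run_crossval(protocol_ds(), perfect_trainer,
                      cv_plan(10L, 20L, seed = 4L))
  expect_equal(res$n_runs, 200L)
  expect_equal(res$n_failed, 0L)
  expect_length(res$run_accuracy, 200L)
  expect_equal(unname(res$overall), c(100, 0))
  expect_equal(sum(res$per_disease$n), 2835L)
})

test_that("a perfect trainer scores (100, 0) under both losses", {
  ds <- fx_ds_noisy()
  for (loss in c("zero_one", "hamming")) {
    res <- run_crossval(ds, perfect_trainer, cv_plan(5L, 2L, seed = 9L),
                        loss_kind = loss)
    expect_equal(unname(res$overall), c(100, 0))
    expect_true(all(res$per_disease$mean == 100))
  }
})

test_that("a constant-majority trainer tracks the class prior", {
  ds <- protocol_ds()
  majority_trainer <- function(train_ds, seed) {
    lab <- as.integer(names(which.max(table(icd10_index(train_ds)))))
    function(test_ds) list(tuple = data.frame(
      icd10 = rep(lab, n_records(test_ds)),
      tcm = rep(train_ds$tcm[1L], n_records(test_ds)),
      stringsAsFactors = FALSE))
  }
  res <- run_crossval(ds, majority_trainer, cv_plan(10L, 2L, seed = 6L))
  # baseline-rate oracle: accuracy equals the realized majority-class prior
  prior <- max(tabulate(icd10_index(ds))) / n_records(ds)
  expect_lt(abs(res$overall[["mean"]] - 100 * prior), 0.5)
  expect_true(res$overall[["mean"]] / 100 >= min(res$run_accuracy) &&
                res$overall[["mean"]] / 100 <= max(res$run_accuracy))
})

test_that("cross-validation is reproducible and failure-tolerant", {
  ds <- fx_ds_noisy()
  flaky_trainer <- function(train_ds, seed) {
    if (seed %% 5L == 0L) stop("synthetic failure")
    perfect_trainer(train_ds, seed)
  }
  r1 <- run_crossval(ds, perfect_trainer, cv_plan(4L, 2L, seed = 11L))
  r2 <- run_crossval(ds, perfect_trainer, cv_plan(4L, 2L, seed = 11L))
  expect_identical(r1$run_accuracy, r2$run_accuracy)
  suppressWarnings(
    rf <- run_crossval(ds, flaky_trainer, cv_plan(4L, 2L, seed = 11L)))
  expect_equal(rf$n_runs, 8L)
  expect_gte(rf$n_failed, 0L)
  expect_equal(length(rf$run_accuracy) + rf$n_failed, 8L)
})

test_that("count_best_method counts strict wins of the first method", {
  b <- icd10_benchmark()
  expect_equal(count_best_method(
    b[, c("ensemble_mean", "mvknn_mean", "cnn_mean")]), 17L)
  # invariance under permuting the comparison methods
  expect_equal(count_best_method(
    b[, c("ensemble_mean", "cnn_mean", "mvknn_mean")]), 17L)
  # single method: trivially best everywhere
  expect_equal(count_best_method(b[, "ensemble_mean", drop = FALSE]), 21L)
  # random table vs brute-force row scan
  set.seed(12)
  tab <- matrix(runif(15), 5L, 3L)
  expect_equal(count_best_method(tab),
               sum(vapply(1:5, function(i)
                 tab[i, 1L] > tab[i, 2L] && tab[i, 1L] > tab[i, 3L],
                 logical(1L))))
  # ties count as not best
  expect_equal(count_best_method(cbind(c(1, 2), c(1, 1))), 1L)
  expect_error(count_best_method(cbind(c(1, NA), c(1, 1))), "missing")
})

test_that("reports render deterministically in both table styles", {
  res <- structure(list(
    per_disease = data.frame(disease = "Insomnia", icd10 = 14L, n = 47L,
                             mean = 90.25, sd = 2.151),
    overall = c(mean = 90.25, sd = 2.151), loss_kind = "zero_one",
    n_runs = 10L, n_failed = 0L), class = "eval_result")
  t4 <- render_report(res, "table4")
  expect_length(t4, 3L)  # header, one disease, Total
  # half-away-from-zero rounding to one decimal
  expect_match(t4[2L], "90\\.3 ± 2\\.2")
  expect_match(t4[3L], "^\\s*Total|Total")
  expect_match(t4[3L], "Total")
  t5 <- render_report(res, "table5")
  expect_match(t5[2L], "90\\.3")
  expect_false(grepl("±", t5[2L]))
  expect_match(t5[3L], "Total.*90\\.3 ± 2\\.2")
})
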