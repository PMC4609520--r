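# small deterministic binary instance: 6 samples, 2 learners
toy_instance <- function(seed = 1L) {
  set.seed(seed)
  n <- 6L; m <- 2L
  H <- matrix(runif(n * m, -1, 1), n, m)
  y <- sample(c(-1, 1), n, replace = TRUE)
  if (all(y == y[1L])) y[1L] <- -y[1L]
  list(H = H, y = y)
}

test_that("penalty-dominated and loss-dominated limits behave as stated", {
  t1 <- toy_instance(3L)
  # enormous lambda: any positive weight costs more than it can save
  huge <- deepboost_weights(t1$H, t1$y,
                            boost_config(lambda = 1e9,
                                         complexities = c(1, 1)))
  expect_equal(huge$alpha, c(0, 0))
  # single perfect learner, lambda = 0: loss strictly decreasing in alpha,
  # so the weight runs to the budget cap
  y <- c(-1, -1, 1, 1)
  H <- matrix(y, 4L, 1L)
  perfect <- deepboost_weights(H, y, boost_config(lambda = 0))
  expect_equal(perfect$alpha, perfect$cap, tolerance = 1e-6)
})

test_that("the solver matches the refined-grid oracle on a toy instance", {
  t1 <- toy_instance(11L)
  cfg <- boost_config(lambda = 0.1, complexities = c(1, 1))
  fit <- deepboost_weights(t1$H, t1$y, cfg)
  oracle <- boost_grid_oracle(t1$H, t1$y, lambda = 0.1, r = c(1, 1))
  got <- boost_oracle_objective(fit$alpha, t1$H, t1$y, 0.1, c(1, 1))
  expect_lt(got - oracle$value, 1e-4)
})

test_that("the objective trace never increases and respects constraints", {
  set.seed(99)
  for (rep in 1:5) {
    n <- sample(4:10, 1L); m <- sample(2:3, 1L)
    H <- matrix(runif(n * m, -1, 1), n, m)
    y <- sample(c(-1, 1), n, replace = TRUE)
    cfg <- boost_config(lambda = runif(1, 0, 0.5), complexities = runif(m),
                        surrogate = sample(c("exponential", "logistic"), 1L))
    fit <- deepboost_weights(H, y, cfg)
    expect_true(all(diff(fit$objective_trace) <= 1e-12))
    expect_true(all(fit$alpha >= 0))
    expect_lte(sum(fit$alpha), fit$cap + 1e-9)
  }
})

test_that("increasing lambda never increases the total weight", {
  t1 <- toy_instance(21L)
  sums <- vapply(c(0, 0.05, 0.2, 1, 5), function(l)
    sum(deepboost_weights(t1$H, t1$y,
                          boost_config(lambda = l,
                                       complexities = c(1, 0.5)))$alpha),
    numeric(1L))
  expect_true(all(diff(sums) <= 1e-6))
})

test_that("the paper-mode budget is 1/n and the unit budget is 1", {
  t1 <- toy_instance(5L)
  unit <- deepboost_weights(t1$H, t1$y, boost_config(weight_cap = "unit"))
  lit <- deepboost_weights(t1$H, t1$y, boost_config(weight_cap = "paper"))
  expect_equal(unit$cap, 1)
  expect_equal(lit$cap, 1 / nrow(t1$H))
  expect_lte(sum(lit$alpha), 1 / nrow(t1$H) + 1e-9)
})

test_that("predict_binary applies the y' >= 0.5 decision rule", {
  model <- structure(list(alpha = c(1, 1), cap = 2,
                          config = boost_config()), class = "boost_model")
  # unit-scale scores averaging exactly 0.5 decide positive, 0.49 negative
  expect_equal(predict_binary(model, cbind(0.5, 0.5), scale = "unit"), 1L)
  expect_equal(predict_binary(model, cbind(0.49, 0.49), scale = "unit"), 0L)
  # abstain-equivalent scores give y' = 0 hence class 0
  expect_equal(predict_binary(model, cbind(0, 0), scale = "unit",
                              type = "response"), 0)
  expect_equal(predict_binary(model, cbind(0, 0), scale = "unit"), 0L)
  # all weight on one learner reproduces that learner's decisions exactly
  one <- structure(list(alpha = c(0.7, 0), cap = 1,
                        config = boost_config()), class = "boost_model")
  set.seed(4)
  S <- matrix(runif(20, -1, 1), 10L, 2L)
  expect_equal(predict_binary(one, S), as.integer(S[, 1L] >= 0))
})

test_that("adaboost reproduces the closed-form round weight and converges", {
  # weighted error 0.25 -> alpha = log(3)/2 (closed form)
  X <- matrix(c(1, 2, 3, 4), ncol = 1L)
  y <- c(1, 1, -1, -1)
  fixed_weak <- function(X, y, w, seed) function(Xn) c(1, 1, -1, 1)[seq_len(nrow(Xn))]
  fit <- adaboost_fit(fixed_weak, X, y, rounds = 1L)
  expect_equal(fit$alpha[1L], 0.5 * log(3), tolerance = 1e-10)
  # separable data with stumps reaches zero training error
  set.seed(8)
  X2 <- matrix(rnorm(40), 20L, 2L)
  y2 <- ifelse(X2[, 1L] + X2[, 2L] > 0, 1L, -1L)
  fit2 <- adaboost_fit(stump_trainer(), X2, y2, rounds = 30L, seed = 2L)
  expect_equal(mean(predict(fit2, X2) == y2), 1.0)
  # the sample distribution sums to 1 after every round
  expect_equal(rowSums(fit2$distribution_trace),
               rep(1, nrow(fit2$distribution_trace)))
  # a chance-level weak learner stops with a warning
  coin <- function(X, y, w, seed) function(Xn) rep(1, nrow(Xn))
  expect_warning(adaboost_fit(coin, X2, rep(c(1, -1), 10L), rounds = 3L),
                 "no better than chance")
})

test_that("multi-output boosting recovers zero-noise data exactly", {
  pool <- fx_pool0()
  ds_tr <- fx_ds0()
  ds_te <- fx_ds0_test()
  model <- suppressWarnings(fit_multioutput_boost(pool, ds_tr))
  pred <- predict(model, ds_te)
  expect_equal(zero_one_accuracy(pred$tuple$icd10, icd10_index(ds_te)), 1.0)
  expect_equal(hamming_loss(pred$acupoints, ds_te$acupoints), 0)
  # argmax over one-vs-rest heads yields exactly one ICD-10 label per record
  expect_true(all(pred$tuple$icd10 %in% seq_len(ds_te$schema$n_icd10)))
  expect_length(pred$tuple$icd10, n_records(ds_te))
  # schema labels unseen in training are excluded with a warning
  expect_warning(fit_multioutput_boost(pool, ds_tr), "absent from training")
})
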