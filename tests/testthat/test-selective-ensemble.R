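make_pred <- function(icd, tcm) data.frame(icd10 = icd, tcm = tcm,
                                           stringsAsFactors = FALSE)

# two-record dataset with known tuples (1, Z1) and (2, Z2)
two_record_ds <- function() {
  schema <- clinical_schema(3L, 1L, 2L, 2L, c("Z1", "Z2"))
  clinical_dataset(icd10 = rbind(c(1L, 0L, 0L), c(0L, 1L, 0L)),
                   basic = matrix(0, 2L, 1L),
                   keywords = matrix(0L, 2L, 2L),
                   acupoints = matrix(0L, 2L, 2L),
                   tcm = c("Z1", "Z2"), schema = schema)
}

test_that("tuple accuracy evaluates the weighted indicator sum", {
  ds <- two_record_ds()
  mc <- metric_config()
  perfect <- make_pred(c(1L, 2L), c("Z1", "Z2"))
  expect_equal(tuple_accuracy(perfect, ds, mc), 1.0)
  allwrong <- make_pred(c(3L, 3L), c("Z2", "Z1"))
  expect_equal(tuple_accuracy(allwrong, ds, mc), 0.0)
  # record 1 fully correct, record 2 correct on the TCM component only:
  # hand evaluation gives (1 + 1/3) / 2
  mixed <- make_pred(c(1L, 3L), c("Z1", "Z2"))
  expect_equal(tuple_accuracy(mixed, ds, mc), (1 + 1 / 3) / 2)
  # range respects the importance weights
  expect_equal(tuple_accuracy(perfect, ds, metric_config(1, 1, 1)), 3)
  expect_error(metric_config(0, 0, 0))
})

test_that("tuple diversity gates on correctness and squares the distance", {
  ds <- two_record_ds()
  correct <- make_pred(c(1L, 2L), c("Z1", "Z2"))
  # agree with the ensemble everywhere -> 0
  expect_equal(tuple_diversity(correct, correct, ds), 0)
  # wrong everywhere -> the correctness gate closes -> 0
  wrong <- make_pred(c(3L, 3L), c("Z2", "Z1"))
  expect_equal(tuple_diversity(wrong, correct, ds), 0)
  # correct on both records, disagreeing with the ensemble in both tuple
  # slots on record 1 and none on record 2: (2^2 + 0) / 2^2 = 1
  ens <- make_pred(c(3L, 2L), c("Z2", "Z2"))
  expect_equal(tuple_diversity(correct, ens, ds), 1.0)
  # one-slot disagreement contributes 1, not 2
  ens1 <- make_pred(c(3L, 2L), c("Z1", "Z2"))
  expect_equal(tuple_diversity(correct, ens1, ds), 1 / 4)
})

test_that("majority vote is a per-component plurality with index tie-break", {
  pool <- fx_pool0()
  ds <- fx_ds0_test()
  same <- majority_vote(list(pool[[1L]], pool[[1L]], pool[[1L]]), ds)
  expect_identical(same, predict_tuple(pool[[1L]], ds))
  # vote counting oracle on raw codes
  icd_votes <- rbind(c(2L, 5L), c(2L, 7L), c(4L, 7L))
  counted <- apply(icd_votes, 2L, function(v)
    as.integer(names(which.max(table(v)))))
  expect_equal(tcmensemble:::vote_codes(icd_votes, sort(unique(as.vector(icd_votes)))),
               counted)
  # 2-2 tie resolves to the lower code
  tie <- rbind(c(1L), c(3L), c(3L), c(1L))
  expect_equal(tcmensemble:::vote_codes(tie, c(1L, 3L)), 1L)
})

test_that("nds_sort reproduces the published six-learner ranking exactly", {
  sc <- nds_sort(acc_rank = c(1L, 2L, 5L, 4L, 3L, 6L),
                 div_rank = c(2L, 3L, 4L, 6L, 1L, 5L))
  expect_equal(sc$sum_rank, c(3L, 5L, 9L, 10L, 4L, 11L))
  expect_equal(sc$nds_rank, c(1L, 3L, 4L, 5L, 2L, 6L))
})

test_that("nds_sort matches the dominance-chain oracle on random instances", {
  set.seed(2024)
  for (rep in 1:200) {
    m <- sample(1:8, 1L)
    acc <- sample(m); div <- sample(m)
    got <- nds_sort(acc_rank = acc, div_rank = div)
    expect_equal(got$nds_rank, nds_oracle(acc, div))
    # a dominated learner never precedes its dominator
    for (i in seq_len(m)) for (j in seq_len(m))
      if (acc[i] < acc[j] && div[i] < div[j])
        expect_lt(got$nds_rank[i], got$nds_rank[j])
  }
})

test_that("nds_sort ranks raw metrics with deterministic tie handling", {
  sc <- nds_sort(accuracy = c(0.9, 0.8, 0.9), diversity = c(0.1, 0.3, 0.2))
  expect_true(setequal(sc$acc_rank, 1:3) && setequal(sc$div_rank, 1:3))
  expect_equal(sc$acc_rank[1L], 1L)  # tie on accuracy broken by index
  expect_error(nds_sort(accuracy = c(1, NA), diversity = c(1, 2)), "finite")
  expect_equal(nds_sort(accuracy = 1, diversity = 1)$nds_rank, 1L)
})

test_that("duplicating a learner never changes who is dominated", {
  set.seed(7)
  for (rep in 1:20) {
    m <- sample(3:6, 1L)
    acc <- runif(m); div <- runif(m)
    dominated <- function(a, d) vapply(seq_along(a), function(i)
      any(a > a[i] & d > d[i]), logical(1L))
    base <- dominated(acc, div)
    dup <- sample(m, 1L)
    with_dup <- dominated(c(acc, acc[dup]), c(div, div[dup]))
    expect_equal(with_dup[seq_len(m)], base)
  }
})

test_that("select_top keeps max(1, round(m b / 100)) NDS-best learners", {
  sc <- nds_sort(accuracy = seq(1, 0.1, length.out = 10L),
                 diversity = seq(0.1, 1, length.out = 10L))
  expect_length(select_top(sc, selection_config(100)), 10L)
  top2 <- select_top(sc, selection_config(20))
  expect_length(top2, 2L)
  expect_equal(sort(sc$nds_rank[match(top2, sc$learner_id)]), c(1L, 2L))
  sc3 <- nds_sort(accuracy = c(0.1, 0.5, 0.9), diversity = c(0.2, 0.5, 0.7))
  expect_length(select_top(sc3, selection_config(1)), 1L)
  expect_error(selection_config(0))
})

test_that("the fitted selective ensemble recovers zero-noise data exactly", {
  pool <- train_pool(fx_ds0(), pool_config(m_tree = 10L, m_margin = 10L,
                                           seed = 13L))
  ens <- fit_selective_ensemble(pool, fx_ds0(), sel = selection_config(20))
  expect_length(ens$learners, 4L)  # round(20 * 20 / 100)
  # the attached score table ranks are permutations of 1..m
  expect_true(setequal(ens$scores$acc_rank, 1:20))
  expect_true(setequal(ens$scores$div_rank, 1:20))
  expect_true(setequal(ens$scores$nds_rank, 1:20))
  pred <- predict(ens, fx_ds0_test())
  expect_equal(zero_one_accuracy(pred$tuple$icd10, icd10_index(fx_ds0_test())),
               1.0)
  expect_equal(hamming_loss(pred$acupoints, fx_ds0_test()$acupoints), 0)
})

test_that("score tables export in ranking-report layout", {
  sc <- nds_sort(acc_rank = c(1L, 2L, 5L, 4L, 3L, 6L),
                 div_rank = c(2L, 3L, 4L, 6L, 1L, 5L))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(sc, p)
  tab <- read.delim(p)
  expect_equal(names(tab),
               c("learner_id", "acc_rank", "div_rank", "sum_rank", "nds_rank"))
  expect_equal(tab$learner_id, c(1L, 5L, 2L, 3L, 4L, 6L))
})
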