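# Selective ensembling: score every base learner by tuple accuracy and by
# vote-distance diversity, rank the pool by nondominated sort over the two
# rank lists, keep the top-b%, and combine the survivors by majority voting.

#' Importance weights of the tuple accuracy
#'
#' The tuple accuracy of a learner averages, over records, a weighted sum of
#' three indicators: the ICD-10 component matching (`alpha`), the TCM
#' diagnosis matching (`beta`), and the full tuple matching (`gamma`). With
#' the default `alpha = beta = gamma = 1/3` the score is normalized to
#' `[0, 1]` and equals 1 exactly when every tuple is reproduced.
#'
#' @param alpha,beta,gamma Nonnegative weights, not all zero.
#' @return An object of class `metric_config`.
#' @export
metric_config <- function(alpha = 1 / 3, beta = 1 / 3, gamma = 1 / 3) {
  if (alpha < 0 || beta < 0 || gamma < 0 || alpha + beta + gamma <= 0)
    stop_config("alpha, beta, gamma must be nonnegative with positive sum")
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "metric_config")
}

#' Fraction of the pool kept by selection
#'
#' @param b_percent Percentage of the base set retained, in `(0, 100]`;
#'   at least one learner is always selected.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(b_percent = 20) {
  if (b_percent <= 0 || b_percent > 100)
    stop_config("b_percent must lie in (0, 100]")
  structure(list(b_percent = b_percent), class = "selection_config")
}

truth_tuples <- function(ds) {
  data.frame(icd10 = icd10_index(ds), tcm = ds$tcm, stringsAsFactors = FALSE)
}

as_tuples <- function(h, ds) {
  if (is.data.frame(h)) h else predict_tuple(h, ds)
}

#' Tuple accuracy of a learner on a dataset
#'
#' Averages `alpha * [ICD-10 matches] + beta * [TCM matches] +
#' gamma * [both match]` over the records, a correctness measure adapted to
#' tuple-valued predictions where plain zero-one loss is too coarse. Range
#' `[0, alpha + beta + gamma]`.
#'
#' @param h A fitted `base_learner`, or a prediction data frame with columns
#'   `icd10` and `tcm` (one row per record of `ds`).
#' @param ds A nonempty `clinical_dataset`.
#' @param mc A [metric_config()].
#' @return A single number.
#' @export
tuple_accuracy <- function(h, ds, mc = metric_config()) {
  if (n_records(ds) < 1L) stop_config("tuple_accuracy needs a nonempty dataset")
  pred <- as_tuples(h, ds)
  tr <- truth_tuples(ds)
  dy <- pred$icd10 == tr$icd10
  dz <- pred$tcm == tr$tcm
  mean(mc$alpha * dy + mc$beta * dz + mc$gamma * (dy & dz))
}

#' Diversity of a learner against the ensemble vote
#'
#' Sums, over records where the learner's tuple is fully correct, the
#' squared tuple Hamming distance (0, 1, or 2 disagreeing components, hence
#' contributions 0, 1, or 4) between the learner's output and the
#' majority-vote ensemble's output, divided by the squared dataset size. A
#' learner only earns diversity credit where it is right: disagreement with
#' the crowd is valuable exactly when the learner is correct.
#'
#' @param h A fitted `base_learner` or a prediction data frame.
#' @param h_ens The reference ensemble: a list of `base_learner`s (its
#'   majority vote is computed) or a prediction data frame.
#' @param ds A nonempty `clinical_dataset`.
#' @return A nonnegative number; 0 when `h` agrees with the ensemble
#'   everywhere or is never fully correct.
#' @export
tuple_diversity <- function(h, h_ens, ds) {
  if (n_records(ds) < 1L) stop_config("tuple_diversity needs a nonempty dataset")
  pred <- as_tuples(h, ds)
  ens <- if (is.data.frame(h_ens)) h_ens else majority_vote(h_ens, ds)
  tr <- truth_tuples(ds)
  d_h <- (pred$icd10 != ens$icd10) + (pred$tcm != ens$tcm)
  phi <- (pred$icd10 == tr$icd10) & (pred$tcm == tr$tcm)
  sum(d_h^2 * phi) / n_records(ds)^2
}

# Plurality vote over integer codes; ties resolve to the smallest code.
vote_codes <- function(mat, codes) {
  apply(mat, 2L, function(col) {
    tab <- tabulate(match(col, codes), nbins = length(codes))
    codes[which.max(tab)]
  })
}

#' Majority vote of a set of base learners
#'
#' Component-wise plurality over the learners' tuple outputs; ties break to
#' the lowest label index (lowest ICD-10 index, earliest schema TCM code).
#'
#' @param learners Nonempty list of fitted `base_learner`s.
#' @param newdata A `clinical_dataset` or feature matrix.
#' @return A prediction data frame with columns `icd10` and `tcm`.
#' @export
majority_vote <- function(learners, newdata) {
  if (length(learners) < 1L) stop_config("majority vote needs >= 1 learner")
  preds <- lapply(learners, predict_tuple, newdata = newdata)
  icd_mat <- do.call(rbind, lapply(preds, `[[`, "icd10"))
  tcm_codes <- learners[[1L]]$schema$tcm_codes
  tcm_mat <- do.call(rbind, lapply(preds, function(p) match(p$tcm, tcm_codes)))
  data.frame(
    icd10 = vote_codes(icd_mat, sort(unique(as.vector(icd_mat)))),
    tcm = tcm_codes[vote_codes(tcm_mat, sort(unique(as.vector(tcm_mat))))],
    stringsAsFactors = FALSE)
}

#' Nondominated sort of learners on (accuracy rank, diversity rank)
#'
#' Accuracy and diversity are each ranked descending (rank 1 = best; raw
#' ties break by learner index, so both rank lists are permutations of
#' `1..m`). Learners are then ordered so that any learner Pareto-dominating
#' another (no worse on both ranks, strictly better on at least one)
#' precedes it: nondominated fronts are peeled off in order, and within the
#' incomparable remainder the sum of the two ranks decides, with remaining
#' ties broken by learner index.
#'
#' @param accuracy,diversity Numeric metric vectors of equal length `m`
#'   (ignored when both rank vectors are supplied).
#' @param acc_rank,div_rank Optional precomputed rank permutations.
#' @return A `data.frame` of class `learner_scores`, one row per learner in
#'   input order, with columns `learner_id`, `accuracy`, `diversity`,
#'   `acc_rank`, `div_rank`, `sum_rank`, `front`, `nds_rank`.
#' @export
#' @examples
#' # six learners with known rank lists; final order 1, 5, 2, 3, 4, 6
#' nds_sort(acc_rank = c(1, 2, 5, 4, 3, 6), div_rank = c(2, 3, 4, 6, 1, 5))
nds_sort <- function(accuracy = NULL, diversity = NULL,
                     acc_rank = NULL, div_rank = NULL) {
  rank_desc <- function(x) {
    if (any(!is.finite(x))) stop_config("metric values must be finite")
    r <- integer(length(x))
    r[order(-x, seq_along(x))] <- seq_along(x)
    r
  }
  if (is.null(acc_rank)) acc_rank <- rank_desc(accuracy)
  if (is.null(div_rank)) div_rank <- rank_desc(diversity)
  m <- length(acc_rank)
  stopifnot(m >= 1L, length(div_rank) == m)
  if (!setequal(acc_rank, seq_len(m)) || !setequal(div_rank, seq_len(m)))
    stop_config("rank vectors must be permutations of 1..m")
  # peel nondominated fronts on the two rank lists (smaller rank = better);
  # ranks are permutations, so dominance is strict on both coordinates
  front <- integer(m)
  remaining <- seq_len(m)
  f <- 0L
  while (length(remaining)) {
    f <- f + 1L
    nd <- remaining[vapply(remaining, function(i) !any(
      acc_rank[remaining] < acc_rank[i] & div_rank[remaining] < div_rank[i]),
      logical(1L))]
    front[nd] <- f
    remaining <- setdiff(remaining, nd)
  }
  sum_rank <- acc_rank + div_rank
  ord <- order(front, sum_rank, seq_len(m))
  nds_rank <- integer(m)
  nds_rank[ord] <- seq_len(m)
  out <- data.frame(learner_id = seq_len(m),
                    accuracy = accuracy %||% rep(NA_real_, m),
                    diversity = diversity %||% rep(NA_real_, m),
                    acc_rank = acc_rank, div_rank = div_rank,
                    sum_rank = sum_rank, front = front, nds_rank = nds_rank)
  class(out) <- c("learner_scores", "data.frame")
  out
}

#' Select the top-b% learners from an NDS-sorted score table
#'
#' Keeps the `max(1, round(m * b / 100))` learners with the smallest NDS
#' ranks.
#'
#' @param scores A `learner_scores` table from [nds_sort()].
#' @param sel A [selection_config()] (or a bare percentage).
#' @return Integer vector of selected `learner_id`s, in NDS order.
#' @export
select_top <- function(scores, sel = selection_config()) {
  if (is.numeric(sel)) sel <- selection_config(sel)
  m <- nrow(scores)
  k <- max(1L, as.integer(round(m * sel$b_percent / 100)))
  scores$learner_id[order(scores$nds_rank)][seq_len(k)]
}

#' Fit a selective majority-vote ensemble
#'
#' Scores every pool learner on `ds_eval` by tuple accuracy and by
#' diversity against the full-pool majority vote (computed once, before any
#' selection), ranks the pool by nondominated sort, keeps the top-b%, and
#' returns a majority-vote ensemble over the selection with the full score
#' table attached.
#'
#' @param pool Nonempty list of fitted `base_learner`s.
#' @param ds_eval Evaluation `clinical_dataset` for the scoring.
#' @param mc A [metric_config()].
#' @param sel A [selection_config()].
#' @return An object of class `selective_ensemble`.
#' @export
fit_selective_ensemble <- function(pool, ds_eval, mc = metric_config(),
                                   sel = selection_config()) {
  if (length(pool) < 1L) stop_config("pool must be nonempty")
  preds <- lapply(pool, predict_tuple, newdata = ds_eval)
  ens <- majority_vote(pool, ds_eval)
  acc <- vapply(preds, tuple_accuracy, numeric(1L), ds = ds_eval, mc = mc)
  div <- vapply(preds, tuple_diversity, numeric(1L), h_ens = ens, ds = ds_eval)
  scores <- nds_sort(accuracy = acc, diversity = div)
  ids <- select_top(scores, sel)
  structure(list(learners = pool[ids], learner_ids = ids, scores = scores,
                 metric = mc, selection = sel,
                 schema = pool[[1L]]$schema),
            class = "selective_ensemble")
}

#' @export
print.selective_ensemble <- function(x, ...) {
  cat(sprintf("<selective_ensemble: %d of %d learners kept (b = %g%%)>\n",
              length(x$learners), nrow(x$scores), x$selection$b_percent))
  invisible(x)
}

#' Predict from a selective ensemble
#'
#' The label tuple is the majority vote of the selected learners; the
#' acupoint recommendation sets each bit by majority over the learners'
#' thresholded margin scores (a learner votes for an acupoint when its
#' score implies probability at least 1/2; half-half splits recommend).
#'
#' @param object A `selective_ensemble`.
#' @param newdata A `clinical_dataset` or feature matrix.
#' @param ... Unused.
#' @return A list with `tuple` (data frame `icd10`, `tcm`) and `acupoints`
#'   (integer 0/1 matrix).
#' @export
predict.selective_ensemble <- function(object, newdata, ...) {
  tuple <- majority_vote(object$learners, newdata)
  n_acu <- object$schema$n_acupoints
  votes <- 0
  for (h in object$learners) {
    sc <- vapply(seq_len(n_acu), function(t)
      score_binary(h, newdata, "acupoint", t) >= 0,
      logical(length(tuple$icd10)))
    votes <- votes + matrix(as.numeric(sc), ncol = n_acu)
  }
  acup <- matrix(as.integer(votes / length(object$learners) >= 0.5),
                 ncol = n_acu)
  list(tuple = tuple, acupoints = acup)
}

#' Export a score table in ranking-report layout
#'
#' One row per learner with its accuracy rank, diversity rank, sum rank and
#' NDS rank, written as delimited text.
#'
#' @param scores A `learner_scores` table.
#' @param path Output file (tab-separated).
#' @export
write_score_table <- function(scores, path) {
  out <- scores[order(scores$nds_rank),
                c("learner_id", "acc_rank", "div_rank", "sum_rank", "nds_rank")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
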